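#' Inject a targeted artifact into a synthetic record
#'
#' Modifies a copy of `record` so that the 2048-sample segment whose CO
#' reading lies nearest to sample `at` (among readings with a full window)
#' violates exactly one quality-control rule:
#'
#' * `spike_ppg` / `spike_art` — a single-sample jump exceeding the slew
#'   threshold (20 a.u. / 30 mmHg) while staying inside the amplitude band;
#' * `flatline_ppg` — the PPG window is collapsed to a near-constant level
#'   (peak-to-peak < 20 a.u.), with gentle ramps outside the window so no
#'   slew violation is created;
#' * `low_pulse_pressure_art` — the ART window is compressed about its mean
#'   to a peak-to-peak of 24 mmHg (< 30);
#' * `out_of_range_art` / `out_of_range_ppg` — a slow smooth bump pushes
#'   samples beyond the admissible band (200 mmHg / 100 a.u.) without
#'   violating the slew limit;
#' * `out_of_range_co` — the targeted CO reading is set above 10 L/min;
#' * `missing_values` — a short run of samples is replaced by `NA`
#'   (completeness failure; `NA`s may additionally mask other checks, which
#'   is why completeness is screened first in practice).
#'
#' @param record A `waveform_record`.
#' @param kind One of `"spike_ppg"`, `"spike_art"`, `"flatline_ppg"`,
#'   `"low_pulse_pressure_art"`, `"out_of_range_art"`, `"out_of_range_ppg"`,
#'   `"out_of_range_co"`, `"missing_values"`.
#' @param at 1-based sample index targeted by the artifact.
#' @param seed Unused randomness hook kept for interface stability; the
#'   injections are deterministic.
#' @return A modified copy of `record`, with attributes `target_center` (the
#'   CO anchor sample of the affected segment), `target_co_index` (which CO
#'   reading), and `target_kind`.
#' @export
inject_artifact <- function(record, kind, at, seed = 1L) {
  kinds <- c("spike_ppg", "spike_art", "flatline_ppg",
             "low_pulse_pressure_art", "out_of_range_art", "out_of_range_ppg",
             "out_of_range_co", "missing_values")
  if (!is.character(kind) || length(kind) != 1L || !(kind %in% kinds)) {
    abort_validation(
      sprintf("unknown artifact kind; must be one of: %s",
              paste(kinds, collapse = ", ")),
      field = "kind"
    )
  }
  n <- length(record$ppg)
  if (!is.numeric(at) || length(at) != 1L || at < 1 || at > n) {
    abort_validation("'at' must be a sample index within the record",
                     field = "at")
  }
  at <- as.integer(at)

  centers <- record$co_sample_indices
  # an anchor c spans samples (c - 1024) .. (c + 1023) in 1-based indexing
  lo_ok <- centers - SEG_HALF >= 1L
  hi_ok <- centers + SEG_HALF - 1L <= n
  eligible <- centers[lo_ok & hi_ok]
  if (!length(eligible)) {
    abort_validation("record has no CO reading with a full 2048-sample window")
  }
  k <- which.min(abs(eligible - at))
  c0 <- eligible[k]
  win <- (c0 - SEG_HALF):(c0 + SEG_HALF - 1L)

  out <- record
  if (kind == "spike_ppg") {
    i <- min(max(at, win[2]), win[length(win) - 1L])
    out$ppg[i] <- out$ppg[i] + if (out$ppg[i] < 55) 25 else -25
  } else if (kind == "spike_art") {
    i <- min(max(at, win[2]), win[length(win) - 1L])
    out$art[i] <- out$art[i] + if (out$art[i] < 150) 40 else -40
  } else if (kind == "flatline_ppg") {
    level <- mean(out$ppg[win])
    flat <- level + 2 * sin(2 * pi * seq_along(win) / length(win))
    out$ppg <- blend_in(out$ppg, win, flat, ramp = 200L)
  } else if (kind == "low_pulse_pressure_art") {
    seg <- out$art[win]
    m <- mean(seg)
    pp <- max(seg) - min(seg)
    s <- if (pp > 0) 24 / pp else 1
    out$art <- blend_in(out$art, win, m + (seg - m) * s, ramp = 200L)
  } else if (kind == "out_of_range_art") {
    # anchored to the window minimum so the bump peak at c0 is certain to
    # exceed the 200 mmHg band whatever the local beat phase
    amp <- 215 - min(out$art[win])
    out$art <- out$art + smooth_bump(n, center = c0, sigma = 300, amp = amp)
  } else if (kind == "out_of_range_ppg") {
    amp <- 110 - min(out$ppg[win])
    out$ppg <- out$ppg + smooth_bump(n, center = c0, sigma = 300, amp = amp)
  } else if (kind == "out_of_range_co") {
    out$co_values[match(c0, centers)] <- 11.5
  } else if (kind == "missing_values") {
    i <- min(max(at, win[1]), win[length(win)] - 4L)
    out$ppg[i:(i + 4L)] <- NA_real_
  }
  attr(out, "target_center") <- c0
  attr(out, "target_co_index") <- match(c0, centers)
  attr(out, "target_kind") <- kind
  out
}

# Replace x[win] by `replacement`, linearly cross-fading from the original
# signal over `ramp` samples on either side OUTSIDE the window, so that the
# window itself is exactly the replacement and no steep transition is
# introduced anywhere.
blend_in <- function(x, win, replacement, ramp = 200L) {
  n <- length(x)
  out <- x
  out[win] <- replacement
  left_edge_val <- replacement[1]
  right_edge_val <- replacement[length(replacement)]
  li <- seq.int(max(1L, win[1] - ramp), win[1] - 1L)
  if (length(li) && win[1] > 1L) {
    w <- seq(0, 1, length.out = length(li) + 1L)[-1]
    out[li] <- (1 - w) * x[li] + w * left_edge_val
  }
  ri <- seq.int(win[length(win)] + 1L, min(n, win[length(win)] + ramp))
  if (length(ri) && win[length(win)] < n) {
    w <- seq(1, 0, length.out = length(ri) + 1L)[-1]
    out[ri] <- (1 - w) * x[ri] + w * right_edge_val
  }
  out
}

# A smooth Gaussian bump of height `amp` centred at `center`, slow enough
# (sigma in samples) that its slope never approaches the slew thresholds.
smooth_bump <- function(n, center, sigma, amp) {
  i <- seq_len(n)
  amp * exp(-0.5 * ((i - center) / sigma)^2)
}
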