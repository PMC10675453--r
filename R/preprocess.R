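#' Band-pass filter configuration
#'
#' A second-order Butterworth band-pass with corner frequencies 0.5-10 Hz,
#' bracketing the respiratory (~0.25 Hz is attenuated, its harmonics within
#' the heart band retained) and cardiac (~1 Hz plus harmonics) content while
#' rejecting baseline wander and high-frequency noise. Applied forward and
#' backward (zero phase) by default so PPG and ART morphology stay aligned
#' in time; a causal single-pass mode is available via `zero_phase = FALSE`.
#'
#' @param order Filter order of the Butterworth prototype (default 2).
#' @param low_cut,high_cut Pass-band corner frequencies in Hz (0.5, 10).
#' @param family Only `"butterworth"` is supported.
#' @param zero_phase Apply forward-backward (`TRUE`, default) or causal.
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(order = 2, low_cut = 0.5, high_cut = 10,
                          family = "butterworth", zero_phase = TRUE) {
  check_number(order, "order", lower = 1, upper = 8)
  check_number(low_cut, "low_cut", lower = 1e-9)
  check_number(high_cut, "high_cut", lower = 1e-9)
  if (low_cut >= high_cut) {
    abort_validation("field 'low_cut' must be below 'high_cut'",
                     field = "low_cut")
  }
  if (!identical(family, "butterworth")) {
    abort_validation("field 'family' must be \"butterworth\"",
                     field = "family")
  }
  structure(list(order = as.integer(order), low_cut = low_cut,
                 high_cut = high_cut, family = family,
                 zero_phase = isTRUE(zero_phase)),
            class = "filter_config")
}

#' Butterworth band-pass filter a waveform
#'
#' @param x Numeric sample sequence (finite; `NA`s must have been screened
#'   by the completeness rule first).
#' @param sampling_rate Sampling frequency in Hz.
#' @param config A [filter_config()].
#' @return Filtered sequence, same length as `x`.
#' @export
bandpass_filter <- function(x, sampling_rate, config = filter_config()) {
  if (!inherits(config, "filter_config")) {
    abort_validation("'config' must be a filter_config object",
                     field = "config")
  }
  if (anyNA(x) || !all(is.finite(x))) {
    stop("input contains non-finite samples; run the missing-value screen ",
         "(completeness rule) before filtering")
  }
  nyq <- sampling_rate / 2
  if (config$high_cut >= nyq) {
    abort_validation("field 'high_cut' must be below the Nyquist frequency",
                     field = "high_cut")
  }
  if (length(x) <= 3 * config$order) {
    abort_validation("signal too short for the requested filter order")
  }
  bf <- signal::butter(config$order,
                       c(config$low_cut, config$high_cut) / nyq,
                       type = "pass")
  if (config$zero_phase) {
    as.numeric(signal::filtfilt(bf, x))
  } else {
    as.numeric(signal::filter(bf, x))
  }
}

#' Extract the middle window of a record
#'
#' Restricts a record to `window_s` seconds centred on its midpoint
#' (`[(start+end)/2 - window_s/2, ... + window_s)`), re-basing CO readings
#' and their waveform anchors. Records containing missing samples inside the
#' window are flagged with attribute `has_missing` so the pipeline can drop
#' the case; records shorter than `window_s` raise a classed warning and
#' return `NULL` (case skipped).
#'
#' @param record A `waveform_record`.
#' @param window_s Window length in seconds (default 60).
#' @return The sub-record, or `NULL` with a `counet_short_record` warning.
#' @export
extract_middle_window <- function(record, window_s = 60) {
  fs <- record$sampling_rate
  n <- length(record$ppg)
  n_win <- round(window_s * fs)
  if (n < n_win) {
    warning(structure(
      class = c("counet_short_record", "warning", "condition"),
      list(message = sprintf("case %s shorter (%.3f s) than window (%g s); skipped",
                             record$case_id, n / fs, window_s),
           call = sys.call())
    ))
    log_event("window", "warn", "record shorter than window; skipped",
              case_id = record$case_id)
    return(NULL)
  }
  start <- floor((n - n_win) / 2)          # samples to drop from the front
  idx <- (start + 1L):(start + n_win)
  keep <- record$co_sample_indices > start &
    record$co_sample_indices <= start + n_win
  out <- record
  out$ppg <- record$ppg[idx]
  out$art <- record$art[idx]
  out$co_values <- record$co_values[keep]
  out$co_sample_indices <- as.integer(record$co_sample_indices[keep] - start)
  if (!is.null(record$true_co)) out$true_co <- record$true_co[keep]
  attr(out, "has_missing") <- anyNA(out$ppg) || anyNA(out$art)
  out
}

#' Cut a record into 2048-sample candidate segments
#'
#' One candidate per CO reading, spanning the 1024 samples before the
#' reading's anchor and the 1024 from it on. Candidates that would extend
#' past either end of the record are dropped and counted (`boundary_dropped`
#' attribute on the returned list). The whole record is band-pass filtered
#' once with `filter_cfg`; each segment keeps both its raw window (for
#' quality control, whose absolute thresholds are only meaningful before the
#' 0.5 Hz high-pass removes the DC level) and its filtered window (for the
#' model, after [normalize_segment()]).
#'
#' If the record contains missing samples, filtering is deferred: filtered
#' windows are set to `NA` and only the raw windows are populated, so the
#' completeness screen can reject the affected segments.
#'
#' @param record A `waveform_record`.
#' @param filter_cfg A [filter_config()].
#' @return List of `co_segment` objects with attribute `boundary_dropped`.
#' @export
segment_record <- function(record, filter_cfg = filter_config()) {
  n <- length(record$ppg)
  stopifnot(length(record$art) == n)
  has_na <- anyNA(record$ppg) || anyNA(record$art)
  if (!has_na) {
    ppg_f <- bandpass_filter(record$ppg, record$sampling_rate, filter_cfg)
    art_f <- bandpass_filter(record$art, record$sampling_rate, filter_cfg)
  }
  segments <- list()
  dropped <- 0L
  for (k in seq_along(record$co_sample_indices)) {
    # the 1024 samples before the anchor and the 1024 from the anchor on
    c0 <- record$co_sample_indices[k]
    lo <- c0 - SEG_HALF
    hi <- c0 + SEG_HALF - 1L
    if (lo < 1L || hi > n) {
      dropped <- dropped + 1L
      log_event("segment", "info", "boundary candidate dropped",
                case_id = record$case_id, center_index = c0)
      next
    }
    idx <- lo:hi
    seg <- structure(
      list(case_id = record$case_id,
           ppg_raw = record$ppg[idx], art_raw = record$art[idx],
           ppg_in = if (has_na) rep(NA_real_, SEG_LEN) else ppg_f[idx],
           art_in = if (has_na) rep(NA_real_, SEG_LEN) else art_f[idx],
           co_label = record$co_values[k],
           co_label_scaled = scale_co_label(record$co_values[k]),
           true_co = if (is.null(record$true_co)) NA_real_
                     else record$true_co[k],
           center_index = c0),
      class = "co_segment"
    )
    segments[[length(segments) + 1L]] <- seg
  }
  attr(segments, "boundary_dropped") <- dropped
  attr(segments, "n_candidates") <- length(record$co_sample_indices)
  segments
}

#' Min-max normalize a segment's model inputs
#'
#' Linearly rescales each filtered channel to `[0, 1]` per segment per
#' channel. The CO label is mapped through the fixed physiologic bounds
#' 2-10 L/min (see [scale_co_label()]), so the inverse map does not depend
#' on the dataset.
#'
#' @param segment A `co_segment`.
#' @return The segment with `ppg_in` and `art_in` rescaled.
#' @export
normalize_segment <- function(segment) {
  for (ch in c("ppg_in", "art_in")) {
    v <- segment[[ch]]
    r <- range(v)
    if (!all(is.finite(r)) || r[2] - r[1] <= 0) {
      stop(sprintf("channel '%s' has zero peak-to-peak or missing values; ",
                   ch),
           "such segments should have been screened out")
    }
    segment[[ch]] <- (v - r[1]) / (r[2] - r[1])
  }
  segment$co_label_scaled <- scale_co_label(segment$co_label)
  segment
}

#' Scale a CO label to the unit interval
#'
#' Affine map from the physiologic range 2-10 L/min to `[0, 1]`.
#'
#' @param co CO in L/min.
#' @return Scaled label.
#' @export
scale_co_label <- function(co) (co - CO_MIN) / (CO_MAX - CO_MIN)

#' Invert the CO label scaling
#'
#' @param scaled Scaled label (unitless).
#' @return CO in L/min.
#' @export
unscale_co_label <- function(scaled) scaled * (CO_MAX - CO_MIN) + CO_MIN
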