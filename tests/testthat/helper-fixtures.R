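# Shared fixtures and independent brute-force oracles.

# A clean default case; heavier fixtures are built once per file where used.
make_case <- function(seed = 1, ...) {
  generate_case(sim_config(seed = seed, ...))
}

# Generate, window, segment, screen and normalize a small dataset.
make_clean_segments <- function(n_cases = 2, seed = 1) {
  recs <- generate_dataset(sim_config(), n_cases = n_cases, seed = seed)
  segs <- list()
  for (r in recs) segs <- c(segs, segment_record(r))
  scr <- screen_dataset(segs)
  lapply(scr$kept, normalize_segment)
}

tiny_model_config <- function(seed = 2, channels = c("ppg", "art")) {
  model_config(input_length = 128, channels = channels, base_filters = 8,
               bottleneck_lstm_units = 16, head_lstm_units = 16, seed = seed)
}

# ---- naive loop oracle for the agreement statistics -----------------------

naive_agreement <- function(y_ref, y_pred) {
  n <- length(y_ref)
  s_d <- 0; s_d2 <- 0; s_ad <- 0; s_ref <- 0
  for (i in seq_len(n)) {
    d <- y_pred[i] - y_ref[i]
    s_d <- s_d + d
    s_d2 <- s_d2 + d^2
    s_ad <- s_ad + abs(d)
    s_ref <- s_ref + y_ref[i]
  }
  bias <- s_d / n
  ssq <- 0
  for (i in seq_len(n)) {
    d <- y_pred[i] - y_ref[i]
    ssq <- ssq + (d - bias)^2
  }
  std <- sqrt(ssq / n)
  mr <- s_ref / n
  mx <- mean(y_ref); my <- mean(y_pred)
  sxy <- 0; sxx <- 0; syy <- 0
  for (i in seq_len(n)) {
    sxy <- sxy + (y_ref[i] - mx) * (y_pred[i] - my)
    sxx <- sxx + (y_ref[i] - mx)^2
    syy <- syy + (y_pred[i] - my)^2
  }
  list(bias = bias, std = std, loa_half_width = 1.96 * std,
       loa_lower = bias - 1.96 * std, loa_upper = bias + 1.96 * std,
       mse = s_d2 / n, mae = s_ad / n, rmse = sqrt(s_d2 / n),
       mean_ref_co = mr,
       rmsne = 100 * sqrt(s_d2 / n) / mr,
       pe = 100 * 1.96 * std / mr,
       pearson_r = sxy / sqrt(sxx * syy))
}

# ---- naive loop oracle for the QC rules -----------------------------------

naive_qc <- function(segment, cfg = qc_config()) {
  ppg <- segment$ppg_raw
  art <- segment$art_raw
  complete <- TRUE
  for (v in c(ppg, art)) if (is.na(v)) complete <- FALSE
  ppg <- ppg[!is.na(ppg)]
  art <- art[!is.na(art)]
  art_amp <- TRUE
  for (v in art) if (v < cfg$art_min || v > cfg$art_max) art_amp <- FALSE
  ppg_amp <- TRUE
  for (v in ppg) if (v < cfg$ppg_min || v > cfg$ppg_max) ppg_amp <- FALSE
  ppg_slew <- TRUE
  for (i in seq_len(length(ppg) - 1)) {
    if (abs(ppg[i + 1] - ppg[i]) > cfg$ppg_slew_max) ppg_slew <- FALSE
  }
  art_slew <- TRUE
  for (i in seq_len(length(art) - 1)) {
    if (abs(art[i + 1] - art[i]) > cfg$art_slew_max) art_slew <- FALSE
  }
  c(co_range = segment$co_label >= cfg$co_min &&
      segment$co_label <= cfg$co_max,
    art_amplitude = art_amp,
    ppg_amplitude = ppg_amp,
    art_peak_to_peak = (max(art) - min(art)) >= cfg$art_pp_min,
    ppg_peak_to_peak = (max(ppg) - min(ppg)) >= cfg$ppg_pp_min,
    ppg_slew = ppg_slew,
    art_slew = art_slew,
    completeness = complete)
}

# A random raw segment whose statistics straddle every QC threshold so each
# rule fires on a sizeable fraction of draws.
random_raw_segment <- function() {
  mid_ppg <- runif(1, 20, 90)
  amp_ppg <- runif(1, 5, 30)
  mid_art <- runif(1, 40, 180)
  amp_art <- runif(1, 8, 40)
  ppg <- mid_ppg + amp_ppg * sin(seq(0, 20 * pi, length.out = 2048)) +
    rnorm(2048, sd = runif(1, 0.1, 12))
  art <- mid_art + amp_art * sin(seq(0, 20 * pi, length.out = 2048)) +
    rnorm(2048, sd = runif(1, 0.1, 18))
  if (runif(1) < 0.1) ppg[sample(2048, 3)] <- NA
  structure(list(case_id = "rand", ppg_raw = ppg, art_raw = art,
                 ppg_in = ppg, art_in = art,
                 co_label = runif(1, 0, 12),
                 co_label_scaled = NA_real_, center_index = 1024L),
            class = "co_segment")
}
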