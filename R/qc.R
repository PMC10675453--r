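#' Quality-control thresholds
#'
#' The seven screening rules applied to every raw candidate segment (plus a
#' completeness check for missing samples):
#'
#' 1. `co_range` — the CO label lies in \[`co_min`, `co_max`\] L/min;
#' 2. `art_amplitude` — every raw ART sample lies in \[`art_min`, `art_max`\]
#'    mmHg (per-sample admissibility band);
#' 3. `ppg_amplitude` — every raw PPG sample lies in \[`ppg_min`, `ppg_max`\];
#' 4. `art_peak_to_peak` — the ART pulse pressure (window max minus min) is
#'    at least `art_pp_min` mmHg;
#' 5. `ppg_peak_to_peak` — the PPG excursion is at least `ppg_pp_min` a.u.
#'    (near-flat PPG traces carry no usable pulse information);
#' 6. `ppg_slew` — no adjacent-sample difference of the PPG exceeds
#'    `ppg_slew_max` in absolute value (2 ms cannot change subcutaneous
#'    blood volume that fast; such jumps are acquisition artifacts);
#' 7. `art_slew` — likewise for ART with `art_slew_max`;
#' 8. `completeness` — no missing samples in either raw window.
#'
#' Rules are evaluated on the RAW windows: the 0.5 Hz high-pass removes the
#' DC level, so absolute thresholds are only meaningful pre-filter.
#'
#' @param co_min,co_max Admissible CO label range, L/min (2, 10).
#' @param art_min,art_max Admissible ART band, mmHg (30, 200).
#' @param ppg_min,ppg_max Admissible PPG band, a.u. (10, 100).
#' @param art_pp_min Minimum ART peak-to-peak, mmHg (30).
#' @param ppg_pp_min Minimum PPG peak-to-peak, a.u. (20).
#' @param ppg_slew_max,art_slew_max Maximum absolute adjacent-sample
#'   difference (20 a.u., 30 mmHg).
#' @return An object of class `qc_config`.
#' @export
qc_config <- function(co_min = 2, co_max = 10, art_min = 30, art_max = 200,
                      ppg_min = 10, ppg_max = 100, art_pp_min = 30,
                      ppg_pp_min = 20, ppg_slew_max = 20, art_slew_max = 30) {
  for (f in c("co_min", "co_max", "art_min", "art_max", "ppg_min", "ppg_max",
              "art_pp_min", "ppg_pp_min", "ppg_slew_max", "art_slew_max")) {
    check_number(get(f), f, lower = 1e-12)
  }
  if (co_min >= co_max) abort_validation("'co_min' must be below 'co_max'",
                                         field = "co_min")
  if (art_min >= art_max) abort_validation("'art_min' must be below 'art_max'",
                                           field = "art_min")
  if (ppg_min >= ppg_max) abort_validation("'ppg_min' must be below 'ppg_max'",
                                           field = "ppg_min")
  structure(list(co_min = co_min, co_max = co_max, art_min = art_min,
                 art_max = art_max, ppg_min = ppg_min, ppg_max = ppg_max,
                 art_pp_min = art_pp_min, ppg_pp_min = ppg_pp_min,
                 ppg_slew_max = ppg_slew_max, art_slew_max = art_slew_max),
            class = "qc_config")
}

QC_RULES <- c("co_range", "art_amplitude", "ppg_amplitude",
              "art_peak_to_peak", "ppg_peak_to_peak", "ppg_slew", "art_slew",
              "completeness")

#' Evaluate the screening rules on one segment
#'
#' Missing samples fail only `completeness`; the remaining rules are
#' evaluated on the non-missing samples so a short `NA` run does not also
#' trip amplitude or slew checks.
#'
#' @param segment A `co_segment` (raw windows of 2048 samples).
#' @param config A [qc_config()].
#' @return An object of class `qc_result`: named logical vector of per-rule
#'   passes plus a `passed` field (logical AND of all rules).
#' @export
evaluate_rules <- function(segment, config = qc_config()) {
  if (length(segment$ppg_raw) != SEG_LEN || length(segment$art_raw) != SEG_LEN) {
    abort_validation(sprintf("raw windows must have exactly %d samples",
                             SEG_LEN))
  }
  ppg <- segment$ppg_raw
  art <- segment$art_raw
  complete <- !anyNA(ppg) && !anyNA(art)
  ppg_ok <- ppg[!is.na(ppg)]
  art_ok <- art[!is.na(art)]
  dppg <- abs(diff(ppg_ok))
  dart <- abs(diff(art_ok))
  rules <- c(
    co_range = !is.na(segment$co_label) &&
      segment$co_label >= config$co_min && segment$co_label <= config$co_max,
    art_amplitude = all(art_ok >= config$art_min & art_ok <= config$art_max),
    ppg_amplitude = all(ppg_ok >= config$ppg_min & ppg_ok <= config$ppg_max),
    art_peak_to_peak = (max(art_ok) - min(art_ok)) >= config$art_pp_min,
    ppg_peak_to_peak = (max(ppg_ok) - min(ppg_ok)) >= config$ppg_pp_min,
    ppg_slew = !length(dppg) || max(dppg) <= config$ppg_slew_max,
    art_slew = !length(dart) || max(dart) <= config$art_slew_max,
    completeness = complete
  )
  structure(list(rules = rules, passed = all(rules)), class = "qc_result")
}

#' Screen a set of segments
#'
#' Applies [evaluate_rules()] to every segment, keeping those that pass all
#' rules (input order preserved) and tallying failures per rule. A segment
#' failing several rules counts once in `n_failed` but in each rule's tally.
#'
#' @param segments List of `co_segment` objects.
#' @param config A [qc_config()].
#' @return A list with elements `kept` (the passing segments) and `report`,
#'   an object of class `qc_report` with fields `n_candidates`, `n_passed`,
#'   `n_failed`, `rule_failures` (named integer vector) and `results`
#'   (per-segment `qc_result`s).
#' @export
screen_dataset <- function(segments, config = qc_config()) {
  results <- lapply(segments, evaluate_rules, config = config)
  passed <- vapply(results, function(r) r$passed, logical(1))
  tally <- stats::setNames(integer(length(QC_RULES)), QC_RULES)
  for (r in results[!passed]) {
    failed_rules <- names(r$rules)[!r$rules]
    tally[failed_rules] <- tally[failed_rules] + 1L
    log_event("qc", "info", "segment rejected",
              rules = paste(failed_rules, collapse = "+"))
  }
  report <- structure(
    list(n_candidates = length(segments),
         n_passed = sum(passed),
         n_failed = sum(!passed),
         rule_failures = tally,
         results = results),
    class = "qc_report"
  )
  list(kept = segments[passed], report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC report: %d candidates, %d kept, %d rejected\n",
              x$n_candidates, x$n_passed, x$n_failed))
  for (r in names(x$rule_failures)) {
    if (x$rule_failures[[r]] > 0) {
      cat(sprintf("  %-18s %d\n", r, x$rule_failures[[r]]))
    }
  }
  invisible(x)
}
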