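#' Method-comparison statistics between predicted and reference CO
#'
#' Computes the full agreement panel between a predicted and a reference CO
#' sequence, treating pairs as independent:
#'
#' * `bias` — signed mean difference `mean(y_pred - y_ref)` (L/min);
#' * `std` — population (1/n) standard deviation of the differences;
#' * `loa_half_width = 1.96 * std`, with `loa_lower`/`loa_upper` at
#'   `bias -/+ loa_half_width` (the 95% limits of agreement);
#' * `mse`, `mae`, `rmse = sqrt(mse)`;
#' * `rmsne = 100 * rmse / mean_ref_co` (percent);
#' * `pe = 100 * loa_half_width / mean_ref_co` (percent; the Critchley
#'   clinical-acceptability criterion is `pe < 30`);
#' * `pearson_r` — Pearson correlation (an error if either sequence is
#'   constant, where the coefficient is undefined).
#'
#' @param y_ref Reference CO values (L/min), length >= 2, finite.
#' @param y_pred Predicted CO values (L/min), same length.
#' @return An object of class `agreement_report` with the fields above plus
#'   `n`, `mean_ref_co` and `clinically_acceptable` (`pe < 30`).
#' @examples
#' rep <- compute_agreement(c(4, 5, 6), c(4.2, 5.1, 5.8))
#' rep$bias
#' @export
compute_agreement <- function(y_ref, y_pred) {
  check_pairs(y_ref, y_pred)
  n <- length(y_ref)
  d <- y_pred - y_ref
  bias <- mean(d)
  std <- sqrt(mean((d - bias)^2))          # population (1/n) SD
  loa_half <- 1.96 * std
  mse <- mean(d^2)
  mae <- mean(abs(d))
  rmse <- sqrt(mse)
  mean_ref <- mean(y_ref)
  if (mean_ref == 0) {
    stop("mean reference CO is zero; RMSNE and PE are undefined")
  }
  if (stats::sd(y_ref) == 0 || stats::sd(y_pred) == 0) {
    stop("Pearson correlation is undefined for a constant sequence")
  }
  r <- stats::cor(y_ref, y_pred)
  structure(
    list(n = n, bias = bias, std = std,
         loa_half_width = loa_half,
         loa_lower = bias - loa_half, loa_upper = bias + loa_half,
         mse = mse, mae = mae, rmse = rmse,
         mean_ref_co = mean_ref,
         rmsne = 100 * rmse / mean_ref,
         pe = 100 * loa_half / mean_ref,
         pearson_r = r,
         clinically_acceptable = (100 * loa_half / mean_ref) < 30),
    class = "agreement_report"
  )
}

check_pairs <- function(y_ref, y_pred) {
  if (!is.numeric(y_ref) || !is.numeric(y_pred) ||
      length(y_ref) != length(y_pred)) {
    abort_validation("y_ref and y_pred must be numeric vectors of equal length")
  }
  if (length(y_ref) < 2) {
    abort_validation("at least 2 pairs are required")
  }
  if (!all(is.finite(y_ref)) || !all(is.finite(y_pred))) {
    abort_validation("all paired values must be finite")
  }
  invisible(TRUE)
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("Agreement over %d pairs (mean reference CO %.3f L/min)\n",
              x$n, x$mean_ref_co))
  cat(sprintf("  bias  %+.3f L/min   std %.3f   LOA [%+.3f, %+.3f]\n",
              x$bias, x$std, x$loa_lower, x$loa_upper))
  cat(sprintf("  MAE %.3f   MSE %.3f   RMSE %.3f L/min\n",
              x$mae, x$mse, x$rmse))
  cat(sprintf("  RMSNE %.1f%%   PE %.1f%% (%s)   Pearson r %.3f\n",
              x$rmsne, x$pe,
              if (x$clinically_acceptable) "clinically acceptable, < 30%"
              else ">= 30%",
              x$pearson_r))
  invisible(x)
}

#' Bland-Altman data for paired CO estimates
#'
#' Per-pair means and differences plus the three reference lines (mean
#' difference and 95% limits of agreement) consistent with
#' [compute_agreement()] on the same pairs.
#'
#' @inheritParams compute_agreement
#' @return An object of class `bland_altman` with `points` (a data frame
#'   with columns `mean` and `difference`), `bias`, `loa_lower`, `loa_upper`.
#' @export
bland_altman <- function(y_ref, y_pred) {
  check_pairs(y_ref, y_pred)
  d <- y_pred - y_ref
  bias <- mean(d)
  std <- sqrt(mean((d - bias)^2))
  structure(
    list(points = data.frame(mean = (y_pred + y_ref) / 2,
                             difference = d),
         bias = bias, loa_lower = bias - 1.96 * std,
         loa_upper = bias + 1.96 * std),
    class = "bland_altman"
  )
}

#' @export
plot.bland_altman <- function(x, ...) {
  plot(x$points$mean, x$points$difference,
       xlab = "Mean of predicted and reference CO (L/min)",
       ylab = "Predicted - reference CO (L/min)",
       pch = 16, col = "steelblue", ...)
  graphics::abline(h = x$bias, col = "red", lty = 2)
  graphics::abline(h = c(x$loa_lower, x$loa_upper), col = "darkgreen", lty = 2)
  invisible(x)
}

#' Least-squares fit of predictions against the identity line
#'
#' Ordinary least squares of `y_pred` on `y_ref`; a slope near 1 and
#' intercept near 0 indicate predictions clustered around the line of
#' equality.
#'
#' @inheritParams compute_agreement
#' @return A list with `slope` and `intercept`.
#' @export
identity_fit <- function(y_ref, y_pred) {
  check_pairs(y_ref, y_pred)
  if (stats::sd(y_ref) == 0) {
    stop("identity fit is undefined for constant reference values")
  }
  fit <- stats::lm(y_pred ~ y_ref)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]))
}
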