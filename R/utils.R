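# Internal helpers shared across modules.

# Segment geometry: each CO reading anchors a 2048-sample window (4.096 s at
# 500 Hz), the 1024 samples before the reading and the 1024 from it on.
SEG_LEN <- 2048L
SEG_HALF <- 1024L

# Run `code` with a temporarily seeded RNG, restoring the caller's RNG state
# afterwards so library calls never perturb user-level reproducibility.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a parent seed and a stage label, deterministically
# and within 32-bit integer range.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 2654435.0 + h) %% .Machine$integer.max)
}

abort_validation <- function(msg, field = NULL) {
  stop(structure(
    class = c("counet_validation_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), field = field)
  ))
}

check_number <- function(x, field, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x < lower || x > upper) {
    abort_validation(
      sprintf("field '%s' must be a finite number in [%g, %g]",
              field, lower, upper),
      field = field
    )
  }
  invisible(x)
}

#' Emit a structured log line
#'
#' All pipeline stages report record drops, QC rejections and stage summaries
#' through this function, so nothing is discarded silently. Logging is
#' suppressed unless `options(counet.verbose = TRUE)` is set.
#'
#' @param stage Character stage name (e.g. `"qc"`, `"segment"`).
#' @param level One of `"info"`, `"warn"`.
#' @param msg Human-readable message.
#' @param ... Named context values appended as `key=value` pairs.
#' @return Invisibly, the formatted line.
#' @export
log_event <- function(stage, level = "info", msg, ...) {
  ctx <- list(...)
  kv <- if (length(ctx)) {
    paste0(" ", paste(sprintf("%s=%s", names(ctx),
                              vapply(ctx, function(v) paste(format(v), collapse = ","),
                                     character(1))),
                      collapse = " "))
  } else ""
  line <- sprintf("[%s] %s: %s%s", stage, level, msg, kv)
  if (isTRUE(getOption("counet.verbose", FALSE))) {
    message(line)
  }
  invisible(line)
}
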