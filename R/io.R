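#' Write / read a case as CSV
#'
#' A case is stored as two CSVs: `<case_id>_waveform.csv` with columns
#' `time_s, ppg, art` and `<case_id>_co.csv` with columns `time_s, co`.
#' Missing samples are written as empty cells and read back as `NA`.
#' Sample values round-trip to better than 1e-6 and the CO alignment
#' (reading-to-sample anchoring) round-trips exactly.
#'
#' @param record A `waveform_record`.
#' @param dir Output directory (created if absent).
#' @return `write_case_csv` returns the two file paths invisibly;
#'   `read_case_csv` returns the reconstructed `waveform_record`.
#' @export
write_case_csv <- function(record, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fs <- record$sampling_rate
  wf_path <- file.path(dir, paste0(record$case_id, "_waveform.csv"))
  co_path <- file.path(dir, paste0(record$case_id, "_co.csv"))
  n <- length(record$ppg)
  utils::write.csv(
    data.frame(time_s = (seq_len(n) - 1) / fs,
               ppg = record$ppg, art = record$art),
    wf_path, row.names = FALSE, na = ""
  )
  utils::write.csv(
    data.frame(time_s = (record$co_sample_indices - 1) / fs,
               co = record$co_values),
    co_path, row.names = FALSE, na = ""
  )
  invisible(c(waveform = wf_path, co = co_path))
}

#' @rdname write_case_csv
#' @param waveform_path,co_path Paths to the two CSVs.
#' @param case_id Case identifier for the restored record (default: derived
#'   from the file name).
#' @export
read_case_csv <- function(waveform_path, co_path,
                          case_id = sub("_waveform\\.csv$", "",
                                        basename(waveform_path))) {
  wf <- utils::read.csv(waveform_path)
  need <- c("time_s", "ppg", "art")
  if (!all(need %in% names(wf))) {
    abort_validation(sprintf("waveform CSV must have columns %s; found %s",
                             paste(need, collapse = ", "),
                             paste(names(wf), collapse = ", ")))
  }
  tt <- wf$time_s
  if (anyNA(tt) || any(diff(tt) <= 0)) {
    abort_validation("column 'time_s' must be strictly increasing")
  }
  fs <- round(1 / stats::median(diff(tt)))
  co <- utils::read.csv(co_path)
  if (!all(c("time_s", "co") %in% names(co))) {
    abort_validation("CO CSV must have columns time_s, co")
  }
  idx <- as.integer(round(co$time_s * fs)) + 1L
  if (any(idx < 1L | idx > nrow(wf))) {
    abort_validation("CO timestamps fall outside the waveform record")
  }
  rec <- structure(
    list(case_id = case_id, ppg = wf$ppg, art = wf$art,
         co_values = co$co, co_sample_indices = idx,
         true_co = NULL, sampling_rate = fs,
         co_interval_s = if (length(idx) > 1)
           stats::median(diff(idx)) / fs else NA_real_),
    class = "waveform_record"
  )
  if (anyNA(rec$ppg) || anyNA(rec$art)) {
    attr(rec, "has_missing") <- TRUE
    log_event("io", "warn", "case contains missing samples",
              case_id = case_id)
  } else {
    attr(rec, "has_missing") <- FALSE
  }
  rec
}

#' Full pipeline configuration
#'
#' Bundles the per-stage configurations plus the dataset size and one
#' global seed, which fans out deterministically to per-stage seeds so any
#' stage can also be re-run standalone.
#'
#' @param n_cases Number of synthetic cases to generate.
#' @param sim A [sim_config()] (per-case settings; population spread comes
#'   from `priors`).
#' @param priors A [case_priors()].
#' @param filter A [filter_config()].
#' @param qc A [qc_config()].
#' @param model A [model_config()].
#' @param train A [train_config()].
#' @param window_s Middle-window length in seconds (default 60).
#' @param seed Global seed.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(n_cases = 20, sim = sim_config(),
                            priors = case_priors(),
                            filter = filter_config(), qc = qc_config(),
                            model = model_config(), train = train_config(),
                            window_s = 60, seed = 1L) {
  check_number(n_cases, "n_cases", lower = 1)
  check_number(seed, "seed")
  structure(list(n_cases = as.integer(n_cases), sim = sim, priors = priors,
                 filter = filter, qc = qc, model = model, train = train,
                 window_s = window_s, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the end-to-end pipeline on synthetic data
#'
#' simulate -> middle window -> segment (+filter) -> QC screen ->
#' normalize -> 8:2 split -> train -> predict -> agreement statistics.
#' Fully reproducible under the global seed. Every dropped case or segment
#' is counted in the manifest and logged.
#'
#' @param config A [pipeline_config()].
#' @param records Optional list of pre-loaded `waveform_record`s (e.g. from
#'   [read_case_csv()]); when supplied, the simulation stage is skipped.
#' @return A list of class `pipeline_result` with elements `manifest`
#'   (stage-by-stage counts, seeds, config snapshot), `agreement`
#'   ([compute_agreement()] on the test set), `fit` ([identity_fit()]),
#'   `trained` (the model), `predictions` (data frame with `case_id`,
#'   `co_ref`, `co_pred`), and `qc_report`.
#' @export
run_pipeline <- function(config, records = NULL) {
  if (!inherits(config, "pipeline_config")) {
    abort_validation("'config' must be a pipeline_config object")
  }
  seeds <- list(sim = derive_seed(config$seed, "sim"),
                split = derive_seed(config$seed, "split"),
                init = derive_seed(config$seed, "init"),
                train = derive_seed(config$seed, "train"))
  if (is.null(records)) {
    records <- generate_dataset(config$sim, config$n_cases,
                                seed = seeds$sim, priors = config$priors)
  }
  n_read <- length(records)
  log_event("pipeline", "info", "cases ready", n = n_read)

  windowed <- list()
  dropped_short <- 0L
  dropped_missing <- 0L
  for (rec in records) {
    w <- withCallingHandlers(
      extract_middle_window(rec, config$window_s),
      counet_short_record = function(cnd) invokeRestart("muffleWarning")
    )
    if (is.null(w)) {
      dropped_short <- dropped_short + 1L
      next
    }
    if (isTRUE(attr(w, "has_missing"))) {
      dropped_missing <- dropped_missing + 1L
      log_event("window", "info", "case dropped: missing samples",
                case_id = rec$case_id)
      next
    }
    windowed[[length(windowed) + 1L]] <- w
  }

  segments <- list()
  n_candidates <- 0L
  boundary_dropped <- 0L
  for (rec in windowed) {
    segs <- segment_record(rec, config$filter)
    n_candidates <- n_candidates + attr(segs, "n_candidates")
    boundary_dropped <- boundary_dropped + attr(segs, "boundary_dropped")
    segments <- c(segments, segs)
  }

  scr <- screen_dataset(segments, config$qc)
  kept <- lapply(scr$kept, normalize_segment)

  parts <- split_dataset(kept, config$train$train_fraction,
                         seed = seeds$split,
                         split_level = config$train$split_level)
  mc <- config$model
  mc$seed <- seeds$init
  tc <- config$train
  tc$seed <- seeds$train
  model <- build_model(mc)
  trained <- train_model(model, parts$train, tc)
  y_pred <- predict_co(trained, parts$test)
  y_ref <- vapply(parts$test, function(s) s$co_label, numeric(1))
  agreement <- compute_agreement(y_ref, y_pred)
  fit <- identity_fit(y_ref, y_pred)

  manifest <- list(
    package_version = as.character(utils::packageVersion("counet")),
    # full config snapshot + seeds: a run is reconstructible from its manifest
    config = lapply(config, function(x) if (is.list(x)) unclass(x) else x),
    seed = config$seed, stage_seeds = seeds,
    n_cases_read = n_read,
    n_cases_dropped_short = dropped_short,
    n_cases_dropped_missing = dropped_missing,
    n_cases_used = length(windowed),
    n_segment_candidates = n_candidates,
    n_boundary_dropped = boundary_dropped,
    n_qc_candidates = scr$report$n_candidates,
    n_qc_kept = scr$report$n_passed,
    n_qc_failed = scr$report$n_failed,
    qc_rule_failures = as.list(scr$report$rule_failures),
    n_train = length(parts$train),
    n_test = length(parts$test),
    n_validation = validation_size(length(parts$train),
                                   config$train$val_fraction_of_train),
    best_epoch = trained$best_epoch
  )
  stopifnot(manifest$n_qc_kept + manifest$n_qc_failed ==
              manifest$n_qc_candidates,
            manifest$n_segment_candidates ==
              manifest$n_qc_candidates + manifest$n_boundary_dropped,
            manifest$n_train + manifest$n_test == manifest$n_qc_kept)
  structure(
    list(manifest = manifest, agreement = agreement, fit = fit,
         trained = trained,
         predictions = data.frame(
           case_id = vapply(parts$test, function(s) s$case_id, character(1)),
           co_ref = y_ref, co_pred = y_pred),
         qc_report = scr$report),
    class = "pipeline_result"
  )
}

#' Write pipeline outputs to a directory
#'
#' Writes `manifest.json`, `agreement.json` and `predictions.csv`.
#'
#' @param result A `pipeline_result` from [run_pipeline()].
#' @param dir Output directory.
#' @return Invisibly, the directory.
#' @export
write_pipeline_outputs <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  jsonlite::write_json(result$manifest,
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(unclass(result$agreement),
                       file.path(dir, "agreement.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(result$predictions, file.path(dir, "predictions.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read a pipeline configuration from YAML
#'
#' Each top-level section (`sim`, `priors`, `filter`, `qc`, `model`,
#' `train`) is passed to the corresponding constructor, so every value is
#' validated before any stage runs; omitted sections take defaults.
#'
#' @param path YAML file path.
#' @return A [pipeline_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  build <- function(ctor, section) {
    do.call(ctor, if (is.null(y[[section]])) list() else y[[section]])
  }
  pipeline_config(
    n_cases = if (is.null(y$n_cases)) 20 else y$n_cases,
    sim = build(sim_config, "sim"),
    priors = build(case_priors, "priors"),
    filter = build(filter_config, "filter"),
    qc = build(qc_config, "qc"),
    model = build(model_config, "model"),
    train = build(train_config, "train"),
    window_s = if (is.null(y$window_s)) 60 else y$window_s,
    seed = if (is.null(y$seed)) 1L else y$seed
  )
}
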