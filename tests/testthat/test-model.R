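test_that("architecture constraints are enforced", {
  expect_error(model_config(input_length = 2047), "multiple of 16")
  expect_error(model_config(input_length = 100), "multiple of 16")
  expect_silent(model_config(input_length = 64))
  expect_silent(model_config(input_length = 2048))
  expect_error(model_config(kernel_size = 4), "odd")
  expect_error(build_model(list()), "model_config")
})

test_that("forward pass honours the shape contract", {
  mc <- model_config(input_length = 64, base_filters = 4,
                     bottleneck_lstm_units = 4, head_lstm_units = 4,
                     seed = 3)
  model <- build_model(mc)
  X <- array(runif(4 * 64 * 2), c(4, 64, 2))
  out <- counet:::model_forward(model$params, mc, X)
  expect_length(out$y, 4)
  expect_true(all(is.finite(out$y)))
  # encoder level widths double while lengths halve: check parameter shapes
  nf <- as.integer(4 * 2^(0:3))
  for (lv in 1:4) {
    expect_identical(ncol(model$params$enc[[lv]]$W), nf[lv])
  }
  # identical seed, identical initialization
  model2 <- build_model(mc)
  expect_identical(serialize(model$params, NULL),
                   serialize(model2$params, NULL))
})

test_that("backpropagation matches finite-difference gradients", {
  mc <- model_config(input_length = 16, depth = 2, base_filters = 3,
                     bottleneck_lstm_layers = 2, bottleneck_lstm_units = 4,
                     head_lstm_units = 3, seed = 7)
  model <- build_model(mc)
  set.seed(1)
  B <- 3
  X <- array(runif(B * 16 * 2), c(B, 16, 2))
  y <- runif(B)
  loss_fn <- function(params) {
    mean((counet:::model_forward(params, mc, X)$y - y)^2)
  }
  fw <- counet:::model_forward(model$params, mc, X, want_cache = TRUE)
  grads <- counet:::model_backward(2 * (fw$y - y) / B, model$params, mc,
                                   fw$caches)
  flat <- function(tree, prefix = "") {
    if (is.list(tree)) {
      out <- list()
      for (i in seq_along(tree)) {
        nm <- if (!is.null(names(tree)) && nzchar(names(tree)[i]))
          names(tree)[i] else i
        out <- c(out, flat(tree[[i]], paste0(prefix, "/", nm)))
      }
      out
    } else stats::setNames(list(tree), prefix)
  }
  pf <- flat(model$params)
  gf <- flat(grads)
  eps <- 1e-5
  worst <- 0
  for (nm in names(pf)) {
    g <- gf[[nm]]
    for (ii in sample(length(pf[[nm]]), min(2, length(pf[[nm]])))) {
      poke <- function(tree, path, delta) {
        key <- path[[1]]
        if (length(path) == 1) {
          tree[[key]][ii] <- tree[[key]][ii] + delta
          tree
        } else {
          tree[[key]] <- poke(tree[[key]], path[-1], delta)
          tree
        }
      }
      path <- strsplit(sub("^/", "", nm), "/")[[1]]
      path <- lapply(path, function(s) {
        if (grepl("^[0-9]+$", s)) as.integer(s) else s
      })
      num <- (loss_fn(poke(model$params, path, eps)) -
                loss_fn(poke(model$params, path, -eps))) / (2 * eps)
      worst <- max(worst, abs(num - g[ii]))
    }
  }
  expect_lt(worst, 1e-7)
})

test_that("train/test split is exact, disjoint and reproducible", {
  fake <- function(n, case = "c1") {
    lapply(seq_len(n), function(i) list(case_id = case, id = i))
  }
  big <- fake(9446)
  sp <- split_dataset(big, 0.8, seed = 5)
  expect_length(sp$train, 7556)
  expect_length(sp$test, 1890)
  ids <- function(x) vapply(x, function(s) s$id, numeric(1))
  expect_length(intersect(ids(sp$train), ids(sp$test)), 0)
  expect_setequal(c(ids(sp$train), ids(sp$test)), 1:9446)
  sp2 <- split_dataset(big, 0.8, seed = 5)
  expect_identical(ids(sp$train), ids(sp2$train))
  small <- split_dataset(fake(10), 0.8, seed = 1)
  expect_length(small$train, 8)
  expect_length(small$test, 2)
  expect_error(split_dataset(fake(1), 0.8), "2 segments")
  # case-level split keeps whole cases together
  mixed <- c(fake(6, "a"), fake(6, "b"), fake(6, "c"))
  spc <- split_dataset(mixed, 0.67, seed = 2, split_level = "case")
  tr_cases <- unique(vapply(spc$train, function(s) s$case_id, character(1)))
  te_cases <- unique(vapply(spc$test, function(s) s$case_id, character(1)))
  expect_length(intersect(tr_cases, te_cases), 0)
})

test_that("validation hold-out size follows the 10% convention", {
  expect_identical(validation_size(7556), 756L)
  expect_identical(validation_size(100, 0.1), 10L)
})

test_that("training tracks history and returns the best-validation epoch", {
  segs <- make_clean_segments(n_cases = 1, seed = 40)
  mc <- model_config(input_length = 64, base_filters = 4,
                     bottleneck_lstm_units = 4, head_lstm_units = 4,
                     seed = 3)
  tr <- train_model(build_model(mc), segs,
                    train_config(epochs = 4, batch_size = 8, seed = 9))
  expect_identical(nrow(tr$history), 4L)
  expect_identical(tr$best_epoch,
                   which.min(tr$history$val_loss))
  expect_true(all(is.finite(tr$history$train_loss)))
  # per-epoch resampling also runs
  tr2 <- train_model(build_model(mc), segs,
                     train_config(epochs = 2, batch_size = 8,
                                  val_mode = "per_epoch_resample", seed = 9))
  expect_identical(nrow(tr2$history), 2L)
  # determinism: same seeds, identical history and predictions
  tr3 <- train_model(build_model(mc), segs,
                     train_config(epochs = 4, batch_size = 8, seed = 9))
  expect_identical(tr$history, tr3$history)
  p1 <- predict_co(tr, segs)
  p3 <- predict_co(tr3, segs)
  expect_identical(p1, p3)
  expect_error(train_model(build_model(mc), list(), train_config()),
               "2 segments")
})

test_that("predictions are deterministic, ordered and unscaled to L/min", {
  segs <- make_clean_segments(n_cases = 1, seed = 41)
  mc <- model_config(input_length = 64, base_filters = 4,
                     bottleneck_lstm_units = 4, head_lstm_units = 4,
                     seed = 3)
  tr <- train_model(build_model(mc), segs,
                    train_config(epochs = 2, batch_size = 8, seed = 10))
  p <- predict_co(tr, segs)
  expect_length(p, length(segs))
  expect_identical(p, predict_co(tr, segs))
  # order preserved: predicting a subset matches the slice
  expect_equal(predict_co(tr, segs[3:5]), p[3:5], tolerance = 1e-12)
  # outputs are on the L/min scale via the inverse label map
  dat <- segments_to_input(segs, 64, mc$channels)
  scaled <- counet:::predict_scaled(tr$params, mc, dat$X)
  expect_equal(p, unscale_co_label(scaled), tolerance = 1e-12)
})

test_that("saved models round-trip and corrupt files are rejected", {
  segs <- make_clean_segments(n_cases = 1, seed = 42)
  mc <- model_config(input_length = 64, base_filters = 4,
                     bottleneck_lstm_units = 4, head_lstm_units = 4,
                     seed = 3)
  tr <- train_model(build_model(mc), segs,
                    train_config(epochs = 2, batch_size = 8, seed = 11))
  path <- tempfile(fileext = ".rds")
  save_model(tr, path)
  tr2 <- load_model(path)
  expect_equal(predict_co(tr2, segs), predict_co(tr, segs),
               tolerance = 1e-6)
  # truncated file
  raw_all <- readBin(path, "raw", file.size(path))
  bad <- tempfile(fileext = ".rds")
  writeBin(raw_all[1:20], bad)
  expect_error(load_model(bad), "cannot read")
  # foreign object
  other <- tempfile(fileext = ".rds")
  saveRDS(list(1, 2), other)
  expect_error(load_model(other), "not a saved counet model")
})
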