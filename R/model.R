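#' Architecture configuration for the dual-channel 1-D U-Net
#'
#' A 4-level encoder/decoder with skip connections, adapted to
#' one-dimensional waveforms: each encoder level applies a same-padded 1-D
#' convolution + rectifier and halves the temporal length by max pooling
#' while the channel count doubles; the decoder mirrors this with
#' nearest-neighbour upsampling, convolution and concatenation of the
#' matching encoder features. Two bidirectional LSTM layers sit at the
#' bottleneck between encoder and decoder, and one further bidirectional
#' LSTM ahead of the fully connected scalar output summarizes the
#' full-resolution decoded sequence into a single CO estimate.
#'
#' With `depth` pooling stages of factor `pool_factor` the input length must
#' be divisible by `pool_factor^depth` — with the defaults, a multiple
#' of 16; the 2048-point (4.096 s) segment satisfies this.
#'
#' @param input_length Samples per input window (default 2048). Windows
#'   longer than `input_length` are subsampled with an integer stride when
#'   tensors are assembled (see [segments_to_input()]), which keeps small
#'   CPU-scale configurations practical.
#' @param channels Which waveform channels feed the model:
#'   `c("ppg", "art")` (default), `"ppg"` or `"art"` (single-channel
#'   ablation switch).
#' @param depth Number of encoder/decoder levels (default 4).
#' @param base_filters Convolution channels at the first level, doubling per
#'   level (default 16).
#' @param kernel_size Convolution kernel length, odd (default 3).
#' @param pool_factor Pooling/upsampling factor per level (fixed at 2).
#' @param bottleneck_lstm_layers Number of bidirectional LSTM layers at the
#'   bottleneck (default 2).
#' @param bottleneck_lstm_units,head_lstm_units Hidden units per direction
#'   (default 64 each).
#' @param seed Seed for parameter initialization.
#' @return An object of class `model_config`.
#' @export
model_config <- function(input_length = 2048, channels = c("ppg", "art"),
                         depth = 4, base_filters = 16, kernel_size = 3,
                         pool_factor = 2, bottleneck_lstm_layers = 2,
                         bottleneck_lstm_units = 64, head_lstm_units = 64,
                         seed = 1L) {
  check_number(input_length, "input_length", lower = 1)
  check_number(depth, "depth", lower = 1, upper = 8)
  check_number(base_filters, "base_filters", lower = 1)
  check_number(kernel_size, "kernel_size", lower = 1)
  check_number(bottleneck_lstm_layers, "bottleneck_lstm_layers", lower = 1)
  check_number(bottleneck_lstm_units, "bottleneck_lstm_units", lower = 1)
  check_number(head_lstm_units, "head_lstm_units", lower = 1)
  if (pool_factor != 2) {
    abort_validation("field 'pool_factor' must be 2", field = "pool_factor")
  }
  if (kernel_size %% 2 != 1) {
    abort_validation("field 'kernel_size' must be odd", field = "kernel_size")
  }
  channels <- match.arg(channels, c("ppg", "art"), several.ok = TRUE)
  divisor <- pool_factor^depth
  if (input_length %% divisor != 0) {
    abort_validation(
      sprintf(paste0("field 'input_length' must be a multiple of %d ",
                     "(%d pooling stages of factor %d)"),
              divisor, depth, pool_factor),
      field = "input_length"
    )
  }
  structure(
    list(input_length = as.integer(input_length), channels = channels,
         in_channels = length(channels), depth = as.integer(depth),
         base_filters = as.integer(base_filters),
         kernel_size = as.integer(kernel_size),
         pool_factor = as.integer(pool_factor),
         bottleneck_lstm_layers = as.integer(bottleneck_lstm_layers),
         bottleneck_lstm_units = as.integer(bottleneck_lstm_units),
         head_lstm_units = as.integer(head_lstm_units),
         seed = as.integer(seed)),
    class = "model_config"
  )
}

#' Training protocol configuration
#'
#' Mean-squared error on the scaled labels is the loss; mean absolute error
#' is tracked as the evaluation metric. The data are split 8:2 into
#' training and test elsewhere ([split_dataset()]); here 10% of the
#' training set is held out for validation, either as one fixed subset
#' (default, reproducible) or freshly resampled every epoch
#' (`val_mode = "per_epoch_resample"`). The returned parameters are those
#' of the epoch with the smallest validation loss.
#'
#' @param learning_rate Adam learning rate (default 0.001).
#' @param batch_size Mini-batch size (default 32).
#' @param epochs Training epochs (default 500).
#' @param train_fraction Fraction of segments assigned to training by
#'   [split_dataset()] (default 0.8).
#' @param val_fraction_of_train Fraction of the training set held out for
#'   validation (default 0.1).
#' @param val_mode `"fixed"` (default) or `"per_epoch_resample"`.
#' @param split_level `"segment"` (default) or `"case"`; case-level keeps
#'   all of a case's segments on one side of the split.
#' @param seed Seed for shuffling and validation draws.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.001, batch_size = 32,
                         epochs = 500, train_fraction = 0.8,
                         val_fraction_of_train = 0.1,
                         val_mode = c("fixed", "per_epoch_resample"),
                         split_level = c("segment", "case"), seed = 1L) {
  check_number(learning_rate, "learning_rate", lower = 1e-12)
  check_number(batch_size, "batch_size", lower = 1)
  check_number(epochs, "epochs", lower = 1)
  check_number(train_fraction, "train_fraction", lower = 1e-9, upper = 1 - 1e-9)
  check_number(val_fraction_of_train, "val_fraction_of_train",
               lower = 1e-9, upper = 1 - 1e-9)
  structure(
    list(loss = "mse", metric = "mae", learning_rate = learning_rate,
         batch_size = as.integer(batch_size), epochs = as.integer(epochs),
         train_fraction = train_fraction,
         val_fraction_of_train = val_fraction_of_train,
         val_mode = match.arg(val_mode),
         split_level = match.arg(split_level),
         seed = as.integer(seed)),
    class = "train_config"
  )
}

#' Number of validation samples for a training-set size
#'
#' `round(fraction * n_train)`: 7,556 training segments at 10% give 756.
#'
#' @param n_train Training-set size.
#' @param fraction Validation fraction (default 0.1).
#' @return Integer count.
#' @export
validation_size <- function(n_train, fraction = 0.1) {
  as.integer(round(fraction * n_train))
}

#' Duration of one segment in seconds
#'
#' @param sampling_rate Sampling frequency in Hz (default 500).
#' @return `2048 / sampling_rate` seconds (4.096 s at 500 Hz).
#' @export
segment_duration_s <- function(sampling_rate = 500) SEG_LEN / sampling_rate

#' Random train/test split of segments
#'
#' @param segments List of segments (length >= 2).
#' @param train_fraction Training fraction; the training set has
#'   `floor(train_fraction * n)` segments (segment-level split).
#' @param seed Integer seed; identical seeds give identical partitions.
#' @param split_level `"segment"` (default) or `"case"`. Case-level assigns
#'   whole cases to the training side until the target size is reached, so
#'   no case leaks across the split (training size then only approximates
#'   the target).
#' @return A list with elements `train` and `test` (original order
#'   preserved within each side).
#' @export
split_dataset <- function(segments, train_fraction = 0.8, seed = 1L,
                          split_level = c("segment", "case")) {
  split_level <- match.arg(split_level)
  n <- length(segments)
  if (n < 2) abort_validation("at least 2 segments are required to split")
  target <- floor(train_fraction * n)
  train_idx <- with_seed(seed, {
    if (split_level == "segment") {
      sort(sample.int(n, target))
    } else {
      ids <- vapply(segments, function(s) s$case_id, character(1))
      cases <- sample(unique(ids))
      take <- integer(0)
      for (cs in cases) {
        if (length(take) >= target) break
        take <- c(take, which(ids == cs))
      }
      sort(take)
    }
  })
  list(train = segments[train_idx], test = segments[-train_idx])
}

# ---- parameter initialization ---------------------------------------------

init_conv <- function(k, cin, cout) {
  list(W = matrix(stats::rnorm(k * cin * cout, sd = sqrt(2 / (k * cin))),
                  k * cin, cout),
       b = numeric(cout))
}

init_lstm_dir <- function(cin, u) {
  s <- sqrt(6 / (cin + 4 * u))
  list(Wx = matrix(stats::runif(cin * 4 * u, -s, s), cin, 4 * u),
       Wh = matrix(stats::runif(u * 4 * u, -s, s), u, 4 * u),
       b = c(numeric(u), rep(1, u), numeric(2 * u)))  # forget bias 1
}

init_bilstm <- function(cin, u) {
  list(f = init_lstm_dir(cin, u), b = init_lstm_dir(cin, u))
}

#' Build an untrained model
#'
#' Allocates and seeds all parameters for the architecture described by a
#' [model_config()].
#'
#' @param config A [model_config()].
#' @return An object of class `counet_model` holding the config and the
#'   parameter tree.
#' @export
build_model <- function(config) {
  if (!inherits(config, "model_config")) {
    abort_validation("'config' must be a model_config object",
                     field = "config")
  }
  k <- config$kernel_size
  nf <- config$base_filters * 2^(seq_len(config$depth) - 1L)
  u_b <- config$bottleneck_lstm_units
  with_seed(config$seed, {
    enc <- vector("list", config$depth)
    cin <- config$in_channels
    for (lv in seq_len(config$depth)) {
      enc[[lv]] <- init_conv(k, cin, nf[lv])
      cin <- nf[lv]
    }
    bott <- vector("list", config$bottleneck_lstm_layers)
    cin_b <- nf[config$depth]
    for (l in seq_len(config$bottleneck_lstm_layers)) {
      bott[[l]] <- init_bilstm(cin_b, u_b)
      cin_b <- 2L * u_b
    }
    dec <- vector("list", config$depth)
    above <- 2L * u_b                       # channels arriving from below
    for (lv in rev(seq_len(config$depth))) {
      dec[[lv]] <- list(up = init_conv(k, above, nf[lv]),
                        merge = init_conv(k, 2L * nf[lv], nf[lv]))
      above <- nf[lv]
    }
    head <- list(lstm = init_bilstm(nf[1], config$head_lstm_units),
                 fc = list(W = matrix(stats::rnorm(2 * config$head_lstm_units,
                                                   sd = sqrt(1 / (2 * config$head_lstm_units))),
                                      2 * config$head_lstm_units, 1),
                           b = 0))
    structure(list(config = config,
                   params = list(enc = enc, bott = bott, dec = dec,
                                 head = head)),
              class = "counet_model")
  })
}

# ---- forward / backward ----------------------------------------------------

# X is a (B, L, C) array; internally everything runs on flat (B*T, C)
# matrices (see nn_ops.R). The temporal length at level k is L / 2^k.
model_forward <- function(params, config, X, want_cache = FALSE) {
  k <- config$kernel_size
  B <- dim(X)[1]
  Tn <- dim(X)[2]
  caches <- if (want_cache) list(enc = list(), bott = list(), dec = list())
  z <- matrix(X, B * Tn, dim(X)[3])
  skips <- vector("list", config$depth)
  for (lv in seq_len(config$depth)) {
    cv <- conv1d_forward(z, B, Tn, params$enc[[lv]]$W, params$enc[[lv]]$b, k)
    rl <- relu_forward(cv$out)
    skips[[lv]] <- rl$out
    mp <- maxpool2_forward(rl$out, B, Tn)
    z <- mp$out
    Tn <- Tn %/% 2L
    if (want_cache) caches$enc[[lv]] <- list(cv = cv$cache, rl = rl$cache,
                                             mp = mp$cache)
  }
  for (l in seq_along(params$bott)) {
    bl <- bilstm_forward(z, B, Tn, params$bott[[l]], "seq")
    z <- bl$out
    if (want_cache) caches$bott[[l]] <- bl$cache
  }
  for (lv in rev(seq_len(config$depth))) {
    up <- upsample2_forward(z, B, Tn)
    Tn <- Tn * 2L
    cv1 <- conv1d_forward(up$out, B, Tn, params$dec[[lv]]$up$W,
                          params$dec[[lv]]$up$b, k)
    r1 <- relu_forward(cv1$out)
    merged <- cbind(r1$out, skips[[lv]])
    cv2 <- conv1d_forward(merged, B, Tn, params$dec[[lv]]$merge$W,
                          params$dec[[lv]]$merge$b, k)
    r2 <- relu_forward(cv2$out)
    z <- r2$out
    if (want_cache) {
      caches$dec[[lv]] <- list(cv1 = cv1$cache, r1 = r1$cache,
                               cv2 = cv2$cache, r2 = r2$cache,
                               up = up$cache, c1 = ncol(r1$out))
    }
  }
  hl <- bilstm_forward(z, B, Tn, params$head$lstm, "final")
  dn <- dense_forward(hl$out, params$head$fc$W, params$head$fc$b)
  if (want_cache) {
    caches$head <- list(lstm = hl$cache, fc = dn$cache)
  }
  list(y = as.numeric(dn$out), caches = caches)
}

model_backward <- function(dy, params, config, caches) {
  g <- list(enc = vector("list", config$depth),
            bott = vector("list", length(params$bott)),
            dec = vector("list", config$depth),
            head = NULL)
  dn <- dense_backward(matrix(dy, ncol = 1), caches$head$fc)
  hb <- bilstm_backward(dn$dX, caches$head$lstm)
  g$head <- list(lstm = hb$grads, fc = list(W = dn$dW, b = dn$db))
  dz <- hb$dX
  dskips <- vector("list", config$depth)
  for (lv in seq_len(config$depth)) {       # decoder, shallow to deep
    cc <- caches$dec[[lv]]
    d2 <- relu_backward(dz, cc$r2)
    bc2 <- conv1d_backward(d2, cc$cv2)
    dskips[[lv]] <- bc2$dX[, -seq_len(cc$c1), drop = FALSE]
    d1 <- relu_backward(bc2$dX[, seq_len(cc$c1), drop = FALSE], cc$r1)
    bc1 <- conv1d_backward(d1, cc$cv1)
    dz <- upsample2_backward(bc1$dX, cc$up)
    g$dec[[lv]] <- list(up = list(W = bc1$dW, b = bc1$db),
                        merge = list(W = bc2$dW, b = bc2$db))
  }
  for (l in rev(seq_along(params$bott))) {
    bb <- bilstm_backward(dz, caches$bott[[l]])
    g$bott[[l]] <- bb$grads
    dz <- bb$dX
  }
  for (lv in rev(seq_len(config$depth))) {  # encoder, deep to shallow
    cc <- caches$enc[[lv]]
    dpool <- maxpool2_backward(dz, cc$mp)
    dpool <- dpool + dskips[[lv]]
    dr <- relu_backward(dpool, cc$rl)
    bc <- conv1d_backward(dr, cc$cv)
    g$enc[[lv]] <- list(W = bc$dW, b = bc$db)
    dz <- bc$dX
  }
  g
}

#' Assemble model input tensors from segments
#'
#' Stacks the normalized filtered windows of `segments` into a
#' `(n, input_length, channels)` array. Windows longer than `input_length`
#' are subsampled with an even integer stride.
#'
#' @param segments List of normalized `co_segment`s.
#' @param input_length Target window length (from the [model_config()]).
#' @param channels Channel subset, e.g. `c("ppg", "art")`.
#' @return A list with `X` (the tensor) and `y` (scaled labels).
#' @export
segments_to_input <- function(segments, input_length,
                              channels = c("ppg", "art")) {
  n <- length(segments)
  stopifnot(n >= 1)
  L0 <- length(segments[[1]]$ppg_in)
  if (L0 %% input_length != 0) {
    abort_validation(sprintf(
      "window length %d is not an integer multiple of input_length %d",
      L0, input_length))
  }
  stride <- L0 %/% input_length
  idx <- seq(1L, L0, by = stride)
  X <- array(0, c(n, input_length, length(channels)))
  for (i in seq_len(n)) {
    for (j in seq_along(channels)) {
      field <- paste0(channels[j], "_in")
      X[i, , j] <- segments[[i]][[field]][idx]
    }
  }
  y <- vapply(segments, function(s) s$co_label_scaled, numeric(1))
  list(X = X, y = y)
}

predict_scaled <- function(params, config, X, chunk = 512L) {
  n <- dim(X)[1]
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    j <- min(i + chunk - 1L, n)
    out[i:j] <- model_forward(params, config,
                              X[i:j, , , drop = FALSE])$y
    i <- j + 1L
  }
  out
}

#' Train the model
#'
#' Mini-batch Adam on the mean-squared error of the scaled labels,
#' shuffling each epoch, with a 10% validation hold-out monitored every
#' epoch. The returned parameters are those of the epoch with the smallest
#' validation loss.
#'
#' @param model A `counet_model` from [build_model()].
#' @param segments Normalized, QC-passed training segments.
#' @param config A [train_config()].
#' @return An object of class `trained_counet` with elements `config`
#'   (architecture), `train_config`, `params` (best-epoch weights),
#'   `history` (per-epoch data frame), `best_epoch`.
#' @export
train_model <- function(model, segments, config = train_config()) {
  if (!inherits(model, "counet_model")) {
    abort_validation("'model' must come from build_model()")
  }
  if (length(segments) < 2) {
    abort_validation("training requires at least 2 segments")
  }
  mc <- model$config
  dat <- segments_to_input(segments, mc$input_length, mc$channels)
  n <- dim(dat$X)[1]
  n_val <- max(1L, validation_size(n, config$val_fraction_of_train))
  params <- model$params
  m <- tree_zeros_like(params)
  v <- tree_zeros_like(params)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        train_mae = numeric(), val_loss = numeric(),
                        val_mae = numeric())
  best <- list(loss = Inf, params = params, epoch = 0L)
  step <- 0L
  with_seed(config$seed, {
    fixed_val <- sample.int(n, n_val)
    for (epoch in seq_len(config$epochs)) {
      val_idx <- if (config$val_mode == "fixed") fixed_val
                 else sample.int(n, n_val)
      tr_idx <- setdiff(seq_len(n), val_idx)
      order_idx <- sample(tr_idx)
      batch_losses <- c(); batch_maes <- c()
      i <- 1L
      while (i <= length(order_idx)) {
        j <- min(i + config$batch_size - 1L, length(order_idx))
        bidx <- order_idx[i:j]
        Xb <- dat$X[bidx, , , drop = FALSE]
        yb <- dat$y[bidx]
        fw <- model_forward(params, mc, Xb, want_cache = TRUE)
        err <- fw$y - yb
        loss <- mean(err^2)
        if (!is.finite(loss)) {
          stop(sprintf("non-finite training loss at epoch %d; ", epoch),
               "check input scaling and learning rate")
        }
        batch_losses <- c(batch_losses, loss)
        batch_maes <- c(batch_maes, mean(abs(err)))
        grads <- model_backward(2 * err / length(err), params, mc, fw$caches)
        step <- step + 1L
        upd <- adam_step(params, grads, m, v, config$learning_rate, step)
        params <- upd$params; m <- upd$m; v <- upd$v
        i <- j + 1L
      }
      val_pred <- predict_scaled(params, mc,
                                 dat$X[val_idx, , , drop = FALSE])
      val_err <- val_pred - dat$y[val_idx]
      val_loss <- mean(val_err^2)
      history[epoch, ] <- list(epoch, mean(batch_losses), mean(batch_maes),
                               val_loss, mean(abs(val_err)))
      if (val_loss < best$loss) {
        best <- list(loss = val_loss, params = params, epoch = epoch)
      }
      log_event("train", "info", "epoch complete", epoch = epoch,
                train_loss = signif(mean(batch_losses), 4),
                val_loss = signif(val_loss, 4))
    }
  })
  structure(
    list(config = mc, train_config = config, params = best$params,
         final_params = params, history = history,
         best_epoch = best$epoch),
    class = "trained_counet"
  )
}

#' Predict CO for a set of segments
#'
#' Runs the best-validation-epoch parameters over the segments (prepared
#' identically to training) and maps the scaled outputs back to L/min.
#'
#' @param trained A `trained_counet` from [train_model()].
#' @param segments Normalized segments.
#' @return Numeric vector of CO predictions in L/min, one per segment,
#'   order preserved.
#' @export
predict_co <- function(trained, segments) {
  if (!inherits(trained, "trained_counet")) {
    abort_validation("'trained' must come from train_model()")
  }
  mc <- trained$config
  dat <- segments_to_input(segments, mc$input_length, mc$channels)
  unscale_co_label(predict_scaled(trained$params, mc, dat$X))
}

#' Save / load a trained model
#'
#' The on-disk representation holds the architecture config, the learned
#' parameters and the training history; predictions after a round trip
#' match to numerical tolerance.
#'
#' @param trained A `trained_counet`.
#' @param path File path.
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   restored `trained_counet` (error on corrupt or foreign files).
#' @export
save_model <- function(trained, path) {
  if (!inherits(trained, "trained_counet")) {
    abort_validation("'trained' must come from train_model()")
  }
  saveRDS(trained, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e) {
    stop(sprintf("cannot read model file '%s': %s", path, conditionMessage(e)))
  })
  if (!inherits(obj, "trained_counet") ||
      !all(c("config", "params", "history", "best_epoch") %in% names(obj))) {
    stop(sprintf("'%s' is not a saved counet model", path))
  }
  obj
}
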