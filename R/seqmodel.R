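#' LSTM training configuration
#'
#' A deliberately lightweight architecture: a single LSTM layer followed by
#' a fully connected readout mapping the final hidden state to a scalar
#' stride length. Training minimizes mean squared error with Adam,
#' mini-batches, dropout on the readout input and early stopping on the
#' validation loss.
#'
#' @param hidden_units LSTM hidden size (default 50).
#' @param dropout_rate Dropout probability on the final hidden state during
#'   training, in `[0, 1)` (default 0.2).
#' @param learning_rate Adam step size (default 1e-3).
#' @param batch_size Mini-batch size (default 16).
#' @param max_epochs Training epoch cap (default 500; 0 returns an
#'   untrained model).
#' @param early_stopping_patience Epochs without validation improvement
#'   before stopping (default 25).
#' @param seed Integer RNG seed for weight init, batching and dropout.
#' @return An object of class `lstm_config`.
#' @export
lstm_config <- function(hidden_units = 50L, dropout_rate = 0.2,
                        learning_rate = 1e-3, batch_size = 16L,
                        max_epochs = 500L, early_stopping_patience = 25L,
                        seed = NULL) {
  if (hidden_units < 1L) stop("hidden_units must be >= 1")
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("dropout_rate must be in [0, 1)")
  structure(list(hidden_units = as.integer(hidden_units), layers = 1L,
                 dropout_rate = dropout_rate,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 early_stopping_patience = as.integer(early_stopping_patience),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "lstm_config")
}

#' Assemble a sequence-regression dataset from stride segments
#'
#' Each variable-length stride segment is linearly resampled to a common
#' length, paired with its reference stride length and assigned to a
#' seeded train/validation/test split. Z-score normalization statistics
#' (for both the signals and the labels) are computed exclusively on the
#' training split.
#'
#' @param segments List of `stride_segment` objects or bare numeric
#'   vectors (each length >= 3).
#' @param labels Numeric vector of stride lengths (m), one per segment.
#' @param target_len Common resampled sequence length (default 50, about
#'   one stride at 50 Hz).
#' @param seed Integer seed for the split.
#' @param split Train/validation/test fractions (default 70/15/15).
#' @return An object of class `sequence_dataset` with the raw resampled
#'   matrix `X` (n x target_len), labels `y`, the `split` factor and the
#'   training-split normalization statistics.
#' @export
prepare_sequences <- function(segments, labels, target_len = 50L,
                              seed = NULL,
                              split = c(0.70, 0.15, 0.15)) {
  if (!length(segments)) stop("no segments supplied")
  sigs <- lapply(segments, function(s)
    if (inherits(s, "stride_segment")) s$samples else as.numeric(s))
  if (length(sigs) != length(labels))
    stop("label mismatch: ", length(sigs), " segments vs ",
         length(labels), " labels")
  if (any(vapply(sigs, length, 1L) < 3L))
    stop("every segment needs >= 3 samples")
  stopifnot(length(split) == 3L, abs(sum(split) - 1) < 1e-8)
  X <- t(vapply(sigs, function(s) {
    if (length(s) == target_len) return(s)
    stats::approx(seq_along(s), s, n = target_len)$y
  }, numeric(target_len)))
  n <- nrow(X)
  if (!is.null(seed)) set.seed(seed)
  perm <- sample.int(n)
  n_train <- max(1L, round(split[1L] * n))
  n_val <- round(split[2L] * n)
  n_val <- min(n_val, n - n_train)
  tags <- rep("test", n)
  tags[perm[seq_len(n_train)]] <- "train"
  if (n_val > 0L) tags[perm[n_train + seq_len(n_val)]] <- "validation"
  tr <- tags == "train"
  x_mean <- mean(X[tr, , drop = FALSE])
  x_sd <- stats::sd(as.numeric(X[tr, , drop = FALSE]))
  if (!is.finite(x_sd) || x_sd == 0) x_sd <- 1
  y_mean <- mean(labels[tr])
  y_sd <- stats::sd(labels[tr])
  if (!is.finite(y_sd) || y_sd == 0) y_sd <- 1
  structure(list(X = X, y = as.numeric(labels),
                 split = factor(tags, c("train", "validation", "test")),
                 target_len = as.integer(target_len),
                 norm = list(x_mean = x_mean, x_sd = x_sd,
                             y_mean = y_mean, y_sd = y_sd)),
            class = "sequence_dataset")
}

#' @export
print.sequence_dataset <- function(x, ...) {
  cat(sprintf("<sequence_dataset> %d sequences x %d samples (%s)\n",
              nrow(x$X), x$target_len,
              paste(sprintf("%s %d", levels(x$split), table(x$split)),
                    collapse = ", ")))
  invisible(x)
}

#' Fit the LSTM stride-length regressor
#'
#' Trains the single-layer LSTM on the training split of a
#' [prepare_sequences()] dataset, minimizing the MSE between predicted and
#' reference stride lengths (both z-scored with training-split statistics).
#' Validation MSE is monitored every epoch; training stops early after
#' `early_stopping_patience` epochs without improvement and the
#' best-validation weights are restored. A fixed `seed` makes the whole
#' loss trajectory reproducible.
#'
#' @param ds A `sequence_dataset`.
#' @param cfg An [lstm_config()].
#' @return An object of class `stride_lstm` with elements `params`,
#'   `history` (per-epoch train/validation MSE on the normalized scale),
#'   `cfg`, `norm`, `target_len` and `best_epoch`.
#' @export
stride_lstm <- function(ds, cfg = lstm_config()) {
  stopifnot(inherits(ds, "sequence_dataset"), inherits(cfg, "lstm_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  tr <- which(ds$split == "train")
  va <- which(ds$split == "validation")
  Xn <- (ds$X - ds$norm$x_mean) / ds$norm$x_sd
  yn <- (ds$y - ds$norm$y_mean) / ds$norm$y_sd
  params <- lstm_init_params(cfg$hidden_units)
  model <- structure(list(params = params,
                          history = data.frame(epoch = integer(),
                                               train_mse = numeric(),
                                               val_mse = numeric()),
                          cfg = cfg, norm = ds$norm,
                          target_len = ds$target_len,
                          best_epoch = 0L),
                     class = "stride_lstm")
  if (cfg$max_epochs == 0L) return(model)
  if (length(tr) < 2L) stop("need >= 2 training sequences")
  opt <- adam_init(params)
  best <- list(loss = Inf, params = params, epoch = 0L)
  wait <- 0L
  hist <- vector("list", cfg$max_epochs)
  for (epoch in seq_len(cfg$max_epochs)) {
    perm <- tr[sample.int(length(tr))]
    nb <- ceiling(length(perm) / cfg$batch_size)
    for (bi in seq_len(nb)) {
      rows <- perm[((bi - 1L) * cfg$batch_size + 1L):
                     min(bi * cfg$batch_size, length(perm))]
      Xb <- Xn[rows, , drop = FALSE]
      mask <- NULL
      if (cfg$dropout_rate > 0) {
        keep <- 1 - cfg$dropout_rate
        mask <- matrix(stats::rbinom(cfg$hidden_units * length(rows), 1,
                                     keep) / keep,
                       cfg$hidden_units, length(rows))
      }
      fw <- lstm_forward(params, Xb, cache = TRUE, dropout_mask = mask)
      gr <- lstm_backward(params, fw, yn[rows], dropout_mask = mask)
      upd <- adam_step(params, gr, opt, cfg$learning_rate)
      params <- upd$params; opt <- upd$state
    }
    train_mse <- lstm_mse(params, Xn[tr, , drop = FALSE], yn[tr])
    val_mse <- if (length(va))
      lstm_mse(params, Xn[va, , drop = FALSE], yn[va]) else NA_real_
    hist[[epoch]] <- data.frame(epoch = epoch, train_mse = train_mse,
                                val_mse = val_mse)
    monitor <- if (length(va)) val_mse else train_mse
    if (monitor < best$loss - 1e-12) {
      best <- list(loss = monitor, params = params, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= cfg$early_stopping_patience) break
    }
  }
  model$params <- best$params
  model$best_epoch <- best$epoch
  model$history <- do.call(rbind, hist[!vapply(hist, is.null, TRUE)])
  model
}

#' Alias of [stride_lstm()] under the pipeline's operation name
#' @inheritParams stride_lstm
#' @export
train_model <- function(ds, cfg = lstm_config()) stride_lstm(ds, cfg)

#' @export
print.stride_lstm <- function(x, ...) {
  cat(sprintf(paste0("<stride_lstm> 1 LSTM layer, %d hidden units ->",
                     " linear readout\n  trained %d epochs (best %d),",
                     " final train MSE %s\n"),
              x$cfg$hidden_units, nrow(x$history), x$best_epoch,
              if (nrow(x$history))
                format(x$history$train_mse[nrow(x$history)], digits = 4)
              else "<untrained>"))
  invisible(x)
}

#' @export
summary.stride_lstm <- function(object, ...) {
  print(object)
  if (nrow(object$history)) {
    h <- object$history
    cat(sprintf("  best validation MSE %s at epoch %d\n",
                format(min(c(h$val_mse, Inf), na.rm = TRUE), digits = 4),
                object$best_epoch))
  }
  invisible(object)
}

#' @export
coef.stride_lstm <- function(object, ...) object$params

#' @export
plot.stride_lstm <- function(x, ...) {
  h <- x$history
  if (!nrow(h)) stop("untrained model: no history to plot")
  graphics::plot(h$epoch, h$train_mse, type = "l", log = "y",
                 xlab = "epoch", ylab = "MSE (normalized)", ...)
  if (any(is.finite(h$val_mse)))
    graphics::lines(h$epoch, h$val_mse, col = "firebrick")
  graphics::legend("topright", bty = "n", lty = 1,
                   col = c("black", "firebrick"),
                   legend = c("train", "validation"))
  invisible(x)
}

#' Predict stride lengths
#'
#' Runs the trained network over a dataset split (or a bare matrix of
#' resampled sequences), de-normalizes to meters and clips at zero.
#'
#' @param object A fitted [stride_lstm()] model.
#' @param ds A `sequence_dataset` or a numeric matrix with `target_len`
#'   columns.
#' @param split Which split to predict for (`"test"` default; `"all"` for
#'   every sequence). Ignored for matrix input.
#' @param ... Unused.
#' @return Numeric vector of predicted stride lengths (m), possibly empty.
#' @export
predict.stride_lstm <- function(object, ds,
                                split = c("test", "train", "validation",
                                          "all"), ...) {
  split <- match.arg(split)
  if (inherits(ds, "sequence_dataset")) {
    rows <- if (split == "all") seq_len(nrow(ds$X))
            else which(ds$split == split)
    X <- ds$X[rows, , drop = FALSE]
  } else {
    X <- as.matrix(ds)
  }
  if (!nrow(X)) return(numeric(0))
  if (ncol(X) != object$target_len)
    stop("sequence length ", ncol(X), " does not match the trained ",
         "configuration (", object$target_len, ")")
  Xn <- (X - object$norm$x_mean) / object$norm$x_sd
  yhat <- lstm_forward(object$params, Xn)$yhat
  pmax(yhat * object$norm$y_sd + object$norm$y_mean, 0)
}

#' @rdname predict.stride_lstm
#' @param model A fitted [stride_lstm()] model.
#' @export
predict_lengths <- function(model, ds, split = "test") {
  predict(model, ds, split = split)
}
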