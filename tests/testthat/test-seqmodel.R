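make_stride_ds <- function(n = 10, target_len = 50, seed = 1,
                           split = c(0.7, 0.15, 0.15),
                           fixed_duration = FALSE) {
  set.seed(seed)
  lens <- runif(n, 1.0, 1.4)
  segs <- lapply(lens, function(L)
    generate_stride_profile(L, if (fixed_duration) 1.0
                            else runif(1, 0.8, 1.2), 0.02))
  prepare_sequences(segs, lens, target_len = target_len, seed = seed,
                    split = split)
}

test_that("prepare_sequences resamples, splits and normalizes correctly", {
  set.seed(3)
  segs <- lapply(sample(40:60, 10, replace = TRUE), rnorm)
  labels <- runif(10, 1, 1.5)
  ds <- prepare_sequences(segs, labels, target_len = 50, seed = 1)
  expect_equal(dim(ds$X), c(10L, 50L))
  expect_equal(as.integer(table(ds$split)), c(7L, 2L, 1L))

  # a constant segment already at target length is unchanged
  segs2 <- c(segs, list(rep(1.5, 50)))
  ds2 <- prepare_sequences(segs2, c(labels, 1), target_len = 50, seed = 1)
  expect_equal(ds2$X[11L, ], rep(1.5, 50))

  expect_error(prepare_sequences(segs, labels[-1], target_len = 50),
               "label mismatch")
  expect_error(prepare_sequences(list(), numeric(0)), "no segments")
  expect_error(prepare_sequences(list(c(1, 2)), 1), ">= 3 samples")

  # normalization statistics come from the training split only
  tr <- ds$split == "train"
  expect_equal(ds$norm$x_mean, mean(ds$X[tr, ]))
  expect_equal(ds$norm$y_mean, mean(ds$y[tr]))
})

test_that("backpropagation matches numerical gradients", {
  set.seed(42)
  params <- stridekit:::lstm_init_params(3)
  X <- matrix(rnorm(2 * 5), 2, 5)
  y <- rnorm(2)
  fw <- stridekit:::lstm_forward(params, X, cache = TRUE)
  gr <- stridekit:::lstm_backward(params, fw, y)
  eps <- 1e-6
  for (nm in names(params)) {
    idx <- sample(seq_along(params[[nm]]), min(4, length(params[[nm]])))
    for (i in idx) {
      p2 <- params; p2[[nm]][i] <- p2[[nm]][i] + eps
      up <- stridekit:::lstm_mse(p2, X, y)
      p2[[nm]][i] <- p2[[nm]][i] - 2 * eps
      dn <- stridekit:::lstm_mse(p2, X, y)
      expect_equal(gr[[nm]][i], (up - dn) / (2 * eps), tolerance = 1e-5)
    }
  }
})

test_that("training is reproducible under a fixed seed", {
  ds <- make_stride_ds(n = 24, seed = 2)
  cfg <- lstm_config(hidden_units = 8, max_epochs = 5, batch_size = 8,
                     dropout_rate = 0.2, seed = 7)
  m1 <- stride_lstm(ds, cfg)
  m2 <- stride_lstm(ds, cfg)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params, m2$params)
})

test_that("test-split labels cannot leak into training", {
  ds <- make_stride_ds(n = 24, seed = 4)
  ds_perm <- ds
  te <- ds$split == "test"
  ds_perm$y[te] <- rev(ds_perm$y[te])
  cfg <- lstm_config(hidden_units = 8, max_epochs = 4, batch_size = 8,
                     seed = 9)
  m1 <- stride_lstm(ds, cfg)
  m2 <- stride_lstm(ds_perm, cfg)
  expect_identical(m1$params, m2$params)
})

test_that("max_epochs = 0 returns an untrained model with empty history", {
  ds <- make_stride_ds(n = 8, seed = 5)
  m <- stride_lstm(ds, lstm_config(hidden_units = 4, max_epochs = 0,
                                   seed = 1))
  expect_equal(nrow(m$history), 0L)
  expect_equal(m$best_epoch, 0L)
  expect_length(predict(m, ds, split = "all"), 8L)
})

test_that("an overfit model reproduces its training labels", {
  # fixed stride duration so the resampled input uniquely determines the
  # label (resampling erases absolute duration)
  ds <- make_stride_ds(n = 8, seed = 6, split = c(1, 0, 0),
                       fixed_duration = TRUE)
  cfg <- lstm_config(hidden_units = 12, learning_rate = 1e-2,
                     batch_size = 8, max_epochs = 250,
                     early_stopping_patience = 250, dropout_rate = 0,
                     seed = 3)
  m <- stride_lstm(ds, cfg)
  pred <- predict(m, ds, split = "train")
  expect_true(all(abs(pred - ds$y[ds$split == "train"]) / ds$y[ds$split == "train"]
                  < 0.05))
})

test_that("prediction guards splits and sequence lengths", {
  ds <- make_stride_ds(n = 12, seed = 8, split = c(0.9, 0.1, 0))
  m <- stride_lstm(ds, lstm_config(hidden_units = 4, max_epochs = 2,
                                   batch_size = 4, seed = 1))
  expect_length(predict(m, ds, split = "test"), 0L)
  expect_error(predict(m, matrix(0, 2, 30)), "does not match")
  expect_true(all(predict(m, ds, split = "all") >= 0))
  expect_error(stride_lstm(make_stride_ds(n = 2, seed = 1, split = c(0.5, 0.5, 0)),
                           lstm_config(hidden_units = 4, max_epochs = 1)),
               ">= 2 training")
})

test_that("an easily learnable mapping is learned to high accuracy", {
  # noiseless dataset whose label equals the mean of each sequence; a
  # closed-form regression on the sequence mean achieves R^2 ~ 1, and the
  # LSTM should come close
  set.seed(1)
  t <- seq_len(50)
  segs <- lapply(1:400, function(i)
    rnorm(1, 5, 1) + runif(1, 0.5, 1.5) * sin(2 * pi * t / 50 +
                                              runif(1, 0, 2 * pi)))
  labels <- vapply(segs, mean, numeric(1))
  ds <- prepare_sequences(segs, labels, target_len = 50, seed = 1)
  tr <- ds$split == "train"; te <- ds$split == "test"
  mu <- rowMeans(ds$X)
  oracle <- lm(y ~ mu, data = data.frame(y = ds$y, mu = mu),
               subset = which(tr))
  oracle_pred <- predict(oracle, newdata = data.frame(mu = mu[te]))
  expect_gt(regression_metrics(ds$y[te], oracle_pred)$r_squared, 0.999)

  m <- stride_lstm(ds, lstm_config(learning_rate = 5e-3, batch_size = 32,
                                   max_epochs = 150,
                                   early_stopping_patience = 30,
                                   dropout_rate = 0, seed = 1))
  expect_lte(nrow(m$history), 150L)
  r2 <- regression_metrics(ds$y[te], predict(m, ds, split = "test"))$r_squared
  expect_gt(r2, 0.9)
})
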