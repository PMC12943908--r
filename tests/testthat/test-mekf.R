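test_that("prediction follows the printed transition exactly", {
  cfg <- filter_config(Q = matrix(0, 3, 3))
  st <- filter_state(c(0, 0, 1), diag(3))
  expect_equal(kf_predict(st, cfg)$x, c(0, 0.02, 1))
  st2 <- filter_state(c(1, 2, 3), diag(3))
  expect_equal(kf_predict(st2, filter_config())$x, c(1.04, 2.06, 3))
  z0 <- filter_state(c(0, 0, 0), matrix(0, 3, 3))
  pred0 <- kf_predict(z0, cfg)
  expect_equal(pred0$x, c(0, 0, 0))
  expect_equal(pred0$P, matrix(0, 3, 3))
  # no 1/2*dt^2 coupling by default; present with full_ca_transition
  expect_equal(filter_config()$A[1, 3], 0)
  expect_equal(filter_config(full_ca_transition = TRUE)$A[1, 3], 2e-4)
})

test_that("measurement update matches the hand-evaluated gain", {
  prior <- filter_state(c(0, 0, 0), diag(3))
  post <- kf_update(prior, 2, filter_config(R = 1))
  expect_equal(post$x, c(0, 0, 1))
  # zero innovation leaves the mean alone
  prior2 <- filter_state(c(0.5, -0.2, 1.5), diag(3))
  post2 <- kf_update(prior2, 1.5, filter_config(R = 0.3))
  expect_equal(post2$x, prior2$x)
  # covariance stays symmetric PSD
  expect_lt(max(abs(post$P - t(post$P))), 1e-12)
  expect_gte(min(eigen(post$P, symmetric = TRUE)$values), -1e-10)
})

test_that("the amplify-mode boost limit forces the acceleration onto the measurement", {
  cfg <- filter_config(R = 0.05, boost_factor = Inf, boost_mode = "amplify")
  prior <- filter_state(c(0.3, -0.1, 1), diag(3))
  post <- kf_update(prior, 5, cfg, boosted = TRUE)
  expect_equal(post$x[3], 5, tolerance = 1e-12)
  # un-boosted update is unaffected by boost_factor
  post_plain <- kf_update(prior, 5, cfg, boosted = FALSE)
  ref <- kf_update(prior, 5, filter_config(R = 0.05), boosted = FALSE)
  expect_equal(post_plain$x, ref$x)
})

test_that("monotone trust: larger amplify factors track the measurement closer", {
  prior <- filter_state(c(0.2, 0.1, 0.4), diag(c(0.5, 0.5, 0.8)))
  z <- 3
  errs <- vapply(c(1, 2, 10, 100, 1e6), function(bf) {
    cfg <- filter_config(R = 0.1, boost_factor = bf, boost_mode = "amplify")
    abs(kf_update(prior, z, cfg, boosted = TRUE)$x[3] - z)
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-12))
})

test_that("zero-crossing detection is strict", {
  expect_true(detect_zero_crossing(0.2, -0.1))
  expect_false(detect_zero_crossing(0.3, 0.1))
  expect_false(detect_zero_crossing(0, -0.1))
  expect_false(detect_zero_crossing(0.1, 0))
})

test_that("sign-flip rule preserves magnitude and ignores zeros", {
  expect_equal(sign_flip_correct(-0.3, 0.5), 0.3)
  expect_equal(sign_flip_correct(0.3, 0.5), 0.3)
  expect_equal(sign_flip_correct(0, 0.5), 0)
  expect_equal(sign_flip_correct(0.4, -0.2), -0.4)
})

test_that("with modifications off the filter equals a textbook KF", {
  cfg <- filter_config(boost_factor = 1, boost_samples = 0,
                       sign_flip_enabled = FALSE)
  set.seed(5)
  for (rep in 1:5) {
    z <- rnorm(500, sd = 2)
    got <- run_mekf(z, cfg)$states
    ref <- textbook_kf(z, cfg$A, c(0, 0, 1), cfg$Q, cfg$R, cfg$x0, cfg$P0)
    expect_lt(max(abs(got - ref)), 1e-10)
  }
})

test_that("posterior acceleration converges to a constant measurement", {
  cfg <- filter_config(Q = 1e-4 * diag(3), R = 0.01, boost_samples = 0,
                       sign_flip_enabled = FALSE)
  fit <- run_mekf(rep(2.5, 600), cfg)
  expect_lt(abs(fit$states[500, "a"] - 2.5), 1e-6)
})

test_that("covariances stay symmetric PSD along noisy trajectories", {
  set.seed(6)
  fit <- run_mekf(rnorm(300), filter_config())
  for (k in c(1, 10, 100, 300)) {
    P <- fit$P[, , k]
    expect_lt(max(abs(P - t(P))), 1e-10)
    expect_gte(min(eigen(P, symmetric = TRUE)$values), -1e-8)
  }
})

test_that("emitted displacement never reverses sign when the rule is on", {
  set.seed(8)
  for (rep in 1:10) {
    fit <- run_mekf(rnorm(200), filter_config())
    p <- fit$states[, "p"]
    expect_true(all(p[-1] * p[-length(p)] >= 0))
  }
})

test_that("run_mekf guards degenerate input and stride extraction works", {
  expect_error(run_mekf(1.0), "at least 2")
  expect_error(run_mekf(numeric(0)), "at least 2")
  tr <- cbind(p = seq(0, 1.3, length.out = 50), v = 0, a = 0)
  expect_equal(stride_length_from_states(tr), 1.3)
  expect_equal(stride_length_from_states(cbind(p = rep(1, 10), v = 0, a = 0)),
               0)
  expect_error(stride_length_from_states(tr[1:2, ]), ">= 3")
  cfg2 <- filter_config(calibration = 2)
  expect_equal(stride_length_from_states(tr, cfg2), 2.6)
})

test_that("a noiseless synthetic stride is recovered by the filter", {
  prof <- generate_stride_profile(1.2, 1.0, 0.02)
  cfg <- filter_config(R = 1e-4)
  fit <- run_mekf(prof, cfg)
  expect_lt(abs(stride_length_from_states(fit, cfg) - 1.2), 0.05)
})

test_that("boost windows follow zero-crossings of the measurement", {
  z <- c(1, 1, -1, -1, -1, -1, -1, 1, 1, 1)
  fit <- run_mekf(z, filter_config(boost_samples = 2))
  expect_equal(which(fit$crossing), c(3L, 8L))
  expect_equal(which(fit$boosted), c(3L, 4L, 8L, 9L))
  fit0 <- run_mekf(z, filter_config(boost_samples = 0))
  expect_false(any(fit0$boosted))
})
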