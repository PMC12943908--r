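# Independent oracles used across the suite. Each deliberately avoids the
# package's own code paths.

# Least-squares cubic fit over an explicit window, evaluated at `at`,
# via lm() -- the brute-force route against which the fixed stencils and
# cubic_smooth are checked.
lsq_cubic_fit_at <- function(xs, offsets, at) {
  fit <- stats::lm(xs ~ poly(offsets, 3, raw = TRUE))
  as.numeric(predict(fit, newdata = data.frame(offsets = at)))
}

# Full brute-force smoother: per-position least-squares fits (symmetric
# interior windows, one-sided boundary windows).
brute_force_smooth <- function(x) {
  m <- length(x)
  y <- numeric(m)
  for (i in seq_len(m)) {
    if (i <= 2L) {
      y[i] <- lsq_cubic_fit_at(x[1:5], 0:4, i - 1L)
    } else if (i >= m - 1L) {
      y[i] <- lsq_cubic_fit_at(x[(m - 4L):m], 0:4, 4L - (m - i))
    } else {
      y[i] <- lsq_cubic_fit_at(x[(i - 2L):(i + 2L)], -2:2, 0L)
    }
  }
  y
}

# Textbook linear Kalman filter, written independently of run_mekf.
textbook_kf <- function(z, A, H, Q, R, x0, P0) {
  n <- length(z)
  out <- matrix(0, n, 3L)
  x <- x0; P <- P0
  for (k in seq_len(n)) {
    x <- A %*% x
    P <- A %*% P %*% t(A) + Q
    S <- as.numeric(H %*% P %*% H) + R
    K <- (P %*% H) / S
    x <- x + K * (z[k] - as.numeric(H %*% x))
    P <- (diag(3) - K %*% t(H)) %*% P
    out[k, ] <- x
  }
  out
}

# Trapezoidal double integration (displacement at the final sample),
# independent of the package's cumtrapz1.
trapz_double_integral <- function(a, dt) {
  v <- pracma::cumtrapz(a) * dt
  p <- pracma::cumtrapz(as.numeric(v)) * dt
  p[length(p)]
}

# Filtered per-stride input sequences for the LSTM comparison.
filtered_segments <- function(signal, events, mode, fcfg = filter_config()) {
  pre <- cubic_smooth(wavelet_denoise(signal))
  cfg <- switch(mode,
                ekf = filter_config(boost_factor = 1, boost_samples = 0,
                                    sign_flip_enabled = FALSE),
                mekf = fcfg)
  lapply(segment_strides(pre, events), function(s) {
    run_mekf(s$samples, cfg)$states[, "a"]
  })
}

raw_segments <- function(signal, events) {
  lapply(segment_strides(signal, events), function(s) s$samples)
}
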