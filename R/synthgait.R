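#' Synthetic gait-signal configuration
#'
#' Study conditions for the synthetic walking generator: quasi-periodic
#' foot acceleration with exactly known per-stride displacement, additive
#' zero-mean Gaussian sensor noise and an impact-like transient at each
#' stride start (heel strike). Defaults emulate steady treadmill walking at
#' 50 Hz.
#'
#' @param n_strides Number of strides (>= 1).
#' @param stride_length_mean,stride_length_sd Stride-length Normal (m);
#'   draws are truncated below at 0.2 m to avoid degenerate strides.
#' @param stride_duration_mean,stride_duration_sd Stride-duration Normal
#'   (s); must satisfy `stride_duration_mean >= 10 * dt`.
#' @param dt Sampling interval (s), default 0.02.
#' @param noise_sd Measurement-noise standard deviation (m/s^2) added to
#'   the measurement channel.
#' @param impact_amplitude Heel-strike transient amplitude (m/s^2) added at
#'   each stride start.
#' @param seed Integer RNG seed (NULL leaves the RNG state alone).
#' @return An object of class `synth_gait_config`.
#' @export
synth_gait_config <- function(n_strides = 100L,
                              stride_length_mean = 1.2,
                              stride_length_sd = 0.1,
                              stride_duration_mean = 1.0,
                              stride_duration_sd = 0.03,
                              dt = 0.02,
                              noise_sd = 0.3,
                              impact_amplitude = 15,
                              seed = NULL) {
  if (n_strides < 1L) stop("n_strides must be >= 1")
  if (stride_length_sd < 0 || stride_duration_sd < 0 || noise_sd < 0)
    stop("standard deviations must be >= 0")
  if (dt <= 0) stop("dt must be > 0")
  if (stride_duration_mean < 10 * dt)
    stop("stride_duration_mean must be >= 10 * dt")
  structure(list(n_strides = as.integer(n_strides),
                 stride_length_mean = stride_length_mean,
                 stride_length_sd = stride_length_sd,
                 stride_duration_mean = stride_duration_mean,
                 stride_duration_sd = stride_duration_sd,
                 dt = dt, noise_sd = noise_sd,
                 impact_amplitude = impact_amplitude,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "synth_gait_config")
}

#' Analytic single-stride acceleration profile
#'
#' One full-period sinusoid `a(t) = A * sin(2*pi*t / T)` sampled at `dt`
#' over `t = 0..T` inclusive (`T` rounded to a whole number of samples),
#' with amplitude `A = 2*pi*length / T^2`. In closed form the velocity
#' `v(t) = (A/omega) * (1 - cos(omega t))` returns exactly to its initial
#' value at the stride end (cyclic gait) and the displacement
#' `integral of v` over `[0, T]` equals `length` exactly, so the
#' construction provides analytic ground truth for every downstream stage.
#'
#' @param length True stride displacement (m); 0 gives an all-zero profile.
#' @param duration Stride duration (s), >= `10 * dt`.
#' @param dt Sampling interval (s).
#' @return Numeric vector of `round(duration/dt) + 1` acceleration samples.
#' @export
generate_stride_profile <- function(length, duration, dt = 0.02) {
  if (duration < 10 * dt) stop("duration too short: need >= 10 * dt")
  n <- as.integer(round(duration / dt))
  Tn <- n * dt
  t <- (0:n) * dt
  if (length == 0) return(numeric(n + 1L))
  A <- 2 * pi * length / Tn^2
  A * sin(2 * pi * t / Tn)
}

#' Generate a synthetic walking record
#'
#' Concatenates `n_strides` analytic stride profiles with lengths and
#' durations drawn from the configured Normals (lengths truncated at 0.2 m,
#' durations at `10*dt`), adds the heel-strike transient at each stride
#' start and i.i.d. Gaussian noise to the measurement channel (`az`); `ax`
#' and `ay` carry low-amplitude correlated filler. Consecutive strides
#' share their boundary sample (the profile is zero there), so the record
#' has `sum(per-stride samples) + 1` samples and the event indices mark the
#' exact stride starts plus the terminal end index. Identical seeds
#' reproduce identical output bit for bit.
#'
#' @param cfg A [synth_gait_config()].
#' @return A list with `seq` ([imu_sequence]), `events` ([stride_events];
#'   `n_strides + 1` 0-based indices) and `true_lengths` (numeric, m).
#' @export
generate_walk <- function(cfg = synth_gait_config()) {
  stopifnot(inherits(cfg, "synth_gait_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- cfg$n_strides
  lengths <- pmax(stats::rnorm(n, cfg$stride_length_mean,
                               cfg$stride_length_sd), 0.2)
  durations <- pmax(stats::rnorm(n, cfg$stride_duration_mean,
                                 cfg$stride_duration_sd), 10 * cfg$dt)
  n_i <- pmax(as.integer(round(durations / cfg$dt)), 10L)
  total <- sum(n_i) + 1L
  az <- numeric(total)
  starts <- cumsum(c(0L, n_i))          # 0-based stride starts + terminal
  for (i in seq_len(n)) {
    prof <- generate_stride_profile(lengths[i], n_i[i] * cfg$dt, cfg$dt)
    # drop the shared trailing boundary sample except for the last stride
    sl <- (starts[i] + 1L):(starts[i] + n_i[i])
    az[sl] <- prof[seq_len(n_i[i])]
  }
  # heel-strike transient: damped high-frequency ring at each stride start.
  # The pattern has zero net (discrete) area: an impact artifact is sensor
  # ringing, not real motion, so it must not change the true displacement
  # the labels encode -- but it does corrupt naive double integration.
  if (cfg$impact_amplitude != 0) {
    ring <- cfg$impact_amplitude * c(1, -1, 0.5, -0.5)
    for (i in seq_len(n)) {
      at <- starts[i] + 1L
      keep <- seq_len(min(length(ring), total - at + 1L))
      az[at + keep - 1L] <- az[at + keep - 1L] + ring[keep]
    }
  }
  if (cfg$noise_sd > 0)
    az <- az + stats::rnorm(total, 0, cfg$noise_sd)
  # off-axis filler: low-amplitude AR(1) wander, clearly sub-gait scale
  ar_filler <- function(total) {
    e <- stats::rnorm(total, 0, 0.1)
    as.numeric(stats::filter(e, 0.95, method = "recursive"))
  }
  seq <- imu_sequence(ax = ar_filler(total), ay = ar_filler(total), az = az,
                      dt = cfg$dt)
  list(seq = seq,
       events = stride_events(starts, total),
       true_lengths = lengths)
}
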