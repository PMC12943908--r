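# Daubechies db4 (8-tap, 4 vanishing moments) scaling filter, full precision.
# Satisfies sum(h) = sqrt(2) and the orthonormality relations
# sum_m h[m] h[m + 2k] = delta_k; both are asserted in the test suite.
DB4_SCALING <- c(
   0.23037781330889650,
   0.71484657055291570,
   0.63088076792985890,
  -0.02798376941685985,
  -0.18703481171909309,
   0.03084138183556076,
   0.03288301166688520,
  -0.01059740178506903)

# Quadrature-mirror high-pass companion of an orthogonal scaling filter.
qmf_highpass <- function(h) {
  L <- length(h)
  g <- rev(h) * (-1)^(seq_len(L) - 1L)
  g
}

#' Wavelet denoising configuration
#'
#' @param wavelet_name Wavelet family; only `"db4"` (Daubechies, 4 vanishing
#'   moments, 8 taps) is provided.
#' @param levels Decomposition depth; `NULL` picks
#'   `min(4, max admissible)` where the maximum admissible depth for a
#'   signal of length n and filter length L is `floor(log2(n / (L - 1)))`.
#' @param threshold_rule One of `"universal_soft"` (default),
#'   `"universal_hard"`, `"none"`. The universal threshold is
#'   `sigma * sqrt(2 * log(n))` with `sigma = MAD(finest details) / 0.6745`.
#' @param padding_mode Boundary extension used to bring the signal to a
#'   dyadic-friendly length: `"symmetric"` (default), `"periodic"`, `"zero"`.
#' @return An object of class `wavelet_config`.
#' @export
wavelet_config <- function(wavelet_name = "db4", levels = NULL,
                           threshold_rule = c("universal_soft",
                                              "universal_hard", "none"),
                           padding_mode = c("symmetric", "periodic",
                                            "zero")) {
  if (!identical(wavelet_name, "db4"))
    stop("only the db4 wavelet is provided")
  threshold_rule <- match.arg(threshold_rule)
  padding_mode <- match.arg(padding_mode)
  if (!is.null(levels)) {
    levels <- as.integer(levels)
    if (levels < 1L) stop("levels must be >= 1")
  }
  structure(list(wavelet_name = wavelet_name, levels = levels,
                 threshold_rule = threshold_rule,
                 padding_mode = padding_mode),
            class = "wavelet_config")
}

wavelet_max_levels <- function(n, filter_len = 8L) {
  if (n < filter_len) return(0L)
  as.integer(floor(log2(n / (filter_len - 1))))
}

# Extend x to length N using the configured boundary rule. The transform
# is periodized (circular), so padding is split across both ends: with
# one-sided padding the head of the data would circularly abut an
# unrelated sample and the boundary artifact would land inside the signal.
# Returns the padded vector and the offset of the original data.
extend_signal <- function(x, N, mode) {
  n <- length(x)
  if (N == n) return(list(s = x, offset = 0L))
  pad_left <- (N - n) %/% 2L
  pad_right <- N - n - pad_left
  take_last <- function(v, k) if (k == 0L) numeric(0) else v[(length(v) - k + 1L):length(v)]
  ext <- switch(mode,
    symmetric = {
      # whole-sample reflection at each end, repeated if the pad is
      # longer than the signal itself
      runL <- numeric(0)
      while (length(runL) < pad_left) runL <- c(rev(x), x, runL)
      runR <- numeric(0)
      while (length(runR) < pad_right) runR <- c(runR, rev(x), x)
      c(take_last(runL, pad_left), x, runR[seq_len(pad_right)])
    },
    periodic = c(take_last(rep_len(x, n + pad_left), pad_left), x,
                 rep_len(x, pad_right)),
    zero = c(numeric(pad_left), x, numeric(pad_right)))
  list(s = ext, offset = pad_left)
}

# One analysis step of the periodized orthogonal filter bank.
# s has even length M >= filter length; returns list(a, d) of length M/2.
dwt_step <- function(s, h, g) {
  M <- length(s)
  K <- M %/% 2L
  a <- numeric(K); d <- numeric(K)
  base <- 2L * (seq_len(K) - 1L)
  for (m in seq_along(h)) {
    idx <- (base + m - 1L) %% M + 1L
    a <- a + h[m] * s[idx]
    d <- d + g[m] * s[idx]
  }
  list(a = a, d = d)
}

# Transpose (= inverse, by orthogonality) of dwt_step.
idwt_step <- function(a, d, h, g) {
  K <- length(a)
  M <- 2L * K
  s <- numeric(M)
  base <- 2L * (seq_len(K) - 1L)
  for (m in seq_along(h)) {
    idx <- (base + m - 1L) %% M + 1L
    s[idx] <- s[idx] + h[m] * a + g[m] * d
  }
  s
}

#' Multilevel db4 wavelet decomposition (periodized, orthogonal)
#'
#' The signal is boundary-extended to a multiple of `2^levels` and analysed
#' with the periodized orthogonal db4 filter bank; because the analysis
#' operator is orthonormal, reconstruction by its transpose is exact to
#' machine precision.
#'
#' @param x Numeric vector.
#' @param levels Decomposition depth.
#' @param padding_mode Boundary extension rule (see [wavelet_config()]).
#' @return A list with the coarse approximation `a`, the per-level detail
#'   coefficients `d` (finest first), the original length `n` and `levels`.
#' @export
wavelet_decompose <- function(x, levels, padding_mode = "symmetric") {
  x <- as.numeric(x)
  n <- length(x)
  h <- DB4_SCALING
  g <- qmf_highpass(h)
  maxlev <- wavelet_max_levels(n, length(h))
  if (maxlev < 1L) stop("signal too short for the db4 filter support")
  if (levels > maxlev)
    stop("requested levels (", levels, ") exceed admissible maximum (",
         maxlev, ") for length ", n)
  block <- 2L^levels
  N <- block * ceiling(n / block)
  ext <- extend_signal(x, N, padding_mode)
  s <- ext$s
  details <- vector("list", levels)
  for (j in seq_len(levels)) {
    st <- dwt_step(s, h, g)
    details[[j]] <- st$d
    s <- st$a
  }
  list(a = s, d = details, n = n, levels = levels, N = N,
       offset = ext$offset)
}

#' @rdname wavelet_decompose
#' @param dec A decomposition as returned by [wavelet_decompose()].
#' @export
wavelet_reconstruct <- function(dec) {
  h <- DB4_SCALING
  g <- qmf_highpass(h)
  s <- dec$a
  for (j in rev(seq_len(dec$levels)))
    s <- idwt_step(s, dec$d[[j]], h, g)
  s[dec$offset + seq_len(dec$n)]
}

#' Wavelet denoising of a 1-D signal
#'
#' Multilevel db4 decomposition, per-level thresholding of the detail
#' coefficients, and reconstruction to the original length. With
#' `threshold_rule = "none"` the round trip is an identity (perfect
#' reconstruction). The noise scale is estimated robustly from the finest
#' detail level as `MAD / 0.6745` and the universal threshold
#' `sigma * sqrt(2 * log(n))` is applied at every level, by soft shrinkage
#' (default) or hard cutting.
#'
#' @param x Numeric vector (length >= 8, the db4 filter support).
#' @param cfg A [wavelet_config()].
#' @return Denoised numeric vector, same length as `x`.
#' @export
wavelet_denoise <- function(x, cfg = wavelet_config()) {
  stopifnot(inherits(cfg, "wavelet_config"))
  x <- as.numeric(x)
  n <- length(x)
  maxlev <- wavelet_max_levels(n)
  if (maxlev < 1L) stop("signal too short for the db4 filter support")
  levels <- if (is.null(cfg$levels)) min(4L, maxlev) else cfg$levels
  dec <- wavelet_decompose(x, levels, cfg$padding_mode)
  if (cfg$threshold_rule != "none") {
    finest <- dec$d[[1L]]
    sigma <- stats::median(abs(finest)) / 0.6745
    lambda <- sigma * sqrt(2 * log(dec$N))
    for (j in seq_len(levels)) {
      d <- dec$d[[j]]
      dec$d[[j]] <- if (cfg$threshold_rule == "universal_soft")
        sign(d) * pmax(abs(d) - lambda, 0)
      else
        d * (abs(d) > lambda)
    }
  }
  wavelet_reconstruct(dec)
}
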