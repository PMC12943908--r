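#' Derive the five-point local cubic least-squares stencils
#'
#' A cubic polynomial p(k) = a0 + a1*k + a2*k^2 + a3*k^3 is fitted by least
#' squares to five consecutive samples; evaluating the fit at a fixed offset
#' yields a fixed convolution stencil. The interior stencil evaluates the
#' symmetric fit (offsets k = -2..2) at the window centre k = 0; because the
#' odd-degree terms vanish at the centre of a symmetric window it coincides
#' with the classical quadratic/cubic Savitzky-Golay smoother
#' `[-3, 12, 17, 12, -3] / 35`. At the end of the signal no symmetric window
#' exists, so the last two samples use one-sided fits over offsets k = 0..4
#' evaluated at k = 3 (next-to-last) and k = 4 (last); the first two samples
#' use the index-mirrored counterparts.
#'
#' All stencils are rows of a least-squares projection ("hat") matrix, so
#' each sums to 1 (constants are preserved) and every polynomial of degree
#' <= 3 is reproduced exactly.
#'
#' @return An object of class `smoother_stencils`: a list with numeric
#'   5-vectors `interior`, `boundary_next_to_last`, `boundary_last`,
#'   `boundary_first`, `boundary_second`.
#' @export
derive_cubic_stencils <- function() {
  hat_row <- function(offsets, at) {
    X <- outer(offsets, 0:3, `^`)
    x0 <- as.numeric(outer(at, 0:3, `^`))
    # row of the hat matrix for evaluation point `at`
    as.numeric(x0 %*% solve(crossprod(X), t(X)))
  }
  interior <- hat_row(-2:2, 0)
  b_next <- hat_row(0:4, 3)
  b_last <- hat_row(0:4, 4)
  structure(list(interior = interior,
                 boundary_next_to_last = b_next,
                 boundary_last = b_last,
                 # start of the signal, handled by index mirroring
                 boundary_first = rev(b_last),
                 boundary_second = rev(b_next)),
            class = "smoother_stencils")
}

#' Five-point local cubic least-squares smoothing
#'
#' One-pass convolution smoother: interior samples use the symmetric
#' five-point stencil, the two samples at each end use the one-sided
#' boundary stencils from [derive_cubic_stencils()]. The output has the
#' same length as the input; the operation is linear and reproduces any
#' sampled polynomial of degree <= 3 exactly (including at the boundaries).
#'
#' @param x Numeric vector, length >= 5.
#' @param stencils Optional precomputed [derive_cubic_stencils()] result.
#' @return Numeric vector of the same length as `x`.
#' @export
cubic_smooth <- function(x, stencils = derive_cubic_stencils()) {
  x <- as.numeric(x)
  m <- length(x)
  if (m < 5L) stop("need >= 5 samples for the five-point smoother")
  y <- as.numeric(stats::filter(x, stencils$interior, sides = 2))
  y[1L] <- sum(stencils$boundary_first * x[1:5])
  y[2L] <- sum(stencils$boundary_second * x[1:5])
  y[m - 1L] <- sum(stencils$boundary_next_to_last * x[(m - 4L):m])
  y[m] <- sum(stencils$boundary_last * x[(m - 4L):m])
  y
}
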