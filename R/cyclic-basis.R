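# Periodic spline basis on the weekly circle (circumference 7) with a
# circulant difference penalty. Day-of-week coefficient curves are linear
# combinations of these basis functions, so estimates at Sunday and Saturday
# are smoothly tied together rather than treated as interval endpoints.

#' Cyclic B-spline basis on the day-of-week circle
#'
#' Evaluates \code{K} wrapped cubic B-splines with uniformly spaced knots on a
#' circle of circumference 7 at the (possibly fractional) day-of-week values
#' \code{d}. The basis is a partition of unity, so a constant coefficient
#' curve is exactly representable, and it is 7-periodic by construction:
#' \code{cyclic_basis(d) == cyclic_basis(d + 7)}.
#'
#' At \code{K = 7} the matrix evaluated at \code{d = 1:7} is a nonsingular
#' circulant, so the basis spans every function on the seven week days (the
#' saturated, unpenalized escape hatch).
#'
#' @param d numeric vector of day-of-week values (1 = Sunday ... 7 = Saturday;
#'   any real value is wrapped)
#' @param K number of basis functions (>= 3)
#' @return numeric matrix, \code{length(d)} rows by \code{K} columns
#' @export
cyclic_basis <- function(d, K = 5) {
  stopifnot(is.numeric(d), length(K) == 1L, K >= 3, K == round(K))
  h <- 7 / K
  # offset of each d from each basis centre, in knot units, wrapped to [0, K)
  u <- outer(d / h, seq_len(K) - 1, "-") %% K
  B <- bspline3(u) + bspline3(u - K)
  dimnames(B) <- NULL
  B
}

# cardinal cubic B-spline centred at 0, support (-2, 2)
bspline3 <- function(t) {
  t <- abs(t)
  out <- numeric(length(t))
  i1 <- t < 1
  i2 <- !i1 & t < 2
  out[i1] <- (4 - 6 * t[i1]^2 + 3 * t[i1]^3) / 6
  out[i2] <- (2 - t[i2])^3 / 6
  dim(out) <- dim(t)
  out
}

#' Circulant difference penalty for the cyclic basis
#'
#' Returns \eqn{S = D'D} where \code{D} is the cyclic (wrap-around) difference
#' operator of the requested order on the \code{K} basis coefficients. The
#' penalty has rank \code{K - 1}; its null space is the constant curve, so the
#' overall level of each coefficient curve is never shrunk, only its
#' within-week variation.
#'
#' @param K number of basis coefficients
#' @param order difference order (default 2)
#' @return \code{K x K} penalty matrix
#' @export
cyclic_penalty <- function(K, order = 2) {
  stopifnot(K >= 3, order >= 1)
  D1 <- diag(-1, K)
  D1[cbind(seq_len(K), c(seq_len(K - 1) + 1L, 1L))] <- 1
  D <- diag(K)
  for (i in seq_len(order)) D <- D1 %*% D
  crossprod(D)
}
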