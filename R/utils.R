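# Shared helpers: validation, Fisher z, upper-triangle vectorisation.

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

check_scalar <- function(x, name, positive = FALSE, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("`%s` must be a single finite number", name)
  if (positive && x <= 0) stopf("`%s` must be positive (got %g)", name, x)
  if (integer && x != round(x)) stopf("`%s` must be an integer (got %g)", name, x)
  invisible(x)
}

is_symmetric_matrix <- function(m, tol = 1e-8) {
  is.matrix(m) && nrow(m) == ncol(m) && max(abs(m - t(m))) <= tol * max(1, max(abs(m)))
}

check_spd <- function(m, name = "covariance", tol = 1e-10) {
  if (!is_symmetric_matrix(m)) stopf("`%s` must be a symmetric matrix", name)
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= tol * max(abs(ev)))
    stopf("`%s` is not positive-definite (min eigenvalue %g)", name, min(ev))
  invisible(m)
}

#' Fisher r-to-z transformation
#'
#' Variance-stabilising `atanh` transform of correlation coefficients.
#' Errors on |r| = 1 (the transform diverges).
#'
#' @param r numeric vector or matrix of correlations in (-1, 1).
#' @return `atanh(r)`, same shape as the input.
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1 - 1e-15, na.rm = TRUE))
    stopf("Fisher z undefined: |r| = 1 encountered")
  atanh(r)
}

#' Vectorise the strict upper triangle of a symmetric matrix
#'
#' Row-major order (edge (1,2), (1,3), ..., (1,N), (2,3), ...), so that
#' centroids can be re-folded to matrices with [unfold_upper_tri()].
#'
#' @param m square matrix.
#' @return numeric vector of length N(N-1)/2.
#' @export
vec_upper_tri <- function(m) {
  t(m)[lower.tri(m)]
}

#' Re-fold an upper-triangle vector into a symmetric matrix
#'
#' Inverse of [vec_upper_tri()]; the diagonal is set to `diag_value`.
#'
#' @param v vector of length N(N-1)/2.
#' @param n matrix dimension N.
#' @param diag_value value placed on the diagonal (default 0).
#' @return symmetric N x N matrix.
#' @export
unfold_upper_tri <- function(v, n, diag_value = 0) {
  if (length(v) != n * (n - 1) / 2)
    stopf("length %d does not match n = %d (need %d)", length(v), n, n * (n - 1) / 2)
  m <- matrix(diag_value, n, n)
  m[lower.tri(m)] <- v
  m <- t(m)
  m[lower.tri(m)] <- v
  m
}

# indices (i, j) of the row-major strict upper triangle, as a 2-column matrix
upper_tri_index <- function(n) {
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
}
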