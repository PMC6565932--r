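#' Test a symmetric matrix for positive definiteness
#'
#' Attempts a Cholesky factorisation and requires every pivot to exceed
#' `tol`.  This is the package-wide PD certificate: an MCMC state or a
#' simulated precision matrix is accepted only if it passes.
#'
#' @param m Square symmetric numeric matrix.
#' @param tol Minimum acceptable Cholesky pivot (default `1e-10`).
#' @return `TRUE` or `FALSE`.
#' @export
is_positive_definite <- function(m, tol = 1e-10) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop("`m` must be a square matrix", call. = FALSE)
  }
  ch <- tryCatch(chol(m), error = function(e) NULL)
  if (is.null(ch)) return(FALSE)
  min(diag(ch)) > tol
}

#' Partial correlations from a precision matrix
#'
#' Normalises a positive-definite precision matrix to the partial-correlation
#' scale: `P[i, j] = -omega[i, j] / sqrt(omega[i, i] * omega[j, j])` off the
#' diagonal, with unit diagonal.  Partial correlations are the package's
#' measure of conditional (direct) association between two nodes.
#'
#' @param omega Symmetric positive-definite precision matrix.
#' @return Symmetric matrix with unit diagonal and entries in `[-1, 1]`.
#' @export
partial_correlation <- function(omega) {
  if (!is_positive_definite(omega)) {
    stop("`omega` must be symmetric positive definite", call. = FALSE)
  }
  d <- sqrt(diag(omega))
  p <- -omega / tcrossprod(d)
  diag(p) <- 1
  dimnames(p) <- dimnames(omega)
  p
}

#' Partition a precision matrix (and its inner products) about one column
#'
#' Splits `omega` into the principal minor with row/column `j` deleted, the
#' off-diagonal part of column `j`, and the diagonal entry, and applies the
#' same partition to the inner-product matrix `s`.  This is the partition
#' underlying the column-wise Gibbs sweep; any column can play the role of
#' the "last" column after permutation.
#'
#' @param omega p x p symmetric matrix.
#' @param s p x p symmetric inner-product matrix (same partition applied).
#' @param j Column index in `1:p`.
#' @return List with `omega11` ((p-1) x (p-1)), `omega12` (length p-1),
#'   `omega22` (scalar), `s12`, `s22`.
#' @export
partition_column <- function(omega, s, j) {
  p <- nrow(omega)
  if (j < 1 || j > p) stop("column index out of range", call. = FALSE)
  keep <- setdiff(seq_len(p), j)
  list(
    omega11 = omega[keep, keep, drop = FALSE],
    omega12 = omega[keep, j],
    omega22 = omega[j, j],
    s12 = s[keep, j],
    s22 = s[j, j]
  )
}

#' Reassemble a precision matrix from a column decomposition
#'
#' Inverts [partition_column()]: given the principal minor, the off-diagonal
#' column `u` and the Schur complement `nu`, rebuilds the full matrix with
#' the diagonal entry `nu + u' omega11^{-1} u`.  When `omega11` is positive
#' definite and `nu > 0`, the result is positive definite by the Schur
#' complement argument — the property that keeps every Gibbs update inside
#' the positive-definite cone.
#'
#' @param omega11 (p-1) x (p-1) symmetric positive-definite matrix.
#' @param u Numeric vector of length p-1 (new off-diagonal column).
#' @param nu Positive scalar Schur complement.
#' @param j Index at which the column is re-inserted (default last).
#' @return p x p symmetric positive-definite matrix.
#' @export
reassemble_column <- function(omega11, u, nu, j = nrow(omega11) + 1L) {
  if (nu <= 0) stop("`nu` must be strictly positive", call. = FALSE)
  m <- nrow(omega11)
  omega22 <- nu + drop(crossprod(u, solve(omega11, u)))
  out <- matrix(0, m + 1L, m + 1L)
  keep <- setdiff(seq_len(m + 1L), j)
  out[keep, keep] <- omega11
  out[keep, j] <- u
  out[j, keep] <- u
  out[j, j] <- omega22
  out
}

#' Nearest positive-definite repair
#'
#' Projects a symmetric matrix onto the set of symmetric matrices whose
#' minimum eigenvalue is at least `epsilon`, by clipping the eigenvalues of
#' the symmetrised input.  This is the Frobenius-nearest such matrix, and is
#' used by the simulators to repair indefinite draws.
#'
#' @param m Symmetric numeric matrix.
#' @param epsilon Target minimum eigenvalue (default `1e-8`).
#' @return Symmetric matrix with smallest eigenvalue `>= epsilon`.
#' @export
nearest_pd <- function(m, epsilon = 1e-8) {
  m <- (m + t(m)) / 2
  e <- eigen(m, symmetric = TRUE)
  if (min(e$values) >= epsilon) return(m)
  v <- pmax(e$values, epsilon)
  out <- e$vectors %*% (v * t(e$vectors))
  (out + t(out)) / 2
}
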