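# Internal numerical helpers shared across modules.

# Symmetrize a nearly-symmetric matrix (guards against floating-point drift
# after products like S %*% A %*% S).
.symmetrize <- function(A) (A + t(A)) / 2

.check_square <- function(A, name = deparse(substitute(A))) {
  if (!is.matrix(A) || nrow(A) != ncol(A))
    stop(sprintf("'%s' must be a square matrix", name), call. = FALSE)
  if (max(abs(A - t(A))) > 1e-8 * max(1, max(abs(A))))
    stop(sprintf("'%s' must be symmetric", name), call. = FALSE)
  invisible(A)
}

# Symmetric inverse square root via eigen-decomposition.  Used instead of a
# Cholesky factor so that the induced inner product treats the orthogonality
# constraints symmetrically.  Eigenvalues below tol * max(eigenvalue) are an
# error: the caller needs an invertible matrix.
.sym_inv_sqrt <- function(A, tol = 1e-12) {
  e <- eigen(.symmetrize(A), symmetric = TRUE)
  if (min(e$values) <= tol * max(abs(e$values)))
    stop("matrix is numerically singular; apply a positive-definite repair first (see repair_psd)",
         call. = FALSE)
  e$vectors %*% (t(e$vectors) / sqrt(e$values))
}

#' Repair a covariance matrix to be positive (semi-)definite
#'
#' Symmetric eigen-decomposition with eigenvalues clipped from below at
#' \code{eps}, then reconstruction.  When \code{rescale_diag} is \code{TRUE}
#' the repaired matrix is rescaled so its diagonal matches the original
#' (positive) diagonal, preserving per-trait variances while fixing only the
#' correlation structure.
#'
#' @param A symmetric matrix.
#' @param eps lower bound imposed on eigenvalues (default 0).
#' @param rescale_diag restore the original diagonal after clipping.
#' @return repaired symmetric matrix with attribute \code{"max_shift"}, the
#'   largest absolute eigenvalue change applied.
#' @export
repair_psd <- function(A, eps = 0, rescale_diag = FALSE) {
  .check_square(A)
  e <- eigen(.symmetrize(A), symmetric = TRUE)
  lam <- pmax(e$values, eps)
  out <- .symmetrize(e$vectors %*% (t(e$vectors) * lam))
  if (rescale_diag && all(diag(A) > 0)) {
    s <- sqrt(diag(A) / pmax(diag(out), .Machine$double.eps))
    out <- out * tcrossprod(s)
  }
  attr(out, "max_shift") <- max(abs(lam - e$values))
  out
}

# Lower Cholesky factor tolerant of PSD (rank-deficient) input: falls back to
# an eigen square root with a small jitter when chol() fails.
.psd_chol <- function(A, jitter = 1e-10) {
  L <- tryCatch(t(chol(A)), error = function(e) NULL)
  if (is.null(L)) {
    e <- eigen(.symmetrize(A), symmetric = TRUE)
    if (min(e$values) < -1e-8 * max(abs(e$values), 1))
      stop("matrix is not positive semi-definite", call. = FALSE)
    L <- e$vectors %*% diag(sqrt(pmax(e$values, 0) + jitter), nrow(A))
  }
  L
}

# Draw n iid rows from N(0, Sigma); returns n x K matrix.  Zero Sigma gives
# exact zeros.
.rmvnorm <- function(n, Sigma) {
  K <- nrow(Sigma)
  if (all(Sigma == 0)) return(matrix(0, n, K))
  matrix(stats::rnorm(n * K), n, K) %*% t(.psd_chol(Sigma))
}

# Derive independent sub-stream seeds from one master seed so that individual
# simulation components can be regenerated on their own.
.sub_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  s <- sample.int(.Machine$integer.max - 1L, n)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  s
}
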