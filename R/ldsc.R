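# Cross-trait LD-score regression: genetic covariance from regression
# slopes, sampling covariance of effect estimates from regression
# intercepts.

# Weighted least squares of y on x, optionally with delete-block jackknife
# standard errors computed from blockwise sufficient statistics.
.wls_jack <- function(x, y, w, n_blocks = 200, jackknife = TRUE) {
  n <- length(x)
  fit <- function(Sw, Sx, Sy, Sxx, Sxy) {
    den <- Sw * Sxx - Sx^2
    slope <- (Sw * Sxy - Sx * Sy) / den
    unname(c(slope, (Sy - slope * Sx) / Sw))
  }
  X <- cbind(w, w * x, w * y, w * x^2, w * x * y)
  if (!jackknife) {
    s <- colSums(X)
    f <- fit(s[1], s[2], s[3], s[4], s[5])
    return(list(slope = f[1], intercept = f[2],
                se_slope = NA_real_, se_intercept = NA_real_))
  }
  n_blocks <- max(2L, min(n_blocks, n %/% 2L))
  grp <- ceiling(seq_len(n) * (n_blocks / n))
  B <- rowsum(X, grp, reorder = FALSE)
  tot <- colSums(B)
  full <- fit(tot[1], tot[2], tot[3], tot[4], tot[5])
  g <- nrow(B)
  D <- sweep(-B, 2, tot, "+")  # delete-one-block sums
  jk <- vapply(seq_len(g), function(i)
    fit(D[i, 1], D[i, 2], D[i, 3], D[i, 4], D[i, 5]), numeric(2))
  se <- sqrt((g - 1) / g * rowSums((jk - rowMeans(jk))^2))
  list(slope = full[1], intercept = full[2],
       se_slope = se[1], se_intercept = se[2])
}

#' Bivariate LD-score regression for one trait pair
#'
#' Regresses the per-SNP products \eqn{z_{jk} z_{jl}} on LD scores
#' \eqn{l_j}.  The slope \eqn{\hat s} maps to the genetic covariance as
#' \eqn{\hat\rho_{g,kl} = \hat s M / \sqrt{N_k N_l}}; the intercept captures
#' confounding and (cross-trait) sample overlap times phenotypic
#' correlation.  With \code{zl = zk} this is univariate LDSC and the slope
#' maps to the SNP-heritability \eqn{\hat h^2_k}.
#'
#' Weights follow the standard two-pass scheme: a preliminary unweighted
#' pass gives heritability estimates, then the final pass uses the product
#' of an over-counting weight \eqn{1/l_j} and the heteroskedasticity weight
#' \eqn{1/[(1 + N_k \hat h^2_k l_j / M)(1 + N_l \hat h^2_l l_j / M)]}.
#'
#' @param zk,zl z-score vectors for the two traits (equal length).
#' @param l LD scores.
#' @param Nk,Nl sample sizes.
#' @param M number of SNPs the genetic covariance refers to (defaults to
#'   \code{length(l)}).
#' @param min_snps minimum number of SNPs required (default 200).
#' @param n_jackknife number of contiguous jackknife blocks for standard
#'   errors (default 200).
#' @return list with \code{rho_g} (genetic covariance), \code{slope},
#'   \code{intercept}, jackknife \code{se_rho_g}, \code{se_slope},
#'   \code{se_intercept}, and the preliminary \code{h2} pair used in the
#'   weights.
#' @export
ldsc_pair <- function(zk, zl, l, Nk, Nl, M = length(l),
                      min_snps = 200, n_jackknife = 200) {
  n <- length(l)
  if (length(zk) != n || length(zl) != n)
    stop("zk, zl and l must have equal length", call. = FALSE)
  if (n < min_snps) stop("too few SNPs for LD-score regression", call. = FALSE)
  if (stats::sd(l) == 0) stop("degenerate LD scores (constant)", call. = FALSE)

  h2_of <- function(z, N) {
    f <- .wls_jack(l, z^2, rep(1, n), jackknife = FALSE)
    min(max(f$slope * M / N, 0), 1)
  }
  h2k <- h2_of(zk, Nk)
  h2l <- if (identical(zk, zl) && Nk == Nl) h2k else h2_of(zl, Nl)
  w <- 1 / pmax(l, 1) /
    ((1 + Nk * h2k * l / M) * (1 + Nl * h2l * l / M))
  f <- .wls_jack(l, zk * zl, w, n_jackknife)
  scale <- M / sqrt(Nk * Nl)
  list(rho_g = f$slope * scale, slope = f$slope, intercept = f$intercept,
       se_rho_g = f$se_slope * scale, se_slope = f$se_slope,
       se_intercept = f$se_intercept, h2 = c(h2k, h2l))
}

#' Covariance set for a group of traits
#'
#' Container pairing the genetic covariance matrix (heritabilities on the
#' diagonal) with the sampling covariance of standardized effect estimates.
#' Users reproducing simulation settings with known truth can construct one
#' directly instead of estimating it.
#'
#' @param Sigma_g K x K genetic covariance matrix.
#' @param Sigma_bhat K x K sampling covariance of the standardized effect
#'   estimates (the same for every SNP).
#' @param N per-trait sample sizes (optional).
#' @param Intercept K x K LDSC intercept matrix (optional; reconstructed
#'   from \code{Sigma_bhat} and \code{N} when those are supplied).
#' @param M SNP count underlying \code{Sigma_g} (optional).
#' @param traits trait labels.
#' @return object of class \code{covariance_set}.
#' @export
covariance_set <- function(Sigma_g, Sigma_bhat, N = NULL, Intercept = NULL,
                           M = NULL, traits = NULL) {
  .check_square(Sigma_g); .check_square(Sigma_bhat)
  K <- nrow(Sigma_g)
  stopifnot(nrow(Sigma_bhat) == K)
  if (is.null(traits)) traits <- colnames(Sigma_g)
  if (is.null(Intercept) && !is.null(N))
    Intercept <- Sigma_bhat * sqrt(outer(N, N))
  if (!is.null(traits))
    dimnames(Sigma_g) <- dimnames(Sigma_bhat) <- list(traits, traits)
  structure(list(Sigma_g = Sigma_g, Sigma_bhat = Sigma_bhat,
                 Intercept = Intercept, N = N, M = M, traits = traits),
            class = "covariance_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Estimate genetic and sampling covariance matrices by LD-score regression
#'
#' Runs \code{\link{ldsc_pair}} for all K(K+1)/2 trait pairs of a harmonized
#' panel, assembles the genetic covariance (slopes) and intercept matrices,
#' converts intercepts to the sampling covariance
#' \eqn{\Sigma_{\hat\beta}[k,l] = Intercept[k,l]/\sqrt{N_k N_l}}, and
#' applies a positive-(semi)definite repair (eigenvalue clipping; for the
#' sampling covariance on the unit-diagonal scale with the diagonal
#' restored).  Pre-repair matrices and jackknife standard errors are kept
#' for diagnostics.
#'
#' @param panel a \code{\link{multi_trait_panel}} with LD scores (or pass
#'   \code{ld}).
#' @param ld optional \code{ld_score_set} overriding \code{panel$ld_scores}.
#' @param M SNP count for the slope-to-covariance map (defaults to the panel
#'   size).
#' @param repair_tol warn if the PSD repair moves any eigenvalue by more
#'   than this (default 1e-6).
#' @param ... passed to \code{\link{ldsc_pair}}.
#' @return a \code{\link{covariance_set}} with elements \code{se} (jackknife
#'   SE matrices for \code{Sigma_g} and \code{Intercept}) and
#'   \code{pre_repair}.
#' @export
estimate_covariances <- function(panel, ld = NULL, M = NULL,
                                 repair_tol = 1e-6, ...) {
  l <- if (!is.null(ld)) ld$l else panel$ld_scores
  if (is.null(l)) stop("no LD scores available for the panel", call. = FALSE)
  Z <- panel$Z
  K <- ncol(Z)
  if (is.null(M)) M <- nrow(Z)
  N <- panel$N
  Sg <- Int <- SEg <- SEi <- matrix(0, K, K,
                                    dimnames = list(panel$traits, panel$traits))
  for (k in seq_len(K)) for (j in k:K) {
    fit <- ldsc_pair(Z[, k], Z[, j], l, N[k], N[j], M = M, ...)
    Sg[k, j] <- Sg[j, k] <- fit$rho_g
    Int[k, j] <- Int[j, k] <- fit$intercept
    SEg[k, j] <- SEg[j, k] <- fit$se_rho_g
    SEi[k, j] <- SEi[j, k] <- fit$se_intercept
  }
  Sb_raw <- Int / sqrt(outer(N, N))
  Sg_rep <- repair_psd(Sg, eps = 0)
  # repair the sampling covariance on the correlation (unit-diagonal) scale
  d <- sqrt(diag(Sb_raw))
  if (any(diag(Sb_raw) <= 0))
    stop("non-positive diagonal in estimated sampling covariance", call. = FALSE)
  Crep <- repair_psd(Sb_raw / tcrossprod(d), eps = 1e-8, rescale_diag = TRUE)
  Sb_rep <- Crep * tcrossprod(d)
  shift <- max(attr(Sg_rep, "max_shift"), attr(Crep, "max_shift"))
  if (shift > repair_tol)
    warning(sprintf("PSD repair moved eigenvalues by up to %.3g", shift))
  out <- covariance_set(Sg_rep, .symmetrize(Sb_rep), N = N, Intercept = Int,
                        M = M, traits = panel$traits)
  out$se <- list(Sigma_g = SEg, Intercept = SEi)
  out$pre_repair <- list(Sigma_g = Sg, Sigma_bhat = Sb_raw)
  out
}

#' @export
print.covariance_set <- function(x, digits = 4, ...) {
  cat(sprintf("covariance set for %d traits\n", nrow(x$Sigma_g)))
  cat("genetic covariance (Sigma_g):\n")
  print(round(x$Sigma_g, digits))
  cat("sampling covariance of effect estimates (Sigma_bhat):\n")
  print(signif(x$Sigma_bhat, digits))
  invisible(x)
}

#' Serialize / load a covariance set as JSON
#' @param cs a \code{covariance_set}.
#' @param file path.
#' @export
write_covariances <- function(cs, file) {
  obj <- list(traits = cs$traits, Sigma_g = cs$Sigma_g,
              Sigma_bhat = cs$Sigma_bhat, Intercept = cs$Intercept,
              N = cs$N, M = cs$M)
  jsonlite::write_json(obj, file, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(file)
}

#' @rdname write_covariances
#' @export
read_covariances <- function(file) {
  obj <- jsonlite::read_json(file, simplifyVector = TRUE)
  covariance_set(as.matrix(obj$Sigma_g), as.matrix(obj$Sigma_bhat),
                 N = obj$N,
                 Intercept = if (!is.null(obj$Intercept)) as.matrix(obj$Intercept),
                 M = obj$M, traits = obj$traits)
}
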