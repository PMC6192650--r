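# MTAG-style moment estimator, implemented for head-to-head comparison with
# the power-optimized components.

#' MTAG weight vector for one trait
#'
#' Solves the moment condition \eqn{E[\hat\beta_j - (\omega_k/\omega_{kk})
#' \beta_{jk}] = 0} in generalized-least-squares form.  With
#' \eqn{x = \omega_k / \omega_{kk}} and
#' \eqn{A = \Omega - \omega_k \omega_k^T/\omega_{kk} + \Sigma_{\hat\beta}},
#' the estimate of the trait-k effect is
#' \eqn{\hat\beta_{MTAG,k} = (x^T A^{-1} \hat\beta) / (x^T A^{-1} x)}, i.e.
#' a linear combination with weight vector \eqn{w = A^{-1} x / (x^T A^{-1}
#' x)}.
#'
#' @param Omega K x K covariance of marginal effect sizes
#'   (\eqn{var(\beta_j)}).
#' @param Sigma_bhat K x K sampling covariance of effect estimates.
#' @param k trait index.
#' @return list with \code{w} (the weight vector applied to
#'   \eqn{\hat\beta_j}), \code{raw} (\eqn{A^{-1} x}) and \code{normalizer}
#'   (\eqn{x^T A^{-1} x}).
#' @export
mtag_weights <- function(Omega, Sigma_bhat, k) {
  .check_square(Omega, "Omega"); .check_square(Sigma_bhat, "Sigma_bhat")
  if (Omega[k, k] <= 0)
    stop("trait has zero genetic variance; MTAG weights undefined", call. = FALSE)
  x <- Omega[, k] / Omega[k, k]
  A <- Omega - tcrossprod(Omega[, k]) / Omega[k, k] + Sigma_bhat
  raw <- solve(A, x)
  normalizer <- sum(x * raw)
  list(w = raw / normalizer, raw = raw, normalizer = normalizer)
}

#' Fit MTAG estimates to a multi-trait panel
#'
#' Computes, for every trait, the moment-based multi-trait effect estimate
#' and its z-statistic \eqn{z = w^T\hat\beta / \sqrt{w^T \Sigma_{\hat\beta}
#' w}}.  The marginal-effect covariance is taken as
#' \eqn{\Omega = (\bar l / M)\, \Sigma_g}, consistent with
#' \eqn{E[\beta\beta^T | l] = l\,\Sigma_g/M}.
#'
#' @param panel a \code{\link{multi_trait_panel}}.
#' @param covariances optional \code{\link{covariance_set}}; estimated by
#'   LD-score regression when \code{NULL}.
#' @param Omega optional explicit marginal-effect covariance overriding the
#'   \eqn{\bar l \Sigma_g / M} construction.
#' @param M SNP count (defaults to panel size).
#' @param ... passed to \code{\link{estimate_covariances}}.
#' @return object of class \code{mtag}: \code{weights} (K x K, column k =
#'   weight vector for trait k), \code{Omega}, per-SNP \code{scores} table
#'   and matrices \code{z}, \code{p}, \code{beta_mtag}.
#' @export
mtag <- function(panel, covariances = NULL, Omega = NULL, M = NULL, ...) {
  cl <- match.call()
  if (is.null(M)) M <- nrow(panel$Z)
  if (is.null(covariances)) covariances <- estimate_covariances(panel, M = M, ...)
  if (is.null(Omega)) {
    if (is.null(panel$ld_scores))
      stop("panel has no LD scores; supply Omega explicitly", call. = FALSE)
    Omega <- mean(panel$ld_scores) / M * covariances$Sigma_g
  }
  K <- ncol(panel$Z)
  Sb <- covariances$Sigma_bhat
  W <- matrix(vapply(seq_len(K), function(k) mtag_weights(Omega, Sb, k)$w,
                     numeric(K)), K, K,
              dimnames = list(panel$traits, panel$traits))
  B <- panel_effects(panel)
  est <- B %*% W
  sd_comb <- sqrt(diag(t(W) %*% Sb %*% W))
  z <- sweep(est, 2, sd_comb, "/")
  p <- 2 * stats::pnorm(-abs(z))
  colnames(z) <- colnames(p) <- colnames(est) <- panel$traits
  scores <- cbind(panel$snps,
                  stats::setNames(as.data.frame(z), paste0("z.", panel$traits)),
                  stats::setNames(as.data.frame(p), paste0("p.", panel$traits)))
  structure(list(weights = W, Omega = Omega, covariances = covariances,
                 beta_mtag = est, z = z, p = p, scores = scores,
                 panel = panel, M = M, call = cl),
            class = "mtag")
}

#' @export
print.mtag <- function(x, digits = 4, ...) {
  cat(sprintf("MTAG fit: %d traits, %d SNPs\n", ncol(x$z), nrow(x$z)))
  cat("weight vectors (column k = weights for trait k):\n")
  print(round(x$weights, digits))
  invisible(x)
}

#' @export
coef.mtag <- function(object, ...) object$weights
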