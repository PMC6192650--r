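# Heritability-informed power optimization: constrained maximization of the
# average non-centrality parameter, solved by eigen-decomposition, plus the
# per-SNP component tests and the user-facing model interface.

#' Solve the power-optimizing eigen problem
#'
#' Finds weight vectors \eqn{c_1, \dots, c_K} maximizing
#' \eqn{c^T \Sigma_g c} subject to \eqn{c^T \Sigma_{\hat\beta} c = 1} and
#' \eqn{\Sigma_{\hat\beta}}-orthogonality to the preceding components.  With
#' \eqn{S = \Sigma_{\hat\beta}^{-1/2}} (symmetric inverse square root) the
#' solutions are \eqn{c_k = S u_k} where \eqn{(\lambda_k, u_k)} are the
#' eigenpairs of \eqn{S \Sigma_g S}, ordered by decreasing eigenvalue.  The
#' eigenvalues are the average non-centrality parameters of the per-SNP
#' chi-square statistics along the components, up to the common scale
#' \eqn{\bar l / M} (see \code{\link{average_ncp}}).
#'
#' @param Sigma_g K x K genetic covariance matrix (positive semi-definite).
#' @param Sigma_bhat K x K sampling covariance of standardized effect
#'   estimates (positive definite; see \code{\link{repair_psd}} if not).
#' @param traits trait labels.
#' @return object of class \code{hipo_decomposition}: \code{weights} (K x K,
#'   columns \eqn{c_k}, each scaled so its largest-magnitude entry is
#'   positive), \code{eigenvalues} (non-increasing), and the input matrices.
#' @export
hipo_decompose <- function(Sigma_g, Sigma_bhat, traits = NULL) {
  if (NROW(Sigma_g) == 0) stop("empty covariance matrices", call. = FALSE)
  .check_square(Sigma_g, "Sigma_g"); .check_square(Sigma_bhat, "Sigma_bhat")
  K <- nrow(Sigma_g)
  if (nrow(Sigma_bhat) != K) stop("dimension mismatch", call. = FALSE)
  if (is.null(traits))
    traits <- colnames(Sigma_g) %||% paste0("trait", seq_len(K))
  S <- .sym_inv_sqrt(Sigma_bhat)
  W <- .symmetrize(S %*% Sigma_g %*% S)
  e <- eigen(W, symmetric = TRUE)
  C <- S %*% e$vectors
  # sign convention: largest-magnitude weight positive, for reproducibility
  for (k in seq_len(K)) {
    i <- which.max(abs(C[, k]))
    if (C[i, k] < 0) C[, k] <- -C[, k]
  }
  dimnames(C) <- list(traits, paste0("HIPO-D", seq_len(K)))
  structure(list(weights = C, eigenvalues = e$values,
                 Sigma_g = Sigma_g, Sigma_bhat = Sigma_bhat, traits = traits),
            class = "hipo_decomposition")
}

#' @export
print.hipo_decomposition <- function(x, digits = 4, ...) {
  cat("HIPO decomposition\n")
  cat("eigenvalues (average-NCP scale):",
      paste(signif(x$eigenvalues, digits), collapse = ", "), "\n")
  cat("component weights (columns):\n")
  print(round(x$weights, digits))
  invisible(x)
}

#' Average non-centrality parameter of each component
#'
#' Scales the decomposition eigenvalues to the average per-SNP
#' non-centrality parameter, \eqn{E[\delta_k] = \lambda_k \bar l / M}, where
#' \eqn{\bar l} is the mean LD score and M the SNP count.
#'
#' @param eigenvalues eigenvalue vector from \code{\link{hipo_decompose}}.
#' @param mean_ld_score mean LD score.
#' @param M number of SNPs.
#' @return average-NCP vector.
#' @export
average_ncp <- function(eigenvalues, mean_ld_score, M) {
  if (M <= 0) stop("M must be positive", call. = FALSE)
  eigenvalues * mean_ld_score / M
}

#' Per-SNP z-statistics along component directions
#'
#' For each component \eqn{c_k}, computes
#' \eqn{z_{j,k} = c_k^T \hat\beta_j / \sqrt{c_k^T \Sigma_{\hat\beta} c_k}}
#' (the denominator is 1 under the normalization constraint but is computed
#' explicitly) and the two-sided normal p-value.
#'
#' @param B M x K matrix of standardized effect estimates (rows = SNPs).
#' @param weights K x K weight matrix (columns = components).
#' @param Sigma_bhat sampling covariance used for the denominators.
#' @return list with matrices \code{z} and \code{p} (M x K).
#' @export
component_zscores <- function(B, weights, Sigma_bhat) {
  B <- as.matrix(B)
  if (ncol(B) != nrow(weights))
    stop("trait dimension of effects and weights disagree", call. = FALSE)
  denom <- sqrt(diag(t(weights) %*% Sigma_bhat %*% weights))
  z <- sweep(B %*% weights, 2, denom, "/")
  colnames(z) <- colnames(weights)
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Fit HIPO components to a multi-trait GWAS panel
#'
#' The central model-fitting function.  Given a harmonized panel of
#' summary statistics, it (unless supplied) estimates the genetic covariance
#' \eqn{\Sigma_g} and the sampling covariance \eqn{\Sigma_{\hat\beta}} by
#' cross-trait LD-score regression, solves the constrained power
#' optimization by eigen-decomposition, and computes per-SNP z-statistics
#' and p-values along every component.
#'
#' @param panel a \code{\link{multi_trait_panel}}.
#' @param covariances optional \code{\link{covariance_set}} (e.g. known
#'   truth in simulations); estimated from the panel when \code{NULL}.
#' @param M SNP count used for the average-NCP scale and, when estimating,
#'   the slope-to-covariance map (defaults to the panel size).
#' @param ... passed to \code{\link{estimate_covariances}}.
#' @return object of class \code{hipo}: the decomposition, average NCPs,
#'   covariances, per-SNP \code{scores} table (SNP index plus z and p per
#'   component) and the call.  Methods: \code{print}, \code{summary},
#'   \code{coef} (weight matrix), \code{predict} (scores for new data),
#'   \code{plot} (QQ or scree).
#' @seealso \code{\link{hipo_decompose}}, \code{\link{mtag}},
#'   \code{\link{clump}}
#' @examples
#' cov <- lipid_covariances()
#' cs <- covariance_set(0.35 * cov$Sigma_g, cov$Sigma_y / 1e5, N = rep(1e5, 4))
#' hipo_decompose(cs$Sigma_g, cs$Sigma_bhat)
#' @export
hipo <- function(panel, covariances = NULL, M = NULL, ...) {
  cl <- match.call()
  if (is.null(M)) M <- nrow(panel$Z)
  if (is.null(covariances)) covariances <- estimate_covariances(panel, M = M, ...)
  if (!is.null(covariances$traits) &&
      !identical(unname(covariances$traits), unname(panel$traits)))
    stop("trait order of panel and covariances disagree", call. = FALSE)
  dec <- hipo_decompose(covariances$Sigma_g, covariances$Sigma_bhat,
                        traits = panel$traits)
  mean_l <- if (!is.null(panel$ld_scores)) mean(panel$ld_scores) else NA_real_
  zs <- component_zscores(panel_effects(panel), dec$weights,
                          covariances$Sigma_bhat)
  scores <- cbind(panel$snps,
                  stats::setNames(as.data.frame(zs$z), paste0("z.", colnames(zs$z))),
                  stats::setNames(as.data.frame(zs$p), paste0("p.", colnames(zs$z))))
  structure(list(decomposition = dec, weights = dec$weights,
                 eigenvalues = dec$eigenvalues,
                 avg_ncp = if (is.na(mean_l)) NULL
                           else average_ncp(dec$eigenvalues, mean_l, M),
                 covariances = covariances, scores = scores,
                 z = zs$z, p = zs$p, panel = panel, M = M, call = cl),
            class = "hipo")
}

#' @export
print.hipo <- function(x, digits = 4, ...) {
  K <- ncol(x$weights)
  cat(sprintf("HIPO fit: %d traits, %d SNPs\n", K, nrow(x$scores)))
  cat("component weights:\n"); print(round(x$weights, digits))
  cat("eigenvalues:", paste(signif(x$eigenvalues, digits), collapse = ", "), "\n")
  if (!is.null(x$avg_ncp))
    cat("average NCP:", paste(signif(x$avg_ncp, digits), collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.hipo <- function(object, ...) object$weights

#' @export
summary.hipo <- function(object, ...) {
  gc <- apply(object$z, 2, function(z) unlist(lambda_gc_mean_chisq(z)))
  comp <- data.frame(eigenvalue = object$eigenvalues,
                     avg_ncp = if (is.null(object$avg_ncp)) NA else object$avg_ncp,
                     lambda_gc = gc["lambda_gc", ],
                     mean_chisq = gc["mean_chisq", ],
                     row.names = colnames(object$weights))
  out <- list(components = comp, weights = object$weights,
              Sigma_g = object$covariances$Sigma_g,
              Sigma_bhat = object$covariances$Sigma_bhat)
  class(out) <- "summary.hipo"
  out
}

#' @export
print.summary.hipo <- function(x, digits = 4, ...) {
  cat("HIPO components:\n")
  print(signif(x$components, digits))
  cat("\nweights:\n"); print(round(x$weights, digits))
  cat("\ngenetic covariance:\n"); print(signif(x$Sigma_g, digits))
  invisible(x)
}

#' @export
#' @param newdata a \code{multi_trait_panel} or an M x K matrix of
#'   standardized effect estimates with traits in the fitted order.
#' @rdname hipo
predict.hipo <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$scores)
  B <- if (inherits(newdata, "multi_trait_panel")) {
    if (!identical(newdata$traits, object$decomposition$traits))
      stop("trait order mismatch between fit and new panel", call. = FALSE)
    panel_effects(newdata)
  } else as.matrix(newdata)
  zs <- component_zscores(B, object$weights, object$covariances$Sigma_bhat)
  out <- as.data.frame(zs$z)
  names(out) <- paste0("z.", colnames(zs$z))
  pv <- as.data.frame(zs$p); names(pv) <- paste0("p.", colnames(zs$z))
  if (inherits(newdata, "multi_trait_panel")) cbind(newdata$snps, out, pv)
  else cbind(out, pv)
}

#' @export
#' @param type \code{"qq"} for per-component QQ curves of -log10 p-values,
#'   \code{"scree"} for the eigenvalue profile.
#' @rdname hipo
plot.hipo <- function(x, type = c("qq", "scree"), components = NULL, ...) {
  type <- match.arg(type)
  if (type == "scree") {
    graphics::plot(seq_along(x$eigenvalues), x$eigenvalues, type = "b",
                   xlab = "component", ylab = "eigenvalue (avg NCP scale)", ...)
    return(invisible(x))
  }
  comps <- components %||% colnames(x$p)
  cols <- seq_along(comps)
  first <- TRUE
  for (i in seq_along(comps)) {
    q <- qq_data(x$p[, comps[i]])
    if (first) {
      graphics::plot(q$expected, q$observed, col = cols[i], pch = 20, cex = 0.4,
                     xlab = "expected -log10(p)", ylab = "observed -log10(p)", ...)
      graphics::abline(0, 1, lty = 2)
      first <- FALSE
    } else graphics::points(q$expected, q$observed, col = cols[i], pch = 20, cex = 0.4)
  }
  graphics::legend("topleft", legend = comps, col = cols, pch = 20, bty = "n")
  invisible(x)
}

#' Export the per-component results of a fit
#'
#' Writes the per-SNP results table (CHR, SNP, BP, alleles, per-component Z
#' and P) as delimited text and the weight / eigenvalue / average-NCP tables
#' as JSON.
#'
#' @param fit a \code{hipo} or \code{mtag} fit.
#' @param prefix output path prefix; writes \code{<prefix>.tsv} and
#'   \code{<prefix>.json}.
#' @export
write_results <- function(fit, prefix) {
  utils::write.table(fit$scores, paste0(prefix, ".tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  meta <- list(weights = fit$weights)
  if (!is.null(fit$eigenvalues)) meta$eigenvalues <- fit$eigenvalues
  if (!is.null(fit$avg_ncp)) meta$avg_ncp <- fit$avg_ncp
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}
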