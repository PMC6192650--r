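# Direct simulation of multi-trait GWAS summary statistics with LD,
# phenotypic correlation, sample overlap and population stratification,
# with full truth tracking.
#
# Model: beta_hat_j = beta_j + v_j + e_j, where beta_j are LD-weighted
# marginal genetic effects, v_j ~ iid N(0, Sigma_v) captures population
# stratification, and the estimation errors follow N(0, R (x) Sigma_e)
# (Kronecker of the LD matrix with the sampling covariance).  Errors are
# sampled exactly per LD block, which has the identical target distribution
# to a null-phenotype GWAS on a genotype reference panel.

#' Reference covariance structures for the simulation studies
#'
#' Genetic-covariance patterns (scaled so the largest diagonal entry is 1;
#' multiply by the maximum heritability \code{h2max} to obtain
#' \eqn{\Sigma_g}) and phenotypic covariance matrices estimated from
#' consortium GWAS of four blood lipid traits (LDL, HDL, TG, TC) and three
#' psychiatric disorders (ASD, BIP, SCZ).
#'
#' @return list with \code{Sigma_g} (unit-scaled pattern), \code{Sigma_y}
#'   and \code{traits}.
#' @export
lipid_covariances <- function() {
  traits <- c("LDL", "HDL", "TG", "TC")
  Sg <- matrix(c(0.87, -0.04, 0.30, 0.85,
                 -0.04, 1.00, -0.62, 0.18,
                 0.30, -0.62, 0.93, 0.30,
                 0.85, 0.18, 0.30, 0.95), 4, 4, byrow = TRUE,
               dimnames = list(traits, traits))
  Sy <- matrix(c(1.00, -0.10, 0.21, 0.86,
                 -0.10, 1.00, -0.36, 0.12,
                 0.21, -0.36, 1.00, 0.32,
                 0.86, 0.12, 0.32, 1.00), 4, 4, byrow = TRUE,
               dimnames = list(traits, traits))
  list(Sigma_g = Sg, Sigma_y = Sy, traits = traits)
}

#' @rdname lipid_covariances
#' @export
psychiatric_covariances <- function() {
  traits <- c("ASD", "BIP", "SCZ")
  Sg <- matrix(c(0.69, 0.02, 0.12,
                 0.02, 0.88, 0.63,
                 0.12, 0.63, 1.00), 3, 3, byrow = TRUE,
               dimnames = list(traits, traits))
  Sy <- matrix(c(1.00, 0.01, 0.00,
                 0.01, 1.00, 0.01,
                 0.00, 0.01, 1.00), 3, 3, byrow = TRUE,
               dimnames = list(traits, traits))
  list(Sigma_g = Sg, Sigma_y = Sy, traits = traits)
}

#' Per-SNP stratification covariance pattern
#'
#' \eqn{\sigma^2_v} times a matrix with 1 on the diagonal and 0.5 off the
#' diagonal; with the default scale \eqn{7.35 \times 10^{-8}} the per-SNP
#' stratification variance is about 25\% of the per-SNP heritability when
#' the maximum heritability is 0.35 spread over 1.2 million SNPs.
#'
#' @param K number of traits.
#' @param scale per-SNP stratification variance (default 7.35e-8).
#' @export
stratification_covariance <- function(K, scale = 7.35e-8) {
  V <- matrix(0.5, K, K); diag(V) <- 1
  scale * V
}

#' Simulation configuration
#'
#' Bundles and validates the generating parameters of a summary-statistic
#' simulation.  \code{Sigma_g} is the total genetic covariance of the
#' simulated genome of \code{M} SNPs.
#'
#' @param Sigma_g K x K genetic covariance matrix.
#' @param Sigma_y K x K phenotypic covariance matrix (positive definite).
#' @param N per-trait sample sizes (scalar recycled).
#' @param M total SNP count.
#' @param m_causal number of causal SNPs (shared across traits by default).
#' @param N_overlap K x K pairwise overlapping sample counts; default is
#'   complete overlap \code{min(N_k, N_l)}.  Use \code{diag(N)} for
#'   disjoint samples.
#' @param causal_overlap fraction of causal SNPs shared across traits
#'   (1 = identical causal sets, 0 = independent sets).
#' @param Sigma_v K x K population-stratification covariance (\code{NULL}
#'   disables stratification).
#' @param window_bp LD neighborhood radius for the marginal-effect
#'   construction (default 1 Mb).
#' @param r2_min minimum squared LD for a neighbor to contribute to the
#'   marginal effect (default 0.01).
#' @param seed master RNG seed; independent sub-streams are derived for the
#'   LD panel, effects, stratification and errors.
#' @param traits trait labels.
#' @return validated list of class \code{sim_config}.
#' @export
sim_config <- function(Sigma_g, Sigma_y, N, M, m_causal,
                       N_overlap = NULL, causal_overlap = 1,
                       Sigma_v = NULL, window_bp = 1e6, r2_min = 0.01,
                       seed = 1L, traits = NULL) {
  .check_square(Sigma_g, "Sigma_g"); .check_square(Sigma_y, "Sigma_y")
  K <- nrow(Sigma_g)
  N <- rep_len(N, K)
  if (is.null(N_overlap)) N_overlap <- outer(N, N, pmin)
  .check_square(N_overlap, "N_overlap")
  if (any(N_overlap > outer(N, N, pmin) + 1e-8))
    stop("N_overlap cannot exceed min(N_k, N_l)", call. = FALSE)
  if (any(abs(diag(N_overlap) - N) > 1e-8))
    stop("diagonal of N_overlap must equal N", call. = FALSE)
  if (min(eigen(Sigma_y, symmetric = TRUE, only.values = TRUE)$values) <
      -1e-10 * max(abs(Sigma_y), 1))
    stop("Sigma_y must be positive semi-definite", call. = FALSE)
  if (m_causal > M) stop("m_causal cannot exceed M", call. = FALSE)
  if (causal_overlap < 0 || causal_overlap > 1)
    stop("causal_overlap must be in [0, 1]", call. = FALSE)
  if (is.null(traits))
    traits <- colnames(Sigma_g) %||% paste0("trait", seq_len(K))
  structure(list(Sigma_g = Sigma_g, Sigma_y = Sigma_y, N = N, M = as.integer(M),
                 m_causal = as.integer(m_causal), N_overlap = N_overlap,
                 causal_overlap = causal_overlap, Sigma_v = Sigma_v,
                 window_bp = window_bp, r2_min = r2_min,
                 seed = as.integer(seed), traits = traits, K = K),
            class = "sim_config")
}

#' Study-condition configurations for the reference simulation settings
#'
#' Builds a \code{\link{sim_config}} reproducing the blood-lipid (or
#' psychiatric) simulation design: printed covariance structures, maximum
#' heritability \code{h2max} in \{0.1, 0.2, 0.35, 0.5\}, equal sample sizes
#' with complete overlap, 1\% causal fraction, and optional population
#' stratification at per-SNP variance 7.35e-8.  When \code{M} is below the
#' reference genome size of 1.2 million SNPs, \code{Sigma_g} is scaled by
#' \code{M / genome_M} so that per-SNP variance components (per-SNP
#' heritability, per-causal-SNP effect variance, stratification and
#' sampling variances) stay at their full-scale values.
#'
#' @param N sample size (all traits; complete overlap).
#' @param h2max maximum heritability across traits at full scale.
#' @param M simulated SNP count.
#' @param stratification include population stratification.
#' @param setting \code{"lipids"} (K = 4) or \code{"psychiatric"} (K = 3).
#' @param genome_M reference genome size the heritability refers to.
#' @param seed master seed.
#' @param ... further arguments to \code{\link{sim_config}}.
#' @export
reference_sim_config <- function(N, h2max, M = 1.2e6,
                                 stratification = FALSE,
                                 setting = c("lipids", "psychiatric"),
                                 genome_M = 1.2e6, seed = 1L, ...) {
  setting <- match.arg(setting)
  cov <- if (setting == "lipids") lipid_covariances() else psychiatric_covariances()
  K <- length(cov$traits)
  sim_config(Sigma_g = h2max * cov$Sigma_g * (M / genome_M),
             Sigma_y = cov$Sigma_y, N = N, M = M,
             m_causal = round(0.01 * M),
             Sigma_v = if (stratification) stratification_covariance(K),
             seed = seed, traits = cov$traits, ...)
}

#' Draw joint (causal) effect sizes
#'
#' Selects \code{m_causal} causal SNPs uniformly and draws their joint
#' effect rows i.i.d. from \eqn{N(0, \Sigma_g / m_{causal})}; all other rows
#' are zero.  With \code{causal_overlap < 1} each trait keeps the shared
#' core and receives its own independent remainder; entries outside a
#' trait's causal set are zeroed.
#'
#' @param config a \code{\link{sim_config}}.
#' @param seed optional seed (defaults to the active RNG state).
#' @return list with \code{beta_joint} (M x K) and \code{causal} (list of
#'   per-trait causal index vectors).
#' @export
draw_joint_effects <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  M <- config$M; m <- config$m_causal; K <- config$K
  beta <- matrix(0, M, K)
  if (m == 0) return(list(beta_joint = beta, causal = rep(list(integer(0)), K)))
  if (config$causal_overlap >= 1) {
    idx <- sort(sample.int(M, m))
    causal <- rep(list(idx), K)
    beta[idx, ] <- .rmvnorm(m, config$Sigma_g / m)
  } else {
    n_shared <- round(config$causal_overlap * m)
    shared <- sort(sample.int(M, n_shared))
    causal <- lapply(seq_len(K), function(k) {
      own <- sample(setdiff(seq_len(M), shared), m - n_shared)
      sort(c(shared, own))
    })
    union_idx <- sort(unique(unlist(causal)))
    draws <- .rmvnorm(length(union_idx), config$Sigma_g / m)
    beta[union_idx, ] <- draws
    for (k in seq_len(K))
      beta[setdiff(union_idx, causal[[k]]), k] <- 0
  }
  list(beta_joint = beta, causal = causal)
}

# Within-block LD weight matrix used for the joint-to-marginal map: entries
# with r^2 <= r2_min or beyond the bp window are zeroed (self term kept).
.ld_weight_matrix <- function(R, pos, window_bp, r2_min) {
  W <- R
  W[W^2 <= r2_min] <- 0
  if (length(pos) > 1) W[abs(outer(pos, pos, "-")) > window_bp] <- 0
  diag(W) <- diag(R)
  W
}

#' Marginal effects from joint effects through LD
#'
#' \eqn{\beta_j = \sum_{j' \in N_j} \beta^{(J)}_{j'} r_{jj'}}, where the
#' neighborhood holds SNPs within \code{window_bp} with \eqn{r^2 >
#' r2\_min} of SNP j (the SNP itself always included).
#'
#' @param beta_joint M x K joint-effect matrix.
#' @param panel an \code{\link{ld_panel}} covering the same SNPs.
#' @param window_bp neighborhood radius in bp.
#' @param r2_min minimum squared correlation for inclusion.
#' @return M x K matrix of marginal effects.
#' @export
marginal_effects <- function(beta_joint, panel, window_bp = 1e6, r2_min = 0.01) {
  beta_joint <- as.matrix(beta_joint)
  if (nrow(beta_joint) != nrow(panel$snps))
    stop("panel does not cover all SNPs", call. = FALSE)
  out <- matrix(0, nrow(beta_joint), ncol(beta_joint))
  nz_blocks <- unique(panel$snps$block[rowSums(beta_joint != 0) > 0])
  W1 <- if (panel$uniform)
    .ld_weight_matrix(panel$blocks[[1]],
                      panel$snps$pos_bp[seq_len(panel$sizes[1])],
                      window_bp, r2_min)
  for (b in nz_blocks) {
    rows <- panel$block_start[b] + seq_len(panel$sizes[b]) - 1L
    W <- if (panel$uniform) W1 else
      .ld_weight_matrix(panel$blocks[[b]], panel$snps$pos_bp[rows],
                        window_bp, r2_min)
    out[rows, ] <- W %*% beta_joint[rows, , drop = FALSE]
  }
  out
}

#' Sampling covariance of effect estimates across traits
#'
#' \eqn{\Sigma_e[k,l] = N_{kl} / (N_k N_l)\, cov(y_k, y_l)}: the covariance
#' of estimation errors for one SNP across studies with pairwise sample
#' overlap \eqn{N_{kl}}; the diagonal reduces to \eqn{var(y_k)/N_k}.
#'
#' @param Sigma_y phenotypic covariance.
#' @param N sample sizes.
#' @param N_overlap pairwise overlap counts (default complete overlap).
#' @return K x K matrix.
#' @export
error_covariance <- function(Sigma_y, N, N_overlap = outer(N, N, pmin)) {
  .check_square(Sigma_y, "Sigma_y")
  N <- rep_len(N, nrow(Sigma_y))
  N_overlap / outer(N, N) * Sigma_y
}

#' Draw estimation errors with LD and cross-trait covariance
#'
#' Exact sampling from \eqn{N(0, R \otimes \Sigma_e)} exploiting the
#' block-diagonal LD structure: per block, \eqn{E_b = L_b G \Lambda^T} with
#' \eqn{L_b L_b^T = R_b}, \eqn{\Lambda\Lambda^T = \Sigma_e} and G a matrix
#' of i.i.d. standard normals; blocks are independent.
#'
#' @param panel an \code{\link{ld_panel}}.
#' @param Sigma_e K x K sampling covariance (positive semi-definite).
#' @param seed optional seed.
#' @return M x K error matrix.
#' @export
draw_errors <- function(panel, Sigma_e, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  .check_square(Sigma_e, "Sigma_e")
  K <- nrow(Sigma_e)
  M <- nrow(panel$snps)
  if (all(Sigma_e == 0)) return(matrix(0, M, K))
  ev <- eigen(Sigma_e, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(abs(ev)))
    stop("Sigma_e must be positive semi-definite", call. = FALSE)
  Lam <- .psd_chol(Sigma_e)
  G <- matrix(stats::rnorm(M * K), M, K)
  if (panel$uniform) {
    s <- panel$sizes[1]
    L <- .psd_chol(panel$blocks[[1]])
    E <- matrix(L %*% matrix(G, nrow = s), nrow = M)
  } else {
    E <- G
    for (b in seq_along(panel$blocks)) {
      rows <- panel$block_start[b] + seq_len(panel$sizes[b]) - 1L
      E[rows, ] <- .psd_chol(panel$blocks[[b]]) %*% G[rows, , drop = FALSE]
    }
  }
  E %*% t(Lam)
}

#' Draw population-stratification effects
#'
#' Rows i.i.d. K-variate normal with covariance \code{Sigma_v}.
#'
#' @param Sigma_v stratification covariance (or \code{NULL}/zero for none).
#' @param M number of SNPs.
#' @param K number of traits (needed when \code{Sigma_v} is \code{NULL}).
#' @param seed optional seed.
#' @return M x K matrix.
#' @export
draw_stratification <- function(Sigma_v, M, K = nrow(Sigma_v), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(Sigma_v)) return(matrix(0, M, K))
  .check_square(Sigma_v, "Sigma_v")
  ev <- eigen(Sigma_v, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(abs(ev), 1))
    stop("Sigma_v must be positive semi-definite", call. = FALSE)
  .rmvnorm(M, Sigma_v)
}

#' Simulate a multi-trait GWAS summary-statistic study
#'
#' Composes the generative model \eqn{\hat\beta_j = \beta_j + v_j + e_j}:
#' causal joint effects spread into marginal effects through LD, i.i.d.
#' stratification effects, and estimation errors with Kronecker LD-by-trait
#' covariance.  Per-trait standard errors are
#' \eqn{\sqrt{diag(\Sigma_e)}} and \eqn{z = \hat\beta / se}.  Deterministic
#' given the master seed; the panel, effects, stratification and errors use
#' independent derived sub-streams so components can be regenerated
#' separately.
#'
#' @param config a \code{\link{sim_config}}.
#' @param panel optional pre-built \code{\link{ld_panel}} (must cover
#'   \code{config$M} SNPs); one is generated from the master seed when
#'   \code{NULL}.
#' @param block_size,decay_rate LD-panel parameters used when \code{panel}
#'   is \code{NULL}.
#' @return object of class \code{simulated_study}: a
#'   \code{\link{multi_trait_panel}} of the simulated statistics (with LD
#'   scores), the truth set (causal indices, joint/marginal effects,
#'   stratification draws, null-SNP mask), the LD panel, \code{Sigma_e},
#'   per-trait \code{se} and the config echo.
#' @export
simulate_sumstats <- function(config, panel = NULL, block_size = 10,
                              decay_rate = 0.5) {
  stopifnot(inherits(config, "sim_config"))
  seeds <- .sub_seeds(config$seed, 4)
  if (is.null(panel)) {
    nb <- config$M %/% block_size; rem <- config$M %% block_size
    if (rem == 0) {
      panel <- make_ld_panel(nb, block_size, decay_rate = decay_rate,
                             window_bp = config$window_bp, seed = seeds[1])
    } else {
      ar1 <- function(s) decay_rate^abs(outer(seq_len(s), seq_len(s), "-"))
      panel <- make_ld_panel(blocks = c(rep(list(ar1(block_size)), nb),
                                        list(ar1(rem))),
                             window_bp = config$window_bp, seed = seeds[1])
    }
  }
  if (nrow(panel$snps) != config$M)
    stop("LD panel size does not match config$M", call. = FALSE)

  je <- draw_joint_effects(config, seed = seeds[2])
  beta <- marginal_effects(je$beta_joint, panel,
                           window_bp = config$window_bp, r2_min = config$r2_min)
  v <- draw_stratification(config$Sigma_v, config$M, K = config$K,
                           seed = seeds[3])
  Sigma_e <- error_covariance(config$Sigma_y, config$N, config$N_overlap)
  e <- draw_errors(panel, Sigma_e, seed = seeds[4])
  beta_hat <- beta + v + e
  se <- sqrt(diag(Sigma_e))
  Z <- sweep(beta_hat, 2, ifelse(se > 0, se, 1), "/")  # degenerate se=0 gives z=0
  colnames(Z) <- config$traits
  ld <- compute_ld_scores(panel)
  snps <- panel$snps[, c("snp_id", "chrom", "pos_bp")]
  snps$a1 <- "A"; snps$a2 <- "G"
  mtp <- multi_trait_panel(snps, Z, stats::setNames(config$N, config$traits),
                           ld_scores = ld$l, se = se)
  truth <- list(causal = je$causal, beta_joint = je$beta_joint,
                beta_marginal = beta, stratification = v,
                null_snps = rowSums(beta != 0) == 0)
  structure(list(panel = mtp, truth = truth, ld_panel = panel,
                 Sigma_e = Sigma_e, se = se, beta_hat = beta_hat,
                 config = config),
            class = "simulated_study")
}

#' @export
print.simulated_study <- function(x, ...) {
  cat(sprintf("simulated study: %d SNPs x %d traits, %d causal, %d null\n",
              x$config$M, x$config$K, x$config$m_causal,
              sum(x$truth$null_snps)))
  cat(sprintf("N = %s; stratification: %s\n",
              paste(format(x$config$N, big.mark = ","), collapse = ", "),
              if (is.null(x$config$Sigma_v)) "none" else "yes"))
  invisible(x)
}

#' Read a simulation configuration from YAML or JSON
#'
#' Fields mirror \code{\link{sim_config}}; alternatively give
#' \code{setting}/\code{N}/\code{h2max}/\code{M} (plus optional
#' \code{stratification}, \code{genome_M}) to use
#' \code{\link{reference_sim_config}}.
#'
#' @param file path to a .yaml/.yml or .json config.
#' @return a \code{sim_config}.
#' @export
read_sim_config <- function(file) {
  obj <- if (grepl("\\.ya?ml$", file)) yaml::read_yaml(file)
         else jsonlite::read_json(file, simplifyVector = TRUE)
  # YAML 1.1 reads a bare `N` key as boolean FALSE; restore it
  names(obj)[names(obj) == "FALSE"] <- "N"
  if (!is.null(obj$setting)) {
    args <- obj[intersect(names(obj),
                          c("N", "h2max", "M", "stratification", "setting",
                            "genome_M", "seed", "m_causal", "causal_overlap"))]
    return(do.call(reference_sim_config, args))
  }
  for (f in c("Sigma_g", "Sigma_y", "N_overlap", "Sigma_v"))
    if (!is.null(obj[[f]])) obj[[f]] <- do.call(rbind, lapply(obj[[f]], unlist))
  do.call(sim_config, obj[intersect(names(obj), names(formals(sim_config)))])
}
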