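# Replicated simulation studies of genome-wide type-I error, mirroring the
# standard reporting layout (rates for the power-optimized components and
# the most heritable single trait, per significance threshold).

#' Replicated type-I-error study under a reference simulation design
#'
#' Simulates \code{n_reps} independent multi-trait summary-statistic studies
#' under a \code{\link{reference_sim_config}} design (one shared LD panel;
#' fresh effect, stratification and error draws per replicate), computes
#' per-SNP p-values for the first power-optimized component and for the most
#' heritable single trait, and averages over replicates the fraction of
#' truly null SNPs (zero marginal genetic effect) below each significance
#' threshold.
#'
#' The component test can use the generating ("true") covariance pair --
#' \eqn{\Sigma_g} from the config and \eqn{\Sigma_{\hat\beta} = \Sigma_e +
#' \Sigma_v}, the exact sampling covariance of null effect estimates -- or
#' covariances estimated per replicate by LD-score regression
#' (\code{covariances = "ldsc"}), which is the full method as run on real
#' data.
#'
#' @param N,h2max,M,stratification,setting design parameters passed to
#'   \code{\link{reference_sim_config}}.
#' @param n_reps number of simulation replicates.
#' @param thresholds significance thresholds.
#' @param covariances \code{"true"} or \code{"ldsc"}.
#' @param seed master seed; replicate seeds are derived sub-streams.
#' @param block_size,decay_rate LD-panel construction parameters.
#' @return list with \code{rates} (matrix: tests x thresholds, averaged
#'   over replicates), \code{per_rep} (array of per-replicate rates),
#'   \code{n_null} (null SNPs per replicate) and the design echo.
#' @export
type1_study <- function(N, h2max, M, n_reps = 20,
                        stratification = FALSE,
                        setting = c("lipids", "psychiatric"),
                        thresholds = c(0.05, 0.01, 0.001),
                        covariances = c("true", "ldsc"),
                        seed = 1L, block_size = 10, decay_rate = 0.5) {
  setting <- match.arg(setting)
  covariances <- match.arg(covariances)
  seeds <- .sub_seeds(seed, n_reps + 1L)
  cfg0 <- reference_sim_config(N = N, h2max = h2max, M = M,
                               stratification = stratification,
                               setting = setting, seed = seeds[1])
  panel <- NULL
  k_top <- which.max(diag(cfg0$Sigma_g))
  tests <- c("HIPO-D1", "most_heritable")
  per_rep <- array(NA_real_, c(length(tests), length(thresholds), n_reps),
                   dimnames = list(tests, paste0("p<", thresholds), NULL))
  n_null <- integer(n_reps)
  for (r in seq_len(n_reps)) {
    cfg <- cfg0
    cfg$seed <- seeds[r + 1L]
    study <- simulate_sumstats(cfg, panel = panel,
                               block_size = block_size,
                               decay_rate = decay_rate)
    if (is.null(panel)) panel <- study$ld_panel  # reuse across replicates
    cs <- if (covariances == "true") {
      Sv <- if (is.null(cfg$Sigma_v)) 0 else cfg$Sigma_v
      covariance_set(cfg$Sigma_g, study$Sigma_e + Sv, N = cfg$N,
                     M = cfg$M, traits = cfg$traits)
    } else {
      suppressWarnings(estimate_covariances(study$panel, M = cfg$M))
    }
    fit <- hipo(study$panel, covariances = cs, M = cfg$M)
    nul <- study$truth$null_snps
    n_null[r] <- sum(nul)
    p_trait <- 2 * stats::pnorm(-abs(study$panel$Z[nul, k_top]))
    p_d1 <- fit$p[nul, 1]
    for (t in seq_along(thresholds)) {
      per_rep["HIPO-D1", t, r] <- mean(p_d1 < thresholds[t])
      per_rep["most_heritable", t, r] <- mean(p_trait < thresholds[t])
    }
  }
  list(rates = apply(per_rep, 1:2, mean), per_rep = per_rep,
       n_null = n_null, most_heritable = cfg0$traits[k_top],
       design = list(N = N, h2max = h2max, M = M, n_reps = n_reps,
                     stratification = stratification, setting = setting,
                     covariances = covariances, seed = seed))
}
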