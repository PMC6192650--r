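# Post-processing: fixed-effect meta-analysis comparator, greedy LD
# clumping into independent loci, novel-locus calling, and evaluation
# metrics (type-I error, genomic control, mean chi-square, QQ data).

#' Inverse-standard-error weighted meta-analysis z-scores
#'
#' Fixed-effect combination across traits assuming no sample overlap:
#' \eqn{z_{meta} = \sum_k w_k \hat\beta_k / \sqrt{\sum_k w_k^2 s_k^2}} with
#' \eqn{w_k = 1/s_k^2}.
#'
#' @param panel a \code{\link{multi_trait_panel}}.
#' @param se per-trait standard errors of the standardized effect estimates
#'   (defaults to the panel's).
#' @return per-SNP meta z vector.
#' @export
meta_z <- function(panel, se = panel$se) {
  B <- panel_effects(panel)
  w <- 1 / se^2
  num <- as.vector(B %*% w)
  num / sqrt(sum(w^2 * se^2))
}

#' Greedy LD clumping into independent loci
#'
#' PLINK-style greedy clumping by significance: repeatedly take the
#' smallest remaining p-value at or below \code{p_thresh} as a lead SNP and
#' assign to its locus (removing from further consideration) all SNPs with
#' \eqn{r^2 \ge} \code{r2_thresh} with the lead or within \code{dist_bp} of
#' it.
#'
#' @param pvals per-SNP p-values.
#' @param snps SNP index data frame (snp_id, chrom, pos_bp) aligned with
#'   \code{pvals}.
#' @param panel optional \code{\link{ld_panel}} supplying pairwise
#'   \eqn{r^2}; with \code{NULL} only the distance rule is applied.
#' @param p_thresh significance threshold (default 5e-8).
#' @param r2_thresh LD threshold (default 0.1).
#' @param dist_bp distance threshold (default 500 kb; 1 Mb is the common
#'   sensitivity setting).
#' @param source label recorded on each locus.
#' @return data frame of loci in discovery order: lead SNP, position, lead
#'   p-value, member count, source.
#' @export
clump <- function(pvals, snps, panel = NULL, p_thresh = 5e-8,
                  r2_thresh = 0.1, dist_bp = 5e5, source = NA_character_) {
  stopifnot(length(pvals) == nrow(snps))
  cand <- which(pvals <= p_thresh & !is.na(pvals))
  loci <- list()
  alive <- rep(TRUE, length(cand))
  ord <- order(pvals[cand])
  for (i in ord) {
    if (!alive[i]) next
    lead <- cand[i]
    near <- abs(snps$pos_bp[cand] - snps$pos_bp[lead]) <= dist_bp &
      snps$chrom[cand] == snps$chrom[lead]
    linked <- if (!is.null(panel)) .ld_r2(panel, lead, cand) >= r2_thresh
              else rep(FALSE, length(cand))
    member <- alive & (near | linked)
    alive[member] <- FALSE
    loci[[length(loci) + 1L]] <- data.frame(
      snp_id = snps$snp_id[lead], chrom = snps$chrom[lead],
      pos_bp = snps$pos_bp[lead], p = pvals[lead], idx = lead,
      n_members = sum(member), source = source, stringsAsFactors = FALSE)
  }
  if (!length(loci))
    return(data.frame(snp_id = character(), chrom = integer(),
                      pos_bp = integer(), p = numeric(), idx = integer(),
                      n_members = integer(), source = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, loci)
}

#' Identify novel loci relative to a reference set
#'
#' A candidate locus is novel only if its lead SNP is at least
#' \code{dist_bp} away from \emph{and} has \eqn{r^2 <} \code{r2_thresh}
#' with every reference lead (both conditions required).
#'
#' @param candidate,reference loci data frames from \code{\link{clump}}
#'   (clumped against the same panel).
#' @param panel optional \code{\link{ld_panel}} for \eqn{r^2}.
#' @param dist_bp,r2_thresh novelty thresholds (defaults 0.5 Mb, 0.1).
#' @return the novel subset of \code{candidate}.
#' @export
novel_loci <- function(candidate, reference, panel = NULL,
                       dist_bp = 5e5, r2_thresh = 0.1) {
  if (nrow(reference) == 0 || nrow(candidate) == 0) return(candidate)
  keep <- vapply(seq_len(nrow(candidate)), function(i) {
    same_chr <- reference$chrom == candidate$chrom[i]
    far <- !same_chr | abs(reference$pos_bp - candidate$pos_bp[i]) >= dist_bp
    if (!all(far)) return(FALSE)
    if (!is.null(panel)) {
      r2 <- .ld_r2(panel, candidate$idx[i], reference$idx)
      if (any(r2 >= r2_thresh)) return(FALSE)
    }
    TRUE
  }, logical(1))
  candidate[keep, , drop = FALSE]
}

#' Classify loci as true or false discoveries against simulation truth
#'
#' A locus counts as true if its lead SNP lies within \code{dist_bp} of, or
#' has \eqn{r^2 \ge} \code{r2_thresh} with, any SNP of nonzero marginal
#' effect (inclusive boundary).  The matching rule is recorded in the
#' result.
#'
#' @param loci loci data frame from \code{\link{clump}}.
#' @param truth truth set of a \code{\link{simulate_sumstats}} study
#'   (needs \code{beta_marginal}).
#' @param snps SNP index aligned with the truth matrices.
#' @param panel optional \code{\link{ld_panel}}.
#' @param dist_bp,r2_thresh matching thresholds.
#' @return list with counts \code{true}, \code{false}, logical vector
#'   \code{is_true} and the rule description.
#' @export
classify_true_loci <- function(loci, truth, snps, panel = NULL,
                               dist_bp = 5e5, r2_thresh = 0.1) {
  assoc <- which(rowSums(truth$beta_marginal != 0) > 0)
  is_true <- vapply(seq_len(nrow(loci)), function(i) {
    same_chr <- snps$chrom[assoc] == loci$chrom[i]
    if (any(same_chr &
            abs(snps$pos_bp[assoc] - loci$pos_bp[i]) <= dist_bp)) return(TRUE)
    if (!is.null(panel) &&
        any(.ld_r2(panel, loci$idx[i], assoc) >= r2_thresh)) return(TRUE)
    FALSE
  }, logical(1))
  list(true = sum(is_true), false = sum(!is_true), is_true = is_true,
       rule = sprintf("lead within %g bp of, or r2 >= %g with, a SNP of nonzero marginal effect (inclusive)",
                      dist_bp, r2_thresh))
}

#' Empirical type-I error over truly null SNPs
#'
#' Fraction of null-SNP p-values below each threshold; with a matrix of
#' p-values (replicates in columns) the per-replicate rates are averaged.
#'
#' @param pvals vector (one replicate) or matrix (replicates in columns) of
#'   p-values at truly null SNPs.
#' @param thresholds significance thresholds.
#' @return named vector of rates.
#' @export
type1_error <- function(pvals, thresholds = c(0.05, 0.01, 0.001)) {
  pm <- as.matrix(pvals)
  if (nrow(pm) == 0) stop("empty null set", call. = FALSE)
  rates <- vapply(thresholds, function(t) mean(colMeans(pm < t)), numeric(1))
  stats::setNames(rates, paste0("p<", thresholds))
}

#' Genomic control factor and mean chi-square
#'
#' \eqn{\lambda_{GC} = median(z^2) / 0.4549364} (the null
#' \eqn{\chi^2_1} median) and the mean \eqn{\chi^2 = mean(z^2)}.
#'
#' @param z z-score vector.
#' @return list with \code{lambda_gc} and \code{mean_chisq}.
#' @export
lambda_gc_mean_chisq <- function(z) {
  if (!length(z)) stop("empty z vector", call. = FALSE)
  list(lambda_gc = stats::median(z^2) / stats::qchisq(0.5, 1),
       mean_chisq = mean(z^2))
}

#' QQ-plot coordinates
#'
#' Pairs of expected versus observed \eqn{-\log_{10} p} under the uniform
#' null, sorted by significance.
#'
#' @param pvals p-value vector.
#' @return data frame with \code{expected} and \code{observed}.
#' @export
qq_data <- function(pvals) {
  p <- sort(pvals[!is.na(pvals)])
  n <- length(p)
  data.frame(expected = -log10(stats::ppoints(n)), observed = -log10(p))
}

#' Bonferroni-adjusted genome-wide threshold
#'
#' \eqn{5 \times 10^{-8} / (n_{traits} + n_{components})}, accounting for
#' testing each trait and each retained component.
#'
#' @param n_traits,n_components counts (sum must be at least 1).
#' @export
bonferroni_threshold <- function(n_traits, n_components) {
  if (n_traits < 0 || n_components < 0 || n_traits + n_components < 1)
    stop("counts must be non-negative and sum to at least 1", call. = FALSE)
  5e-8 / (n_traits + n_components)
}

#' Evaluation report for a simulated study
#'
#' Computes, for each supplied test (columns of p-value/z matrices), the
#' type-I error over truly null SNPs, genomic control factor, mean
#' chi-square, locus counts (total / true / novel relative to single-trait
#' loci) and QQ coordinates; mirrors the standard simulation-report layout.
#'
#' @param study a \code{\link{simulate_sumstats}} study.
#' @param z,p matrices of z-scores and p-values (columns = tests).
#' @param thresholds type-I-error thresholds.
#' @param p_thresh,r2_thresh,dist_bp clumping parameters.
#' @param reference_loci optional loci data frame defining "known" loci for
#'   novelty calling (e.g. single-trait discoveries).
#' @param qq include QQ coordinates per test.
#' @return list of per-test metrics plus the matching rule used.
#' @export
evaluation_report <- function(study, z, p, thresholds = c(0.05, 0.01, 0.001),
                              p_thresh = 5e-8, r2_thresh = 0.1, dist_bp = 5e5,
                              reference_loci = NULL, qq = FALSE) {
  null_mask <- study$truth$null_snps
  snps <- study$panel$snps
  tests <- colnames(p) %||% paste0("test", seq_len(ncol(p)))
  out <- lapply(seq_len(ncol(p)), function(j) {
    loci <- clump(p[, j], snps, study$ld_panel, p_thresh = p_thresh,
                  r2_thresh = r2_thresh, dist_bp = dist_bp,
                  source = tests[j])
    cls <- if (nrow(loci)) classify_true_loci(loci, study$truth, snps,
                                              study$ld_panel,
                                              dist_bp = dist_bp,
                                              r2_thresh = r2_thresh)
           else list(true = 0L, false = 0L)
    nov <- if (!is.null(reference_loci))
      nrow(novel_loci(loci, reference_loci, study$ld_panel,
                      dist_bp = dist_bp, r2_thresh = r2_thresh))
    gc <- lambda_gc_mean_chisq(z[, j])
    res <- list(test = tests[j],
                type1_error = type1_error(p[null_mask, j], thresholds),
                lambda_gc = gc$lambda_gc, mean_chisq = gc$mean_chisq,
                n_loci = nrow(loci), n_true_loci = cls$true,
                n_false_loci = cls$false)
    if (!is.null(nov)) res$n_novel_loci <- nov
    if (qq) res$qq <- qq_data(p[, j])
    res
  })
  names(out) <- tests
  attr(out, "rule") <- sprintf(
    "loci: p<=%g, greedy clump r2>=%g or <=%g bp; truth match inclusive",
    p_thresh, r2_thresh, dist_bp)
  out
}
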