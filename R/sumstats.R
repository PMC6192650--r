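# Reading, QC-filtering and harmonization of per-trait GWAS summary
# statistics into a multi-trait panel on the standardized (per 1-SD genotype,
# 1-SD phenotype) scale.

#' Effective sample size of a case-control GWAS
#'
#' The equivalent quantitative-trait sample size of a binary-trait GWAS,
#' \eqn{N_{eff} = N_{case} N_{control} / (N_{case} + N_{control})}.
#'
#' @param n_case,n_control positive case and control counts (vectorized).
#' @return effective sample size.
#' @examples
#' effective_sample_size(1000, 1000)  # 500
#' @export
effective_sample_size <- function(n_case, n_control) {
  if (any(n_case <= 0) || any(n_control <= 0))
    stop("case and control counts must be positive", call. = FALSE)
  n_case * n_control / (n_case + n_control)
}

# Canonical internal column names for a summary-statistic table.
.SUMSTAT_COLS <- c("snp_id", "chrom", "pos_bp", "a1", "a2",
                   "beta", "se", "z", "n", "maf")

#' Construct a per-trait summary-statistic table
#'
#' Validates and normalizes one trait's GWAS summary statistics.  Missing
#' \code{z} is reconstructed as \code{beta/se}, missing \code{beta} as
#' \code{z*se}; if case/control counts are supplied instead of \code{n}, the
#' effective sample size is used.  Rows are sorted by (chrom, pos_bp).
#'
#' @param df data frame with columns \code{snp_id}, \code{chrom},
#'   \code{pos_bp}, \code{a1} (effect allele), \code{a2} (other allele), and
#'   at least two of \code{beta}, \code{se}, \code{z}; optionally \code{n} or
#'   \code{n_case}/\code{n_control}, and \code{maf}.
#' @param trait_id trait label.
#' @return object of class \code{sumstat_table} (a data frame).
#' @export
sumstat_table <- function(df, trait_id) {
  need <- c("snp_id", "chrom", "pos_bp", "a1", "a2")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(df$snp_id)) stop("duplicated snp_id in table", call. = FALSE)
  if (is.null(df$n) && !is.null(df$n_case) && !is.null(df$n_control))
    df$n <- effective_sample_size(df$n_case, df$n_control)
  if (is.null(df$se) && !is.null(df$beta) && !is.null(df$z))
    df$se <- ifelse(df$z == 0, NA_real_, df$beta / df$z)
  if (!is.null(df$se) && any(df$se <= 0, na.rm = TRUE))
    stop("standard errors must be positive", call. = FALSE)
  if (is.null(df$z) && !is.null(df$beta) && !is.null(df$se)) df$z <- df$beta / df$se
  if (is.null(df$beta) && !is.null(df$z) && !is.null(df$se)) df$beta <- df$z * df$se
  if (is.null(df$z)) stop("need two of beta/se/z to build a summary-statistic table", call. = FALSE)
  if (!is.null(df$beta) && !is.null(df$se)) {
    bad <- abs(df$z - df$beta / df$se) >= 1e-8 * pmax(1, abs(df$z))
    if (any(bad, na.rm = TRUE)) stop("inconsistent beta/se/z in input", call. = FALSE)
  }
  if (!is.null(df$maf) && any(df$maf < 0 | df$maf > 0.5, na.rm = TRUE))
    stop("maf must lie in [0, 0.5]", call. = FALSE)
  df$a1 <- toupper(df$a1); df$a2 <- toupper(df$a2)
  df <- df[order(df$chrom, df$pos_bp), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, trait_id = trait_id, class = c("sumstat_table", "data.frame"))
}

#' Read a GWAS summary-statistic file
#'
#' Whitespace/tab-delimited text with a header; gzip is handled
#' transparently.  Column names are mapped to the internal schema through
#' \code{col_map}; the defaults match the common GWAS file conventions.
#'
#' @param file path to the file (optionally gzipped).
#' @param trait_id trait label (defaults to the file name).
#' @param col_map named character vector mapping internal names
#'   (\code{snp_id}, \code{chrom}, \code{pos_bp}, \code{a1}, \code{a2},
#'   \code{beta}, \code{se}, \code{z}, \code{n}, \code{n_case},
#'   \code{n_control}, \code{maf}) to column names in the file.
#' @return a \code{\link{sumstat_table}}.
#' @export
read_sumstats <- function(file, trait_id = sub("\\.(txt|tsv|gz)+$", "", basename(file)),
                          col_map = c(snp_id = "SNP", chrom = "CHR", pos_bp = "BP",
                                      a1 = "A1", a2 = "A2", beta = "BETA", se = "SE",
                                      z = "Z", n = "N", n_case = "N_CASE",
                                      n_control = "N_CONTROL", maf = "FRQ")) {
  raw <- utils::read.table(file, header = TRUE, stringsAsFactors = FALSE,
                           check.names = FALSE)
  present <- col_map[col_map %in% names(raw)]
  df <- raw[, present, drop = FALSE]
  names(df) <- names(present)
  sumstat_table(df, trait_id)
}

#' Write a summary-statistic table
#'
#' Inverse of \code{\link{read_sumstats}} under the default column map.
#'
#' @param table a \code{sumstat_table}.
#' @param file output path.
#' @export
write_sumstats <- function(table, file) {
  out <- data.frame(SNP = table$snp_id, CHR = table$chrom, BP = table$pos_bp,
                    A1 = table$a1, A2 = table$a2, BETA = table$beta,
                    SE = table$se, Z = table$z, N = table$n)
  if (!is.null(table$maf)) out$FRQ <- table$maf
  utils::write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Quality-control filter for a summary-statistic table
#'
#' Removes markers that (1) have an extremely large effect
#' (\eqn{\chi^2 = z^2 > 80}), (2) fall in the MHC region (chromosome 6,
#' 26-34 Mb inclusive), (3) have reference MAF below 5\%, (4) have sample
#' size below 0.67 times the 90th percentile of the table's sample sizes
#' (computed after rules 1-3, once; the threshold is recorded so that
#' re-filtering is idempotent), or (5) whose allele pair does not match the
#' reference alleles (a swap of effect/other allele is allowed; missing
#' reference entries are removed under this rule and logged separately).
#'
#' @param table a \code{\link{sumstat_table}}.
#' @param reference data frame with columns \code{snp_id}, \code{a1},
#'   \code{a2} and \code{maf} giving reference-panel alleles and allele
#'   frequencies.
#' @param n_quantile_factor multiplier on the 90th sample-size percentile
#'   (default 0.67).
#' @param chisq_max chi-square cutoff (default 80, strict inequality).
#' @param maf_min minimum reference MAF (default 0.05).
#' @param mhc length-2 base-pair bounds of the excluded chromosome-6 region.
#' @return the filtered \code{sumstat_table}; attribute \code{removal_log}
#'   holds per-rule removal counts, attribute \code{qc_n_threshold} the
#'   sample-size cutoff applied.
#' @export
qc_filter <- function(table, reference, n_quantile_factor = 0.67,
                      chisq_max = 80, maf_min = 0.05,
                      mhc = c(26e6, 34e6)) {
  if (nrow(table) == 0) stop("empty summary-statistic table", call. = FALSE)
  idx <- match(table$snp_id, reference$snp_id)
  ref_found <- !is.na(idx)
  ref_a1 <- toupper(reference$a1[idx]); ref_a2 <- toupper(reference$a2[idx])
  ref_maf <- reference$maf[idx]

  r1 <- table$z^2 > chisq_max
  r2 <- table$chrom == 6 & table$pos_bp >= mhc[1] & table$pos_bp <= mhc[2]
  r3 <- ref_found & ref_maf < maf_min
  allele_ok <- ref_found &
    ((table$a1 == ref_a1 & table$a2 == ref_a2) |
     (table$a1 == ref_a2 & table$a2 == ref_a1))
  r5 <- !allele_ok
  # sequential attribution: each record counted under the first rule it hits
  hit1 <- r1
  hit2 <- r2 & !hit1
  hit3 <- r3 & !(hit1 | hit2)
  hit5 <- r5 & !(hit1 | hit2 | hit3)
  hit5_missing <- hit5 & !ref_found

  keep <- !(hit1 | hit2 | hit3 | hit5)
  surv <- table[keep, , drop = FALSE]

  # rule 4: the quantile is a property of the study's sample-size
  # distribution; reuse a previously recorded threshold so the filter is
  # idempotent under re-application.
  n_thresh <- attr(table, "qc_n_threshold")
  if (is.null(n_thresh)) {
    if (is.null(surv$n) || all(is.na(surv$n))) n_thresh <- -Inf
    else n_thresh <- n_quantile_factor *
        stats::quantile(surv$n, 0.9, na.rm = TRUE, names = FALSE)
  }
  hit4 <- !is.null(surv$n) & !is.na(surv$n) & surv$n < n_thresh
  out <- surv[!hit4, , drop = FALSE]
  rownames(out) <- NULL

  log <- c(chisq_gt_max = sum(hit1), mhc_region = sum(hit2),
           low_maf = sum(hit3), low_n = sum(hit4),
           allele_mismatch = sum(hit5) - sum(hit5_missing),
           missing_in_reference = sum(hit5_missing))
  structure(out, trait_id = attr(table, "trait_id"),
            removal_log = log, qc_n_threshold = n_thresh,
            class = class(table))
}

.PALINDROMIC <- c("A.T", "T.A", "C.G", "G.C")

#' Harmonize summary-statistic tables into a multi-trait panel
#'
#' Intersects SNPs across traits, orients every record to the reference
#' effect allele (flipping the sign of beta/z when a trait reports the
#' swapped allele pair), and optionally drops strand-ambiguous (A/T, C/G)
#' SNPs.  SNPs with an irreconcilable allele pair in any trait are dropped
#' and logged.
#'
#' @param tables list of QC-filtered \code{\link{sumstat_table}} objects.
#' @param reference data frame with \code{snp_id}, \code{a1}, \code{a2} (the
#'   orientation target).
#' @param drop_ambiguous drop palindromic SNPs (default \code{TRUE}).
#' @return a \code{\link{multi_trait_panel}}; attribute \code{harmonize_log}
#'   counts dropped SNPs.
#' @export
harmonize <- function(tables, reference, drop_ambiguous = TRUE) {
  stopifnot(length(tables) >= 1)
  traits <- vapply(tables, function(t) attr(t, "trait_id"), character(1))
  ids <- Reduce(intersect, lapply(tables, `[[`, "snp_id"))
  ids <- intersect(ids, reference$snp_id)
  if (length(ids) == 0) stop("no SNPs shared across all traits and the reference", call. = FALSE)

  ridx <- match(ids, reference$snp_id)
  ref_a1 <- toupper(reference$a1[ridx]); ref_a2 <- toupper(reference$a2[ridx])
  n_ambig <- 0L
  if (drop_ambiguous) {
    ambig <- paste(ref_a1, ref_a2, sep = ".") %in% .PALINDROMIC
    n_ambig <- sum(ambig)
    ids <- ids[!ambig]; ref_a1 <- ref_a1[!ambig]; ref_a2 <- ref_a2[!ambig]
  }
  K <- length(tables)
  M <- length(ids)
  Z <- matrix(NA_real_, M, K, dimnames = list(NULL, traits))
  N <- numeric(K); names(N) <- traits
  bad <- logical(M)
  for (k in seq_len(K)) {
    t <- tables[[k]]
    i <- match(ids, t$snp_id)
    same <- t$a1[i] == ref_a1 & t$a2[i] == ref_a2
    swap <- t$a1[i] == ref_a2 & t$a2[i] == ref_a1
    bad <- bad | !(same | swap)
    Z[, k] <- ifelse(swap, -t$z[i], t$z[i])
    N[k] <- if (is.null(t$n)) NA_real_ else stats::median(t$n[i], na.rm = TRUE)
  }
  n_irrec <- sum(bad)
  ids <- ids[!bad]; Z <- Z[!bad, , drop = FALSE]
  ref_a1 <- ref_a1[!bad]; ref_a2 <- ref_a2[!bad]
  if (length(ids) == 0) stop("no SNPs left after allele reconciliation", call. = FALSE)

  t1 <- tables[[1]]
  i1 <- match(ids, t1$snp_id)
  snps <- data.frame(snp_id = ids, chrom = t1$chrom[i1], pos_bp = t1$pos_bp[i1],
                     a1 = ref_a1, a2 = ref_a2, stringsAsFactors = FALSE)
  ord <- order(snps$chrom, snps$pos_bp)
  panel <- multi_trait_panel(snps[ord, , drop = FALSE], Z[ord, , drop = FALSE], N)
  attr(panel, "harmonize_log") <- c(ambiguous_dropped = n_ambig,
                                    irreconcilable_dropped = n_irrec)
  panel
}

#' Standardized effect sizes from z-scores
#'
#' On the standardized genotype/phenotype scale the per-SNP effect estimate
#' is approximately \eqn{z / \sqrt{N}}; the map is exactly invertible.
#'
#' @param Z z-score matrix (M x K) or vector.
#' @param N per-trait sample sizes (length K, recycled for a vector Z).
#' @return matrix (or vector) of standardized effects.
#' @export
standardized_effects <- function(Z, N) {
  if (any(N <= 1)) stop("sample sizes must exceed 1", call. = FALSE)
  if (is.matrix(Z)) sweep(Z, 2, sqrt(N), "/") else Z / sqrt(N)
}

#' Multi-trait summary-statistic panel
#'
#' Harmonized container for K traits over M SNPs: SNP index, z-score matrix,
#' per-trait sample sizes and (optionally) per-SNP LD scores.
#'
#' @param snps data frame with \code{snp_id}, \code{chrom}, \code{pos_bp} and
#'   optionally alleles.
#' @param Z M x K numeric matrix of z-scores (column names = trait labels).
#' @param N per-trait sample sizes.
#' @param ld_scores optional length-M LD-score vector.
#' @param se optional per-trait standard errors of the standardized effect
#'   estimates (defaults to \code{1/sqrt(N)}).
#' @return object of class \code{multi_trait_panel}.
#' @export
multi_trait_panel <- function(snps, Z, N, ld_scores = NULL, se = NULL) {
  Z <- as.matrix(Z)
  stopifnot(nrow(snps) == nrow(Z), length(N) == ncol(Z))
  if (any(!is.finite(Z))) stop("z-scores must be finite", call. = FALSE)
  if (!is.null(ld_scores)) stopifnot(length(ld_scores) == nrow(Z))
  if (is.null(colnames(Z))) colnames(Z) <- paste0("trait", seq_len(ncol(Z)))
  if (is.null(names(N))) names(N) <- colnames(Z)
  if (is.null(se)) se <- 1 / sqrt(N)
  structure(list(snps = snps, Z = Z, N = N, se = se, ld_scores = ld_scores,
                 traits = colnames(Z)),
            class = "multi_trait_panel")
}

#' @export
print.multi_trait_panel <- function(x, ...) {
  cat(sprintf("multi-trait panel: %d SNPs x %d traits (%s)\n",
              nrow(x$Z), ncol(x$Z), paste(x$traits, collapse = ", ")))
  cat("sample sizes:", paste(signif(x$N, 4), collapse = ", "), "\n")
  if (!is.null(x$ld_scores))
    cat(sprintf("mean LD score: %.3f\n", mean(x$ld_scores)))
  invisible(x)
}

# Standardized effect matrix of a panel (B = Z / sqrt(N) columnwise).
#' Extract the standardized effect matrix of a panel
#' @param panel a \code{multi_trait_panel}.
#' @return M x K matrix of standardized effect estimates.
#' @export
panel_effects <- function(panel) standardized_effects(panel$Z, panel$N)

#' Write / read a harmonized panel
#'
#' The panel is serialized as one delimited table (SNP index, per-SNP LD
#' score, one z column per trait) plus a JSON sidecar holding trait labels
#' and sample sizes.
#'
#' @param panel a \code{multi_trait_panel}.
#' @param file output path (sidecar written to \code{<file>.json}).
#' @export
write_panel <- function(panel, file) {
  df <- panel$snps
  if (!is.null(panel$ld_scores)) df$L2 <- panel$ld_scores
  for (k in panel$traits) df[[paste0("z.", k)]] <- panel$Z[, k]
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(traits = panel$traits, N = as.list(panel$N), se = as.list(panel$se))
  jsonlite::write_json(meta, paste0(file, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname write_panel
#' @param file path written by \code{write_panel}.
#' @export
read_panel <- function(file) {
  df <- utils::read.table(file, header = TRUE, stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(paste0(file, ".json"), simplifyVector = TRUE)
  zc <- paste0("z.", meta$traits)
  Z <- as.matrix(df[, zc, drop = FALSE]); colnames(Z) <- meta$traits
  snps <- df[, setdiff(names(df), c(zc, "L2")), drop = FALSE]
  multi_trait_panel(snps, Z, unlist(meta$N),
                    ld_scores = if ("L2" %in% names(df)) df$L2 else NULL,
                    se = unlist(meta$se))
}
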