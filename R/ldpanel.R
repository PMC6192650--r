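# Synthetic LD reference panel (block-diagonal genotype correlation) and LD
# score computation.

#' Construct a block-diagonal LD reference panel
#'
#' Builds a synthetic stand-in for a genotype reference panel: SNPs are
#' grouped into LD blocks, with within-block genotype correlation following
#' an AR(1) profile \eqn{r_{jj'} = \rho^{|j-j'|}} (or user-supplied block
#' matrices).  Blocks are positioned further apart than \code{window_bp}, so
#' all LD is contained within blocks.
#'
#' @param n_blocks number of LD blocks.
#' @param block_size SNPs per block.
#' @param decay_rate AR(1) correlation parameter \eqn{\rho} in [0, 1).
#' @param maf_range range for uniformly drawn reference minor allele
#'   frequencies.
#' @param spacing_bp base-pair distance between adjacent SNPs in a block.
#' @param window_bp LD window radius; blocks are separated by more than this.
#' @param blocks optional list of correlation matrices overriding the AR(1)
#'   construction (lengths define block sizes).
#' @param seed RNG seed for the MAF draw.
#' @return object of class \code{ld_panel}: SNP index (snp_id, chrom,
#'   pos_bp, maf, block), list of per-block correlation matrices, and the
#'   window.
#' @export
make_ld_panel <- function(n_blocks = NULL, block_size = NULL, decay_rate = 0.5,
                          maf_range = c(0.05, 0.5), spacing_bp = 2500,
                          window_bp = 1e6, blocks = NULL, seed = 1L) {
  if (is.null(blocks)) {
    if (decay_rate >= 1 || decay_rate < 0) stop("decay_rate must be in [0, 1)", call. = FALSE)
    if (block_size < 1) stop("block_size must be >= 1", call. = FALSE)
    R <- decay_rate^abs(outer(seq_len(block_size), seq_len(block_size), "-"))
    blocks <- rep(list(R), n_blocks)
    uniform <- TRUE
  } else {
    n_blocks <- length(blocks)
    for (R in blocks) .check_square(R, "LD block")
    sizes <- vapply(blocks, nrow, integer(1))
    uniform <- length(unique(sizes)) == 1 &&
      all(vapply(blocks, function(R) identical(R, blocks[[1]]), logical(1)))
  }
  sizes <- vapply(blocks, nrow, integer(1))
  M <- sum(sizes)
  block_id <- rep(seq_len(n_blocks), sizes)
  within <- unlist(lapply(sizes, seq_len))
  gap <- window_bp + max(sizes) * spacing_bp + 1
  # lay blocks contiguously over (at least) 22 chromosomes, capping the
  # per-chromosome span so positions stay in integer range
  per_chrom <- max(1, min(ceiling(n_blocks / 22),
                          floor((.Machine$integer.max - gap) / gap)))
  chrom <- (block_id - 1L) %/% per_chrom + 1L
  chrom_block <- (block_id - 1L) %% per_chrom
  pos <- chrom_block * gap + (within - 1) * spacing_bp + 1
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  maf <- stats::runif(M, maf_range[1], maf_range[2])
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  snps <- data.frame(snp_id = paste0("rs", seq_len(M)), chrom = chrom,
                     pos_bp = as.integer(pos), maf = maf, block = block_id,
                     stringsAsFactors = FALSE)
  structure(list(snps = snps, blocks = blocks, sizes = sizes,
                 block_start = c(0L, cumsum(sizes))[seq_len(n_blocks)] + 1L,
                 window_bp = window_bp, uniform = uniform),
            class = "ld_panel")
}

#' @export
print.ld_panel <- function(x, ...) {
  cat(sprintf("LD panel: %d SNPs in %d blocks (sizes %s), window %g bp\n",
              nrow(x$snps), length(x$blocks),
              paste(range(x$sizes), collapse = "-"), x$window_bp))
  invisible(x)
}

# Squared genotype correlation between SNP indices of a panel (0 across
# blocks).  i and j are recycled to a common length.
.ld_r2 <- function(panel, i, j) {
  n <- max(length(i), length(j))
  i <- rep_len(i, n); j <- rep_len(j, n)
  bi <- panel$snps$block[i]; bj <- panel$snps$block[j]
  r2 <- numeric(n)
  for (s in which(bi == bj)) {
    o <- panel$block_start[bi[s]]
    r2[s] <- panel$blocks[[bi[s]]][i[s] - o + 1L, j[s] - o + 1L]^2
  }
  r2
}

#' Compute LD scores from an LD panel
#'
#' The LD score of SNP j is the sum of squared genotype correlations
#' \eqn{l_j = \sum_{j'} r^2_{jj'}} over SNPs within \code{window_bp} (same
#' block; the self term is included).  With \code{adjusted = TRUE} the
#' finite-reference-panel bias correction
#' \eqn{\tilde r^2 = r^2 - (1 - r^2)/(n_{ref} - 2)} is applied.
#'
#' @param panel an \code{\link{ld_panel}}.
#' @param adjusted apply the small-panel adjustment.
#' @param n_ref reference panel sample count (required when
#'   \code{adjusted = TRUE}; must exceed 2).
#' @return object of class \code{ld_score_set}: vector \code{l} and
#'   \code{mean_l}.
#' @export
compute_ld_scores <- function(panel, adjusted = FALSE, n_ref = NULL) {
  if (adjusted && (is.null(n_ref) || n_ref <= 2))
    stop("adjusted LD scores require n_ref > 2", call. = FALSE)
  window <- panel$window_bp
  score_block <- function(R, pos) {
    r2 <- R^2
    if (length(pos) > 1) {
      inwin <- abs(outer(pos, pos, "-")) <= window
      r2[!inwin] <- 0
    }
    if (adjusted) {
      adj <- r2 - (1 - r2) / (n_ref - 2)
      adj[!is.finite(adj)] <- 0
      r2 <- ifelse(r2 > 0 | row(r2) == col(r2), adj, 0)
      diag(r2) <- 1
    }
    rowSums(r2)
  }
  pos_split <- split(panel$snps$pos_bp, panel$snps$block)
  if (panel$uniform) {
    # all blocks identical: score one block, tile
    l1 <- score_block(panel$blocks[[1]], pos_split[[1]])
    l <- rep(l1, length(panel$blocks))
  } else {
    l <- unlist(lapply(seq_along(panel$blocks), function(b)
      score_block(panel$blocks[[b]], pos_split[[b]])), use.names = FALSE)
  }
  structure(list(l = l, mean_l = mean(l)), class = "ld_score_set")
}

#' @export
print.ld_score_set <- function(x, ...) {
  cat(sprintf("LD scores: %d SNPs, mean %.4f, range [%.4f, %.4f]\n",
              length(x$l), x$mean_l, min(x$l), max(x$l)))
  invisible(x)
}

#' Write / read LD scores in the conventional delimited format
#'
#' Columns CHR, SNP, BP, L2.
#'
#' @param ld an \code{ld_score_set}.
#' @param snps SNP index data frame (snp_id, chrom, pos_bp) aligned with
#'   \code{ld$l}.
#' @param file output path.
#' @export
write_ld_scores <- function(ld, snps, file) {
  utils::write.table(data.frame(CHR = snps$chrom, SNP = snps$snp_id,
                                BP = snps$pos_bp, L2 = ld$l),
                     file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_ld_scores
#' @export
read_ld_scores <- function(file) {
  df <- utils::read.table(file, header = TRUE, stringsAsFactors = FALSE)
  structure(list(l = df$L2, mean_l = mean(df$L2), snps = df),
            class = "ld_score_set")
}
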