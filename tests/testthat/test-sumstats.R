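test_that("effective sample size follows the case-control harmonic form", {
  expect_equal(effective_sample_size(1000, 1000), 500)
  # trio-equivalent ASD counts
  expect_equal(effective_sample_size(4949, 5314), 2562.504726, tolerance = 1e-6)
  expect_equal(effective_sample_size(1, 1), 0.5)
  expect_error(effective_sample_size(0, 10), "positive")
  expect_error(effective_sample_size(10, -1), "positive")
})

test_that("sumstat_table reconstructs missing fields and enforces invariants", {
  df <- data.frame(snp_id = c("a", "b"), chrom = 1L, pos_bp = c(100L, 200L),
                   a1 = "A", a2 = "G", beta = c(0.02, -0.01), se = 0.01)
  t <- sumstat_table(df, "t1")
  expect_equal(t$z, c(2, -1))
  t2 <- sumstat_table(data.frame(snp_id = "a", chrom = 1L, pos_bp = 1L,
                                 a1 = "a", a2 = "g", z = 3, se = 0.1), "t2")
  expect_equal(t2$beta, 0.3)
  expect_equal(t2$a1, "A")  # alleles upper-cased
  expect_error(sumstat_table(data.frame(snp_id = "a", chrom = 1L, pos_bp = 1L,
                                        a1 = "A", a2 = "G", beta = 1, se = 0.1,
                                        z = 5), "t"),
               "inconsistent")
  expect_error(sumstat_table(df[, -1], "t"), "missing columns")
})

test_that("qc removes markers by each rule with a per-rule log", {
  ids <- paste0("s", 1:8)
  tab <- make_table("t1", ids, chrom = c(1, 1, 6, 6, 1, 1, 1, 1),
                    pos_bp = c(1e5, 2e5, 30e6, 35e6, 5e5, 6e5, 7e5, 8e5),
                    z = c(9, 8.94, 1, 1, 1, 1, 1, 1),  # 8.94^2 = 79.92 < 80
                    n = c(1e4, 1e4, 1e4, 1e4, 1e4, 100, 1e4, 1e4))
  ref <- make_reference(ids)
  ref$maf[5] <- 0.01          # low-frequency marker
  ref$a1[7] <- "C"; ref$a2[7] <- "T"  # allele mismatch
  ref <- ref[ref$snp_id != "s8", ]    # missing from reference
  out <- qc_filter(tab, ref)
  log <- attr(out, "removal_log")
  expect_equal(unname(log), c(1, 1, 1, 1, 1, 1))  # one removal per rule path
  # chi^2 = 80 exactly is kept (strict > 80); chrom-6 boundary is inclusive
  expect_true("s2" %in% out$snp_id)
  expect_false("s1" %in% out$snp_id)   # chi^2 = 81
  expect_false("s3" %in% out$snp_id)   # 30 Mb inside MHC
  expect_true("s4" %in% out$snp_id)    # 35 Mb outside MHC
  expect_false("s6" %in% out$snp_id)   # low n
  expect_equal(nrow(out), 2)
})

test_that("qc boundary records behave as specified", {
  tab <- make_table("t", c("a", "b"), chrom = 6L, pos_bp = c(26e6, 34e6), z = 1)
  out <- qc_filter(tab, make_reference(c("a", "b")))
  expect_equal(nrow(out), 0)  # both MHC endpoints removed (inclusive)
})

test_that("qc is idempotent and a clean table passes untouched", {
  set.seed(1)
  ids <- paste0("s", 1:200)
  tab <- make_table("t", ids, z = rnorm(200), n = sample(c(9000, 10000), 200, TRUE))
  ref <- make_reference(ids)
  once <- qc_filter(tab, ref)
  twice <- qc_filter(once, ref)
  expect_equal(as.data.frame(twice), as.data.frame(once))
  expect_equal(sum(attr(once, "removal_log")), 0)
  expect_equal(attr(twice, "removal_log"),
               attr(once, "removal_log"))
})

test_that("harmonize flips swapped alleles and intersects SNPs", {
  ids <- c("a", "b", "c")
  ref <- make_reference(ids)
  t1 <- make_table("t1", ids, z = c(1, 2, 3))
  t2 <- make_table("t2", ids, z = c(3, -1, 2), a1 = "G", a2 = "A")  # swapped
  p <- harmonize(list(t1, t2), ref)
  expect_equal(p$Z[, "t1"], c(1, 2, 3))
  expect_equal(p$Z[, "t2"], c(-3, 1, -2))  # sign flipped
  # flipping twice restores the original orientation
  t2b <- t2; t2b$a1 <- "A"; t2b$a2 <- "G"; t2b$z <- -t2b$z; t2b$beta <- -t2b$beta
  p2 <- harmonize(list(t1, t2b), ref)
  expect_equal(p2$Z, p$Z)
})

test_that("harmonize keeps only SNPs present in every trait", {
  ref <- make_reference(c("a", "b", "c", "d"))
  # pairwise overlaps of 2 but only one SNP in all three tables
  t1 <- make_table("t1", c("a", "b"), pos_bp = c(1e5, 2e5))
  t2 <- make_table("t2", c("a", "c"), pos_bp = c(1e5, 3e5))
  t3 <- make_table("t3", c("a", "d"), pos_bp = c(1e5, 4e5))
  p <- harmonize(list(t1, t2, t3), ref)
  expect_equal(nrow(p$Z), 1)
  expect_equal(p$snps$snp_id, "a")
  expect_error(harmonize(list(make_table("x", "q")), ref), "no SNPs shared")
})

test_that("harmonize output is invariant to input order up to columns", {
  ids <- paste0("s", 1:5)
  ref <- make_reference(ids)
  t1 <- make_table("t1", ids, z = rnorm(5))
  t2 <- make_table("t2", ids, z = rnorm(5))
  a <- harmonize(list(t1, t2), ref)
  b <- harmonize(list(t2, t1), ref)
  expect_equal(a$Z, b$Z[, colnames(a$Z)])
  expect_equal(a$snps, b$snps)
})

test_that("palindromic SNPs are dropped by default but kept on request", {
  ids <- c("a", "b")
  ref <- make_reference(ids, a1 = c("A", "A"), a2 = c("T", "G"))
  t1 <- make_table("t1", ids, a1 = c("A", "A"), a2 = c("T", "G"))
  expect_equal(nrow(harmonize(list(t1), ref)$Z), 1)
  expect_equal(nrow(harmonize(list(t1), ref, drop_ambiguous = FALSE)$Z), 2)
})

test_that("standardized effects invert exactly", {
  Z <- matrix(c(2, 0, -1.5, 3), 2, 2)
  N <- c(10000, 40000)
  B <- standardized_effects(Z, N)
  expect_equal(B[1, 1], 0.02)
  expect_equal(B[2, 1], 0)
  expect_equal(sweep(B, 2, sqrt(N), "*"), Z, tolerance = 1e-12)
  expect_error(standardized_effects(Z, c(1, 10)), "exceed 1")
})

test_that("sumstat and panel files round-trip through disk", {
  dir <- withr::local_tempdir()
  ids <- paste0("s", 1:6)
  t1 <- make_table("t1", ids, z = rnorm(6))
  f <- file.path(dir, "t1.tsv")
  write_sumstats(t1, f)
  back <- read_sumstats(f, trait_id = "t1")
  expect_equal(back$z, t1$z, tolerance = 1e-12)
  p <- harmonize(list(t1, make_table("t2", ids, z = rnorm(6))),
                 make_reference(ids))
  p$ld_scores <- rep(1, 6)
  pf <- file.path(dir, "panel.tsv")
  write_panel(p, pf)
  p2 <- read_panel(pf)
  expect_equal(p2$Z, p$Z, tolerance = 1e-12)
  expect_equal(unname(p2$N), unname(p$N))
})
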