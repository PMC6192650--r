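test_that("identity covariances give unit eigenvalues and trivial weights", {
  d <- hipo_decompose(diag(3), diag(3))
  expect_equal(d$eigenvalues, rep(1, 3))
  # weights form an orthonormal set (identity up to sign and order)
  expect_equal(crossprod(d$weights), diag(3), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("symmetric two-trait case has the analytic solution", {
  Sg <- matrix(c(0.5, 0.25, 0.25, 0.5), 2)
  Sb <- 1e-5 * diag(2)
  d <- hipo_decompose(Sg, Sb)
  a <- sqrt(1 / 2e-5)  # equal weights normalized to unit sampling variance
  expect_equal(unname(d$weights[, 1]), c(a, a), tolerance = 1e-6)
  expect_equal(d$eigenvalues[1] / d$eigenvalues[2], 3, tolerance = 1e-10)
})

test_that("components satisfy the normalization and orthogonality constraints", {
  set.seed(31)
  for (K in c(2, 4, 6)) {
    Sg <- rand_pd(K, 0.3)
    Sb <- rand_pd(K, 1e-4)
    d <- hipo_decompose(Sg, Sb)
    G <- t(d$weights) %*% Sb %*% d$weights
    expect_equal(G, diag(K), tolerance = 1e-8, ignore_attr = TRUE)
    expect_true(all(diff(d$eigenvalues) <= 1e-8))
    expect_true(all(d$eigenvalues >= -1e-8))
    # eigenvalue sum identity
    expect_equal(sum(d$eigenvalues), sum(diag(solve(Sb) %*% Sg)),
                 tolerance = 1e-8)
    # first eigenvalue dominates every single-trait average NCP
    expect_gte(d$eigenvalues[1], max(diag(Sg) / diag(Sb)) - 1e-8)
  }
})

test_that("eigen solution matches a brute-force constrained maximizer", {
  set.seed(17)
  Sg <- rand_pd(3, 0.2)
  Sb <- rand_pd(3, 1e-4)
  d <- hipo_decompose(Sg, Sb)
  bf <- brute_force_components(Sg, Sb)
  for (k in 1:3) {
    u <- d$weights[, k] / sqrt(sum(d$weights[, k]^2))
    v <- bf[, k] / sqrt(sum(bf[, k]^2))
    expect_lt(min(max(abs(u - v)), max(abs(u + v))), 1e-4)
  }
})

test_that("singular sampling covariance is rejected with guidance", {
  Sb <- matrix(c(1, 1, 1, 1), 2)
  expect_error(hipo_decompose(diag(2), Sb), "repair")
  expect_error(hipo_decompose(matrix(0, 0, 0), matrix(0, 0, 0)), "empty")
  expect_error(hipo_decompose(diag(2), diag(3)), "dimension")
})

test_that("component z-scores behave at the edges", {
  Sg <- matrix(c(0.4, 0.1, 0.1, 0.3), 2)
  Sb <- diag(2) * 1e-4
  d <- hipo_decompose(Sg, Sb)
  zs <- component_zscores(matrix(0, 5, 2), d$weights, Sb)
  expect_equal(zs$z, matrix(0, 5, 2), ignore_attr = TRUE)
  expect_equal(zs$p, matrix(1, 5, 2), ignore_attr = TRUE)
  expect_error(component_zscores(matrix(0, 5, 3), d$weights, Sb), "disagree")
  # sign flip of a component leaves |z| and p unchanged
  set.seed(2)
  B <- matrix(rnorm(20), 10, 2) * 0.01
  flip <- d$weights; flip[, 1] <- -flip[, 1]
  expect_equal(abs(component_zscores(B, flip, Sb)$z),
               abs(component_zscores(B, d$weights, Sb)$z))
})

test_that("K = 1 component test reduces to the single-trait z exactly", {
  set.seed(4)
  snps <- data.frame(snp_id = paste0("s", 1:50), chrom = 1L,
                     pos_bp = (1:50) * 1e5)
  Z <- matrix(rnorm(50), dimnames = list(NULL, "t1"))
  pan <- multi_trait_panel(snps, Z, c(t1 = 1e4), ld_scores = rep(1, 50))
  cs <- covariance_set(matrix(0.2), matrix(1 / 1e4), N = 1e4)
  fit <- hipo(pan, covariances = cs)
  expect_equal(unname(fit$z[, 1]), unname(Z[, 1]), tolerance = 1e-8)
})

test_that("first component equals inverse-SE meta-analysis under equal h2 and rg 1", {
  set.seed(8)
  K <- 3
  h2 <- 0.3
  Sg <- matrix(h2, K, K)              # genetic correlation exactly 1
  se <- c(0.01, 0.02, 0.005)          # different per-trait precision
  Sb <- diag(se^2)
  snps <- data.frame(snp_id = paste0("s", 1:100), chrom = 1L,
                     pos_bp = (1:100) * 1e5)
  N <- 1 / se^2
  Z <- matrix(rnorm(300), 100, K, dimnames = list(NULL, c("a", "b", "c")))
  pan <- multi_trait_panel(snps, Z, N, ld_scores = rep(1, 100), se = se)
  cs <- covariance_set(Sg, Sb, N = N)
  fit <- hipo(pan, covariances = cs)
  zm <- meta_z(pan)
  expect_equal(unname(abs(fit$z[, 1])), abs(zm), tolerance = 1e-8)
})

test_that("average NCP applies the mean-LD-score over M scale", {
  expect_equal(average_ncp(c(2, 1), 100, 1000), c(0.2, 0.1))
  expect_equal(average_ncp(0, 50, 10), 0)
  expect_error(average_ncp(1, 1, 0), "positive")
})

test_that("average NCP matches the empirical excess chi-square on simulation", {
  set.seed(21)
  cfg <- reference_sim_config(N = 1e5, h2max = 0.35, M = 40000, seed = 13)
  st <- simulate_sumstats(cfg)
  cs <- covariance_set(cfg$Sigma_g, st$Sigma_e, N = cfg$N, traits = cfg$traits)
  fit <- hipo(st$panel, covariances = cs)
  # the dominant component's average NCP is small (~0.05), so the Monte-Carlo
  # sd of mean(chi^2) - 1 over ~40K LD-correlated SNPs is ~25% of it; a 50%
  # relative band is ~2-3 Monte-Carlo sds
  emp <- mean(fit$z[, 1]^2) - 1
  expect_equal(emp, fit$avg_ncp[1], tolerance = 0.5)
})

test_that("hipo fit object supports the standard methods", {
  set.seed(12)
  cfg <- reference_sim_config(N = 5e4, h2max = 0.35, M = 5000, seed = 3)
  st <- simulate_sumstats(cfg)
  cs <- covariance_set(cfg$Sigma_g, st$Sigma_e, N = cfg$N, traits = cfg$traits)
  fit <- hipo(st$panel, covariances = cs)
  expect_s3_class(fit, "hipo")
  expect_equal(dim(coef(fit)), c(4, 4))
  sm <- summary(fit)
  expect_equal(rownames(sm$components), paste0("HIPO-D", 1:4))
  expect_true(all(c("lambda_gc", "mean_chisq") %in% colnames(sm$components)))
  pr <- predict(fit, st$panel)
  expect_equal(pr[["z.HIPO-D1"]], unname(fit$z[, 1]))
  expect_output(print(fit), "HIPO fit")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit, type = "scree"))
  expect_silent(plot(fit, type = "qq", components = "HIPO-D1"))
  dir <- withr::local_tempdir()
  write_results(fit, file.path(dir, "hipo"))
  expect_true(file.exists(file.path(dir, "hipo.tsv")))
  expect_true(file.exists(file.path(dir, "hipo.json")))
})
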