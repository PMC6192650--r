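test_that("AR(1) blocks follow the closed form and stay positive definite", {
  p <- make_ld_panel(n_blocks = 2, block_size = 3, decay_rate = 0.5)
  expect_equal(p$blocks[[1]][1, 3], 0.25)
  p0 <- make_ld_panel(n_blocks = 2, block_size = 3, decay_rate = 0)
  expect_equal(p0$blocks[[1]], diag(3))
  for (R in p$blocks)
    expect_gt(min(eigen(R, symmetric = TRUE, only.values = TRUE)$values), 0)
})

test_that("joint effects have the requested causal structure and moments", {
  cov <- lipid_covariances()
  Sg <- 0.35 * cov$Sigma_g
  cfg <- sim_config(Sigma_g = Sg, Sigma_y = cov$Sigma_y, N = 1e4,
                    M = 20000, m_causal = 10000, seed = 5)
  je <- draw_joint_effects(cfg, seed = 99)
  expect_equal(length(je$causal[[1]]), 10000)
  expect_true(all(vapply(je$causal, identical, TRUE, y = je$causal[[1]])))
  expect_true(all(je$beta_joint[-je$causal[[1]], ] == 0))
  emp <- cov(je$beta_joint[je$causal[[1]], ]) * 10000
  expect_equal(unname(emp), unname(Sg), tolerance = 0.08)
  # no causal SNPs: all-zero effects
  cfg0 <- sim_config(Sigma_g = Sg, Sigma_y = cov$Sigma_y, N = 1e4,
                     M = 100, m_causal = 0, seed = 5)
  expect_true(all(draw_joint_effects(cfg0, seed = 1)$beta_joint == 0))
})

test_that("partially overlapping causal sets share the requested fraction", {
  cfg <- sim_config(Sigma_g = diag(2) * 0.1, Sigma_y = diag(2), N = 1e4,
                    M = 5000, m_causal = 500, causal_overlap = 0.4, seed = 8)
  je <- draw_joint_effects(cfg, seed = 3)
  expect_equal(lengths(je$causal), c(500, 500))
  shared <- intersect(je$causal[[1]], je$causal[[2]])
  expect_gte(length(shared), 200)
  # effects vanish outside each trait's own causal set
  for (k in 1:2)
    expect_true(all(je$beta_joint[-je$causal[[k]], k] == 0))
})

test_that("marginal effects are the LD-weighted joint effects", {
  # identity LD: marginal equals joint
  p0 <- make_ld_panel(n_blocks = 2, block_size = 4, decay_rate = 0)
  bj <- matrix(rnorm(8), 8, 1)
  expect_equal(marginal_effects(bj, p0), bj)
  # two SNPs, r = 0.5
  p1 <- make_ld_panel(blocks = list(matrix(c(1, 0.5, 0.5, 1), 2)))
  expect_equal(marginal_effects(matrix(c(1, 0), 2, 1), p1),
               matrix(c(1, 0.5), 2, 1))
  # 5-SNP AR(1) block against a dense matrix-product oracle
  set.seed(10)
  p5 <- make_ld_panel(n_blocks = 1, block_size = 5, decay_rate = 0.6)
  bj5 <- matrix(rnorm(10), 5, 2)
  R <- 0.6^abs(outer(1:5, 1:5, "-"))
  R[R^2 <= 0.01] <- 0; diag(R) <- 1
  expect_equal(marginal_effects(bj5, p5), R %*% bj5)
})

test_that("error covariance combines sample sizes, overlap and phenotypic covariance", {
  Sy <- matrix(c(1, 0.5, 0.5, 1), 2)
  expect_equal(error_covariance(Sy, c(1000, 1000)),
               matrix(c(1e-3, 5e-4, 5e-4, 1e-3), 2))
  expect_equal(error_covariance(Sy, c(1000, 1000), N_overlap = diag(c(1000, 1000))),
               diag(c(1e-3, 1e-3)))
  expect_equal(error_covariance(Sy, c(1000, 1000),
                                N_overlap = matrix(c(1000, 500, 500, 1000), 2))[1, 2],
               2.5e-4)
})

test_that("partial-overlap error covariance matches individual-level regression", {
  # oracle: one null SNP, two traits on overlapping samples; empirical
  # covariance of the two per-SD effect estimates over many replicates
  set.seed(77)
  n <- 1000; n_ov <- 500; rho <- 0.5; reps <- 10000
  cov_emp <- local({
    x1 <- matrix(rnorm(n * reps), n)        # genotype, study 1 samples
    x2 <- rbind(x1[seq_len(n_ov), ], matrix(rnorm((n - n_ov) * reps), n - n_ov))
    y1 <- matrix(rnorm(n * reps), n)
    shared <- y1[seq_len(n_ov), ]
    y2 <- rbind(rho * shared + sqrt(1 - rho^2) * matrix(rnorm(n_ov * reps), n_ov),
                matrix(rnorm((n - n_ov) * reps), n - n_ov))
    b1 <- colSums(x1 * y1) / n
    b2 <- colSums(x2 * y2) / n
    cov(b1, b2)
  })
  expect_equal(cov_emp, n_ov / (n * n) * rho, tolerance = 0.1)
})

test_that("estimation errors have the Kronecker LD-by-trait covariance", {
  expect_equal(draw_errors(make_ld_panel(2, 2), matrix(0, 2, 2)),
               matrix(0, 4, 2))
  # identity LD, one trait: iid with the requested variance
  set.seed(15)
  p <- make_ld_panel(n_blocks = 50000, block_size = 2, decay_rate = 0)
  e <- draw_errors(p, matrix(4))
  expect_equal(var(as.vector(e)), 4, tolerance = 0.02)
  # cross moment r * Sigma_e[k,l] across SNPs and traits
  Se <- matrix(c(1, 0.5, 0.5, 1), 2)
  p2 <- make_ld_panel(n_blocks = 100000, block_size = 2, decay_rate = 0.5)
  e2 <- draw_errors(p2, Se, seed = 16)
  first <- seq(1, nrow(p2$snps), 2)
  expect_equal(cov(e2[first, 1], e2[first + 1, 2]), 0.5 * 0.5, tolerance = 0.05)
  expect_equal(cov(e2[first, 1], e2[first + 1, 1]), 0.5, tolerance = 0.05)
  expect_equal(cov(e2[first, 1], e2[first, 2]), 0.5, tolerance = 0.05)
  expect_error(draw_errors(p, matrix(-1)), "semi-definite")
})

test_that("stratification draws have the stated per-SNP variance", {
  expect_equal(draw_stratification(matrix(0, 2, 2), 10), matrix(0, 10, 2))
  Sv <- stratification_covariance(4)
  expect_equal(diag(Sv), rep(7.35e-8, 4))
  v <- draw_stratification(Sv, 200000, seed = 30)
  expect_equal(unname(apply(v, 2, var)), rep(7.35e-8, 4), tolerance = 0.02)
  expect_equal(cor(v[, 1], v[, 2]), 0.5, tolerance = 0.02)
})

test_that("simulated studies are deterministic and reconstructible", {
  cfg <- reference_sim_config(N = 1e4, h2max = 0.2, M = 3000, seed = 42)
  a <- simulate_sumstats(cfg)
  b <- simulate_sumstats(cfg)
  expect_identical(a$panel$Z, b$panel$Z)
  expect_identical(a$truth$beta_joint, b$truth$beta_joint)
  # beta_hat decomposes into the stored parts
  e <- a$beta_hat - a$truth$beta_marginal - a$truth$stratification
  expect_equal(a$beta_hat, a$truth$beta_marginal + a$truth$stratification + e)
  # different seed changes the draw
  cfg2 <- reference_sim_config(N = 1e4, h2max = 0.2, M = 3000, seed = 43)
  expect_false(identical(simulate_sumstats(cfg2)$panel$Z, a$panel$Z))
})

test_that("a degenerate study with no variance components is exactly zero", {
  cfg <- sim_config(Sigma_g = matrix(0, 2, 2), Sigma_y = matrix(0, 2, 2),
                    N = 1000, M = 50, m_causal = 0, seed = 1)
  st <- simulate_sumstats(cfg, block_size = 5)
  expect_true(all(st$beta_hat == 0))
  expect_true(all(st$panel$Z == 0))
})

test_that("null-SNP variance equals stratification plus sampling covariance", {
  cov <- lipid_covariances()
  cfg <- sim_config(Sigma_g = 0.35 * cov$Sigma_g * 0.05, Sigma_y = cov$Sigma_y,
                    N = 1000, M = 60000, m_causal = 600,
                    Sigma_v = 2e-4 * (diag(4) * 0.5 + 0.5),
                    N_overlap = matrix(500, 4, 4) + diag(rep(500, 4)),
                    seed = 19)
  st <- simulate_sumstats(cfg)
  target <- cfg$Sigma_v + st$Sigma_e
  emp <- cov(st$beta_hat[st$truth$null_snps, ])
  expect_equal(unname(emp), unname(target), tolerance = 0.05)
})

test_that("single-trait mean chi-square follows the polygenicity expectation", {
  cfg <- sim_config(Sigma_g = matrix(0.01), Sigma_y = matrix(1), N = 5e4,
                    M = 50000, m_causal = 500, seed = 77)
  st <- simulate_sumstats(cfg)
  mean_l <- mean(st$panel$ld_scores)
  expected <- 1 + 5e4 * 0.01 * mean_l / 5e4
  expect_equal(mean(st$panel$Z[, 1]^2), expected, tolerance = 0.05)
})

test_that("reference configs preserve per-SNP variance components at reduced M", {
  cfg <- reference_sim_config(N = 1e4, h2max = 0.35, M = 120000)
  expect_equal(max(diag(cfg$Sigma_g)), 0.35 * 120000 / 1.2e6)
  expect_equal(cfg$m_causal, 1200)  # 1% causal fraction
  # per-causal-SNP effect variance matches the full-scale design
  expect_equal(max(diag(cfg$Sigma_g)) / cfg$m_causal, 0.35 / 12000)
  cfgs <- reference_sim_config(N = 1e4, h2max = 0.1, M = 1000,
                               stratification = TRUE, setting = "psychiatric")
  expect_equal(cfgs$Sigma_v, stratification_covariance(3))
  expect_equal(cfgs$traits, c("ASD", "BIP", "SCZ"))
})

test_that("sim config validates overlap and causal counts", {
  Sy <- diag(2)
  expect_error(sim_config(diag(2), Sy, N = c(100, 200), M = 10, m_causal = 20),
               "m_causal")
  expect_error(sim_config(diag(2), Sy, N = c(100, 200), M = 10, m_causal = 2,
                          N_overlap = matrix(150, 2, 2) + diag(c(-50, 50))),
               "N_overlap")
})
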