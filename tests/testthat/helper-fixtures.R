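# Shared fixtures built in code.

# A small summary-statistic table with controllable fields.
make_table <- function(trait_id, snp_id, chrom = 1L, pos_bp = seq_along(snp_id) * 1e5,
                       a1 = "A", a2 = "G", z = 1, n = 10000, beta = NULL, se = NULL) {
  m <- length(snp_id)
  df <- data.frame(snp_id = snp_id, chrom = rep_len(chrom, m),
                   pos_bp = rep_len(pos_bp, m), a1 = rep_len(a1, m),
                   a2 = rep_len(a2, m), n = rep_len(n, m),
                   stringsAsFactors = FALSE)
  if (is.null(beta) && is.null(se)) {
    df$se <- 1 / sqrt(df$n)
    df$z <- rep_len(z, m)
    df$beta <- df$z * df$se
  } else {
    df$beta <- rep_len(beta, m); df$se <- rep_len(se, m)
  }
  sumstat_table(df, trait_id)
}

make_reference <- function(snp_id, a1 = "A", a2 = "G", maf = 0.3) {
  m <- length(snp_id)
  data.frame(snp_id = snp_id, a1 = rep_len(a1, m), a2 = rep_len(a2, m),
             maf = rep_len(maf, m), stringsAsFactors = FALSE)
}

# Random positive-definite covariance matrix.
rand_pd <- function(K, scale = 1) {
  A <- matrix(rnorm(K * K), K)
  scale * crossprod(A) / K + scale * diag(K) * 0.1
}

# Brute-force constrained maximizer of c' Sg c subject to c' Sb c = 1 and
# Sb-orthogonality to previous components: independent oracle for the eigen
# route, via generic quasi-Newton optimization of the (scale-invariant)
# Rayleigh quotient with a quadratic orthogonality penalty.
brute_force_components <- function(Sg, Sb, n_starts = 8, penalty = 1e6) {
  K <- nrow(Sg)
  comps <- matrix(0, K, K)
  for (k in seq_len(K)) {
    prev <- if (k > 1) comps[, seq_len(k - 1), drop = FALSE] else NULL
    obj <- function(c) {
      q <- sum(c * (Sb %*% c))
      if (q < 1e-12) return(1e12)
      val <- -sum(c * (Sg %*% c)) / q
      if (!is.null(prev)) {
        orth <- as.vector(crossprod(prev, Sb %*% c)) / sqrt(q)
        val <- val + penalty * sum(orth^2)
      }
      val
    }
    best <- NULL
    for (s in seq_len(n_starts)) {
      c0 <- rnorm(K)
      fit <- optim(c0, obj, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-14))
      fit <- optim(fit$par, obj, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-14))
      if (is.null(best) || fit$value < best$value) best <- fit
    }
    c_hat <- best$par / sqrt(sum(best$par * (Sb %*% best$par)))
    i <- which.max(abs(c_hat))
    if (c_hat[i] < 0) c_hat <- -c_hat
    comps[, k] <- c_hat
  }
  comps
}
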