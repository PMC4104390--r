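# Shared fixtures and independent oracles for the test suite.

# random genotype matrix split over two chromosome labels
rand_geno <- function(n, m, maf = c(0.05, 0.5), missing_rate = 0, seed = 1,
                      chroms = c("1", "6")) {
  withr::with_seed(seed, {
    p <- runif(m, maf[1], maf[2])
    dos <- matrix(rbinom(n * m, 2L, rep(p, each = n)), nrow = n)
    if (missing_rate > 0) dos[runif(n * m) < missing_rate] <- NA_integer_
    chrom <- sample(chroms, m, replace = TRUE)
    genotype_matrix(
      dos,
      snps = data.frame(chrom = chrom, id = paste0("s", seq_len(m)),
                        pos = seq_len(m), a1 = "A", a2 = "B"),
      samples = data.frame(fid = paste0("F", seq_len(n)),
                           iid = paste0("I", seq_len(n)))
    )
  })
}

# brute-force per-pair GRM oracle: explicit loop over individual pairs with the
# textbook formulas, independent of the package's matrix-product implementation
grm_oracle <- function(dos, p) {
  n <- nrow(dos)
  A <- matrix(0, n, n)
  N <- matrix(0L, n, n)
  for (j in seq_len(n)) {
    for (k in seq_len(j)) {
      ok <- !is.na(dos[j, ]) & !is.na(dos[k, ])
      xj <- dos[j, ok]; xk <- dos[k, ok]; pi <- p[ok]
      het <- 2 * pi * (1 - pi)
      if (j == k) {
        val <- 1 + sum((xj^2 - (1 + 2 * pi) * xj + 2 * pi^2) / het) / sum(ok)
      } else {
        val <- sum((xj - 2 * pi) * (xk - 2 * pi) / het) / sum(ok)
      }
      A[j, k] <- A[k, j] <- val
      N[j, k] <- N[k, j] <- sum(ok)
    }
  }
  list(A = A, N = N)
}

# independent dense evaluation of the restricted log-likelihood, written with
# solve()/determinant() rather than Cholesky pieces
reml_ll_oracle <- function(y, X, A, sg, se) {
  n <- length(y)
  V <- sg * A + se * diag(n)
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XtViX) %*% t(X) %*% Vi
  ld1 <- as.numeric(determinant(V, logarithm = TRUE)$modulus)
  ld2 <- as.numeric(determinant(XtViX, logarithm = TRUE)$modulus)
  -0.5 * (ld1 + ld2 + drop(t(y) %*% P %*% y))
}

# quick ascertained cohort with all causal SNPs on one chromosome
quick_cohort <- function(n_cases = 60, ratio = 3, K = 0.1, h2 = 0.5,
                         m_focal = 150, m_rest = 150, n_causal = 25,
                         focal = "6", seed = 1) {
  cfg <- simulation_config(
    stats::setNames(c(m_rest, m_focal), c("1", focal)),
    causal = data.frame(chrom = focal, n_causal = n_causal, h2_share = h2),
    prevalence = K, n_cases = n_cases, case_control_ratio = ratio, seed = seed
  )
  simulate_cohort(cfg)
}

# run an inline python script (numpy available in the test image) and return
# its stdout lines; used for independent reference parsing of binary formats
run_python <- function(code, args = character()) {
  f <- tempfile(fileext = ".py")
  writeLines(code, f)
  on.exit(unlink(f))
  system2("python", c(f, args), stdout = TRUE)
}
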