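test_that("tau matches an independent least-squares oracle on a tiny system", {
  s <- make_small_system()
  fit <- sldsc(s$ss, s$L, s$A, n_blocks = 2, two_pass_weights = FALSE,
               chisq_cap = FALSE)
  # oracle: ordinary lm of chi2 on N * ld scores with free intercept
  o <- lm(s$chi2 ~ I(1e4 * s$L[, 1]) + I(1e4 * s$L[, 2]))
  expect_equal(unname(fit$tau), unname(coef(o)[2:3]), tolerance = 1e-8)
  expect_equal(fit$intercept, unname(coef(o)[1]), tolerance = 1e-8)

  # two-pass weights replicated on the oracle side
  fit_w <- sldsc(s$ss, s$L, s$A, n_blocks = 2, two_pass_weights = TRUE,
                 chisq_cap = FALSE)
  h2_1 <- sum(s$A %*% coef(o)[2:3])
  w <- 1 / (pmax(s$L[, 1], 1) * (1 + 1e4 * max(h2_1, 0) * s$L[, 1] / 10)^2)
  ow <- lm(s$chi2 ~ I(1e4 * s$L[, 1]) + I(1e4 * s$L[, 2]), weights = w)
  expect_equal(unname(fit_w$tau), unname(coef(ow)[2:3]), tolerance = 1e-8)
})

test_that("the base annotation has enrichment exactly 1 with zero SE", {
  s <- make_small_system(m = 40, seed = 5)
  fit <- sldsc(s$ss, s$L, s$A, n_blocks = 4)
  expect_identical(unname(fit$enrichment["base"]), 1)
  expect_identical(unname(fit$enrichment_se["base"]), 0)
  expect_equal(fit$h2_total, unname(fit$h2_annot["base"]))
})

test_that("derived quantities satisfy the enrichment/difference identity", {
  s <- make_small_system(m = 40, seed = 7)
  fit <- sldsc(s$ss, s$L, s$A, n_blocks = 4)
  m <- fit$n_snps; M <- fit$M[["annot"]]
  # d = h2 (enrichment - 1) / (p - |a|): zero exactly when enrichment is 1
  expect_equal(unname(fit$d["annot"]),
               fit$h2_total * (fit$enrichment[["annot"]] - 1) / (m - M),
               tolerance = 1e-12)
  expect_equal(unname(fit$d["annot"]),
               fit$h2_annot[["annot"]] / M -
                 (fit$h2_total - fit$h2_annot[["annot"]]) / (m - M),
               tolerance = 1e-12)
})

test_that("jackknife SEs match a direct delete-one-block recomputation", {
  s <- make_small_system(m = 12, seed = 11)
  nb <- 4
  fit <- sldsc(s$ss, s$L, s$A, n_blocks = nb, two_pass_weights = FALSE,
               chisq_cap = FALSE)
  X <- cbind(1, 1e4 * s$L)
  blk <- as.integer(cut(1:12, nb, labels = FALSE))
  d_b <- sapply(1:nb, function(b) {
    keep <- blk != b
    th <- qr.solve(X[keep, ], s$chi2[keep])
    per_snp <- as.numeric(s$A %*% th[-1])
    h2 <- sum(per_snp); h2a <- sum(per_snp[s$A[, 2] == 1])
    M <- sum(s$A[, 2])
    h2a / M - (h2 - h2a) / (12 - M)
  })
  se_oracle <- sqrt((nb - 1) / nb * sum((d_b - mean(d_b))^2))
  expect_equal(unname(fit$d_se["annot"]), se_oracle, tolerance = 1e-8)
})

test_that("enrichment is invariant to consistent chi-square and N rescaling", {
  s <- make_small_system(m = 30, seed = 13)
  f1 <- sldsc(s$ss, s$L, s$A, n_blocks = 3, two_pass_weights = FALSE,
              chisq_cap = FALSE)
  ss2 <- s$ss
  ss2$Z <- sqrt(5) * ss2$Z
  ss2$N <- 5 * ss2$N
  f2 <- sldsc(ss2, s$L, s$A, n_blocks = 3, two_pass_weights = FALSE,
              chisq_cap = FALSE)
  expect_equal(f2$enrichment, f1$enrichment, tolerance = 1e-8)
  expect_equal(f2$h2_total, f1$h2_total, tolerance = 1e-8)
})

test_that("singular designs are rejected naming the collinear column", {
  s <- make_small_system(m = 20, seed = 17)
  A <- cbind(s$A, dup = s$A[, "annot"])
  L <- cbind(s$L, dup = s$L[, "annot"])
  expect_error(sldsc(s$ss, L, A, n_blocks = 2, two_pass_weights = FALSE),
               "collinear")
  expect_error(sldsc(s$ss, s$L, cbind(base = rep(0L, 20), s$A[, 2]),
                     n_blocks = 2),
               "all-ones base")
})

test_that("sumstats QC filters MAF inclusively and gates on the h2 Z-score", {
  gen <- simulate_genome(5, 4000, 40, 2e7, seed = 19)
  gen$snp_map$maf[1:10] <- 0.049
  gen$snp_map$maf[11:20] <- 0.05          # exactly at the threshold: kept
  A <- matrix(1L, 4000, 1, dimnames = list(NULL, "base"))
  L <- compute_ld_scores(ar1_ld(0.5), gen$snp_map, A)

  strong <- simulate_gwas(gen$snp_map, A, tau = 0.5 / 4000, N = 1e5,
                          rho = 0.5, seed = 2)
  # at this small SNP count the jackknife h2 SE is large, so the Z gate is
  # exercised with a threshold the simulated trait can reach
  qs <- qc_sumstats(strong$sumstats, gen$snp_map, L, h2_z_min = 1)
  expect_equal(nrow(qs$sumstats), 3990)
  expect_true(all(qs$sumstats$maf >= 0.05))
  expect_true(gen$snp_map$snp_id[11] %in% qs$sumstats$SNP)
  expect_false(gen$snp_map$snp_id[10] %in% qs$sumstats$SNP)
  expect_true(qs$pass)

  null <- simulate_gwas(gen$snp_map, A, tau = 0, N = 1e5, rho = 0.5, seed = 3)
  qn <- qc_sumstats(null$sumstats, gen$snp_map, L)
  expect_false(qn$pass)
  expect_lt(abs(qn$h2), 0.05)

  bogus <- strong$sumstats
  bogus$SNP <- paste0("xx", seq_len(nrow(bogus)))
  expect_error(qc_sumstats(bogus, gen$snp_map, L), "no SNP")
})

test_that("the per-SNP difference SE shrinks as the panel grows", {
  # d scales as h2/m (factor 4 here) and its SE shrinks further with the
  # larger SNP panel; the enrichment ratio SE is not used because under
  # near-constant base LD scores h2 is weakly identified against the free
  # intercept, which the paired per-SNP difference avoids
  run_one <- function(m, seed) {
    gen <- simulate_genome(5, m, m / 100, 5e7, seed = seed)
    set.seed(seed)
    A <- cbind(base = 1L,
               annot = as.integer(seq_len(m) %in% sample.int(m, m / 10)))
    L <- compute_ld_scores(ar1_ld(0.5), gen$snp_map, A)
    tau <- enrichment_tau(0.4, 2, sum(A[, 2]), m)
    g <- simulate_gwas(gen$snp_map, A, tau, N = 5e4, rho = 0.5, seed = seed)
    sldsc(g$sumstats, L, A, n_blocks = 20)$d_se[["annot"]]
  }
  se5 <- run_one(5000, 23)
  se20 <- run_one(20000, 23)
  expect_gt(se5 / se20, 2)
  expect_lt(se5 / se20, 12)
})
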