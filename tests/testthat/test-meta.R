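test_that("DerSimonian-Laird pooling matches closed-form hand computation", {
  # identical studies: pooled unchanged, no heterogeneity
  m0 <- meta_random(rep(0.8, 4), rep(0.1, 4))
  expect_equal(m0$estimate, 0.8)
  expect_equal(m0$tau2, 0)

  # two studies (1.0, se 0.1) and (2.0, se 0.1):
  # w = 100 each, Q = 50, tau2 = 49/100, w* = 2, pooled 1.5, SE 0.5
  m2 <- meta_random(c(1, 2), c(0.1, 0.1))
  expect_equal(m2$estimate, 1.5, tolerance = 1e-10)
  expect_equal(m2$tau2, 0.49, tolerance = 1e-10)
  expect_equal(m2$se, 0.5, tolerance = 1e-10)

  # single study returned unchanged
  m1 <- meta_random(0.7, 0.2)
  expect_equal(m1$estimate, 0.7)
  expect_equal(m1$se, 0.2)
  expect_equal(m1$n_studies, 1)

  expect_error(meta_random(numeric(0), numeric(0)), "no studies")
  expect_error(meta_random(c(1, 2), c(0.1, 0)), "positive")
})

test_that("DL pooling agrees with metafor and stays inside the study range", {
  skip_if_not_installed("metafor")
  set.seed(4)
  for (i in 1:5) {
    est <- rnorm(7, 1, 0.5)
    se <- runif(7, 0.05, 0.4)
    m <- meta_random(est, se)
    ref <- metafor::rma(yi = est, sei = se, method = "DL")
    expect_equal(m$estimate, as.numeric(ref$beta), tolerance = 1e-10)
    expect_equal(m$se, ref$se, tolerance = 1e-10)
    expect_equal(m$tau2, ref$tau2, tolerance = 1e-10)
    expect_gte(m$estimate, min(est))
    expect_lte(m$estimate, max(est))
  }
})

test_that("zero heterogeneity reduces DL to fixed-effect pooling", {
  est <- c(1.0, 1.02, 0.98)
  se <- c(0.5, 0.4, 0.6)  # Q < n - 1 here, so tau2 = 0
  m <- meta_random(est, se)
  w <- 1 / se^2
  expect_equal(m$tau2, 0)
  expect_equal(m$estimate, sum(w * est) / sum(w), tolerance = 1e-12)
  expect_equal(m$se, 1 / sqrt(sum(w)), tolerance = 1e-12)
})

test_that("the one-sided Z test follows the normal upper tail", {
  null <- meta_random(0, 1)
  expect_equal(one_sided_test(null), 0.5)
  m <- meta_random(1.645, 1)
  expect_equal(one_sided_test(m), pnorm(1.645, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(one_sided_test(m), 0.05, tolerance = 1e-3)
  set.seed(6)
  for (z in rnorm(10)) {
    expect_equal(one_sided_test(list(estimate = z, se = 1)),
                 1 - pnorm(z), tolerance = 1e-12)
  }
})

test_that("gene-set comparisons use the difference Z under independence", {
  a <- meta_random(rep(1.5, 3), rep(0.1, 3))
  expect_equal(compare_gene_sets(a, a), 0.5)
  b <- meta_random(rep(0.5, 3), rep(0.01, 3))
  expect_lt(compare_gene_sets(a, b), 1e-10)
  z <- (a$estimate - b$estimate) / sqrt(a$se^2 + b$se^2)
  expect_equal(compare_gene_sets(a, b), pnorm(z, lower.tail = FALSE))
  # paired route pools per-trait differences
  p <- compare_gene_sets_paired(c(1.5, 1.6), c(0.1, 0.1),
                                c(1.0, 1.1), c(0.1, 0.1))
  oracle <- one_sided_test(meta_random(c(0.5, 0.5), sqrt(c(0.02, 0.02))))
  expect_equal(p, oracle)
})

test_that("trait selection and clustering recover obvious structure", {
  e <- rbind(matrix(3, 4, 2), matrix(1, 4, 2))
  e <- e + matrix(rnorm(16, sd = 0.01), 8, 2)
  e[, 2] <- e[, 2] * 0.5
  rownames(e) <- paste0("t", 1:8)
  colnames(e) <- c("setA", "setB")
  p <- matrix(0.01, 8, 2, dimnames = dimnames(e))
  cl <- select_and_cluster_traits(e, p, k = 2)
  expect_equal(length(unique(cl$cluster[1:4])), 1)
  expect_equal(length(unique(cl$cluster[5:8])), 1)
  expect_false(cl$cluster[1] == cl$cluster[5])
  expect_true(all(cl$specific_set == "setA"))  # argmax column everywhere

  one <- select_and_cluster_traits(e[1, , drop = FALSE],
                                   p[1, , drop = FALSE])
  expect_equal(nrow(one), 1)
  expect_equal(one$cluster, 1L)

  pnone <- matrix(0.9, 8, 2, dimnames = dimnames(e))
  expect_warning(empty <- select_and_cluster_traits(e, pnone), "no trait")
  expect_equal(nrow(empty), 0)
})

test_that("cluster-aging association matches exact-test enumeration", {
  lab <- rep(c("inflammaging_specific", "other"), each = 10)
  aging <- rep(c(TRUE, FALSE), each = 10)
  res <- cluster_group_association(lab, aging)
  # brute force over all tables with the observed margins
  obs <- as.vector(res$table)
  p_tab <- function(a) dhyper(a, 10, 10, 10)
  probs <- sapply(0:10, p_tab)
  oracle <- sum(probs[probs <= p_tab(obs[1]) + 1e-12])
  expect_equal(res$p, oracle, tolerance = 1e-10)

  # swapping the label rows leaves the p unchanged
  res2 <- cluster_group_association(
    factor(lab, levels = c("other", "inflammaging_specific")), aging)
  expect_equal(res2$p, res$p)

  # near-independent margins: large p
  set.seed(8)
  res3 <- cluster_group_association(rep(c("a", "b"), 10),
                                    rep(c(TRUE, FALSE), each = 10))
  expect_gt(res3$p, 0.5)

  expect_warning(res4 <- cluster_group_association(rep("a", 20), aging),
                 "degenerate")
  expect_equal(res4$p, 1)
})
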