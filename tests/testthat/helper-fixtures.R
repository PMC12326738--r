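# Shared builders for small simulated screens and genomes.

make_tiny_screen <- function(n_genes = 60, sgrnas = 5, nt = 20,
                             beta_rss = 0, beta_iss = 0,
                             depth_per_sgrna = 500, dispersion = 0.05,
                             sgrna_noise_sd = 0.2, seed = 7) {
  lib <- make_library(n_genes, sgrnas, nt)
  genes <- unique(lib$gene_id[lib$gene_id != "NON_TARGETING"])
  eff <- screen_effects(genes, beta_rss = beta_rss, beta_iss = beta_iss)
  sim <- simulate_screen(lib, eff, depth = depth_per_sgrna * nrow(lib),
                         dispersion = dispersion,
                         sgrna_noise_sd = sgrna_noise_sd, seed = seed)
  list(lib = lib, genes = genes, eff = eff, sim = sim)
}

# small fully synthetic regression system for S-LDSC oracle checks
make_small_system <- function(m = 10, seed = 3) {
  withr::with_seed(seed, {
    snp_map <- data.frame(snp_id = paste0("rs", 1:m), chromosome = 1L,
                          position = seq(1000, by = 1000, length.out = m),
                          maf = runif(m, 0.05, 0.5),
                          block_id = rep(1:2, each = m / 2))
    A <- cbind(base = 1L, annot = rbinom(m, 1, 0.5))
    L <- cbind(base = runif(m, 1, 5), annot = runif(m, 0, 3))
    chi2 <- runif(m, 0.5, 8)
    ss <- data.frame(SNP = snp_map$snp_id, A1 = "A", A2 = "G",
                     Z = sqrt(chi2), N = 1e4)
    list(snp_map = snp_map, A = A, L = L, ss = ss, chi2 = chi2)
  })
}

# brute-force AUC over all positive/negative pairs (ties count 1/2)
auc_bruteforce <- function(scores, gold) {
  pos <- scores[names(scores) %in% gold$positives]
  neg <- scores[names(scores) %in% gold$negatives]
  tot <- 0
  for (p in pos) for (n in neg) {
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# independent IRLS for logistic regression (Newton on the canonical link)
irls_logistic <- function(X, y, maxit = 50, tol = 1e-12) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / w
    beta_new <- solve(crossprod(X, X * w), crossprod(X, w * z))
    if (max(abs(beta_new - beta)) < tol) { beta <- beta_new; break }
    beta <- beta_new
  }
  drop(beta)
}
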