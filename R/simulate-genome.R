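#' Simulate a toy genome: gene intervals and a common-SNP map
#'
#' Places `n_genes` non-overlapping transcribed intervals and `n_snps`
#' common SNPs on a single chromosome. SNP minor-allele frequencies are
#' uniform on \[0.05, 0.5\] so every SNP passes the common-variant filter,
#' and SNPs are assigned to `n_blocks` contiguous LD blocks of (near-)equal
#' size along the chromosome. Gene coordinates are 1-based inclusive.
#'
#' @param n_genes,n_snps,n_blocks counts; `n_blocks <= n_snps`.
#' @param chrom_length chromosome length in bp.
#' @param gene_length_range min/max transcribed-region length in bp.
#' @param seed integer seed.
#' @return list with `gene_map` (`gene_id`, `chromosome`, `tx_start`,
#'   `tx_end`) and `snp_map` (`snp_id`, `chromosome`, `position`, `maf`,
#'   `block_id`).
#' @export
simulate_genome <- function(n_genes, n_snps, n_blocks, chrom_length,
                            gene_length_range = c(5e3, 5e4), seed = 1L) {
  stopifnot(n_genes >= 0, n_snps >= 1, n_blocks >= 1, n_blocks <= n_snps,
            chrom_length >= n_snps)
  withr::local_seed(seed)

  gene_map <- data.frame(gene_id = character(0), chromosome = integer(0),
                         tx_start = integer(0), tx_end = integer(0))
  if (n_genes > 0) {
    # one gene per equal-width slot guarantees non-overlap
    slot <- floor(chrom_length / n_genes)
    len <- round(runif(n_genes, gene_length_range[1],
                       min(gene_length_range[2], slot - 2)))
    if (any(len < 1) || slot <= 2) {
      stop("cannot pack ", n_genes, " genes of the requested length into ",
           chrom_length, " bp")
    }
    start <- (seq_len(n_genes) - 1L) * slot +
      floor(runif(n_genes, 1, slot - len))
    gene_map <- data.frame(
      gene_id = sprintf("GENE%05d", seq_len(n_genes)),
      chromosome = 1L, tx_start = as.integer(start),
      tx_end = as.integer(start + len - 1L), stringsAsFactors = FALSE)
  }

  pos <- sort(sample.int(chrom_length, n_snps))
  block_id <- as.integer(ceiling(seq_len(n_snps) / (n_snps / n_blocks)))
  block_id[block_id > n_blocks] <- n_blocks
  snp_map <- data.frame(
    snp_id = sprintf("rs%06d", seq_len(n_snps)),
    chromosome = 1L, position = pos,
    maf = runif(n_snps, 0.05, 0.5),
    block_id = block_id, stringsAsFactors = FALSE)
  list(gene_map = gene_map, snp_map = snp_map)
}

#' Block AR(1) linkage-disequilibrium specification
#'
#' Describes an LD structure in which SNP correlations within each block of
#' the SNP map follow `r(i, j) = rho^|i - j|` (by SNP index) and SNPs in
#' different blocks are uncorrelated. Because the correlation matrix is
#' known exactly, true LD scores are available without estimation error.
#'
#' @param rho within-block AR(1) correlation, `|rho| < 1`.
#' @return an object of class `"ar1_ld"`.
#' @export
ar1_ld <- function(rho) {
  stopifnot(is.numeric(rho), length(rho) == 1L, abs(rho) < 1)
  structure(list(rho = rho), class = "ar1_ld")
}

#' Simulate GWAS summary statistics under annotation-stratified heritability
#'
#' Draws standardized per-SNP effects `beta_k ~ N(0, sum_c tau_c A_kc)` and
#' block-wise z-scores `z ~ MVN(sqrt(N) R beta, R)` where `R` is the AR(1)
#' within-block correlation, so that `E[chi2_j] = 1 + N sum_c tau_c l(j, c)`
#' with `l` the true stratified LD scores. Ground truth records the exact
#' realised total heritability and per-annotation heritability.
#'
#' @param snp_map SNP map from [simulate_genome()].
#' @param annotations binary SNP x C matrix; first column is conventionally
#'   the all-ones base annotation.
#' @param tau per-annotation per-SNP heritability coefficients.
#' @param N GWAS sample size.
#' @param rho within-block AR(1) correlation, `|rho| < 1`.
#' @param seed integer seed.
#' @return list with `sumstats` (`SNP`, `A1`, `A2`, `Z`, `N`) and `truth`
#'   (`tau`, `h2_total`, `h2_annot`, `per_snp_h2`, `N`).
#' @export
simulate_gwas <- function(snp_map, annotations, tau, N, rho = 0, seed = 1L) {
  annotations <- as.matrix(annotations)
  m <- nrow(snp_map)
  stopifnot(nrow(annotations) == m, length(tau) == ncol(annotations),
            abs(rho) < 1, N > 0)
  sigma2 <- as.numeric(annotations %*% tau)
  if (any(sigma2 < 0)) stop("tau implies negative per-SNP heritability")
  withr::local_seed(seed)

  beta <- rnorm(m, 0, sqrt(sigma2))
  z <- numeric(m)
  for (b in split(seq_len(m), snp_map$block_id)) {
    k <- length(b)
    if (rho == 0) {
      z[b] <- sqrt(N) * beta[b] + rnorm(k)
    } else {
      R <- rho^abs(outer(seq_len(k), seq_len(k), "-"))
      U <- chol(R)
      z[b] <- sqrt(N) * drop(R %*% beta[b]) + drop(crossprod(U, rnorm(k)))
    }
  }
  sumstats <- data.frame(SNP = snp_map$snp_id, A1 = "A", A2 = "G",
                         Z = z, N = N, stringsAsFactors = FALSE)
  h2_annot <- colSums(annotations * sigma2)
  names(h2_annot) <- colnames(annotations)
  list(sumstats = sumstats,
       truth = list(tau = tau, h2_total = sum(sigma2), h2_annot = h2_annot,
                    per_snp_h2 = sigma2, N = N))
}
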