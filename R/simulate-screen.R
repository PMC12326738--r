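#' Build a pooled CRISPRi library table
#'
#' Constructs an sgRNA-to-gene mapping with a fixed number of guides per gene
#' plus non-targeting control guides. Non-targeting guides carry the reserved
#' sentinel gene label `"NON_TARGETING"`; downstream fitting groups them into
#' pseudo-genes so they form an empirical null. A genome-wide human CRISPRi
#' library typically targets ~19,000 genes with ~5 sgRNAs per gene and
#' includes on the order of 2,000 non-targeting guides; note that real
#' libraries vary the number of guides per gene (a 18,905-gene, ~5/gene
#' library can hold 104,535 rather than 94,525 targeting guides), whereas
#' this generator is exactly rectangular.
#'
#' @param n_genes number of targeted genes.
#' @param sgrnas_per_gene guides per gene.
#' @param n_nontargeting number of non-targeting control guides.
#' @param seed optional integer seed (the construction is deterministic; the
#'   seed is accepted for interface symmetry with the other generators).
#' @return a `data.frame` with columns `sgrna_id`, `gene_id`.
#' @export
make_library <- function(n_genes, sgrnas_per_gene, n_nontargeting, seed = NULL) {
  for (v in c(n_genes, sgrnas_per_gene, n_nontargeting)) {
    if (length(v) != 1L || is.na(v) || v < 0 || v != floor(v)) {
      stop("n_genes, sgrnas_per_gene and n_nontargeting must be nonnegative integers")
    }
  }
  genes <- if (n_genes > 0) sprintf("GENE%05d", seq_len(n_genes)) else character(0)
  tg <- if (n_genes > 0 && sgrnas_per_gene > 0) {
    data.frame(
      sgrna_id = paste0(rep(genes, each = sgrnas_per_gene), "_sg",
                        rep(seq_len(sgrnas_per_gene), times = n_genes)),
      gene_id = rep(genes, each = sgrnas_per_gene),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(sgrna_id = character(0), gene_id = character(0))
  }
  nt <- if (n_nontargeting > 0) {
    data.frame(
      sgrna_id = sprintf("NT_%05d", seq_len(n_nontargeting)),
      gene_id = NON_TARGETING,
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(sgrna_id = character(0), gene_id = character(0))
  }
  out <- rbind(tg, nt)
  rownames(out) <- NULL
  out
}

#' Ground-truth selection effects for a simulated screen
#'
#' Assembles the per-gene true log-scale selection coefficients used by
#' [simulate_screen()]. `beta_rss` acts in the replicative-senescence arm,
#' `beta_iss` in the inflammatory (IL-6) arm. Class labels follow the
#' screen semantics: `pro_senescence_inflammaging` genes act only (or mostly)
#' under inflammation, `pro_senescence_common` in both arms, `essential`
#' genes are depleted, and `null` genes have both effects zero.
#'
#' @param gene_id character vector of gene ids.
#' @param beta_rss,beta_iss numeric effect sizes, recycled to length of
#'   `gene_id`.
#' @param class_label optional character labels; derived from the betas when
#'   omitted.
#' @return data.frame with columns `gene_id`, `beta_rss`, `beta_iss`,
#'   `class_label`.
#' @export
screen_effects <- function(gene_id, beta_rss = 0, beta_iss = 0,
                           class_label = NULL) {
  n <- length(gene_id)
  if (anyDuplicated(gene_id)) stop("gene_id must be unique")
  beta_rss <- rep_len(beta_rss, n)
  beta_iss <- rep_len(beta_iss, n)
  if (is.null(class_label)) {
    class_label <- ifelse(
      beta_rss == 0 & beta_iss == 0, "null",
      ifelse(beta_rss < 0 & beta_iss < 0, "essential",
             ifelse(abs(beta_iss) > abs(beta_rss), "pro_senescence_inflammaging",
                    "pro_senescence_common")))
  }
  class_label <- rep_len(class_label, n)
  bad <- class_label == "null" & (beta_rss != 0 | beta_iss != 0)
  if (any(bad)) stop("null genes must have beta_rss = beta_iss = 0")
  data.frame(gene_id = as.character(gene_id), beta_rss = beta_rss,
             beta_iss = beta_iss, class_label = class_label,
             stringsAsFactors = FALSE)
}

#' Simulate pooled screen counts under a negative-binomial model
#'
#' Generates initial and final sgRNA counts for one or two selection arms
#' (replicative senescence, `rss`, and inflammatory senescence, `iss`).
#' Baseline sgRNA abundances are log-normal(0, 1) and renormalised to sum to
#' one, matching the skewed representation of pooled lentiviral libraries.
#' Final relative abundance is proportional to
#' `initial * exp(beta_gene(condition) + noise)`, where the per-sgRNA noise
#' is Normal(0, `sgrna_noise_sd`) and models guide-efficacy variation.
#' Counts are drawn negative-binomial with variance `mu + dispersion * mu^2`.
#' Non-targeting guides always have effect zero.
#'
#' @param library a library table from [make_library()].
#' @param effects ground truth from [screen_effects()]; must only reference
#'   genes present in the library.
#' @param depth expected total reads per sample.
#' @param dispersion negative-binomial dispersion `alpha` (variance
#'   `mu + alpha mu^2`); 0 gives Poisson counts.
#' @param n_replicates replicates per (condition, timepoint).
#' @param conditions subset of `c("rss", "iss")`.
#' @param sgrna_noise_sd sd of per-sgRNA effect noise around the gene effect.
#' @param seed integer seed.
#' @return a list of class `"screen_sim"` with elements `counts` (integer
#'   matrix, sgRNA x sample), `design` (sample metadata: `sample_id`,
#'   `condition`, `timepoint`, `replicate`), `library`, `effects`, and
#'   `baseline` (true relative abundances).
#' @export
simulate_screen <- function(library, effects, depth = 5e5, dispersion = 0.05,
                            n_replicates = 2, conditions = c("rss", "iss"),
                            sgrna_noise_sd = 0.2, seed = 1L) {
  stopifnot(depth > 0, dispersion >= 0, n_replicates >= 1)
  conditions <- match.arg(conditions, c("rss", "iss"), several.ok = TRUE)
  genes <- unique(library$gene_id[library$gene_id != NON_TARGETING])
  unknown <- setdiff(effects$gene_id, genes)
  if (length(unknown) > 0) {
    stop("effects reference genes absent from the library: ",
         paste(head(unknown, 5), collapse = ", "))
  }
  withr::local_seed(seed)

  n <- nrow(library)
  base <- rlnorm(n, 0, 1)
  base <- base / sum(base)

  beta <- matrix(0, n, 2, dimnames = list(library$sgrna_id, c("rss", "iss")))
  idx <- match(library$gene_id, effects$gene_id)
  hit <- !is.na(idx) & library$gene_id != NON_TARGETING
  beta[hit, "rss"] <- effects$beta_rss[idx[hit]]
  beta[hit, "iss"] <- effects$beta_iss[idx[hit]]

  design <- expand.grid(replicate = seq_len(n_replicates),
                        timepoint = c("initial", "final"),
                        condition = conditions,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  design <- design[, c("condition", "timepoint", "replicate")]
  design$sample_id <- paste(design$condition, design$timepoint,
                            paste0("r", design$replicate), sep = "_")

  counts <- matrix(0L, n, nrow(design),
                   dimnames = list(library$sgrna_id, design$sample_id))
  rnb <- function(mu) {
    if (dispersion == 0) rpois(length(mu), mu)
    else rnbinom(length(mu), mu = mu, size = 1 / dispersion)
  }
  for (cond in conditions) {
    noise <- if (sgrna_noise_sd > 0) rnorm(n, 0, sgrna_noise_sd) else numeric(n)
    noise[library$gene_id == NON_TARGETING] <- 0
    fin <- base * exp(beta[, cond] + ifelse(beta[, cond] != 0, noise, 0))
    fin <- fin / sum(fin)
    for (i in which(design$condition == cond)) {
      p <- if (design$timepoint[i] == "initial") base else fin
      counts[, i] <- as.integer(rnb(depth * p))
    }
  }
  structure(list(counts = counts, design = design, library = library,
                 effects = effects, baseline = base),
            class = "screen_sim")
}

#' @export
print.screen_sim <- function(x, ...) {
  cat("Simulated pooled screen:", nrow(x$counts), "sgRNAs x",
      ncol(x$counts), "samples\n")
  cat("  conditions:", paste(unique(x$design$condition), collapse = ", "),
      "| median sample depth:",
      format(median(colSums(x$counts)), big.mark = ","), "\n")
  invisible(x)
}
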