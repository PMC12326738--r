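#' Per-SNP heritability coefficients giving a target enrichment
#'
#' Solves for the base and annotation coefficients `(tau_base, tau_annot)`
#' such that total heritability is `h2` and the annotation covering `M` of
#' `m` SNPs has the requested fold enrichment: inside per-SNP heritability
#' `E h2 / m`, outside `(h2 - E h2 M / m) / (m - M)`.
#'
#' @param h2 total SNP heritability.
#' @param enrichment target fold enrichment (1 = none).
#' @param M SNPs inside the annotation.
#' @param m total SNPs.
#' @return named vector `c(base =, annot =)`; errors if the outside
#'   per-SNP heritability would be negative.
#' @export
enrichment_tau <- function(h2, enrichment, M, m) {
  stopifnot(M > 0, M < m, h2 > 0, enrichment >= 0)
  v_in <- enrichment * h2 / m
  v_out <- (h2 - enrichment * h2 * M / m) / (m - M)
  if (v_out < 0) stop("enrichment ", enrichment, " infeasible for M/m = ",
                      signif(M / m, 3))
  c(base = v_out, annot = v_in - v_out)
}

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end synthetic workflow
#' (screen simulation -> beta-score fit -> classification -> annotation ->
#' stratified LD-score regression -> meta-analysis) in one serialisable
#' list. Every random stage derives its own seed deterministically from
#' `seed`.
#'
#' @param seed master integer seed.
#' @param n_genes,sgrnas_per_gene,n_nontargeting library layout.
#' @param n_inflammaging,n_common,n_essential designated true gene classes;
#'   the remainder are null.
#' @param effect_size true |beta| of designated genes.
#' @param depth_per_sgrna expected reads per sgRNA per sample.
#' @param dispersion,n_replicates,sgrna_noise_sd screen noise model.
#' @param n_perm permutations for the FDR stage.
#' @param p_threshold signature-gene significance cut.
#' @param k k-means cluster count.
#' @param control_size control gene-set size.
#' @param n_snps,n_blocks_ld,chrom_length,ld_rho toy genome and LD layout.
#' @param window_bp gene-set annotation window (bp).
#' @param ld_window_bp LD-score window (bp).
#' @param n_traits_aging,n_traits_null simulated trait counts; aging traits
#'   carry the true inflammaging annotation enriched `true_enrichment`-fold.
#' @param gwas_n GWAS sample size per trait.
#' @param h2 total SNP heritability per trait.
#' @param true_enrichment fold enrichment of the true annotation in aging
#'   traits.
#' @param maf_min,h2_z_min summary-statistics QC gates.
#' @param n_blocks_jackknife jackknife blocks for [sldsc()].
#' @param stages named logical list toggling `screen`, `fdr`, `classify`,
#'   `gwas`, `sldsc`, `meta`.
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(seed = 1L,
                            n_genes = 500, sgrnas_per_gene = 5,
                            n_nontargeting = 100,
                            n_inflammaging = 50, n_common = 50,
                            n_essential = 25,
                            effect_size = 1, depth_per_sgrna = 500,
                            dispersion = 0.05, n_replicates = 2,
                            sgrna_noise_sd = 0.2,
                            n_perm = 20, p_threshold = 0.05, k = 4,
                            control_size = 50,
                            n_snps = 10000, n_blocks_ld = 100,
                            chrom_length = 5e7, ld_rho = 0.9,
                            window_bp = 1e5, ld_window_bp = 1e6,
                            n_traits_aging = 10, n_traits_null = 10,
                            gwas_n = 50000, h2 = 0.5, true_enrichment = 2,
                            maf_min = 0.05, h2_z_min = 6,
                            n_blocks_jackknife = 20,
                            stages = list(screen = TRUE, fdr = FALSE,
                                          classify = TRUE, gwas = TRUE,
                                          sldsc = TRUE, meta = TRUE)) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path JSON file path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg$stages <- as.list(cfg$stages)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full synthetic workflow
#'
#' Executes the enabled stages in dependency order, writing every artifact
#' as TSV/GMT/JSON under `out_dir` and returning a manifest with an MD5
#' content hash per artifact; a rerun with the same configuration
#' reproduces the hashes. No stage mutates its inputs on disk.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if absent).
#' @return list of class `"pipeline_run"` with `manifest` (data.frame:
#'   `artifact`, `path`, `md5`) and `results` (in-memory stage outputs).
#' @export
run_pipeline <- function(config, out_dir = tempfile("senescreen_run_")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- config
  seeds <- cfg$seed + c(screen = 0L, classify = 1L, genome = 2L,
                        gwas = 3L, fdr = 4L)
  res <- list()
  manifest <- data.frame(artifact = character(0), path = character(0),
                         md5 = character(0))
  emit <- function(name, path) {
    manifest <<- rbind(manifest, data.frame(
      artifact = name, path = path, md5 = unname(tools::md5sum(path))))
  }

  lib <- make_library(cfg$n_genes, cfg$sgrnas_per_gene, cfg$n_nontargeting)
  genes <- unique(lib$gene_id[lib$gene_id != NON_TARGETING])
  n_eff <- cfg$n_inflammaging + cfg$n_common + cfg$n_essential
  stopifnot(n_eff <= cfg$n_genes)
  cls <- rep(c("pro_senescence_inflammaging", "pro_senescence_common",
               "essential", "null"),
             c(cfg$n_inflammaging, cfg$n_common, cfg$n_essential,
               cfg$n_genes - n_eff))
  eff <- screen_effects(
    genes,
    beta_rss = ifelse(cls == "pro_senescence_common", cfg$effect_size,
                      ifelse(cls == "essential", -cfg$effect_size, 0)),
    beta_iss = ifelse(cls %in% c("pro_senescence_common",
                                 "pro_senescence_inflammaging"),
                      cfg$effect_size,
                      ifelse(cls == "essential", -cfg$effect_size, 0)),
    class_label = cls)
  res$truth <- eff

  if (isTRUE(cfg$stages$screen)) {
    sim <- simulate_screen(lib, eff,
                           depth = cfg$depth_per_sgrna * nrow(lib),
                           dispersion = cfg$dispersion,
                           n_replicates = cfg$n_replicates,
                           sgrna_noise_sd = cfg$sgrna_noise_sd,
                           seed = seeds[["screen"]])
    write_counts(sim$counts, lib, file.path(out_dir, "counts.tsv"))
    emit("counts", file.path(out_dir, "counts.tsv"))
    write_library(lib, file.path(out_dir, "library.tsv"))
    emit("library", file.path(out_dir, "library.tsv"))
    fits <- list()
    for (cond in c("rss", "iss")) {
      f <- screen_mle(sim$counts, lib, sim$design, cond,
                      pseudo_size = cfg$sgrnas_per_gene)
      if (isTRUE(cfg$stages$fdr)) {
        f <- permutation_fdr(sim$counts, lib, sim$design, cond,
                             n_perm = cfg$n_perm, seed = seeds[["fdr"]],
                             fit = f)
      }
      p <- file.path(out_dir, paste0("gene_results_", cond, ".tsv"))
      write_gene_results(f, p)
      emit(paste0("gene_results_", cond), p)
      fits[[cond]] <- f
    }
    res$screen <- fits
  }

  if (isTRUE(cfg$stages$classify)) {
    sig <- select_signature_genes(res$screen$rss, res$screen$iss,
                                  p_threshold = cfg$p_threshold)
    cl <- kmeans_classify(sig, k = cfg$k, seed = seeds[["classify"]])
    p <- file.path(out_dir, "clusters.tsv")
    write_tsv_(cl, p); emit("clusters", p)
    sets <- list(
      inflammaging = cl$gene[cl$set_label == "inflammaging"],
      common_aging = cl$gene[cl$set_label == "common_aging"])
    sets$control <- sample_control_genes(
      genes, sets, min(cfg$control_size, length(genes) - length(unlist(sets))),
      seed = seeds[["classify"]])
    gsc <- gene_set_collection(sets, genes)
    p <- file.path(out_dir, "gene_sets.gmt")
    write_gmt(gsc, p); emit("gene_sets", p)
    res$gene_sets <- gsc
  }

  if (isTRUE(cfg$stages$gwas)) {
    gen <- simulate_genome(cfg$n_genes, cfg$n_snps, cfg$n_blocks_ld,
                           cfg$chrom_length, seed = seeds[["genome"]])
    write_gene_map(gen$gene_map, file.path(out_dir, "gene_map.tsv"))
    emit("gene_map", file.path(out_dir, "gene_map.tsv"))
    write_gene_bed(gen$gene_map, file.path(out_dir, "gene_map.bed"))
    emit("gene_map_bed", file.path(out_dir, "gene_map.bed"))

    # true annotation (from designated inflammaging genes) drives the
    # generative enrichment; estimation uses the classified sets
    true_annot <- build_annotation(
      eff$gene_id[eff$class_label == "pro_senescence_inflammaging"],
      gen$gene_map, gen$snp_map, cfg$window_bp)
    M <- sum(true_annot)
    tau_enr <- enrichment_tau(cfg$h2, cfg$true_enrichment, M, cfg$n_snps)
    A_true <- cbind(base = 1L, true = true_annot)
    traits <- data.frame(
      trait_id = c(sprintf("aging_%02d", seq_len(cfg$n_traits_aging)),
                   sprintf("nonaging_%02d", seq_len(cfg$n_traits_null))),
      aging = rep(c(TRUE, FALSE),
                  c(cfg$n_traits_aging, cfg$n_traits_null)))
    sumstats <- vector("list", nrow(traits))
    for (i in seq_len(nrow(traits))) {
      tau <- if (traits$aging[i]) tau_enr else
        c(base = cfg$h2 / cfg$n_snps, annot = 0)
      g <- simulate_gwas(gen$snp_map, A_true, tau, N = cfg$gwas_n,
                         rho = cfg$ld_rho, seed = seeds[["gwas"]] + i)
      sumstats[[i]] <- g$sumstats
      p <- file.path(out_dir, paste0("sumstats_", traits$trait_id[i], ".tsv"))
      write_sumstats(g$sumstats, p)
      emit(paste0("sumstats_", traits$trait_id[i]), p)
    }
    write_tsv_(traits, file.path(out_dir, "traits.tsv"))
    emit("traits", file.path(out_dir, "traits.tsv"))
    res$genome <- gen
    res$traits <- traits
    res$sumstats <- sumstats
  }

  if (isTRUE(cfg$stages$sldsc)) {
    A <- annotation_matrix(res$gene_sets, res$genome$gene_map,
                           res$genome$snp_map, cfg$window_bp)
    write_annotations(A, res$genome$snp_map,
                      file.path(out_dir, "annotations.tsv"))
    emit("annotations", file.path(out_dir, "annotations.tsv"))
    L <- compute_ld_scores(ar1_ld(cfg$ld_rho), res$genome$snp_map, A,
                           window_bp = cfg$ld_window_bp)
    write_ld_scores(L, res$genome$snp_map,
                    file.path(out_dir, "ld_scores.tsv"))
    emit("ld_scores", file.path(out_dir, "ld_scores.tsv"))
    set_names <- setdiff(colnames(A), "base")
    fits <- list()
    rows <- list()
    for (i in seq_along(res$sumstats)) {
      for (s in set_names) {
        # each gene set is fitted separately, conditional on the base
        f <- sldsc(res$sumstats[[i]], L[, c("base", s)], A[, c("base", s)],
                   n_blocks = cfg$n_blocks_jackknife)
        d <- per_snp_difference(f, s)
        rows[[length(rows) + 1]] <- data.frame(
          trait_id = res$traits$trait_id[i], aging = res$traits$aging[i],
          gene_set = s, M = unname(f$M[s]),
          enrichment = unname(f$enrichment[s]),
          enrichment_se = unname(f$enrichment_se[s]),
          d = d[["d"]], d_se = d[["se"]],
          p_one_sided = unname(f$p_one_sided[s]))
        fits[[paste(res$traits$trait_id[i], s, sep = ".")]] <- f
      }
    }
    res$sldsc <- do.call(rbind, rows)
    p <- file.path(out_dir, "sldsc_results.tsv")
    write_tsv_(res$sldsc, p); emit("sldsc_results", p)
  }

  if (isTRUE(cfg$stages$meta)) {
    tab <- res$sldsc
    groups <- split(tab, list(tab$gene_set, tab$aging))
    rows <- lapply(groups, function(g) {
      md <- meta_random(g$d, g$d_se)
      me <- meta_random(g$enrichment, g$enrichment_se)
      data.frame(gene_set = g$gene_set[1], aging = g$aging[1],
                 n_traits = md$n_studies,
                 enrichment = me$estimate, enrichment_se = me$se,
                 d = md$estimate, d_se = md$se,
                 p_one_sided = md$p_one_sided)
    })
    res$meta <- do.call(rbind, c(rows, make.row.names = FALSE))
    p <- file.path(out_dir, "meta_results.tsv")
    write_tsv_(res$meta, p); emit("meta_results", p)

    wide_e <- stats::reshape(
      tab[, c("trait_id", "gene_set", "enrichment")],
      idvar = "trait_id", timevar = "gene_set", direction = "wide")
    wide_p <- stats::reshape(
      tab[, c("trait_id", "gene_set", "p_one_sided")],
      idvar = "trait_id", timevar = "gene_set", direction = "wide")
    em <- as.matrix(wide_e[, -1]); rownames(em) <- wide_e$trait_id
    pm <- as.matrix(wide_p[, -1]); rownames(pm) <- wide_p$trait_id
    colnames(em) <- sub("^enrichment\\.", "", colnames(em))
    colnames(pm) <- sub("^p_one_sided\\.", "", colnames(pm))
    res$trait_clusters <- suppressWarnings(
      select_and_cluster_traits(em, pm, p_threshold = cfg$p_threshold))
    p <- file.path(out_dir, "enrichment_matrix.tsv")
    write_tsv_(data.frame(trait_id = rownames(em), em, check.names = FALSE), p)
    emit("enrichment_matrix", p)
  }

  cfg_path <- file.path(out_dir, "config.json")
  write_config(cfg, cfg_path); emit("config", cfg_path)
  structure(list(manifest = manifest, results = res, out_dir = out_dir),
            class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("Pipeline run:", nrow(x$manifest), "artifacts in", x$out_dir, "\n")
  print(x$manifest[, c("artifact", "md5")], row.names = FALSE)
  invisible(x)
}
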