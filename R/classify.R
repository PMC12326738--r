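#' Select signature genes significant in either screen arm
#'
#' Keeps genes with Wald p below `p_threshold` in the replicative (RSS) or
#' the inflammatory (ISS) arm, and attaches both beta scores.
#'
#' @param rss,iss per-gene tables (a [screen_mle()] object or its
#'   `$results`) for the two arms; non-targeting pseudo-genes are excluded.
#' @param p_threshold significance cut (default 0.05).
#' @return data.frame with `gene`, `beta_rss`, `beta_iss`, `p_rss`, `p_iss`.
#' @export
select_signature_genes <- function(rss, iss, p_threshold = 0.05) {
  get <- function(x) {
    if (inherits(x, "screen_fit")) x <- x$results
    if (!is.null(x$is_control)) x <- x[!x$is_control, , drop = FALSE]
    x
  }
  r <- get(rss); i <- get(iss)
  m <- merge(r[, c("gene", "beta", "wald_p")],
             i[, c("gene", "beta", "wald_p")],
             by = "gene", suffixes = c("_rss", "_iss"))
  keep <- (is.finite(m$wald_p_rss) & m$wald_p_rss < p_threshold) |
    (is.finite(m$wald_p_iss) & m$wald_p_iss < p_threshold)
  out <- m[keep, ]
  if (nrow(out) == 0) {
    stop("no gene reaches p < ", p_threshold, " in either arm")
  }
  names(out) <- c("gene", "beta_rss", "p_rss", "beta_iss", "p_iss")
  out <- out[, c("gene", "beta_rss", "beta_iss", "p_rss", "p_iss")]
  rownames(out) <- NULL
  out
}

#' Classify signature genes by k-means on the two beta scores
#'
#' Runs Lloyd's k-means (best of `n_restarts`) on the unscaled
#' `(beta_rss, beta_iss)` matrix — both columns are beta scores on a shared
#' scale, so no standardisation is applied — then labels each cluster from
#' its centroid: a centroid whose ISS component is large while its RSS
#' component is small marks an inflammaging cluster (ISS-specific
#' selection); large concordant components in both arms mark a common-aging
#' cluster; anything else is unassigned. "Large" means at least
#' `large_frac` times the largest absolute centroid component over all
#' clusters, so the rule depends only on the centroids, not on cluster
#' numbering.
#'
#' @param signature table from [select_signature_genes()].
#' @param k number of clusters (default 4: enriched and depleted groups in
#'   each of the two patterns).
#' @param n_restarts random restarts; the best within-cluster SS is kept.
#' @param seed integer seed.
#' @param large_frac fraction of the maximum absolute centroid component
#'   above which a component counts as "large".
#' @return data.frame with `gene`, `beta_rss`, `beta_iss`, `cluster`,
#'   `set_label` in `{"inflammaging", "common_aging", "unassigned"}`;
#'   attribute `"centers"` holds the centroid matrix.
#' @export
kmeans_classify <- function(signature, k = 4, n_restarts = 50, seed = 1L,
                            large_frac = 0.5) {
  x <- as.matrix(signature[, c("beta_rss", "beta_iss")])
  if (nrow(x) < k) stop("k = ", k, " exceeds the ", nrow(x), " genes supplied")
  withr::local_seed(seed)
  # random Lloyd restarts routinely produce empty-cluster warnings that the
  # multi-start selection already absorbs, so they are muffled here
  km <- withCallingHandlers(
    kmeans(x, centers = k, nstart = n_restarts,
           algorithm = "Lloyd", iter.max = 200),
    warning = function(w) {
      if (grepl("empty cluster", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  centers <- km$centers
  thr <- large_frac * max(abs(centers))
  lab <- character(k)
  for (j in seq_len(k)) {
    rss_large <- abs(centers[j, "beta_rss"]) >= thr
    iss_large <- abs(centers[j, "beta_iss"]) >= thr
    concordant <- sign(centers[j, "beta_rss"]) == sign(centers[j, "beta_iss"])
    lab[j] <- if (iss_large && !rss_large) "inflammaging"
    else if (iss_large && rss_large && concordant) "common_aging"
    else "unassigned"
  }
  out <- data.frame(gene = signature$gene,
                    beta_rss = signature$beta_rss,
                    beta_iss = signature$beta_iss,
                    cluster = km$cluster,
                    set_label = lab[km$cluster],
                    stringsAsFactors = FALSE)
  attr(out, "centers") <- centers
  attr(out, "cluster_labels") <- lab
  out
}

#' Sample a control gene set from the genome
#'
#' Uniform sample without replacement from the universe after removing the
#' excluded sets (the classified inflammaging and common-aging genes).
#'
#' @param universe character vector of all gene ids.
#' @param excluded character vector (or list of vectors) of gene ids to
#'   exclude.
#' @param size number of control genes.
#' @param seed integer seed.
#' @return character vector of `size` gene ids.
#' @export
sample_control_genes <- function(universe, excluded, size, seed = 1L) {
  pool <- setdiff(universe, unlist(excluded))
  if (size > length(pool)) {
    stop("requested ", size, " control genes but only ", length(pool),
         " are available")
  }
  if (size == 0) return(character(0))
  withr::local_seed(seed)
  sample(pool, size)
}

#' Hypergeometric over-representation of a gene set
#'
#' Upper-tail hypergeometric test `P(X >= overlap)` of a query gene set
#' against each reference set within a universe, with Benjamini-Hochberg
#' correction across reference sets.
#'
#' @param query character vector of gene ids, a subset of `universe`.
#' @param reference_sets named list of gene-id vectors; members outside the
#'   universe are dropped with a warning.
#' @param universe character vector defining the background.
#' @return data.frame with `set`, `set_size`, `overlap`, `p`, `q` (BH).
#' @export
hypergeometric_enrichment <- function(query, reference_sets, universe) {
  universe <- unique(universe)
  query <- unique(query)
  if (!all(query %in% universe)) stop("query must be a subset of the universe")
  N <- length(universe); n <- length(query)
  rows <- lapply(names(reference_sets), function(nm) {
    ref <- unique(reference_sets[[nm]])
    out <- setdiff(ref, universe)
    if (length(out) > 0) {
      warning("reference set '", nm, "': ", length(out),
              " gene(s) outside the universe dropped")
      ref <- intersect(ref, universe)
    }
    K <- length(ref)
    ov <- length(intersect(query, ref))
    p <- phyper(ov - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, set_size = K, overlap = ov, p = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$q <- p.adjust(res$p, method = "BH")
  rownames(res) <- NULL
  res
}

#' Assemble a named gene-set collection
#'
#' @param sets named list of gene-id vectors; each must be a subset of the
#'   universe; `inflammaging`/`common_aging` must be disjoint and a
#'   `control` set must not intersect either.
#' @param universe character vector of all gene ids.
#' @return list of class `"gene_set_collection"`.
#' @export
gene_set_collection <- function(sets, universe) {
  universe <- unique(universe)
  for (nm in names(sets)) {
    sets[[nm]] <- unique(as.character(sets[[nm]]))
    if (!all(sets[[nm]] %in% universe)) {
      stop("set '", nm, "' is not a subset of the universe")
    }
  }
  both <- intersect(sets[["inflammaging"]], sets[["common_aging"]])
  if (length(both) > 0) stop("inflammaging and common_aging sets overlap")
  if (!is.null(sets[["control"]])) {
    bad <- intersect(sets[["control"]],
                     c(sets[["inflammaging"]], sets[["common_aging"]]))
    if (length(bad) > 0) stop("control set overlaps a classified set")
  }
  structure(list(sets = sets, universe = universe),
            class = "gene_set_collection")
}
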