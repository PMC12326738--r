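#' Build a distance-based binary SNP annotation from a gene set
#'
#' Marks a SNP as inside the annotation if it lies within `window_bp` of the
#' transcribed region of any gene in the set, i.e. its position falls in
#' `[tx_start - window_bp, tx_end + window_bp]` on the same chromosome,
#' boundaries inclusive. Coordinates are 1-based inclusive.
#'
#' @param gene_set character vector of gene ids; genes absent from
#'   `gene_map` are skipped with a warning.
#' @param gene_map data.frame with `gene_id`, `chromosome`, `tx_start`,
#'   `tx_end`.
#' @param snp_map data.frame with `snp_id`, `chromosome`, `position`.
#' @param window_bp flanking distance in bp (default 100 kb).
#' @return integer 0/1 vector aligned to the rows of `snp_map`.
#' @export
build_annotation <- function(gene_set, gene_map, snp_map, window_bp = 1e5) {
  stopifnot(window_bp >= 0)
  missing <- setdiff(gene_set, gene_map$gene_id)
  if (length(missing) > 0) {
    warning(length(missing), " gene(s) absent from the gene map skipped: ",
            paste(head(missing, 5), collapse = ", "))
  }
  gm <- gene_map[gene_map$gene_id %in% gene_set, , drop = FALSE]
  if (nrow(gm) == 0) return(integer(nrow(snp_map)))
  genes <- GenomicRanges::GRanges(
    seqnames = gm$chromosome,
    ranges = IRanges::IRanges(start = pmax(1, gm$tx_start - window_bp),
                              end = gm$tx_end + window_bp))
  snps <- GenomicRanges::GRanges(
    seqnames = snp_map$chromosome,
    ranges = IRanges::IRanges(start = snp_map$position, width = 1))
  as.integer(IRanges::overlapsAny(snps, genes))
}

#' Annotation matrix with a base column
#'
#' Stacks one [build_annotation()] column per gene set after an all-ones
#' base column covering every SNP (the layout expected by [sldsc()]).
#'
#' @param gene_sets named list of gene-id vectors, or a
#'   [gene_set_collection()].
#' @inheritParams build_annotation
#' @return integer SNP x (1 + n_sets) matrix; first column `base`.
#' @export
annotation_matrix <- function(gene_sets, gene_map, snp_map, window_bp = 1e5) {
  if (inherits(gene_sets, "gene_set_collection")) gene_sets <- gene_sets$sets
  cols <- vapply(gene_sets, build_annotation, integer(nrow(snp_map)),
                 gene_map = gene_map, snp_map = snp_map,
                 window_bp = window_bp)
  out <- cbind(base = 1L, cols)
  rownames(out) <- snp_map$snp_id
  out
}

#' Stratified LD scores
#'
#' Computes `l(j, c) = sum_k r2[j, k] A[k, c]` over SNPs `k` within
#' `window_bp` of SNP `j` (always including `j` itself, `r2[j, j] = 1`).
#' The LD source may be an exact AR(1) block specification ([ar1_ld()]), a
#' reference genotype panel (samples x SNPs matrix, correlations estimated
#' within each LD block and optionally bias-adjusted by
#' `r2 - (1 - r2) / (n_ref - 2)`), or a full SNP x SNP correlation matrix
#' (must be positive definite).
#'
#' @param ld an [ar1_ld()] object, a genotype matrix (rows = samples), or a
#'   SNP x SNP correlation matrix.
#' @param snp_map SNP map with `position` and `block_id`.
#' @param annotations binary SNP x C matrix.
#' @param window_bp physical window for the LD-score sum (default 1 Mb).
#' @param adjust apply the small-panel bias adjustment (panel source only).
#' @return numeric SNP x C matrix with attributes `window_bp` and
#'   `adjusted`.
#' @export
compute_ld_scores <- function(ld, snp_map, annotations, window_bp = 1e6,
                              adjust = FALSE) {
  annotations <- as.matrix(annotations)
  m <- nrow(snp_map)
  stopifnot(nrow(annotations) == m, window_bp >= 0)
  out <- matrix(0, m, ncol(annotations),
                dimnames = list(snp_map$snp_id, colnames(annotations)))
  full_R <- NULL
  if (is.matrix(ld) && nrow(ld) == m && ncol(ld) == m) {
    ok <- tryCatch({ chol(ld); TRUE }, error = function(e) FALSE)
    if (!ok) stop("supplied correlation matrix is not positive definite")
    full_R <- ld
  } else if (is.matrix(ld)) {
    if (ncol(ld) != m) stop("genotype panel must have one column per SNP")
    if (adjust && nrow(ld) <= 2) stop("bias adjustment needs n_ref > 2")
  } else if (!inherits(ld, "ar1_ld")) {
    stop("ld must be an ar1_ld(), a genotype panel, or a correlation matrix")
  }
  if (!is.null(full_R)) {
    # a full correlation matrix may carry LD across blocks; use it as given
    w <- abs(outer(snp_map$position, snp_map$position, "-")) <= window_bp
    out[, ] <- (full_R^2 * w) %*% annotations
    attr(out, "window_bp") <- window_bp
    attr(out, "adjusted") <- FALSE
    return(out)
  }
  blocks <- split(seq_len(m), snp_map$block_id)
  for (b in blocks) {
    k <- length(b)
    r2 <- if (inherits(ld, "ar1_ld")) {
      ld$rho^(2 * abs(outer(seq_len(k), seq_len(k), "-")))
    } else {
      r <- suppressWarnings(stats::cor(ld[, b, drop = FALSE]))
      r[!is.finite(r)] <- 0
      diag(r) <- 1
      r2b <- r^2
      if (adjust) {
        n_ref <- nrow(ld)
        r2b <- r2b - (1 - r2b) / (n_ref - 2)
        diag(r2b) <- 1
      }
      r2b
    }
    pos <- snp_map$position[b]
    w <- abs(outer(pos, pos, "-")) <= window_bp
    out[b, ] <- (r2 * w) %*% annotations[b, , drop = FALSE]
  }
  attr(out, "window_bp") <- window_bp
  attr(out, "adjusted") <- isTRUE(adjust)
  out
}
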