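
# schema guard shared by all readers: errors name the missing column
check_cols <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop(what, ": missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  invisible(df)
}

check_unique <- function(x, what, key) {
  if (anyDuplicated(x)) {
    stop(what, ": duplicated ", key, ": ",
         paste(head(unique(x[duplicated(x)]), 5), collapse = ", "))
  }
  invisible(x)
}

read_tsv_ <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE)
}

write_tsv_ <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write screen count tables
#'
#' TSV with columns `sgrna`, `gene`, then one integer column per sample.
#'
#' @param path file path.
#' @return `read_counts`: list with `counts` (integer matrix, sgRNA x
#'   sample) and `library` (`sgrna_id`, `gene_id`).
#' @export
read_counts <- function(path) {
  df <- read_tsv_(path)
  check_cols(df, c("sgrna", "gene"), "counts file")
  check_unique(df$sgrna, "counts file", "sgrna")
  samp <- setdiff(names(df), c("sgrna", "gene"))
  counts <- as.matrix(df[, samp, drop = FALSE])
  if (length(samp) > 0 && !is.numeric(counts)) {
    stop("counts file: non-numeric sample column(s)")
  }
  storage.mode(counts) <- "integer"
  rownames(counts) <- df$sgrna
  list(counts = counts,
       library = data.frame(sgrna_id = df$sgrna, gene_id = df$gene,
                            stringsAsFactors = FALSE))
}

#' @rdname read_counts
#' @param counts integer matrix with sgRNA rownames.
#' @param library matching sgRNA-to-gene table.
#' @export
write_counts <- function(counts, library, path) {
  stopifnot(identical(rownames(counts), library$sgrna_id))
  df <- data.frame(sgrna = library$sgrna_id, gene = library$gene_id,
                   counts, check.names = FALSE)
  write_tsv_(df, path)
}

#' Read and write sgRNA library tables
#'
#' TSV with columns `sgrna_id`, `gene_id` and optional `sequence`.
#' @param path file path.
#' @export
read_library <- function(path) {
  df <- read_tsv_(path)
  check_cols(df, c("sgrna_id", "gene_id"), "library file")
  check_unique(df$sgrna_id, "library file", "sgrna_id")
  df
}

#' @rdname read_library
#' @param library library table.
#' @export
write_library <- function(library, path) write_tsv_(library, path)

#' Read and write gene coordinate tables
#'
#' TSV with `gene_id`, `chromosome`, `tx_start`, `tx_end` (1-based
#' inclusive). `write_gene_bed` exports the same intervals in BED
#' convention (0-based half-open).
#' @param path file path.
#' @export
read_gene_map <- function(path) {
  df <- read_tsv_(path)
  check_cols(df, c("gene_id", "chromosome", "tx_start", "tx_end"),
             "gene map")
  check_unique(df$gene_id, "gene map", "gene_id")
  if (any(df$tx_start > df$tx_end)) stop("gene map: tx_start > tx_end")
  df
}

#' @rdname read_gene_map
#' @param gene_map gene coordinate table.
#' @export
write_gene_map <- function(gene_map, path) write_tsv_(gene_map, path)

#' @rdname read_gene_map
#' @export
write_gene_bed <- function(gene_map, path) {
  bed <- data.frame(chrom = gene_map$chromosome,
                    start = gene_map$tx_start - 1L,  # 0-based half-open
                    end = gene_map$tx_end,
                    name = gene_map$gene_id)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read and write GWAS summary statistics
#'
#' Sumstats-style TSV with columns `SNP`, `A1`, `A2`, `Z`, `N`.
#' @param path file path.
#' @export
read_sumstats <- function(path) {
  df <- read_tsv_(path)
  check_cols(df, c("SNP", "A1", "A2", "Z", "N"), "sumstats file")
  check_unique(df$SNP, "sumstats file", "SNP")
  df
}

#' @rdname read_sumstats
#' @param sumstats summary-statistics table.
#' @export
write_sumstats <- function(sumstats, path) write_tsv_(sumstats, path)

#' Read and write SNP annotation matrices
#'
#' LDSC-style layout: `CHR`, `SNP`, `BP`, then one 0/1 column per
#' annotation (first the all-ones `base`). `read_annotations` returns the
#' matrix with SNP rownames. LD-score tables use the same layout with
#' annotation columns suffixed `L2`.
#' @param path file path.
#' @export
read_annotations <- function(path) {
  df <- read_tsv_(path)
  check_cols(df, c("CHR", "SNP", "BP"), "annotation file")
  check_unique(df$SNP, "annotation file", "SNP")
  a <- as.matrix(df[, setdiff(names(df), c("CHR", "SNP", "BP")), drop = FALSE])
  rownames(a) <- df$SNP
  a
}

#' @rdname read_annotations
#' @param annotations SNP x C matrix with SNP rownames.
#' @param snp_map SNP map supplying `CHR` and `BP`.
#' @export
write_annotations <- function(annotations, snp_map, path) {
  stopifnot(nrow(annotations) == nrow(snp_map))
  df <- data.frame(CHR = snp_map$chromosome, SNP = snp_map$snp_id,
                   BP = snp_map$position, annotations, check.names = FALSE)
  write_tsv_(df, path)
}

#' @rdname read_annotations
#' @param ld_scores SNP x C matrix of LD scores.
#' @export
write_ld_scores <- function(ld_scores, snp_map, path) {
  ls <- as.matrix(ld_scores)
  colnames(ls) <- paste0(colnames(ls), "L2")
  df <- data.frame(CHR = snp_map$chromosome, SNP = snp_map$snp_id,
                   BP = snp_map$position, ls, check.names = FALSE)
  write_tsv_(df, path)
}

#' @rdname read_annotations
#' @export
read_ld_scores <- function(path) {
  a <- read_annotations(path)
  l2 <- grepl("L2$", colnames(a))
  if (!all(l2)) stop("LD-score file: column(s) without L2 suffix: ",
                     paste(colnames(a)[!l2], collapse = ", "))
  colnames(a) <- sub("L2$", "", colnames(a))
  a
}

#' Read and write GMT gene-set files
#'
#' Standard GMT: one set per line — name, description, then tab-separated
#' member genes.
#' @param path file path.
#' @return `read_gmt`: named list of gene-id vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 2) stop("malformed GMT line: ", substr(ln, 1, 40))
    out[[f[1]]] <- f[-(1:2)]
  }
  out
}

#' @rdname read_gmt
#' @param sets named list of gene-id vectors (or a
#'   [gene_set_collection()]).
#' @param descriptions optional character vector matching `sets`.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (inherits(sets, "gene_set_collection")) sets <- sets$sets
  descriptions <- descriptions %||% rep("", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read and write per-gene screen result tables
#'
#' TSV with columns `gene`, `condition`, `beta`, `se`, `wald_p`, `fdr`,
#' `n_sgrnas`.
#' @param path file path.
#' @export
read_gene_results <- function(path) {
  df <- read_tsv_(path)
  check_cols(df, c("gene", "condition", "beta", "se", "wald_p", "fdr",
                   "n_sgrnas"), "gene results")
  df
}

#' @rdname read_gene_results
#' @param results a [screen_mle()] fit or its `$results`.
#' @export
write_gene_results <- function(results, path) {
  if (inherits(results, "screen_fit")) results <- results$results
  cols <- c("gene", "condition", "beta", "se", "wald_p", "fdr", "n_sgrnas")
  write_tsv_(results[, cols], path)
}
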