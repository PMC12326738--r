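#' Random-effects meta-analysis (DerSimonian-Laird)
#'
#' Pools per-trait estimates with inverse-variance weights allowing
#' between-study variance: `tau2 = max(0, (Q - (n-1)) / (S1 - S2/S1))` with
#' `w = 1/se^2`, `S1 = sum w`, `S2 = sum w^2`, then
#' `pooled = sum(w* est) / sum(w*)` with `w* = 1/(se^2 + tau2)` and
#' `SE = 1/sqrt(sum w*)`. A single study is returned unchanged with
#' `tau2 = 0`.
#'
#' @param estimates numeric vector of study estimates.
#' @param ses positive standard errors, same length.
#' @return object of class `"meta_re"`: `estimate`, `se`, `tau2`, `z`,
#'   `p_one_sided` (upper tail), `Q`, `n_studies`.
#' @export
meta_random <- function(estimates, ses) {
  ok <- is.finite(estimates) & is.finite(ses)
  estimates <- estimates[ok]; ses <- ses[ok]
  n <- length(estimates)
  if (n == 0) stop("no studies to pool")
  if (any(ses <= 0)) stop("all standard errors must be positive")
  if (n == 1) {
    est <- estimates; se <- ses; tau2 <- 0; Q <- 0
  } else {
    w <- 1 / ses^2
    fixed <- sum(w * estimates) / sum(w)
    Q <- sum(w * (estimates - fixed)^2)
    tau2 <- max(0, (Q - (n - 1)) / (sum(w) - sum(w^2) / sum(w)))
    ws <- 1 / (ses^2 + tau2)
    est <- sum(ws * estimates) / sum(ws)
    se <- 1 / sqrt(sum(ws))
  }
  z <- est / se
  structure(list(estimate = unname(est), se = unname(se), tau2 = tau2,
                 z = unname(z), p_one_sided = pnorm(z, lower.tail = FALSE),
                 Q = unname(Q), n_studies = n),
            class = "meta_re")
}

#' @export
print.meta_re <- function(x, ...) {
  cat(sprintf(
    "Random-effects meta-analysis (%d studies)\n  pooled = %.4g (se %.3g), tau2 = %.3g, one-sided p = %.3g\n",
    x$n_studies, x$estimate, x$se, x$tau2, x$p_one_sided))
  invisible(x)
}

#' One-sided test that a pooled quantity exceeds zero
#'
#' Upper-tail standard-normal p-value of `pooled / SE`.
#'
#' @param meta a [meta_random()] result (or any list with `estimate`, `se`).
#' @return p-value in (0, 1].
#' @export
one_sided_test <- function(meta) {
  if (meta$se <= 0) stop("pooled SE must be positive")
  pnorm(meta$estimate / meta$se, lower.tail = FALSE)
}

#' Compare the pooled estimates of two gene sets
#'
#' One-sided p-value that set A's pooled estimate exceeds set B's, from
#' `z = (A - B) / sqrt(SE_A^2 + SE_B^2)` assuming independence. When both
#' sets were evaluated on the same traits this is approximate (shared
#' traits induce positive correlation, making the test conservative when
#' the correlation is positive); for a trait-paired alternative,
#' meta-analyse the per-trait differences with [meta_random()] (see
#' [compare_gene_sets_paired()]).
#'
#' @param metaA,metaB [meta_random()] results for the two gene sets.
#' @return one-sided p-value for A > B.
#' @export
compare_gene_sets <- function(metaA, metaB) {
  z <- (metaA$estimate - metaB$estimate) / sqrt(metaA$se^2 + metaB$se^2)
  pnorm(z, lower.tail = FALSE)
}

#' Trait-paired comparison of two gene sets
#'
#' Meta-analyses the per-trait differences `estA - estB` (SE of each
#' difference taken as `sqrt(seA^2 + seB^2)`) with [meta_random()] and
#' returns the upper-tail p that the pooled difference exceeds zero.
#'
#' @param estA,seA,estB,seB per-trait estimates and SEs, aligned by trait.
#' @return one-sided p-value for A > B.
#' @export
compare_gene_sets_paired <- function(estA, seA, estB, seB) {
  one_sided_test(meta_random(estA - estB, sqrt(seA^2 + seB^2)))
}

#' Select traits with any enriched gene set and cluster them
#'
#' Keeps traits whose one-sided enrichment p falls below `p_threshold` for
#' at least one gene set, clusters the retained rows of the enrichment
#' matrix (hierarchical, Euclidean distance, complete linkage, cut at `k`),
#' and labels each trait by its argmax gene set ("specific" set: the set
#' contributing the most enrichment).
#'
#' @param enrichment trait x gene-set numeric matrix (rownames = traits).
#' @param p_values matching matrix of one-sided enrichment p-values.
#' @param p_threshold selection threshold (default 0.05).
#' @param k number of clusters (default `min(4, n_selected)`).
#' @return data.frame with `trait`, `cluster`, `specific_set`; empty (with
#'   a warning) when no trait passes.
#' @export
select_and_cluster_traits <- function(enrichment, p_values,
                                      p_threshold = 0.05, k = NULL) {
  enrichment <- as.matrix(enrichment)
  p_values <- as.matrix(p_values)
  stopifnot(identical(dim(enrichment), dim(p_values)))
  pass <- apply(p_values, 1, function(p) any(is.finite(p) & p < p_threshold))
  if (!any(pass)) {
    warning("no trait shows enrichment below p = ", p_threshold)
    return(data.frame(trait = character(0), cluster = integer(0),
                      specific_set = character(0)))
  }
  e <- enrichment[pass, , drop = FALSE]
  k <- k %||% min(4L, nrow(e))
  cl <- if (nrow(e) == 1) 1L else cutree(hclust(dist(e), method = "complete"), k = k)
  data.frame(
    trait = rownames(e),
    cluster = as.integer(cl),
    specific_set = colnames(e)[apply(e, 1, which.max)],
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Association between a trait cluster label and the aging annotation
#'
#' Cross-tabulates a binary trait label (e.g. inflammaging-specific vs
#' other) against the aging / non-aging annotation and applies Fisher's
#' exact test (two-sided). Degenerate margins return p = 1 with a warning.
#'
#' @param label logical or two-level vector per trait.
#' @param aging logical or two-level vector per trait.
#' @return list with `table` (2x2), `p`, `odds_ratio`.
#' @export
cluster_group_association <- function(label, aging) {
  label <- factor(label)
  aging <- factor(aging)
  if (nlevels(label) < 2 || nlevels(aging) < 2) {
    warning("degenerate margin; association test undefined")
    return(list(table = table(label, aging), p = 1, odds_ratio = NA_real_))
  }
  tab <- table(label, aging)
  ft <- fisher.test(tab)
  list(table = tab, p = ft$p.value, odds_ratio = unname(ft$estimate))
}
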