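#' Gold-standard gene sets for screen validation
#'
#' @param positives,negatives disjoint, non-empty character vectors of gene
#'   ids (e.g. predefined essential genes as positives and non-essential
#'   genes as negatives).
#' @return list of class `"gold_standard"`.
#' @export
gold_standard <- function(positives, negatives) {
  positives <- unique(as.character(positives))
  negatives <- unique(as.character(negatives))
  if (length(positives) == 0 || length(negatives) == 0) {
    stop("both classes must be non-empty")
  }
  if (length(intersect(positives, negatives)) > 0) {
    stop("positives and negatives overlap")
  }
  structure(list(positives = positives, negatives = negatives),
            class = "gold_standard")
}

#' Combine beta score and p-value into a single gene score
#'
#' Fits an additive logistic regression of the gold-standard labels on the
#' beta score and `-log10(p)`, and returns the fitted linear predictor for
#' every scored gene. The model is fitted and evaluated on the same genes
#' (no held-out split), so downstream AUCs are optimistic; the permutation
#' test in [auc_permutation_p()] accounts for this by applying the identical
#' procedure to shuffled data.
#'
#' @param results per-gene table from [screen_mle()] (`$results`) or any
#'   data.frame with `gene`, `beta`, `wald_p`.
#' @param gold a [gold_standard()] object used to fit the combiner.
#' @return named numeric vector of scores for all genes with finite
#'   `beta` and `wald_p`.
#' @export
combine_scores <- function(results, gold) {
  if (inherits(results, "screen_fit")) results <- results$results
  keep <- is.finite(results$beta) & is.finite(results$wald_p)
  d <- data.frame(gene = results$gene[keep], beta = results$beta[keep],
                  nlp = -log10(pmax(results$wald_p[keep], 1e-300)))
  lab <- ifelse(d$gene %in% gold$positives, 1L,
                ifelse(d$gene %in% gold$negatives, 0L, NA_integer_))
  train <- !is.na(lab)
  if (sum(lab[train] == 1) == 0 || sum(lab[train] == 0) == 0) {
    stop("gold standard does not intersect both classes of scored genes")
  }
  if (sd(d$beta[train]) == 0 && sd(d$nlp[train]) == 0) {
    stop("both predictors are constant on the labelled genes")
  }
  fit <- suppressWarnings(
    glm(lab[train] ~ beta + nlp, data = d[train, ], family = binomial(),
        control = list(maxit = 50)))
  sc <- suppressWarnings(predict(fit, newdata = d, type = "link"))
  setNames(as.numeric(sc), d$gene)
}

#' ROC area under the curve by the Mann-Whitney statistic
#'
#' AUC is the probability that a random positive outranks a random
#' negative, with ties counted one half (midranks). Invariant under any
#' strictly monotone transform of the scores.
#'
#' @param scores named numeric vector of gene scores (higher = more
#'   positive-like).
#' @param gold a [gold_standard()] object; genes absent from `scores` are
#'   dropped.
#' @return list of class `"auc_result"` with `auc`, `p_perm` (`NA` here; see
#'   [auc_permutation_p()]), `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, gold) {
  pos <- scores[names(scores) %in% gold$positives]
  neg <- scores[names(scores) %in% gold$negatives]
  n_pos <- length(pos); n_neg <- length(neg)
  if (n_pos == 0 || n_neg == 0) stop("empty class after intersecting with scores")
  r <- rank(c(pos, neg))
  auc <- (sum(r[seq_len(n_pos)]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  structure(list(auc = auc, p_perm = NA_real_, n_pos = n_pos, n_neg = n_neg),
            class = "auc_result")
}

#' @export
print.auc_result <- function(x, ...) {
  cat(sprintf("AUC = %.4f (%d positives, %d negatives)",
              x$auc, x$n_pos, x$n_neg))
  if (is.finite(x$p_perm)) cat(sprintf(", permutation p = %.4g", x$p_perm))
  cat("\n")
  invisible(x)
}

#' Permutation p-value for the screen AUC
#'
#' Shuffles the sgRNA-to-gene assignments, refits the beta scores, refits
#' the logistic combiner and recomputes the AUC, `n_perm` times; the
#' p-value is `(1 + #{null AUC >= observed}) / (1 + n_perm)`.
#'
#' @inheritParams permutation_fdr
#' @param gold a [gold_standard()] object.
#' @return an `"auc_result"` with the observed AUC and `p_perm` filled in.
#' @export
auc_permutation_p <- function(counts, library, design, condition, gold,
                              n_perm = 100L, seed = 1L, fit = NULL, ...) {
  stopifnot(n_perm >= 1)
  if (is.null(fit)) fit <- screen_mle(counts, library, design, condition, ...)
  obs <- roc_auc(combine_scores(fit$results, gold), gold)
  withr::local_seed(seed)
  n_ge <- 0L
  for (b in seq_len(n_perm)) {
    perm_lib <- library
    perm_lib$gene_id <- sample(library$gene_id)
    pf <- suppressMessages(
      screen_mle(counts, perm_lib, design, condition, ...))
    a <- roc_auc(combine_scores(pf$results, gold), gold)$auc
    if (a >= obs$auc) n_ge <- n_ge + 1L
  }
  obs$p_perm <- (1 + n_ge) / (1 + n_perm)
  obs$n_perm <- n_perm
  obs
}
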