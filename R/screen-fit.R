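#' Median-of-ratios size factors
#'
#' Per-sample scale factors computed by the median-of-ratios method on the
#' sgRNAs that are nonzero in every sample, then rescaled so the geometric
#' mean of the factors is 1.
#'
#' @param counts integer matrix, sgRNA x sample.
#' @return positive numeric vector, one factor per sample.
#' @export
estimate_size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (any(colSums(counts) == 0)) stop("sample with all-zero counts")
  keep <- rowSums(counts == 0) == 0
  if (!any(keep)) stop("no sgRNA is nonzero in every sample")
  lc <- log(counts[keep, , drop = FALSE])
  ref <- rowMeans(lc)
  sf <- exp(apply(lc - ref, 2, median))
  sf <- sf / exp(mean(log(sf)))
  names(sf) <- colnames(counts)
  sf
}

#' Method-of-moments per-sgRNA dispersions
#'
#' For each sgRNA, estimates the negative-binomial dispersion
#' `alpha = (s^2 - m) / m^2` from size-factor-normalized counts across
#' replicate samples sharing a (condition, timepoint) group, floored at
#' `floor`. Groups with fewer than two samples carry no information; if no
#' group is replicated the function warns and returns the floor everywhere.
#'
#' With few replicates the raw per-sgRNA moment estimate is very noisy, so
#' by default it is shrunk toward the library-wide mean estimate with a
#' weight of `prior_df` pseudo-degrees of freedom against the sgRNA's own
#' replicate degrees of freedom; set `prior_df = 0` for the raw estimates.
#'
#' @param counts integer matrix, sgRNA x sample.
#' @param size_factors per-sample factors from [estimate_size_factors()].
#' @param design optional sample metadata with `sample_id`, `condition`,
#'   `timepoint`; when omitted all samples are treated as one group.
#' @param floor minimum dispersion.
#' @param prior_df strength of shrinkage toward the library-wide mean.
#' @return numeric vector of dispersions, one per sgRNA.
#' @export
estimate_dispersions <- function(counts, size_factors, design = NULL,
                                 floor = 0.01, prior_df = 50) {
  counts <- as.matrix(counts)
  y <- sweep(counts, 2, size_factors, "/")
  groups <- if (is.null(design)) {
    list(seq_len(ncol(counts)))
  } else {
    idx <- if (is.null(colnames(counts))) seq_len(ncol(counts))
           else match(colnames(counts), design$sample_id)
    split(seq_len(ncol(counts)),
          paste(design$condition[idx], design$timepoint[idx]))
  }
  groups <- Filter(function(g) length(g) >= 2, groups)
  if (length(groups) == 0) {
    warning("no replicated (condition, timepoint) group; using the floor ",
            "dispersion everywhere")
    return(rep(floor, nrow(counts)))
  }
  est <- matrix(NA_real_, nrow(counts), length(groups))
  for (j in seq_along(groups)) {
    yg <- y[, groups[[j]], drop = FALSE]
    m <- rowMeans(yg)
    v <- apply(yg, 1, var)
    est[, j] <- ifelse(m > 0, (v - m) / m^2, NA_real_)
  }
  a <- rowMeans(est, na.rm = TRUE)          # raw MOM, may be negative
  df <- sum(lengths(groups) - 1)            # replicate df per sgRNA
  target <- mean(a[is.finite(a)])
  if (!is.finite(target)) target <- floor
  a[!is.finite(a)] <- target
  if (prior_df > 0) {
    a <- (df * a + prior_df * target) / (df + prior_df)
  }
  pmax(a, floor)
}

# Fisher-scoring NB fit for one gene.
# K: m x S counts; sf: length-S size factors; tfin: logical, final sample;
# alpha: length-m dispersions. Model mu[i,s] = sf[s] exp(b[i] + tfin[s] beta).
# Returns beta, se, loglik, converged.
fit_one_gene <- function(K, sf, tfin, alpha, tol = 1e-8, max_iter = 100L) {
  m <- nrow(K)
  A <- matrix(alpha, m, length(sf))
  loglik <- function(mu) {
    sum(ifelse(A > 0,
               dnbinom(K, size = 1 / A, mu = mu, log = TRUE),
               dpois(K, mu, log = TRUE)))
  }
  s0 <- sum(sf[!tfin]); s1 <- sum(sf[tfin])
  b <- log((rowSums(K[, !tfin, drop = FALSE]) + 0.5) / s0)
  beta <- log((sum(K[, tfin, drop = FALSE]) + 0.5) / (m * s1)) -
    log((sum(K[, !tfin, drop = FALSE]) + 0.5) / (m * s0))
  mu <- exp(b) %o% sf * rep(exp(beta * tfin), each = m)
  ll <- loglik(mu)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    den <- 1 + A * mu
    u <- (K - mu) / den                # score in the linear predictor
    w <- mu / den                      # expected information weights
    g_b <- rowSums(u)
    g_beta <- sum(u[, tfin, drop = FALSE])
    d <- rowSums(w)
    cc <- rowSums(w[, tfin, drop = FALSE])
    s <- sum(cc)
    denom <- s - sum(cc^2 / d)
    if (!is.finite(denom) || denom <= 0) break
    dbeta <- (g_beta - sum(cc * g_b / d)) / denom
    db <- (g_b - cc * dbeta) / d
    # step halving with a bounded step keeps the log scale in range
    step <- 1
    cap <- max(abs(c(db, dbeta)))
    if (cap > 10) step <- 10 / cap
    repeat {
      b_new <- b + step * db
      beta_new <- beta + step * dbeta
      mu_new <- exp(b_new) %o% sf * rep(exp(beta_new * tfin), each = m)
      ll_new <- loglik(mu_new)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
      step <- step / 2
      if (step < 1e-8) break
    }
    if (!is.finite(ll_new) || ll_new < ll - 1e-12) break
    delta <- ll_new - ll
    b <- b_new; beta <- beta_new; mu <- mu_new; ll <- ll_new
    if (abs(delta) < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    return(list(beta = NA_real_, se = NA_real_, loglik = ll,
                converged = FALSE))
  }
  # Wald SE from the observed information at the optimum
  den <- 1 + A * mu
  w_o <- mu * (1 + A * K) / den^2
  d_o <- rowSums(w_o)
  c_o <- rowSums(w_o[, tfin, drop = FALSE])
  s_o <- sum(c_o)
  vb <- s_o - sum(c_o^2 / d_o)
  se <- if (is.finite(vb) && vb > 0) sqrt(1 / vb) else NA_real_
  list(beta = beta, se = se, loglik = ll, converged = TRUE)
}

# Replace the non-targeting sentinel by pseudo-gene labels of fixed size so
# the controls are fitted identically to real genes (empirical null).
group_nontargeting <- function(library, pseudo_size = 5L) {
  gene <- library$gene_id
  nt <- which(gene == NON_TARGETING)
  if (length(nt) > 0) {
    grp <- ceiling(seq_along(nt) / pseudo_size)
    gene[nt] <- sprintf("NT_PSEUDO%04d", grp)
  }
  gene
}

#' Fit per-gene beta scores by negative-binomial maximum likelihood
#'
#' For one selection arm, fits per gene `g` the model
#' `count[i, s] ~ NB(mean = S_s exp(b_i + t_s beta_g), alpha_i)`, where
#' `S_s` is the sample size factor, `b_i` the baseline abundance of sgRNA
#' `i`, and `t_s = 1` for final-population samples, maximising jointly over
#' the `b_i` and `beta_g` by Fisher scoring. `beta_g` is the beta score: a
#' positive value means the gene's guides are enriched in the final
#' population (positive selection). The Wald standard error comes from the
#' observed information and the p-value from a two-sided normal test.
#' Non-targeting guides are grouped into pseudo-genes of `pseudo_size`
#' guides and fitted identically, providing a calibration null.
#'
#' @param counts integer matrix, sgRNA x sample; rownames are sgRNA ids.
#' @param library sgRNA-to-gene table ([make_library()] layout).
#' @param design sample metadata (`sample_id`, `condition`, `timepoint`,
#'   `replicate`).
#' @param condition `"rss"` or `"iss"`; the arm to fit (each arm is fitted
#'   against its own initial population).
#' @param size_factors,dispersions optional; computed from the selected
#'   samples when omitted.
#' @param pseudo_size guides per non-targeting pseudo-gene.
#' @param tol,max_iter Fisher-scoring convergence control (absolute
#'   log-likelihood change and iteration cap).
#' @return an object of class `"screen_fit"`; `$results` is the per-gene
#'   table (`gene`, `condition`, `beta`, `se`, `wald_p`, `fdr`,
#'   `n_sgrnas`, `is_control`, `converged`), with `fdr` `NA` until
#'   [permutation_fdr()] is run.
#' @seealso [permutation_fdr()], [roc_auc()]
#' @export
screen_mle <- function(counts, library, design, condition,
                       size_factors = NULL, dispersions = NULL,
                       pseudo_size = 5L, tol = 1e-8, max_iter = 100L) {
  counts <- as.matrix(counts)
  stopifnot(condition %in% design$condition)
  sel <- design[design$condition == condition, , drop = FALSE]
  if (!all(c("initial", "final") %in% sel$timepoint)) {
    stop("need at least one initial and one final sample for condition '",
         condition, "'")
  }
  cols <- match(sel$sample_id, colnames(counts))
  if (anyNA(cols)) stop("design sample_id absent from counts columns")
  K_all <- counts[library$sgrna_id, cols, drop = FALSE]
  if (is.null(size_factors)) size_factors <- estimate_size_factors(K_all)
  if (is.null(dispersions)) {
    dispersions <- estimate_dispersions(K_all, size_factors, design = sel)
  }
  tfin <- sel$timepoint == "final"
  gene <- group_nontargeting(library, pseudo_size)
  groups <- split(seq_len(nrow(library)), gene)

  res <- lapply(names(groups), function(g) {
    idx <- groups[[g]]
    K <- K_all[idx, , drop = FALSE]
    keep <- rowSums(K) > 0
    if (!any(keep)) {
      return(data.frame(gene = g, beta = NA_real_, se = NA_real_,
                        wald_p = NA_real_, n_sgrnas = 0L, converged = FALSE))
    }
    f <- fit_one_gene(K[keep, , drop = FALSE], size_factors, tfin,
                      dispersions[idx][keep], tol = tol, max_iter = max_iter)
    p <- if (is.finite(f$beta) && is.finite(f$se) && f$se > 0) {
      2 * pnorm(-abs(f$beta / f$se))
    } else NA_real_
    data.frame(gene = g, beta = f$beta, se = f$se, wald_p = p,
               n_sgrnas = sum(keep), converged = f$converged)
  })
  res <- do.call(rbind, res)
  res$condition <- condition
  res$fdr <- NA_real_
  res$is_control <- startsWith(res$gene, "NT_PSEUDO")
  res <- res[, c("gene", "condition", "beta", "se", "wald_p", "fdr",
                 "n_sgrnas", "is_control", "converged")]
  rownames(res) <- NULL
  if (any(!res$converged)) {
    message(sum(!res$converged), " gene(s) did not converge; beta set to NA")
  }
  structure(list(results = res, condition = condition,
                 size_factors = size_factors, pseudo_size = pseudo_size,
                 call = match.call()),
            class = "screen_fit")
}

#' @export
print.screen_fit <- function(x, ...) {
  r <- x$results
  cat("Negative-binomial screen fit, condition:", x$condition, "\n")
  cat("  ", sum(!r$is_control), "genes +", sum(r$is_control),
      "non-targeting pseudo-genes;",
      sum(!r$converged), "non-converged\n")
  cat("  beta range:",
      paste(signif(range(r$beta, na.rm = TRUE), 3), collapse = " .. "), "\n")
  invisible(x)
}

#' @export
coef.screen_fit <- function(object, ...) {
  setNames(object$results$beta, object$results$gene)
}

#' @export
summary.screen_fit <- function(object, p_threshold = 0.05, ...) {
  r <- object$results[!object$results$is_control, ]
  out <- list(condition = object$condition,
              n_genes = nrow(r),
              n_significant = sum(r$wald_p < p_threshold, na.rm = TRUE),
              top = head(r[order(r$wald_p), ], 10))
  class(out) <- "summary.screen_fit"
  out
}

#' @export
print.summary.screen_fit <- function(x, ...) {
  cat("Screen fit (", x$condition, "): ", x$n_genes, " genes, ",
      x$n_significant, " with Wald p < 0.05\nTop genes:\n", sep = "")
  print(x$top, row.names = FALSE)
  invisible(x)
}

#' Permutation-based gene-level false discovery rate
#'
#' Re-runs the full beta-score fit `n_perm` times with the sgRNA-to-gene
#' assignments randomly shuffled (gene sizes preserved), pools the null Wald
#' p-values across permutations, and converts them to an empirical FDR:
#' `FDR(g) = [(1 + #null p <= p_g) / (1 + n_null)] / [#obs p <= p_g / n_obs]`,
#' capped at 1 and made monotone non-decreasing in `p` by a step-up pass.
#' Null p-value counts are accumulated per permutation, so memory use does
#' not grow with `n_perm`.
#'
#' @inheritParams screen_mle
#' @param n_perm number of permutations (the screen convention is 100).
#' @param seed integer seed for the shuffles.
#' @param fit optional pre-computed observed [screen_mle()] fit (must match
#'   the other arguments); avoids refitting the observed data.
#' @return the observed `screen_fit` with `$results$fdr` filled in.
#' @export
permutation_fdr <- function(counts, library, design, condition,
                            n_perm = 100L, seed = 1L, fit = NULL, ...) {
  stopifnot(n_perm >= 1)
  if (is.null(fit)) {
    fit <- screen_mle(counts, library, design, condition, ...)
  }
  obs <- fit$results
  p_obs <- obs$wald_p
  ok <- which(is.finite(p_obs))
  ord <- ok[order(p_obs[ok])]
  p_sorted <- p_obs[ord]
  n_obs <- length(ord)

  withr::local_seed(seed)
  n_le <- numeric(n_obs)
  n_null <- 0
  for (b in seq_len(n_perm)) {
    perm_lib <- library
    perm_lib$gene_id <- sample(library$gene_id)
    pf <- suppressMessages(
      screen_mle(counts, perm_lib, design, condition,
                 pseudo_size = fit$pseudo_size, ...))
    p_null <- pf$results$wald_p
    p_null <- sort(p_null[is.finite(p_null)])
    n_le <- n_le + findInterval(p_sorted, p_null)
    n_null <- n_null + length(p_null)
  }
  frac_null <- (1 + n_le) / (1 + n_null)
  frac_obs <- seq_len(n_obs) / n_obs
  fdr <- pmin(1, frac_null / frac_obs)
  fdr <- rev(cummin(rev(fdr)))   # monotone non-decreasing in p
  out <- rep(NA_real_, nrow(obs))
  out[ord] <- fdr
  fit$results$fdr <- out
  fit$n_perm <- n_perm
  fit
}
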