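#' Quality-control GWAS summary statistics
#'
#' Joins the summary statistics to the SNP map, drops SNPs below the
#' minor-allele-frequency floor (`maf >= maf_min` retained), and gates the
#' dataset on the observed-scale heritability Z-score from a base-only
#' (single-annotation) LD-score regression: datasets with `h2 / se(h2)`
#' below `h2_z_min` fail.
#'
#' @param sumstats data.frame with `SNP`, `Z`, `N`.
#' @param snp_map SNP map with `snp_id`, `maf`, `block_id`, `position`.
#' @param ld_scores SNP x C matrix from [compute_ld_scores()] (only the
#'   base column is used for the gate), aligned to `snp_map`.
#' @param maf_min MAF floor (default 0.05, the common-variant convention).
#' @param h2_z_min heritability Z-score gate (default 6).
#' @param n_blocks jackknife blocks for the gate regression.
#' @return list with `sumstats` (filtered, joined to `maf`), `keep`
#'   (logical over input rows), `h2`, `h2_se`, `h2_z`, `pass`.
#' @export
qc_sumstats <- function(sumstats, snp_map, ld_scores, maf_min = 0.05,
                        h2_z_min = 6, n_blocks = 20) {
  idx <- match(sumstats$SNP, snp_map$snp_id)
  if (all(is.na(idx))) stop("no SNP in the summary statistics joins the SNP map")
  keep <- !is.na(idx) & snp_map$maf[idx] >= maf_min
  ss <- sumstats[keep, , drop = FALSE]
  ss$maf <- snp_map$maf[idx[keep]]
  sm <- snp_map[idx[keep], , drop = FALSE]
  ls <- ld_scores[idx[keep], 1, drop = FALSE]
  base <- matrix(1L, nrow(ss), 1, dimnames = list(NULL, "base"))
  fit <- sldsc(ss, ls, base, snp_map = sm, n_blocks = n_blocks)
  h2_z <- fit$h2_total / fit$h2_se
  list(sumstats = ss, keep = keep, h2 = fit$h2_total, h2_se = fit$h2_se,
       h2_z = h2_z, pass = is.finite(h2_z) && h2_z >= h2_z_min)
}

#' Stratified LD score regression
#'
#' Fits `E[chi2_j] = N_j sum_c tau_c l(j, c) + intercept` by weighted least
#' squares with a free intercept, partitioning SNP heritability across
#' (possibly overlapping) annotations. The heritability of annotation `a`
#' is `h2_a = sum_{k in a} sum_c tau_c A_kc` and its enrichment is
#' `(h2_a / h2) / (|a| / p)` with `|a|` the number of SNPs in `a` and `p`
#' the total SNP count; the base annotation has enrichment 1 by
#' construction. Standard errors for every derived quantity — tau, total
#' and per-annotation heritability, enrichment, and the inside-vs-outside
#' per-SNP heritability difference `d_a = h2_a/|a| - (h2 - h2_a)/(p - |a|)`
#' — come from a delete-one-block jackknife over contiguous SNP blocks.
#'
#' Weights: with `two_pass_weights = TRUE` (default) a first unweighted
#' pass gives a provisional total heritability, and the second pass uses
#' `w_j = 1 / [max(l_base_j, 1) (1 + N h2 l_base_j / p)^2]`, combining the
#' over-counting and heteroskedasticity corrections. Chi-square values are
#' capped at `max(80, 0.001 N)` unless `chisq_cap = FALSE`.
#'
#' @param sumstats data.frame with `Z` and `N` (and `SNP`, checked against
#'   the LD-score rownames when both are present).
#' @param ld_scores SNP x C matrix of stratified LD scores.
#' @param annotations binary SNP x C matrix; first column must be the
#'   all-ones base.
#' @param snp_map optional; unused in the fit but kept for interface
#'   symmetry.
#' @param n_blocks number of jackknife blocks (>= 2).
#' @param two_pass_weights use the two-pass weighting scheme.
#' @param chisq_cap cap large chi-square outliers.
#' @return object of class `"sldsc"`: `tau`, `tau_se`, `intercept`,
#'   `h2_total`, `h2_se`, `h2_annot`, `M` (SNPs per annotation),
#'   `enrichment`, `enrichment_se`, `d`, `d_se`, `p_one_sided` (upper-tail
#'   test of `d > 0`), `n_snps`, `n_blocks`, and the per-block jackknife
#'   estimates in `jackknife`.
#' @export
sldsc <- function(sumstats, ld_scores, annotations, snp_map = NULL,
                  n_blocks = 20, two_pass_weights = TRUE, chisq_cap = TRUE) {
  A <- as.matrix(annotations)
  L <- as.matrix(ld_scores)
  m <- nrow(A)
  stopifnot(nrow(L) == m, ncol(L) == ncol(A), nrow(sumstats) == m,
            n_blocks >= 2, m >= n_blocks)
  if (any(A[, 1] != 1)) stop("first annotation column must be the all-ones base")
  if (!is.null(sumstats$SNP) && !is.null(rownames(L)) &&
      !identical(as.character(sumstats$SNP), rownames(L))) {
    stop("sumstats SNP order does not match the LD-score rows")
  }
  cn <- colnames(A) %||% paste0("annot", seq_len(ncol(A)))
  chi2 <- sumstats$Z^2
  N <- rep_len(sumstats$N, m)
  if (chisq_cap) chi2 <- pmin(chi2, max(80, 0.001 * median(N)))

  X <- cbind(intercept = 1, L * N)
  k <- ncol(X)
  wls <- function(w) {
    sw <- sqrt(w)
    qr_ <- qr(X * sw)
    if (qr_$rank < k) {
      bad <- setdiff(seq_len(k), qr_$pivot[seq_len(qr_$rank)])
      stop("singular design; collinear column(s): ",
           paste(c("intercept", cn)[bad], collapse = ", "))
    }
    qr.coef(qr_, chi2 * sw)
  }
  w <- rep(1, m)
  if (two_pass_weights) {
    th1 <- wls(w)
    h2_1 <- sum(A %*% th1[-1])
    lb <- L[, 1]
    w <- 1 / (pmax(lb, 1) * (1 + N * max(h2_1, 0) * lb / m)^2)
  }

  # block-wise crossproducts for the fit and the delete-one-block jackknife
  blk <- as.integer(cut(seq_len(m), n_blocks, labels = FALSE))
  Sxx <- array(0, c(k, k, n_blocks))
  Sxy <- matrix(0, k, n_blocks)
  for (b in seq_len(n_blocks)) {
    i <- which(blk == b)
    Xb <- X[i, , drop = FALSE] * sqrt(w[i])
    Sxx[, , b] <- crossprod(Xb)
    Sxy[, b] <- crossprod(Xb, chi2[i] * sqrt(w[i]))
  }
  Txx <- apply(Sxx, c(1, 2), sum)
  Txy <- rowSums(Sxy)
  solve_or_fail <- function(xx, xy) {
    out <- tryCatch(solve(xx, xy), error = function(e) NULL)
    if (is.null(out)) {
      d <- diag(xx)
      stop("singular design; collinear column(s): ",
           paste(c("intercept", cn)[d <= max(d) * 1e-12], collapse = ", "))
    }
    out
  }
  theta <- solve_or_fail(Txx, Txy)

  M <- colSums(A)
  derive <- function(th) {
    tau <- th[-1]
    per_snp <- as.numeric(A %*% tau)
    h2 <- sum(per_snp)
    h2a <- colSums(A * per_snp)
    enr <- (h2a / h2) / (M / m)
    d <- ifelse(M > 0 & M < m, h2a / M - (h2 - h2a) / (m - M), NA_real_)
    c(tau, th[1], h2, h2a, enr, d)
  }
  pt <- derive(theta)
  jk <- matrix(NA_real_, n_blocks, length(pt))
  for (b in seq_len(n_blocks)) {
    th_b <- solve_or_fail(Txx - Sxx[, , b], Txy - Sxy[, b])
    jk[b, ] <- derive(th_b)
  }
  jse <- sqrt((n_blocks - 1) / n_blocks *
                colSums(sweep(jk, 2, colMeans(jk))^2))
  C <- ncol(A)
  ix <- list(tau = 1:C, intercept = C + 1, h2 = C + 2,
             h2a = C + 2 + 1:C, enr = 2 * C + 2 + 1:C, d = 3 * C + 2 + 1:C)
  d <- setNames(pt[ix$d], cn)
  d_se <- setNames(jse[ix$d], cn)
  p1 <- ifelse(is.finite(d) & d_se > 0, pnorm(d / d_se, lower.tail = FALSE),
               NA_real_)
  structure(list(
    tau = setNames(pt[ix$tau], cn), tau_se = setNames(jse[ix$tau], cn),
    intercept = unname(pt[ix$intercept]),
    intercept_se = unname(jse[ix$intercept]),
    h2_total = unname(pt[ix$h2]), h2_se = unname(jse[ix$h2]),
    h2_annot = setNames(pt[ix$h2a], cn),
    h2_annot_se = setNames(jse[ix$h2a], cn),
    M = setNames(M, cn),
    enrichment = setNames(pt[ix$enr], cn),
    enrichment_se = setNames(jse[ix$enr], cn),
    d = d, d_se = d_se, p_one_sided = setNames(p1, cn),
    n_snps = m, n_blocks = n_blocks, jackknife = jk,
    weights = w, call = match.call()),
    class = "sldsc")
}

#' @export
print.sldsc <- function(x, ...) {
  cat("Stratified LD score regression:", x$n_snps, "SNPs,",
      length(x$tau), "annotations,", x$n_blocks, "jackknife blocks\n")
  cat(sprintf("  h2 = %.4g (se %.3g), intercept = %.3f\n",
              x$h2_total, x$h2_se, x$intercept))
  tab <- data.frame(M = x$M, enrichment = x$enrichment,
                    se = x$enrichment_se, p_one_sided = x$p_one_sided)
  print(format(tab, digits = 3))
  invisible(x)
}

#' @export
coef.sldsc <- function(object, ...) object$tau

#' @export
summary.sldsc <- function(object, ...) {
  data.frame(annotation = names(object$tau), tau = object$tau,
             tau_se = object$tau_se, M = object$M,
             h2_annot = object$h2_annot, enrichment = object$enrichment,
             enrichment_se = object$enrichment_se, d = object$d,
             d_se = object$d_se, p_one_sided = object$p_one_sided,
             row.names = NULL)
}

#' Inside-vs-outside per-SNP heritability difference
#'
#' Extracts, for one annotation, the statistic
#' `d = h2_a / |a| - (h2 - h2_a) / (p - |a|)` — the mean per-SNP
#' heritability inside the annotation minus that outside — and its
#' block-jackknife standard error. This is the quantity pooled across
#' traits before the one-sided enrichment Z-test.
#'
#' @param fit an [sldsc()] object.
#' @param annotation annotation name.
#' @return named numeric vector `c(d =, se =)`.
#' @export
per_snp_difference <- function(fit, annotation) {
  stopifnot(inherits(fit, "sldsc"))
  if (!annotation %in% names(fit$d)) stop("unknown annotation: ", annotation)
  M <- fit$M[[annotation]]
  if (M == 0 || M == fit$n_snps) {
    stop("per-SNP difference undefined for an empty or all-SNP annotation")
  }
  c(d = unname(fit$d[[annotation]]), se = unname(fit$d_se[[annotation]]))
}
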