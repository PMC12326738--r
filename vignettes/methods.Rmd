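---
title: "Methods: from screen counts to heritability enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from screen counts to heritability enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(senescreen)
```

This vignette documents the statistical models implemented in
**senescreen**, the assumptions behind them, what the synthetic-data
generators do and do not emulate, and the numerical choices made in the
implementation. The package covers the analysis chain of a two-arm
senescence CRISPRi screen — a replicative senescence screen (RSS) and an
inflammatory senescence screen (ISS) — feeding gene-set SNP-heritability
enrichment estimated by stratified LD score regression (S-LDSC) and pooled
across traits by random-effects meta-analysis.

## 1. Screen count model and beta scores

For one selection arm, counts for sgRNA $i$ of gene $g$ in sample $s$ are
modelled as negative binomial,

$$k_{is} \sim \mathrm{NB}\!\left(\mu_{is} = S_s\,e^{\,b_i + t_s \beta_g},\;
\alpha_i\right),$$

where $S_s$ is a per-sample size factor, $b_i$ a free per-sgRNA baseline,
$t_s \in \{0,1\}$ indicates a final-population sample, $\beta_g$ is the
gene's *beta score*, and $\alpha_i$ the sgRNA's dispersion
($\mathrm{Var} = \mu + \alpha\mu^2$). A positive $\beta_g$ means the
gene's guides are enriched in the final population. `screen_mle()`
maximises the likelihood jointly over $(b_1,\dots,b_m,\beta_g)$ per gene
by Fisher scoring. The per-iteration update exploits the arrow structure
of the information matrix (each $b_i$ interacts only with $\beta_g$), so
a gene costs $O(m S)$ per iteration. Standard errors use the *observed*
information at the optimum; p-values are two-sided Wald tests.

Numerical choices:

* steps are capped at 10 on the log scale and halved until the
  log-likelihood does not decrease, so early iterations cannot overshoot;
* convergence is declared when the log-likelihood changes by less than
  `tol = 1e-8`; non-converged genes are reported with `beta = NA` rather
  than a half-converged number;
* at $\alpha = 0$ the model degenerates to Poisson and the fit matches a
  Poisson GLM (this limit is used as an independent oracle in the tests).

**Size factors** are DESeq-style median-of-ratios: the per-sample median
of log-ratios to the per-sgRNA geometric mean, computed over sgRNAs
nonzero in every sample, then rescaled to geometric mean 1.

**Dispersions** are per-sgRNA method-of-moments estimates
$\hat\alpha = (s^2 - \bar m)/\bar m^2$ from size-factor-normalised counts
across replicates sharing a (condition, timepoint) group. With only two
replicates the raw estimate is extremely noisy — noisy enough to make the
null Wald p-values anti-conservative — so by default it is shrunk toward
the library-wide mean with `prior_df = 50` pseudo-degrees of freedom
against each sgRNA's own replicate degrees of freedom, floored at 0.01.
`prior_df = 0` recovers the raw moment estimator.

**Non-targeting controls** are grouped into pseudo-genes of
`pseudo_size = 5` guides and fitted identically to real genes, giving an
empirical null that experiences the same estimation pipeline.

## 2. Permutation false discovery rate

`permutation_fdr()` shuffles the sgRNA-to-gene assignment (gene sizes
preserved), refits every gene, and pools the null Wald p-values over
`n_perm` permutations. The gene-level FDR is

$$\widehat{\mathrm{FDR}}(g) =
\frac{(1 + \#\{p_\text{null} \le p_g\})/(1 + n_\text{null})}
     {\#\{p_\text{obs} \le p_g\}/n_\text{obs}},$$

capped at 1 and made monotone non-decreasing in $p$ by a step-up pass.
The add-one numerator keeps the estimate strictly positive and gives a
floor of roughly $1/n_\text{perm}$ for the top gene. Null counts are
accumulated per permutation with `findInterval()`, so memory does not
grow with `n_perm`.

## 3. Screen validation

`roc_auc()` computes the AUC as the Mann–Whitney midrank statistic
(ties count 1/2), `combine_scores()` fits a logistic combiner of the beta
score and $-\log_{10} p$ against a gold standard, and
`auc_permutation_p()` attaches an add-one permutation p-value
$(1 + \#\{\mathrm{AUC}_\text{null} \ge \mathrm{AUC}\})/(1 + n_\text{perm})$.

## 4. Gene classification

`select_signature_genes()` keeps genes significant in *either* arm, and
`kmeans_classify()` runs `stats::kmeans` (Lloyd, 50 restarts,
`iter.max = 200`) on the unscaled $(\beta_\mathrm{RSS},
\beta_\mathrm{ISS})$ plane with $k = 4$. Centroids are labelled by a
threshold at half the largest absolute centroid component: ISS-large with
RSS-small is *inflammaging*; both large and concordant is *common
aging*; anything else is *unassigned*. The coordinates are left unscaled
deliberately — both axes are beta scores in the same units, and scaling
would inflate whichever arm has less signal.

## 5. Annotations, LD scores and S-LDSC

`build_annotation()` marks SNPs within an inclusive 100 kb window of any
transcript of a gene set (via GenomicRanges overlaps);
`annotation_matrix()` prepends the all-ones `base` column. LD scores
$\ell(j,c) = \sum_{k \in c} r^2_{jk}$ are computed over a 1 Mb window
from either an analytic block-AR(1) model, a genotype reference panel
(with the finite-panel bias adjustment
$\tilde r^2 = r^2 - (1 - r^2)/(n_\mathrm{ref} - 2)$), or an explicit
correlation matrix.

`sldsc()` regresses GWAS $\chi^2_j$ on $N\,\ell(j,c)$ with a free
intercept:

$$E[\chi^2_j] = N \sum_c \tau_c\, \ell(j,c) + b.$$

Numerical choices, matching standard S-LDSC practice:

* two-pass weights $w_j = 1/[\max(\ell_\mathrm{base}, 1)\,
  (1 + N \hat h^2 \ell_\mathrm{base}/p)^2]$, with $\hat h^2$ from an
  unweighted first pass — down-weighting both LD-induced correlation and
  heteroscedasticity;
* $\chi^2$ capped at $\max(80,\, 0.001\,N)$;
* delete-one-block jackknife over contiguous SNP blocks for every derived
  quantity, $\mathrm{SE}^2 = \frac{B-1}{B}\sum_b (\theta_b -
  \bar\theta)^2$, computed from per-block crossproduct accumulators so no
  block is ever refitted from scratch;
* collinear annotation columns are rejected with an error naming the
  column rather than silently dropped.

Derived quantities per annotation $a$: $h^2_a = \sum_{j} A_{ja}
\sum_c \tau_c A_{jc}$, enrichment $(h^2_a/h^2)/(|a|/p)$, and the per-SNP
inside-vs-outside difference

$$d_a = \frac{h^2_a}{|a|} - \frac{h^2 - h^2_a}{p - |a|}
      = \frac{h^2(\mathrm{enr}_a - 1)}{p - |a|},$$

tested one-sided against $d_a > 0$. The base annotation covers the whole
panel, so its enrichment is identically 1 with SE identically 0; $d$ is
undefined for a whole-panel annotation (the outside set is empty) and
`per_snp_difference()` errors rather than returning 0/0. The difference
$d$ is the quantity pooled downstream: unlike the enrichment ratio it
does not divide by $\hat h^2$, which is weakly identified against the
free intercept when LD scores have little variance (e.g. stationary
AR(1) LD).

`qc_sumstats()` applies the standard gates before regression: MAF
$\ge$ 0.05 (inclusive) and total-heritability $Z \ge 6$ from a base-only
fit. At the reduced SNP counts used in this package's simulations the
jackknife SE of $h^2$ is large, so simulated traits are gated with a
lower threshold where the gate's mechanics are being exercised.

## 6. Meta-analysis and trait clustering

`meta_random()` implements DerSimonian–Laird:
$\hat\tau^2 = \max\!\big(0, (Q - (n-1))/(\sum w - \sum w^2/\sum w)\big)$
with inverse-variance weights, then inverse-variance pooling with
$w^*_i = 1/(s_i^2 + \hat\tau^2)$. Tests are one-sided upper-tail Z
tests. `compare_gene_sets()` compares two pooled estimates assuming
independence; `compare_gene_sets_paired()` pools per-trait differences.
`select_and_cluster_traits()` keeps traits significant for at least one
gene set, clusters them by complete-linkage hierarchical clustering on
the enrichment profiles, and labels each trait by its argmax set.
`cluster_group_association()` tests cluster membership against a binary
trait grouping with Fisher's exact test (a degenerate margin returns
p = 1 with a warning rather than an error).

## 7. What the generators emulate — and what they do not

`make_library()` / `simulate_screen()` emulate a pooled CRISPRi screen:
lognormal baseline abundances, per-condition selection acting
multiplicatively ($\propto e^{\beta}$) between initial and final
populations, per-sgRNA lognormal efficacy noise (sd 0.2) on genes with a
true effect, and NB sampling at a fixed expected depth per sample
(`dispersion = 0.05` by default). Deliberate simplifications:

* the library is rectangular (equal guides per gene), unlike real
  libraries with variable coverage and missing guides;
* efficacy noise is applied only where $\beta \ne 0$, keeping null genes
  exactly on-model so calibration tests measure the estimator, not the
  generator;
* per-sample totals are calibrated in expectation only — the lognormal
  baselines give the realised totals a heavy-tailed spread of a few
  percent;
* no guide-level off-target structure, no cell-cycle or bottleneck
  effects, no PCR jackpotting beyond the NB dispersion.

`simulate_genome()` / `ar1_ld()` / `simulate_gwas()` emulate a single
chromosome with non-overlapping genes, uniform MAF in [0.05, 0.5],
contiguous LD blocks with AR(1) correlation, causal effects
$\beta_k \sim N(0, \sum_c \tau_c A_{kc})$, and block-wise
$z \mid \beta \sim \mathrm{MVN}(\sqrt{N} R \beta, R)$. Not emulated:
MAF-dependent LD and architecture, multiple chromosomes, imputation
error, sample overlap between traits, and population stratification
(so the true regression intercept is 1, though it is always fitted
free).

## 8. Problem sizes

The simulation scales used in the tests and in `scripts/acceptance.R` —
a 1,000-gene screen at depth 500 per sgRNA, 20,000-SNP panels for
enrichment recovery over 20 seeds, 200 replicates of a 2,000-SNP null,
and a 20-trait end-to-end run — are this package's own choices: large
enough that estimator behaviour (calibration, recovery bands, SE
scaling) is measurable, small enough that the whole suite runs in a few
minutes on one CPU. They are *not* the scales of a real study, which
involves ~10^5 sgRNAs, millions of SNPs and hundreds of GWAS traits.

## 9. Limitations

* The NB fit treats dispersions as known after plug-in estimation; no
  uncertainty is propagated from $\hat\alpha$ into the Wald SE (the
  shrinkage of section 1 is what keeps this approximation calibrated at
  two replicates).
* The permutation FDR assumes exchangeability of sgRNAs across genes
  under the null; guide-intrinsic effects (e.g. toxicity) would violate
  this.
* S-LDSC estimates are asymptotic in the number of jackknife blocks;
  with few blocks the SEs are themselves noisy. The total-$h^2$
  denominator of the enrichment ratio is weakly identified when base LD
  scores are nearly constant — the per-SNP difference $d$ is preferred
  for inference throughout.
* The DL estimator is known to under-estimate $\tau^2$ with few
  studies; pooled SEs with ~10 traits should be read accordingly.
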