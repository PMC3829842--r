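---
title: "Benchmarking gene set analysis: models, statistics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking gene set analysis: models, statistics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gsabench)
```

# The problem

A two-group transcriptomics experiment yields one differential-expression
statistic per gene; gene set analysis aggregates those signals over
predefined groups of functionally related genes. Methods differ in two
fundamental ways. The **null hypothesis**: *competitive* methods ask
whether the set's genes are more associated with the phenotype than the
remaining genes on the array (genes are the sampling unit, so they work
with a single sample per group but are sensitive to inter-gene
correlation), while *self-contained* methods ask whether the set's genes
are associated with the phenotype at all (subjects are the sampling unit,
so they need replicates but inherit the experiment's true sampling
variability). The **aggregation strategy**: a direct set statistic over
gene scores, or a per-sample pathway activity score tested downstream.

`gsabench` implements sixteen such statistics behind one interface and a
framework for comparing them on three axes: **sensitivity** (does a
relevant set get a small p-value?), **prioritization** (does it rank near
the top of the output?), and **specificity** (how often are sets called
significant when the phenotype carries no signal?).

# Gene-level model

All fold-change-based statistics build on a moderated t. For gene $g$ with
pooled residual variance $s_g^2$ on $d$ degrees of freedom, the posterior
variance is

$$ s_{g,\mathrm{post}}^2 = \frac{d_0 s_0^2 + d\, s_g^2}{d_0 + d}, $$

with $(s_0^2, d_0)$ estimated by moment-matching the scaled-F marginal of
the $s_g^2$ (via `limma::squeezeVar`, the canonical implementation of that
estimator). The statistic $t_g = \hat\beta_g / \sqrt{s_{g,\mathrm{post}}^2 c}$
is referred to a t distribution on $\min(d_0 + d,\ G\,d)$ degrees of
freedom — the cap at the pooled total keeps the reference distribution a t
when the prior degrees of freedom are estimated as infinite. Paired
designs are analyzed as a one-sample moderated t on within-block
case-minus-control differences, an equivalent formulation of the blocked
two-group model. Gene-level p-values are two-sided throughout; direction
is retained in the log2 fold change and the sign of $t$.

`gene_stats(ds, prior = list(d0 = 0))` and `prior = list(d0 = Inf, s02 =)`
expose the shrinkage limits (ordinary and pooled-variance t), which the
test suite verifies to $10^{-8}$.

# The sixteen statistics

Sampling type `gene` marks competitive methods (ORA, MRGSE,
SIGPATHWAY-Q1, GAGE, GSEAP); the rest resample subjects or use
distributional nulls.

* **ORA** — one-tailed hypergeometric test on a DE list selected by a
  three-stage cascade: all genes at BH-FDR < 0.1 if more than 200; else
  all genes with p < 0.05 and |log2 FC| > log2 1.5 if more than 200; else
  the top 1% by p. The fold-change cut is interpreted on the ratio scale;
  the cascade makes ORA usable even in underpowered studies.
* **MRGSE** — Wilcoxon rank-sum on the p-value ranks of set genes versus
  the background, one-sided toward more-significant ranks; exact
  enumeration when the universe holds at most 20 genes, otherwise a
  tie-corrected normal approximation with continuity correction.
* **SAFE** — Wilcoxon rank sum of |t| ranks, set versus complement, with
  a sample-permutation null.
* **SIGPATHWAY Q1/Q2** — standardized mean of the set genes' moderated t;
  Q1 draws its null from random equal-size gene sets, Q2 from label
  permutations. Both are reported two-sided on the standardized statistic
  (disease sets may be regulated in either direction), which is why a set
  whose scores merely match the background distribution is reported as
  non-significant rather than p ≈ 0.5.
* **GSA** — the *maxmean* statistic $\max(s^+, s^-)$ (sign retained),
  restandardized by the mean and SD of maxmean over random size-matched
  gene sets, with a two-sided sample-permutation p. The restandardization
  ensemble (default 100 sets per size) is drawn once per run and reused
  across permutation columns; it calibrates the scale of the statistic
  and need not vary with the relabeling.
* **PADOG** — mean of $|t_g| w_g$ over the set with
  $w_g = 1 + \sqrt{(f_{\max} - f_g)/(f_{\max} - f_{\min})}$, where $f_g$
  counts the analyzed sets containing gene $g$: ubiquitous genes carry
  less set-specific evidence. Scores are standardized across sets within
  each permutation.
* **GAGE** — per case sample, per-gene fold changes against the
  control-group mean; a Welch t compares set against background fold
  changes, and the per-case p-values are combined assuming independence.
  The default combination is Stouffer on signed z-scores, which preserves
  direction; Fisher is available (`combine = "fisher"`). The independence
  assumption is exactly what inflates GAGE's false positives under
  correlation, and the benchmark reproduces that behavior.
* **CAMERA** — standardized mean difference of moderated t between set
  and background, variance-inflated by $1 + (m-1)\bar\rho$ with
  $\bar\rho$ the mean inter-gene correlation of the set genes' residuals
  (group means removed); two-sided normal p. Implemented in the
  parametric VIF form without small-sample residual-df corrections.
* **GLOBALTEST** — score statistic
  $Q = (y-\bar y)^\top X^\top X (y-\bar y)/m$ on the row-standardized set
  submatrix. Because the kernel $X^\top X$ is doubly centered, $Q$ equals
  the sum of the kernel submatrix over the case samples, whose exact mean
  and variance over all case/control relabelings have closed forms; the
  default p is a Satterthwaite scaled chi-square matched to those exact
  permutation moments. A Gaussian-theory variance is badly conservative
  here — binary labels have strongly negative excess kurtosis — which is
  why the exact subset moments are used. The suite verifies agreement
  with a 10,000-permutation p within 0.02, and
  `p_method = "permutation"` remains available as the assumption-free
  fallback.
* **GSEA / GSEAP** — weighted Kolmogorov–Smirnov enrichment score:
  walking the t-ranked gene list, hits add $|t|^{w}/\sum_{set}|t|^{w}$
  (default $w = 1$; $w = 0$ recovers the classic KS statistic), misses
  subtract $1/(G-m)$; ES is the signed maximum deviation. GSEA permutes
  sample labels; GSEAP (pre-ranked, the variant that accommodates paired
  designs) samples random gene sets. The p-value is the sign-matched tail
  proportion, the convention of the original implementation.
* **PLAGE** — first right singular vector (scaled by its singular value)
  of the row-standardized set submatrix: the projection of samples on the
  set's first principal axis. The SVD sign is fixed against the set's
  mean profile. The suite asserts equality with an independent
  eigendecomposition to $10^{-8}$.
* **Z-score** — $\sum_g z_{gs}/\sqrt{m}$ over standardized expression.
* **ssGSEA** — per sample, the integrated difference between the
  rank-weighted in-set ECDF (weights $\mathrm{rank}^\tau$, default
  $\tau = 0.25$) and the unweighted out-of-set ECDF; scores optionally
  range-normalized. $\tau$ and the GSVA bandwidth below are the standard
  defaults of the cited single-sample methods, exposed as arguments.
* **GSVA** — expression mapped through a Gaussian-kernel CDF across
  samples (bandwidth $\mathrm{sd}_g/4$; zero-variance genes map to 0.5),
  then a weight-1 KS running statistic per sample; the score is the
  maximum positive plus minimum negative deviation.

Single-sample score matrices are tested for phenotype association with
the same paired/unpaired moderated t used at gene level; with a single
set no variance moderation is possible and the ordinary t is used.

# Resampling engine

All sample-permutation methods consume one shared stream of group-label
relabelings (paired designs: independent within-block swaps), so a
sixteen-method run prices the permutation t-matrix once. Permutation
p-values are $(b+1)/(B+1)$ with $b$ the number of null statistics at
least as extreme — never zero, and exact under exchangeability. When the
space of distinct relabelings (or gene subsets) fits within the requested
budget, it is enumerated exhaustively with the identity excluded; the
$+1$ in the p-value re-admits the identity, so small designs give exact
p-values with no Monte-Carlo noise.

The specificity experiment permutes each dataset's phenotype labels
(group sizes preserved; pairing blocks dropped — under the null the
labels are exchangeable across blocks), reruns every method on every
permuted copy, and reports the percentage of set-level p-values below
each $\alpha$. Per-method failures are logged and excluded rather than
fatal: a benchmark of 16 methods across many datasets must not abort
atomically.

# Benchmark metrics and ranking

Each benchmark dataset carries a designated *target* set — the set named
for the condition under study — and contributes one p-value and one rank
percentage per method. Medians over datasets are the sensitivity and
prioritization surrogates (threshold-free, and no multiple-testing
adjustment is needed since exactly one target is read out per dataset).
Methods are assigned category I or II by their FP percentage at
$\alpha = 1\%$ under phenotype permutation; the threshold is
`threshold_factor` × 1% with a default factor of 3, the value that
separates the near-nominal cluster (up to ~2.5%) from the clearly
inflated one (from ~4.9%) in the bundled reference benchmark.

Within a category, metrics are combined as robust Z-scores,
$z = (x - \mathrm{median})/(1.4826\,\mathrm{MAD})$; the
normal-consistency factor is required to reproduce the reference table's
printed Z-scores, so the unnormalized MAD is not an option. Category II
adds the Z of the FP percentage, penalizing sensitivity bought with false
positives. Methods are ranked by ascending Z sum; ties break by lower
median rank, then method id. Scenario stability splits datasets at the
median of each stratifying factor (total samples, target-set size,
design, percentage of genes with p < 0.05) and reports the Spearman
correlation of each subset ranking with the overall one, flagging
subsets with fewer than three datasets.

The raw columns of the published 42-dataset benchmark are bundled
(`reference_metrics()`, `reference_scenario_ranks()`) so this machinery
can be validated against an established reference: feeding the printed
raw columns through `rank_methods()` reproduces the published Z sums to
the printed precision and every within-category rank. One cell is known
to disagree by one unit in the last digit (MRGSE's category II sum,
recomputed −3.55 against a printed −3.54) because the published table
prints rounded inputs; the recomputation is the self-consistent value.

# Synthetic data: what it emulates and what it does not

`synth_config()` describes an RMA-like two-group study: Gaussian log2
intensities (baseline mean 8, sd 2 — the scale of RMA-normalized
arrays), `n_genes = 2000`, 50 sets of 10–100 genes, 10 samples per
group. Genes within a set share a latent factor giving compound-symmetry
correlation `rho` (default 0.1, weak within-pathway co-expression; genes
in several sets take the factor of their first set so the covariance
stays well defined). Cases receive a shift of `effect_size` per-gene sd
on a `de_fraction` subset of the target genes (defaults 1 and 0.5: a
partially responding pathway), with `direction_mix` of the shifted genes
going down instead of up. Paired designs add a per-block intercept with
sd `baseline_sd/2`.

This structure is sufficient to reproduce the qualitative phenomena the
benchmark framework measures: calibrated subject-sampling methods on
uncorrelated nulls, inflated gene-sampling methods once `rho > 0`, and
target prioritization that grows with the effect size. It does **not**
model probe-level effects, batch structure, heavy-tailed noise,
mean-variance trends or count data — so green tests certify the
statistics and the framework, not performance on any particular real
dataset.

# Numerical choices and problem sizes

* Permutation default `n_perm = 1000` everywhere, matching standard
  practice for these methods. The packaged simulation studies (null
  calibration, correlation inflation, effect-size recovery) run at
  `n_perm = 200`: resolution $1/201 \approx 0.005$ is ample for FP
  measurement at $\alpha \in \{0.01, 0.05\}$ and for median-rank
  recovery, and it keeps a 16-method × 80-dataset study on a single core
  within minutes. The studies use the generator defaults above, 10 null
  datasets (500 set-level tests) for the calibration/inflation checks
  and 20 replicates per effect size for the recovery check, with
  replicate-matched seeds across effect sizes (a paired comparison that
  removes between-replicate noise from the monotonicity contract).
* Probeset collapsing keeps the probeset with the highest mean
  expression; exact ties break to the lexicographically smallest feature
  id so results never depend on input order.
* Sets are filtered to a minimum of 3 measured genes by default — the
  smallest size at which the set statistics are non-degenerate;
  configurable.
* Missing values are rejected at load time rather than imputed: upstream
  normalization pipelines produce complete matrices, and silent
  imputation would mask data errors.
* Degenerate cases are defined, not exceptional: constant genes get
  $t = 0, p = 1$; constant data drives every permutation statistic to
  $p = 1$; zero-variance genes are dropped from PLAGE/Z-score sets with
  a warning and mapped to 0.5 by the GSVA kernel.

# Known limitations

Only two-group (optionally paired) designs are supported — no
multi-factor models, covariates or longitudinal structures, although the
single-sample scores can be exported and modeled freely. CAMERA uses the
large-sample normal form; GLOBALTEST's chi-square matches the exact
permutation moments but approximates the null's shape (the permutation
fallback is exact in distribution). The
implementations follow the published definitions of the sixteen methods
but are not bit-compatible with the original software distributions;
exactness is instead guaranteed against enumeration oracles on small
instances.
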