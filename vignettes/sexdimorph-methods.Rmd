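---
title: "Methods: sex-differential expression in repeated-measures cortex cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sex-differential expression in repeated-measures cortex cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its statistical machinery: the
models, the tunable parameters and their defaults, what the synthetic
cohorts do and do not emulate, and the numerical choices made where the
design was genuinely open. Nothing here states an empirical result that the
test suite or `scripts/acceptance.R` does not itself compute.

## The setting

Post-mortem cortex expression studies of sex differences have a
characteristic structure that the whole package is built around:

* few subjects (5–10 per sex), each contributing samples from several
  cortical regions, so samples are **not independent** — region samples of
  one brain share a subject effect;
* extreme sex-chromosome signatures (*XIST* female-only, Y genes
  male-only) alongside **subtle autosomal effects**, fold differences (FD)
  of roughly 1.2–1.5;
* nuisance covariates — RNA integrity (RIN), age, post-mortem interval
  (PMI, hours), tissue pH, cortical lobe — some missing for some samples;
* inference targeted at curated **gene sets** (risk genes, co-expression
  modules, cell-type markers), each with its own appropriate background
  universe.

## Preprocessing

Stage order is fixed: expression filter → outlier passes → quantile
normalization → sex matching → re-filter.

* **Expression filter.** A gene is dropped when the fraction of samples
  below the level threshold *exceeds* the cutoff in either sex (RNA-seq
  preset: log2 value < 1 in > 50%; array preset: < 6 in > 80%). The
  inequalities are strict; a gene sitting exactly at the boundary (e.g.
  5 of 10 samples low) is retained. The two readings differ only at exact
  boundaries, which the tests pin down.
* **Outlier removal.** Per pass (within each sex, then all samples), each
  sample's mean product-moment correlation with the rest of its group is
  computed; samples more than `z_threshold` (default 2.5) SD *below* the
  group mean of these means are removed, and the pass recomputes after
  removal. Only the low side is flagged — an unusually *high* mean
  correlation cannot indicate a degraded sample. A single application per
  pass (no within-pass iteration) keeps the rule auditable. The alternative
  single-pass rule used for replication-style data sets (summed-correlation
  z > 2) is the configuration `outlier_spec(z_threshold = 2, passes = "all")`,
  not a separate code path.
* **Quantile normalization.** Every sample is mapped onto the per-rank mean
  of the sorted columns. Ties within a sample receive the mean of the
  reference values over their tied ranks, making the operation
  deterministic and idempotent; within-sample rank order is preserved.
* **Sex matching.** All samples of the minority sex are kept; each is
  paired greedily (ascending absolute age difference, ties broken by sample
  ID) with an unused majority-sex sample from the same region. Greedy
  matching is deterministic and optimal on the small instances this design
  produces; minority samples with no region partner are dropped and
  reported. When counts tie, males are the reference side, matching the
  convention of matching female samples to male samples.

## The differential expression model

Per gene $g$:
$$y_{g,i} = \beta_0 + \beta_{\text{sex}} \cdot \mathbb{1}[\text{male}_i]
  + \textstyle\sum_k \beta_k x_{k,i} + u_{g,\text{subj}(i)} + \varepsilon_{g,i}$$

with `log2FD` $= \beta_{\text{sex}}$ (positive = male-higher, so
FD $= 2^{\beta_{\text{sex}}}$ is the male/female ratio). The subject random
intercept is not fit per gene; instead a single **consensus intra-subject
correlation** $\rho$ is estimated and every gene is fit by generalized
least squares under block compound-symmetry covariance (blocks = subjects).
This is the standard small-sample strategy for repeated-measures
expression designs: per-gene variance-component estimates are unstable at
5–10 subjects, while a genome-pooled correlation is well determined.

* **Estimating $\rho$.** For each gene, the REML criterion of the
  compound-symmetry model (profiled over the residual variance) is
  evaluated on a grid of feasible correlations; whitening uses a
  block-Helmert orthonormal transform, so the whole genome is processed
  with matrix products per grid point. The per-gene optimum is refined by
  parabolic interpolation, and the consensus is
  $\tanh(\text{trimmed mean}_{15\%}(\operatorname{atanh}\hat\rho_g))$,
  clamped to $(-0.99, 0.99)$. The grid default (31 points) resolves
  $\rho$ to well under the Monte-Carlo error of the designs in scope.
  With no repeated subjects the estimator returns 0 with a warning and the
  model collapses to OLS.
* **Covariates.** Numeric covariates enter unstandardized (scaling affects
  no reported statistic); lobe enters as indicator contrasts. Missing
  PMI/pH are imputed by the subject mean, falling back to the cohort mean
  (reported). Rank-deficient designs are rejected, naming the collinear
  columns.
* **Variance moderation.** Residual variances $s^2_g$ (on $d_g = n - p$
  degrees of freedom) are assumed drawn from a scaled inverse-chi-square
  prior with hyperparameters $(d_0, s_0^2)$, estimated by the closed-form
  method of moments on $\log s^2_g$ (digamma/trigamma matching; the
  trigamma inverse is solved by Newton iteration). The posterior variance
  $\tilde s^2_g = (d_0 s_0^2 + d_g s^2_g)/(d_0 + d_g)$ yields a moderated
  t on $d_0 + d_g$ degrees of freedom. If the moment estimate of the
  spread is non-positive, $d_0 = \infty$ (complete shrinkage) is used —
  not an error. Two-sided p-values throughout; BH adjustment across genes.
* **Sex-DE calling.** Male-DE at tier $\alpha$: FD $\ge 1.2$ and
  $p \le \alpha$; female-DE: FD $\le 1/1.2$. Tiers 0.005 / 0.01 / 0.05 are
  nested by construction. Every gene is also labelled by threshold-free
  direction (male-higher / female-higher); genes with log2FD exactly 0
  belong to neither and are excluded from the binomial shift counts, since
  both directional categories are defined by strict inequalities.

## The dual enrichment framework

Both tests run against a per-set **background** universe:
expression-dependent categories (protein-coding, source-publication) are
intersected with the expressed genes of the data set at hand, while the
genome-wide one-to-one orthologue category is used as-is, because it is
defined independently of the tissue analysed.

* **Thresholded Fisher.** For each set × direction × tier, a 2×2 table
  within the background; the two-sided p sums all hypergeometric point
  probabilities not exceeding the observed one (relative tolerance 1e-7 on
  the comparison). Both the sample odds ratio $ad/bc$ and the
  fold-of-expected $(a/(a{+}b))/((a{+}c)/N)$ are reported side by side:
  the two statistics are often conflated in the literature, and emitting
  both keeps results auditable. Bonferroni adjustment covers sets × 2
  directions, applied within each tier.
* **Binomial shift.** The set's male-higher proportion is tested against
  the background proportion with an exact two-sided binomial test (same
  minimum-likelihood summation), with an exact Clopper–Pearson 95% CI —
  the interval consistent with the exact test. The *shift* is the set
  proportion minus the background proportion, in percentage points. The
  set's own genes stay in the background by default (the curated
  backgrounds contain their sets); `exclude_set_from_background = TRUE`
  provides the other convention. Bonferroni adjustment covers the number
  of sets.

A set equal to its whole background has shift 0 and Fisher p 1 at every
tier; relabelling the sexes swaps the two Fisher directions exactly and
negates every shift. Both properties are asserted in the test suite.

## Concordance between analyses

Fold-difference concordance is the product-moment correlation of log2FD
over shared genes (log2, not raw FD, since raw FD is asymmetric around 1),
with the t-transform p-value on $n-2$ degrees of freedom; "expression
level" concordance correlates per-gene mean log2 expression, the natural
summary when no other is specified. Directional replication requires
FD $\ge$ threshold in *both* analyses; fold enrichment of a set within the
replicated list uses the genes tested in both analyses as background,
since only such genes can enter the list.

## The synthetic cohort generator

`sim_config()` defaults encode the study conditions the package is
designed for: 5 subjects per sex × 3 regions (the balanced small-cohort
design), gene variances from the moderated-t hyperprior with $d_0 = 4$,
$s_0^2 = 0.05$ log2²-units, intra-subject correlation 0.3 (a plausible
placeholder — real cohorts' values are not well characterized), baselines
uniform on 2–10 log2 units, one XIST-like and six Y-like markers, and
covariate effects of 0.1 log2 units per covariate SD (subtle relative to
marker effects, comparable to planted autosomal shifts). The sex effect is
split symmetrically ($\pm$log2FD/2 around baseline) so the truth table is
directly comparable to the estimated log2FD, and the subject-intercept
variance is $\rho/(1-\rho)$ times the noise variance, making the marginal
intra-subject correlation exactly $\rho$. Note the marginal per-gene
variance is therefore $s^2_g/(1-\rho)$, which is what the GLS residual
variance estimates. Sex-chromosome markers are encoded as 6.0 log2 units
in the expressing sex and 0.05 in the other — reproducing the extreme-FD
wings of a sex volcano plot without modelling copy number. Every planted
set is paired with an unplanted control set of the same size, a built-in
negative-control surface for the enrichment tests.

What the simulation does **not** emulate: count-level (negative binomial)
noise and mean–variance coupling, GC/batch artefacts, correlated gene–gene
structure beyond the subject effect, unbalanced or missing-region designs,
and sex-chromosome dosage mechanics. Passing tests therefore demonstrate
the statistical machinery is correct under the declared model, not that
real-tissue artefacts are handled; the preprocessing stages exist
precisely because real data violate these idealizations.

## Numerical choices and degenerate inputs

* Exact-test summations compare point probabilities with a 1e-7 relative
  tolerance, the convention of the standard exact-test implementations,
  and are verified against enumeration oracles (all 2×2 tables with
  N ≤ 40; binomial tails up to n = 500).
* Zero-variance genes are excluded from correlation estimation; perfect
  fits ($s^2 = 0$) are legal and are shrunk toward $s_0^2$.
* Odds ratios with empty cells report 0 or ∞ as appropriate (NaN when both
  margins degenerate); p-values remain exact.
* `d0 = 0` (no moderation) and `d0 = Inf` (complete shrinkage) are exposed
  as overrides of `ebayes_moderate()` and reproduce the ordinary-t and
  fixed-prior limits exactly.
* All generators and the pipeline runner are seed-deterministic; the
  pipeline manifest records an MD5 checksum per artifact, and two runs
  with the same config and seed are byte-identical.

## Problem sizes

The test and acceptance workloads were sized for a single CPU while keeping
Monte-Carlo error well inside the asserted tolerances: null calibration
uses 20 cohorts of 2000 genes (5+5 subjects × 3 regions); effect recovery
uses 20 cohorts of 5000 genes with a 200-gene set planted at
log2FD = log2(1.3) (10+10 subjects × 3 regions); hyperparameter recovery
uses 20,000 genes; the exact-test sweep enumerates all 134,888 tables with
N ≤ 40 and 1000 random binomial cases. The full suite completes in a few
minutes.

## Known limitations

* The consensus-correlation GLS is an approximation to per-gene mixed
  models; it is the right trade-off at 5–10 subjects but can under-fit
  when intra-subject correlation truly varies across genes.
* The moment estimator of $(d_0, s_0^2)$ assumes a common residual
  degrees-of-freedom structure; designs with per-gene missingness are out
  of scope.
* Greedy age/region matching is not globally optimal for adversarial age
  configurations; for the small cohorts in scope it coincides with the
  optimum (asserted on enumerable instances).
* The binomial shift test treats genes as independent Bernoulli draws;
  co-expression within a set makes the test anti-conservative, which is
  why the Fisher and shift tests are reported together.
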