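# sexdimorph

Sex-differential expression analysis of repeated-measures brain
transcriptomes.

## The problem

Post-mortem brain expression cohorts are small and structured: each subject
contributes several samples (different cortical regions of one brain), the
sexes are often unbalanced, and the autosomal sex differences of interest
are subtle (fold differences of 1.2–1.5) compared with the extreme
signatures of *XIST* and Y-chromosome genes. `sexdimorph` implements a
complete, tested pipeline for this setting, for researchers asking whether
curated gene sets — disease risk genes, co-expression modules, cell-type
markers — are skewed toward male- or female-biased expression in cortex.

## The model

**Preprocessing.** Genes are kept when expressed (log2 value ≥ threshold)
in at least half the samples of each sex; samples whose mean inter-sample
correlation falls more than 2.5 SD below the group mean are removed (within
each sex, then overall); the matrix is quantile normalized; the sexes are
balanced by matching samples on region and age; expressed genes are
re-derived on the matched cohort.

**Differential expression.** For gene *g* with expression *y<sub>g</sub>*:

> *y<sub>g</sub>* = β₀ + β<sub>sex</sub>·male + Σ β<sub>k</sub>·covariate<sub>k</sub> + subject + ε

with fixed covariates (RIN, age, PMI, lobe, pH) and a subject random
effect handled as a consensus intra-subject correlation ρ: every gene is
fit by generalized least squares under block compound-symmetry covariance,
with ρ estimated by per-gene REML and pooled by a trimmed mean on the
atanh scale. `log2FD = β<sub>sex</sub>` (positive = male-higher). Residual
variances are shrunk toward an inverse-chi-square prior (d₀, s₀²) estimated
by closed-form moments on log variances, giving moderated t-statistics on
d₀ + d<sub>g</sub> degrees of freedom. Genes with |FD| ≥ 1.2 and p ≤
0.005 / 0.01 / 0.05 are called sex-DE (male-DE or female-DE by sign);
Benjamini–Hochberg adjusted p-values are also reported.

**Enrichment.** Each annotation set is tested two ways against its own
background universe (protein-coding expressed genes, genes tested in the
source publication, or genome-wide 1:1 human–mouse orthologues):

* a two-sided Fisher's exact test of overlap with male-DE and female-DE
  genes at each tier, Bonferroni-adjusted for sets × 2 directions per tier
  (both the odds ratio and the fold-of-expected are reported);
* a threshold-free two-sided binomial *shift* test: the set's proportion of
  male-higher genes (log2FD > 0, any p) against the background proportion,
  with an exact Clopper–Pearson CI, Bonferroni-adjusted over the sets.

**Concordance.** Fold-difference correlations between two analyses,
directional replication overlap at FD ≥ 1.2 in both, and hypergeometric
fold enrichment of annotation sets within the replicated list.

**Simulation.** `generate_cohort()` draws cohorts with exactly this
structure — balanced subjects × regions, gene variances from the moderated-t
hyperprior, a configurable intra-subject correlation, XIST-like and Y-like
markers, covariate effects, and autosomal gene sets planted at chosen
log2FD — plus a ground-truth table, so every downstream stage is testable
without any external data.

## Worked example

```r
library(sexdimorph)

cfg <- sim_config(
  n_subjects_per_sex = 5, n_regions_per_subject = 3, n_genes = 2000,
  planted_sets = list(glial = list(n_genes = 150, log2fd = 0.4)), seed = 42)
cohort <- generate_cohort(cfg)

res <- run_sex_de(cohort$expression, cohort$samples)
str(res$params)
#> List of 3
#>  $ d0   : num 3.85
#>  $ s0_sq: num 0.0699
#>  $ rho  : num 0.268
table(res$table$de_p0.05)
#> female-DE   male-DE        ns
#>        48       132      1820

report <- run_enrichment_suite(res$table, cohort$sets)
subset(report$shift,
       select = c(set, n_set, k_male, prop, p_bg, shift, p_adj, significant))
#>          set n_set k_male  prop  p_bg    shift    p_adj significant
#> 1      glial   150    141 0.940 0.508  0.43200 1.22e-30        TRUE
#> 2 ctrl_glial   150     76 0.507 0.508 -0.00133 1.00e+00       FALSE
```

The cohort hides a 150-gene set planted at log2FD = 0.4 (≈1.3-fold
male-higher). The fitted intra-subject correlation (0.27) recovers the
simulated 0.3, and the variance-prior estimates (d₀ ≈ 3.9, s₀² ≈ 0.07)
match the generative hyperprior (d₀ = 4; marginal variance
s₀²/(1−ρ) ≈ 0.071). The shift test finds 94% of the planted set
male-higher — a +43 percentage-point shift from the 51% background — while
the unplanted control set of the same size sits at background level. The
male-DE Fisher test at the 0.05 tier gives odds ratio 36.0 (7.9-fold over
expectation, adjusted p = 3.1e-61) for the planted set and no signal for
the control.

A whole run (simulate → preprocess → DE → enrichment → concordance, with a
manifest of output checksums) can be driven from one config:

```r
run_pipeline(list(seed = 42, out_dir = "out",
                  simulate = list(n_genes = 2000, n_subjects_per_sex = 5)))
```

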