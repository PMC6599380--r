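---
title: "Methods: permutation empirical-Bayes differential methylation and downstream analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: permutation empirical-Bayes differential methylation and downstream analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(monomethir)
```

## The analysis problem

monomethir analyzes Illumina 450K-style DNA methylation beta values
(per-CpG methylation fractions in [0, 1]) from monocytes of a cohort
stratified by insulin resistance: insulin-resistant (IR) samples have
HOMA-IR >= 2.0, insulin-sensitive (IS) samples fall below. The package
covers the full chain from differential methylation calling through probe
filtering, cell-identity quality control, comparison with the
hematopoietic stem cell (HSC) methylome, and single-CpG biomarker models.

Beta values are heteroscedastic — their variance shrinks towards the 0 and
1 boundaries — and not normally distributed, which motivates the two
central choices: an empirical-Bayes moderated statistic (stable variance
estimates at modest sample sizes) combined with a label-permutation null
(no distributional assumption), and non-parametric rank statistics
(Mann-Whitney, Spearman) everywhere else.

## Differential methylation calling

For each probe, `group_stats()` computes the group means, their difference
`delta = mean(IR) - mean(IS)`, the pooled two-sample variance `s^2`, and
residual degrees of freedom `d = n1 + n2 - 2` (adjusted probewise for
missing values; a probe with fewer than two usable values in a group is
marked unusable and skipped).

`estimate_shrinkage()` fits a scaled inverse-chi-square prior with `d0`
degrees of freedom and scale `s0^2` to the per-probe variances by moment
matching on the log scale: the spread of `log(s^2)` in excess of the
chi-square sampling noise at `d` degrees of freedom determines `d0`
through a Newton inversion of the trigamma function, and the location
determines `s0^2`. Two numerical edge cases are handled explicitly:

* when the excess spread is not positive (variances essentially constant),
  `d0` is capped at 1e6 and `s0^2` is set to the mean observed variance,
  so the moderated t reduces *exactly* to the ordinary pooled t in this
  limit (the log-scale bias correction would otherwise leave a small
  offset that has no justification when the variances show no spread);
* estimation requires at least 50 probes with finite positive variance;
  below that the permutation machinery falls back to the unshrunken
  pooled t (`d0 = 0`), since a prior fitted to a handful of variances is
  noise.

The moderated statistic is `t_mod = delta / sqrt(s_tilde^2 (1/n1 + 1/n2))`
with `s_tilde^2 = (d0 s0^2 + d s^2) / (d0 + d)`.

`permutation_pvalues()` recomputes the *entire* pipeline — group
statistics, shrinkage estimation, moderated t — under each of `B` random
relabelings of the samples (default `B = 1000`; the shrinkage
re-estimation preserves exchangeability and can be switched off for
speed). Two-sided empirical p-values use the add-one convention
`p = (1 + #{null |t| >= |t_obs|}) / (1 + N_null)`, so p is never zero. By
default the null is pooled across probes (`N_null = B x P`), which gives
p-value resolution far below `1/B`; a per-probe mode is retained for
diagnostics. A permutation FDR (`q_perm`) is reported alongside: at each
observed |t| threshold, the expected number of null exceedances per
permutation divided by the observed exceedance count, monotonized.

For cohorts of at most 10 samples, `B = "exhaustive"` enumerates all
`choose(n, n2)` label assignments. Note that this enumeration includes
each partition's group-swapped complement, which produces the identical
|t|; the smallest attainable two-sided p in a 4-vs-4 design is therefore
`(1 + 2) / (1 + 70)`, not `2/71`. The test suite pins this against an
independent enumeration oracle.

A probe is a DML iff `p_perm < 0.05` and `|delta| >= 0.10` and no
exclusion flag is set. The delta boundary is *inclusive* (a probe at
exactly 10% absolute difference passes): the threshold is quoted both as
"greater than 10%" and as "delta >= |0.10|" in the field, and the
inclusive reading wins here. The p threshold is pointwise, not
FDR-adjusted; `q_perm` is reported next to it so users can apply either.

## Probe exclusion filters

Three independent flags can veto a candidate DML; because each is an
independent boolean, their application order cannot change the result
(the pipeline applies them in the order: confounder overlap, then SNP
flags, and logs counts at each stage).

* **SNP pattern** (`snp_pattern_flag`): samples are assigned to the
  nearest of the modes {0, 0.5, 1} when within `tol = 0.12`; the probe is
  flagged when >= 80% of samples are assigned and >= 2 distinct modes are
  occupied. The trimodal 0/50/100% pattern is what a segregating SNP in
  the probe body produces; requiring two occupied modes avoids flagging
  constitutively hemimethylated loci that sit at 0.5 in every sample.
  These three defaults are declared heuristics — a reproducible surrogate
  for the manual review such patterns usually get — and are exposed as
  arguments. The flag is invariant to sample order and to the reflection
  `beta -> 1 - beta`.
* **Known SNP** (`known_snp_flag`): taken directly from the manifest-style
  annotation column.
* **Confounder overlap** (`confound_overlap_filter`): set subtraction of a
  second contrast's DML list (e.g. a serostatus comparison), reporting the
  overlap count and its percentage of the primary list (nearest whole
  percent).

## Cell identity scoring

`build_panel()` reuses the permutation machinery on two reference sample
sets and keeps probes with `|delta| > 0.30` (strictly) at `p < 0.05` —
0.30 for a monocyte-vs-PBMC panel, 0.10 for finer subset panels.
`purity_score()` is the Spearman correlation between a sample and the
target type's mean profile at the panel probes. Rank correlation is used
for every association in the package; it makes the score invariant to
monotone distortions of a sample's measurements (e.g. residual
intensity bias).
Scores computed on fewer than 20 shared probes are refused rather than
returned noisy.

## HSC maintenance classification

Each DML is compared per group against the HSC mean profile:
"maintained" when `|group mean - HSC mean| < 0.10`, "hyper" when the
difference is `>= 0.10`, "hypo" when `<= -0.10`. The boundary belongs to
the divergent classes; a 1e-9 epsilon keeps a difference of exactly 0.10
divergent despite binary floating point (0.6 - 0.5 is fractionally below
0.1 in doubles). The HSC comparator is the mean over the HSC reference
samples. Note the rule is a threshold, not a significance test: a group
can differ significantly from HSCs yet be classified "maintained" when
the difference is below 0.10 (this situation occurs at one of the four
printed biomarker CpGs, where the IS-vs-HSC difference is 0.09).

`pca_dmls()` performs PCA on centered, unscaled beta values (they already
share a scale) with a deterministic sign convention: each component's
largest-magnitude loading is made positive.

## Biomarker models

Candidates are selected by per-probe Mann-Whitney tests with
Benjamini-Hochberg adjustment at q < 0.01 (strict, matching the selection
rule's statement; `q_threshold = 1` disables the filter since adjusted
p-values are capped at 1). `fit_logistic()` fits by maximum likelihood;
perfect separation — the expected regime for a strong CpG in a 37-sample
cohort — is detected from the glm warnings and the fit falls back to a
small ridge penalty (IRLS with unpenalized intercept, lambda = 0.01),
with the model flagged. The AUC is computed in-sample by the rank formula
(no cross-validation, matching how such cohort models are usually
reported; treat it as optimistic). `stepwise_select()` is greedy forward
selection by AIC — criterion and direction are this package's choice, as
stepwise procedures are rarely specified fully — and with collinear
features exactly one of a correlated pair enters.

For a single-feature model, `beta_cutoff()` returns the methylation value
where the fitted probability crosses 0.5, `-b0/b1`; a negative slope
yields a "beta below the cutoff predicts IR" rule. Per-class accuracies
use class-size denominators (IR accuracy = correctly called IR / n_IR),
and their unweighted mean is reported as a macro average.

## Cohort statistics

* HOMA-IR = glucose (mg/dL) x insulin (uU/mL) / 405; the divisor is the
  standard mass-unit convention (22.5 for SI units) and a HOMA-IR of
  exactly 2.0 stratifies as IR.
* `mann_whitney()` is exact by full enumeration of `choose(n, n1)` label
  assignments for combined n <= 12 — valid in the presence of ties via
  midranks, which is why it is implemented directly rather than delegated
  (the standard exact algorithm declines ties) — and a tie- and
  continuity-corrected normal approximation above that.
* `region_enrichment()` tests each annotation category against the sum of
  all others with a two-cell chi-square goodness-of-fit (1 df), expected
  counts from the proportions of the analysis's retained probe universe
  (not the full manifest), Bonferroni-corrected within the family.
  Categories with expected count below 1 are skipped with a warning.
* `manhattan_cluster()` uses L1 distances and complete linkage; samples
  are ordered by id before clustering so tie-breaking is deterministic.
* `power_sample_size()` iterates the noncentral-t power function of the
  two-sided two-sample t test and returns the smallest per-group n
  reaching the target power. For delta = 0.10, sd = 0.08, alpha = 0.05,
  power = 0.80 this gives n = 12 (power 0.796 at n = 11, 0.833 at n = 12);
  the commonly used normal approximation gives ~10.05 and would round to
  11, which is why the iterated answer differs from back-of-envelope
  values.
* `gene_set_fisher()` is a generic one-sided Fisher over-representation
  test over user-supplied gene sets, replacing web-service ontology
  queries.

## The synthetic cohort generator

`simulate_cohort()` emulates the statistical structure the analysis
relies on, with defaults set to the study conditions (23 IS vs 14 IR
samples):

* null probes share a per-probe mean drawn from
  `0.45 Beta(0.5, 5) + 0.45 Beta(5, 0.5) + 0.10 U(0.2, 0.8)` — the
  bimodal methylome with a midrange minority, which gives the shrinkage
  estimator a realistic variance landscape;
* each observation is `Beta(mu * kappa, (1 - mu) * kappa)` with a common
  concentration `kappa = 50`, reproducing the variance-towards-the-
  boundaries heteroscedasticity of array beta values. Per-probe variance
  magnitudes are not published for the emulated data, so `kappa` is a
  modeling choice, exposed as the `precision` argument; 50 puts midrange
  per-group standard deviations near 0.07, a plausible array scale;
* planted DMLs shift the IR mean by `delta` (default 0.15) with random
  sign, redrawing the base mean if the shift would leave (0.01, 0.99);
* SNP-like probes draw per-sample genotypes from {0.03, 0.5, 0.97} under
  Hardy-Weinberg frequencies with allele frequency uniform on (0.2, 0.8),
  plus tight Beta noise — the filter's target pattern;
* HOMA-IR, fasting glucose and insulin are generated so that the
  stratification rule reproduces the group labels exactly.

`simulate_references()` shares the cohort's probe universe. The first
cell type keeps the cohort's baseline profile, so the cohort scores as
that type — emulating an enriched-monocyte cohort against a
monocyte/PBMC reference panel; other types are shifted by at least the
marker delta at their marker probes. The HSC profile can be configured to
match the IR mean, the IS mean, or their midpoint at chosen numbers of
planted DMLs ("maintained in IR / in IS / in both"), and diverges by at
least 0.10 from both groups at the remainder. With the planted delta of
0.15, a "maintained in both" probe sits 0.075 from each group mean — a
0.025 margin to the classification boundary — so sample-mean estimates
flip a small fraction of classes; exact count reproduction is therefore a
property of the generator's true means, while estimates from a simulated
cohort agree with the planted classes to within a few percent.

What the generator does **not** emulate: probe-level spatial correlation,
chip/batch effects, Infinium type-I/type-II chemistry differences, and
cell-composition heterogeneity. Tests passing on synthetic cohorts
validate the statistical machinery under the stated model; they do not
certify performance on real arrays, where these artifacts add structure.

## Problem sizes and runtime choices

The test suite and the acceptance script run cohorts of 1,500-5,000
probes with 37 samples and B = 200 permutations; the calibration and
recovery checks use 5,000 probes. These sizes were chosen so the whole
suite runs in about a minute while leaving the binomial noise of the
calibration check (fraction of null p-values below 0.05 over 5,000
probes) well inside its tolerance band. The demo pipeline config uses
1,500 probes with 80 planted DMLs.

## Known limitations

* The moderated-t/permutation formulation is this package's concrete
  rendering of "resampling-based empirical-Bayes" testing; other
  implementations of that idea may differ numerically.
* No covariate adjustment in the differential model (by design; use the
  confounder-overlap filter for a second contrast).
* In-sample AUC and accuracies are optimistic; cross-validation is out of
  scope.
* The permutation FDR is a plug-in estimate and can be conservative at
  small B.
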