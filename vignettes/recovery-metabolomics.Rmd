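---
title: "Recovery-stratified amino-acid metabolomics: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recovery-stratified amino-acid metabolomics: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strokemet)
```

## The scientific problem

After an ischemic stroke, patients admitted to inpatient rehabilitation
recover at very different rates, and serum amino-acid levels are plausible
correlates of that rate. `strokemet` implements the full analysis chain
for a *recovery-stratified* targeted-metabolomics design: rather than
comparing stroke patients with controls, it contrasts the extremes of a
rehabilitation cohort — the best and worst recoverers — and asks which
amino acids, alone or in panels, separate them.

## Recovery scoring

Functional status is measured by the total Functional Independence
Measure (FIM), an 18-item scale with totals from 18 to 126. Raw FIM gain
is confounded by the ceiling effect: a patient admitted at 100 can gain at
most 26 points. The Montebello Rehabilitation Factor Score normalizes the
gain by the patient's potential for improvement,

$$\mathrm{MRFS} = \frac{\mathrm{FIM}_{discharge} - \mathrm{FIM}_{admission}}
                      {\mathrm{FIM}_{max} - \mathrm{FIM}_{admission}},$$

and MRFS *efficiency* divides by the length of stay in days, giving a
per-day relative recovery rate. `compute_mrfs()` treats
$\mathrm{FIM}_{max} = 126$ as a default, overridable for other scales; an
admission score equal to the maximum makes the denominator zero and is an
error, and deterioration yields a negative score (the score can never
exceed 1).

Screening (`screen_cohort()`) applies inclusive bounds for age
[50, 85] and admission FIM [36, 71] and a strict bound for length of stay
(> 6 days), mirroring the usual phrasing of such criteria
("between … and …" vs "> 6 days"). `stratify_extremes()` then takes the
top and bottom `n_per_group` patients by MRFS efficiency. Selection is
defined as the head and tail of a full stable sort by
(efficiency, patient id), which makes tie handling deterministic and
reproducible — with continuous efficiencies ties are rare, but a defined
order matters for exact rerun equality.

## Preprocessing of peak areas

Targeted UHPLC-MS peak areas carry per-sample technical scale (injection
volume, ionization efficiency) on top of biology. The pipeline:

1. **drops sparse metabolites** whose missing fraction exceeds 0.5
   ("undetectable in most samples" — glycine in the motivating study);
   the threshold is configurable;
2. **median-normalizes** each sample by its own median over the
   *retained* metabolites. Normalizing after the sparse drop keeps a
   mostly-missing column from perturbing divisors; the ordering is
   recorded in the run manifest;
3. **imputes** remaining scattered non-detects by half the minimum
   observed value of that metabolite — the standard targeted-metabolomics
   convention for values below the detection limit;
4. **UV-scales** (mean-center, unit variance) each metabolite before
   multivariate modelling, using the sample ($n-1$) standard deviation,
   the common chemometrics convention. Centers and scales are retained so
   held-out samples can be projected without leakage.

Group contrasts are summarized by fold changes, defined as
poor-recovery over good-recovery means of normalized quantities (so > 1 =
elevated in poor recoverers), and by a heat-map matrix of values relative
to the good-recovery mean.

## The PLS-DA model

The discriminant model is two-class PLS-DA fitted by the PLS1 NIPALS
sequence. The class label is coded 0/1 (good = 0, poor = 1) and centered;
this coding makes the first weight vector exactly proportional to the
class-mean difference of the standardized data, a property the test suite
exploits as an oracle. For each component the weight is the normalized
covariance of the current X residual with the current y residual, the
score is the projection of the X residual onto the weight, loadings are
least-squares regressions on the score, and **both X and y are deflated**
(symmetric NIPALS). PLS1 variants differ in whether y is deflated; with a
single response the fitted subspace is identical, and we deflate for
consistency with the textbook presentation.

Model quality is reported as:

* **R2Y** — cumulative fraction of label variance explained,
  $1 - \mathrm{RSS}/\mathrm{TSS}$, non-decreasing in the number of
  components;
* **Q2Y** — cross-validated counterpart, $1 - \mathrm{PRESS}/\mathrm{SS}$,
  where PRESS accumulates squared held-out prediction errors over
  stratified folds (7 by default, the convention of the chemometrics tool
  family) and each fold refits centering, scaling, and the PLS model on
  its training split only. SS is the total sum of squares of the coded
  labels about their global mean; this denominator choice is not universal
  across implementations and is therefore stated here and in the manifest.

The default of **two components** follows standard practice for
two-group score plots; the count is configurable, and requesting more
components than the data's rank is an error.

**Permutation validation** (`permutation_validate()`) refits the model on
`n = 200` permuted label vectors, records each refit's R2/Q2 against the
absolute correlation of permuted with original labels, and extrapolates
least-squares lines (including the unpermuted point at correlation 1) to
correlation zero. A **negative Q2 intercept** is the usual pass criterion:
it means label-compatible structure, not overfitting capacity, drives the
predictive power.

**VIP scores** use Wold's formula,
$\mathrm{VIP}_j = \sqrt{p \sum_a \mathrm{SSY}_a w_{aj}^2 / \sum_a \mathrm{SSY}_a}$,
whose squared values average to 1; biomarkers are selected by the strict
threshold VIP > 1 (a score of exactly 1 is excluded), in descending VIP
order with name tie-breaks.

## Panel evaluation

All $2^k - 1$ nonempty subsets of the selected biomarkers are evaluated
(`panel_search()`), each by 10 independent replicates of stratified
10-fold cross-validation:

* The classifier inside CV is **unpenalized logistic regression** on
  training-standardized features — the simplest probabilistic scorer with
  no hyperparameters; a training-split PLS-DA scorer is available as an
  alternative (`classifier = "plsda"`). With 36 training samples and a
  strong panel the logistic fit often separates perfectly; that only
  pushes coefficients toward infinity along a fixed direction, leaving
  the score *ranking* (and hence AUC) stable, so the non-convergence
  chatter is deliberately muffled.
* Folds are stratified by class. With 20 + 20 samples and 10 folds,
  unstratified splits can produce single-class test folds where AUC is
  undefined; when even stratification cannot give every test fold both
  classes, the fold count is reduced with a warning.
* Standardization is recomputed inside each training split, so no test
  information leaks into the scorer.
* AUC is the rank-sum (Mann-Whitney) probability with ties counted one
  half; `roc_points()` returns the matching staircase whose trapezoidal
  area equals the rank-sum value to numerical precision — the two routes
  are kept as mutually checking implementations.
* The summary convention is: mean test AUC over all folds of all
  replicates; SD over the 10 replicate-level means; and a Student-t 95%
  interval $\bar a \pm t_{0.975,\,9}\, s/\sqrt{10}$ over the replicate
  means (`ci_mean_auc()`, `ci_from_summary()`). This convention
  numerically reproduces published interval tables of this design.
  Training AUC is computed on each fold's training split, not by
  refitting on all data.
* Rankings sort by mean test AUC, then mean training AUC, then panel
  name — fully deterministic. All panels share one seed, so fold
  assignments are identical across panels and comparisons are paired.

A clinical covariate (age, in years) can be appended as one standardized
column (`augment_with_covariate()`) and competes like any metabolite.

## The synthetic cohort generator

No patient-level data ships with the package; `generate_cohort()` stands
in for it with known ground truth. Per sample $i$ in group $g$ and
metabolite $j$:

$$x_{ij} = \mathrm{base}_j \cdot \mathrm{fc}_j^{[g = \mathrm{PR}]}
           \cdot \varepsilon_{ij} \cdot s_i,$$

with mean-one lognormal biological noise $\varepsilon_{ij}$ at CV 0.35,
a per-sample lognormal technical factor $s_i$ (log-SD 0.3 — large enough
that median normalization is load-bearing in tests, small relative to
biology), and default fold changes 0.65 (leucine-isoleucine), 0.54
(proline), 2.11 (glutamate), 1.74 (arginine), 0.66 (threonine), 1.0
elsewhere. Detection failures are masked as missing with probability 0.9
for glycine (so the sparse-drop rule removes it essentially always) and
0.02 elsewhere. Clinical records draw age from group-specific normals
(61.25 ± 7.84 vs 71.55 ± 10.39 years) truncated to the [50, 85] inclusion
window — the simulated cohort represents patients already past screening,
and untruncated ages would silently break the 20 + 20 stratification
contract — admission FIM uniform on 36–71, MRFS from truncated normals
(0.71 ± 0.11 vs 0.14 ± 0.10), and stays of 10.7 ± 3.19 vs 22.9 ± 9.26
days truncated above 6, which lands MRFS efficiency near 0.071 ± 0.023 vs
0.007 ± 0.003 per day. Lognormal multiplicative noise matches the
positive, right-skewed character of peak areas.

What the generator does **not** emulate: correlation between metabolites
(defaults to independence — real amino acids share pathways and
correlate substantially), instrument drift and batch structure,
non-ignorable missingness, and any genuine age-metabolite coupling (age
separates groups only through its group means). Tests passing on this
generator therefore validate the *pipeline machinery and its statistical
calibration*, not the biological claims.

```{r walkthrough, eval = FALSE}
cohort <- generate_cohort()          # default seed 20200124
config <- run_config(cohort = cohort, out_dir = "strokemet_demo")
run <- run_pipeline(config)
run
```

## Numerical and design choices worth knowing

* **Tie-breaks** are deterministic everywhere: patient id in
  stratification, name in VIP ordering, training AUC then name in panel
  ranking.
* **Degenerate inputs** error early with the offending field, sample, or
  metabolite named: zero-median samples, zero-variance columns,
  single-class labels, all-missing metabolites, admission FIM at the
  scale maximum.
* **Both t-test flavors** are reported (pooled primary, Welch secondary)
  because the convention behind a bare "t-test" in clinical tables is
  ambiguous; the chi-square is Pearson without continuity correction,
  with a small-cell warning below expected counts of 5.
* **Seeds**: every stochastic routine takes an explicit seed; the
  pipeline derives per-stage seeds deterministically from one master
  seed, so reruns are byte-identical.
* **Constant columns inside a CV fold** are centered but not scaled
  (scale factor 1) rather than erroring, since they can arise in small
  training splits even when the full column varies.

## Problem sizes used by the test suite

The suite exercises the pipeline at the design's native size (40 samples,
21 metabolites). Monte-Carlo checks use 50–200 cohort seeds for
distributional properties, 1,000 seeds for null calibration of the CV-AUC
machinery, 100 seeds for selection-recovery rates, and 50 seeds × 200
permutations for the validation-intercept behavior; these counts keep the
whole suite in the minutes range while leaving binomial noise on
estimated rates at a few percentage points.

## Known limitations

* With five spiked analytes of similar standardized effect size
  (roughly 1–1.5 SD at CV 0.35), repeated-CV test AUCs of the larger
  panels saturate near 1, so fine ranking among top panels is dominated
  by CV noise; expecting one particular analyte to dominate the top ranks
  is not realistic under these conditions, even though it can happen in a
  single real cohort.
* For the same reason, VIP > 1 recovers the spiked set *as a subset*
  far more reliably than it recovers it *exactly*: with 20 UV-scaled
  variables, each null metabolite has a non-trivial chance of crossing
  VIP = 1 in any one 40-sample cohort, and some null metabolite does so
  in roughly half of cohorts. Exact-set recovery claims at these effect
  sizes should be read accordingly.
* Q2Y depends on the fold draw; with 40 samples and 7 folds the
  seed-to-seed spread is a few hundredths. The permutation intercepts
  inherit that noise, which is why validity conclusions use 200
  permutations and, in the tests, many seeds.
* The logistic scorer's coefficients are meaningless under separation;
  only scores/rankings should be interpreted.
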