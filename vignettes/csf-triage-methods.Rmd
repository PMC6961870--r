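---
title: "Methods: DSI classification, PCC confidence, and simulated-CSF triage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DSI classification, PCC confidence, and simulated-CSF triage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csftriage)
```

# The problem

Differential diagnosis in the memory clinic weighs evidence from
neuropsychological testing, structural MRI markers, APOE genotype and —
when a lumbar puncture is performed — CSF biomarkers.  CSF testing is
informative but invasive, and guidance on who should receive it is
worded loosely.  `csftriage` implements a quantitative triage: estimate,
per patient, what CSF knowledge *would* contribute before ordering the
test, by simulating a canonical positive (AD-like) and negative
(normal) CSF profile and recomputing the confidence in the diagnosis.

This vignette documents the statistical machinery, the choices that
were genuinely open when building it, the synthetic data the tests run
on, and the limitations of both.

# Cohort model and covariate correction

A cohort is a tibble with one row per patient: demographics, an
optional diagnosis label among CONTROL (subjective cognitive decline),
AD, FTD and VAD, and up to 17 features across four modalities
(`feature_catalog()`).  Missing measurements are first-class: the
classifier only ever uses observed values, so no imputation exists
anywhere in the package.

Every continuous feature is corrected for age and sex before entering
the classifier: a per-feature least-squares model `value ~ age + sex`
is fitted on the *control group only* and the residual plus the
control mean replaces the raw value.  Controls-only fitting avoids
absorbing disease effects into the correction (an AD-heavy pooled fit
would partially regress out the disease signal itself); adding the
control mean back keeps corrected values on the measurement scale.
Binary features (APOE carrier status) are not corrected — a
residualized indicator is no longer the evidence "carrier yes/no" the
fitness machinery expects.  Correction is idempotent in effect:
refitting the covariate models on a corrected cohort returns
coefficients of zero up to numerical noise, which the test suite
asserts.

# The Disease State Index

For one feature and one ordered pair of groups (positive, negative),
the reference cohort defines a fitness function evaluated at the
patient's value $x$ used as a cutoff:

$$f(x) = \frac{FN(x)}{FN(x) + FP(x)}$$

with $FN$ the share of positive-group reference values below the
cutoff and $FP$ the share of negative-group values at or above it.
$f$ rises from 0 below the pooled reference minimum to 1 above the
pooled maximum and is weakly monotone in between.  Conventions that
the formula alone does not fix:

* **Orientation.**  Whether high or low values indicate the positive
  group is chosen per (feature, pair) as the direction maximizing
  Youden's J on the reference data, ties toward higher-is-positive.
  This keeps the method fully data-driven; no clinical direction
  table is hard-coded.
* **Evaluation between reference points.**  $FN$ and $FP$ are step
  functions of the empirical counts (strict `<` for $FN$, `>=` for
  $FP$).  On the separation gap where $FN + FP = 0$ (possible only
  between the negative group's maximum and the positive group's
  minimum when the groups are disjoint), $f$ is linearly interpolated
  in $x$ from 0 to 1, which keeps it defined and monotone.
* **Degenerate references.**  If all reference values of both groups
  are identical, $f \equiv 0.5$ with a flag; its relevance is 0, so it
  can never influence a result.

**Relevance** is $\max_c(\text{sens}(c) + \text{spec}(c) - 1)$ over
all cutoffs, under the chosen orientation — the maximum is what makes
relevance a property of the feature rather than of an arbitrary
threshold.  Features with relevance 0 carry weight 0; if every
observed feature has weight 0 the pairwise DSI is the neutral 0.5.

The pairwise DSI is the relevance-weighted mean of fitness values over
the features observed for the patient and fitted for the pair (a
feature enters a pair only with at least `min_ref = 5` observations in
both groups; below that the empirical rates are too granular).  Six
canonical pairs are fitted; the reversed comparison is defined as the
complement $1 - DSI$, which halves the fitting cost and enforces the
symmetry exactly.  The total DSI of a group is the unweighted mean of
its three pairwise values; the predicted class is the argmax with a
fixed tie-break order (CONTROL < AD < FTD < VAD, ties flagged).  The
test suite verifies the whole chain against an independent brute-force
implementation (direct counting loops, exhaustive midpoint cutoff
scans) to $10^{-9}$ on small references.

# Probability of correct class

A high top DSI $d_1$ or a wide margin $\delta = d_1 - d_2$ to the
runner-up group warrants more confidence than a bare class label.  PCC
makes this local and personal: the share of correctly classified
reference cases whose $(d_1, \delta)$ lie close to the patient's.

* Reference points are built by **leave-one-out**: each reference case
  is classified under a model refitted without it (only the pairs
  containing the case's own group actually change, which keeps the
  build cheap).  Without this, a case's own values would inflate its
  fitness functions and the points would be optimistic.
* "Close to" is a **k-nearest-neighbor** query on z-standardized
  $(d_1, \delta)$, $k = \max(20, \lceil 0.1 N \rceil)$, with all
  points tied at the k-th distance included so results do not depend
  on sort order.  The neighborhood definition is a reconstruction —
  the published description of the estimator is not precise enough to
  pin it down — and is deliberately isolated behind `estimate_pcc()`.
* One PCC model belongs to one feature subset.  Confidence before and
  after adding CSF lives in different $(d_1, \delta)$ geometries, so
  the triage workflow carries a no-CSF and a with-CSF model.

`pcc_calibration()` quantifies how well PCC tracks empirical accuracy
on a held-out cohort, binned by estimated PCC.  On default synthetic
cohorts at $n = 2000$ the calibration is good globally (mean PCC
matches overall accuracy to well under 0.01) and in the dense
high-confidence region, but the sparse mid-confidence bins (PCC
0.6–0.8) show a systematic *over*-estimate of up to about 0.1: with a
global $k$, neighborhoods of low-confidence queries reach into the
dense high-accuracy cloud.  Bins near 50–100 patients additionally
carry binomial noise of 0.05–0.07 per seed.  A per-bin agreement
within 0.07 is therefore *not* reliably achieved by this estimator at
this cohort size — smaller $k$ trades the bias for variance without
fixing it.  This is a known property of plain k-NN confidence
estimation under strongly skewed score densities; kernel weighting or
monotone recalibration would reduce it but are deliberately out of
scope (the estimator is kept exactly as simple as described).  Users
should read mid-range PCC values as slightly optimistic.

# The scenario engine

`run_scenarios()` evaluates four testing policies; all thresholds are
parameters (`pcc_threshold` default 0.80, the appropriate-use gate
`auc_dsi_ad_threshold` default 0.6 on the no-CSF DSI for AD).

* **A — stepwise decision support.**  Step 1: patients with no-CSF PCC
  at or above the threshold are diagnosed directly, no CSF (decision
  group 1).  Step 2: for the rest, the positive and negative CSF
  profiles are substituted (all three analytes at once, on the
  corrected scale) and the with-CSF PCC recomputed; if neither
  simulation reaches the threshold, CSF is predicted unhelpful (group
  2).  Step 3: otherwise actual CSF values are used and the final PCC
  decides diagnosed (group 3) versus tested-but-undiagnosed (group 4,
  suggestive of mixed pathology).  The trigger records which
  simulation(s) fired (`positive_only` / `negative_only` / `both`).
* **B — no CSF**, **D — CSF for all**: the two ends of the spectrum.
* **C — appropriate-use criteria**: CSF exactly for patients whose
  no-CSF DSI for AD exceeds the gate.  The gate uses the no-CSF model
  because the decision to order CSF cannot depend on CSF.

The simulated profiles are the per-analyte medians of the corrected AD
group (positive) and the corrected control group (negative) — a
coherent "textbook AD" and "textbook normal" CSF result.  Decision
logic is pure thresholding of a per-patient evaluation table
(`triage_evaluate()`), which is what makes `sweep_pcc_cutoffs()` over
a grid of thresholds cheap.  Structural guarantees, all
property-tested: groups 1–4 partition the cohort; everyone diagnosed
under B is in group 1 under A; the share diagnosed is weakly
decreasing in the threshold for every scenario; B tests nobody, D
everybody, C exactly the gate set.  A patient selected for testing who
lacks an actual CSF value is a hard error in scenarios A and C;
scenario D carries such patients with a flag, mirroring the
classifier's missing-data tolerance.

# Synthetic cohorts

Patient-level data cannot be shipped, so the test bed is a seeded
generator (`generate_cohort()`) emulating the published cohort
structure: four groups of 139/286/82/28, per-group feature means and
SDs, per-group age distributions and sex/APOE frequencies, and
per-feature missingness from 1% (MMSE) to 24% (TMT-B), APOE 12%,
MRI and CSF always present (both were inclusion criteria for the
cohort the defaults emulate).

Design of the marginals: published tables give means and SDs only.
Truncated normals would respect the physiologic bounds but shift the
realized moments (control WMH 2.9 ± 4.7 ml truncated at 0 would gain
~25% of its mass; MMSE 28 ± 1 is pinned at 30), so each feature is a
scaled Beta on its plausible range, moment-matched to the configured
mean/SD — exact first two moments, correct support, and realistically
skewed where the table implies skew.  Features are coupled by a
Gaussian copula with two factors: a within-modality common factor
(equicorrelation 0.3) and the latent normal rank of age with loading
0.3 and a fixed clinical sign per feature (cognition and AB42 decline
with age, atrophy/lesions/tau rise).  Routing the age effect through
the copula rather than adding a slope keeps the marginals — and hence
the configured moments — exact while still giving the age/sex
correction a real monotone effect to remove.

`separation_scale` interpolates *every* group-specific parameter
(feature means and SDs, age, sex and APOE frequencies) between the
pooled size-weighted value (0) and the configured profile (1), beyond
(> 1) for exaggerated contrasts.  At 0 the four groups are literally
one distribution, which is what makes the chance-level tests (accuracy
and mean PCC ≈ 0.25) meaningful.  At exaggerated separations a mean
can approach its range bound; means are pulled just inside the Beta
feasibility region, SDs capped at the bounded-range feasibility limit,
and a mean that would need to move by more than 20% of the range is an
error.

What the generator does *not* emulate: the real joint covariance
beyond one correlation knob, the three-center structure, informative
missingness (the generator is MCAR), mixed pathology beyond what group
overlap produces, and measurement noise idiosyncrasies.  Passing tests
therefore demonstrate the correctness and internal consistency of the
machinery under a controlled data-generating process — not clinical
performance on real patients.

# Numerical conventions and problem sizes

* Percentages print as nearest integers, halves away from zero.
* The two-sample proportion test uses the pooled-variance z and the
  unpooled Wald 95% CI, no continuity correction; it treats the two
  scenario arms as independent samples (the convention of the test it
  reproduces) even though they are the same patients.
* Ties: argmax ties are broken by the fixed group order and flagged;
  k-NN distance ties at the k-th neighbor are all included;
  orientation ties favor higher-is-positive.
* DSI/fitness/relevance equality with the brute-force oracles is
  asserted to $10^{-9}$; covariate-correction algebra to
  $10^{-9}\cdot$scale.
* Moment-recovery checks use 3 standard errors with the CLT SE for
  means and a kurtosis-adjusted SE for SDs (the normal-theory
  $s/\sqrt{2n}$ is wrong under skewed Beta marginals).
* Test-suite problem sizes, chosen to exercise the study conditions
  while keeping a full run in minutes: oracle comparisons at 8–10
  cases per group; chance-level checks at $n = 400$; calibration at
  $n = 2000$ reference and evaluation over 5 seeds; moment recovery at
  $n = 5000$ per group; separation monotonicity at the default
  $n = 535$ over 5 seeds and scales $\{0.5, 1, 2\}$.

# Limitations

* The PCC neighborhood is a reconstruction (see above); its
  mid-range over-confidence is documented rather than patched.
* Covariate models are linear in age; a strongly nonlinear age effect
  would leave residual structure (the generator's copula age effect is
  monotone but not exactly linear — correction removes its linear
  component, which the idempotence tests confirm is all that a linear
  model can claim).
* The published cohort's headline shares (26% tested, 71% diagnosed)
  depend on the original three-center patient data and are not
  reproducible from synthetic cohorts; the package reproduces the
  *arithmetic* on the published counts exactly and the *structure*
  (partition, nesting, monotonicity, trigger taxonomy) on synthetic
  data.
* MRI quantification, assay chemistry and diagnostic criteria are all
  upstream of this package: markers arrive as numbers.
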