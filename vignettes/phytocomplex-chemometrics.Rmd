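---
title: "Linking metabolite profiles to antioxidant capacity: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking metabolite profiles to antioxidant capacity: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

phytoPLS models the relationship between the metabolite composition of fruit
extracts — anthocyanins, quercetin glycosides, hydroxycinnamic acids and
ascorbic acid, quantified in mg per 100 g fresh weight — and their in vitro
antioxidant capacity measured by plate assays (FRAP at 593 nm, ABTS at
734 nm) and expressed as Trolox-equivalent antioxidant capacity (TEAC,
mmol TE/kg). This vignette records the statistical models the package
implements, the tunable parameters that matter, and the design decisions
taken where the methodology was genuinely open.

## Assay calibration

Trolox standard curves are fit by ordinary least squares with a free
intercept (`fit_standard_curve()`): blank wells have nonzero absorbance, so
forcing the line through the origin would bias low readings. A sample's
Trolox-equivalent concentration is `(A - intercept) / slope` in the units of
the standards (mM); `teac_from_absorbance()` converts to mmol TE per kg of
starting material by multiplying with the extract dilution factor and the
solvent-to-mass ratio. Because the extraction uses a fixed number of solvent
volumes per gram of powder (default: nine volumes, as in acidified-methanol
FRAP protocols), the conversion is independent of the powder mass itself —
only `solvent_volumes * dilution_factor` enters. Replicate absorbances below
the blank clamp to zero TEAC and raise a flag rather than an error: plate
noise routinely produces small negatives on weak samples.

## Preprocessing

Untargeted LC-MS peak-area matrices carry per-sample global intensity
differences (injection volume, source drift). `median_fold_change_normalize()`
removes them: the reference profile is the per-feature *geometric mean* over
samples (computed on features detected in every sample), each sample's
factor is the median of its feature-wise ratios to that reference, and
factors are rescaled to median 1. The geometric-mean reference is a
deliberate choice: with it, renormalizing an already-normalized matrix
provably returns factors of exactly 1 (the recomputed raw factors collapse
to a constant, which the median rescale maps to 1), so the operation is
idempotent to machine precision. A per-feature *median* reference — the other
common convention — does not have this property: iterating it cycles without
converging, which we verified numerically before settling on the geometric
mean. Zeros are excluded from the ratio median rather than pseudo-counted,
keeping the normalization scale-free; the pseudo-count (default 1 area unit)
applies only at the log step.

`log_mean_center()` uses the natural log for feature matrices (the base is
irrelevant after centering) and stores column means so the transform is
invertible. Targeted concentration tables are modelled untransformed by
default (`log_x = FALSE` in `build_model_inputs()`); the response can be
modelled as log10(TEAC), the usual convention for FRAP. Variables are
centered but not unit-variance scaled by default; scaling is a documented
option, and the cross-validation re-estimates centering inside each
training fold in either case so held-out samples never leak into the model.

## PLS regression, Q² and VIP selection

`fit_pls1()` implements NIPALS projection to latent structures for a single
response. With one response the weight vector is closed-form per component
(`w_a` proportional to `X_a' y`), so no inner iteration is needed; only X is
deflated. Variable influence on projection is

    VIP_j = sqrt( p * sum_a SSY_a (w_aj / ||w_a||)^2 / sum_a SSY_a ),

with `SSY_a = q_a^2 t_a' t_a`, normalized so the mean squared VIP is exactly
1 — a variable with VIP above 1 contributes more than an average variable.

Predictive performance is estimated by seven-fold full cross-validation:
`Q2 = 1 - PRESS / TSS` with TSS about the training-fold means, and
`SDECV = sqrt(PRESS / n)` (the n convention, not n − 1; both are in use and
the choice is flagged here). Folds are random with a recorded seed and are
stratified by cultivar when labels are available, so no fold loses an
entire cultivar by chance. The component count A is chosen by maximizing Q²
over 1..min(5, rank); a fixed-A override exists.

`select_by_vip()` scans candidate VIP thresholds — the sorted unique VIP
values plus zero — refits on the variables above each threshold, and
recomputes Q² on a shared fold partition so the values are comparable.
Two rules are provided for picking the winner:

* `rule = "max"`: the threshold with the largest Q², ties toward fewer
  variables.
* `rule = "1se"` (default): the sparsest threshold whose Q² is within one
  standard error of the maximum, the standard error being estimated from
  the spread of the squared cross-validation residuals.

The default is the 1-SE rule because cross-validated Q² paths are nearly
flat around their optimum: a strict argmax frequently drags along variables
that correlate with the response only by chance in the given sample, since
removing them changes Q² by less than its own sampling noise. The 1-SE rule
is the standard parsimony device for exactly this situation and, in our
simulations with planted informative variables, removes the chance
correlates without ever discarding genuine signal.

The over-fitting control is a response permutation test
(`permutation_test()`): the response is permuted and the cross-validated Q²
(maximized over A, the same statistic the model selection uses) is
recomputed; `p = (1 + #{Q2_perm >= Q2_obs}) / (n_perm + 1)`, so p is never
zero. Default 1000 permutations standalone; inside stability selection a
19-permutation gate is used instead — the smallest count that can resolve
p <= 0.05 under the +1 correction — because the gate runs once per
subsample and only needs to separate clearly informative models from
clearly uninformative ones.

`post_transform()` rotates a fitted model so a single component
`tp = X_c b / ||b||` carries all the response-predictive variation, with the
remaining components re-orthogonalized against it. The coefficient vector is
untouched, so predictions are bitwise unchanged; only the score-space
presentation rotates. We guarantee the contract (prediction invariance, one
predictive component, correlation 1 with the fitted values), not any
particular rotation matrix.

## Monte-Carlo stability selection

`stability_select_pls()` draws subsamples by including each sample
independently with probability 0.70 (the "prior probability"
interpretation of Monte-Carlo subsampling; a fixed-quota mode is available),
runs the full VIP selection on each of 1000 subsamples, and reports
per-variable selection frequencies. Variables selected in more than 50% of
models (strict inequality) form the relevant set. Each model's standard
deviation error in prediction (SDEP) is computed on its excluded samples
from the selected-variable refit — the natural reading of predicting "the
samples excluded during subsampling"; whether the original analysis used
the selected refit or the full model is not documented anywhere we know of,
so this choice is recorded as an assumption. Subsamples whose permutation
gate fails (p > 0.05) contribute an empty selection, so pure-noise data
yields empty relevant sets rather than stable false positives. All
per-subsample seeds derive deterministically from one master seed.

The simple-linear-regression analogue (`stability_select_slr()`) regresses
the response on each variable separately per subsample and averages R²,
out-of-subsample SDEP and the slope-test p-value; "selection" within a
subsample is slope p < 0.05 (an assumption — the approach is described only
as "a similar strategy" in the tradition this follows), aggregated by the
same frequency rule.

## Synergy analysis of reconstituted phytocomplexes

An artificial simplified phytocomplex (ASP) is a mixture of authentic
standards at extract-matched concentrations. Removing one metabolite class
and comparing three conditions — the full mixture, the depleted mixture and
the isolated class — distinguishes interaction types: the synergy index is

    index = (TEAC_full - TEAC_depleted) - TEAC_component,

zero under additivity, positive when the class contributes more in context
than alone (synergy), negative for antagonism. Classification follows a
confidence interval for the index: synergistic if the lower bound exceeds
zero, antagonistic if the upper bound is below zero, additive otherwise.
Antagonism is included even though depletion studies often report only the
additive/synergistic dichotomy, because the sign structure of the decision
rule forces the third class and the mixture-interaction literature reports
it.

Uncertainty is quantified by a t-calibrated parametric bootstrap on the
index: draws are `index + se * t(df)` with `se^2 = sum sd_i^2 / n_i` over
the three conditions and Satterthwaite degrees of freedom. With n = 3
replicates per condition a nonparametric bootstrap is degenerate, and a
plain normal plug-in (`Normal(mean, sd^2/n)` per condition) ignores the
uncertainty of the variance estimates: its nominal 95% intervals cover an
additive truth only ~89% of the time at n = 3 in our calibration
simulations, while the Satterthwaite-t form achieves ~97%. Conditions are
treated as independent (separate wells; no pairing). A nested depletion —
e.g. testing quercetin removal from an already anthocyanin-free baseline —
is expressed simply as a separate design whose "full" condition is the
reduced mixture.

`coverage_fraction()` reports the ratio of an ASP's TEAC to its natural
extract's TEAC with a bootstrap interval, the quantity used to say how much
of an extract's activity a reconstitution accounts for.

## MS/MS annotation rules

Negative-mode fragmentation trees are annotated by two rule families:
neutral losses of 132, 146 and 162 Da on any parent-to-fragment edge
(precursor to MS2 or MS2 to MS3) mark pentose, deoxyhexose and hexose
conjugates; and the diagnostic chains 179 → 135 (caffeic), 163 → 119
(coumaric), 191 → 173 (quinic) and 193 → 134/149/178 (ferulic) identify
hydroxycinnamic-acid derivative classes. The default mass tolerance is
0.5 Da (ion-trap unit resolution; no tolerance is standard in this rule
set, so it is exposed as a parameter). Ferulic annotation accepts any one
of its three MS3 children by default because the rule lists them without
conjunction semantics; an "all" mode is available. Annotation is invariant
to node order and monotone in tolerance: widening the window can only add
annotations.

## The synthetic study generator

`sim_config()` defines the simulated study; its defaults are the conditions
every test and the acceptance script run under, chosen once:

* design 18 cultivars x 2 vintages x 3 replicate pools (108 samples), the
  scale of the multi-cultivar cherry studies this package targets;
* per-cultivar mean concentrations drawn inside published ranges:
  anthocyanin totals 14–114 mg/100 g fw, ascorbic acid 7–15, hydroxycinnamic
  acids up to 65, quercetin glycosides up to 7; class totals split between
  glycosides with a cultivar-varying share so no two metabolites are
  collinear;
* a weak multiplicative vintage effect (log-SD 0.05, shared across cultivars
  per metabolite) under a dominant cultivar effect, reproducing the observed
  variance hierarchy; replicate pools carry mean-one log-normal noise
  (CV 0.15);
* TEAC responses are linear in concentrations (unit activities ranked
  cyanidin-3-O-rutinoside > ascorbate > cyanidin-3-O-glucoside > others)
  plus optional pairwise product interaction terms — the minimal form able
  to express the additive/synergistic dichotomy — with Gaussian noise
  (SD 1 mmol TE/kg, sized so default fits reach R² ~ 0.8);
* each metabolite expands into a monoisotopic LC-MS feature, a +1
  isotopologue and an adduct at fixed relative intensity, all scaled by a
  log-normal per-sample intensity factor (log-SD 0.25) that the
  normalization must recover, plus 104 uninformative features.

The generator emulates the statistical structure the analysis assumes —
cultivar-dominant variance, multiplicative intensity artifacts,
isotope/adduct correlation — and deliberately not chromatography-level
reality: no peak shapes, no retention drift, no missing-value mechanism, no
matrix effects. Passing tests therefore demonstrate correctness of the
statistical chain under its stated assumptions, not robustness to every
pathology of real spectra. Per-sample assay values for real cultivars are
not publicly available, so the response generator's parameters are
calibrated to plausible ranges rather than to any study's raw data, and the
depletion-panel fixtures use synthetic compositions.

## Problem sizes used in validation

The test suite validates oracle equivalences on 100 random small instances
(n ≤ 30, p ≤ 8), parameter recovery with 3 informative + 20 noise variables
at n = 54 and 200 subsamples, null calibration on 400 simulated datasets
(permutation test, 99 permutations each) and 50 stability runs of 100
subsamples, and synergy classification on 100 simulated depletion panels.
The acceptance script runs the full default study (108 samples, 1000
stability subsamples, 999 permutations) plus reduced-size replicas of the
same checks.

## Known limitations

* PLS1 only: one response at a time; no PLS2, no kernel or orthogonalized
  variants beyond the post-transformation contract.
* The SDECV n-versus-(n−1) convention and the center-only default mirror
  common practice but are assumptions; both are parameterized.
* Bootstrap classification of synergy treats condition means as normal with
  estimated variances; with n = 3 this is honest about df but still a
  small-sample approximation.
* The 1-SE selection rule trades a small amount of in-sample Q² for
  stability; analyses that require the literal Q²-argmax threshold should
  set `rule = "max"`.
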