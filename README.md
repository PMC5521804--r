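# phytoPLS

Chemometric modelling of the link between fruit metabolite composition and
in vitro antioxidant capacity.

Plant extracts are mixtures: anthocyanins, quercetin glycosides,
hydroxycinnamic acids and ascorbic acid all reduce the FRAP and ABTS assay
probes, and the measured Trolox-equivalent antioxidant capacity (TEAC,
mmol TE/kg) may be the additive sum of those contributions — or more,
when components interact synergistically. phytoPLS implements the full
analysis chain used to dissect this question in multi-cultivar fruit
studies:

* **Assay calibration** — ordinary-least-squares Trolox standard curves and
  conversion of plate absorbances (593 nm FRAP, 734 nm ABTS) to TEAC through
  the extraction dilution arithmetic.
* **Preprocessing** — median fold change normalization of untargeted LC-MS
  feature matrices (geometric-mean reference; exactly idempotent),
  log transform and mean centering.
* **PLS regression with VIP selection** — NIPALS PLS1; variable influence on
  projection, `VIP_j = sqrt(p Σ_a SSY_a (w_aj/‖w_a‖)² / Σ_a SSY_a)`,
  normalized so mean VIP² = 1; seven-fold cross-validated `Q² = 1 − PRESS/TSS`
  and `SDECV = √(PRESS/n)`; VIP-threshold selection by Q² with a
  one-standard-error parsimony rule; response permutation test against
  over-fitting; PCA; predictive post-transformation.
* **Monte-Carlo stability selection** — 1000 random subsamples at inclusion
  probability 0.70, VIP-based PLS per subsample, relevant variables =
  selected in >50% of models, out-of-subsample SDEP; plus a simple linear
  regression analogue (per-variable R², mean SDEP, mean p).
* **Synergy analysis** — artificial simplified phytocomplex depletion
  experiments scored by the synergy index
  `(TEAC_full − TEAC_depleted) − TEAC_component`, with a t-calibrated
  parametric bootstrap classifying each metabolite class as additive,
  synergistic or antagonistic.
* **MS/MS annotation** — glycoside neutral losses (132/146/162 Da = pentose/
  deoxyhexose/hexose) and diagnostic hydroxycinnamic-acid fragment chains
  (179→135 caffeic, 163→119 coumaric, 191→173 quinic, 193→134/149/178
  ferulic).
* **Synthetic study generator** — cultivar-dominant metabolite tables,
  TEAC responses with optional interaction terms, feature matrices with
  isotope/adduct structure and plate simulations, so the whole chain is
  testable end to end.

## Worked example

```r
library(phytoPLS)

# a synthetic 18-cultivar x 2-vintage x 3-replicate study
cfg    <- sim_config(seed = 42)
tab    <- generate_metabolite_table(cfg)     # mg / 100 g fresh weight
resp   <- generate_responses(tab, cfg)       # TEAC, mmol TE/kg
inputs <- build_model_inputs(tab, resp)

sel <- select_by_vip(inputs$X, inputs$y, folds = 7, seed = 1, n_perm = 999)
sel
#> VIP-based PLS selection: threshold 0.357 -> 2/7 variables
#> PLS1 model: A = 1, p = 2, R2 = 0.828, Q2 = 0.817, SDECV = 1.06
#>   permutation p = 0.001

stability_select_pls(inputs$X, inputs$y, n_subsamples = 200, seed = 2)
#> Stability selection: 200 subsamples, prior 0.70
#>   relevant (frequency > 0.50): cyanidin_3_rutinoside, cyanidin_3_glucoside
#>   mean SDEP = 1.072
```

The model explains ~83% of the TEAC variance with one latent component and
keeps that predictive power under seven-fold cross-validation (Q² 0.82);
the permutation p of 0.001 says no permuted response came close. Stability
selection identifies the two anthocyanins — the dominant antioxidants in
this simulation — as the only variables selected in more than half of 200
subsample models; the mean SDEP (1.07 mmol TE/kg) is the typical prediction
error on held-out samples.

A depletion panel on a reconstituted phytocomplex with a planted
anthocyanin × quercetin / anthocyanin × ascorbate interaction:

```r
demo  <- synthetic_depletion_panel(seed = 3)
panel <- run_depletion_panel(demo$designs, demo$plates, demo$curve,
                             demo$protocol, seed = 4)
panel[panel$design == "ST", c("class", "teac_full", "teac_depleted",
                              "teac_component", "synergy_index",
                              "classification")]
#>                 class teac_full teac_depleted teac_component synergy_index classification
#>           anthocyanin      14.6          1.50          7.473         5.657    synergistic
#>             quercetin      14.6         12.83          0.123         1.677    synergistic
#>  hydroxycinnamic_acid      14.6         14.32          0.206         0.107       additive
#>         ascorbic_acid      14.6          9.61          1.017         4.012    synergistic
```

Removing anthocyanins, quercetins or ascorbic acid loses far more activity
than those components show in isolation (synergy), while hydroxycinnamic
acids contribute exactly their own activity (additive) — and in the
anthocyanin-free designs of the same panel the synergy disappears,
reproducing the anthocyanin-dependence of the interaction.

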