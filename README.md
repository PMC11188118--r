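# traumaViper

Analysis toolkit for multiplex plasma-protein (cytokine/chemokine)
panels in trauma cohorts, built around explicit handling of assay
limits of detection (LOD), and for deriving compact survival scores
from such panels. It is aimed at biostatisticians and immunologists
analyzing subject-by-analyte concentration tables (pg/mL) with
per-analyte detection windows and clinical covariates (trauma vs
control, age, sex, trauma activation level, discharge outcome).

## What it computes

* **LOD-aware preprocessing** — above-LOD cells set to
  `upper_lod * 1.1`; below-LOD cells left-censored for regression,
  zeroed for display (with 0–100 within-marker normalization), or
  substituted with `min(curve_min, lowest detected)` for ratio work.
* **Left-censored (Tobit) regression** per analyte, by maximum
  likelihood on the censored Gaussian log-likelihood

  `ℓ(β,σ) = Σ_obs [log φ((y−Xβ)/σ) − log σ] + Σ_cens log Φ((c−Xβ)/σ)`,

  with coefficients reported as percent change `(e^β − 1) × 100` and
  significance by **directional FDR**: one-sided Wald p-values
  adjusted (Benjamini–Hochberg) separately within the
  positive-association and negative-association families at
  FDR 0.01.
* **Below-LOD prevalence comparison** (Fisher exact, BH-adjusted).
* **All-pairs ratio screening** — per-subject concentration ratios for
  every ordered analyte pair, median fold change deceased vs
  discharged-to-home, antisymmetric on the log scale.
* **Random-forest permutation importance** (own compiled forest;
  Balanced-Random-Forest sampling for rare outcomes) with the
  per-iteration 0–100 relative normalization and median-over-10
  iterations selection at threshold 10.
* **ROC metrics** — trapezoidal AUC ≡ Mann–Whitney statistic (ties ½),
  DeLong confidence intervals, Wilson score intervals for
  sensitivity/specificity, Youden and max-sensitivity operating
  points.
* **VIPER survival score** — a five-analyte logistic score on log
  concentrations, derived by intersecting the ratio screen with
  deceased-vs-discharged importance and pruning by per-analyte AUC,
  then evaluated by stratified 5-fold cross-validation overall and by
  trauma-activation level.
* **Synthetic cohort generator** — a 59-analyte, 1000-trauma +
  50-control world with realistic censoring, effect sizes, 2.5%
  mortality and five outcome-linked analytes, so the entire pipeline
  is testable without patient-level data.

## Worked example

```r
library(traumaViper)

sim   <- simulateCohort(paperlikeConfig(seed = 1))
panel <- sim$panel
panel
#> CytokinePanel: 59 analytes x 1050 subjects
#>   groups: control=50, trauma=1000
#>   cells: below=22728, within=39208, above=14, missing=0

## trauma vs control, left-censored regression + directional FDR
proc <- applyLodRules(panel, "analysis")
res  <- directionalFdr(fitPanel(proc, "univariable_group"))
sum(res$significant)
#> [1] 24
head(res[res$significant, c("analyte", "percent_change", "ci_lo", "ci_hi", "direction")], 3)
#>    analyte percent_change     ci_lo     ci_hi direction
#> 2      MIF       21.16587  10.86519  32.42361  positive
#> 10   MCP-4      -26.79170 -37.75030 -13.90393  negative
#> 11   IP-10      -33.94768 -45.72275 -19.61811  negative

## derive and evaluate the survival panel
der <- derivePanel(panel, seed = 1)
der$final_panel
#> [1] "IL-29"  "IL-6"   "IL-21"  "VEGF-A" "IL-10"
evaluateByLevel(panel, der$final_panel, seed = 1)
#> ViperEvaluation (5-fold cross-validated)
#>   all      AUC 0.9743 (0.9549-0.9938)
#>   level1   AUC 0.9657 (0.9214-1.0000)
#>   level4   AUC 0.9700 (0.9408-0.9993)
```

The 24 significant associations are the generator's embedded
trauma shifts that are detectable at this cohort size (MIF up ~21%
against its configured +18%, the chemokine block down 27–95%); the
derived five-analyte panel recovers exactly the five outcome-linked
analytes, and the cross-validated score separates deceased from
discharged patients with AUC ≈ 0.97 overall.

Real data enter through `readPanel(panel_csv, lod_csv, clinical_csv)`
(subjects × analytes concentrations, an
`analyte,lower_lod,upper_lod,curve_min` sidecar, and a clinical
table); `runPipeline(config)` drives the whole analysis from a YAML
or list config and writes tidy CSVs, a JSON summary and a run log.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the full analysis from scratch against the installed
package — generates the default synthetic cohort from the given seed,
runs preprocessing, censored regression with directional FDR,
below-LOD prevalence, the ratio screen, permutation importance, panel
derivation and the cross-validated score evaluation — writing the
pipeline outputs next to the JSON results file. The methods behind
every stage are documented in
`vignettes/trauma-panel-methods.Rmd`.
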