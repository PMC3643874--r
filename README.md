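# bmdserum

Covariate-adjusted benchmark-dose analysis of serum perfluoroalkyl
(PFOS/PFOA) exposures and vaccine antibody responses in children.

Childhood serum concentrations of perfluorinated compounds (PFCs) have been
associated with reduced antibody responses to tetanus and diphtheria
vaccinations. For risk assessment, the question is quantitative: at what
serum concentration does the antibody concentration fall by a specified
fraction (the benchmark response, BMR) relative to an unexposed reference?
bmdserum estimates that benchmark dose (BMD) and its lower one-sided 95%
confidence limit (BMDL) — the quantity regulators divide by uncertainty
factors to set reference doses and drinking-water limits.

The package is aimed at biostatisticians and risk assessors working with
continuous outcomes in epidemiological benchmark-dose analysis.

## The model

Antibody outcomes are log-transformed and regressed on covariates and a
dose–response function constrained to f(0) = 0:

    log(antibody) = α₀ + α₁·sex + α₂·age + α₃·booster + f(d) + ε,   ε ~ N(0, σ²)

with four dose–response families (d = serum concentration, ng/mL):

* linear: f(d) = β·d
* logarithmic: f(d) = β·ln(d + 1)
* K-power: f(d) = β·d^K, K ≥ 1 (nests the linear model at K = 1)
* piecewise linear: slope change at the median exposure, continuous at the knot

plus a low-dose-threshold variant of each (flat below the lowest observed
dose) for sensitivity analysis. The BMD solves f(BMD) = ln(1 − BMR),
independently of the covariates. BMDLs come from a closed-form lower
confidence band of f for the linear-in-parameters families, and from the
iterative profile-likelihood method (χ²₁(0.90) = 2.7055 cutoff) for the
K-power family. Model fit is compared by −2 log(L), over the full sample and
over the lowest exposure quartile.

Because the underlying cohort data are not public, the package ships a
seed-deterministic synthetic cohort generator (`cohort_defaults()`,
`generate_cohort()`) calibrated to the published marginal summaries of the
431-child Faroese birth cohort, with a configurable injected dose–response.

## Worked example

Simulate a cohort with a known adverse linear effect, fit three families
with and without the low-dose threshold, and render the benchmark table:

```r
library(bmdserum)

cfg <- cohort_defaults(
  injected_effect = dose_response("linear", beta = -0.019),
  seed = 2026)
res <- run_analysis(cfg, exposures = "pfos", outcomes = "tetanus",
                    families = c("linear", "log", "piecewise"),
                    threshold = "both")
cat(render_benchmark_table(res, format = "text"), sep = "\n")
#> Outcome  Exposure  Model      Threshold  BMD_5pct  BMDL_5pct  BMD_10pct  BMDL_10pct  Fit_full  Fit_lowdose
#> tetanus  pfos      linear     no         2.80      1.44       5.76       2.95        1382.93   340.87
#> tetanus  pfos      linear     yes        9.74      8.37       12.70      9.89        1382.93   340.87
#> tetanus  pfos      log        no         0.17      0.08       0.37       0.17        1383.28   340.63
#> tetanus  pfos      log        yes        8.25      7.56       9.86       8.28        1383.28   340.63
#> tetanus  pfos      piecewise  no         4.29      0.90       8.80       1.84        1382.87   340.96
#> tetanus  pfos      piecewise  yes        11.22     7.83       15.74      8.78        1382.87   340.96
```

Reading the linear row: a 5% reduction in the tetanus antibody level
corresponds to an estimated serum PFOS concentration of 2.80 ng/mL, with a
one-sided 95% lower limit (BMDL) of 1.44 ng/mL; at a 10% BMR the doses are
exactly ln(0.90)/ln(0.95) ≈ 2.054 times higher. The log family yields much
lower benchmark doses (it is steepest near zero), while the threshold
variants — which assume no effect below the lowest observed exposure —
raise the linear BMDL several-fold. Smaller −2 log(L) indicates better fit.

Converting the linear BMDL to regulatory quantities:

```r
rfd <- derive_rfd(1.44, uncertainty_factor = 10)  # 0.144 ng/mL serum
serum_to_water(rfd, serum_water_ratio = 100)      # 1.44 ng/L drinking water
```

Individual stages are exposed as pipe-friendly functions:
`fit_dose_response()` (with broom-style `tidy()`/`glance()` methods and
`autoplot()`), `compare_fits()`, `compute_bmd()`,
`compute_bmdl_closed_form()`, `compute_bmdl_profile()`,
`benchmark_doses()`, `read_cohort()`/`write_cohort()`. A thin command-line
wrapper lives at `inst/cli/bmdserum.R`
(`simulate` / `analyze` / `report` subcommands).

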