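---
title: "Benchmark-dose methods for serum-PFC immunotoxicity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmark-dose methods for serum-PFC immunotoxicity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bmdserum)
library(dplyr)
```

## The problem

Perfluorinated compounds (PFCs) such as PFOS and PFOA are persistent
environmental contaminants with experimental and epidemiological evidence of
immunotoxicity. In children, serum PFC concentrations have been associated
with reduced antibody responses to routine tetanus and diphtheria
vaccinations — a clinically meaningful, continuous measure of immune
function. Regulatory risk assessment asks: at what serum concentration does
the antibody response fall by a given fraction relative to an unexposed
reference? That dose is the benchmark dose (BMD), and its lower one-sided
95% confidence limit (BMDL) is the quantity regulators divide by uncertainty
factors to obtain a reference dose (RfD).

bmdserum implements this covariate-adjusted benchmark-dose analysis as a
reusable pipeline, together with a synthetic cohort generator calibrated to
the published summary statistics of a Faroese birth cohort (431 children
with complete serum measurements at ages 5 and 7), so that every stage can
be exercised and validated without access to the original individual-level
data, which are not public.

## The model

Antibody concentrations are right-skewed and are analysed on the natural-log
scale. The regression model is

$$\log(\text{antibody}) = \alpha_0 + \alpha_1\,\text{sex} +
\alpha_2\,\text{age} + \alpha_3\,\text{booster} + f(d) + \varepsilon,
\qquad \varepsilon \sim N(0, \sigma^2),$$

where $d$ is the child's serum PFOS or PFOA concentration (ng/mL) at age 5
and $f$ is a dose–response function constrained to $f(0) = 0$. Four families
are provided:

| family | $f(d)$ | parameters |
|---|---|---|
| linear | $\beta d$ | $\beta$ |
| log | $\beta \log(d + 1)$ | $\beta$ |
| K-power | $\beta d^K$, $K \ge 1$ | $\beta, K$ |
| piecewise | $\beta \min(d, m) + \beta_2 \max(d - m, 0)$ | $\beta, \beta_2$ |

"log" is always the natural logarithm. The piecewise curve is continuous at
the knot $m$, which defaults to the in-sample median exposure; only the
slope changes there. The K-power family nests the linear family at $K = 1$.

Each family has a low-dose-threshold variant used as a sensitivity analysis:
$f_{\text{thr}}(d) = f_0(\max(d, d_{\min})) - f_0(d_{\min})$, flat below
$d_{\min}$ and identical to the base curve (up to the baseline shift) above
it. $d_{\min}$ defaults to the minimum observed exposure — the point below
which the data carry no information about the curve. This matters because
the fitted dose–response can be steep enough that the BMD falls below the
lowest observed dose; the threshold variant shows how much the results
depend on that unobserved region. We fix $d_{\min}$ at the minimum observed
dose rather than estimating it: it is a sensitivity device, not a model
parameter, and estimating a free breakpoint at the edge of the support is
statistically ill-behaved.

### A note on the log family's units

The $+1$ offset in $\beta\log(d+1)$ is applied to the dose in ng/mL. The
resulting BMD is therefore not invariant to a change of dose units, unlike
the linear and piecewise families. This is inherent to the functional form;
we keep ng/mL throughout and document the dependence rather than attempting
to remove it.

## Fitting

For the linear, log and piecewise families — and all threshold variants —
the model is linear in its parameters, so the maximum-likelihood estimate
under normal errors is the exact least-squares solution; no iterative
optimisation is involved. The K-power family is non-linear in $K$ only, so
the likelihood is profiled: for each trial $K$ the inner fit is an exact
linear solve, and the outer search runs a 29-point grid over
$K \in [1, 15]$ followed by a bounded scalar minimisation (tolerance
$10^{-6}$). The boundary $K = 1$ is a legitimate profile minimum and is
reported as such — in that case the fitted model is identical to the linear
model, and downstream reports flag it accordingly.

Two variance conventions coexist deliberately:

* $-2\log L$ uses the ML variance $\hat\sigma^2 = RSS/n$, so
  $-2\log L = n\log(2\pi\hat\sigma^2) + n$ and model comparisons are
  likelihood-based;
* the coefficient covariance uses the unbiased $RSS/(n-p)$ convention, so
  confidence limits match standard regression software.

Additive constants cancel in comparisons either way.

### The low-dose fit diagnostic

Because regulatory interest focuses on low exposures, each fit also reports
$-2\log L$ accumulated over the children in the lowest exposure quartile
(first quartile by the linear-interpolation sample quantile; ties at the cut
included). By default these per-observation contributions are evaluated at
the *full-sample* parameter estimates: the diagnostic then measures how well
the model fitted to everyone describes the low-dose children, which is the
question the sensitivity analysis asks. Re-fitting within the subset is
available (`lowdose_refit = TRUE`) but is a different question — it always
improves the subset likelihood and no longer diagnoses the full model.

The covariate `age` entering the model is the age at the 7-year examination,
when the antibody outcomes are measured; booster type uses reference-level
dummy coding with the lexicographically first level as reference.

## Benchmark dose and its confidence limit

With a log-transformed outcome, a fractional reduction BMR in the outcome
corresponds to an additive shift $\log(1-\text{BMR})$ on the log scale, so
the BMD solves $f(\text{BMD}) = \log(1-\text{BMR})$ independently of the
covariate coefficients. Closed forms exist for the linear, log and K-power
families; the piecewise family and all threshold variants are solved by
bisection on the monotone curve to relative tolerance $10^{-9}$, with a
bracket expanding geometrically from 1 up to $10^3 \times$ the maximum
observed dose. Both 5% and 10% BMR are computed by default: 10% is the
toxicological convention, 5% is common for adverse effects in human studies.

Two BMDL constructions are provided.

**Closed form** (linear-in-parameters families): the dose effect is
$f(d) = c(d)^\top\gamma$ with known $c(d)$, so a pointwise lower one-sided
confidence band of $f$ is
$\hat f(d) - t_{1-\alpha,\,n-p}\sqrt{c(d)^\top \Sigma\, c(d)}$, and the
BMDL is the dose where the band crosses $\log(1-\text{BMR})$, found by the
same bisection. For the pure linear family this reduces to
$\log(1-\text{BMR})/(\hat\beta - t\,se(\hat\beta))$. We use the $t$ quantile
with $n - p$ degrees of freedom rather than the normal quantile; at
$n = 431$ the difference is negligible (fourth decimal of the BMDL), and the
$t$ choice matches what standard regression software reports. The
`alpha_level` argument makes the level configurable.

**Profile likelihood** (required for K-power, available for all): the model
is reparameterised so the BMD is explicit — for one-slope families the
constraint $f(\text{BMD}) = \log(1-\text{BMR})$ fixes the slope; for the
piecewise family it imposes one linear restriction on $(\beta, \beta_2)$,
handled by constrained least squares; for K-power,
$\beta = \log(1-\text{BMR})/\text{BMD}^K$ with the inner fit re-profiled
over $K$. The BMDL is the smallest BMD whose profile $-2\log L$ exceeds the
full-model minimum by $\chi^2_1(0.90) = 2.7055$ — the standard cutoff for a
one-sided 95% limit. The two constructions agree asymptotically; the test
suite verifies agreement within 2% at $n = 10^4$.

Degenerate cases are handled explicitly: with a noise-free fit the BMDL
equals the BMD; with a non-adverse fitted slope ($\hat\beta \ge 0$) the BMD
is undefined and propagates as a flagged `NA` into every report, never a
silent omission. BMDs below the minimum observed exposure are reported, not
censored — the threshold variants are the principled way to probe that
dependence.

Useful internal identities (used heavily in testing): for the linear family
$\text{BMD}(0.10)/\text{BMD}(0.05) = \ln(0.90)/\ln(0.95) = 2.0541\ldots$,
and identically for closed-form BMDLs; for the log family the same ratio
holds for $\ln(1+\text{BMD})$.

## Regulatory conversions

`derive_rfd()` divides a BMDL by an uncertainty factor (default 10,
covering within-population variability in vulnerability). `serum_to_water()`
converts a serum concentration (ng/mL) to an equivalent drinking-water
concentration (ng/L) using an approximate steady-state serum:water ratio
(default 100, as observed for PFOA in exposed communities): a serum RfD of
0.1 ng/mL corresponds to 1 ng/L in water.

## The synthetic cohort generator

`cohort_defaults()` encodes the published cohort structure: $n = 431$,
48.5% girls, ages $5.0 \pm 0.1$ and $7.5 \pm 0.1$ years (truncated at
$\pm 4$ sd to exclude nonphysical values), and lognormal serum exposures
with log-medians at the printed medians and log-sigmas recovered from the
printed interquartile ranges by normal-quantile scaling
($\sigma = \ln(q_3/q_1)/(2 \times 0.6745)$): PFOS 17.3 (14.1–21.3) ng/mL,
PFOA 4.06 (3.33–4.95) ng/mL. Antibody outcomes are lognormal with total
log-scale spread matching the printed IQRs (tetanus 1.80 (0.75–4.60) IU/mL,
spread $\approx 1.34$; diphtheria 0.80 (0.40–1.60) IU/mL, spread
$\approx 1.03$).

Several generator settings are assumptions, not published facts, and are
therefore configurable with documented defaults chosen once:

* **PFOS–PFOA log correlation 0.70** — the source study reports only a
  "close" correlation; 0.70 is typical of childhood serum panels where both
  analytes share exposure routes.
* **Booster type** — two equiprobable levels (`DT`, `DT-IPV`); the actual
  categories are not described in the published summary.
* **Covariate effects** — modest defaults ($\alpha_{sex} = 0.20$,
  $\alpha_{age} = 0.15$, $\alpha_{booster} = 0.20$ on the log scale),
  consistent with the published observation that sex and age affected
  results only negligibly; the residual sd absorbs the remaining spread so
  the total matches the printed IQRs.
* **Injected dose–response** — zero slope by default: the default cohort is
  observational structure only, and experiments inject an effect explicitly
  (e.g. `dose_response("linear", beta = -0.02)`, a slope of the same order
  as the fitted curves behind the published table).

The intercepts are centred so the outcome median matches the printed median
at the typical child. Generation is fully seed-deterministic.

What the generator does *not* emulate: maternal pregnancy exposures, PCB
co-exposures, loss to follow-up, measurement error in the exposure, or any
dependence between the two antibody outcomes beyond shared covariates and
dose. Passing tests on synthetic cohorts therefore demonstrate that the
estimation machinery recovers known truth under the stated model — they do
not validate the model against real biology.

## Numerical choices

* Bisection bracket for all dose solves: $[10^{-12}, 10^3 \times
  \max(d)]$ (curve-only solves expand geometrically, capped at $10^{12}$);
  relative tolerance $10^{-9}$.
* K-power profile: grid of 29 points on $[1, 15]$, then `optimize()` with
  tolerance $10^{-6}$; $K = 1$ returned whenever its RSS is within
  $10^{-12}$ of the interior optimum.
* Profile-likelihood BMDL: bisection between the MLE BMD and a lower
  bracket found by repeated halving; inner fits are exact linear solves.
* Rank deficiency is detected from the pivoted QR and reported with the
  names of the collinear columns; $n \le p$ raises an insufficient-data
  error before fitting.
* Ties at the first-quartile cut are included in the low-dose subset.

## Problem sizes used by the test suite

The suite calibrates marginals at $n = 10^5$, cross-checks the profile
against the closed form at $n = 10^4$, compares the closed-form BMDL with a
dense grid-search oracle on 50 small random datasets, and runs 500
replicate cohorts at the published size $n = 431$ for slope recovery and
one-sided coverage (expected $\ge 93\%$ at the nominal 95%). These sizes
give Monte Carlo error comfortably inside the asserted tolerances while the
whole suite runs in seconds.

## A worked run

```{r example}
cfg <- cohort_defaults(
  injected_effect = dose_response("linear", beta = -0.019),
  seed = 2026)
res <- run_analysis(cfg, exposures = "pfos", outcomes = "tetanus",
                    families = c("linear", "log", "piecewise"),
                    threshold = "both")
cat(render_benchmark_table(res, format = "text"), sep = "\n")
```

The qualitative pattern of the published analysis reappears: the log curve
gives far lower benchmark doses than the linear curve, the piecewise BMDL
sits below the linear one, and the threshold variants raise the linear BMDL
several-fold by discounting the unobserved low-dose region.

```{r convert}
bmdl5 <- res |>
  dplyr::filter(family == "linear", !threshold, bmr == 0.05) |>
  dplyr::pull(bmdl)
derive_rfd(bmdl5, uncertainty_factor = 10)
serum_to_water(derive_rfd(bmdl5, 10))
```

## Known limitations

* PFOS and PFOA cannot be mutually adjusted in one model: their correlation
  makes the joint design ill-conditioned, so each exposure is analysed
  separately and the single-exposure estimates partly absorb each other's
  effect.
* The exact confidence construction behind the published BMDLs cannot be
  pinned down from the text ($t$ vs normal quantile, Wald on $\beta$ vs
  Wald on $f(d)$); for the pure linear family these coincide, and this
  package's default reproduces the published linear-family internal
  identities exactly.
* The log-family BMD depends on the dose unit through the $+1$ offset (see
  above).
* The generator emulates marginal structure, not the full joint
  distribution of a real cohort; headline BMDLs from synthetic data are
  illustrative, not estimates of the published ones.
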