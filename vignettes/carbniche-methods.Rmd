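---
title: "Models and methods behind carbniche"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind carbniche}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carbniche)
```

`carbniche` maps phytoplankton fitness across seawater carbonate-chemistry
space. This vignette explains the models it implements, the assumptions
they carry, the tunable parameters and their defaults, what the synthetic
experiment generator does and does not emulate, and the numerical choices
made where the design was genuinely open. It states no empirical result
that the test suite and `scripts/acceptance.R` do not themselves compute.

## The carbonate system

All speciation is on the total hydrogen-ion scale at surface pressure.
Given temperature and practical salinity, `carb_constants()` evaluates a
fixed formulation set: Weiss (1974) CO2 solubility; Lueker et al. (2000)
carbonic acid dissociation (characterised on the total scale, the standard
choice for this kind of culture work); Dickson (1990) boric acid and
bisulfate; Dickson & Riley (1979) fluoride; Millero (1995) water,
phosphoric and silicic acid, converted from the seawater to the total
scale through the sulfate/fluoride ion pairs; Mucci (1983) aragonite
solubility; Uppstrom (1974) borate and Riley & Tongudai (1967) calcium,
both proportional to salinity. The set is deterministic — identical inputs
give bit-identical constants — and is checked in the tests against
published check values (pK1 = 5.847, pK2 = 8.966 at 25 °C, S = 35) and
against an independently written reference solver over a 100-point
Latin-hypercube of (TA, DIC, T, S).

The total alkalinity balance includes the carbonate, borate, water,
silicate and phosphate systems and the free-H+/bisulfate/fluoride terms:

$$TA = [HCO_3^-] + 2[CO_3^{2-}] + [B(OH)_4^-] + [OH^-] + [SiO(OH)_3^-]
      + ([HPO_4^{2-}] + 2[PO_4^{3-}] - [H_3PO_4]) - [H^+]_F - [HSO_4^-] - [HF]$$

Three entry points cover the measurement pairs that occur in practice:

* `speciate_ta_ph()` — closed form. At known pH every non-carbonate term
  is fixed, so carbonate alkalinity and DIC follow without iteration.
  Inconsistent inputs (non-carbonate alkalinity exceeding TA) raise an
  error naming the offending values.
* `speciate_ta_dic()` — Brent-bracketed root-finding for pH on
  [2, 12]. The balance is strictly monotone in pH, so the root is unique;
  the solver tolerance (1e-11 in pH) keeps the residual far below
  1e-3 µmol kg⁻¹ of TA.
* `speciate_ta_pco2()` — dissolved CO2 fixed by Henry's law
  (`CO2 = K0 · pCO2`), pH from the same bracketed search with CO2 held
  constant.

Units are µmol kg⁻¹ and µatm at every interface; mol kg⁻¹ internally, with
the 1e-6 conversion applied exactly once at the boundary. pCO2 is reported
as a partial pressure via K0, without a fugacity correction: the source
conventions for published "pCO2" values rarely distinguish the two, the
difference is ~0.4% at 15 °C, and keeping the pure Henry's-law convention
makes round trips exact. Phosphate defaults to 3 µmol kg⁻¹ (the value
assumed for unmeasured culture media); silicate defaults to 0; both can be
zeroed for nutrient-free literature data. `ph_to_total()` converts free-
and seawater-scale pH for ingestion of published records; NBS is not
supported because it requires activity coefficients foreign to the rest of
the framework.

## The growth model

Growth rate versus dissolved CO2 follows an optimum curve,

$$V(c) = \frac{X\,c}{Y + c} - S\,c, \qquad S \ge 0,$$

a Michaelis-Menten uptake term with a linear inhibition term. The
inhibition is physiologically attributed to H+, but CO2 and H+ are so
tightly log-correlated across TA/DIC space (R² > 0.95 over the factorial
design; verified in the tests) that the curve is parameterised in CO2
alone. `S = 0` recovers the standard saturating Michaelis-Menten form
exactly; the two are nested.

Derived quantities (`derive_kinetics()`): for `S > 0` the stationary point
is $C_{opt} = \sqrt{XY/S} - Y$ and $V_{max} = V(C_{opt})$. The
half-saturation constant $K_{1/2}$ is defined as the ascending-limb
concentration where the rate first reaches $V_{max}/2$, found by bracketed
root-finding on $(0, C_{opt})$. This definition was an open choice — the
source convention defers the conversion to earlier kinetics literature
without reprinting it — and was adopted because it reduces exactly to the
Michaelis constant ($K_{1/2} = Y$, $V_{max} = X$) in the nested `S = 0`
limit. `kinetic_params()` inverts the mapping by nested bracketed
root-finding, so generator profiles can be specified in the reported
quantities.

### Fitting

`growthfit()` estimates (X, Y, S) by Levenberg-Marquardt least squares
with an analytic Jacobian and `S` constrained non-negative. Starting
values are data-driven — X from the maximum observed rate, Y from the CO2
value nearest half that rate, S from the terminal slope — plus four
deterministically seeded log-jittered restarts; the best sum of squares
wins, so the fit is reproducible given the data and seed. A fit whose S
lands on the zero boundary is refit as the saturating form. R² is computed
against the mean-only model on the fitted scale, unadjusted for parameter
count. Rows carrying an `excluded` flag are kept in the object but never
enter the fit.

Model choice (`model = "auto"` or `select_growth_model()`) fits the
inhibited form and bootstraps S: the inhibited model is retained only when
the percentile interval of S excludes zero, i.e. when a decline at high
CO2 is actually evident; otherwise the saturating form is used. This
operationalises a visual judgement ("no decline evident") as a resampling
test.

### Bootstrap uncertainty

`bootstrap_ci()` implements both modes: nonparametric (resampling
observation pairs with replacement; the default, 1000 replicates) and
parametric (resampling residuals onto fitted values). Each replicate is
refit from the point estimate; replicates that fail to converge or whose
parameters admit no interior optimum are dropped and counted, and more
than 50% failures is an error. Intervals are percentile-based on the raw
parameters and the derived kinetics. Data are put in a canonical
(CO2, rate) order before resampling, which makes the intervals exactly
invariant to input row order at a fixed seed. The suite verifies
calibration empirically: 95% intervals for $K_{1/2}$ cover the truth in
90-99% of simulated datasets (200 simulations, 1000 replicates, at the
factorial design's size and noise).

## Culture processing

Growth rates are ordinary least-squares slopes of log fluorescence against
day (`growth_rate_from_fluorescence()`), requiring a span of at least
3 days; the estimator is exact on noise-free exponential series for any
sampling times. All available days are used — no automatic lag-phase
trimming, since none is described for the source protocol. Cultures with
slope ≤ 0 are flagged (`zero net growth` / `mortality`) and barred from
fitting but retained in outputs; the threshold is configurable and
defaults to exactly 0, as no numeric epsilon is documented anywhere.
Each culture's condition value is the arithmetic mean of its speciated
start and harvest states (`process_cultures()`, `mean_state()`), the
standard convention for batch cultures whose chemistry drifts as they
grow. ΔDSi is signed so that positive means uptake; per-cell silica
metrics are plain normalisations by the end-point cell count. Fv/Fm is
carried as data and correlated with growth (`rsquared()`), never modelled
mechanistically.

## Landscapes, optima, scenarios

`predict_landscape()` speciates every cell of a TA × DIC lattice and
evaluates the fitted curve at each cell's CO2, so predicted rate is
constant along iso-CO2 contours by construction. Rates are floored at zero
before normalising to the landscape maximum (the inhibition term would
otherwise produce negative "growth" in strongly supersaturated corners);
cells with no pH root are masked as infeasible rather than failing.

The **optimum** is the set of CO2 values with $V(c) \ge f \cdot V_{max}$,
default $f = 0.9$ — a fraction of the fitted maximum, not an empirical
quantile of observed rates, because the quantity of interest is the
fitted niche. Intervals are nested in $f$ and collapse onto $C_{opt}$ as
$f \to 1$ (half-width $\propto \sqrt{1-f}$). Endpoint CO2 values map to
H+ at a stated reference DIC (default 2030 µmol kg⁻¹, a mean surface-ocean
value) through a closed-form quadratic, avoiding any iteration.

`oae_scenario()` models alkalinity enhancement: baseline seawater
equilibrated with the atmosphere, an instantaneous TA addition at constant
DIC, then re-equilibration parameterised as a linear bridge in pCO2
between the unequilibrated and atmospheric endpoints. The linear bridge is
a documented choice — no canonical interpolation exists for the
equilibration fan — and guarantees the fraction-1 endpoint
restores atmospheric pCO2 exactly, with the stored carbon appearing as the
DIC excess over baseline. `alkalinity_threshold()` bisects on the addition
(tolerance 0.01 µmol kg⁻¹, bracket [0, 2000]) for the point where
predicted growth leaves the optimum; a baseline already below the optimum
returns 0, and never leaving it returns `Inf`, both with explanatory
notes. `oa_threshold()` reports the upper optimum edge as pCO2 and H+,
with a sentinel for saturating fits that never decline.

## The synthetic experiment generator

`simulate_experiment()` emulates the statistical structure of a dilute
batch-culture factorial: 11 TA levels (2000-3350 µmol kg⁻¹) × 8 DIC levels
(1800-3666.67 µmol kg⁻¹) at 15 °C, salinity 33.06, media nitrate
48 µmol kg⁻¹ and silicate 3 µmol kg⁻¹ — 88 nominal cells. Cells whose
dissolved CO2 exceeds 800 µmol kg⁻¹ (pCO2 ≳ 20,000 µatm) are masked as
un-culturable, since strongly supersaturated media outgas during handling;
72 cells survive, comfortably above the 67-treatment floor the design
aims for. One culture per cell.

Per culture: the true rate is the optimum curve evaluated at the
growth-period mean CO2 — the mean of the start state and the harvest
state, matching the condition value the analysis assigns — plus additive
Gaussian noise (default σ = 0.05 d⁻¹). Generating growth at the start
state instead would be inconsistent with the analysis convention and
biases half-saturation recovery badly under 5-10% DIC drawdowns. Harvest
is imposed at a uniform 5-10% DIC drawdown (the generator does not solve
carbon uptake dynamically; dilute batch protocols harvest at that point
precisely so that chemistry stays near its target).
Nitrate assimilation raises TA one-for-one with N consumed, tied to the
carbon drawdown by a Redfield 16:106 ratio and capped by the media pool.
End TA and pH are recomputed by speciation, so simulated "measurements"
are exactly chemistry-consistent. Fluorescence is exponential at the
realised rate — declining for mortality cultures — with multiplicative
lognormal noise (default 5%); series length adapts to the rate (3-14
days). Cell yield, DSi drawdown and BSi all scale with the carbon
drawdown, so per-cell silica metrics carry no built-in carbonate-chemistry
trend (a null the tests verify by rank correlation). Fv/Fm follows a
coupled optimum curve, `0.10 + 0.55 · V/Vmax` plus Gaussian noise (default
σ = 0.02), which keeps the growth-Fv/Fm R² above 0.75 at coupling noise up
to 0.05.

Default species profiles anchor to published species-level kinetics for
five coastal diatoms: half-saturation constants 1.22, 1.21, 0.90, 5.55 and
0.44 µmol kg⁻¹, with the printed inhibition extremes assigned to the
narrow-niche (0.0065) and broad-niche (0.0005) species; the three
unprinted S values (0.0020, 0.0030, 0.0010) were placed once inside the
printed range, and maximum rates (0.6-1.4 d⁻¹) chosen as plausible
batch-culture values, since vertical scale is normalised away in
relative-growth comparisons. These choices were made once and are not
tuned.

What the generator does **not** emulate: within-day chemistry dynamics,
light/temperature effects, replicate vessels per cell, lag phases,
measurement error on TA/pH (start/end states are exact), strain-level
variability, and any mechanistic Fv/Fm or silicification model. Passing
recovery tests therefore demonstrates that the estimation chain is
unbiased and calibrated *under the stated noise model*, not that real
cultures satisfy that model.

## Literature harmonisation

Published records enter as (study, species, growth rate, up to two
carbonate parameters, pH scale, T, S, manipulation). Screening applies a
strict "more than 3 distinct CO2 levels" rule for model eligibility, a
two-parameter rule for landscape eligibility, and an acid/base
manipulation flag. Harmonisation resolves CO2 directly, via Henry's law
from pCO2, or by speciation from any supported pair; undeclared pH scales
are assumed total and missing salinity defaults to 35, each with one
logged warning, since the source conventions are silent. Rates are
normalised per study-species to the group maximum (which leaves $K_{1/2}$
invariant), and the pooled "average response" weights every point equally
— per-study weighting is not described anywhere and was not invented.

## Problem sizes and runtime choices

The recovery and calibration studies run at sizes chosen to exercise the
design without dominating the suite: the end-to-end half-saturation
recovery uses 100 seeds at 500 bootstrap replicates; interval calibration
uses the stated 200 simulations at 1000 replicates; smaller property
checks use 12-30 seeds. The orchestration layer (`run_pipeline()`) is a
plain R function over the module surface — configuration list or YAML in,
per-species results and a seeded manifest out — rather than a shell
executable, which suits an analysis package driven from R scripts.

## Known limitations

* The OAE equilibration fan is a linear pCO2 bridge, not a gas-exchange
  model; timescales are outside scope.
* `K_{1/2}` for strongly inhibited curves is a definition-dependent
  quantity; alternative conversions from (X, Y, S) exist in the kinetics
  literature.
* Species whose half-saturation constant lies below the lowest achievable
  design CO2 (~0.24 µmol kg⁻¹) are weakly identified at the design's
  level spacing; the broad-niche default profile sits near this limit.
* Published pCO2/fCO2 conventions are heterogeneous; reproductions of
  printed scenario endpoints can differ by a few percent depending on the
  convention assumed (the package states and keeps one: partial pressure
  via K0).
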