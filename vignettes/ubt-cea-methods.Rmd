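---
title: "Methods: decision-analytic cost-effectiveness of UBT devices for atonic PPH"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: decision-analytic cost-effectiveness of UBT devices for atonic PPH}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ubtcea)
```

## The decision problem

Atonic post-partum hemorrhage (PPH) — bleeding caused by failure of the
uterus to contract after delivery — is the leading direct cause of maternal
death in India. When uterotonic drugs fail, uterine balloon tamponade (UBT)
is the recommended next step before surgery. Three devices are in use in
Indian public facilities: the improvised condom catheter (condom-UBT, the
standard of care), the low-cost ESM-UBT kit, and the commercial Bakri
balloon. `ubtcea` implements a cohort decision-tree model that asks, for an
annual cohort of women eligible for UBT after atonic PPH, which device
offers the best value from a disaggregated societal perspective.

The model is a pure decision tree (no health-state cycling): UBT management
is a discrete short episode, and only its sequelae — hysterectomy-related
infertility and premature death — extend over the lifetime horizon.

## Model structure

Each device strategy is evaluated as its own tree on the whole cohort,
since policy would deploy one common device system-wide. The tree:

1. splits the cohort across the facility level where care is sought
   (primary 0.1861, secondary 0.3293, tertiary as the complement);
2. primary-level cases receive the device at primary prices, incur one
   referral (INR 1,001), and then follow the secondary-level clinical
   pathway — primary facilities cannot operate;
3. at secondary or tertiary level, bleeding is controlled with the
   device's effectiveness (condom 0.923, ESM 0.953, Bakri 0.843).
   Controlled cases face a 0.025 ICU probability; uncontrolled cases
   enter the surgical cascade — immediate hysterectomy with probability
   0.14634, otherwise devascularization (conservative procedures pooled as
   one), followed by hysterectomy with probability 0.21951 when bleeding
   persists — and face a 0.769 ICU probability;
4. ICU care exists only at tertiary level and is costed at the tertiary
   rate (INR 4,896); cases sitting at secondary level add one referral;
5. every terminal adds inpatient admission at the treating level, the
   per-patient provider-training cost (INR 375) and the household
   out-of-pocket expenditure (INR 2,755).

Branch probabilities are symbolic — resolved against the parameter registry
at evaluation time — so one-way and probabilistic sensitivity analyses
re-evaluate the same structure. Binary chance nodes use a structural
complement branch, making sum-to-one a property of the tree rather than of
the numbers. An exhaustive path-enumeration oracle (`enumerate_paths()`)
cross-checks the rollback evaluator to 1e-12 in the test suite.

```{r}
fit <- ubt_cea()
fit
```

## Costs

Unit costs (2017-18 INR) enter per event: device insertion at the level of
first contact, inpatient admission at the treating level, surgery costs
specific to device and level, ICU and referral costs, training, and
household OOPE. Costs are undiscounted: the intervention is a one-time
event. The societal perspective sums health-system and household items;
`health_system` drops the household OOPE. The published per-patient
health-system figure appears to additionally exclude the annual training
component (the published societal-minus-health-system gap is 3,131 ≈ OOPE
2,755 + training 375); this package keeps training as a health-system item,
which leaves every incremental comparison unchanged because the component
cancels between arms.

## Outcomes: DALYs

DALY = YLL + YLD, without age weighting.

* YLL: deaths x remaining life expectancy at the cohort age (53.79 years at
  age 21). The package's default death model applies background all-cause
  maternal mortality (0.00308) at every terminal; an optional excess-PPH
  death probability on uncontrolled cases (default 0) is available because
  the published death-assignment rule cannot be recovered from the printed
  inputs (the printed 214/214/216 deaths are not the product of the cohort
  with either printed mortality probability).
* YLD: bleeding controlled by UBT alone takes the mild-haemorrhage weight
  (0.114) for the six-week postpartum period (0.11 y); any surgical or ICU
  pathway takes the severe weight (0.324, once per patient — weights
  describe a health state, not events); hysterectomy survivors additionally
  accrue the secondary-infertility weight (0.005) to the end of
  reproductive life (25 y). ICU-admitted but UBT-controlled cases take the
  severe weight, following the grouping of ICU admission with severe
  haemorrhage. Decedents accrue YLL only.

Discounting of future health outcomes is configurable: `annual_annuity`
(default, the Indian reference-case convention: a duration L discounts to
`(1-(1+r)^-L)/r`), `continuous`, or `none`. The published per-patient DALY
level (0.2156 for condom-UBT) is better matched by undiscounted YLL, so
both modes are first-class rather than guessed; per-patient DALY *levels*
are therefore not asserted anywhere — only the device ordering
(ESM < condom < Bakri), which holds under every discounting mode.

## Cost-effectiveness

Pairwise comparisons against condom-UBT report the incremental cost, DALYs
averted, ICER, and net monetary benefit at the Indian willingness-to-pay
threshold of INR 24,211 per DALY averted:

`NMB = DALYs averted x WTP - incremental cost.`

A bare negative ICER is ambiguous — it arises both when a device saves
money and DALYs (dominant) and when it costs more and loses DALYs
(dominated) — so every ICER is reported with its dominance quadrant and
NMB. No efficiency frontier across all three devices is computed; the
analysis is deliberately pairwise.

## Sensitivity analysis

**Distributions.** Probabilities, proportions and disability weights are
Beta; costs and resource counts Gamma. The registry publishes point values
with lower/upper limits but no hyperparameters, so these are derived by
method of moments treating the limits as a symmetric 95% interval:
mean = the base value, sd = (high - low)/3.92. A Beta-group parameter whose
implied variance is unattainable falls back to a fixed value with a
warning.

**Effectiveness ceiling.** Device effectiveness is capped at 0.983, the
highest effectiveness reported in the underlying evidence. The cap is
enforced by clamping draws at the ceiling (default) rather than
rejection-resampling: the ceiling expresses a hard bound on attainable
effectiveness, not a reshaping of belief below it, and clamping preserves
the distribution mean (the ESM Beta has 40% of its mass above the cap, so
resampling would shift its mean from 0.953 to about 0.926 and bias every
downstream result). Resampling remains available via `truncation_mode`.

**OWSA.** Each parameter in turn is set to its lower and upper limit, the
model re-evaluated, and the incremental NMB recorded. Swing is measured on
the NMB scale (finite everywhere, unlike the ICER near zero effect
difference) with the ICER reported alongside; rankings agree in regular
regions. At reference values the tornado is led by condom-UBT and ESM-UBT
effectiveness, then the ESM tertiary insertion cost.

**PSA.** `run_psa()` draws all non-fixed parameters independently (no
correlation structure is published), re-evaluates both trees per draw, and
summarizes the incremental cost/effect cloud: probability cost-effective at
the base WTP, quadrant shares, the CEAC over a 0-400,000 INR grid (always
including the WTP, 1x and 3x GDP per capita), and EVPI. Parameters shared
by both arms take one value per draw (common random numbers); device
-specific parameters are distinct registry entries and vary per device.
Cohort-size inputs are held at base inside the PSA: per-patient incremental
results are cohort-invariant and both arms share one cohort.

**EVPI.** With two strategies the comparator's incremental NMB is
identically zero, so per-person EVPI = `E[max(0, NMB)] - max(0, E[NMB])`
over the draws; the population figure multiplies by the undiscounted
one-time annual cohort (59,962).

```{r}
psa <- run_psa("esm", "condom", n = 2000, seed = 1)
psa
```

## Numerical and design choices

* Probabilities must sum to one within 1e-9 at every chance node; terminal
  masses conserve the cohort to 1e-6 relative.
* The eligible cohort is `round(deliveries x PPH incidence x atonic share
  x uterotonic-failure share)` = 59,962.
* Hysterectomy is definitive for bleeding control; there is no
  post-hysterectomy uncontrolled branch.
* Report files round INR to whole rupees, DALYs to 4 decimals and
  probabilities to 3; internal computation is never rounded. USD values
  divide unrounded INR by the fixed 2017-18 rate (64.5) and then round.
* Ties at the cost-effectiveness plane origin are labelled `tradeoff_ne`
  with zero magnitudes.
* Default problem sizes: the full tree has 24 terminals per strategy; the
  shipped analyses use the full 59,962 cohort, 10,000 PSA draws, and the
  complete parameter set in the OWSA. The vignette uses 2,000 draws purely
  for illustration.

## What the synthetic generator does and does not emulate

`make_micro_model()` builds reduced single-level scenarios whose expected
counts, costs and DALYs are computed by independent closed-form arithmetic
embedded in the generator; the engine must reproduce them to 1e-9.
`make_random_parameter_file()` emits randomized, structurally valid
registries (facility shares renormalized, probabilities clamped to [0, 1],
log-uniform costs with +/-40% limits) so the pipeline is exercised without
the reference fixture. Neither emulates real-world features such as
correlated costs and effectiveness, within-level facility heterogeneity,
time-varying probabilities, or reporting biases in the effectiveness
evidence — passing tests demonstrate arithmetic correctness of the model,
not external validity of its inputs.

## Known limitations

* The published death-assignment rule, YLL discounting convention and PSA
  hyperparameterization are not stated; deaths, per-patient DALY levels and
  the exact PSA fractions are therefore reproduced only up to orderings and
  bands, and the probability-cost-effective for ESM vs condom computes
  several points below the published 63.5% under the method-of-moments
  calibration implemented here.
* Anemia comorbidity, productivity losses and blood-transfusion
  itemization are out of scope, as in the source analysis.
* The ICER is reported as an explicit `undefined` marker when the effect
  difference is below 1e-12 in absolute value.
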