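---
title: "Methods: a lifetime cost-effectiveness model of lifestyle intervention for diabetes prevention"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a lifetime cost-effectiveness model of lifestyle intervention for diabetes prevention}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diabprev)
```

## The decision problem

`diabprev` models a cohort of Chinese adults with impaired glucose
tolerance (IGT), aged 45 at entry, who either receive a six-year diet and
exercise program or no preventive intervention. The question is the
lifetime one: does delaying or preventing progression to type 2 diabetes
(T2DM) — and with it myocardial infarction, stroke, congestive heart
failure, end-stage renal disease, blindness, clinical neuropathy, foot
ulcers and amputations — buy enough quality-adjusted life-years (QALYs)
and avoid enough spending to justify the program cost? Outcomes are
expressed as incremental cost (2019 US$), incremental QALYs, the
incremental cost-effectiveness ratio (ICER) and a dominance
classification at a willingness-to-pay threshold of $10,276/QALY, China's
2019 per-capita GDP.

## Model structure

The engine (`run_cohort()`) is a deterministic expected-value cohort
model with annual cycles from age 45 to age 100. Within each cycle the
order of operations is fixed: (1) all-cause death, (2) diabetes onset,
(3) complication incidence, (4) risk-factor drift, (5) ageing and the
shift of the diabetes-duration distribution. The order matters at the
half-cycle scale; it is stated here because results shift by O(half a
cycle) under permutations. There is no half-cycle correction by default
(`options$half_cycle_correction` enables a trapezoid occupancy variant).
Occupancy is counted at the start of each cycle, so a cohort facing a
constant death probability of 0.5 over three cycles accrues exactly
1 + 0.5 + 0.25 = 1.75 life-years — the basis of the package's
hand-checkable toy configuration (`toy_model_config()`).

**Onset.** Time to diabetes follows a Weibull survival function
S(t) = exp(−αt^β) on the time-since-entry clock (age 45 = t = 0), with
arm-specific parameters fitted to the 23-year Kaplan–Meier curves of the
Da Qing prevention trial: α = 0.177, β = 0.8551 (no prevention) and
α = 0.0749, β = 0.96 (lifestyle). The two arms use their own fits rather
than a single baseline deformed by the trial hazard ratio (HR 0.55,
95% CI 0.40–0.76), because the two printed fits are not related by a
constant HR; the HR enters only through sensitivity analyses via
`scale_onset_hazard()`, a proportional-hazards action on the cumulative
hazard. The annual onset probability in cycle k is
1 − S(k+1)/S(k), computed from the cumulative-hazard increment so it
remains finite where S itself underflows; the product of the annual
complements telescopes back to S(K) to machine precision. Beyond the
23-year fit horizon the Weibull is extrapolated unchanged — an
extrapolation assumption, flagged as such.

**Mortality.** Background mortality comes from a life table (`age,qx`
CSV). The bundled fixture is a synthetic Gompertz–Makeham table
(a = 3.2e-5, b = 0.100, c = 6e-4) matched to WHO China-2009 summary
demography — life expectancy ~74.0 at birth and ~31.5 at age 45 — and is
a stand-in for the WHO table, not the table itself. Diabetics die at
qx × `m_dm`, a single calibratable multiplier (resolved to ~1.58 by the
life-year calibration below). Optional per-complication mortality
structure exists (MI/stroke case fatality, CHF/ESRD multipliers) but
defaults to off: in experiments, loading the diabetic excess onto
complications pulled the incremental life expectancy *away* from
published values, so the blanket multiplier is retained as the default.

**Complications.** Each of the ten complications is an independent
submodel with a tracker prevalence; a patient can hold several at once,
and prevalences are treated as marginal (independence across
complications). MI and stroke are acute events with a per-event cost and
a one-month hospitalization utility decrement (prorated 1/12 in the
incident cycle), whose survivors enter absorbing post-event states with
annual care costs and decrements. CHF, ESRD, blindness and neuropathy
are absorbing states; amputations are events entering absorbing states;
foot ulcers are recurrent cost events with a one-cycle decrement.
Non-diabetics face the diabetic hazard deflated by the published
relative risks (e.g. MI 2.0, stroke 2.27, CHF 2.5, neuropathy 4.6);
amputations and foot ulcers are treated as diabetes-specific
(no non-diabetic incidence). The annual probability is 1 − exp(−h) from
the annual hazard h.

**Age dependence of complication hazards.** Hazards are parameterised as
h(age) = h₄₅ · exp(g·(age − 45)) with g = ln(2)/10 by default: incidence
doubles per decade of age, the standard epidemiologic magnitude for
cardiovascular and microvascular disease, and the qualitative behaviour
of published T2DM risk equations. This choice is structural, not fitted:
with constant hazards (g = 0, available via
`options$hazard_age_gradient`), a model calibrated to the same lifetime
cumulative incidences places complications too early in life, which
inflates discounted costs and utility losses and roughly doubles the
between-arm complication differences; the age gradient corrects the
*timing* while calibration pins the *level*. A log-link risk-equation
interface (`risk_equations`) accepts published coefficient vectors on the
tracked covariates (SBP, HbA1c, lipids, …) for users who have them; none
ship by default, and the covariate drift hooks (`drift`) default to zero.

## Economics

Life-years accrue undiscounted; QALYs and costs are discounted at 5%
per year, factor (1+r)^(−t) with t the cycle index. (An undiscounted
life-expectancy reading is the only one consistent with published
lifetime LY values of ~28 years from age 45, while discounted QALY
totals of ~13 match a 5% annuity.) Utilities are combined additively:
non-diabetics carry utility 1.0 (configurable; whether prediabetes
itself carries a decrement is unsettled, so the default is none),
diabetics 0.876 minus the decrements of their prevalent complications,
floored at zero at the group-mean level. Costs sum the lifestyle program
($134/year, charged while alive and non-diabetic, capped at the six-year
program duration — the trial design leaves open whether conversion stops
the program; this default is the conservative reading and is prominently
configurable), duration-banded antidiabetic therapy (0.5/0.8/1.2/1.8
US$/day for durations [0,3), [3,6), [6,10), [10,∞) years — half-open
integer bands reconciling the overlapping printed labels), annual care
costs on prevalent states and per-event costs on incident fractions.
Severe hypoglycemia is a cost-only event with a configurable annual rate
among diabetics, default 0 (no rate is published).

`compute_icer()` reports ΔC, ΔE, ΔC/ΔE and a classification:
*dominant* requires strictly ΔC < 0 and ΔE > 0; *dominated* the reverse;
ΔE = 0 leaves the ICER undefined and the trade-off is resolved by the
sign of the net monetary benefit λ·ΔE − ΔC. The NMB decision and the
ICER-versus-λ decision agree identically (property-tested).

## Calibration

The complication hazards inside the progression model are published in
external modelling work rather than as reusable numbers, so the package
resolves them by calibration (`calibrate_all()`): each complication's
h₄₅ is fitted by bracketing bisection to the published control-arm
lifetime cumulative incidence (MI 10.56%, stroke 24.17%, CHF 14.89%,
ESRD 4.61%, blindness 5.79%, neuropathy 21.28%, minor amputation 12.21%,
major amputation 9.22%), and `m_dm` to the control-arm undiscounted
life expectancy of 27.87 years, in up to three coordinate sweeps.
Each response is monotone in its own scalar (checked at the bracket
endpoints) and interactions run only through mortality, so convergence
is fast; residuals land below 2e-4 on fractions and 5e-3 years. The
procedure is deterministic and bit-reproducible. Foot-ulcer rates have
no published cumulative incidence and stay at their configured defaults,
excluded from calibration. Crucially, the intervention arm is never
fitted: after calibration its outcomes are predictions from the
intervention Weibull alone, which is what makes the incremental results
a genuine model test.

With the default configuration this protocol predicts an incremental
0.59 life-years, 0.60 QALYs and −$1,269 (saving) per person, a dominant
strategy. The saving decomposes into −$1,132 of duration-banded
antidiabetic therapy, −$750 of complication care and events, against
+$603 of program cost; the therapy component follows almost mechanically
from the two printed onset curves (≈2.4 fewer discounted diabetic
person-years), so the package's saving is larger than published
lifetime-cost differences of similar analyses that embed richer
survivor-cost structure.

## Sensitivity analysis

The varied parameter set is the published input table: the onset HR,
the relative risks, every unit cost, and the utility weight and
decrements — not the calibrated internals, which are derived quantities.
Distribution families follow the standard assignment: beta for
utilities/probabilities (moment-matched on base and SE, with a
range-supported uniform fallback and warning where the printed base of
1.0 makes beta moments infeasible), triangular for costs (mode at the
base value), normal truncated at zero for hazard and relative risks.
When no range is printed, the one-way range defaults to 75–125% of base
and the SE to 25% of base; when a range is printed, SE = (high−low)/3.92.

`one_way_sa()` reruns both arms at each parameter's range ends and sorts
the ICER bars by width (switching to the NMB scale when ΔE changes sign
inside a range). On the default calibrated configuration the program
cost and the onset HR rank among the widest bars, matching the published
sensitivity ordering. `run_psa()` draws all parameters jointly
(second-order Monte Carlo), applies one common draw to both arms per
iteration, and drives the intervention arm's onset by the drawn HR
acting on the control-arm fit — the published account does not say
whether the Weibull parameters or the HR carried the onset uncertainty,
and the HR is the only quantity with a published interval, so it is the
varied one (flagged as an assumption). A single seeded generator with a
fixed, documented draw order makes the PSA bitwise reproducible.
`ceac()` counts the fraction of iterations with positive NMB on a
threshold grid; at $10,276/QALY the default analysis yields ≥ 95%
probability of cost-effectiveness. `psa_summary()` reports the
ratio-of-means ICER, a percentile interval of per-sample ICERs
restricted to iterations with ΔE > 0 (dominant iterations keep their
negative ratio — ICER percentiles are reported because negative
published intervals imply that convention, with NMB summaries emitted as
the statistically safer alternative) and a 95% covariance ellipse of the
(ΔE, ΔC) cloud.

## Synthetic data and what the tests show

`simulate_event_times()` draws Weibull event times by inverse CDF with
administrative censoring, `km_estimate()` recovers the product-limit
curve, and `fit_weibull()` refits (α, β) by the log-cumulative-hazard
linearization — the loop closes to within ±5% at n = 5000, and exactly
(1e-6) on noiseless curves. `make_life_table()` generates
Gompertz–Makeham tables, including the bundled fixture. These generators
emulate the *structure* of trial and registry inputs (event-time
censoring, monotone mortality), not their sampling quirks: there is no
interval censoring, no covariate heterogeneity (the cohort profile is a
mean vector), and no correlation between parameters in the PSA. Passing
tests therefore demonstrate internal consistency and faithful mechanics
under the stated conditions, not agreement with any new patient
population.

## Numerical choices

Problem sizes were chosen to keep every analysis deterministic or
cheaply repeatable: 55 annual cycles per run, 1000 PSA iterations,
n = 5000 event times for recovery checks, n = 1e5 draws for sampler
moment checks and the onset microsimulation cross-check. Bisection runs
to an absolute tolerance of a quarter of each calibration target's
tolerance with at most 60 iterations; cohort mass is asserted conserved
to 1e-12 every cycle; ages beyond the life table use the terminal death
probability of 1; the utility floor applies at the group mean; ties in
the tornado ordering keep the enumeration order. The acute
hospitalization decrement printed as 1.000 with range 0.236–1 is stored
as printed (the ambiguity of whether the lower end refers to the
post-discharge decrement is left to the range).

## Known limitations

Cardiovascular disease appears only as a relative-risk entry for CVD
death in the input table and is not a separately counted outcome, so the
corresponding parameter is stored but inert. Complication prevalences
are marginal, so comorbidity clustering is not modelled. The engine is a
cohort model: individual-level stochasticity is available only for the
onset/mortality skeleton (`microsim_diabetes()`), used as a Monte-Carlo
cross-check. The lifetime extrapolation of a 23-year fit, the synthetic
life table, and the age-gradient default are structural assumptions a
user can and should vary for their own setting.
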