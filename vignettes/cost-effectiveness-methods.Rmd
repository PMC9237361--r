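---
title: "Model and methods: partitioned-survival cost-effectiveness of first-line pembrolizumab plus chemotherapy in advanced ESCC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pembropsm)
```

## The decision problem

Adding pembrolizumab (an anti-PD-1 antibody) to cisplatin/5-fluorouracil
chemotherapy prolongs overall survival (OS) and progression-free survival
(PFS) in previously untreated advanced oesophageal squamous cell carcinoma
(ESCC) with PD-L1 CPS ≥ 10, at a drug cost far above the chemotherapy
backbone. `pembropsm` implements the standard cohort model used to ask
whether that survival gain is worth the cost from a payer perspective (here
the Chinese health system, with a willingness-to-pay of three times 2021
GDP per capita, $37,663.26 per QALY): three mutually exclusive health
states — progression-free disease (PFD), progressive disease (PD), death —
a 21-day model cycle matching the q3w dosing interval, and a 10-year
horizon with 5% annual discounting of both costs and effects.

## Survival model

State membership is derived directly from the two survival curves
(partitioned survival, the area-under-curve approach): at each cycle
boundary $t$,

$$\mathrm{PFD}(t) = \min\{\mathrm{PFS}(t),\, \mathrm{OS}(t)\}, \qquad
  \mathrm{PD}(t) = \mathrm{OS}(t) - \mathrm{PFD}(t), \qquad
  \mathrm{Death}(t) = 1 - \mathrm{OS}(t).$$

This structure is the natural one when the only clinical inputs are the
OS and PFS curves themselves: no post-progression transition rates need to
be invented, and the trace reproduces both curves exactly. A fitted PFS
curve can cross above OS in the far tail; the trace clamps PFD at OS and
records the (tiny) clamped mass.

The curves are log-logistic,

$$S(t) = \frac{1}{1 + \lambda t^{\gamma}},$$

with time in months (1 month = 30.4375 days, so one 21-day cycle is 0.690
months). The defaults are the fitted shape/scale pairs for the four
arm–endpoint combinations (OS: $\gamma = 1.59, \lambda = 0.015$
pembrolizumab arm, $1.70/0.022$ chemotherapy arm; PFS: $1.75/0.029$ and
$2.27/0.028$). The month scale is not arbitrary: the implied medians
$(1/\lambda)^{1/\gamma}$ are then 14.0 months (OS) and 7.6 months (PFS)
for the pembrolizumab arm, matching the trial's reported 13.9 and 7.5
months; on any other time unit they do not.

Where per-cycle transition probabilities are needed they are the
conditional probabilities $p_i = 1 - S(t_{i+1})/S(t_i)$, never a constant
rate; the telescoping product $\prod_{i<n}(1-p_i) = S(t_n)$ then holds to
machine precision and is asserted in the tests.

### Fitting and model selection

`fit_parametric()` estimates any of six families (log-logistic, Weibull,
log-normal, Gompertz, exponential, gamma) by maximum likelihood under
right censoring, via `flexsurv`; `select_best()` picks the minimum-AIC fit
with BIC and then parsimony as tie-breaks. Two fitting modes are offered
because published curve-based analyses are ambiguous about theirs:
likelihood fitting of (reconstructed pseudo-)individual times is the
primary contract, and `fit_curve_ls()` fits digitised curve coordinates by
least squares as a secondary mode. Parameterisations per family are pinned
down by simulate-then-refit round-trip tests; the Gompertz is the one
family allowed a negative shape (decreasing hazard), since real fits
frequently land there.

A note on AIC selection with six candidate families: on genuinely
memoryless (exponential) data the exponential family is the modal winner
but is out-selected by one of the five two-parameter families in roughly a
third of replicates — the usual $\chi^2$ behaviour of likelihood-ratio
gains against a 2-point AIC penalty. The test suite asserts modal/majority
selection, not near-certainty.

### The synthetic Kaplan–Meier generator

`draw_surv_times()` simulates subjects by inverse-CDF from any supported
law (for the log-logistic, $t = ((1-u)/(\lambda u))^{1/\gamma}$), with
administrative censoring emulated as Uniform(0, 24 months) by default —
a stand-in for staggered accrual with a fixed cutoff, since real trial
censoring detail is not available. `km_curve()` returns the product-limit
curve (via `survival::survfit`) in the coordinate form a plot digitiser
would emit. This generator is what makes the fitting stage testable end to
end without any external data; it does not emulate number-at-risk
attrition patterns, informative censoring, or digitisation error, so
passing round-trip tests demonstrate estimator correctness, not robustness
to digitiser noise.

## Costs and utilities

All costs are 2021 USD. Per-cycle drug cost is
`dose_mg × admins_per_cycle × unit_cost`, with per-m² doses scaled by a
body surface area of 1.72 m². The default strategies are:

* **Pembrolizumab + chemotherapy**: pembrolizumab 200 mg flat q3w
  ($25.98/mg, up to 35 cycles), 5-FU 800 mg/m² on days 1–5 (5
  administrations per cycle, $0.03956/mg, up to 35 cycles), cisplatin
  80 mg/m² day 1 ($0.1036/mg, up to 6 cycles).
* **Chemotherapy**: the same backbone without pembrolizumab.

First-line drugs accrue against PFD occupancy up to their cycle caps —
treatment-until-progression capped at 35 (or 6) cycles, not the trial's
observed mean exposure. After progression both arms receive a 50/50 mix of
docetaxel 75 mg/m² q3w ($1.77/mg) and irinotecan 180 mg/m² q2w
($1.64/mg); the q2w schedule inside a 21-day cycle is rate-matched as 1.5
administrations per cycle rather than alternating integer doses. The
second-line mix runs for the whole PD occupancy (no duration is published
for it), and routine follow-up ($51.50 per cycle) accrues in both alive
states. Whether 5-FU stops with cisplatin at 6 cycles is unstated in the
source regimen; the default continues it to 35 (configurable via
`max_cycles_first_line`).

Grade ≥ 3 anaemia and neutropenia are modelled as acute one-off events at
model entry: expected cost $\sum_e p_e c_e$ and expected QALY loss
$\sum_e p_e |u_e| d$ with the disutility duration $d$ defaulting to one
cycle (21 days) in years. Incidences are arm-specific (12%/23%
pembrolizumab arm, 15%/17% chemotherapy arm); event costs ($73.68,
$67.56) and disutilities (−0.074, −0.090) are shared. State utilities are
0.741 (PFD) and 0.581 (PD).

## Accrual, discounting, half-cycle correction

Discounting is $1/(1+r)^{t/12}$ with $r = 0.05$ per year. Half-cycle
correction is on by default: per-cycle occupancy is the trapezoid average
of the cycle-start and cycle-end memberships, discounted at the mid-cycle
time; with the flag off, cycle-start membership and cycle-start
discounting are used (the convention under which the geometric-series
closed form in the tests is exact). Life-years are reported both
discounted and undiscounted; the headline comparisons use the discounted
variant. At the 21-day step the discretisation is converged — halving the
cycle length moves undiscounted life-years by well under 1%.

## Sensitivity analysis

**One-way (tornado)**: each configured parameter is set to its low and
high bound (drug prices use their published ranges — pembrolizumab
$12.99–25.98, i.e. −50% of the current price; most others ±20%; discount
0–8%) and the ICER is recomputed; bars are sorted by width. The
pembrolizumab cycle cap is varied as an integer 1–35, consistent with the
duration-threshold framing below.

**Probabilistic**: 10,000 Monte-Carlo draws re-run the deterministic model
with parameters sampled independently — gamma for costs, beta for
probabilities, utilities and disutility magnitudes, with hyper-parameters
moment-matched to mean = base value and sd = (high − low)/(2 × 1.96).
Three beta-labelled parameters (follow-up cost, body surface area,
discount rate) cannot live on [0, 1]; they are sampled from a beta
rescaled to their stated [low, high] range (a stretched beta), the
standard practice when a bounded quantity is given only a range. An
infeasible beta moment match (sd too large for the mean) is clipped to
the largest feasible sd with a message. Survival-curve parameters carry no
published uncertainty and are held fixed — a real limitation, since curve
uncertainty usually dominates; the CEAC therefore understates decision
uncertainty. Results are summarised as the incremental scatter (with a
bivariate-normal 95% ellipse) and the cost-effectiveness acceptability
curve, the fraction of draws with positive incremental net monetary
benefit $\mathrm{iNMB} = \mathrm{WTP}\cdot\Delta E - \Delta C$ at each
WTP.

**Thresholds**: `threshold_price()` bisects the pembrolizumab unit price
until the ICER is within $0.01/QALY of a target (the ICER is strictly
increasing in the price, a tested invariant); `threshold_cycles()` scans
integer caps 1–35 for the largest with ICER ≤ WTP.

## Numerical choices and degenerate inputs

* 174 cycles = `round(10 × 365.25 / 21)`; boundaries are exact multiples
  of 0.690 months.
* ICERs are formed from unrounded totals; rounding only at presentation
  (printed result tables that round components first are internally
  inconsistent at 2 decimals).
* Zero QALY difference returns an `undefined` flag rather than an
  infinite ICER; dominance quadrants are flagged, not thrown.
* All-censored fitting input and sub-10-subject tables are rejected;
  non-convergent optimisations surface as errors naming the family.
* Simulation seeds are mandatory arguments; draws save and restore the
  caller's RNG state.

## What the defaults reproduce — and what they cannot

With the default configuration the package computes a discounted
chemotherapy-arm total cost of about $9.5k, pembrolizumab-arm fitted
medians of 14.0 (OS) and 7.6 (PFS) months, and a base-case ICER far above
the WTP threshold — the qualitative conclusion that the combination is
not cost-effective at the current price, with the price and the
pembrolizumab cycle cap the dominant tornado bars.

Users should not expect the absolute life-year and QALY totals to match
every published cohort model built on the same trial. The log-logistic
parameters above imply 10-year restricted mean survival of roughly 2.0
(pembrolizumab arm) and 1.3 (chemotherapy arm) undiscounted life-years —
the area under the printed curves is an upper bound no partitioned-survival
model can exceed — whereas published TreeAge-based analyses of this
comparison report substantially larger totals without stating the
transition-probability construction, half-cycle convention, or
treatment-duration rule that would produce them. Where such structural
choices are unstated, this package documents its own (partitioned
survival, conditional per-cycle probabilities, half-cycle on,
treatment-to-progression with caps) and reports what they honestly yield.

## Problem sizes

The test suite simulates cohorts of 200–10,000 subjects for fitting and
KM checks, 1,000 subjects per parameter set for recovery, 60/30
replicates for the model-selection studies, and a 10,000-draw PSA; the
full deterministic model (two arms × 174 cycles) runs in a few
milliseconds, so the threshold scans and tornado are exact re-runs, not
approximations.
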