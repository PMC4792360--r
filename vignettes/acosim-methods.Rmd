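---
title: "Methods: an agent-based model of shared-savings ACOs for heart failure care"
author: "acosim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an agent-based model of shared-savings ACOs for heart failure care}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# What the model is

`acosim` simulates an accountable care organization (ACO) demonstration for
congestive heart failure (CHF) care in a Medicare 65+ population. Three kinds
of agents interact:

* **Patients** progress through a four-state disease model
  (`CHF_FREE`, `CHF_ONSITE` — diagnosed and managed as an outpatient,
  `CHF_HOSPITALIZED`, `DEAD`) on a 15-day cycle.
* **Providers** — 3 hospitals and 15 primary-care physicians (PCPs) per
  network — decide once a year whether to deliver a transitional-care
  intervention (comprehensive discharge planning with post-discharge
  follow-up), using a Theory of Planned Behavior (TPB) decision model.
* **A payer** reimburses fee-for-service care in both networks and settles a
  shared-savings contract with the ACO network, governed by the shared
  saving rate (SSR) and the sharing rate to hospitals (SRH).

Two provider networks serve statistically identical patient populations: the
**ACO network** under the shared-savings contract and a **controlled
network** under plain fee-for-service. The difference between the networks'
cost per CHF patient is the realized saving; the payer keeps `(1 - SSR)` of
it (the *saving to payer*, SSP) and distributes the rest to the ACO
providers (`SRH` of the pool to hospitals, the rest to PCPs, equal shares
within each type).

The simulator is a decision-support tool: outputs are Monte Carlo means and
95% confidence intervals of the annual CHF-related admission rate, the CHF
mortality rate, the payment per CHF patient and the SSP, plus experiment
drivers for payment-design sweeps and sensitivity analysis.

# Patient model

## Synthetic population

Patient characteristics (age group, race, gender, income; diabetes,
hypertension, CHF) are sampled through a conditional-probability chain,

$$P(C, H, D, \text{demo}) =
  P(C \mid H, D, \text{demo})\, P(H \mid D, \text{demo})\,
  P(D \mid \text{demo})\, P(\text{demo}),$$

so comorbidity correlations are induced by the conditional tables. The
tables that parameterise this chain are **synthetic**: the survey-derived
tables such a model would ideally be estimated from are not bundled, so
`default_population_spec()` ships implementer-chosen values that are
plausible for US Medicare 65+ (CHF prevalence ≈ 9–10%, diabetes ≈ 21%,
hypertension 55–85% depending on race and diabetes; all values are listed in
its help page). Every simulation-level test that depends on the population
mix is therefore a *property* test (orderings, conservation laws,
distributional identities), never a point match against externally reported outcome
levels: a green suite establishes that the mechanisms are wired correctly,
not that the synthetic cohort equals any particular real cohort.

Patients are assigned to a network by an independent fair coin (an exact
50/50 split is available as `network_assignment = "stratified"` for variance
reduction), and uniformly to one of the network's 15 PCPs and 3 hospitals.
Income is carried but has no effect on transitions — no effect size is established
— and remains available to user-supplied tables. Patients age by one year at
each year boundary, updating their age group.

## Disease dynamics

The cycle is 15 days; a simulation year is 24 cycles (a 360-day year). This
convention keeps every survival-curve knot on a cycle boundary and makes the
annual accounting exact; it also fixes the outpatient-visit process at a
per-cycle Poisson mean of $9/24 = 0.375$, so the expected number of regular
visits per year is exactly the configured 9. (Using 365.25-day years would
make "9 visits per year" unattainable in whole cycles.)

From `CHF_FREE`, a patient faces background mortality (a life-table-like
annual probability by age group and gender, converted per-cycle) and
risk-adjusted CHF incidence. Incidence risk multipliers (age group,
diabetes, hypertension) act on the hazard scale,
$p = 1 - (1-p_0)^{m}$, which keeps probabilities in $[0,1]$ for any
multiplier. Incident CHF enters through an outpatient diagnosis
(→ `CHF_ONSITE`) or an inpatient one (→ `CHF_HOSPITALIZED`) with a
configurable split (default 0.5); the diagnosis source permanently selects
which survival curve the patient faces, reflecting the clinical finding
that inpatient-diagnosed CHF carries much worse survival.

Diagnosed patients face a per-cycle hospitalization probability by age group
(0.01663 / 0.02360 / 0.03489 for 65–74 / 75–84 / 85+) and survival-curve
mortality. The survival curves (outpatient diagnosis: 1.00, 0.98, 0.87,
0.49; inpatient: 1.00, 0.84, 0.66, 0.33 at 0 d, 30 d, 1 y, 5 y) are
converted to per-cycle probabilities by piecewise-exponential
interpolation: within a knot interval the hazard is constant,
$\lambda_i = -\log(S_{i+1}/S_i)/(t_{i+1}-t_i)$, and the per-cycle
probability is $1 - e^{-15\lambda_i}$. Composition over the cycles of an
interval telescopes, so the tabulated proportions are reproduced exactly at
every knot; beyond 5 years the last hazard is extrapolated. CHF mortality
**replaces** background mortality for CHF patients (the source curves are
all-cause for CHF cohorts); an `"augment"` mode that combines both hazards
is available. Prevalent CHF cases at baseline receive a time-since-onset
drawn uniformly over the curve's 5-year support — the prevalent onset distribution is unknown, and this choice avoids concentrating the
(very high) early inpatient hazards on the whole prevalent pool.

Hospitalization is a one-cycle state: survivors are discharged back to
`CHF_ONSITE` at the next cycle, which is what makes a 30-day (2-cycle)
readmission window resolvable. Diabetes, hypertension and CHF are incurable:
the flags are monotone for the rest of the simulation. Death removes the
agent; the dead are not replaced.

## Intervention effects

The intervention reduces a covered CHF patient's per-cycle hospitalization
probability by 20% and mortality by 13% — but only at full strength when
**both** the patient's home hospital and PCP deliver it. If exactly one side
intervenes, the reductions are scaled by the partial-effect fraction
$\varphi$ (default 0.5, configurable; the partial effect has no
established magnitude). Coverage is annual: a patient is covered during a year in
which its providers intervene, matching the per-patient-*year*
intervention cost and the one-year duration of the intervention effect. A
post-discharge follow-up visit is generated in the cycle after each
discharge whenever the patient's PCP intervenes.

Non-CHF patients' regular visits are not simulated: every ledger in the
model counts CHF-related services only, so they could not affect any
output.

# Provider model

Each year, every ACO provider agent chooses its next-year behavior
$k \in \{0, 1\}$ (1 = deliver the intervention) by TPB: intention is formed
from attitude, subjective norm and perceived behavioral control, and
behavior follows a softmax choice over intentions. Controlled-network
agents always provide usual care.

## Attitude

$$A^k = \beta_1 U_p(EP^k) + \beta_2 U_q(EQ^k)$$

with provider types profit-oriented $\beta = (0.8, 0.2)$, quality-oriented
$(0.2, 0.8)$ and neutral $(0.5, 0.5)$. The expectations are adaptive:
$EP^0$ is the realized prior-year service profit per attributed CHF patient
and $EQ^0$ the realized admission and mortality rates; under $k = 1$ the
agent subtracts its intervention cost ($648 hospital, $69 PCP per
patient-year), adds its expected shared-saving receipt, and applies the
known 20%/13% risk reductions to the quality rates.

Only the range requirement is fixed — the $U$ transforms map into $[0, 1]$;
the package defaults are $U_p(x) = \operatorname{logistic}(x / 500)$ on
per-patient-year dollars (losses below 0.5, gains above; $500 is of the
order of the decision-relevant amounts — intervention costs and per-patient
shares) and
$U_q = 1 - \tfrac12 \min(h/1.5, 1) - \tfrac12 \min(m/0.5, 1)$ for an
admission rate $h$ and mortality rate $m$ against reference bounds 1.5
admissions/patient-year and 0.5 mortality. Both transforms are pluggable
through configuration.

**Shared-saving forecast.** The expected receipt in $EP^1$ is an *ex ante*
forecast: the agent projects the saving its intervention would sustain from
its own prior-year admission rate, $\hat S = h \cdot (14{,}822 + 2{,}668)
\cdot 0.20$ per patient, and takes its share of the projected pool
($\text{SSR} \cdot \text{SRH}$ of it for a hospital, scaled by attribution;
$\text{SSR}(1-\text{SRH})$ for a PCP). A purely backward-looking forecast
(last year's realized settlement share) cannot start the system — shares are
zero until someone adopts — and, worse, makes the adoption decision
insensitive to SSR, which is the central policy lever being studied. With
the ex-ante forecast, provider behavior responds to the payment design the
way the underlying theory intends.

## Subjective norm, PBC, intention, choice

Each cycle, every ACO agent sends one supportive message — for the behavior
its current attitude favors — to a uniformly random other ACO agent.
$SN^1 = nm^1 / (nm^0 + nm^1)$ over the year's received messages (0.5 when
none), $SN^0 = 1 - SN^1$.

Perceived behavioral control reflects that intervening is collaborative:
$PBC^1 = ni/ti$, the fraction of the year's discharge interactions (hospital
and PCP communicating at a patient's discharge) in which the counterpart was
intervening; with no interactions the prior value carries forward (initial
0.5). Not intervening needs no collaboration: $PBC^0 \equiv 1$.

Intention combines the three predictors as a convex combination with
configurable weights (equal by default; the underlying theory specifies the
predictors but not their combination), and behavior follows

$$P^1 = \frac{e^{I^1/\tau}}{e^{I^0/\tau} + e^{I^1/\tau}},$$

with $\tau = 0$ (the default) degenerating to the rational argmax, ties
breaking to usual care.

## Year-1 initialization

ACO agents start year 1 delivering the intervention (`initial_behavior = 1`,
configurable). The alternative — everyone starting at usual care — is an
**absorbing state** under the model's own rules: with no one intervening,
every discharge interaction records a non-intervening counterpart, so
$PBC^1 = 0$ while $PBC^0 = 1$; under equal intention weights the one-third
PBC deficit can never be overcome by attitude and norm (both confined to
$[0,1]$), so no rational agent can ever adopt and the entire
payment-response machinery is dead on arrival. Starting enrolled — as a
demonstration program would — lets incentives determine *sustainment*:
agents whose expected utilities do not justify the intervention drop out in
later years, which is what produces the SSR- and SRH-dependence of the
outcomes.

# Payment model

All flows are USD (2011). A CHF-related hospitalization costs the payer
$14,822 (hospital reimbursement) plus $2,668 (inpatient physician fee, 18%
of the hospital reimbursement); the hospital's own margin is −$1,186 per
admission. The printed −$1,186 is kept verbatim rather than re-derived from
an often-cited "−8.4%" Medicare margin estimate (whose base is ambiguous; −$1,186 is 8.0% of
$14,822). An outpatient visit costs the payer $85, of which the PCP nets
$34 after a 60% operating-cost share. The hospital intervention cost of
$648 per enrolled patient-year arises from a pooled $108/month over a
6-month program amortized across the 1-year effect window ($54/month); the
PCP's $69 is the opportunity cost of one forgone standard visit.

At each year end, the payer computes the CHF-related cost per CHF patient
in each network ("CHF patient" = anyone with CHF at any point of the year),
floors the saving at zero, shares `SSR` of it, splits the pool `SRH` /
`1 - SRH` between hospitals and PCPs with equal shares within type, and
keeps the rest. Internally all flows are kept at full floating precision;
only reports round. Two invariants are recomputed from independent
accumulation paths every year and exposed per-year as `ledger_ok`: payer
reimbursements equal the sum of gross provider receipts plus physician
fees, and the distributed pools sum exactly to the shared total.

# Engine and experiments

A run is deterministic given `(config, seed)`. Three named RNG streams —
`population`, `disease`, `behavior` — are derived from the master seed, so
changing, say, a behavioral parameter does not perturb the clinical event
sequence. Replications use per-replicate seeds derived from the master seed
and report mean ± 1.96·sd/√n for every outcome (normal approximation,
appropriate at the default 500 replications; tests and examples scale the
replicate count down and say so).

An "annual CHF-related hospitalization rate" is ambiguous between admissions per CHF patient-year and the share of CHF
patients with ≥ 1 admission; both are computed and reported
(`adm_rate`, `any_adm_share`), and neither is asserted against external point
values, which depend on population tables this package does not carry.

`run_baseline()` runs the mixed-provider design at SSR 0.5 / SRH 0.7;
`sweep_payment()` re-runs the replication experiment over SSR × SRH grids
for the baseline / all-profit / all-quality scenarios (common random
numbers across grid points); `run_sensitivity()` perturbs each of six
cost/effect parameters to 0.8× and 1.2× and ranks them by the absolute SSP
range. In the packaged configuration the SSP falls monotonically in SSR
(the payer keeps a smaller slice of a saving that grows more slowly than
the give-away), and the SSP is most sensitive to the intervention's effect
on hospitalization — the mechanism that generates essentially all of the
saving.

# Numerical choices and degenerate inputs

* Transition vectors are validated to sum to 1 within 1e-12; hazard-scale
  multipliers keep all probabilities in range by construction.
* Survival curves must start at (0, 1.0) and be non-increasing; an
  increasing segment is a validation error, zero survival is rejected
  (infinite hazard).
* Settlement inputs are floored at zero saving; a network-year with no CHF
  patients yields no settlement (the per-patient cost is undefined and
  `compute_network_cost_per_chf_patient()` errors on direct call).
* Softmax ties at `tau = 0` break to usual care; `tau > 0` draws from the
  exact logistic probability.
* Agents with no attributed CHF patients in a year fall back to
  network-level average rates and profits for their expectations.
* Messaging in a singleton network is a warned no-op.

# Limitations

* The population tables are synthetic; absolute outcome levels (e.g. the
  payment per CHF patient) depend on them and should not be read as
  calibrated estimates. Relative and qualitative results (orderings,
  responses to SSR/SRH, sensitivity rankings) are the intended outputs.
* The TPB utility transforms and intention weights are structural choices,
  not estimates from physician surveys; all are configurable.
* Only CHF-related utilization is modeled; comorbidity incidence affects
  CHF risk but carries no cost of its own.
* Quality gates on shared savings, risk-adjusted benchmarks, capitation and
  bundled payment are out of scope.
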