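# acosim

An agent-based simulator of **accountable care organization (ACO)
demonstrations for congestive heart failure (CHF) care**, for health-policy
analysts and health-services researchers who want to explore how
shared-savings payment designs shape provider behavior and payer outcomes
before committing to a costly real-world pilot.

Two provider networks — an ACO under a shared-savings contract and a
controlled network under plain fee-for-service — serve statistically
identical Medicare 65+ cohorts. Three mechanisms interact:

* **Disease microsimulation** (15-day cycle). Patients move through
  `CHF_FREE → CHF_ONSITE → CHF_HOSPITALIZED → DEAD` with age-group
  hospitalization probabilities (0.01663 / 0.02360 / 0.03489 per cycle for
  65–74 / 75–84 / 85+) and mortality from diagnosis-source-specific
  survival curves converted piecewise-exponentially: within a knot interval,
  λᵢ = −log(Sᵢ₊₁/Sᵢ)/(tᵢ₊₁−tᵢ) and the per-cycle death probability is
  1 − e^(−15λᵢ). A transitional-care intervention cuts a covered patient's
  hospitalization hazard by 20% and mortality by 13% — at full strength only
  when both the patient's hospital **and** PCP deliver it.

* **Provider decisions** (Theory of Planned Behavior, annual). Each ACO
  provider forms an attitude A^k = β₁U_p(EP^k) + β₂U_q(EQ^k) from expected
  profit and quality, a subjective norm from peer messages, and perceived
  behavioral control PBC¹ = ni/ti from discharge interactions (PBC⁰ ≡ 1),
  then chooses by softmax
  P¹ = exp(I¹/τ) / (exp(I⁰/τ) + exp(I¹/τ)), with τ = 0 the rational argmax.
  Provider types: profit-oriented β = (0.8, 0.2), quality-oriented
  (0.2, 0.8), neutral (0.5, 0.5).

* **Shared-savings settlement** (annual). The payer compares cost per CHF
  patient across networks, floors the saving at zero, awards the fraction
  **SSR** to providers (**SRH** of that pool to hospitals, the rest to
  PCPs, equal shares within type) and keeps the remainder (the saving to
  payer, SSP).

The population module generates synthetic cohorts through a conditional
chain P(CHF | HTN, DM, demo)·P(HTN | DM, demo)·P(DM | demo)·P(demo); the
shipped tables are documented synthetic choices, so simulation outputs are
meaningful as *relative* comparisons and response surfaces, not calibrated
national estimates (see the methods vignette, `vignettes/acosim-methods.Rmd`).

## Worked example

A settlement at illustrative values — controlled cost
$13,550, ACO cost $12,020 per CHF patient, SSR 0.5, SRH 0.7, 1,000 CHF
patients:

```r
library(acosim)
settle_shared_saving(13550, 12020, 1000, payment_config(ssr = 0.5, srh = 0.7))
#> Shared-saving settlement
#>   cost per CHF patient: controlled $13550, ACO $12020
#>   saving per CHF patient: $1530
#>   shared saving total: $765000 (each hospital $178500, each PCP $15300)
#>   saving to payer per CHF patient: $765 (5.65% of controlled cost)
```

Half of the $1,530 per-patient saving is shared; 70% of the shared pool is
split over 3 hospitals and 30% over 15 PCPs; the payer keeps $765 per CHF
patient — 5.65% of the controlled-network payment.

A scaled-down baseline experiment (2,000 patients, 5 years, 20
replications; the full design is 10,000 × 500):

```r
cfg <- simulation_config(n_patients = 2000, years = 5, seed = 42)
run_baseline(cfg, n_reps = 20, seed = 42)
#> Replication summary (scenario 'baseline', 20 runs), mean [95% CI]:
#>   aco_adm_rate               0.4779 [0.4665, 0.4892]
#>   controlled_adm_rate        0.5694 [0.5589, 0.58]
#>   aco_mort                   0.1338 [0.1297, 0.1379]
#>   controlled_mort            0.147 [0.1413, 0.1528]
#>   aco_reimb_per_chf          9033 [8834, 9231]
#>   controlled_reimb_per_chf   10590 [10410, 10780]
#>   saving_per_chf             1630 [1445, 1815]
#>   ssp_per_chf                815 [722.6, 907.5]
#>   intervening_hospitals      3 [3, 3]
#>   intervening_pcps           14.99 [14.97, 15.01]
```

Under the baseline SSR 0.5 / SRH 0.7 contract, the incentives sustain the
intervention across essentially all ACO providers; ACO patients are admitted
16% less often (0.478 vs 0.569 admissions per CHF patient-year) and die less
often (13.4% vs 14.7% annually), and the payer keeps about $815 per CHF
patient per year after distributing the providers' share. `sweep_payment()`
maps these outcomes over SSR × SRH grids and `run_sensitivity()` ranks
parameter influences on the SSP (a ±20% tornado analysis).

A thin command-line front end is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts", "acosim", package = "acosim"))')" \
  run --n 2000 --reps 20 --seed 42
```

## Acceptance script

`scripts/acceptance.R` re-runs the package's main computation from scratch —
the baseline replication experiment (2,000 patients, 5 years, 30
replications) — prints its summary, and writes the acceptance JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
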