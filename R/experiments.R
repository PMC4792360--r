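#' Provider-mix scenarios
#'
#' The three scenarios examined for payment-design sweeps: `"baseline"`
#' (one profit-oriented, one quality-oriented and one neutral hospital, PCPs
#' equally mixed across the three types), `"profit"` (all provider agents
#' profit-oriented) and `"quality"` (all quality-oriented).
#'
#' @param cfg a [simulation_config()] to re-type.
#' @param scenario scenario name.
#' @return the configuration with the scenario's provider mix applied.
#' @export
scenario_config <- function(cfg, scenario = c("baseline", "profit", "quality")) {
  scenario <- match.arg(scenario)
  mix <- switch(scenario,
    baseline = list(h = c("profit", "quality", "neutral"),
                    p = c(profit = 1 / 3, quality = 1 / 3, neutral = 1 / 3)),
    profit = list(h = "profit", p = c(profit = 1, quality = 0, neutral = 0)),
    quality = list(h = "quality", p = c(profit = 0, quality = 1, neutral = 0)))
  cfg$hospital_types <- mix$h
  cfg$pcp_mix <- mix$p
  cfg$scenario <- scenario
  cfg
}

#' Baseline experiment
#'
#' Runs the baseline design -- mixed provider types, SSR = 0.5, SRH = 0.7 --
#' and summarises the headline outcomes (admission rate, CHF mortality,
#' payment and saving per CHF patient) for both networks over replications.
#'
#' @param cfg a [simulation_config()]; its payment parameters are reset to
#'   the baseline SSR/SRH unless `keep_payment = TRUE`.
#' @param n_reps replications (default `cfg$n_replications`).
#' @param seed master seed.
#' @param keep_payment keep `cfg$payment` instead of the baseline (0.5, 0.7).
#' @return a [run_replications()] summary.
#' @export
run_baseline <- function(cfg = simulation_config(), n_reps = cfg$n_replications,
                         seed = cfg$seed, keep_payment = FALSE) {
  cfg <- scenario_config(cfg, "baseline")
  if (!keep_payment) {
    cfg$payment <- payment_config("shared_saving", ssr = 0.5, srh = 0.7)
  }
  run_replications(cfg, n_reps, seed)
}

#' Payment-parameter sweep
#'
#' Re-runs the replication experiment over a grid of SSR and SRH values for
#' a provider-mix scenario, returning one tidy row per (scenario, SSR, SRH)
#' with the replicate means and confidence bounds of the saving to payer,
#' admission rate and mortality outcomes.
#'
#' @param cfg a [simulation_config()].
#' @param scenario `"baseline"`, `"profit"` or `"quality"`.
#' @param ssr_grid,srh_grid numeric grids in `[0,1]` (defaults
#'   `seq(0.1, 0.9, 0.1)` and `seq(0, 1, 0.1)`).
#' @param n_reps replications per grid point.
#' @param seed master seed (each grid point uses the same replicate seeds,
#'   so grid contrasts are common-random-number comparisons).
#' @return data frame with columns `scenario`, `ssr`, `srh`, then for each
#'   outcome its replicate mean and 95% CI bounds.
#' @export
sweep_payment <- function(cfg = simulation_config(),
                          scenario = c("baseline", "profit", "quality"),
                          ssr_grid = seq(0.1, 0.9, by = 0.1),
                          srh_grid = seq(0, 1, by = 0.1),
                          n_reps = 50L, seed = cfg$seed) {
  scenario <- match.arg(scenario)
  if (any(ssr_grid < 0 | ssr_grid > 1 | srh_grid < 0 | srh_grid > 1)) {
    stop_acosim("grid values must lie in [0,1]")
  }
  cfg <- scenario_config(cfg, scenario)
  grid <- expand.grid(ssr = ssr_grid, srh = srh_grid, KEEP.OUT.ATTRS = FALSE)
  pick <- c("ssp_per_chf", "saving_per_chf", "aco_adm_rate",
            "controlled_adm_rate", "aco_mort", "controlled_mort")
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cfg$payment <- payment_config("shared_saving", ssr = grid$ssr[i],
                                  srh = grid$srh[i])
    rs <- run_replications(cfg, n_reps, seed)
    s <- rs$summary[match(pick, rs$summary$outcome), ]
    out <- data.frame(scenario = scenario, ssr = grid$ssr[i],
                      srh = grid$srh[i])
    for (j in seq_along(pick)) {
      out[[pick[j]]] <- s$mean[j]
      out[[paste0(pick[j], "_lo")]] <- s$lo[j]
      out[[paste0(pick[j], "_hi")]] <- s$hi[j]
    }
    out
  })
  do.call(rbind, rows)
}

sensitivity_parameters <- function() {
  c("rr_hosp", "rr_mort", "hospital_intervention_cost",
    "hospital_operating_cost", "pcp_intervention_cost",
    "pcp_operating_cost_fraction")
}

# apply a one-at-a-time multiplicative perturbation to a configuration
perturb_config <- function(cfg, parameter, factor) {
  cl <- cfg$clinical
  cs <- cfg$costs
  switch(parameter,
    rr_hosp = {
      cl <- utils::modifyList(unclass(cl),
                              list(rr_hosp = min(cl$rr_hosp * factor, 1)))
      class(cl) <- "transition_parameters"
    },
    rr_mort = {
      cl <- utils::modifyList(unclass(cl),
                              list(rr_mort = min(cl$rr_mort * factor, 1)))
      class(cl) <- "transition_parameters"
    },
    hospital_intervention_cost = {
      cs$hospital_intervention_cost_per_patient_year <-
        cs$hospital_intervention_cost_per_patient_year * factor
    },
    pcp_intervention_cost = {
      cs$pcp_intervention_cost_per_patient_year <-
        cs$pcp_intervention_cost_per_patient_year * factor
    },
    hospital_operating_cost = {
      # operating cost = reimbursement - (negative) margin
      op <- cs$hosp_reimbursement - cs$hospital_net_per_admission
      cs$hospital_net_per_admission <- cs$hosp_reimbursement - op * factor
    },
    pcp_operating_cost_fraction = {
      frac <- min(cs$pcp_operating_cost_fraction * factor, 0.95)
      cs <- cost_schedule(
        hosp_reimbursement = cs$hosp_reimbursement,
        hospital_net_per_admission = cs$hospital_net_per_admission,
        outpatient_reimbursement = cs$outpatient_reimbursement,
        physician_fee_fraction_of_hosp = cs$physician_fee_fraction_of_hosp,
        pcp_operating_cost_fraction = frac,
        pcp_net_per_visit = (1 - frac) * cs$outpatient_reimbursement,
        hospital_intervention_cost_per_patient_year =
          cs$hospital_intervention_cost_per_patient_year,
        pcp_intervention_cost_per_patient_year =
          cs$pcp_intervention_cost_per_patient_year,
        strict = FALSE)
    },
    stop_acosim("unknown sensitivity parameter: ", parameter))
  cfg$clinical <- cl
  cfg$costs <- cs
  cfg
}

#' One-at-a-time sensitivity analysis
#'
#' Perturbs each parameter to a lower (x0.8) and higher (x1.2) value with
#' everything else at baseline, recording the saving to payer (SSP) per CHF
#' patient, and ranks parameters by the absolute SSP range (tornado order).
#'
#' @param cfg a [simulation_config()].
#' @param parameters parameter names among
#'   `rr_hosp`, `rr_mort`, `hospital_intervention_cost`,
#'   `hospital_operating_cost`, `pcp_intervention_cost`,
#'   `pcp_operating_cost_fraction`.
#' @param factors perturbation factors, default `c(0.8, 1.2)`.
#' @param n_reps replications per point.
#' @param seed master seed (shared across points: common random numbers).
#' @return data frame (tornado table) sorted by decreasing `ssp_range`:
#'   `parameter`, `ssp_low`, `ssp_high`, `ssp_baseline`, `ssp_range`.
#' @export
run_sensitivity <- function(cfg = simulation_config(),
                            parameters = sensitivity_parameters(),
                            factors = c(0.8, 1.2),
                            n_reps = 20L, seed = cfg$seed) {
  if (length(factors) != 2L) stop_acosim("factors must give a low/high pair")
  ssp_of <- function(c2) {
    rs <- run_replications(c2, n_reps, seed)
    rs$summary$mean[rs$summary$outcome == "ssp_per_chf"]
  }
  base <- ssp_of(cfg)
  rows <- lapply(parameters, function(p) {
    lo <- ssp_of(perturb_config(cfg, p, factors[1]))
    hi <- ssp_of(perturb_config(cfg, p, factors[2]))
    data.frame(parameter = p, ssp_low = lo, ssp_high = hi,
               ssp_baseline = base, ssp_range = abs(hi - lo),
               factor_low = factors[1], factor_high = factors[2])
  })
  out <- do.call(rbind, rows)
  out[order(-out$ssp_range), , drop = FALSE]
}
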