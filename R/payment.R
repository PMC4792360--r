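#' Healthcare cost schedule (USD 2011)
#'
#' Cash flows of the modeled CHF services from each agent's perspective.
#' Defaults: a CHF-related hospitalization costs the payer the hospital
#' reimbursement of $14,822 plus an inpatient physician fee of $2,668 (18%
#' of the hospital reimbursement); the hospital itself loses $1,186 per
#' admission (negative Medicare margin). An outpatient visit costs the payer
#' $85, of which the PCP nets $34 after a 60% operating cost. The
#' transitional-care intervention costs a hospital $648 per enrolled patient
#' per year (see [amortize_intervention_cost()]) and a PCP $69 (the
#' opportunity cost of one forgone standard visit).
#'
#' @param hosp_reimbursement payer cost of hospital service per admission.
#' @param hospital_net_per_admission hospital margin per admission (negative).
#' @param outpatient_reimbursement payer cost per outpatient visit.
#' @param physician_fee_fraction_of_hosp inpatient physician fee as a
#'   fraction of the hospital reimbursement (0.18).
#' @param pcp_operating_cost_fraction PCP operating cost as a fraction of
#'   visit revenue (0.60).
#' @param inpatient_physician_fee,pcp_net_per_visit derived when omitted
#'   (`round(0.18 * 14822) = 2668`, `round(0.40 * 85) = 34`); if supplied
#'   they must satisfy those identities within rounding unless
#'   `strict = FALSE`.
#' @param hospital_intervention_cost_per_patient_year,pcp_intervention_cost_per_patient_year
#'   annual intervention costs (648, 69).
#' @param strict validate the derived-field identities (default TRUE;
#'   sensitivity perturbations disable it).
#' @return object of class `cost_schedule`.
#' @export
cost_schedule <- function(hosp_reimbursement = 14822,
                          hospital_net_per_admission = -1186,
                          outpatient_reimbursement = 85,
                          physician_fee_fraction_of_hosp = 0.18,
                          pcp_operating_cost_fraction = 0.60,
                          inpatient_physician_fee = NULL,
                          pcp_net_per_visit = NULL,
                          hospital_intervention_cost_per_patient_year = 648,
                          pcp_intervention_cost_per_patient_year = 69,
                          strict = TRUE) {
  derived_fee <- round(physician_fee_fraction_of_hosp * hosp_reimbursement)
  derived_net <- round((1 - pcp_operating_cost_fraction) *
                         outpatient_reimbursement)
  inpatient_physician_fee <- inpatient_physician_fee %||% derived_fee
  pcp_net_per_visit <- pcp_net_per_visit %||% derived_net
  if (strict) {
    if (abs(inpatient_physician_fee - derived_fee) > 0.5) {
      stop_acosim("inpatient_physician_fee must equal ",
                  "round(physician_fee_fraction_of_hosp * hosp_reimbursement)")
    }
    if (abs(pcp_net_per_visit - derived_net) > 0.5) {
      stop_acosim("pcp_net_per_visit must equal round((1 - ",
                  "pcp_operating_cost_fraction) * outpatient_reimbursement)")
    }
  }
  structure(list(
    hosp_reimbursement = hosp_reimbursement,
    hospital_net_per_admission = hospital_net_per_admission,
    inpatient_physician_fee = inpatient_physician_fee,
    outpatient_reimbursement = outpatient_reimbursement,
    pcp_net_per_visit = pcp_net_per_visit,
    physician_fee_fraction_of_hosp = physician_fee_fraction_of_hosp,
    pcp_operating_cost_fraction = pcp_operating_cost_fraction,
    hospital_intervention_cost_per_patient_year =
      hospital_intervention_cost_per_patient_year,
    pcp_intervention_cost_per_patient_year =
      pcp_intervention_cost_per_patient_year
  ), class = "cost_schedule")
}

#' Amortized intervention cost
#'
#' The pooled intervention cost is `monthly_cost` per patient per month over
#' an intervention of `months` months, while its clinical effect lasts
#' `window_months`; spreading the total over the effect window gives the
#' average monthly and annual cost. Defaults reproduce $108/month for 6
#' months amortized over 1 year: $54/month, $648/year.
#'
#' @param monthly_cost pooled cost per patient per month during delivery.
#' @param months delivery duration, months.
#' @param window_months amortization window, months.
#' @return list with `monthly` and `annual` amortized costs (USD).
#' @examples
#' amortize_intervention_cost(108, 6, 12)
#' @export
amortize_intervention_cost <- function(monthly_cost = 108, months = 6,
                                       window_months = 12) {
  monthly <- monthly_cost * months / window_months
  list(monthly = monthly, annual = monthly * 12)
}

#' Payment model configuration
#'
#' @param model `"shared_saving"` (the ACO contract) or `"ffs"` (plain
#'   fee-for-service; no settlement).
#' @param ssr shared saving rate: fraction of the realized saving awarded to
#'   providers (baseline 0.5).
#' @param srh sharing rate to hospital: fraction of the providers' share
#'   distributed to hospital agents, remainder to PCPs (baseline 0.7).
#' @return object of class `payment_config`.
#' @export
payment_config <- function(model = c("shared_saving", "ffs"),
                           ssr = 0.5, srh = 0.7) {
  model <- match.arg(model)
  if (ssr < 0 || ssr > 1 || srh < 0 || srh > 1) {
    stop_acosim("ssr and srh must lie in [0,1]")
  }
  structure(list(model = model, ssr = ssr, srh = srh),
            class = "payment_config")
}

#' Cash flows generated by a single billable event
#'
#' A hospitalization costs the payer the hospital reimbursement plus the
#' inpatient physician fee ($17,490 at defaults) and leaves the hospital
#' with its (negative) margin; an outpatient visit costs the payer $85 and
#' nets the PCP $34.
#'
#' @param event `"hospitalization"` or `"visit"`.
#' @param schedule a [cost_schedule()].
#' @return named list of flows (`payer`, `hospital`, `pcp`), payer outflows
#'   negative.
#' @export
reimburse_event <- function(event, schedule) {
  switch(event,
    hospitalization = list(
      payer = -(schedule$hosp_reimbursement + schedule$inpatient_physician_fee),
      hospital = schedule$hospital_net_per_admission,
      pcp = 0),
    visit = list(
      payer = -schedule$outpatient_reimbursement,
      hospital = 0,
      pcp = schedule$pcp_net_per_visit),
    stop_acosim("unknown event type: ", event))
}

#' Annual intervention cost for a provider
#'
#' @param kind `"hospital"` or `"pcp"`.
#' @param n_enrolled number of patients enrolled in the intervention that
#'   year (>= 0).
#' @param schedule a [cost_schedule()].
#' @return total cost, USD.
#' @export
annual_intervention_cost <- function(kind, n_enrolled, schedule) {
  if (n_enrolled < 0) stop_acosim("n_enrolled must be >= 0")
  per <- switch(kind,
                hospital = schedule$hospital_intervention_cost_per_patient_year,
                pcp = schedule$pcp_intervention_cost_per_patient_year,
                stop_acosim("unknown provider kind: ", kind))
  per * n_enrolled
}

#' Payer cost per CHF patient for a network-year
#'
#' @param payer_outflow total CHF-related payer outflow for the network-year
#'   (hospitalizations plus visits of CHF patients, and any shared saving
#'   already distributed), USD, as a positive number.
#' @param n_chf number of CHF patients the network served that year (> 0).
#' @return cost per CHF patient, USD.
#' @export
compute_network_cost_per_chf_patient <- function(payer_outflow, n_chf) {
  if (length(n_chf) != 1L || n_chf <= 0) {
    stop_acosim("cost per CHF patient is undefined when n_chf <= 0")
  }
  payer_outflow / n_chf
}

#' Shared-saving settlement
#'
#' The saving per CHF patient is the (floored-at-zero) difference between
#' the controlled network's and the ACO network's cost per CHF patient. The
#' providers' share is `ssr` of the total saving; `srh` of that pool goes to
#' the hospital agents and the remainder to the PCP agents, each pool split
#' equally within type. The payer keeps `(1 - ssr)` of the saving (SSP).
#'
#' @param controlled_cost,aco_cost cost per CHF patient in each network, USD
#'   (>= 0).
#' @param n_chf_aco number of CHF patients served by the ACO network.
#' @param cfg a [payment_config()].
#' @param n_hospitals,n_pcps provider counts in the ACO network.
#' @return object of class `savings_report`: `cost_per_chf_patient` (both
#'   networks), `saving_per_chf_patient`, `shared_saving_total`,
#'   `hospital_share_each`, `pcp_share_each`, `ssp_per_patient`,
#'   `percent_saving`.
#' @examples
#' settle_shared_saving(13550, 12020, 1000, payment_config(ssr = 0.5, srh = 0.7))
#' @export
settle_shared_saving <- function(controlled_cost, aco_cost, n_chf_aco, cfg,
                                 n_hospitals = 3L, n_pcps = 15L) {
  if (controlled_cost < 0 || aco_cost < 0 || n_chf_aco < 0) {
    stop_acosim("settlement inputs must be non-negative")
  }
  saving <- max(0, controlled_cost - aco_cost)
  shared_total <- if (cfg$model == "shared_saving") {
    cfg$ssr * saving * n_chf_aco
  } else {
    0
  }
  hospital_pool <- shared_total * cfg$srh
  pcp_pool <- shared_total - hospital_pool
  ssp_per_patient <- if (cfg$model == "shared_saving") {
    saving - cfg$ssr * saving
  } else {
    saving
  }
  structure(list(
    cost_per_chf_patient = c(controlled = controlled_cost, ACO = aco_cost),
    saving_per_chf_patient = saving,
    shared_saving_total = shared_total,
    hospital_share_each = hospital_pool / n_hospitals,
    pcp_share_each = pcp_pool / n_pcps,
    ssp_per_patient = ssp_per_patient,
    percent_saving = if (controlled_cost > 0) {
      100 * ssp_per_patient / controlled_cost
    } else {
      0
    }
  ), class = "savings_report")
}

#' @export
print.savings_report <- function(x, ...) {
  cat("Shared-saving settlement\n")
  cat(sprintf("  cost per CHF patient: controlled $%.0f, ACO $%.0f\n",
              x$cost_per_chf_patient[["controlled"]],
              x$cost_per_chf_patient[["ACO"]]))
  cat(sprintf("  saving per CHF patient: $%.0f\n", x$saving_per_chf_patient))
  cat(sprintf("  shared saving total: $%.0f (each hospital $%.0f, each PCP $%.0f)\n",
              x$shared_saving_total, x$hospital_share_each, x$pcp_share_each))
  cat(sprintf("  saving to payer per CHF patient: $%.0f (%.2f%% of controlled cost)\n",
              x$ssp_per_patient, x$percent_saving))
  invisible(x)
}
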