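#' Convert a survival curve to per-cycle mortality probabilities
#'
#' Piecewise-exponential interpolation: within each knot interval
#' `[t_i, t_{i+1}]` the hazard is constant,
#' `lambda_i = -log(S(t_{i+1}) / S(t_i)) / (t_{i+1} - t_i)`, so the per-cycle
#' death probability is `1 - exp(-lambda_i * cycle_days)`. Composing the
#' per-cycle survival over the cycles spanning an interval reproduces the
#' tabulated survival proportions exactly at the knots.
#'
#' @param curve data frame with columns `time_days` (ascending, starting at 0)
#'   and `survival` (non-increasing, starting at 1).
#' @param cycle_days cycle length in days (default 15).
#' @return data frame with one row per interval: `t_start`, `t_end`,
#'   `hazard_per_day`, `p_cycle`.
#' @examples
#' curve <- data.frame(time_days = c(0, 30, 360, 1800),
#'                     survival  = c(1, 0.98, 0.87, 0.49))
#' cycle_hazards_from_survival(curve)
#' @export
cycle_hazards_from_survival <- function(curve, cycle_days = 15) {
  if (!all(c("time_days", "survival") %in% names(curve))) {
    stop_acosim("survival curve needs columns time_days and survival")
  }
  t <- curve$time_days
  s <- curve$survival
  if (length(t) < 2L || t[1] != 0 || abs(s[1] - 1) > 1e-12) {
    stop_acosim("survival curve must start at (0 days, 1.0)")
  }
  if (any(diff(t) <= 0)) stop_acosim("survival curve times must be increasing")
  if (any(diff(s) > 1e-12)) {
    stop_acosim("survival curve has an increasing segment")
  }
  if (any(s <= 0)) stop_acosim("survival proportions must be positive")
  k <- length(t) - 1L
  lambda <- -log(s[-1] / s[-length(s)]) / diff(t)
  data.frame(t_start = t[-length(t)], t_end = t[-1],
             hazard_per_day = lambda,
             p_cycle = 1 - exp(-lambda * cycle_days))
}

default_survival_outpatient <- function() {
  data.frame(time_days = c(0, 30, 360, 1800),
             survival = c(1.00, 0.98, 0.87, 0.49))
}

default_survival_inpatient <- function() {
  data.frame(time_days = c(0, 30, 360, 1800),
             survival = c(1.00, 0.84, 0.66, 0.33))
}

default_background_mortality <- function() {
  # synthetic per-year all-cause mortality for non-CHF elders by age group
  # and gender, life-table-like magnitudes
  data.frame(age_group = rep(1:5, each = 2),
             gender = rep(c("female", "male"), 5),
             p_year = c(0.014, 0.020, 0.022, 0.032, 0.036, 0.051,
                        0.060, 0.079, 0.130, 0.151))
}

per_cycle_from_annual <- function(p_year, cycles_per_year) {
  1 - (1 - p_year)^(1 / cycles_per_year)
}

#' Clinical transition parameters
#'
#' Bundles every input of the 15-day-cycle patient state-transition model:
#' age-group-specific hospitalization probabilities for diagnosed CHF
#' patients, the outpatient- and inpatient-diagnosis survival curves (their
#' per-cycle hazards are precomputed piecewise-exponentially), risk-adjusted
#' CHF incidence, background mortality, comorbidity incidence, intervention
#' risk reductions, and the outpatient visit process.
#'
#' The simulation year is 24 cycles of 15 days (a 360-day year), so the
#' 1-year and 5-year survival knots fall on cycle boundaries and the Poisson
#' visit process with `visit_rate` 9/year has per-cycle mean 9/24 = 0.375.
#'
#' @param cycle_days cycle length, days (15).
#' @param cycles_per_year cycles per simulation year (24).
#' @param hosp_prob_by_age per-cycle probability of CHF-related
#'   hospitalization from the CHF-diagnosed state, by age group 1-5. Default
#'   `c(0.01663, 0.01663, 0.02360, 0.02360, 0.03489)` (65-74 / 75-84 / 85+).
#' @param survival_outpatient,survival_inpatient survival curves
#'   (`time_days`, `survival`) by diagnosis source; defaults 1.00/0.98/0.87/0.49
#'   and 1.00/0.84/0.66/0.33 at 0 d / 30 d / 1 y / 5 y.
#' @param chf_incidence_base per-cycle CHF incidence for an age-group-1
#'   patient with no comorbidity (default from 0.8%/year).
#' @param incidence_age_multipliers,incidence_diabetes_multiplier,
#'   incidence_hypertension_multiplier hazard-scale risk multipliers on CHF
#'   incidence (synthetic defaults 1/1.4/1.9/2.6/3.5 by age group, 2.0, 1.8).
#' @param p_incidence_inpatient share of incident CHF entering through a
#'   hospitalization rather than an outpatient diagnosis (default 0.5).
#' @param background_mortality data frame (`age_group`, `gender`, `p_year`)
#'   of annual all-cause mortality for patients without CHF.
#' @param diabetes_incidence_year annual diabetes incidence (default 0.012).
#' @param hypertension_incidence_year named annual hypertension incidence by
#'   race (default white 0.035, black 0.050, hispanic 0.040, other 0.035).
#' @param rr_hosp,rr_mort full-intervention relative risk reductions for
#'   hospitalization (0.20) and mortality (0.13).
#' @param partial_effect_fraction fraction phi of the risk reduction achieved
#'   when only one of hospital/PCP intervenes (default 0.5).
#' @param visit_rate regular outpatient visits per year (Poisson, 9).
#' @param mortality_mode `"replace"` (CHF survival-curve mortality replaces
#'   background mortality for CHF patients; default) or `"augment"`.
#' @return object of class `transition_parameters` with precomputed per-cycle
#'   quantities (`chf_mort_cycle`, `cycle_breaks`, per-cycle incidences).
#' @export
transition_parameters <- function(
    cycle_days = 15,
    cycles_per_year = 24L,
    hosp_prob_by_age = c(0.01663, 0.01663, 0.02360, 0.02360, 0.03489),
    survival_outpatient = default_survival_outpatient(),
    survival_inpatient = default_survival_inpatient(),
    chf_incidence_base = per_cycle_from_annual(0.008, 24),
    incidence_age_multipliers = c(1, 1.4, 1.9, 2.6, 3.5),
    incidence_diabetes_multiplier = 2.0,
    incidence_hypertension_multiplier = 1.8,
    p_incidence_inpatient = 0.5,
    background_mortality = default_background_mortality(),
    diabetes_incidence_year = 0.012,
    hypertension_incidence_year = c(white = 0.035, black = 0.050,
                                    hispanic = 0.040, other = 0.035),
    rr_hosp = 0.20,
    rr_mort = 0.13,
    partial_effect_fraction = 0.5,
    visit_rate = 9,
    mortality_mode = c("replace", "augment")) {
  mortality_mode <- match.arg(mortality_mode)
  probs <- c(hosp_prob_by_age, chf_incidence_base, p_incidence_inpatient,
             rr_hosp, rr_mort, partial_effect_fraction)
  if (any(probs < 0 | probs > 1)) {
    stop_acosim("all probabilities and risk reductions must lie in [0,1]")
  }
  if (length(hosp_prob_by_age) != 5L) {
    stop_acosim("hosp_prob_by_age must give one probability per age group 1-5")
  }
  if (visit_rate < 0) stop_acosim("visit_rate must be non-negative")
  haz_out <- cycle_hazards_from_survival(survival_outpatient, cycle_days)
  haz_in <- cycle_hazards_from_survival(survival_inpatient, cycle_days)
  if (!identical(haz_out$t_start, haz_in$t_start)) {
    stop_acosim("the two survival curves must share knot times")
  }
  bg <- background_mortality
  bg$p_cycle <- per_cycle_from_annual(bg$p_year, cycles_per_year)
  bgm <- matrix(NA_real_, 5, 2, dimnames = list(NULL, c("female", "male")))
  bgm[cbind(bg$age_group, match(bg$gender, colnames(bgm)))] <- bg$p_cycle
  if (anyNA(bgm)) {
    stop_acosim("background_mortality must cover all age groups and genders")
  }
  structure(list(
    cycle_days = cycle_days,
    cycles_per_year = as.integer(cycles_per_year),
    hosp_prob_by_age = hosp_prob_by_age,
    survival_outpatient = survival_outpatient,
    survival_inpatient = survival_inpatient,
    chf_mort_cycle = list(outpatient = haz_out$p_cycle,
                          inpatient = haz_in$p_cycle),
    cycle_breaks = haz_out$t_start / cycle_days,
    chf_incidence_base = chf_incidence_base,
    incidence_age_multipliers = incidence_age_multipliers,
    incidence_diabetes_multiplier = incidence_diabetes_multiplier,
    incidence_hypertension_multiplier = incidence_hypertension_multiplier,
    p_incidence_inpatient = p_incidence_inpatient,
    background_mortality = bg,
    bgm_matrix = bgm,
    diabetes_incidence = per_cycle_from_annual(diabetes_incidence_year,
                                               cycles_per_year),
    hypertension_incidence = per_cycle_from_annual(hypertension_incidence_year,
                                                   cycles_per_year),
    rr_hosp = rr_hosp,
    rr_mort = rr_mort,
    partial_effect_fraction = partial_effect_fraction,
    visit_rate = visit_rate,
    mortality_mode = mortality_mode
  ), class = "transition_parameters")
}

#' Per-cycle CHF mortality probability by time since onset
#'
#' Looks up the precomputed piecewise-exponential per-cycle death probability
#' for a CHF patient, given the diagnosis source (which survival curve) and
#' the number of completed cycles since onset. Beyond the last knot the final
#' interval's hazard is extrapolated.
#'
#' @param params [transition_parameters()].
#' @param source `"outpatient"` or `"inpatient"` (vectorised).
#' @param cycles_since_onset completed cycles since CHF onset (vectorised).
#' @return numeric vector of per-cycle death probabilities.
#' @export
chf_mortality_cycle_prob <- function(params, source, cycles_since_onset) {
  brk <- params$cycle_breaks          # interval start cycles, e.g. 0, 2, 24
  idx <- findInterval(cycles_since_onset, brk)
  idx[idx < 1L] <- 1L
  idx[idx > length(brk)] <- length(brk)
  out <- numeric(length(idx))
  for (src in c("outpatient", "inpatient")) {
    sel <- source == src
    if (any(sel)) out[sel] <- params$chf_mort_cycle[[src]][idx[sel]]
  }
  out
}

#' Effective intervention risk reduction
#'
#' Full risk reductions require collaboration: both the admitting hospital
#' and the patient's PCP must deliver the intervention. If only one side
#' intervenes, the reductions are scaled by the partial-effect fraction phi;
#' if neither, they are zero.
#'
#' @param hospital_intervenes,pcp_intervenes logical (vectorised).
#' @param params [transition_parameters()].
#' @return list with components `hosp` and `mort` (reductions in `[0,1]`).
#' @examples
#' effective_risk_reduction(TRUE, TRUE, transition_parameters())
#' @export
effective_risk_reduction <- function(hospital_intervenes, pcp_intervenes,
                                     params) {
  frac <- intervention_effect_fraction(hospital_intervenes, pcp_intervenes,
                                       params$partial_effect_fraction)
  list(hosp = frac * params$rr_hosp, mort = frac * params$rr_mort)
}

intervention_effect_fraction <- function(hosp, pcp, phi) {
  ifelse(hosp & pcp, 1, ifelse(hosp | pcp, phi, 0))
}

state_levels <- c("CHF_FREE", "CHF_ONSITE", "CHF_HOSPITALIZED", "DEAD")

#' Per-cycle transition probability vector for one patient
#'
#' Returns the categorical distribution over next states for a single
#' patient-cycle. From `CHF_FREE`: background mortality and risk-adjusted CHF
#' incidence, split between outpatient onset (to `CHF_ONSITE`) and inpatient
#' onset (to `CHF_HOSPITALIZED`). From `CHF_ONSITE`: survival-curve mortality
#' and the age-group hospitalization probability, both scaled down by the
#' effective intervention risk reduction. From `CHF_HOSPITALIZED`: mortality,
#' otherwise discharge back to `CHF_ONSITE`. Comorbidity incidence
#' (diabetes/hypertension) does not change the CHF state; the per-cycle
#' probabilities of acquiring each are attached as attributes
#' `p_new_diabetes` / `p_new_hypertension`.
#'
#' @param patient list or one-row data frame with `state`, `age_group`,
#'   `gender`, `race`, `has_diabetes`, `has_hypertension`, `chf_dx_source`,
#'   `cycles_since_onset`.
#' @param params [transition_parameters()].
#' @param hospital_intervenes,pcp_intervenes does the effective intervention
#'   currently cover this patient (from its admitting hospital / PCP)?
#' @return named probability vector over
#'   `CHF_FREE, CHF_ONSITE, CHF_HOSPITALIZED, DEAD`, summing to 1.
#' @export
transition_probabilities <- function(patient, params,
                                     hospital_intervenes = FALSE,
                                     pcp_intervenes = FALSE) {
  state <- patient$state
  if (state == "DEAD") stop_acosim("patient is dead; DEAD is absorbing")
  if (!state %in% state_levels) stop_acosim("unknown health state: ", state)
  ag <- patient$age_group
  if (is.na(ag) || ag < 1 || ag > 5) {
    stop_acosim("unknown age group: ", ag)
  }
  rr <- effective_risk_reduction(hospital_intervenes, pcp_intervenes, params)
  p <- c(CHF_FREE = 0, CHF_ONSITE = 0, CHF_HOSPITALIZED = 0, DEAD = 0)
  if (state == "CHF_FREE") {
    p_death <- params$bgm_matrix[ag, patient$gender]
    mult <- params$incidence_age_multipliers[ag] *
      (if (isTRUE(patient$has_diabetes)) params$incidence_diabetes_multiplier else 1) *
      (if (isTRUE(patient$has_hypertension)) params$incidence_hypertension_multiplier else 1)
    p_onset <- 1 - (1 - params$chf_incidence_base)^mult
    p_in <- p_onset * params$p_incidence_inpatient
    p["DEAD"] <- p_death
    p["CHF_HOSPITALIZED"] <- p_in
    p["CHF_ONSITE"] <- p_onset - p_in
    p["CHF_FREE"] <- 1 - p_death - p_onset
  } else {
    p_mort <- chf_mortality_cycle_prob(params, patient$chf_dx_source,
                                       patient$cycles_since_onset) *
      (1 - rr$mort)
    if (params$mortality_mode == "augment") {
      bg <- params$bgm_matrix[ag, patient$gender]
      p_mort <- 1 - (1 - p_mort) * (1 - bg)
    }
    if (state == "CHF_ONSITE") {
      p_hosp <- params$hosp_prob_by_age[ag] * (1 - rr$hosp)
      p["DEAD"] <- p_mort
      p["CHF_HOSPITALIZED"] <- p_hosp
      p["CHF_ONSITE"] <- 1 - p_mort - p_hosp
    } else {
      p["DEAD"] <- p_mort
      p["CHF_ONSITE"] <- 1 - p_mort  # discharge
    }
  }
  if (any(p < -1e-12)) stop_acosim("transition probabilities underflow zero")
  attr(p, "p_new_diabetes") <-
    if (isTRUE(patient$has_diabetes)) 0 else params$diabetes_incidence
  attr(p, "p_new_hypertension") <- if (isTRUE(patient$has_hypertension)) {
    0
  } else {
    unname(params$hypertension_incidence[patient$race])
  }
  p
}

#' Advance one patient by one cycle
#'
#' Draws the next state from [transition_probabilities()] and the comorbidity
#' side-transitions, and reports the events generated.
#'
#' @inheritParams transition_probabilities
#' @return list with the updated `patient` and an `events` character vector
#'   among `"hospitalization"`, `"discharge"`, `"death"`, `"chf_onset"`,
#'   `"new_diabetes"`, `"new_hypertension"`.
#' @export
step_patient <- function(patient, params, hospital_intervenes = FALSE,
                         pcp_intervenes = FALSE) {
  p <- transition_probabilities(patient, params, hospital_intervenes,
                                pcp_intervenes)
  old <- patient$state
  new <- state_levels[sample.int(4L, 1L, prob = p)]
  events <- character(0)
  if (new == "DEAD") events <- c(events, "death")
  if (old == "CHF_FREE" && new %in% c("CHF_ONSITE", "CHF_HOSPITALIZED")) {
    events <- c(events, "chf_onset")
    patient$has_chf <- TRUE
    patient$chf_dx_source <- if (new == "CHF_HOSPITALIZED") "inpatient" else "outpatient"
    patient$cycles_since_onset <- 0L
  } else if (isTRUE(patient$has_chf)) {
    patient$cycles_since_onset <- patient$cycles_since_onset + 1L
  }
  if (new == "CHF_HOSPITALIZED") events <- c(events, "hospitalization")
  if (old == "CHF_HOSPITALIZED" && new == "CHF_ONSITE") {
    events <- c(events, "discharge")
  }
  if (new != "DEAD") {
    if (stats::runif(1) < attr(p, "p_new_diabetes")) {
      patient$has_diabetes <- TRUE
      events <- c(events, "new_diabetes")
    }
    if (stats::runif(1) < attr(p, "p_new_hypertension")) {
      patient$has_hypertension <- TRUE
      events <- c(events, "new_hypertension")
    }
  }
  patient$state <- new
  list(patient = patient, events = events)
}

#' Outpatient visits generated in one cycle
#'
#' Regular visits follow a Poisson process with rate `visit_rate` per year,
#' i.e. per-cycle mean `visit_rate / cycles_per_year` (0.375 at the
#' defaults). A deterministic post-discharge follow-up visit is added in the
#' cycle after a discharge when the patient's PCP delivers the intervention.
#'
#' @param params [transition_parameters()].
#' @param n number of patient-cycles to draw (default 1).
#' @param followup_due logical (recycled): discharge occurred last cycle and
#'   the PCP intervenes.
#' @return integer vector of visit counts.
#' @export
sample_outpatient_visits <- function(params, n = 1L, followup_due = FALSE) {
  lambda <- params$visit_rate / params$cycles_per_year
  stats::rpois(n, lambda) + as.integer(rep_len(followup_due, n))
}
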