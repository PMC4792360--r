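#' Provider agent roster
#'
#' Builds the hospital and PCP agents of the two networks. Each agent has a
#' type (profit-oriented beta = (0.8, 0.2), quality-oriented (0.2, 0.8) or
#' neutral (0.5, 0.5)) governing how its attitude weighs expected profit
#' against expected quality, a current behavior `k` (1 = deliver the CHF
#' intervention, 0 = usual care), and Theory-of-Planned-Behavior bookkeeping
#' (supportive-message counts, discharge-interaction counts, prior perceived
#' behavioral control). Controlled-network agents always keep `k = 0`.
#'
#' @param n_hospitals,n_pcps agents per network (3 and 15).
#' @param hospital_types character vector recycled over the ACO hospitals
#'   (baseline: one profit-oriented, one quality-oriented, one neutral).
#' @param pcp_mix named proportions over `profit`, `quality`, `neutral` for
#'   ACO PCP typing.
#' @param pcp_assignment `"exact"` (deterministic proportional split,
#'   variance reduction) or `"bernoulli"` (independent draw per PCP; uses the
#'   current RNG state).
#' @param initial_behavior starting behavior of ACO agents in year 1
#'   (default 1: the demonstration begins with every ACO provider enrolled;
#'   see the methods vignette for why an all-usual-care start is absorbing
#'   under rational choice).
#' @return data frame of class `provider_roster`, one row per agent.
#' @export
provider_roster <- function(n_hospitals = 3L, n_pcps = 15L,
                            hospital_types = c("profit", "quality", "neutral"),
                            pcp_mix = c(profit = 1 / 3, quality = 1 / 3,
                                        neutral = 1 / 3),
                            pcp_assignment = c("exact", "bernoulli"),
                            initial_behavior = 1L) {
  pcp_assignment <- match.arg(pcp_assignment)
  if (abs(sum(pcp_mix) - 1) > 1e-9 || any(pcp_mix < 0)) {
    stop_acosim("pcp_mix proportions must be non-negative and sum to 1")
  }
  h_types <- rep_len(hospital_types, n_hospitals)
  p_types <- if (pcp_assignment == "exact") {
    counts <- diff(round(cumsum(c(0, pcp_mix)) * n_pcps))
    rep(names(pcp_mix), times = counts)
  } else {
    sample(names(pcp_mix), n_pcps, replace = TRUE, prob = pcp_mix)
  }
  one_network <- function(network, behavior) {
    kind <- c(rep("hospital", n_hospitals), rep("pcp", n_pcps))
    type <- c(h_types, p_types)
    data.frame(
      id = sprintf("%s_%s_%d", network, kind,
                   c(seq_len(n_hospitals), seq_len(n_pcps))),
      network = network, kind = kind,
      idx = c(seq_len(n_hospitals), seq_len(n_pcps)),
      type = type,
      beta1 = beta_weights(type)[, 1], beta2 = beta_weights(type)[, 2],
      behavior = behavior,
      fav = behavior,               # attitude-favored behavior (messaging)
      nm0 = 0, nm1 = 0,             # supportive messages received, by k
      ni = 0, ti = 0,               # intervening / total discharge interactions
      pbc_prev = 0.5,
      gross = 0, net_service = 0, int_cost = 0, share = 0,
      adm_own = 0, deaths_own = 0, n_chf_own = 0,
      stringsAsFactors = FALSE)
  }
  roster <- rbind(one_network("ACO", as.integer(initial_behavior)),
                  one_network("controlled", 0L))
  class(roster) <- c("provider_roster", "data.frame")
  roster
}

beta_weights <- function(type) {
  tab <- rbind(profit = c(0.8, 0.2), quality = c(0.2, 0.8),
               neutral = c(0.5, 0.5))
  bad <- !type %in% rownames(tab)
  if (any(bad)) stop_acosim("unknown provider type: ", type[bad][1])
  tab[type, , drop = FALSE]
}

check_simplex <- function(w, what) {
  if (any(w < 0) || abs(sum(w) - 1) > 1e-9) {
    stop_acosim(what, " must be non-negative and sum to 1")
  }
}

#' Attitude toward a behavior
#'
#' `A = beta1 * U_p + beta2 * U_q`: a convex combination of the profit
#' utility and the quality utility of the expected consequences of the
#' behavior. Profit-oriented agents use beta = (0.8, 0.2), quality-oriented
#' (0.2, 0.8), neutral (0.5, 0.5).
#'
#' @param u_profit,u_quality utilities in `[0,1]`.
#' @param beta length-2 non-negative weights summing to 1.
#' @return attitude in `[0,1]`.
#' @examples
#' compute_attitude(0.5, 0.25, c(0.8, 0.2))  # 0.45
#' @export
compute_attitude <- function(u_profit, u_quality, beta) {
  check_simplex(beta, "beta")
  if (any(u_profit < 0 | u_profit > 1 | u_quality < 0 | u_quality > 1)) {
    stop_acosim("utilities must lie in [0,1]")
  }
  beta[1] * u_profit + beta[2] * u_quality
}

#' Utility transforms for expected profit and expected quality
#'
#' The model only requires monotone maps into `[0,1]`; these are the package
#' defaults. `utility_profit` is a logistic transform of expected profit per
#' CHF patient-year (USD): losses map below 0.5, gains above, with
#' sensitivity set by `scale`. `utility_quality` scores an expected
#' (hospitalization rate, mortality rate) pair linearly against reference
#' upper bounds; lower adverse-event rates give higher utility.
#'
#' @param x expected profit per patient-year, USD.
#' @param scale logistic scale in USD (default 500).
#' @return utility in `[0,1]`.
#' @export
utility_profit <- function(x, scale = 500) {
  stats::plogis(x / scale)
}

#' @rdname utility_profit
#' @param hosp_rate expected annual admissions per CHF patient.
#' @param mort_rate expected annual CHF mortality rate.
#' @param ref named reference bounds `c(hosp = , mort = )` at which each
#'   component's utility reaches 0 (defaults 1.5 admissions/patient-year and
#'   0.5 mortality).
#' @export
utility_quality <- function(hosp_rate, mort_rate,
                            ref = c(hosp = 1.5, mort = 0.5)) {
  1 - 0.5 * pmin(pmax(hosp_rate, 0) / ref[["hosp"]], 1) -
    0.5 * pmin(pmax(mort_rate, 0) / ref[["mort"]], 1)
}

#' Expected profit and quality of each behavior
#'
#' Adaptive expectations from the agent's prior-year experience. For usual
#' care (`k = 0`) the expectations are the realized per-CHF-patient service
#' profit and the realized admission and mortality rates. For intervening
#' (`k = 1`) the agent subtracts its intervention cost per patient-year,
#' adds the expected shared-saving share per patient, and applies the known
#' intervention risk reductions to the quality rates.
#'
#' @param service_profit_per_patient realized prior-year service profit per
#'   CHF patient, USD.
#' @param hosp_rate,mort_rate realized prior-year annual admission and
#'   mortality rates among the agent's CHF patients.
#' @param intervention_cost_per_patient 648 (hospital) or 69 (PCP) USD.
#' @param shared_saving_forecast_per_patient expected shared-saving receipt
#'   per CHF patient if the intervention sustains the saving (0 under pure
#'   fee-for-service).
#' @param params [transition_parameters()] (supplies `rr_hosp`, `rr_mort`).
#' @param profit_scale,quality_ref passed to [utility_profit()] /
#'   [utility_quality()].
#' @return list with `ep0`, `ep1` (USD), `eq0`, `eq1` (rate pairs), and the
#'   utilities `up0`, `up1`, `uq0`, `uq1`.
#' @export
estimate_expectations <- function(service_profit_per_patient,
                                  hosp_rate, mort_rate,
                                  intervention_cost_per_patient,
                                  shared_saving_forecast_per_patient,
                                  params,
                                  profit_scale = 500,
                                  quality_ref = c(hosp = 1.5, mort = 0.5)) {
  ep0 <- service_profit_per_patient
  ep1 <- service_profit_per_patient - intervention_cost_per_patient +
    shared_saving_forecast_per_patient
  eq0 <- c(hosp = hosp_rate, mort = mort_rate)
  eq1 <- c(hosp = hosp_rate * (1 - params$rr_hosp),
           mort = mort_rate * (1 - params$rr_mort))
  list(ep0 = ep0, ep1 = ep1, eq0 = eq0, eq1 = eq1,
       up0 = utility_profit(ep0, profit_scale),
       up1 = utility_profit(ep1, profit_scale),
       uq0 = utility_quality(eq0[["hosp"]], eq0[["mort"]], quality_ref),
       uq1 = utility_quality(eq1[["hosp"]], eq1[["mort"]], quality_ref))
}

#' One round of peer message passing
#'
#' Each agent in the network sends one supportive message per round -- for
#' the behavior its current attitude favors (column `fav`) -- to a uniformly
#' random *other* agent in the same network. Recipients accumulate the
#' counts `nm0` / `nm1` that feed the subjective norm.
#'
#' @param roster a [provider_roster()].
#' @param network which network's agents exchange messages (default "ACO";
#'   controlled-network agents make no decisions so never message).
#' @param rounds number of rounds (default 1).
#' @return the roster with updated `nm0`, `nm1`.
#' @export
exchange_messages <- function(roster, network = "ACO", rounds = 1L) {
  rows <- which(roster$network == network)
  m <- length(rows)
  if (m < 2L) {
    warning("message exchange needs at least two agents; no-op")
    return(roster)
  }
  for (r in seq_len(rounds)) {
    pos <- sample.int(m - 1L, m, replace = TRUE)
    rec <- rows[ifelse(pos >= seq_len(m), pos + 1L, pos)]
    supp <- roster$fav[rows]
    roster$nm1[rows] <- roster$nm1[rows] +
      tabulate(match(rec[supp == 1L], rows), m)
    roster$nm0[rows] <- roster$nm0[rows] +
      tabulate(match(rec[supp == 0L], rows), m)
  }
  roster
}

#' Subjective norm from received messages
#'
#' `SN^1` is the share of supportive messages favoring the intervention,
#' `nm1 / (nm0 + nm1)`; with no messages received the agent is uninformed
#' and both norms default to 0.5. `SN^0 = 1 - SN^1`.
#'
#' @param nm0,nm1 message counts (vectorised, non-negative).
#' @return list with components `sn0` and `sn1` in `[0,1]`.
#' @examples
#' compute_subjective_norm(1, 3)$sn1  # 0.75
#' @export
compute_subjective_norm <- function(nm0, nm1) {
  if (any(nm0 < 0 | nm1 < 0)) stop_acosim("message counts must be >= 0")
  tot <- nm0 + nm1
  sn1 <- ifelse(tot > 0, nm1 / tot, 0.5)
  list(sn0 = 1 - sn1, sn1 = sn1)
}

#' Record a discharge interaction
#'
#' When a patient is discharged, its hospital and PCP communicate; each side
#' counts the interaction (`ti`) and additionally counts it as an
#' intervening interaction (`ni`) when the counterpart's behavior is
#' `k = 1`.
#'
#' @param roster a [provider_roster()].
#' @param hospital_row,pcp_row row indices of the two parties.
#' @return the updated roster.
#' @export
record_interaction <- function(roster, hospital_row, pcp_row) {
  roster$ti[c(hospital_row, pcp_row)] <- roster$ti[c(hospital_row, pcp_row)] + 1
  roster$ni[hospital_row] <- roster$ni[hospital_row] + roster$behavior[pcp_row]
  roster$ni[pcp_row] <- roster$ni[pcp_row] + roster$behavior[hospital_row]
  roster
}

#' Perceived behavioral control
#'
#' `PBC^1 = ni / ti`, the observed fraction of discharge interactions in
#' which the counterpart was delivering the intervention; with no
#' interactions the previous year's value carries forward (initial 0.5).
#' Not intervening requires no collaboration, so `PBC^0 = 1` always.
#'
#' @param ni,ti interaction counts, `ni <= ti` (vectorised).
#' @param prev carried-forward value used when `ti = 0` (default 0.5).
#' @return list with components `pbc1` and `pbc0`.
#' @examples
#' compute_pbc(3, 4)$pbc1  # 0.75
#' @export
compute_pbc <- function(ni, ti, prev = 0.5) {
  if (any(ni < 0 | ti < 0)) stop_acosim("interaction counts must be >= 0")
  if (any(ni > ti)) stop_acosim("ni cannot exceed ti")
  list(pbc1 = ifelse(ti > 0, ni / ti, prev), pbc0 = rep_len(1, length(ni)))
}

#' Behavioral intention
#'
#' Convex combination of the three TPB predictors,
#' `I^k = w_A A^k + w_SN SN^k + w_PBC PBC^k`, equal weights by default (the
#' underlying theory fixes the predictors, not their combination).
#'
#' @param attitude,subjective_norm,pbc predictor values in `[0,1]`
#'   (vectorised).
#' @param weights length-3 non-negative weights summing to 1.
#' @return intention in `[0,1]`.
#' @export
compute_intention <- function(attitude, subjective_norm, pbc,
                              weights = c(1, 1, 1) / 3) {
  check_simplex(weights, "intention weights")
  vals <- c(attitude, subjective_norm, pbc)
  if (any(vals < -1e-12 | vals > 1 + 1e-12)) {
    stop_acosim("TPB predictors must lie in [0,1]")
  }
  weights[1] * attitude + weights[2] * subjective_norm + weights[3] * pbc
}

#' Softmax probability of choosing the intervention
#'
#' `P^1 = exp(I^1/tau) / (exp(I^0/tau) + exp(I^1/tau))`. The temperature
#' `tau` sets the irrationality level; as `tau -> 0` the choice degenerates
#' to the argmax (rational agent), with ties broken toward usual care.
#'
#' @param i0,i1 intentions of the two behaviors.
#' @param tau temperature, `>= 0`; `tau = 0` selects the argmax.
#' @return probability of `k = 1`.
#' @examples
#' choice_probability(0, 1, 1)  # exp(1) / (1 + exp(1))
#' @export
choice_probability <- function(i0, i1, tau) {
  if (any(tau < 0)) stop_acosim("tau must be >= 0")
  if (tau == 0) return(as.numeric(i1 > i0))
  d <- (i1 - i0) / tau
  1 / (1 + exp(-d))
}

#' Choose a behavior from intentions
#'
#' Draws `k` from the softmax distribution (or deterministically at
#' `tau = 0`), using the current RNG state.
#'
#' @inheritParams choice_probability
#' @return integer behavior, 0 or 1.
#' @export
choose_behavior <- function(i0, i1, tau = 0) {
  p1 <- choice_probability(i0, i1, tau)
  if (tau == 0) return(as.integer(p1))
  as.integer(stats::runif(1) < p1)
}

# Annual TPB decision pass over the ACO agents. `stats` carries network-level
# fallbacks for agents with no attributed CHF patients. Uses the current RNG
# state for softmax draws.
tpb_update <- function(roster, pay, costs, params, opts, stats) {
  aco <- which(roster$network == "ACO")
  trace <- vector("list", length(aco))
  for (j in seq_along(aco)) {
    r <- aco[j]
    kind <- roster$kind[r]
    n_own <- roster$n_chf_own[r]
    if (n_own > 0) {
      adm_rate <- roster$adm_own[r] / n_own
      mort_rate <- roster$deaths_own[r] / n_own
      profit_pt <- roster$net_service[r] / n_own
    } else {
      adm_rate <- stats$adm_rate
      mort_rate <- stats$mort_rate
      profit_pt <- stats$profit_pt[[kind]]
    }
    c_int <- if (kind == "hospital") {
      costs$hospital_intervention_cost_per_patient_year
    } else {
      costs$pcp_intervention_cost_per_patient_year
    }
    share_fc <- 0
    if (identical(pay$model, "shared_saving") && stats$n_chf_aco > 0) {
      saving_fc <- adm_rate *
        (costs$hosp_reimbursement + costs$inpatient_physician_fee) *
        params$rr_hosp
      pool_frac <- if (kind == "hospital") pay$srh else 1 - pay$srh
      n_kind <- sum(roster$network == "ACO" & roster$kind == kind)
      share_fc <- pay$ssr * saving_fc * pool_frac *
        stats$n_chf_aco / (n_kind * max(n_own, 1))
    }
    ex <- estimate_expectations(profit_pt, adm_rate, mort_rate, c_int,
                                share_fc, params,
                                profit_scale = opts$profit_scale,
                                quality_ref = opts$quality_ref)
    beta <- c(roster$beta1[r], roster$beta2[r])
    a1 <- compute_attitude(ex$up1, ex$uq1, beta)
    a0 <- compute_attitude(ex$up0, ex$uq0, beta)
    sn <- compute_subjective_norm(roster$nm0[r], roster$nm1[r])
    pbc <- compute_pbc(roster$ni[r], roster$ti[r], roster$pbc_prev[r])
    i1 <- compute_intention(a1, sn$sn1, pbc$pbc1, opts$intention_weights)
    i0 <- compute_intention(a0, sn$sn0, pbc$pbc0, opts$intention_weights)
    k <- choose_behavior(i0, i1, opts$tau)
    roster$pbc_prev[r] <- pbc$pbc1
    roster$behavior[r] <- k
    roster$fav[r] <- if (a1 > a0) 1L else if (a1 < a0) 0L else k
    trace[[j]] <- data.frame(id = roster$id[r], kind = kind,
                             type = roster$type[r],
                             A0 = a0, A1 = a1, SN1 = sn$sn1, PBC1 = pbc$pbc1,
                             I0 = i0, I1 = i1, behavior = k,
                             stringsAsFactors = FALSE)
  }
  list(roster = roster, trace = do.call(rbind, trace))
}
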