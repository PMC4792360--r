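#' Simulation configuration
#'
#' Assembles every input of a simulation run: the cohort and network sizes,
#' horizon, payment model, population specification, clinical transition
#' parameters, cost schedule, provider mix and the behavioral-model options.
#' Defaults follow the demonstration setting: 10,000 patients, two networks
#' of 3 hospitals and 15 PCPs, 5 simulation years of 24 fifteen-day cycles,
#' SSR 0.5 / SRH 0.7, and 500 replications.
#'
#' @param years simulation horizon in years (default 5).
#' @param n_patients cohort size (default 10000).
#' @param n_hospitals,n_pcps providers per network (3, 15).
#' @param n_replications default replication count for
#'   [run_replications()] (500).
#' @param seed default master seed.
#' @param payment a [payment_config()].
#' @param population a [population_spec()].
#' @param clinical a [transition_parameters()].
#' @param costs a [cost_schedule()].
#' @param hospital_types,pcp_mix,pcp_assignment ACO provider typing, see
#'   [provider_roster()].
#' @param network_assignment patient-to-network rule, see
#'   [generate_cohort()].
#' @param tau softmax temperature (0 = rational argmax, the default).
#' @param intention_weights TPB predictor weights (equal by default).
#' @param initial_behavior year-1 behavior of ACO agents (default 1).
#' @param force_behavior `NULL` (agents decide via TPB) or 0/1 to pin every
#'   ACO agent's behavior for the whole run (used for null-model and
#'   full-intervention experiments).
#' @param profit_scale,quality_ref utility-transform options, see
#'   [utility_profit()].
#' @param messages_per_cycle supportive messages each ACO agent sends per
#'   cycle (default 1, i.e. 24 per year).
#' @param scenario free-text label carried into outputs.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(years = 5L,
                              n_patients = 10000L,
                              n_hospitals = 3L,
                              n_pcps = 15L,
                              n_replications = 500L,
                              seed = 1L,
                              payment = payment_config(),
                              population = default_population_spec(),
                              clinical = transition_parameters(),
                              costs = cost_schedule(),
                              hospital_types = c("profit", "quality", "neutral"),
                              pcp_mix = c(profit = 1 / 3, quality = 1 / 3,
                                          neutral = 1 / 3),
                              pcp_assignment = c("exact", "bernoulli"),
                              network_assignment = c("bernoulli", "stratified"),
                              tau = 0,
                              intention_weights = c(1, 1, 1) / 3,
                              initial_behavior = 1L,
                              force_behavior = NULL,
                              profit_scale = 500,
                              quality_ref = c(hosp = 1.5, mort = 0.5),
                              messages_per_cycle = 1L,
                              scenario = "baseline") {
  counts <- c(years, n_patients, n_hospitals, n_pcps)
  if (any(counts < 1)) stop_acosim("years and all counts must be >= 1")
  stopifnot(inherits(payment, "payment_config"),
            inherits(population, "population_spec"),
            inherits(clinical, "transition_parameters"),
            inherits(costs, "cost_schedule"))
  check_simplex(intention_weights, "intention weights")
  if (!is.null(force_behavior) && !force_behavior %in% c(0L, 1L)) {
    stop_acosim("force_behavior must be NULL, 0 or 1")
  }
  structure(list(
    years = as.integer(years), n_patients = as.integer(n_patients),
    n_hospitals = as.integer(n_hospitals), n_pcps = as.integer(n_pcps),
    n_replications = as.integer(n_replications), seed = as.integer(seed),
    payment = payment, population = population, clinical = clinical,
    costs = costs,
    hospital_types = hospital_types, pcp_mix = pcp_mix,
    pcp_assignment = match.arg(pcp_assignment),
    network_assignment = match.arg(network_assignment),
    tau = tau, intention_weights = intention_weights,
    initial_behavior = as.integer(initial_behavior),
    force_behavior = force_behavior,
    profit_scale = profit_scale, quality_ref = quality_ref,
    messages_per_cycle = as.integer(messages_per_cycle),
    scenario = scenario
  ), class = "simulation_config")
}

#' Initialize simulation state
#'
#' Generates the cohort (population stream), builds the provider roster and
#' pre-computes per-patient lookups. The returned environment is mutated in
#' place by [run_year()].
#'
#' @param cfg a [simulation_config()].
#' @param seed master seed (defaults to `cfg$seed`).
#' @return an environment of class `aco_state`.
#' @export
initialize_simulation <- function(cfg, seed = cfg$seed) {
  streams <- make_rng_streams(seed)
  S <- new.env(parent = emptyenv())
  S$cfg <- cfg
  S$params <- cfg$clinical
  S$costs <- cfg$costs
  S$pay <- cfg$payment
  S$streams <- streams
  S$year <- 0L
  S$trace <- list()

  cohort <- with_rng_stream(streams, "population", {
    generate_cohort(cfg$population, cfg$n_patients, cfg$n_hospitals,
                    cfg$n_pcps, cfg$network_assignment)
  })
  roster <- with_rng_stream(streams, "population", {
    provider_roster(cfg$n_hospitals, cfg$n_pcps, cfg$hospital_types,
                    cfg$pcp_mix, cfg$pcp_assignment, cfg$initial_behavior)
  })
  if (!is.null(cfg$force_behavior)) {
    aco <- roster$network == "ACO"
    roster$behavior[aco] <- cfg$force_behavior
    roster$fav[aco] <- cfg$force_behavior
  }
  S$roster <- roster

  n <- nrow(cohort)
  nh <- cfg$n_hospitals
  np <- cfg$n_pcps
  net_i <- ifelse(cohort$network == "ACO", 1L, 2L)
  block <- (net_i - 1L) * (nh + np)
  P <- new.env(parent = emptyenv())
  P$n <- n
  P$age <- as.integer(cohort$age)
  P$age_group <- as.integer(cohort$age_group)
  P$gender_i <- match(cohort$gender, c("female", "male"))
  P$race <- cohort$race
  P$income <- cohort$income
  P$diab <- cohort$has_diabetes
  P$hyp <- cohort$has_hypertension
  P$chf <- cohort$has_chf
  P$dx <- cohort$chf_dx_source
  P$state <- ifelse(cohort$has_chf, 1L, 0L)
  P$network_i <- net_i
  P$hrow <- block + cohort$hospital
  P$prow <- block + nh + cohort$pcp
  P$hyp_inc <- unname(S$params$hypertension_incidence[cohort$race])
  P$cso <- integer(n)
  last_cycle <- max(S$params$cycle_breaks) # start of the last hazard interval
  prev <- which(cohort$has_chf)
  if (length(prev)) {
    # prevalent cases: onset time unknown; uniform over the survival-curve
    # support (0 to 5 years)
    P$cso[prev] <- with_rng_stream(streams, "disease", {
      sample.int(5L * S$params$cycles_per_year, length(prev),
                 replace = TRUE) - 1L
    })
  }
  P$eff <- numeric(n)      # effective intervention fraction, set annually
  P$fu <- logical(n)
  P$chf_year <- logical(n)
  P$adm_year <- integer(n)
  S$pat <- P
  class(S) <- "aco_state"
  S
}

# one 15-day cycle: state transitions, events, reimbursements, discharge
# interactions and message passing; mutates S in place
sim_cycle <- function(S) {
  P <- S$pat
  par <- S$params
  cs <- S$costs
  R <- S$roster
  nr <- nrow(R)
  acct <- S$acct
  with_rng_stream(S$streams, "disease", {
    st <- P$state
    alive <- which(st < 3L)
    die <- integer(0)

    f <- alive[st[alive] == 0L]
    on_in <- on_out <- integer(0)
    if (length(f)) {
      pd <- par$bgm_matrix[cbind(P$age_group[f], P$gender_i[f])]
      mult <- par$incidence_age_multipliers[P$age_group[f]] *
        ifelse(P$diab[f], par$incidence_diabetes_multiplier, 1) *
        ifelse(P$hyp[f], par$incidence_hypertension_multiplier, 1)
      pon <- 1 - (1 - par$chf_incidence_base)^mult
      pin <- pon * par$p_incidence_inpatient
      u <- stats::runif(length(f))
      die <- c(die, f[u < pd])
      on_in <- f[u >= pd & u < pd + pin]
      on_out <- f[u >= pd + pin & u < pd + pon]
    }

    o <- alive[st[alive] == 1L]
    adm_o <- integer(0)
    if (length(o)) {
      pm <- chf_mortality_cycle_prob(par, P$dx[o], P$cso[o]) *
        (1 - P$eff[o] * par$rr_mort)
      if (par$mortality_mode == "augment") {
        pm <- 1 - (1 - pm) *
          (1 - par$bgm_matrix[cbind(P$age_group[o], P$gender_i[o])])
      }
      ph <- par$hosp_prob_by_age[P$age_group[o]] * (1 - P$eff[o] * par$rr_hosp)
      u <- stats::runif(length(o))
      die <- c(die, o[u < pm])
      adm_o <- o[u >= pm & u < pm + ph]
    }

    h <- alive[st[alive] == 2L]
    dis <- integer(0)
    if (length(h)) {
      pm <- chf_mortality_cycle_prob(par, P$dx[h], P$cso[h]) *
        (1 - P$eff[h] * par$rr_mort)
      if (par$mortality_mode == "augment") {
        pm <- 1 - (1 - pm) *
          (1 - par$bgm_matrix[cbind(P$age_group[h], P$gender_i[h])])
      }
      u <- stats::runif(length(h))
      die <- c(die, h[u < pm])
      dis <- h[u >= pm]
    }

    # incurable comorbidity side-transitions (monotone flags)
    nd <- alive[!P$diab[alive]]
    if (length(nd)) {
      P$diab[nd[stats::runif(length(nd)) < par$diabetes_incidence]] <- TRUE
    }
    nhp <- alive[!P$hyp[alive]]
    if (length(nhp)) {
      P$hyp[nhp[stats::runif(length(nhp)) < P$hyp_inc[nhp]]] <- TRUE
    }

    # time-since-onset clock for existing CHF patients (new onsets stay at 0)
    P$cso[c(o, h)] <- P$cso[c(o, h)] + 1L

    if (length(die)) {
      P$state[die] <- 3L
      acct$deaths <- acct$deaths + tabulate(P$network_i[die], 2L)
      chfdie <- die[P$chf[die]]
      if (length(chfdie)) {
        acct$chf_deaths <- acct$chf_deaths + tabulate(P$network_i[chfdie], 2L)
        R$deaths_own <- R$deaths_own +
          tabulate(c(P$hrow[chfdie], P$prow[chfdie]), nr)
      }
    }

    new_onsets <- c(on_in, on_out)
    if (length(new_onsets)) {
      P$chf[new_onsets] <- TRUE
      P$chf_year[new_onsets] <- TRUE
      P$cso[new_onsets] <- 0L
      P$dx[on_in] <- "inpatient"
      P$dx[on_out] <- "outpatient"
      P$state[on_out] <- 1L
    }

    adm <- c(on_in, adm_o)
    if (length(adm)) {
      P$state[adm] <- 2L
      P$adm_year[adm] <- P$adm_year[adm] + 1L
      wtab <- tabulate(P$network_i[adm], 2L)
      acct$admissions <- acct$admissions + wtab
      acct$hosp_pay <- acct$hosp_pay + wtab * cs$hosp_reimbursement
      acct$phys_pay <- acct$phys_pay + wtab * cs$inpatient_physician_fee
      htab <- tabulate(P$hrow[adm], nr)
      R$gross <- R$gross + htab * cs$hosp_reimbursement
      R$net_service <- R$net_service + htab * cs$hospital_net_per_admission
      R$adm_own <- R$adm_own + htab + tabulate(P$prow[adm], nr)
    }

    if (length(dis)) {
      P$state[dis] <- 1L
      da <- dis[P$network_i[dis] == 1L]   # interactions happen in the ACO
      if (length(da)) {
        hr <- P$hrow[da]
        pr <- P$prow[da]
        hb <- R$behavior[hr]
        pb <- R$behavior[pr]
        R$ti <- R$ti + tabulate(c(hr, pr), nr)
        R$ni <- R$ni + tabulate(c(hr[pb == 1L], pr[hb == 1L]), nr)
        P$fu[da[pb == 1L]] <- TRUE   # post-discharge follow-up visit
      }
    }

    # outpatient visits of diagnosed CHF patients (Poisson), plus scheduled
    # follow-ups; only CHF-related services enter any ledger
    vi <- o[P$state[o] != 3L]
    v <- if (length(vi)) {
      stats::rpois(length(vi), par$visit_rate / par$cycles_per_year)
    } else {
      integer(0)
    }
    fu_now <- which(P$fu & P$state == 1L)
    fu_now <- setdiff(fu_now, dis)  # follow-up happens the cycle *after* discharge
    P$fu[fu_now] <- FALSE
    P$fu[P$state == 3L] <- FALSE
    vis_pat <- c(rep(vi, v), fu_now)
    if (length(vis_pat)) {
      wtab <- tabulate(P$network_i[vis_pat], 2L)
      acct$visit_pay <- acct$visit_pay + wtab * cs$outpatient_reimbursement
      acct$visits <- acct$visits + wtab
      ptab <- tabulate(P$prow[vis_pat], nr)
      R$gross <- R$gross + ptab * cs$outpatient_reimbursement
      R$net_service <- R$net_service + ptab * cs$pcp_net_per_visit
    }

    S$roster <- R
  })

  if (S$cfg$messages_per_cycle > 0L) {
    S$roster <- with_rng_stream(S$streams, "behavior", {
      exchange_messages(S$roster, "ACO", S$cfg$messages_per_cycle)
    })
  }
  invisible(S)
}

#' Run one simulation year
#'
#' Executes the annual loop: 24 patient cycles (transitions, visits,
#' reimbursements, discharge interactions, message passing), then the
#' shared-saving settlement, then the ACO providers' TPB decisions for the
#' next year, then aging. Controlled-network agents never enter the decision
#' step.
#'
#' @param S state from [initialize_simulation()] (mutated in place).
#' @param year_index 1-based year number (must follow on from the state).
#' @return a list: the annual report (per-network outcomes, settlement,
#'   ledger checks, provider behavior counts).
#' @export
run_year <- function(S, year_index = S$year + 1L) {
  stopifnot(inherits(S, "aco_state"))
  if (year_index != S$year + 1L) {
    stop_acosim("years must be simulated consecutively")
  }
  S$year <- as.integer(year_index)
  cfg <- S$cfg
  P <- S$pat
  R <- S$roster
  # annual resets
  R$nm0 <- R$nm1 <- R$ni <- R$ti <- 0
  R$gross <- R$net_service <- R$int_cost <- R$share <- 0
  R$adm_own <- R$deaths_own <- R$n_chf_own <- 0
  S$roster <- R
  P$chf_year <- P$chf & P$state < 3L
  P$adm_year <- integer(P$n)
  # intervention coverage for the year: a CHF patient's risk reductions are
  # scaled by whether its home hospital and/or PCP conduct the intervention
  P$eff <- intervention_effect_fraction(R$behavior[P$hrow] == 1L,
                                        R$behavior[P$prow] == 1L,
                                        S$params$partial_effect_fraction)
  S$acct <- new.env(parent = emptyenv())
  for (nm in c("hosp_pay", "phys_pay", "visit_pay", "visits", "admissions",
               "chf_deaths", "deaths")) {
    assign(nm, numeric(2L), envir = S$acct)
  }

  for (cyc in seq_len(S$params$cycles_per_year)) sim_cycle(S)

  R <- S$roster
  acct <- S$acct
  chf_sel <- which(P$chf_year)
  n_chf <- tabulate(P$network_i[chf_sel], 2L)
  R$n_chf_own <- tabulate(c(P$hrow[chf_sel], P$prow[chf_sel]), nrow(R))
  # intervention cost: per attributed CHF patient-year while intervening
  R$int_cost <- R$behavior * R$n_chf_own *
    ifelse(R$kind == "hospital",
           S$costs$hospital_intervention_cost_per_patient_year,
           S$costs$pcp_intervention_cost_per_patient_year)

  reimb <- acct$hosp_pay + acct$phys_pay + acct$visit_pay
  cost_pt <- ifelse(n_chf > 0, reimb / n_chf, NA_real_)

  settlement <- NULL
  shared_total <- 0
  ssp_pt <- 0
  saving_pt <- 0
  aco_rows <- which(R$network == "ACO")
  if (S$pay$model == "shared_saving" && all(n_chf > 0)) {
    settlement <- settle_shared_saving(cost_pt[2L], cost_pt[1L], n_chf[1L],
                                       S$pay, cfg$n_hospitals, cfg$n_pcps)
    shared_total <- settlement$shared_saving_total
    ssp_pt <- settlement$ssp_per_patient
    saving_pt <- settlement$saving_per_chf_patient
    R$share[aco_rows] <- ifelse(R$kind[aco_rows] == "hospital",
                                settlement$hospital_share_each,
                                settlement$pcp_share_each)
  }

  # conservation checks from independent accumulation paths
  ledger_ok <- abs(sum(acct$hosp_pay + acct$visit_pay) - sum(R$gross)) < 1e-6 &&
    abs(sum(acct$phys_pay) -
          sum(acct$admissions) * S$costs$inpatient_physician_fee) < 1e-6 &&
    (is.null(settlement) ||
       abs(settlement$hospital_share_each * cfg$n_hospitals +
             settlement$pcp_share_each * cfg$n_pcps - shared_total) < 1e-6)
  alive_end <- sum(P$state < 3L)
  pop_ok <- alive_end + sum(P$state == 3L) == P$n

  any_adm <- vapply(1:2, function(w) {
    sel <- chf_sel[P$network_i[chf_sel] == w]
    if (length(sel)) mean(P$adm_year[sel] > 0L) else NA_real_
  }, numeric(1))

  # next-year behavior decisions (ACO agents only)
  S$roster <- R
  if (is.null(cfg$force_behavior)) {
    profit_pt <- lapply(c(hospital = "hospital", pcp = "pcp"), function(k) {
      rows <- aco_rows[R$kind[aco_rows] == k]
      tot <- sum(R$n_chf_own[rows])
      if (tot > 0) sum(R$net_service[rows]) / tot else 0
    })
    stats <- list(n_chf_aco = n_chf[1L],
                  adm_rate = if (n_chf[1L] > 0) {
                    acct$admissions[1L] / n_chf[1L]
                  } else {
                    0
                  },
                  mort_rate = if (n_chf[1L] > 0) {
                    acct$chf_deaths[1L] / n_chf[1L]
                  } else {
                    0
                  },
                  profit_pt = profit_pt)
    opts <- list(tau = cfg$tau, intention_weights = cfg$intention_weights,
                 profit_scale = cfg$profit_scale,
                 quality_ref = cfg$quality_ref)
    upd <- with_rng_stream(S$streams, "behavior", {
      tpb_update(S$roster, S$pay, S$costs, S$params, opts, stats)
    })
    S$roster <- upd$roster
    upd$trace$year <- year_index
    S$trace[[year_index]] <- upd$trace
  }

  # aging at the year boundary
  grow <- P$state < 3L
  P$age[grow] <- P$age[grow] + 1L
  P$age_group <- age_group_of(P$age)

  report <- list(
    year = year_index,
    n_chf = stats::setNames(n_chf, c("ACO", "controlled")),
    admissions = stats::setNames(acct$admissions, c("ACO", "controlled")),
    adm_rate = stats::setNames(ifelse(n_chf > 0, acct$admissions / n_chf,
                                      NA_real_), c("ACO", "controlled")),
    any_adm_share = stats::setNames(any_adm, c("ACO", "controlled")),
    chf_deaths = stats::setNames(acct$chf_deaths, c("ACO", "controlled")),
    mort_rate = stats::setNames(ifelse(n_chf > 0, acct$chf_deaths / n_chf,
                                       NA_real_), c("ACO", "controlled")),
    visits = stats::setNames(acct$visits, c("ACO", "controlled")),
    reimb_per_chf = stats::setNames(cost_pt, c("ACO", "controlled")),
    payment_per_chf = stats::setNames(
      c(if (n_chf[1L] > 0) (reimb[1L] + shared_total) / n_chf[1L] else NA_real_,
        cost_pt[2L]), c("ACO", "controlled")),
    saving_per_chf = saving_pt,
    ssp_per_chf = ssp_pt,
    shared_saving_total = shared_total,
    settlement = settlement,
    n_intervening = c(
      hospital = sum(R$behavior[aco_rows] == 1L &
                       R$kind[aco_rows] == "hospital"),
      pcp = sum(R$behavior[aco_rows] == 1L & R$kind[aco_rows] == "pcp")),
    alive = alive_end,
    dead = P$n - alive_end,
    ledger_ok = ledger_ok,
    population_ok = pop_ok
  )
  report
}

#' Run a full simulation
#'
#' Deterministic given `(cfg, seed)`: the population, disease and behavior
#' random streams are all derived from the master seed.
#'
#' @param cfg a [simulation_config()].
#' @param seed master seed (defaults to `cfg$seed`).
#' @return object of class `aco_simulation`: `annual` (per-year, per-network
#'   data frame), `years` (raw annual reports), `means` (per-run outcome
#'   summary averaged over years), `trace` (TPB decision trace), `roster`
#'   (final provider roster).
#' @export
run_simulation <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "simulation_config"))
  S <- initialize_simulation(cfg, seed)
  reports <- vector("list", cfg$years)
  for (y in seq_len(cfg$years)) reports[[y]] <- run_year(S, y)

  annual <- do.call(rbind, lapply(reports, function(r) {
    data.frame(year = r$year,
               network = c("ACO", "controlled"),
               n_chf = as.numeric(r$n_chf),
               admissions = as.numeric(r$admissions),
               adm_rate = as.numeric(r$adm_rate),
               any_adm_share = as.numeric(r$any_adm_share),
               mort_rate = as.numeric(r$mort_rate),
               reimb_per_chf = as.numeric(r$reimb_per_chf),
               payment_per_chf = as.numeric(r$payment_per_chf),
               saving_per_chf = r$saving_per_chf,
               ssp_per_chf = r$ssp_per_chf,
               ledger_ok = r$ledger_ok,
               row.names = NULL)
  }))

  avg <- function(field, w) {
    mean(vapply(reports, function(r) as.numeric(r[[field]][w]), numeric(1)),
         na.rm = TRUE)
  }
  means <- c(
    aco_adm_rate = avg("adm_rate", 1L),
    controlled_adm_rate = avg("adm_rate", 2L),
    aco_any_adm = avg("any_adm_share", 1L),
    controlled_any_adm = avg("any_adm_share", 2L),
    aco_mort = avg("mort_rate", 1L),
    controlled_mort = avg("mort_rate", 2L),
    aco_reimb_per_chf = avg("reimb_per_chf", 1L),
    controlled_reimb_per_chf = avg("reimb_per_chf", 2L),
    aco_payment_per_chf = avg("payment_per_chf", 1L),
    saving_per_chf = mean(vapply(reports, `[[`, numeric(1), "saving_per_chf")),
    ssp_per_chf = mean(vapply(reports, `[[`, numeric(1), "ssp_per_chf")),
    shared_saving_total = mean(vapply(reports, `[[`, numeric(1),
                                      "shared_saving_total")),
    intervening_hospitals = mean(vapply(reports, function(r) {
      as.numeric(r$n_intervening[["hospital"]])
    }, numeric(1))),
    intervening_pcps = mean(vapply(reports, function(r) {
      as.numeric(r$n_intervening[["pcp"]])
    }, numeric(1)))
  )

  structure(list(scenario = cfg$scenario, seed = as.integer(seed),
                 annual = annual, years = reports, means = means,
                 trace = do.call(rbind, S$trace),
                 roster = S$roster),
            class = "aco_simulation")
}

#' @export
print.aco_simulation <- function(x, ...) {
  cat(sprintf("ACO simulation (scenario '%s', seed %d): %d year(s)\n",
              x$scenario, x$seed, max(x$annual$year)))
  m <- x$means
  cat(sprintf("  CHF admissions per patient-year: ACO %.3f, controlled %.3f\n",
              m[["aco_adm_rate"]], m[["controlled_adm_rate"]]))
  cat(sprintf("  CHF mortality rate:              ACO %.3f, controlled %.3f\n",
              m[["aco_mort"]], m[["controlled_mort"]]))
  cat(sprintf("  payer payment per CHF patient:   ACO $%.0f, controlled $%.0f\n",
              m[["aco_payment_per_chf"]], m[["controlled_reimb_per_chf"]]))
  cat(sprintf("  saving to payer per CHF patient: $%.0f\n", m[["ssp_per_chf"]]))
  invisible(x)
}

#' Monte Carlo replications with confidence intervals
#'
#' Runs the simulation `n_reps` times with replicate-specific seeds derived
#' from the master seed, and summarises every outcome as mean and 95%
#' normal-approximation confidence interval.
#'
#' @param cfg a [simulation_config()].
#' @param n_reps number of replications (>= 2; default `cfg$n_replications`).
#' @param seed master seed.
#' @param level confidence level (0.95).
#' @return object of class `replication_summary`: `summary` (one row per
#'   outcome: mean, lo, hi, sd) and `runs` (one row per replicate).
#' @export
run_replications <- function(cfg, n_reps = cfg$n_replications,
                             seed = cfg$seed, level = 0.95) {
  if (n_reps < 2) stop_acosim("n_reps must be >= 2")
  runs <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    rep_seed <- as.integer((as.double(seed) + 77777 * r) %% 2147483629)
    runs[[r]] <- run_simulation(cfg, rep_seed)$means
  }
  runs <- as.data.frame(do.call(rbind, runs))
  runs$rep <- seq_len(n_reps)
  outcomes <- setdiff(names(runs), "rep")
  summ <- do.call(rbind, lapply(outcomes, function(nm) {
    ci <- mean_ci(runs[[nm]], level)
    data.frame(outcome = nm, mean = ci[["mean"]], lo = ci[["lo"]],
               hi = ci[["hi"]], sd = ci[["sd"]], row.names = NULL)
  }))
  structure(list(summary = summ, runs = runs, n_reps = n_reps,
                 scenario = cfg$scenario),
            class = "replication_summary")
}

#' @export
print.replication_summary <- function(x, digits = 4, ...) {
  cat(sprintf("Replication summary (scenario '%s', %d runs), mean [95%% CI]:\n",
              x$scenario, x$n_reps))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-26s %s [%s, %s]\n", s$outcome[i],
                signif(s$mean[i], digits), signif(s$lo[i], digits),
                signif(s$hi[i], digits)))
  }
  invisible(x)
}
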