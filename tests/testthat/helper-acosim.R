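# shared fixtures, built in code

# minimal valid spec: all demographic mass on age group 1 (the demographics
# table must still cover groups 1-5), constant conditional probabilities
tiny_spec <- function(p_diab = 0.3, p_hyp = 0.5, p_chf = 0.2,
                      p_initial_inpatient_dx = 0.5) {
  dem <- data.frame(age_group = 1:5, race = "white", gender = "female",
                    income = "middle", prob = c(1, 0, 0, 0, 0))
  population_spec(
    dem,
    p_diabetes = data.frame(age_group = 1:5, p = p_diab),
    p_hypertension = data.frame(race = "white", p = p_hyp),
    p_chf = data.frame(age_group = 1:5, p = p_chf),
    p_initial_inpatient_dx = p_initial_inpatient_dx)
}

# brute-force oracle: exact joint distribution of (diabetes, hypertension,
# CHF) implied by a population_spec, by enumerating every demographics cell
# and comorbidity combination through the same conditional chain
enumerate_joint <- function(spec) {
  dem <- spec$demographics
  look <- function(tbl, df) acosim:::lookup_prob(tbl, df)
  out <- array(0, c(2, 2, 2))
  for (i in seq_len(nrow(dem))) {
    row <- dem[i, , drop = FALSE]
    if (row$prob == 0) next
    pd <- look(spec$p_diabetes, row)
    for (d in c(FALSE, TRUE)) {
      r2 <- cbind(row, diabetes = d)
      ph <- look(spec$p_hypertension, r2)
      for (h in c(FALSE, TRUE)) {
        r3 <- cbind(r2, hypertension = h)
        pc <- look(spec$p_chf, r3)
        for (cc in c(FALSE, TRUE)) {
          out[d + 1, h + 1, cc + 1] <- out[d + 1, h + 1, cc + 1] +
            row$prob * (if (d) pd else 1 - pd) * (if (h) ph else 1 - ph) *
            (if (cc) pc else 1 - pc)
        }
      }
    }
  }
  dimnames(out) <- list(diabetes = c("no", "yes"), hypertension = c("no", "yes"),
                        chf = c("no", "yes"))
  out
}

# a CHF-diagnosed patient for scalar disease-model calls
chf_patient <- function(age_group = 3L, state = "CHF_ONSITE",
                        source = "outpatient", cycles_since_onset = 30L,
                        gender = "female", race = "white",
                        diabetes = FALSE, hypertension = FALSE) {
  list(state = state, age_group = age_group, gender = gender, race = race,
       has_diabetes = diabetes, has_hypertension = hypertension, has_chf = TRUE,
       chf_dx_source = source, cycles_since_onset = cycles_since_onset)
}

# small, fast simulation configuration for engine tests
quick_cfg <- function(n_patients = 400L, years = 2L, seed = 101L, ...) {
  simulation_config(n_patients = n_patients, years = years, seed = seed, ...)
}
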