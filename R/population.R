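#' Population specification for the synthetic Medicare cohort
#'
#' A `population_spec` describes the joint distribution of patient
#' characteristics through a conditional-probability chain: demographics
#' (age group, race, gender, income) are drawn from a joint categorical
#' table, then diabetes given demographics, then hypertension given diabetes
#' and demographics, then CHF given everything upstream. This mirrors the
#' factorization
#' `P(CHF, HTN, DM, demo) = P(CHF | HTN, DM, demo) P(HTN | DM, demo) P(DM | demo) P(demo)`.
#'
#' Each conditional table is a data frame with a `p` column plus any subset
#' of the upstream variables as key columns (rows must cover every sampled
#' combination of its keys). Age groups are the five Medicare bands:
#' 1 = 65-69, 2 = 70-74, 3 = 75-79, 4 = 80-84, 5 = 85+.
#'
#' @param demographics data frame with columns `age_group` (1-5), `race`,
#'   `gender`, `income`, `prob`; `prob` must sum to 1 within 1e-9.
#' @param p_diabetes conditional probability table for diabetes.
#' @param p_hypertension conditional table for hypertension; may key on
#'   `diabetes` in addition to demographics.
#' @param p_chf conditional table for CHF; may key on `diabetes` and
#'   `hypertension`.
#' @param p_initial_inpatient_dx probability that a *prevalent* CHF case was
#'   originally diagnosed in the inpatient setting (selects the survival
#'   curve). Default 0.5.
#' @return an object of class `population_spec`.
#' @seealso [default_population_spec()], [sample_patient()], [generate_cohort()]
#' @export
population_spec <- function(demographics, p_diabetes, p_hypertension, p_chf,
                            p_initial_inpatient_dx = 0.5) {
  spec <- structure(
    list(demographics = as.data.frame(demographics),
         p_diabetes = as.data.frame(p_diabetes),
         p_hypertension = as.data.frame(p_hypertension),
         p_chf = as.data.frame(p_chf),
         p_initial_inpatient_dx = p_initial_inpatient_dx),
    class = "population_spec")
  validate_population_spec(spec)
  spec
}

#' Validate a population specification
#'
#' Checks table normalization and probability ranges; errors name the
#' offending table.
#'
#' @param spec a [population_spec()].
#' @return `spec`, invisibly.
#' @export
validate_population_spec <- function(spec) {
  dem <- spec$demographics
  need <- c("age_group", "race", "gender", "income", "prob")
  if (!all(need %in% names(dem))) {
    stop_acosim("demographics table must have columns ",
                paste(need, collapse = ", "))
  }
  if (any(dem$prob < 0 | dem$prob > 1)) {
    stop_acosim("demographics table contains probabilities outside [0,1]")
  }
  if (abs(sum(dem$prob) - 1) > 1e-9) {
    stop_acosim(sprintf("demographics table does not sum to 1 (sum = %.12f)",
                        sum(dem$prob)))
  }
  if (!setequal(unique(dem$age_group), 1:5)) {
    stop_acosim("demographics table must cover exactly age groups 1-5")
  }
  for (nm in c("p_diabetes", "p_hypertension", "p_chf")) {
    tbl <- spec[[nm]]
    if (!"p" %in% names(tbl)) {
      stop_acosim(sprintf("%s table lacks a 'p' column", nm))
    }
    if (any(tbl$p < 0 | tbl$p > 1)) {
      stop_acosim(sprintf("%s table contains probabilities outside [0,1]", nm))
    }
  }
  p0 <- spec$p_initial_inpatient_dx
  if (!is.numeric(p0) || p0 < 0 || p0 > 1) {
    stop_acosim("p_initial_inpatient_dx must be a probability in [0,1]")
  }
  invisible(spec)
}

age_band_bounds <- list(`1` = c(65L, 69L), `2` = c(70L, 74L), `3` = c(75L, 79L),
                        `4` = c(80L, 84L), `5` = c(85L, 94L))

age_group_of <- function(age) {
  pmin(findInterval(age, c(65, 70, 75, 80, 85)), 5L)
}

# vectorised chain sampler shared by sample_patient() and generate_cohort();
# uses the current RNG state.
sample_profiles <- function(spec, n) {
  validate_population_spec(spec)
  dem <- spec$demographics
  cell <- sample.int(nrow(dem), n, replace = TRUE, prob = dem$prob)
  df <- dem[cell, c("age_group", "race", "gender", "income")]
  rownames(df) <- NULL
  lo <- vapply(age_band_bounds, `[`, integer(1), 1L)[df$age_group]
  hi <- vapply(age_band_bounds, `[`, integer(1), 2L)[df$age_group]
  df$age <- lo + floor(stats::runif(n) * (hi - lo + 1L))
  # chain order: demographics -> diabetes -> hypertension -> CHF
  df$diabetes <- stats::runif(n) <
    lookup_prob(spec$p_diabetes, df, "p_diabetes")
  df$hypertension <- stats::runif(n) <
    lookup_prob(spec$p_hypertension, df, "p_hypertension")
  df$chf <- stats::runif(n) < lookup_prob(spec$p_chf, df, "p_chf")
  src <- rep("none", n)
  if (any(df$chf)) {
    inpat <- stats::runif(sum(df$chf)) < spec$p_initial_inpatient_dx
    src[df$chf] <- ifelse(inpat, "inpatient", "outpatient")
  }
  data.frame(id = seq_len(n),
             age = df$age,
             age_group = df$age_group,
             race = df$race,
             gender = df$gender,
             income = df$income,
             has_diabetes = df$diabetes,
             has_hypertension = df$hypertension,
             has_chf = df$chf,
             chf_dx_source = src,
             stringsAsFactors = FALSE)
}

#' Sample one patient profile
#'
#' Draws a single patient through the conditional chain (demographics, then
#' diabetes, then hypertension, then CHF) using the current RNG state.
#'
#' @param spec a [population_spec()].
#' @return one-row data frame with the profile variables (`age`, `age_group`,
#'   `race`, `gender`, `income`, comorbidity flags, `chf_dx_source`).
#' @export
sample_patient <- function(spec) {
  sample_profiles(spec, 1L)
}

#' Generate a patient cohort and assign it to networks and providers
#'
#' Samples `n` profiles and assigns each patient to the ACO or the controlled
#' network (fair coin by default, exact 50/50 split optionally), then to a
#' primary-care physician uniformly among `n_pcps` and a home hospital
#' uniformly among `n_hospitals` within the network. Both networks therefore
#' serve populations with identical characteristics in expectation.
#'
#' @param spec a [population_spec()].
#' @param n cohort size (>= 1).
#' @param n_hospitals,n_pcps providers per network (defaults 3 and 15).
#' @param network_assignment `"bernoulli"` (independent fair coin, default)
#'   or `"stratified"` (exact split, variance reduction).
#' @return data frame of patient profiles with `network` ("ACO"/"controlled"),
#'   `hospital` and `pcp` (network-local 1-based provider indices).
#' @export
generate_cohort <- function(spec, n, n_hospitals = 3L, n_pcps = 15L,
                            network_assignment = c("bernoulli", "stratified")) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop_acosim("cohort size n must be >= 1")
  }
  n <- as.integer(n)
  network_assignment <- match.arg(network_assignment)
  prof <- sample_profiles(spec, n)
  prof$network <- if (network_assignment == "bernoulli") {
    ifelse(stats::runif(n) < 0.5, "ACO", "controlled")
  } else {
    sample(rep(c("ACO", "controlled"), length.out = n))
  }
  prof$hospital <- sample.int(n_hospitals, n, replace = TRUE)
  prof$pcp <- sample.int(n_pcps, n, replace = TRUE)
  class(prof) <- c("aco_cohort", "data.frame")
  prof
}

#' Default synthetic population fixture
#'
#' Returns a documented, versioned `population_spec` with marginals chosen to
#' be plausible for the US Medicare 65+ population. The values are synthetic
#' implementer choices, not survey estimates:
#'
#' * age-group shares 0.30/0.25/0.19/0.14/0.12 (groups 1-5);
#' * race white 0.80, black 0.09, hispanic 0.07, other 0.04;
#' * gender female 0.56, male 0.44; income low 0.30, middle 0.50, high 0.20;
#'   demographics are independent across these four margins;
#' * diabetes prevalence by age group 0.20/0.22/0.23/0.22/0.18;
#' * hypertension by race (white/black/hispanic/other 0.55/0.70/0.58/0.55),
#'   +0.15 if diabetic (capped at 0.90);
#' * CHF base prevalence by age group 0.04/0.06/0.08/0.10/0.13, multiplied by
#'   1.8 if diabetic and 1.5 if hypertensive (capped at 0.60), giving an
#'   overall CHF prevalence near 9-10%.
#'
#' @return a [population_spec()].
#' @export
default_population_spec <- function() {
  age_p <- c(0.30, 0.25, 0.19, 0.14, 0.12)
  race_p <- c(white = 0.80, black = 0.09, hispanic = 0.07, other = 0.04)
  gender_p <- c(female = 0.56, male = 0.44)
  income_p <- c(low = 0.30, middle = 0.50, high = 0.20)
  dem <- expand.grid(age_group = 1:5, race = names(race_p),
                     gender = names(gender_p), income = names(income_p),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  dem$prob <- age_p[dem$age_group] * race_p[dem$race] *
    gender_p[dem$gender] * income_p[dem$income]

  p_diab <- data.frame(age_group = 1:5,
                       p = c(0.20, 0.22, 0.23, 0.22, 0.18))

  hyp <- expand.grid(race = names(race_p), diabetes = c(FALSE, TRUE),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  base_h <- c(white = 0.55, black = 0.70, hispanic = 0.58, other = 0.55)
  hyp$p <- pmin(base_h[hyp$race] + ifelse(hyp$diabetes, 0.15, 0), 0.90)

  chf <- expand.grid(age_group = 1:5, diabetes = c(FALSE, TRUE),
                     hypertension = c(FALSE, TRUE),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  base_c <- c(0.04, 0.06, 0.08, 0.10, 0.13)
  chf$p <- pmin(base_c[chf$age_group] *
                  ifelse(chf$diabetes, 1.8, 1) *
                  ifelse(chf$hypertension, 1.5, 1), 0.60)

  population_spec(dem, p_diab, hyp[, c("race", "diabetes", "p")],
                  chf[, c("age_group", "diabetes", "hypertension", "p")])
}

#' @rdname default_population_spec
#' @export
make_default_population_fixture <- default_population_spec

#' Read / write a population specification as JSON
#'
#' @param spec a [population_spec()].
#' @param path file path.
#' @return `read_population_spec` returns a `population_spec`;
#'   `write_population_spec` returns `path` invisibly.
#' @export
write_population_spec <- function(spec, path) {
  validate_population_spec(spec)
  jsonlite::write_json(unclass(spec), path, dataframe = "columns",
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_population_spec
#' @export
read_population_spec <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  population_spec(as.data.frame(raw$demographics),
                  as.data.frame(raw$p_diabetes),
                  as.data.frame(raw$p_hypertension),
                  as.data.frame(raw$p_chf),
                  raw$p_initial_inpatient_dx %||% 0.5)
}
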