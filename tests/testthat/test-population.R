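test_that("degenerate spec with unit probabilities yields the unique fully comorbid profile", {
  set.seed(1)
  spec <- tiny_spec(1, 1, 1, p_initial_inpatient_dx = 1)
  prof <- do.call(rbind, replicate(20, sample_patient(spec), simplify = FALSE))
  expect_true(all(prof$age_group == 1L))
  expect_true(all(prof$has_diabetes & prof$has_hypertension & prof$has_chf))
  expect_true(all(prof$chf_dx_source == "inpatient"))
  expect_true(all(prof$age >= 65 & prof$age <= 69))
})

test_that("the chain samples in order demographics, diabetes, hypertension, CHF", {
  # hypertension keyed on diabetes and CHF keyed on hypertension can only be
  # honored if each draw conditions on the upstream draws
  set.seed(2)
  dem <- data.frame(age_group = 1:5, race = "white", gender = "male",
                    income = "low", prob = c(0.5, 0.5, 0, 0, 0))
  spec <- population_spec(
    dem,
    p_diabetes = data.frame(age_group = 1:5, p = 0.5),
    p_hypertension = data.frame(diabetes = c(FALSE, TRUE), p = c(0, 1)),
    p_chf = data.frame(hypertension = c(FALSE, TRUE), p = c(0, 1)))
  prof <- acosim:::sample_profiles(spec, 500)
  expect_identical(prof$has_hypertension, prof$has_diabetes)
  expect_identical(prof$has_chf, prof$has_hypertension)
  expect_true(all(prof$chf_dx_source[prof$has_chf] != "none"))
  expect_true(all(prof$chf_dx_source[!prof$has_chf] == "none"))
})

test_that("empirical joint of sampled profiles matches the enumerated product within 3 SE", {
  set.seed(3)
  spec <- tiny_spec(0.3, 0.5, 0.2)
  n <- 1e5
  prof <- acosim:::sample_profiles(spec, n)
  exact <- enumerate_joint(spec)
  # independence spec: P(D,H,C) = 0.3 * 0.5 * 0.2 = 0.03 from the oracle
  expect_equal(exact["yes", "yes", "yes"], 0.03, tolerance = 1e-12)
  emp <- table(factor(prof$has_diabetes, c(FALSE, TRUE)),
               factor(prof$has_hypertension, c(FALSE, TRUE)),
               factor(prof$has_chf, c(FALSE, TRUE))) / n
  for (i in 1:2) for (j in 1:2) for (k in 1:2) {
    p <- exact[i, j, k]
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(emp[i, j, k] - p), 3 * se + 1e-12)
  }
})

test_that("default fixture validates and its cohort reproduces the nominal CHF marginal", {
  spec <- default_population_spec()
  expect_silent(validate_population_spec(spec))
  expect_equal(sum(spec$demographics$prob), 1, tolerance = 1e-12)
  ag <- tapply(spec$demographics$prob, spec$demographics$age_group, sum)
  expect_equal(sum(ag), 1, tolerance = 1e-12)

  p_chf <- sum(enumerate_joint(spec)[, , "yes"])
  expect_gt(p_chf, 0.05)  # plausible elderly CHF prevalence
  expect_lt(p_chf, 0.20)
  set.seed(4)
  n <- 1e4
  prof <- acosim:::sample_profiles(spec, n)
  se <- sqrt(p_chf * (1 - p_chf) / n)
  expect_lt(abs(mean(prof$has_chf) - p_chf), 3 * se)
})

test_that("network assignment is balanced and independent of health status", {
  spec <- default_population_spec()
  set.seed(5)
  n <- 1e4
  coh <- generate_cohort(spec, n)
  n_aco <- sum(coh$network == "ACO")
  expect_lt(abs(n_aco - n / 2), 3 * sqrt(n / 4))
  chi <- suppressWarnings(
    stats::chisq.test(table(coh$network, coh$has_chf)))
  expect_gt(chi$p.value, 0.01)
  expect_true(all(coh$hospital %in% 1:3), all(coh$pcp %in% 1:15))

  strat <- generate_cohort(spec, 2, network_assignment = "stratified")
  expect_setequal(strat$network, c("ACO", "controlled"))
  strat2 <- generate_cohort(spec, n, network_assignment = "stratified")
  expect_equal(sum(strat2$network == "ACO"), n / 2)
})

test_that("validation errors name the offending table and bad sizes are rejected", {
  spec <- tiny_spec()
  bad <- spec
  bad$demographics$prob[1] <- 0.9
  expect_error(validate_population_spec(bad), "demographics")
  bad2 <- spec
  bad2$p_chf$p[1] <- 1.5
  expect_error(validate_population_spec(bad2), "p_chf")
  bad3 <- spec
  bad3$demographics <- bad3$demographics[bad3$demographics$age_group != 3, ]
  bad3$demographics$prob <- c(1, 0, 0, 0)
  expect_error(validate_population_spec(bad3), "age group")
  expect_error(generate_cohort(spec, 0), "n must be >= 1")
  # a sampled combination missing from a conditional table is reported
  spec$p_hypertension <- data.frame(race = "black", p = 0.5)
  expect_error(acosim:::sample_profiles(spec, 10), "p_hypertension")
})

test_that("population spec survives a JSON round trip", {
  spec <- default_population_spec()
  path <- tempfile(fileext = ".json")
  write_population_spec(spec, path)
  back <- read_population_spec(path)
  expect_equal(back$demographics$prob, spec$demographics$prob)
  expect_equal(back$p_chf$p, spec$p_chf$p)
  expect_equal(back$p_initial_inpatient_dx, spec$p_initial_inpatient_dx)
  unlink(path)
})
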