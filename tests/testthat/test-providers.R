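test_that("attitude is the beta-weighted mix of profit and quality utilities", {
  expect_equal(compute_attitude(1, 1, c(0.3, 0.7)), 1)
  expect_equal(compute_attitude(0.5, 0.25, c(0.8, 0.2)), 0.45)
  # profit-oriented agents weight profit 4:1 over quality
  b <- acosim:::beta_weights("profit")
  expect_equal(unname(b[1, 1] / b[1, 2]), 4)
  expect_error(compute_attitude(0.5, 0.5, c(0.8, 0.4)), "sum to 1")
  expect_error(compute_attitude(1.2, 0.5, c(0.5, 0.5)), "\\[0,1\\]")
})

test_that("utility transforms stay in [0,1] and point the right way", {
  x <- seq(-5000, 5000, by = 500)
  u <- utility_profit(x)
  expect_true(all(u >= 0 & u <= 1))
  expect_true(all(diff(u) > 0))
  expect_equal(utility_profit(0), 0.5)
  q <- utility_quality(c(0, 0.5, 2), c(0, 0.2, 1))
  expect_true(all(q >= 0 & q <= 1))
  expect_true(all(diff(q) < 0))  # worse rates, lower utility
})

test_that("expectation estimates encode the intervention trade-off", {
  params <- transition_parameters()
  ex <- estimate_expectations(service_profit_per_patient = -700,
                              hosp_rate = 0.6, mort_rate = 0.18,
                              intervention_cost_per_patient = 648,
                              shared_saving_forecast_per_patient = 0,
                              params = params)
  # with no shared-saving forecast the intervention is a pure cost
  expect_lt(ex$ep1, ex$ep0)
  expect_equal(ex$ep0 - ex$ep1, 648)
  # quality expectation under k=1 applies the 20% / 13% reductions
  expect_equal(unname(ex$eq1["hosp"]), 0.6 * 0.80)
  expect_equal(unname(ex$eq1["mort"]), 0.18 * 0.87)
  expect_gt(ex$uq1, ex$uq0)
  ex2 <- estimate_expectations(-700, 0.6, 0.18, 648, 1000, params)
  expect_equal(ex2$ep1 - ex$ep1, 1000)
})

test_that("message exchange conserves messages and routes by favored behavior", {
  roster <- provider_roster()
  aco <- roster$network == "ACO"
  set.seed(11)
  out <- exchange_messages(roster, rounds = 3)
  # conservation: every sent message is received exactly once
  expect_equal(sum(out$nm0 + out$nm1), 3 * sum(aco))
  # all senders favored k = 1 (initial behavior), so only nm1 accumulates
  expect_equal(sum(out$nm0), 0)
  expect_true(all(out$nm1[!aco] == 0))

  one <- roster[c(1, which(roster$network == "controlled")), ]
  expect_warning(exchange_messages(one), "at least two")
})

test_that("subjective norm is the supportive-message proportion with an uninformed default", {
  expect_equal(compute_subjective_norm(0, 0)$sn1, 0.5)
  expect_equal(compute_subjective_norm(1, 3)$sn1, 0.75)
  sn <- compute_subjective_norm(c(2, 0), c(2, 5))
  expect_equal(sn$sn0 + sn$sn1, c(1, 1))
  expect_error(compute_subjective_norm(-1, 2), ">= 0")
})

test_that("discharge interactions accumulate into perceived behavioral control", {
  roster <- provider_roster()
  h <- 1L
  p <- 4L
  roster$behavior[] <- 0L
  counterparts <- c(1L, 1L, 1L, 0L)  # 3 of 4 counterparts intervening
  for (b in counterparts) {
    roster$behavior[p] <- b
    roster <- record_interaction(roster, h, p)
  }
  expect_equal(roster$ti[h], 4)
  expect_equal(roster$ni[h], 3)
  pbc <- compute_pbc(roster$ni[h], roster$ti[h])
  expect_equal(pbc$pbc1, 0.75)
  expect_equal(pbc$pbc0, 1)
  expect_equal(compute_pbc(0, 0, prev = 0.5)$pbc1, 0.5)
  expect_error(compute_pbc(5, 4), "exceed")
})

test_that("intention is a convex combination confined to [0,1]", {
  expect_equal(compute_intention(1, 1, 1), 1)
  expect_equal(compute_intention(0, 0, 0), 0)
  expect_equal(compute_intention(0.6, 0.9, 0.75), 0.75)
  expect_equal(compute_intention(0.6, 0.9, 0.75, c(1, 0, 0)), 0.6)
  expect_error(compute_intention(0.5, 0.5, 0.5, c(0.5, 0.5, 0.5)), "sum to 1")
  expect_error(compute_intention(1.4, 0.5, 0.5), "\\[0,1\\]")
})

test_that("softmax choice normalizes, is symmetric, and degenerates to argmax", {
  expect_equal(choice_probability(0.7, 0.7, 1), 0.5)
  expect_equal(choice_probability(0, 1, 1), exp(1) / (1 + exp(1)))
  for (tau in c(0.1, 0.5, 2)) {
    p1 <- choice_probability(0.3, 0.8, tau)
    p0 <- choice_probability(0.8, 0.3, tau)
    expect_equal(p0 + p1, 1, tolerance = 1e-12)
  }
  gaps <- seq(-1, 1, by = 0.25)
  probs <- vapply(gaps, function(g) choice_probability(0, g, 0.5), numeric(1))
  expect_true(all(diff(probs) > 0))  # monotone in the intention gap
  # rational limit: higher intention wins, ties break to usual care
  expect_identical(choose_behavior(0.4, 0.6, 0), 1L)
  expect_identical(choose_behavior(0.6, 0.4, 0), 0L)
  expect_identical(choose_behavior(0.5, 0.5, 0), 0L)
  expect_error(choice_probability(0, 1, -1), ">= 0")
})

test_that("roster construction respects types, networks and mixes", {
  set.seed(12)
  roster <- provider_roster()
  expect_equal(nrow(roster), 36)
  expect_true(all(roster$beta1 + roster$beta2 == 1))
  ctrl <- roster$network == "controlled"
  expect_true(all(roster$behavior[ctrl] == 0L))
  aco_pcp <- roster$kind == "pcp" & roster$network == "ACO"
  expect_equal(as.vector(table(roster$type[aco_pcp])[c("profit", "quality",
                                                       "neutral")]),
               c(5L, 5L, 5L))  # exact equal split of 15
  all_q <- provider_roster(hospital_types = "quality",
                           pcp_mix = c(profit = 0, quality = 1, neutral = 0))
  expect_true(all(all_q$type[all_q$network == "ACO"] == "quality"))
  expect_error(provider_roster(pcp_mix = c(profit = 0.5, quality = 0.2,
                                           neutral = 0.2)), "sum to 1")
})
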