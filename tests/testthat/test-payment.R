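test_that("cost schedule derives its fee fields and enforces their identities", {
  cs <- cost_schedule()
  expect_equal(cs$inpatient_physician_fee, round(0.18 * 14822))
  expect_equal(cs$pcp_net_per_visit, round((1 - 0.60) * 85))
  expect_error(cost_schedule(inpatient_physician_fee = 3000),
               "inpatient_physician_fee")
  expect_error(cost_schedule(pcp_net_per_visit = 50), "pcp_net_per_visit")
  # non-strict mode is the hook for sensitivity perturbations
  loose <- cost_schedule(pcp_net_per_visit = 50, strict = FALSE)
  expect_equal(loose$pcp_net_per_visit, 50)
})

test_that("intervention cost amortization gives $54/month and $648/year", {
  am <- amortize_intervention_cost(108, 6, 12)
  expect_equal(am$monthly, 54)
  expect_equal(am$annual, 648)
  expect_equal(cost_schedule()$hospital_intervention_cost_per_patient_year,
               am$annual)
})

test_that("event reimbursement moves the tabulated cash flows", {
  cs <- cost_schedule()
  hosp <- reimburse_event("hospitalization", cs)
  expect_equal(hosp$payer, -(14822 + 2668))
  expect_equal(hosp$hospital, -1186)
  expect_equal(hosp$pcp, 0)
  visit <- reimburse_event("visit", cs)
  expect_equal(visit$payer, -85)
  expect_equal(visit$pcp, 34)
  expect_error(reimburse_event("dialysis", cs), "unknown event")
})

test_that("annual intervention cost scales with enrollment", {
  cs <- cost_schedule()
  expect_equal(annual_intervention_cost("hospital", 1, cs), 648)
  expect_equal(annual_intervention_cost("pcp", 1, cs), 69)
  expect_equal(annual_intervention_cost("hospital", 0, cs), 0)
  expect_equal(annual_intervention_cost("pcp", 120, cs), 69 * 120)
  expect_error(annual_intervention_cost("hospital", -1, cs), ">= 0")
  expect_error(annual_intervention_cost("clinic", 1, cs), "unknown provider")
})

test_that("network cost per CHF patient is a guarded linear average", {
  # 1 CHF patient, 1 hospitalization and 9 visits
  outflow <- (14822 + 2668) + 9 * 85
  expect_equal(compute_network_cost_per_chf_patient(outflow, 1), 18255)
  expect_equal(compute_network_cost_per_chf_patient(0, 10), 0)
  expect_equal(compute_network_cost_per_chf_patient(2 * outflow, 1),
               2 * 18255)
  expect_error(compute_network_cost_per_chf_patient(100, 0), "undefined")
})

test_that("shared-saving settlement distributes the pools as specified", {
  cfg <- payment_config("shared_saving", ssr = 0.5, srh = 0.7)
  rep <- settle_shared_saving(13550, 12020, 1000, cfg, 3, 15)
  expect_equal(rep$saving_per_chf_patient, 1530)
  expect_equal(rep$shared_saving_total, 765000)
  expect_equal(rep$hospital_share_each, 765000 * 0.7 / 3)   # 178,500
  expect_equal(rep$pcp_share_each, 765000 * 0.3 / 15)       # 15,300
  expect_equal(rep$ssp_per_patient, 765)
  expect_equal(rep$percent_saving, 100 * 765 / 13550)

  # pools sum exactly to the shared total; payer keeps the remainder
  expect_equal(rep$hospital_share_each * 3 + rep$pcp_share_each * 15,
               rep$shared_saving_total)
  expect_equal(rep$ssp_per_patient + cfg$ssr * rep$saving_per_chf_patient,
               rep$saving_per_chf_patient)
})

test_that("settlement floors at zero and is homogeneous of degree one", {
  cfg <- payment_config("shared_saving", ssr = 0.5, srh = 0.7)
  flo <- settle_shared_saving(12000, 12500, 1000, cfg)
  expect_equal(flo$saving_per_chf_patient, 0)
  expect_equal(flo$shared_saving_total, 0)
  expect_equal(flo$ssp_per_patient, 0)

  a <- settle_shared_saving(13550, 12020, 500, cfg)
  b <- settle_shared_saving(2 * 13550, 2 * 12020, 500, cfg)
  expect_equal(b$saving_per_chf_patient, 2 * a$saving_per_chf_patient)
  expect_equal(b$shared_saving_total, 2 * a$shared_saving_total)
  expect_equal(b$ssp_per_patient, 2 * a$ssp_per_patient)

  expect_error(settle_shared_saving(-1, 100, 10, cfg), "non-negative")
  # fee-for-service: nothing is shared
  ffs <- settle_shared_saving(13550, 12020, 1000, payment_config("ffs"))
  expect_equal(ffs$shared_saving_total, 0)
  expect_error(payment_config(ssr = 1.2), "\\[0,1\\]")
})
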