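dp_ref <- daly_params(ref_params)                      # 3% annuity
dp_none <- daly_params(ref_params, discount_method = "none")

test_that("discounted durations match the closed forms", {
  expect_equal(discounted_duration(25, 0.03, "annual_annuity"), 17.4131,
               tolerance = 1e-4)
  expect_equal(discounted_duration(53.79, 0.03, "annual_annuity"), 26.5347,
               tolerance = 1e-4)
  expect_equal(discounted_duration(53.79, 0.03, "continuous"), 26.6950,
               tolerance = 1e-4)
  for (m in c("none", "annual_annuity", "continuous")) {
    expect_equal(discounted_duration(7.3, 0, m), 7.3)
  }
  expect_error(discounted_duration(-1, 0.03), "non-negative")
})

test_that("discounting is strictly decreasing in the rate", {
  rates <- seq(0, 0.05, by = 0.01)
  for (m in c("annual_annuity", "continuous")) {
    vals <- vapply(rates, function(r) discounted_duration(30, r, m),
                   numeric(1))
    expect_true(all(diff(vals) < 0))
    expect_equal(vals[1], 30)
  }
})

test_that("YLL and YLD follow their defining products", {
  expect_equal(compute_yll(0, dp_ref), 0)
  expect_equal(compute_yll(1, dp_none), 53.79)
  expect_equal(compute_yll(100, dp_ref),
               100 * discounted_duration(53.79, 0.03, "annual_annuity"))
  expect_equal(compute_yld(1, 0.114, 0.11, dp_none), 0.114 * 0.11)
  expect_equal(compute_yld(5, 0, 0.11, dp_ref), 0)
  expect_equal(compute_yld(1, 0.005, 25, dp_ref), 0.0870657,
               tolerance = 1e-6)
})

test_that("outcome profiles assign mild/severe/infertility weights correctly", {
  mild <- assign_outcome_profile(
    terminal_payload(flags = "ubt_only_control"), dp_ref)
  expect_equal(mild$weight, 0.114)
  expect_equal(mild$duration, 0.11)

  full <- assign_outcome_profile(
    terminal_payload(flags = c("devascularization", "hysterectomy", "icu")),
    dp_ref)
  expect_equal(full$weight, c(0.324, 0.005))   # severe once + infertility
  expect_equal(full$duration, c(0.11, 25))

  icu_ctrl <- assign_outcome_profile(
    terminal_payload(flags = c("ubt_only_control", "icu")), dp_ref)
  expect_equal(icu_ctrl$weight, 0.324)         # ICU admission counts severe

  none <- assign_outcome_profile(terminal_payload(), dp_ref)
  expect_equal(nrow(none), 0L)
})

test_that("cohort DALYs are linear and equal YLL + YLD", {
  mm <- make_micro_model(scenario_spec(cohort = 1000, effectiveness = 1,
                                       include_icu = FALSE,
                                       include_cascade = FALSE))
  td <- rollback_evaluate(mm$tree, mm$params, mm$cohort)
  dal <- compute_dalys(td, daly_params(mm$params,
                                       discount_method = "none"))
  expect_equal(dal$daly, 1000 * 0.114 * 0.11, tolerance = 1e-9)
  expect_equal(dal$daly, dal$yll + dal$yld)
  expect_equal(dal$yll, 0)

  td0 <- rollback_evaluate(mm$tree, mm$params, 0)
  dal0 <- compute_dalys(td0, daly_params(mm$params))
  expect_equal(dal0$daly, 0)

  # linearity in the cohort
  td2 <- rollback_evaluate(mm$tree, mm$params, 2000)
  dal2 <- compute_dalys(td2, daly_params(mm$params,
                                         discount_method = "none"))
  expect_equal(dal2$daly, 2 * dal$daly, tolerance = 1e-12)
})

test_that("reference runs keep the DALY = YLL + YLD identity with deaths", {
  td <- rollback_evaluate(build_ubt_tree("condom", ref_params), ref_params,
                          59962)
  for (dp in list(dp_ref, dp_none)) {
    dal <- compute_dalys(td, dp, params = ref_params)
    expect_equal(dal$daly, dal$yll + dal$yld)
    expect_gte(dal$yll, 0)
    expect_gte(dal$yld, 0)
    expect_equal(dal$deaths, 59962 * 0.00308, tolerance = 1e-9)
  }
})

test_that("per-patient DALY ordering is ESM < condom < Bakri for every discount method", {
  for (m in c("none", "annual_annuity", "continuous")) {
    dp <- daly_params(ref_params, discount_method = m)
    daly <- vapply(c("esm", "condom", "bakri"), function(s) {
      td <- rollback_evaluate(build_ubt_tree(s, ref_params), ref_params,
                              59962)
      compute_dalys(td, dp, params = ref_params)$per_patient_daly
    }, numeric(1))
    expect_lt(daly["esm"], daly["condom"])
    expect_lt(daly["condom"], daly["bakri"])
  }
})

test_that("excess-death policy adds YLL and removes YLD mass", {
  pol <- pathway_policies(death_model = "background_plus_excess",
                          excess_pph_death_prob = 0.05)
  td <- rollback_evaluate(build_ubt_tree("condom", ref_params, pol),
                          ref_params, 59962)
  base <- compute_dalys(td, dp_ref, pathway_policies(), ref_params)
  excess <- compute_dalys(td, dp_ref, pol, ref_params)
  expect_gt(excess$yll, base$yll)
  expect_lt(excess$yld, base$yld)
  expect_gt(excess$deaths, base$deaths)
})
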