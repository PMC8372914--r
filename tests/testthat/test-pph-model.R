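cohort_ref <- 59962

test_that("UBT trees validate and conserve mass", {
  for (s in c("condom", "esm", "bakri")) {
    tr <- build_ubt_tree(s, ref_params)
    expect_length(validate_tree(tr, ref_params), 0L)
    td <- rollback_evaluate(tr, ref_params, cohort_ref)
    expect_equal(sum(td$rows$path_prob), 1, tolerance = 1e-9)
    expect_equal(sum(td$rows$count), cohort_ref,
                 tolerance = 1e-6 * cohort_ref)
    expect_equal(nrow(td$rows), 24L)  # 3 pathways x 8 outcome states
  }
})

test_that("terminal masses equal hand products of the branch probabilities", {
  tr <- build_ubt_tree("condom", ref_params)
  td <- rollback_evaluate(tr, ref_params, cohort_ref)
  counts <- setNames(td$rows$count, td$rows$terminal)
  eff <- 0.923
  # uncontrolled-after-UBT mass across all pathways
  surgical <- vapply(td$rows$terminal, function(t) {
    any(c("devascularization", "hysterectomy") %in% td$payloads[[t]]$flags)
  }, logical(1))
  expect_equal(sum(td$rows$count[surgical]), cohort_ref * (1 - eff),
               tolerance = 1e-9 * cohort_ref)
  # controlled-by-UBT-alone mass
  expect_equal(sum(td$rows$count[!surgical]), cohort_ref * eff,
               tolerance = 1e-9 * cohort_ref)
  # one specific terminal: tertiary, controlled, no ICU
  expect_equal(unname(counts["tertiary_ctrl_noicu"]),
               cohort_ref * 0.48460 * eff * (1 - 0.025),
               tolerance = 1e-9 * cohort_ref)
  # devascularization-then-hysterectomy with ICU at secondary
  expect_equal(unname(counts["secondary_devasc_hyst_icu"]),
               cohort_ref * 0.32930 * (1 - eff) * (1 - 0.14634) *
                 0.21951 * 0.769,
               tolerance = 1e-9 * cohort_ref)
})

test_that("event counts follow the closed-form branch products", {
  pol <- pathway_policies()
  for (s in c("condom", "esm", "bakri")) {
    eff <- unname(param_value(ref_params, paste0("p_eff_", s)))
    td <- rollback_evaluate(build_ubt_tree(s, ref_params), ref_params,
                            cohort_ref)
    ev <- compute_event_counts(td, pol, ref_params)
    u <- cohort_ref * (1 - eff)
    expect_equal(ev$patients_operated, u, tolerance = 1e-9 * cohort_ref)
    h1 <- 0.14634; h2 <- 0.21951
    expect_equal(ev$hysterectomies, u * (h1 + (1 - h1) * h2),
                 tolerance = 1e-9 * cohort_ref)
    expect_equal(ev$procedures, u * (1 + (1 - h1) * h2),
                 tolerance = 1e-9 * cohort_ref)
    expect_equal(ev$icu_admissions,
                 cohort_ref * (eff * 0.025 + (1 - eff) * 0.769),
                 tolerance = 1e-9 * cohort_ref)
    # referrals: all primary mass once, plus ICU cases sitting at
    # secondary (primary-referred cases included)
    icu_sec <- cohort_ref * (0.18610 + 0.32930) *
      (eff * 0.025 + (1 - eff) * 0.769)
    expect_equal(ev$referrals, cohort_ref * 0.18610 + icu_sec,
                 tolerance = 1e-9 * cohort_ref)
    # background deaths
    expect_equal(ev$deaths, cohort_ref * 0.00308, tolerance = 1e-9)
    expect_lte(ev$patients_operated, ev$procedures)
    expect_lte(ev$hysterectomies, ev$procedures)
  }
})

test_that("perfect effectiveness empties the surgical cascade", {
  ps <- override_param(ref_params, "p_eff_condom", 1)
  td <- rollback_evaluate(build_ubt_tree("condom", ps), ps, 1000)
  ev <- compute_event_counts(td)
  expect_equal(ev$patients_operated, 0)
  expect_equal(ev$procedures, 0)
  # only the 0.025 controlled-ICU branch remains
  expect_equal(ev$icu_admissions, 1000 * 0.025, tolerance = 1e-9)
})

test_that("zero cohort yields zero counts and totals", {
  td <- rollback_evaluate(build_ubt_tree("esm", ref_params), ref_params, 0)
  ev <- compute_event_counts(td, params = ref_params)
  expect_equal(ev$patients_operated, 0)
  expect_equal(ev$deaths, 0)
  expect_equal(accumulate_costs(td, "societal")$total, 0)
})

test_that("societal minus health-system cost is the household OOPE", {
  for (s in c("condom", "esm", "bakri")) {
    td <- rollback_evaluate(build_ubt_tree(s, ref_params), ref_params,
                            cohort_ref)
    soc <- accumulate_costs(td, "societal")
    hs <- accumulate_costs(td, "health_system")
    expect_equal(soc$per_patient - hs$per_patient,
                 unname(param_value(ref_params, "cost_oope")),
                 tolerance = 1e-9)
    expect_lte(hs$total, soc$total)
  }
})

test_that("device monotonicity: higher effectiveness, fewer events and lower cost", {
  effs <- c(0.80, 0.90, 0.97)
  ops <- icus <- costs <- numeric(length(effs))
  for (i in seq_along(effs)) {
    ps <- override_param(ref_params, "p_eff_condom", effs[i])
    td <- rollback_evaluate(build_ubt_tree("condom", ps), ps, cohort_ref)
    ev <- compute_event_counts(td, params = ps)
    ops[i] <- ev$patients_operated
    icus[i] <- ev$icu_admissions
    costs[i] <- accumulate_costs(td, "societal")$total
  }
  expect_true(all(diff(ops) < 0))
  expect_true(all(diff(icus) < 0))
  expect_true(all(diff(costs) < 0))
})

test_that("strategy orderings at reference parameters match the published ranking", {
  fit <- ubt_cea(ref_params)
  df <- fit$strategies
  op <- setNames(df$patients_operated, df$strategy)
  expect_lt(op["esm"], op["condom"])
  expect_lt(op["condom"], op["bakri"])
  cost <- setNames(df$per_patient_societal_cost, df$strategy)
  expect_gt(cost["bakri"], cost["condom"])
})

test_that("policy switches change referral costing as documented", {
  pol <- pathway_policies(referral_primary_to_secondary = FALSE,
                          icu_at_tertiary_only = FALSE)
  td <- rollback_evaluate(build_ubt_tree("condom", ref_params, pol),
                          ref_params, cohort_ref)
  ev <- compute_event_counts(td, pol, ref_params)
  expect_equal(ev$referrals, 0)
  soc <- accumulate_costs(td, "societal")
  td_def <- rollback_evaluate(build_ubt_tree("condom", ref_params),
                              ref_params, cohort_ref)
  expect_lt(soc$total, accumulate_costs(td_def, "societal")$total)
})
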