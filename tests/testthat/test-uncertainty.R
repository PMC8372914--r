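all_fixed <- local({
  df <- as.data.frame(ref_params)
  df$family <- "fixed"
  df$low <- df$value
  df$high <- df$value
  ubt_params(df, provenance = "all fixed")
})

test_that("PSA is deterministic given the seed", {
  a <- run_psa("esm", "condom", n = 50, seed = 123)
  b <- run_psa("esm", "condom", n = 50, seed = 123)
  expect_identical(a$draws, b$draws)
  expect_identical(a$p_ce_at_base_wtp, b$p_ce_at_base_wtp)
  expect_identical(a$ceac, b$ceac)
  c <- run_psa("esm", "condom", n = 50, seed = 124)
  expect_false(identical(a$draws$nmb, c$draws$nmb))
})

test_that("degenerate PSA with fixed parameters reproduces the base case", {
  psa <- run_psa("esm", "condom", params = all_fixed, n = 5, seed = 1)
  expect_equal(length(unique(psa$draws$nmb)), 1L)
  expect_true(psa$p_ce_at_base_wtp %in% c(0, 1))
  fit <- ubt_cea(ref_params)
  soc <- fit$comparisons[fit$comparisons$perspective == "societal" &
                           fit$comparisons$intervention == "esm", ]
  expect_equal(psa$draws$delta_cost[1], soc$delta_cost_per_patient,
               tolerance = 1e-9)
  expect_equal(psa$draws$dalys_averted[1], soc$dalys_averted_per_patient,
               tolerance = 1e-9)
  expect_equal(psa$evpi_per_person, 0)
})

test_that("PSA rejects non-positive draw counts", {
  expect_error(run_psa("esm", "condom", n = 0), "n must be")
})

test_that("joint draws respect domains and recover parameter means", {
  n <- 4000
  draws <- sample_parameter_draws(ref_params, n, seed = 5,
                                  hold_fixed = c("deliveries_public",
                                                 "cohort_ubt_eligible"))
  beta_cols <- ref_params$name[ref_params$group %in%
                                 c("probability", "proportion", "weight")]
  expect_true(all(draws[, beta_cols] >= 0 & draws[, beta_cols] <= 1))
  cost_cols <- ref_params$name[ref_params$group == "cost"]
  expect_true(all(draws[, cost_cols] >= 0))
  expect_true(all(draws[, "deliveries_public"] == 20785669))
  for (i in seq_len(nrow(ref_params))) {
    p <- ref_params[i, ]
    spec <- suppressWarnings(derive_sampling_distribution(p))
    if (spec$family == "fixed" || p$name %in%
          c("deliveries_public", "cohort_ubt_eligible")) next
    se <- spec$sd / sqrt(n)
    tol <- if (grepl("^p_eff_", p$name)) 0.01 + 4 * se else 4 * se
    expect_lt(abs(mean(draws[, p$name]) - p$value), tol, label = p$name)
  }
})

test_that("CEAC at zero WTP equals the cost-saving fraction and quadrants sum to 1", {
  psa <- run_psa("esm", "condom", n = 400, seed = 7)
  expect_equal(psa$ceac$probability[psa$ceac$wtp == 0],
               mean(psa$draws$delta_cost < 0))
  expect_true(all(psa$ceac$probability >= 0 & psa$ceac$probability <= 1))
  expect_equal(sum(psa$quadrant_shares), 1)
})

test_that("CEAC is non-decreasing when every draw averts DALYs", {
  fake <- list(draws = data.frame(
    draw = 1:500,
    delta_cost = stats::rnorm(500, 100, 300),
    dalys_averted = stats::runif(500, 1e-4, 0.05)))
  fake$draws$nmb <- fake$draws$dalys_averted * 24211 - fake$draws$delta_cost
  ceac <- compute_ceac(fake, seq(0, 2e5, by = 5000))
  expect_true(all(diff(ceac$probability) >= 0))
})

test_that("EVPI is non-negative, zero without decision uncertainty, linear in population", {
  psa <- run_psa("esm", "condom", n = 500, seed = 3)
  expect_gte(psa$evpi_per_person, 0)
  e1 <- compute_evpi(psa, population = 1000)
  e2 <- compute_evpi(psa, population = 2000)
  expect_equal(e2$population, 2 * e1$population)
  agree <- list(draws = data.frame(nmb = abs(stats::rnorm(100)) + 1))
  expect_equal(compute_evpi(agree, population = 10)$per_person, 0,
               tolerance = 1e-12)
})

test_that("OWSA ranks device effectiveness as the most influential parameters", {
  ow <- run_owsa("esm", "condom", ref_params)
  expect_setequal(ow$parameter[1:2], c("p_eff_condom", "p_eff_esm"))
  expect_true(all(diff(ow$swing) <= 0))
  expect_true(all(ow$swing >= 0))
  expect_equal(anyDuplicated(ow$parameter), 0L)
  # cohort-size parameters cannot move per-patient incrementals
  expect_lt(ow$swing[ow$parameter == "deliveries_public"], 1e-9)
})

test_that("degenerate intervals produce zero swing", {
  ps <- local({
    df <- as.data.frame(ref_params)
    i <- match("cost_referral", df$name)
    df$low[i] <- df$value[i]; df$high[i] <- df$value[i]
    ubt_params(df)
  })
  ow <- run_owsa("esm", "condom", ps, vary = "cost_referral")
  expect_equal(ow$swing, 0)
})

test_that("condom effectiveness at its upper limit makes ESM dominated", {
  df <- as.data.frame(ref_params)
  i <- match("p_eff_condom", df$name)
  df$value[i] <- df$high[i]
  fit <- ubt_cea(ubt_params(df), strategies = c("condom", "esm"))
  soc <- fit$comparisons[fit$comparisons$perspective == "societal", ]
  expect_equal(soc$dominance, "dominated")
})
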