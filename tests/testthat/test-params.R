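test_that("parameter CSV round-trips field-by-field", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_parameter_table(ref_params, path)
  back <- load_parameter_table(path)
  expect_equal(as.data.frame(back), as.data.frame(ref_params),
               ignore_attr = TRUE)
})

test_that("empty data section loads as an empty set without error", {
  lines <- c("name,group,value,low,high,family,units,description")
  ps <- load_parameter_table(c(lines, ""))
  expect_s3_class(ps, "ubt_params")
  expect_equal(nrow(ps), 0L)
})

test_that("format and validation errors name the offending column/parameter", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("name,group,value,low,high,family,units",
               "x,probability,0.5,0.4,0.6,beta,-"), path)
  expect_error(load_parameter_table(path), "description")

  bad <- as.data.frame(ref_params)
  bad$value[bad$name == "p_pph_incidence"] <- 1.2
  bad$high[bad$name == "p_pph_incidence"] <- 1.4
  expect_error(ubt_params(bad), "p_pph_incidence")

  bad2 <- as.data.frame(ref_params)
  bad2$low[bad2$name == "cost_referral"] <- 2000
  expect_error(ubt_params(bad2), "cost_referral")
})

test_that("reference registry carries the published inputs", {
  expect_equal(unname(param_value(ref_params, "deliveries_public")),
               20785669)
  expect_equal(unname(param_value(ref_params, "p_eff_condom")), 0.923)
  row <- ref_params[ref_params$name == "p_eff_condom", ]
  expect_equal(c(row$low, row$high), c(0.738, 0.983))
  row <- ref_params[ref_params$name == "dw_severe_haem", ]
  expect_equal(c(row$value, row$low, row$high), c(0.324, 0.220, 0.442))
  expect_equal(unname(param_value(ref_params, "wtp_per_daly")), 24211)
})

test_that("eligible cohort reproduces the published count", {
  expect_equal(eligible_cohort(ref_params), 59962)
})

test_that("method-of-moments specs match hand-derived hyperparameters", {
  icu <- derive_sampling_distribution(ref_params, "p_icu_controlled")
  expect_equal(icu$family, "beta")
  expect_equal(icu$hyper1, 93.61, tolerance = 1e-3)
  expect_equal(icu$hyper2, 3650.9, tolerance = 1e-3)

  cost <- derive_sampling_distribution(ref_params, "cost_icu_tertiary")
  expect_equal(cost$family, "gamma")
  expect_equal(cost$hyper1, 30.04, tolerance = 1e-3)
  expect_equal(cost$hyper2, 163.0, tolerance = 1e-3)

  wtp <- derive_sampling_distribution(ref_params, "wtp_per_daly")
  expect_equal(wtp$family, "fixed")
  expect_equal(wtp$hyper1, 24211)
})

test_that("analytic moments of every derived spec match value and range/3.92", {
  for (i in seq_len(nrow(ref_params))) {
    p <- ref_params[i, ]
    spec <- suppressWarnings(derive_sampling_distribution(p))
    if (spec$family == "fixed") next
    if (spec$family == "beta") {
      a <- spec$hyper1; b <- spec$hyper2
      mean_an <- a / (a + b)
      sd_an <- sqrt(a * b / ((a + b)^2 * (a + b + 1)))
    } else {
      mean_an <- spec$hyper1 * spec$hyper2
      sd_an <- sqrt(spec$hyper1) * spec$hyper2
    }
    expect_equal(mean_an, p$value, tolerance = 1e-9, label = p$name)
    expect_equal(sd_an, (p$high - p$low) / 3.92, tolerance = 1e-9,
                 label = p$name)
  }
})

test_that("implied-variance overflow for a beta group falls back to fixed", {
  df <- data.frame(name = "p_wide", group = "probability", value = 0.5,
                   low = 0, high = 1, family = "beta", units = "-",
                   description = "degenerately wide interval")
  # sd = 1/3.92 = 0.255; var 0.065 < 0.25, attainable -> widen artificially
  df2 <- data.frame(name = "p_tiny", group = "probability", value = 1e-4,
                    low = 0, high = 1, family = "beta", units = "-",
                    description = "variance exceeds mean(1-mean)")
  ps <- ubt_params(rbind(df, df2))
  expect_warning(spec <- derive_sampling_distribution(ps, "p_tiny"),
                 "fixed")
  expect_equal(spec$family, "fixed")
  expect_silent(derive_sampling_distribution(ps, "p_wide"))
})

test_that("sampling recovers the parameter mean", {
  set.seed(42)
  n <- 10000
  for (nm in c("p_icu_controlled", "cost_icu_tertiary", "dw_severe_haem",
               "p_facility_primary")) {
    spec <- derive_sampling_distribution(ref_params, nm)
    x <- sample_distribution(spec, n)
    se <- spec$sd / sqrt(n)
    expect_lt(abs(mean(x) - spec$mean), 4 * se)
  }
  # ceiling-clamped effectiveness: mean shifts down only by the small
  # clamped excess mass
  spec <- derive_sampling_distribution(ref_params, "p_eff_esm")
  x <- sample_distribution(spec, n)
  expect_lte(max(x), 0.983)
  expect_lt(spec$mean - mean(x), 0.01)
})

test_that("perturbation is deterministic, identity at scale 0, unbiased at scale 1", {
  expect_equal(as.data.frame(perturb_parameters(ref_params, 0, seed = 7)),
               as.data.frame(ref_params), ignore_attr = TRUE)
  a <- perturb_parameters(ref_params, 0.5, seed = 11)
  b <- perturb_parameters(ref_params, 0.5, seed = 11)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_false(identical(a$value, ref_params$value))
  # all perturbed sets remain valid
  expect_length(validate_parameters(as.data.frame(a)), 0L)

  # replicate means stay within 3 Monte Carlo standard errors of base
  nm <- c("p_icu_controlled", "cost_icu_tertiary")
  reps <- 300
  vals <- matrix(NA_real_, reps, length(nm))
  for (r in seq_len(reps)) {
    pp <- perturb_parameters(ref_params, 1, seed = 1000 + r)
    vals[r, ] <- unname(param_value(pp, nm))
  }
  for (j in seq_along(nm)) {
    spec <- derive_sampling_distribution(ref_params, nm[j])
    se <- spec$sd / sqrt(reps)
    expect_lt(abs(mean(vals[, j]) - spec$mean), 3 * se, label = nm[j])
  }
})
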