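# Reproducible-run plumbing: run configuration, report writers for the
# base case and the full published-analysis pipeline, and a content-hash
# manifest. All outputs are plain CSV, UTF-8, "." decimals, no thousands
# separators. Internal computation is never rounded; report cells are
# rounded to whole rupees (INR), 4 decimals (DALYs) and 3 decimals
# (probabilities), with USD derived from unrounded INR and then rounded.

#' Run configuration
#'
#' @param parameter_file path to a parameter CSV; `NULL` uses the packaged
#'   reference registry.
#' @param strategies devices to evaluate.
#' @param comparator comparator device.
#' @param perspective cost perspective for the incremental table.
#' @param wtp WTP override (INR/DALY); `NULL` uses the registry value.
#' @param discount_rate,discount_method DALY discounting controls.
#' @param psa_n,seed PSA size and seed.
#' @param output_dir directory for report files (created if missing).
#' @param policies [pathway_policies()].
#' @param verbose log per-terminal dumps.
#' @return Object of class `ubt_run_config`.
#' @export
run_config <- function(parameter_file = NULL,
                       strategies = c("condom", "esm", "bakri"),
                       comparator = "condom",
                       perspective = "societal",
                       wtp = NULL,
                       discount_rate = NULL,
                       discount_method = "annual_annuity",
                       psa_n = 10000, seed = 1,
                       output_dir = "ubtcea_reports",
                       policies = pathway_policies(),
                       verbose = FALSE) {
  if (psa_n < 1) stop("psa_n must be >= 1", call. = FALSE)
  if (!is.null(parameter_file) && !file.exists(parameter_file)) {
    stop("parameter file does not exist: ", parameter_file, call. = FALSE)
  }
  structure(list(parameter_file = parameter_file, strategies = strategies,
                 comparator = comparator, perspective = perspective,
                 wtp = wtp, discount_rate = discount_rate,
                 discount_method = discount_method, psa_n = psa_n,
                 seed = seed, output_dir = output_dir, policies = policies,
                 verbose = verbose),
            class = "ubt_run_config")
}

log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

load_config_params <- function(cfg) {
  if (is.null(cfg$parameter_file)) {
    ubt_reference_parameters()
  } else {
    load_parameter_table(cfg$parameter_file)
  }
}

round_inr <- function(x) round(x)
round_daly <- function(x) round(x, 4)
round_prob <- function(x) round(x, 3)

#' Write the per-strategy results table
#'
#' One row per strategy with cohort totals and per-patient values in INR
#' and USD, DALYs and event counts.
#'
#' @param fit an `ubt_cea`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_strategy_results <- function(fit, path) {
  df <- fit$strategies
  usd <- function(x) round(convert_currency(x, fit$settings), 2)
  out <- data.frame(
    strategy = df$strategy,
    total_societal_cost_inr = round_inr(df$total_societal_cost),
    total_societal_cost_usd = usd(df$total_societal_cost),
    total_health_system_cost_inr = round_inr(df$total_health_system_cost),
    total_health_system_cost_usd = usd(df$total_health_system_cost),
    per_patient_societal_cost_inr = round_inr(df$per_patient_societal_cost),
    per_patient_societal_cost_usd = usd(df$per_patient_societal_cost),
    per_patient_health_system_cost_inr =
      round_inr(df$per_patient_health_system_cost),
    per_patient_health_system_cost_usd =
      usd(df$per_patient_health_system_cost),
    per_patient_daly = round_daly(df$per_patient_daly),
    deaths = round_inr(df$deaths),
    surgeries = round_inr(df$patients_operated),
    procedures = round_inr(df$procedures),
    icu_admissions = round_inr(df$icu_admissions),
    referrals = round_inr(df$referrals),
    cohort = df$cohort)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Write the incremental cost-effectiveness table
#'
#' One row per intervention and perspective with incremental cost, DALYs
#' averted, ICER, NMB (INR and USD) and the dominance label. Undefined
#' ICERs (zero effect difference) appear as the literal `undefined`.
#'
#' @param fit an `ubt_cea`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cea_results <- function(fit, path) {
  df <- fit$comparisons
  usd <- function(x) round(convert_currency(x, fit$settings), 2)
  fmt_icer <- function(x) ifelse(is.na(x), "undefined",
                                 as.character(round_inr(x)))
  out <- data.frame(
    intervention = df$intervention,
    comparator = df$comparator,
    perspective = df$perspective,
    delta_cost_inr = round_inr(df$delta_cost_per_patient),
    delta_cost_usd = usd(df$delta_cost_per_patient),
    dalys_averted = round_daly(df$dalys_averted_per_patient),
    icer_inr_per_daly = fmt_icer(df$icer),
    nmb_inr = round_inr(df$nmb_per_patient),
    nmb_usd = usd(df$nmb_per_patient),
    dominance = df$dominance)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

write_manifest <- function(dir, files, cfg, params, elapsed) {
  pf <- if (is.null(cfg$parameter_file)) "packaged reference registry"
        else cfg$parameter_file
  pf_hash <- if (is.null(cfg$parameter_file)) {
    unname(tools::md5sum(system.file("extdata", "table1_reference.csv",
                                     package = "ubtcea")))
  } else unname(tools::md5sum(cfg$parameter_file))
  meta <- data.frame(
    name = c("package_version", "seed", "psa_n", "parameter_file",
             "parameter_file_md5", "elapsed_seconds"),
    value = c(as.character(utils::packageVersion("ubtcea")),
              as.character(cfg$seed), as.character(cfg$psa_n), pf, pf_hash,
              sprintf("%.2f", elapsed)),
    stringsAsFactors = FALSE)
  hashes <- data.frame(
    name = paste0("file:", files),
    value = unname(tools::md5sum(file.path(dir, files))),
    stringsAsFactors = FALSE)
  utils::write.csv(rbind(meta, hashes), file.path(dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(NULL)
}

#' Run the base-case analysis and write its reports
#'
#' Evaluates all configured strategies from the parameter file and writes
#' `strategy_results.csv`, `cea_results.csv` and a `manifest.csv` carrying
#' the parameter-file hash, seed and package version.
#'
#' @param cfg a [run_config()].
#' @return The `ubt_cea` fit, invisibly.
#' @export
run_base_case <- function(cfg = run_config()) {
  t0 <- proc.time()["elapsed"]
  if (!dir.exists(cfg$output_dir)) {
    dir.create(cfg$output_dir, recursive = TRUE)
    log_stage("setup", "created output directory %s", cfg$output_dir)
  }
  log_stage("params", "loading parameters (%s)",
            if (is.null(cfg$parameter_file)) "packaged reference"
            else cfg$parameter_file)
  params <- load_config_params(cfg)
  settings <- cea_settings(params, wtp = cfg$wtp)
  dp <- daly_params(params, discount_rate = cfg$discount_rate,
                    discount_method = cfg$discount_method)
  log_stage("model", "evaluating strategies: %s",
            paste(cfg$strategies, collapse = ", "))
  fit <- ubt_cea(params, strategies = cfg$strategies,
                 comparator = cfg$comparator, settings = settings,
                 daly = dp, policies = cfg$policies)
  if (cfg$verbose) {
    for (s in fit$strategies$strategy) {
      td <- rollback_evaluate(build_ubt_tree(s, params, cfg$policies),
                              params, fit$cohort)
      log_stage("terminals", "%s:", s)
      print(td)
    }
  }
  files <- c("strategy_results.csv", "cea_results.csv")
  write_strategy_results(fit, file.path(cfg$output_dir, files[1]))
  write_cea_results(fit, file.path(cfg$output_dir, files[2]))
  log_stage("report", "wrote %s", paste(files, collapse = ", "))
  write_manifest(cfg$output_dir, files, cfg, params,
                 proc.time()["elapsed"] - t0)
  invisible(fit)
}

#' Run the complete published-analysis pipeline
#'
#' Base case plus one-way sensitivity (tornado) for both device pairs, PSA
#' with CEAC for both pairs, and EVPI, all written under one manifest.
#'
#' @param cfg a [run_config()].
#' @return Named list with the fit, OWSA and PSA objects, invisibly.
#' @export
run_full_reproduction <- function(cfg = run_config()) {
  t0 <- proc.time()["elapsed"]
  fit <- run_base_case(cfg)
  if (cfg$psa_n < 10000) {
    warning(sprintf(
      "PSA downscaled to %d draws; published fractions carry wider Monte Carlo error",
      cfg$psa_n), call. = FALSE)
  }
  params <- load_config_params(cfg)
  settings <- cea_settings(params, wtp = cfg$wtp)
  pairs <- setdiff(fit$strategies$strategy, cfg$comparator)
  files <- c("strategy_results.csv", "cea_results.csv")
  owsas <- list(); psas <- list()
  evpi_rows <- list()
  for (s in pairs) {
    log_stage("owsa", "%s vs %s", s, cfg$comparator)
    ow <- run_owsa(s, cfg$comparator, params, settings,
                   policies = cfg$policies,
                   discount_method = cfg$discount_method,
                   perspective = cfg$perspective)
    f <- sprintf("tornado_%s_vs_%s.csv", s, cfg$comparator)
    df <- as.data.frame(ow)
    df$rank <- seq_len(nrow(df))
    utils::write.csv(df, file.path(cfg$output_dir, f), row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
    files <- c(files, f)
    owsas[[s]] <- ow

    log_stage("psa", "%s vs %s, n = %d, seed = %d", s, cfg$comparator,
              cfg$psa_n, cfg$seed)
    psa <- run_psa(s, cfg$comparator, params, settings, n = cfg$psa_n,
                   seed = cfg$seed, policies = cfg$policies,
                   discount_method = cfg$discount_method,
                   perspective = cfg$perspective)
    f1 <- sprintf("psa_draws_%s_vs_%s.csv", s, cfg$comparator)
    draws <- psa$draws
    draws$seed <- cfg$seed
    utils::write.csv(draws, file.path(cfg$output_dir, f1),
                     row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
    f2 <- sprintf("ceac_%s_vs_%s.csv", s, cfg$comparator)
    ceac <- psa$ceac
    ceac$probability <- round_prob(ceac$probability)
    utils::write.csv(ceac, file.path(cfg$output_dir, f2),
                     row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
    files <- c(files, f1, f2)
    psas[[s]] <- psa
    evpi_rows[[s]] <- data.frame(
      intervention = s, comparator = cfg$comparator,
      p_ce_at_base_wtp = round_prob(psa$p_ce_at_base_wtp),
      evpi_per_person_inr = round(psa$evpi_per_person, 2),
      evpi_population_inr = round_inr(psa$evpi_population),
      cohort = psa$cohort, n = psa$n, seed = psa$seed)
  }
  f <- "evpi.csv"
  utils::write.csv(do.call(rbind, evpi_rows), file.path(cfg$output_dir, f),
                   row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  files <- c(files, f)
  write_manifest(cfg$output_dir, files, cfg, params,
                 proc.time()["elapsed"] - t0)
  log_stage("done", "%d report files in %s", length(files) + 1L,
            cfg$output_dir)
  invisible(list(fit = fit, owsa = owsas, psa = psas))
}

#' Write the packaged reference fixtures to a directory
#'
#' @param dir destination directory.
#' @param which `"table1"`, `"constants"` or `"both"`.
#' @return Paths written, invisibly.
#' @export
dump_reference_fixture <- function(dir = ".", which = c("both", "table1",
                                                        "constants")) {
  which <- match.arg(which)
  files <- switch(which,
                  both = c("table1_reference.csv", "constants.csv"),
                  table1 = "table1_reference.csv",
                  constants = "constants.csv")
  out <- character()
  for (f in files) {
    src <- system.file("extdata", f, package = "ubtcea", mustWork = TRUE)
    dst <- file.path(dir, f)
    file.copy(src, dst, overwrite = TRUE)
    out <- c(out, dst)
  }
  invisible(out)
}
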