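# Cost-effectiveness arithmetic: ICER, net monetary benefit, dominance
# quadrants, strategy summaries and currency conversion. A bare negative
# ICER is ambiguous (it arises in both the dominant and the dominated
# quadrant), so every comparison carries its dominance label and NMB.

#' Cost-effectiveness settings
#'
#' @param params parameter set supplying the willingness-to-pay threshold
#'   (`wtp_per_daly`), GDP per capita and the INR/USD conversion rate;
#'   defaults to the reference registry.
#' @param wtp override for the WTP threshold (INR per DALY averted).
#' @return Object of class `ubt_cea_settings` with `wtp`, `gdp_per_capita`,
#'   `usd_rate`.
#' @export
cea_settings <- function(params = ubt_reference_parameters(), wtp = NULL) {
  v <- param_value(params, c("wtp_per_daly", "gdp_per_capita", "usd_rate"))
  out <- list(wtp = if (is.null(wtp)) unname(v["wtp_per_daly"]) else wtp,
              gdp_per_capita = unname(v["gdp_per_capita"]),
              usd_rate = unname(v["usd_rate"]))
  stopifnot(out$wtp > 0, out$gdp_per_capita > 0, out$usd_rate > 0)
  class(out) <- "ubt_cea_settings"
  out
}

#' Incremental cost-effectiveness ratio
#'
#' @param delta_cost incremental cost (INR per patient).
#' @param dalys_averted incremental DALYs averted per patient.
#' @return `delta_cost / dalys_averted`, or `NA` (the undefined marker) when
#'   `|dalys_averted| < 1e-12`.
#' @export
compute_icer <- function(delta_cost, dalys_averted) {
  ifelse(abs(dalys_averted) < 1e-12, NA_real_, delta_cost / dalys_averted)
}

#' Incremental net monetary benefit
#'
#' `NMB = DALYs averted x WTP - incremental cost`.
#'
#' @param delta_cost incremental cost (INR per patient).
#' @param dalys_averted incremental DALYs averted per patient.
#' @param wtp willingness-to-pay threshold (INR per DALY averted).
#' @return NMB in INR per patient.
#' @export
compute_nmb <- function(delta_cost, dalys_averted, wtp) {
  stopifnot(all(wtp > 0))
  dalys_averted * wtp - delta_cost
}

#' Dominance classification
#'
#' Quadrant of the incremental cost-effectiveness plane: `dominant` (saves
#' money, averts DALYs), `dominated` (costs more, loses DALYs),
#' `tradeoff_ne` (costs more, averts more) or `tradeoff_sw` (saves money,
#' averts fewer). The origin (both zero) is reported as `tradeoff_ne` with
#' zero magnitudes.
#'
#' @param delta_cost incremental cost.
#' @param dalys_averted incremental DALYs averted.
#' @return Character label (vectorised).
#' @export
classify_dominance <- function(delta_cost, dalys_averted) {
  lab <- function(dc, de) {
    if (is.na(dc) || is.na(de)) return(NA_character_)
    if (dc == 0 && de == 0) return("tradeoff_ne")
    if (dc <= 0 && de >= 0) return("dominant")
    if (dc >= 0 && de <= 0) return("dominated")
    if (dc > 0) "tradeoff_ne" else "tradeoff_sw"
  }
  mapply(lab, delta_cost, dalys_averted, USE.NAMES = FALSE)
}

#' Convert INR to USD
#'
#' @param inr amount in INR.
#' @param settings [cea_settings()].
#' @return Amount in USD at the fixed 2017-18 conversion rate.
#' @export
convert_currency <- function(inr, settings = cea_settings()) {
  inr / settings$usd_rate
}

#' Summarize one strategy's costs, outcomes and events
#'
#' @param strategy strategy name.
#' @param costs list with `societal` and `health_system`, each a list
#'   `total`/`per_patient` as from [accumulate_costs()].
#' @param dalys an `ubt_daly` from [compute_dalys()].
#' @param events an `ubt_events` from [compute_event_counts()].
#' @param cohort cohort size.
#' @return One-row data frame of class `ubt_strategy_result`.
#' @export
summarize_strategy <- function(strategy, costs, dalys, events, cohort) {
  out <- data.frame(
    strategy = strategy,
    total_societal_cost = costs$societal$total,
    total_health_system_cost = costs$health_system$total,
    per_patient_societal_cost = costs$societal$per_patient,
    per_patient_health_system_cost = costs$health_system$per_patient,
    per_patient_daly = dalys$per_patient_daly,
    total_daly = dalys$daly,
    deaths = events$deaths,
    patients_operated = events$patients_operated,
    procedures = events$procedures,
    hysterectomies = events$hysterectomies,
    icu_admissions = events$icu_admissions,
    referrals = events$referrals,
    cohort = cohort,
    stringsAsFactors = FALSE)
  class(out) <- c("ubt_strategy_result", "data.frame")
  out
}

#' Pairwise incremental comparison
#'
#' @param intervention,comparator one-row `ubt_strategy_result` each.
#' @param settings [cea_settings()].
#' @param perspective `"societal"` or `"health_system"` cost column.
#' @return One-row data frame of class `ubt_cea_result` with the incremental
#'   cost, DALYs averted, ICER, NMB and dominance label.
#' @export
compare_strategies <- function(intervention, comparator,
                               settings = cea_settings(),
                               perspective = c("societal", "health_system")) {
  perspective <- match.arg(perspective)
  col <- paste0("per_patient_", perspective, "_cost")
  delta_cost <- intervention[[col]] - comparator[[col]]
  dalys_averted <- comparator$per_patient_daly - intervention$per_patient_daly
  out <- data.frame(
    intervention = intervention$strategy,
    comparator = comparator$strategy,
    perspective = perspective,
    delta_cost_per_patient = delta_cost,
    dalys_averted_per_patient = dalys_averted,
    icer = compute_icer(delta_cost, dalys_averted),
    nmb_per_patient = compute_nmb(delta_cost, dalys_averted, settings$wtp),
    dominance = classify_dominance(delta_cost, dalys_averted),
    stringsAsFactors = FALSE)
  class(out) <- c("ubt_cea_result", "data.frame")
  out
}

#' Evaluate the UBT cost-effectiveness model
#'
#' The central entry point: builds and evaluates the decision tree for each
#' requested device on the eligible cohort, values costs (societal and
#' health-system, undiscounted), DALYs (discounted per `daly`) and event
#' counts, and forms pairwise incremental comparisons against the
#' comparator.
#'
#' @param params parameter set; defaults to the reference registry.
#' @param strategies devices to evaluate.
#' @param comparator comparator device for the incremental comparisons.
#' @param cohort cohort size; defaults to [eligible_cohort()] when the
#'   parameter set carries the cohort ingredients, else the
#'   `cohort_ubt_eligible` entry.
#' @param settings [cea_settings()].
#' @param daly [daly_params()].
#' @param policies [pathway_policies()].
#' @return Object of class `ubt_cea`: list with `strategies` (per-strategy
#'   results data frame), `comparisons` (both perspectives for each
#'   non-comparator device), `cohort`, `settings`, `daly`, `policies`,
#'   `params`.
#' @examples
#' fit <- ubt_cea()
#' fit$strategies[, c("strategy", "per_patient_societal_cost")]
#' summary(fit)
#' @export
ubt_cea <- function(params = ubt_reference_parameters(),
                    strategies = c("condom", "esm", "bakri"),
                    comparator = "condom",
                    cohort = NULL,
                    settings = cea_settings(params),
                    daly = daly_params(params),
                    policies = pathway_policies()) {
  strategies <- vapply(strategies, function(s) ubt_strategy(s)$short, "")
  comparator <- ubt_strategy(comparator)$short
  if (!comparator %in% strategies) strategies <- c(comparator, strategies)
  if (is.null(cohort)) {
    cohort <- if (all(c("deliveries_public", "p_pph_incidence",
                        "p_atonic_share", "p_uterotonic_failure")
                      %in% params$name)) {
      eligible_cohort(params)
    } else {
      unname(param_value(params, "cohort_ubt_eligible"))
    }
  }
  res_list <- list()
  for (s in strategies) {
    tree <- build_ubt_tree(s, params, policies)
    td <- rollback_evaluate(tree, params, cohort)
    costs <- list(societal = accumulate_costs(td, "societal"),
                  health_system = accumulate_costs(td, "health_system"))
    dal <- compute_dalys(td, daly, policies, params)
    ev <- compute_event_counts(td, policies, params)
    res_list[[s]] <- summarize_strategy(s, costs, dal, ev, cohort)
  }
  strat_df <- do.call(rbind, res_list)
  rownames(strat_df) <- NULL
  class(strat_df) <- c("ubt_strategy_result", "data.frame")
  comps <- list()
  for (s in setdiff(strategies, comparator)) {
    for (persp in c("societal", "health_system")) {
      comps[[paste(s, persp, sep = ".")]] <-
        compare_strategies(res_list[[s]], res_list[[comparator]],
                           settings, persp)
    }
  }
  comp_df <- do.call(rbind, comps)
  rownames(comp_df) <- NULL
  class(comp_df) <- c("ubt_cea_result", "data.frame")
  structure(list(strategies = strat_df, comparisons = comp_df,
                 cohort = cohort, settings = settings, daly = daly,
                 policies = policies, params = params),
            class = "ubt_cea")
}

#' @export
print.ubt_cea <- function(x, digits = 0, ...) {
  cat(sprintf("UBT cost-effectiveness model: cohort %s, WTP %s INR/DALY averted\n\n",
              format(x$cohort, big.mark = ","),
              format(x$settings$wtp, big.mark = ",")))
  df <- x$strategies
  cat("Per-strategy results (per patient):\n")
  show <- data.frame(
    strategy = df$strategy,
    societal_cost_INR = round(df$per_patient_societal_cost),
    health_system_cost_INR = round(df$per_patient_health_system_cost),
    DALYs = round(df$per_patient_daly, 4),
    surgeries = round(df$patients_operated),
    icu = round(df$icu_admissions),
    deaths = round(df$deaths))
  print(show, row.names = FALSE)
  cat("\nIncremental comparisons vs ",
      x$comparisons$comparator[1], " (societal):\n", sep = "")
  soc <- x$comparisons[x$comparisons$perspective == "societal", ]
  show2 <- data.frame(
    intervention = soc$intervention,
    delta_cost_INR = round(soc$delta_cost_per_patient),
    DALYs_averted = round(soc$dalys_averted_per_patient, 4),
    ICER = round(soc$icer),
    NMB_INR = round(soc$nmb_per_patient),
    dominance = soc$dominance)
  print(show2, row.names = FALSE)
  invisible(x)
}

#' @export
summary.ubt_cea <- function(object, ...) {
  structure(list(fit = object), class = "summary.ubt_cea")
}

#' @export
print.summary.ubt_cea <- function(x, ...) {
  fit <- x$fit
  print(fit)
  cat("\nTotals over the cohort:\n")
  df <- fit$strategies
  for (i in seq_len(nrow(df))) {
    cat(sprintf("  %s: societal INR %s (USD %.2f million), health system INR %s\n",
                df$strategy[i],
                format(round(df$total_societal_cost[i]), big.mark = ","),
                convert_currency(df$total_societal_cost[i], fit$settings) / 1e6,
                format(round(df$total_health_system_cost[i]), big.mark = ",")))
  }
  cat(sprintf("\nDALY valuation: %s discounting at %.1f%%; deaths model: %s\n",
              fit$daly$discount_method, 100 * fit$daly$discount_rate,
              fit$policies$death_model))
  invisible(x)
}
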