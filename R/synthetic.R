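# Scenario generator: reduced single-level micro-models whose expected
# results are computed by independent closed-form arithmetic (embedded
# here, not via the tree engine), and randomized-but-valid parameter files
# so the pipeline can be exercised without the reference fixture.

#' Micro-model scenario specification
#'
#' A reduced single-facility scenario with optional surgical cascade and
#' ICU, used to cross-check the tree engine against hand formulas.
#'
#' @param cohort cohort size.
#' @param effectiveness device effectiveness in `[0, 1]`.
#' @param p_hyst_immediate,p_hyst_after_devasc surgical cascade proportions
#'   (used when `include_cascade`).
#' @param p_icu_controlled,p_icu_uncontrolled ICU probabilities (used when
#'   `include_icu`).
#' @param insertion_cost,ipd_cost,training_cost,oope,icu_cost unit costs
#'   (INR); `oope` is the household item, the rest health-system.
#' @param devasc_cost,hyst_cost surgery unit costs; with the cascade off,
#'   every uncontrolled case incurs one `devasc_cost` procedure.
#' @param dw_mild,dw_severe,dw_infertility disability weights.
#' @param duration_haemorrhage,duration_infertility disability durations
#'   (years).
#' @param include_cascade,include_icu structural switches.
#' @return Object of class `ubt_scenario`.
#' @export
scenario_spec <- function(cohort = 1000,
                          effectiveness = 0.9,
                          p_hyst_immediate = 0.15,
                          p_hyst_after_devasc = 0.22,
                          p_icu_controlled = 0.025,
                          p_icu_uncontrolled = 0.769,
                          insertion_cost = 400,
                          ipd_cost = 1800,
                          training_cost = 375,
                          oope = 2755,
                          icu_cost = 4900,
                          devasc_cost = 3400,
                          hyst_cost = 5500,
                          dw_mild = 0.114,
                          dw_severe = 0.324,
                          dw_infertility = 0.005,
                          duration_haemorrhage = 0.11,
                          duration_infertility = 25,
                          include_cascade = TRUE,
                          include_icu = TRUE) {
  spec <- as.list(environment())
  probs <- c(spec$effectiveness, spec$p_hyst_immediate,
             spec$p_hyst_after_devasc, spec$p_icu_controlled,
             spec$p_icu_uncontrolled)
  stopifnot(all(probs >= 0), all(probs <= 1), spec$cohort >= 0)
  class(spec) <- "ubt_scenario"
  spec
}

#' Build a micro-model with closed-form expected results
#'
#' Constructs a reduced single-level decision tree through the engine's
#' node/branch API, a matching parameter set, and the expected event
#' counts, costs and DALYs computed by independent closed-form arithmetic.
#' The engine and the closed forms agree to numerical precision; tests use
#' this as an oracle.
#'
#' @param spec a [scenario_spec()].
#' @return List with `tree` (an `ubt_tree`), `params` (an [ubt_params]
#'   resolving the tree and DALY references), `cohort`, and `expected`
#'   (closed-form `patients_operated`, `procedures`, `hysterectomies`,
#'   `icu_admissions`, `total_societal_cost`, `total_health_system_cost`,
#'   `total_daly`).
#' @examples
#' mm <- make_micro_model(scenario_spec(include_icu = FALSE,
#'                                      include_cascade = FALSE))
#' mm$expected$patients_operated  # cohort x (1 - effectiveness)
#' @export
make_micro_model <- function(spec = scenario_spec()) {
  stopifnot(inherits(spec, "ubt_scenario"))
  e <- spec$effectiveness
  h1 <- if (spec$include_cascade) spec$p_hyst_immediate else 0
  h2 <- if (spec$include_cascade) spec$p_hyst_after_devasc else 0
  qc <- if (spec$include_icu) spec$p_icu_controlled else 0
  qu <- if (spec$include_icu) spec$p_icu_uncontrolled else 0
  N <- spec$cohort

  param_df <- data.frame(
    name = c("mm_eff", "mm_h1", "mm_h2", "mm_qc", "mm_qu",
             "mm_insert", "mm_ipd", "mm_training", "mm_oope", "mm_icu",
             "mm_devasc", "mm_hyst",
             "dw_mild_haem", "dw_severe_haem", "dw_infertility",
             "duration_haemorrhage", "infertility_end_age", "cohort_age",
             "life_expectancy_remaining", "discount_rate"),
    group = c(rep("proportion", 5), rep("cost", 7),
              rep("weight", 3), rep("duration", 3), "duration", "rate"),
    value = c(e, h1, h2, qc, qu,
              spec$insertion_cost, spec$ipd_cost, spec$training_cost,
              spec$oope, spec$icu_cost, spec$devasc_cost, spec$hyst_cost,
              spec$dw_mild, spec$dw_severe, spec$dw_infertility,
              spec$duration_haemorrhage, 21 + spec$duration_infertility,
              21, 53.79, 0),
    family = "fixed", units = "", description = "micro-model input",
    stringsAsFactors = FALSE)
  param_df$low <- param_df$value
  param_df$high <- param_df$value
  params <- ubt_params(param_df, provenance = "micro-model scenario")

  nodes <- list(); branches <- list(); payloads <- list()
  add_node <- function(id, kind, label = id) {
    nodes[[length(nodes) + 1L]] <<- data.frame(id = id, kind = kind,
                                               label = label,
                                               stringsAsFactors = FALSE)
  }
  add_branch <- function(parent, child, prob) {
    branches[[length(branches) + 1L]] <<-
      data.frame(parent = parent, child = child, prob = as.character(prob),
                 stringsAsFactors = FALSE)
  }
  common <- rbind(
    cost_item("ubt_insertion", "mm_insert", "health_system"),
    cost_item("ipd_admission", "mm_ipd", "health_system"),
    cost_item("provider_training", "mm_training", "health_system"),
    cost_item("oope_childbirth", "mm_oope", "household"))
  icu_item <- cost_item("icu_admission", "mm_icu", "health_system")
  term <- function(id, items, flags, icu) {
    add_node(id, "terminal")
    its <- rbind(common, items)
    if (icu) { its <- rbind(its, icu_item); flags <- union(flags, "icu") }
    payloads[[id]] <<- terminal_payload(its, flags = flags,
                                        bleeding_status = "controlled")
    id
  }
  maybe_icu_split <- function(parent_id, q_param, base_id, items, flags) {
    if (spec$include_icu) {
      add_node(parent_id, "chance")
      add_branch(parent_id, term(paste0(base_id, "_icu"), items, flags, TRUE),
                 q_param)
      add_branch(parent_id, term(paste0(base_id, "_noicu"), items, flags,
                                 FALSE), COMPLEMENT)
      parent_id
    } else {
      term(base_id, items, flags, FALSE)
    }
  }

  add_node("root", "chance")
  ctrl_id <- maybe_icu_split("ctrl_split", "mm_qc", "ctrl", NULL,
                             "ubt_only_control")
  add_branch("root", ctrl_id, "mm_eff")
  if (spec$include_cascade) {
    add_node("unc", "chance")
    add_branch("root", "unc", COMPLEMENT)
    hyst_items <- cost_item("obstetric_hysterectomy", "mm_hyst",
                            "health_system")
    dh_items <- rbind(cost_item("devascularization_surgery", "mm_devasc",
                                "health_system"), hyst_items)
    dv_items <- cost_item("devascularization_surgery", "mm_devasc",
                          "health_system")
    hy_id <- maybe_icu_split("hyst_split", "mm_qu", "hyst", hyst_items,
                             "hysterectomy")
    add_branch("unc", hy_id, "mm_h1")
    add_node("devasc", "chance")
    add_branch("unc", "devasc", COMPLEMENT)
    dh_id <- maybe_icu_split("dh_split", "mm_qu", "devasc_hyst", dh_items,
                             c("devascularization", "hysterectomy"))
    add_branch("devasc", dh_id, "mm_h2")
    dc_id <- maybe_icu_split("dc_split", "mm_qu", "devasc_ctrl", dv_items,
                             "devascularization")
    add_branch("devasc", dc_id, COMPLEMENT)
  } else {
    unc_id <- maybe_icu_split("unc_split", "mm_qu", "unc_surgery",
                              cost_item("devascularization_surgery",
                                        "mm_devasc", "health_system"),
                              "devascularization")
    add_branch("root", unc_id, COMPLEMENT)
  }
  tree <- decision_tree("root", do.call(rbind, nodes),
                        do.call(rbind, branches), payloads)

  # --- independent closed forms -------------------------------------------
  u <- 1 - e
  hyst_share <- h1 + (1 - h1) * h2
  procedures_per_unc <- if (spec$include_cascade) 1 + (1 - h1) * h2 else 1
  surgery_cost_per_unc <- if (spec$include_cascade) {
    (1 - h1) * spec$devasc_cost + hyst_share * spec$hyst_cost
  } else spec$devasc_cost
  icu_adm <- N * (e * qc + u * qu)
  hs_cost <- N * (spec$insertion_cost + spec$ipd_cost +
                    spec$training_cost) +
    N * u * surgery_cost_per_unc + icu_adm * spec$icu_cost
  soc_cost <- hs_cost + N * spec$oope
  mild_cases <- N * e * (1 - qc)
  severe_cases <- N * (e * qc + u)
  hyst_cases <- if (spec$include_cascade) N * u * hyst_share else 0
  daly <- mild_cases * spec$dw_mild * spec$duration_haemorrhage +
    severe_cases * spec$dw_severe * spec$duration_haemorrhage +
    hyst_cases * spec$dw_infertility * spec$duration_infertility
  expected <- list(
    patients_operated = N * u,
    procedures = N * u * procedures_per_unc,
    hysterectomies = hyst_cases,
    icu_admissions = icu_adm,
    total_societal_cost = soc_cost,
    total_health_system_cost = hs_cost,
    total_daly = daly)
  list(tree = tree, params = params, cohort = N, expected = expected)
}

#' Generate a randomized, valid parameter file
#'
#' Emits CSV content in the parameter dialect with the same names and
#' groups as the reference registry but randomized values and limits: costs
#' drawn log-uniformly with +/-40 percent limits, probabilities and
#' proportions jittered with +/-20 percent limits clamped to `[0, 1]`,
#' facility shares renormalized to sum to one. Every generated file loads
#' without violations and runs the full pipeline. Deterministic per seed.
#'
#' @param seed integer seed.
#' @param path optional file path; when given the content is written there.
#' @return Character vector of CSV lines (invisibly when `path` is given).
#' @export
make_random_parameter_file <- function(seed = 1, path = NULL) {
  set.seed(seed)
  ref <- ubt_reference_parameters()
  df <- as.data.frame(ref)
  clamp01 <- function(x) pmin(1, pmax(0, x))
  shares <- stats::rgamma(3, shape = 4)
  shares <- shares / sum(shares)
  for (i in seq_len(nrow(df))) {
    nm <- df$name[i]
    if (df$family[i] == "fixed") next   # analysis constants stay put
    g <- df$group[i]
    if (nm == "p_facility_primary") v <- shares[1]
    else if (nm == "p_facility_secondary") v <- shares[2]
    else if (nm == "p_facility_tertiary") v <- shares[3]
    else if (grepl("^p_eff_", nm)) v <- stats::runif(1, 0.70, 0.96)
    else if (g %in% BETA_GROUPS) {
      v <- clamp01(df$value[i] * stats::runif(1, 0.7, 1.3))
      v <- min(v, 0.97)
    } else if (g == "cost") {
      v <- exp(stats::runif(1, log(50), log(12000)))
    } else if (g == "count") {
      v <- round(stats::runif(1, 1e5, 3e7))
    } else if (g == "rate") {
      v <- stats::runif(1, 0, 0.05)
    } else {  # duration
      v <- df$value[i] * stats::runif(1, 0.8, 1.2)
    }
    if (g %in% BETA_GROUPS) {
      low <- clamp01(0.8 * v)
      high <- if (grepl("^p_eff_", nm)) min(0.983, clamp01(1.2 * v))
              else clamp01(1.2 * v)
      high <- max(high, v)
    } else if (g == "rate") {
      low <- 0; high <- max(0.05, v)
    } else {
      low <- 0.6 * v; high <- 1.4 * v
    }
    df$value[i] <- v; df$low[i] <- low; df$high[i] <- high
  }
  ps <- ubt_params(df, provenance = sprintf("randomized (seed %d)", seed))
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  write_parameter_table(ps, tmp)
  lines <- readLines(tmp, encoding = "UTF-8")
  if (!is.null(path)) {
    writeLines(lines, path, useBytes = TRUE)
    return(invisible(lines))
  }
  lines
}
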