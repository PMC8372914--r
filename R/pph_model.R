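# Builder for the atonic-PPH / UBT decision tree, one tree per device
# strategy. The device decision is modelled as three separate trees evaluated
# on the same cohort, since every eligible woman is assumed to receive the
# one chosen device. Facility levels: primary cases are stabilized, receive
# the device, and are referred to secondary care for all downstream
# management; ICU beds exist only at tertiary level, so secondary-sitting
# cases needing ICU incur one extra referral.

STRATEGY_NAMES <- c(condom = "condom_ubt", esm = "esm_ubt", bakri = "bakri_ubt")

#' Device strategy descriptor
#'
#' Maps a device name to the parameter references its tree uses:
#' effectiveness, per-level insertion costs and per-level, per-procedure
#' surgery costs.
#'
#' @param name `"condom"`, `"esm"` or `"bakri"` (long forms
#'   `condom_ubt` etc. also accepted).
#' @return Object of class `ubt_strategy`.
#' @export
ubt_strategy <- function(name) {
  short <- sub("_ubt$", "", tolower(name))
  if (!short %in% names(STRATEGY_NAMES)) {
    stop("unknown strategy: ", name,
         " (expected condom, esm or bakri)", call. = FALSE)
  }
  structure(list(
    name = STRATEGY_NAMES[[short]],
    short = short,
    effectiveness_param = paste0("p_eff_", short),
    insertion_cost_params = c(
      primary = paste0("cost_insert_", short, "_primary"),
      secondary = paste0("cost_insert_", short, "_secondary"),
      tertiary = paste0("cost_insert_", short, "_tertiary")),
    surgery_cost_params = list(
      secondary = c(devascularization = paste0("cost_devasc_", short, "_secondary"),
                    hysterectomy = paste0("cost_hyst_", short, "_secondary")),
      tertiary = c(devascularization = paste0("cost_devasc_", short, "_tertiary"),
                   hysterectomy = paste0("cost_hyst_", short, "_tertiary")))
  ), class = "ubt_strategy")
}

#' Clinical pathway policies
#'
#' Structural switches for under-specified parts of the care pathway.
#'
#' @param death_model `"background_only"` applies all-cause maternal
#'   mortality to the whole cohort at the terminals; `"background_plus_excess"`
#'   additionally removes `excess_pph_death_prob` of the
#'   uncontrolled-after-UBT mass before the surgical cascade.
#' @param excess_pph_death_prob excess death probability on uncontrolled
#'   cases (default 0).
#' @param hysterectomy_definitive hysterectomy always controls bleeding.
#' @param referral_primary_to_secondary primary-level cases are referred to
#'   secondary care (incurring one referral cost) after insertion.
#' @param icu_at_tertiary_only secondary-sitting cases needing ICU incur one
#'   extra referral to tertiary care.
#' @return Object of class `ubt_policies`.
#' @export
pathway_policies <- function(death_model = c("background_only",
                                             "background_plus_excess"),
                             excess_pph_death_prob = 0,
                             hysterectomy_definitive = TRUE,
                             referral_primary_to_secondary = TRUE,
                             icu_at_tertiary_only = TRUE) {
  death_model <- match.arg(death_model)
  stopifnot(excess_pph_death_prob >= 0, excess_pph_death_prob <= 1)
  structure(list(death_model = death_model,
                 excess_pph_death_prob = excess_pph_death_prob,
                 hysterectomy_definitive = hysterectomy_definitive,
                 referral_primary_to_secondary = referral_primary_to_secondary,
                 icu_at_tertiary_only = icu_at_tertiary_only),
            class = "ubt_policies")
}

# One cost item row.
cost_item <- function(label, amount, payer) {
  data.frame(label = label, amount = as.character(amount), payer = payer,
             stringsAsFactors = FALSE)
}

#' Build the UBT decision tree for one device strategy
#'
#' Topology: the root splits the cohort across primary, secondary and
#' tertiary facility levels. Primary cases pay the primary insertion cost,
#' a referral and then follow the secondary clinical pathway. At each
#' pathway, bleeding is controlled with device effectiveness; controlled
#' cases face a small ICU probability, uncontrolled cases enter the
#' surgical cascade (immediate hysterectomy vs devascularization, the
#' latter followed by hysterectomy when bleeding persists) and a high ICU
#' probability. ICU care is costed at tertiary rates; secondary-sitting ICU
#' cases add one referral. Every terminal carries the per-patient training
#' cost (health system) and the household out-of-pocket expenditure.
#'
#' @param strategy an [ubt_strategy] or a device name.
#' @param params parameter set resolving all references.
#' @param policies [pathway_policies()].
#' @return An `ubt_tree`.
#' @examples
#' ps <- ubt_reference_parameters()
#' tr <- build_ubt_tree("condom", ps)
#' validate_tree(tr, ps)
#' @export
build_ubt_tree <- function(strategy, params,
                           policies = pathway_policies()) {
  if (!inherits(strategy, "ubt_strategy")) strategy <- ubt_strategy(strategy)
  # fail early on unresolved references
  param_value(params, c(strategy$effectiveness_param,
                        unname(strategy$insertion_cost_params),
                        unlist(strategy$surgery_cost_params, use.names = FALSE),
                        "p_facility_primary", "p_facility_secondary",
                        "p_hyst_immediate", "p_hyst_after_devasc",
                        "p_icu_controlled", "p_icu_uncontrolled",
                        "cost_icu_tertiary", "cost_ipd_secondary",
                        "cost_ipd_tertiary", "cost_referral",
                        "cost_training", "cost_oope"))

  nodes <- list(); branches <- list(); payloads <- list()
  add_node <- function(id, kind, label) {
    nodes[[length(nodes) + 1L]] <<- data.frame(id = id, kind = kind,
                                               label = label,
                                               stringsAsFactors = FALSE)
  }
  add_branch <- function(parent, child, prob) {
    branches[[length(branches) + 1L]] <<-
      data.frame(parent = parent, child = child, prob = as.character(prob),
                 stringsAsFactors = FALSE)
  }

  add_node("facility", "chance", "facility level accessed")

  # One clinical pathway. `level` prices IPD/surgery; `insertion_level`
  # prices device insertion; `base_items` are costs already incurred before
  # entering the pathway (primary referral); `base_flags` likewise.
  add_pathway <- function(prefix, level, insertion_level,
                          base_items, base_flags) {
    s <- strategy
    insertion <- cost_item("ubt_insertion",
                           s$insertion_cost_params[[insertion_level]],
                           "health_system")
    ipd <- cost_item("ipd_admission", paste0("cost_ipd_", level),
                     "health_system")
    common <- rbind(base_items, insertion, ipd,
                    cost_item("provider_training", "cost_training",
                              "health_system"),
                    cost_item("oope_childbirth", "cost_oope", "household"))
    icu_extra <- cost_item("icu_admission", "cost_icu_tertiary",
                           "health_system")
    icu_flags <- "icu"
    if (level == "secondary" && policies$icu_at_tertiary_only) {
      icu_extra <- rbind(icu_extra,
                         cost_item("referral", "cost_referral",
                                   "health_system"))
      icu_flags <- c("icu", "referred")
    }
    surg <- s$surgery_cost_params[[level]]
    devasc_item <- cost_item("devascularization_surgery",
                             surg[["devascularization"]], "health_system")
    hyst_item <- cost_item("obstetric_hysterectomy",
                           surg[["hysterectomy"]], "health_system")

    ctrl <- paste0(prefix, "_controlled")
    unc <- paste0(prefix, "_uncontrolled")
    add_node(ctrl, "chance", "bleeding controlled by UBT: ICU?")
    add_node(unc, "chance", "uncontrolled after UBT: surgical cascade")
    add_branch(prefix, ctrl, s$effectiveness_param)
    add_branch(prefix, unc, COMPLEMENT)

    add_terminal <- function(id, label, items, flags, icu) {
      tid <- paste0(prefix, "_", id)
      add_node(tid, "terminal", label)
      its <- rbind(common, items)
      fl <- union(base_flags, flags)
      if (icu) {
        its <- rbind(its, icu_extra)
        fl <- union(fl, icu_flags)
      }
      payloads[[tid]] <<- terminal_payload(its, flags = fl,
                                           bleeding_status = "controlled")
      tid
    }

    # controlled by UBT alone
    add_branch(ctrl, add_terminal("ctrl_icu", "controlled, ICU care",
                                  NULL, "ubt_only_control", TRUE),
               "p_icu_controlled")
    add_branch(ctrl, add_terminal("ctrl_noicu", "controlled by UBT alone",
                                  NULL, "ubt_only_control", FALSE),
               COMPLEMENT)

    # uncontrolled: immediate hysterectomy vs devascularization cascade
    hyst <- paste0(prefix, "_hyst")
    devasc <- paste0(prefix, "_devasc")
    add_node(hyst, "chance", "immediate hysterectomy: ICU?")
    add_node(devasc, "chance", "devascularization: hysterectomy needed?")
    add_branch(unc, hyst, "p_hyst_immediate")
    add_branch(unc, devasc, COMPLEMENT)

    add_branch(hyst, add_terminal("hyst_icu", "immediate hysterectomy, ICU",
                                  hyst_item, "hysterectomy", TRUE),
               "p_icu_uncontrolled")
    add_branch(hyst, add_terminal("hyst_noicu", "immediate hysterectomy",
                                  hyst_item, "hysterectomy", FALSE),
               COMPLEMENT)

    dh <- paste0(prefix, "_devasc_hyst")
    dc <- paste0(prefix, "_devasc_ctrl")
    add_node(dh, "chance", "hysterectomy after devascularization: ICU?")
    add_node(dc, "chance", "controlled by devascularization: ICU?")
    add_branch(devasc, dh, "p_hyst_after_devasc")
    add_branch(devasc, dc, COMPLEMENT)

    dh_items <- rbind(devasc_item, hyst_item)
    add_branch(dh, add_terminal("devasc_hyst_icu",
                                "hysterectomy after devascularization, ICU",
                                dh_items,
                                c("devascularization", "hysterectomy"), TRUE),
               "p_icu_uncontrolled")
    add_branch(dh, add_terminal("devasc_hyst_noicu",
                                "hysterectomy after devascularization",
                                dh_items,
                                c("devascularization", "hysterectomy"), FALSE),
               COMPLEMENT)
    add_branch(dc, add_terminal("devasc_ctrl_icu",
                                "controlled by devascularization, ICU",
                                devasc_item, "devascularization", TRUE),
               "p_icu_uncontrolled")
    add_branch(dc, add_terminal("devasc_ctrl_noicu",
                                "controlled by devascularization",
                                devasc_item, "devascularization", FALSE),
               COMPLEMENT)
    invisible(NULL)
  }

  # primary: insert at primary, refer, manage at secondary
  add_node("primary", "chance", "primary level: insertion then referral")
  primary_base <- if (policies$referral_primary_to_secondary) {
    cost_item("referral", "cost_referral", "health_system")
  } else NULL
  primary_flags <- if (policies$referral_primary_to_secondary) "referred"
                   else character()
  add_branch("facility", "primary", "p_facility_primary")
  add_branch("facility", "secondary", "p_facility_secondary")
  add_branch("facility", "tertiary", COMPLEMENT)
  # the "primary"/"secondary"/"tertiary" ids double as pathway roots
  add_pathway("primary", level = "secondary", insertion_level = "primary",
              base_items = primary_base, base_flags = primary_flags)
  add_node("secondary", "chance", "secondary level pathway")
  add_pathway("secondary", level = "secondary",
              insertion_level = "secondary",
              base_items = NULL, base_flags = character())
  add_node("tertiary", "chance", "tertiary level pathway")
  add_pathway("tertiary", level = "tertiary", insertion_level = "tertiary",
              base_items = NULL, base_flags = character())

  nodes_df <- do.call(rbind, nodes)
  branches_df <- do.call(rbind, branches)
  tree <- decision_tree("facility", nodes_df, branches_df, payloads)
  attr(tree, "strategy") <- strategy$name
  tree
}

#' Event counts from a terminal distribution
#'
#' Reduces a UBT terminal distribution to the expected numbers of operated
#' patients, surgical procedures, hysterectomies, ICU admissions, referrals
#' and deaths. Surgical and ICU masses are decremented by the configured
#' excess-PPH death probability (those deaths occur before definitive care);
#' background all-cause mortality applies at the terminals and therefore
#' does not reduce event counts.
#'
#' @param td an `ubt_terminal_dist` from a UBT tree.
#' @param policies [pathway_policies()].
#' @param params parameter set supplying the background all-cause maternal
#'   mortality (`p_mort_all_cause`); when `NULL` background deaths are 0.
#' @return Object of class `ubt_events`: list with `patients_operated`,
#'   `procedures`, `hysterectomies`, `icu_admissions`, `referrals`, `deaths`.
#' @export
compute_event_counts <- function(td, policies = pathway_policies(),
                                 params = NULL) {
  stopifnot(inherits(td, "ubt_terminal_dist"))
  excess <- if (policies$death_model == "background_plus_excess")
    policies$excess_pph_death_prob else 0
  p_bg <- if (is.null(params)) 0 else
    unname(param_value(params, "p_mort_all_cause"))

  operated <- procedures <- hysterectomies <- icu <- referrals <- 0
  uncontrolled_mass <- 0
  for (i in seq_len(nrow(td$rows))) {
    t <- td$rows$terminal[i]
    n <- td$rows$count[i]
    p <- td$payloads[[t]]
    surgical <- any(c("devascularization", "hysterectomy") %in% p$flags)
    n_surv <- if (surgical) n * (1 - excess) else n
    if (surgical) {
      uncontrolled_mass <- uncontrolled_mass + n
      operated <- operated + n_surv
      procedures <- procedures + n_surv *
        (("devascularization" %in% p$flags) + ("hysterectomy" %in% p$flags))
      hysterectomies <- hysterectomies + n_surv *
        ("hysterectomy" %in% p$flags)
    }
    if ("icu" %in% p$flags) icu <- icu + n_surv
    n_ref <- sum(p$cost_items$label == "referral")
    referrals <- referrals + n_surv * n_ref
  }
  excess_deaths <- uncontrolled_mass * excess
  deaths <- excess_deaths + p_bg * (td$cohort - excess_deaths)
  structure(list(patients_operated = operated,
                 procedures = procedures,
                 hysterectomies = hysterectomies,
                 icu_admissions = icu,
                 referrals = referrals,
                 deaths = deaths),
            class = "ubt_events")
}

#' @export
print.ubt_events <- function(x, ...) {
  cat(sprintf(paste0("Expected events: %.1f patients operated, ",
                     "%.1f procedures (%.1f hysterectomies), ",
                     "%.1f ICU admissions, %.1f referrals, %.1f deaths\n"),
              x$patients_operated, x$procedures, x$hysterectomies,
              x$icu_admissions, x$referrals, x$deaths))
  invisible(x)
}

#' Accumulate costs over a terminal distribution
#'
#' @param td an `ubt_terminal_dist`.
#' @param perspective `"societal"` (health-system plus household items) or
#'   `"health_system"`. Costs are undiscounted: the intervention is a
#'   one-time event.
#' @return Named list `total` and `per_patient` (INR).
#' @export
accumulate_costs <- function(td,
                             perspective = c("societal", "health_system")) {
  perspective <- match.arg(perspective)
  total <- 0
  for (i in seq_len(nrow(td$rows))) {
    ci <- td$payloads[[td$rows$terminal[i]]]$cost_items
    keep <- if (perspective == "societal") rep(TRUE, nrow(ci))
            else ci$payer == "health_system"
    total <- total + td$rows$count[i] * sum(ci$amount_value[keep])
  }
  list(total = total,
       per_patient = if (td$cohort > 0) total / td$cohort else NA_real_)
}
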