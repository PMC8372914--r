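# One-way (tornado) and probabilistic sensitivity analysis, CEAC and EVPI.
# The PSA samples every non-fixed parameter independently from its derived
# Beta/Gamma distribution; parameters shared between arms (facility shares,
# ICU probabilities, surgical proportions, mortality, weights, costs common
# to both devices) take one value per draw for both arms, while
# device-specific parameters are distinct names and so vary per device.
# Cohort-size inputs are held at base inside the PSA: incremental
# per-patient results are cohort-invariant and both arms share one cohort.

PSA_HOLD_FIXED <- c("deliveries_public", "cohort_ubt_eligible")

default_wtp_grid <- function(settings) {
  sort(unique(c(seq(0, 400000, by = 1000), settings$wtp,
                settings$gdp_per_capita, 3 * settings$gdp_per_capita)))
}

# Vectorised discounting over a rate vector.
dd_vec <- function(L, r, method) {
  if (method == "none") return(rep.int(L, length(r)))
  out <- switch(method,
                annual_annuity = (1 - (1 + r)^(-L)) / r,
                continuous = (1 - exp(-r * L)) / r)
  out[r == 0] <- L
  out
}

# Per-draw per-patient societal / health-system cost and DALY for one
# strategy tree under a lookup of parameter draw vectors.
psa_eval_strategy <- function(tree, lookup, n, discount_method, excess) {
  ev <- evaluate_tree_draws(tree, lookup, n)
  terminals <- ev$terminals
  cost_soc <- rowSums(ev$path_prob * (ev$cost_health_system +
                                        ev$cost_household))
  cost_hs <- rowSums(ev$path_prob * ev$cost_health_system)

  r <- lookup[["discount_rate"]]
  if (length(r) == 1L) r <- rep.int(r, n)
  p_bg <- lookup[["p_mort_all_cause"]]
  if (length(p_bg) == 1L) p_bg <- rep.int(p_bg, n)
  le <- lookup[["life_expectancy_remaining"]][1L]
  dur_h <- lookup[["duration_haemorrhage"]][1L]
  dur_inf <- lookup[["infertility_end_age"]][1L] - lookup[["cohort_age"]][1L]
  dd_le <- dd_vec(le, r, discount_method)
  dd_h <- dd_vec(dur_h, r, discount_method)
  dd_inf <- dd_vec(dur_inf, r, discount_method)
  w_mild <- lookup[["dw_mild_haem"]]
  w_severe <- lookup[["dw_severe_haem"]]
  w_inf <- lookup[["dw_infertility"]]
  expand <- function(x) if (length(x) == 1L) rep.int(x, n) else x
  w_mild <- expand(w_mild); w_severe <- expand(w_severe)
  w_inf <- expand(w_inf)

  daly <- numeric(n)
  severe_flags <- c("devascularization", "hysterectomy", "icu")
  for (t in terminals) {
    p <- tree$payloads[[t]]
    mass <- ev$path_prob[, t]
    surgical <- any(c("devascularization", "hysterectomy") %in% p$flags)
    n_excess <- if (surgical) mass * excess else 0
    n_bg <- (mass - n_excess) * p_bg
    survivors <- mass - n_excess - n_bg
    yld_w <- numeric(n)
    if (any(severe_flags %in% p$flags)) {
      yld_w <- yld_w + w_severe * dd_h
    } else if ("ubt_only_control" %in% p$flags) {
      yld_w <- yld_w + w_mild * dd_h
    }
    if ("hysterectomy" %in% p$flags) yld_w <- yld_w + w_inf * dd_inf
    daly <- daly + (n_excess + n_bg) * dd_le + survivors * yld_w
  }
  list(cost_societal = unname(cost_soc), cost_health_system = unname(cost_hs),
       daly = unname(daly))
}

#' Probabilistic sensitivity analysis
#'
#' Runs `n` Monte Carlo draws of the full model for an intervention /
#' comparator pair. Every non-fixed parameter is sampled independently from
#' its method-of-moments Beta or Gamma distribution; device effectiveness is
#' resampled above the 0.983 ceiling; cohort-size inputs are held at base.
#' Each draw re-evaluates both device trees and records the per-patient
#' incremental cost and DALYs averted.
#'
#' @param intervention,comparator device names.
#' @param params parameter set.
#' @param settings [cea_settings()].
#' @param n number of draws (>= 1).
#' @param seed integer seed; results are deterministic given it.
#' @param policies [pathway_policies()].
#' @param discount_method DALY discounting method (see [daly_params()]).
#' @param perspective cost perspective for the incremental comparison.
#' @param wtp_grid WTP grid (INR/DALY) for the acceptability curve.
#' @return Object of class `ubt_psa`: `draws` (data frame `draw`,
#'   `delta_cost`, `dalys_averted`, `nmb`), `p_ce_at_base_wtp`, `ceac`,
#'   `quadrant_shares`, `evpi_per_person`, `evpi_population`, `n`, `seed`,
#'   `wtp`, `cohort`, strategy names.
#' @examples
#' psa <- run_psa("esm", "condom", n = 200, seed = 1)
#' psa$p_ce_at_base_wtp
#' @export
run_psa <- function(intervention, comparator = "condom",
                    params = ubt_reference_parameters(),
                    settings = cea_settings(params),
                    n = 10000, seed = 1,
                    policies = pathway_policies(),
                    discount_method = "annual_annuity",
                    perspective = c("societal", "health_system"),
                    wtp_grid = default_wtp_grid(settings)) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  perspective <- match.arg(perspective)
  intervention <- ubt_strategy(intervention)$short
  comparator <- ubt_strategy(comparator)$short
  excess <- if (policies$death_model == "background_plus_excess")
    policies$excess_pph_death_prob else 0
  cohort <- eligible_cohort(params)

  draws <- sample_parameter_draws(params, n, seed = seed,
                                  hold_fixed = PSA_HOLD_FIXED)
  lookup <- lapply(seq_len(ncol(draws)), function(j) draws[, j])
  names(lookup) <- colnames(draws)

  tree_int <- build_ubt_tree(intervention, params, policies)
  tree_cmp <- build_ubt_tree(comparator, params, policies)
  res_int <- psa_eval_strategy(tree_int, lookup, n, discount_method, excess)
  res_cmp <- psa_eval_strategy(tree_cmp, lookup, n, discount_method, excess)

  cost_col <- paste0("cost_", perspective)
  delta_cost <- res_int[[cost_col]] - res_cmp[[cost_col]]
  dalys_averted <- res_cmp$daly - res_int$daly
  nmb <- compute_nmb(delta_cost, dalys_averted, settings$wtp)
  dom <- classify_dominance(delta_cost, dalys_averted)
  shares <- vapply(c("dominant", "dominated", "tradeoff_ne", "tradeoff_sw"),
                   function(q) mean(dom == q), numeric(1))

  psa <- structure(list(
    draws = data.frame(draw = seq_len(n), delta_cost = delta_cost,
                       dalys_averted = dalys_averted, nmb = nmb),
    n = n, seed = seed, wtp = settings$wtp, cohort = cohort,
    intervention = intervention, comparator = comparator,
    perspective = perspective,
    p_ce_at_base_wtp = mean(nmb > 0),
    quadrant_shares = shares,
    parameter_means = colMeans(draws)), class = "ubt_psa")
  psa$ceac <- compute_ceac(psa, wtp_grid)
  evpi <- compute_evpi(psa, settings, population = cohort)
  psa$evpi_per_person <- evpi$per_person
  psa$evpi_population <- evpi$population
  psa
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the fraction of PSA draws with
#' positive incremental net monetary benefit. At WTP 0 this is the fraction
#' of cost-saving draws.
#'
#' @param psa an `ubt_psa`.
#' @param wtp_grid non-empty vector of WTP values (INR/DALY, >= 0).
#' @return Data frame `wtp`, `probability`.
#' @export
compute_ceac <- function(psa, wtp_grid) {
  stopifnot(length(wtp_grid) > 0, all(wtp_grid >= 0))
  de <- psa$draws$dalys_averted
  dc <- psa$draws$delta_cost
  prob <- vapply(wtp_grid, function(w) mean(de * w - dc > 0), numeric(1))
  data.frame(wtp = wtp_grid, probability = prob)
}

#' Expected value of perfect information
#'
#' Two-strategy decision problem: the comparator's incremental NMB is
#' identically zero, so per-person EVPI equals
#' `E[max(0, NMB)] - max(0, E[NMB])` over the PSA draws. The population
#' figure multiplies by an undiscounted one-time cohort.
#'
#' @param psa an `ubt_psa`.
#' @param settings [cea_settings()] (kept for interface symmetry; the NMB
#'   draws already embed the WTP).
#' @param population cohort size; defaults to the PSA's cohort.
#' @return List `per_person`, `population` (INR).
#' @export
compute_evpi <- function(psa, settings = NULL, population = psa$cohort) {
  nmb <- psa$draws$nmb
  per_person <- mean(pmax(0, nmb)) - max(0, mean(nmb))
  list(per_person = per_person, population = per_person * population)
}

#' @export
print.ubt_psa <- function(x, ...) {
  cat(sprintf("PSA: %s vs %s, %d draws (seed %d), %s perspective\n",
              x$intervention, x$comparator, x$n, x$seed, x$perspective))
  cat(sprintf("  P(cost-effective at WTP %s): %.3f\n",
              format(x$wtp, big.mark = ","), x$p_ce_at_base_wtp))
  cat(sprintf("  quadrants: dominant %.3f, dominated %.3f, tradeoff NE %.3f, tradeoff SW %.3f\n",
              x$quadrant_shares["dominant"], x$quadrant_shares["dominated"],
              x$quadrant_shares["tradeoff_ne"],
              x$quadrant_shares["tradeoff_sw"]))
  cat(sprintf("  EVPI: %.2f INR per person, %s INR for the cohort of %s\n",
              x$evpi_per_person,
              format(round(x$evpi_population), big.mark = ","),
              format(x$cohort, big.mark = ",")))
  invisible(x)
}

#' Plot PSA results
#'
#' @param x an `ubt_psa`.
#' @param type `"ce_plane"` scatter of incremental cost vs DALYs averted
#'   with the WTP line, or `"ceac"` acceptability curve.
#' @param ... passed to the underlying plot call.
#' @export
plot.ubt_psa <- function(x, type = c("ce_plane", "ceac"), ...) {
  type <- match.arg(type)
  if (type == "ce_plane") {
    graphics::plot(x$draws$dalys_averted, x$draws$delta_cost,
                   pch = 16, cex = 0.3, col = grDevices::grey(0.4),
                   xlab = "DALYs averted per patient",
                   ylab = "Incremental cost per patient (INR)",
                   main = sprintf("%s vs %s", x$intervention, x$comparator),
                   ...)
    graphics::abline(h = 0, v = 0, col = "grey70")
    graphics::abline(a = 0, b = x$wtp, col = "red", lty = 2)
  } else {
    graphics::plot(x$ceac$wtp, x$ceac$probability, type = "l",
                   ylim = c(0, 1),
                   xlab = "Willingness to pay (INR per DALY averted)",
                   ylab = "Probability cost-effective",
                   main = sprintf("CEAC: %s vs %s", x$intervention,
                                  x$comparator),
                   ...)
    graphics::abline(v = x$wtp, col = "red", lty = 2)
  }
  invisible(x)
}

#' One-way sensitivity analysis (tornado)
#'
#' Sets each varied parameter in turn to its lower and upper limit (all
#' others at base), re-evaluates both strategies, and records the
#' incremental NMB and ICER. The swing `|NMB(high) - NMB(low)|` orders the
#' tornado; NMB is used as the outcome scale because the ICER is unbounded
#' near zero effect difference, and the ranking agrees in regular regions.
#'
#' @param intervention,comparator device names.
#' @param params parameter set.
#' @param settings [cea_settings()].
#' @param policies [pathway_policies()].
#' @param discount_method DALY discounting method.
#' @param perspective cost perspective.
#' @param vary parameter names to vary; defaults to every parameter with a
#'   non-degenerate interval.
#' @return Object of class `ubt_owsa`: data frame `parameter`, `low`,
#'   `high`, `nmb_at_low`, `nmb_at_high`, `icer_at_low`, `icer_at_high`,
#'   `swing`, sorted by decreasing swing, with the base NMB as an attribute.
#' @export
run_owsa <- function(intervention, comparator = "condom",
                     params = ubt_reference_parameters(),
                     settings = cea_settings(params),
                     policies = pathway_policies(),
                     discount_method = "annual_annuity",
                     perspective = c("societal", "health_system"),
                     vary = NULL) {
  perspective <- match.arg(perspective)
  intervention <- ubt_strategy(intervention)$short
  comparator <- ubt_strategy(comparator)$short
  if (is.null(vary)) vary <- params$name[params$high > params$low]
  excess <- if (policies$death_model == "background_plus_excess")
    policies$excess_pph_death_prob else 0

  tree_int <- build_ubt_tree(intervention, params, policies)
  tree_cmp <- build_ubt_tree(comparator, params, policies)

  outcome <- function(lookup) {
    ri <- psa_eval_strategy(tree_int, lookup, 1L, discount_method, excess)
    rc <- psa_eval_strategy(tree_cmp, lookup, 1L, discount_method, excess)
    cost_col <- paste0("cost_", perspective)
    dc <- ri[[cost_col]] - rc[[cost_col]]
    de <- rc$daly - ri$daly
    c(nmb = compute_nmb(dc, de, settings$wtp), icer = compute_icer(dc, de))
  }
  base_lookup <- param_lookup(params)
  base <- outcome(base_lookup)
  rows <- vector("list", length(vary))
  for (k in seq_along(vary)) {
    nm <- vary[k]
    i <- match(nm, params$name)
    lo_lookup <- base_lookup; lo_lookup[[nm]] <- params$low[i]
    hi_lookup <- base_lookup; hi_lookup[[nm]] <- params$high[i]
    at_low <- outcome(lo_lookup)
    at_high <- outcome(hi_lookup)
    rows[[k]] <- data.frame(
      parameter = nm, low = params$low[i], high = params$high[i],
      nmb_at_low = at_low[["nmb"]], nmb_at_high = at_high[["nmb"]],
      icer_at_low = at_low[["icer"]], icer_at_high = at_high[["icer"]],
      swing = abs(at_high[["nmb"]] - at_low[["nmb"]]),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$swing), ]
  rownames(out) <- NULL
  attr(out, "base_nmb") <- base[["nmb"]]
  attr(out, "base_icer") <- base[["icer"]]
  attr(out, "intervention") <- intervention
  attr(out, "comparator") <- comparator
  attr(out, "perspective") <- perspective
  class(out) <- c("ubt_owsa", "data.frame")
  out
}

#' @export
print.ubt_owsa <- function(x, n = 10, ...) {
  cat(sprintf("One-way sensitivity analysis: %s vs %s (%s), base NMB %.1f INR\n",
              attr(x, "intervention"), attr(x, "comparator"),
              attr(x, "perspective"), attr(x, "base_nmb")))
  top <- utils::head(as.data.frame(x)[, c("parameter", "nmb_at_low",
                                          "nmb_at_high", "swing")], n)
  top[-1] <- lapply(top[-1], round, digits = 1)
  print(top, row.names = FALSE)
  invisible(x)
}

#' Tornado plot
#'
#' @param x an `ubt_owsa`.
#' @param n number of parameters to show (most influential first).
#' @param ... passed to [graphics::barplot()].
#' @export
plot.ubt_owsa <- function(x, n = 10, ...) {
  df <- utils::head(as.data.frame(x), n)
  df <- df[rev(seq_len(nrow(df))), ]
  base <- attr(x, "base_nmb")
  lo <- pmin(df$nmb_at_low, df$nmb_at_high) - base
  hi <- pmax(df$nmb_at_low, df$nmb_at_high) - base
  old <- graphics::par(mar = c(5, 14, 3, 2))
  on.exit(graphics::par(old))
  ylim <- c(0, nrow(df) + 1)
  graphics::plot(NULL, xlim = range(c(lo, hi)), ylim = ylim, yaxt = "n",
                 xlab = "Incremental NMB minus base (INR per patient)",
                 ylab = "",
                 main = sprintf("Tornado: %s vs %s", attr(x, "intervention"),
                                attr(x, "comparator")), ...)
  for (i in seq_len(nrow(df))) {
    graphics::rect(lo[i], i - 0.35, hi[i], i + 0.35, col = "steelblue",
                   border = NA)
  }
  graphics::abline(v = 0, col = "grey40")
  graphics::axis(2, at = seq_len(nrow(df)), labels = df$parameter, las = 1,
                 cex.axis = 0.7)
  invisible(x)
}
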