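# DALY engine. DALY = YLL + YLD; YLL = deaths x (discounted) remaining life
# expectancy; YLD = cases x disability weight x (discounted) duration.
# Disability profiles: bleeding controlled by UBT alone takes the mild
# maternal-haemorrhage weight over the six-week postpartum period; any
# surgical or ICU pathway takes the severe weight (once per patient);
# hysterectomy additionally accrues the secondary-infertility weight over
# the remaining reproductive life-span. No age weighting.

#' DALY valuation parameters
#'
#' @param params parameter set supplying disability weights, durations, life
#'   expectancy and the discount rate; defaults to the reference registry.
#' @param discount_rate annual rate in `[0, 0.05]`; default taken from
#'   `params` (`discount_rate`).
#' @param discount_method `"annual_annuity"` (default) discounts a duration
#'   of L years to `(1 - (1+r)^-L)/r`; `"continuous"` to `(1 - exp(-rL))/r`;
#'   `"none"` leaves durations undiscounted.
#' @return Object of class `ubt_daly_params`.
#' @export
daly_params <- function(params = ubt_reference_parameters(),
                        discount_rate = NULL,
                        discount_method = c("annual_annuity", "none",
                                            "continuous")) {
  discount_method <- match.arg(discount_method)
  v <- param_value(params, c("dw_mild_haem", "dw_severe_haem",
                             "dw_infertility", "duration_haemorrhage",
                             "infertility_end_age", "cohort_age",
                             "life_expectancy_remaining", "discount_rate"))
  r <- if (is.null(discount_rate)) unname(v["discount_rate"]) else discount_rate
  stopifnot(r >= 0, r <= 0.05)
  structure(list(dw_mild = unname(v["dw_mild_haem"]),
                 dw_severe = unname(v["dw_severe_haem"]),
                 dw_infertility = unname(v["dw_infertility"]),
                 duration_haemorrhage = unname(v["duration_haemorrhage"]),
                 infertility_end_age = unname(v["infertility_end_age"]),
                 cohort_age = unname(v["cohort_age"]),
                 life_expectancy_remaining =
                   unname(v["life_expectancy_remaining"]),
                 discount_rate = r,
                 discount_method = discount_method),
            class = "ubt_daly_params")
}

#' Discounted duration of a health state
#'
#' Present value, in years, of one year of healthy life lost per year over a
#' duration of `L` years.
#'
#' @param L duration in years (>= 0).
#' @param r annual discount rate.
#' @param method `"none"`, `"annual_annuity"` or `"continuous"`.
#' @return Discounted years; equals `L` when `r = 0` for every method, and
#'   is strictly decreasing in `r` for `L > 0`.
#' @examples
#' discounted_duration(25, 0.03, "annual_annuity")  # 17.41
#' @export
discounted_duration <- function(L, r,
                                method = c("annual_annuity", "none",
                                           "continuous")) {
  method <- match.arg(method)
  if (any(L < 0)) stop("duration must be non-negative", call. = FALSE)
  if (r == 0 || method == "none") return(L)
  switch(method,
         annual_annuity = (1 - (1 + r)^(-L)) / r,
         continuous = (1 - exp(-r * L)) / r)
}

#' Years of life lost
#'
#' @param deaths expected number of deaths.
#' @param dp [daly_params()].
#' @return Deaths times the (discounted) remaining life expectancy.
#' @export
compute_yll <- function(deaths, dp) {
  stopifnot(deaths >= 0)
  deaths * discounted_duration(dp$life_expectancy_remaining,
                               dp$discount_rate, dp$discount_method)
}

#' Years lived with disability
#'
#' @param cases expected number of surviving cases.
#' @param weight disability weight in `[0, 1]`.
#' @param duration duration of the health state in years.
#' @param dp [daly_params()].
#' @return Cases times weight times the (discounted) duration.
#' @export
compute_yld <- function(cases, weight, duration, dp) {
  stopifnot(cases >= 0, weight >= 0, weight <= 1)
  cases * weight * discounted_duration(duration, dp$discount_rate,
                                       dp$discount_method)
}

#' Disability profile of a terminal node
#'
#' @param payload a [terminal_payload()].
#' @param dp [daly_params()].
#' @return Data frame of `(weight, duration)` contributions for survivors at
#'   this terminal: mild haemorrhage for control by UBT alone; severe
#'   haemorrhage (once) for any of devascularization, hysterectomy or ICU
#'   admission; plus infertility over the remaining reproductive span after
#'   hysterectomy. Decedents accrue YLL only.
#' @export
assign_outcome_profile <- function(payload, dp) {
  severe_flags <- c("devascularization", "hysterectomy", "icu")
  w <- numeric(0); d <- numeric(0)
  if (any(severe_flags %in% payload$flags)) {
    w <- c(w, dp$dw_severe); d <- c(d, dp$duration_haemorrhage)
  } else if ("ubt_only_control" %in% payload$flags) {
    w <- c(w, dp$dw_mild); d <- c(d, dp$duration_haemorrhage)
  }
  if ("hysterectomy" %in% payload$flags) {
    w <- c(w, dp$dw_infertility)
    d <- c(d, dp$infertility_end_age - dp$cohort_age)
  }
  data.frame(weight = w, duration = d)
}

#' DALYs over a terminal distribution
#'
#' Sums YLL over the death mass and YLD over the surviving mass at each
#' terminal. Background all-cause maternal mortality applies at every
#' terminal; the configured excess-PPH death probability additionally
#' removes uncontrolled-after-UBT mass before the surgical outcome states.
#'
#' @param td an `ubt_terminal_dist`.
#' @param dp [daly_params()].
#' @param policies [pathway_policies()].
#' @param params parameter set supplying `p_mort_all_cause`; `NULL` means no
#'   background mortality.
#' @return Object of class `ubt_daly`: list with `yll`, `yld`, `daly`
#'   (= yll + yld), `per_patient_daly`, `deaths`.
#' @export
compute_dalys <- function(td, dp, policies = pathway_policies(),
                          params = NULL) {
  stopifnot(inherits(td, "ubt_terminal_dist"))
  excess <- if (policies$death_model == "background_plus_excess")
    policies$excess_pph_death_prob else 0
  p_bg <- if (is.null(params)) 0 else
    unname(param_value(params, "p_mort_all_cause"))
  yll_deaths <- 0
  yld <- 0
  for (i in seq_len(nrow(td$rows))) {
    t <- td$rows$terminal[i]
    n <- td$rows$count[i]
    p <- td$payloads[[t]]
    surgical <- any(c("devascularization", "hysterectomy") %in% p$flags)
    n_excess <- if (surgical) n * excess else 0
    n_bg <- (n - n_excess) * p_bg
    survivors <- n - n_excess - n_bg
    yll_deaths <- yll_deaths + n_excess + n_bg
    prof <- assign_outcome_profile(p, dp)
    for (j in seq_len(nrow(prof))) {
      yld <- yld + compute_yld(survivors, prof$weight[j], prof$duration[j], dp)
    }
  }
  yll <- compute_yll(yll_deaths, dp)
  daly <- yll + yld
  structure(list(yll = yll, yld = yld, daly = daly,
                 per_patient_daly = if (td$cohort > 0) daly / td$cohort
                                    else 0,
                 deaths = yll_deaths),
            class = "ubt_daly")
}

#' @export
print.ubt_daly <- function(x, ...) {
  cat(sprintf("DALYs: %.2f (YLL %.2f + YLD %.2f), %.6f per patient, %.1f deaths\n",
              x$daly, x$yll, x$yld, x$per_patient_daly, x$deaths))
  invisible(x)
}
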