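PARAM_COLUMNS <- c("name", "group", "value", "low", "high", "family",
                   "units", "description")
PARAM_GROUPS <- c("probability", "proportion", "cost", "count", "weight",
                  "rate", "duration")
BETA_GROUPS <- c("probability", "proportion", "weight")
GAMMA_GROUPS <- c("cost", "count", "rate", "duration")

# Highest effectiveness reported for any UBT device in the underlying
# evidence review; sampled effectiveness never exceeds it.
EFFECTIVENESS_CEILING <- 0.983

#' Parameter set constructor
#'
#' Wraps a data frame of model inputs (one row per parameter, columns
#' `name,group,value,low,high,family,units,description`) as a validated
#' parameter set. All invariants are enforced: `low <= value <= high`;
#' probabilities, proportions and disability weights live in [0, 1] and
#' sample from Beta distributions; costs, counts, rates and durations are
#' non-negative and sample from Gamma distributions.
#'
#' @param df data frame with the eight parameter columns.
#' @param provenance free-text label recording where the values came from.
#' @return An object of class `ubt_params` (a data frame).
#' @export
ubt_params <- function(df, provenance = "unspecified") {
  missing_cols <- setdiff(PARAM_COLUMNS, names(df))
  if (length(missing_cols) > 0L) {
    stop("parameter table format error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- df[, PARAM_COLUMNS, drop = FALSE]
  df$name <- as.character(df$name)
  df$group <- as.character(df$group)
  df$family <- as.character(df$family)
  df$units <- as.character(df$units)
  df$description <- as.character(df$description)
  for (col in c("value", "low", "high")) df[[col]] <- as.numeric(df[[col]])
  violations <- validate_parameters(df)
  if (length(violations) > 0L) {
    stop("parameter validation error:\n  ",
         paste(violations, collapse = "\n  "), call. = FALSE)
  }
  rownames(df) <- df$name
  attr(df, "provenance") <- provenance
  class(df) <- c("ubt_params", "data.frame")
  df
}

#' Validate a parameter table
#'
#' @param df data frame with the parameter columns.
#' @return Character vector of violations (empty when valid).
#' @export
validate_parameters <- function(df) {
  v <- character()
  if (anyDuplicated(df$name)) {
    v <- c(v, paste0("duplicate parameter name(s): ",
                     paste(unique(df$name[duplicated(df$name)]),
                           collapse = ", ")))
  }
  for (i in seq_len(nrow(df))) {
    r <- df[i, ]
    nm <- r$name
    if (!r$group %in% PARAM_GROUPS) {
      v <- c(v, sprintf("%s: unknown group '%s'", nm, r$group))
      next
    }
    if (any(!is.finite(c(r$value, r$low, r$high)))) {
      v <- c(v, sprintf("%s: non-finite value/low/high", nm))
      next
    }
    if (r$low > r$high) {
      v <- c(v, sprintf("%s: low (%g) > high (%g)", nm, r$low, r$high))
    }
    if (r$value < r$low || r$value > r$high) {
      v <- c(v, sprintf("%s: value %g outside [%g, %g]",
                        nm, r$value, r$low, r$high))
    }
    if (r$group %in% BETA_GROUPS) {
      if (r$low < 0 || r$high > 1) {
        v <- c(v, sprintf("%s: %s limits [%g, %g] outside [0, 1]",
                          nm, r$group, r$low, r$high))
      }
      if (!r$family %in% c("beta", "fixed")) {
        v <- c(v, sprintf("%s: group %s requires family beta or fixed, got %s",
                          nm, r$group, r$family))
      }
    } else {
      if (r$low < 0) {
        v <- c(v, sprintf("%s: %s lower limit %g is negative",
                          nm, r$group, r$low))
      }
      if (!r$family %in% c("gamma", "fixed")) {
        v <- c(v, sprintf("%s: group %s requires family gamma or fixed, got %s",
                          nm, r$group, r$family))
      }
    }
  }
  v
}

#' Load a parameter table from CSV
#'
#' Reads the comma-separated parameter dialect (UTF-8, "." decimal separator,
#' one header row with columns `name,group,value,low,high,family,units,
#' description`) and returns a validated parameter set. The whole file is
#' rejected on any invariant violation.
#'
#' @param source path to a CSV file, a connection, or a character vector of
#'   CSV lines.
#' @param provenance free-text label; defaults to the file path.
#' @return An object of class [ubt_params].
#' @export
load_parameter_table <- function(source, provenance = NULL) {
  if (is.character(source) && length(source) > 1L) {
    source <- textConnection(source)
    on.exit(close(source))
    if (is.null(provenance)) provenance <- "in-memory"
  } else if (is.character(source)) {
    if (!file.exists(source)) {
      stop("parameter file not found: ", source, call. = FALSE)
    }
    if (is.null(provenance)) provenance <- source
  }
  df <- utils::read.csv(source, stringsAsFactors = FALSE,
                        colClasses = "character", encoding = "UTF-8")
  missing_cols <- setdiff(PARAM_COLUMNS, names(df))
  if (length(missing_cols) > 0L) {
    stop("parameter table format error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0L) {
    df <- data.frame(name = character(), group = character(),
                     value = numeric(), low = numeric(), high = numeric(),
                     family = character(), units = character(),
                     description = character(), stringsAsFactors = FALSE)
  }
  ubt_params(df, provenance = if (is.null(provenance)) "connection" else provenance)
}

#' Write a parameter set to CSV
#'
#' Inverse of [load_parameter_table()]: the written file round-trips
#' field-by-field.
#'
#' @param ps parameter set.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_parameter_table <- function(ps, path) {
  stopifnot(inherits(ps, "ubt_params"))
  df <- as.data.frame(ps)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Reference parameter set
#'
#' The model's full input registry: every epidemiological, clinical and cost
#' input with its base value and lower/upper limits, plus the named analysis
#' constants (WTP threshold, GDP per capita, USD conversion rate, remaining
#' life expectancy, disability durations). Shipped with the package as two
#' plain-text fixtures (`table1_reference.csv`, `constants.csv`).
#'
#' @return An object of class [ubt_params].
#' @examples
#' ps <- ubt_reference_parameters()
#' param_value(ps, "p_eff_condom")
#' @export
ubt_reference_parameters <- function() {
  t1 <- system.file("extdata", "table1_reference.csv", package = "ubtcea",
                    mustWork = TRUE)
  cn <- system.file("extdata", "constants.csv", package = "ubtcea",
                    mustWork = TRUE)
  d1 <- utils::read.csv(t1, stringsAsFactors = FALSE)
  d2 <- utils::read.csv(cn, stringsAsFactors = FALSE)
  ubt_params(rbind(d1, d2), provenance = "reference model inputs")
}

#' Published headline results
#'
#' The published base-case totals, incrementals and sensitivity-analysis
#' headline figures for the three devices, as a named numeric vector. These
#' are reported values (not model inputs); they are used as inputs to the
#' cost-effectiveness arithmetic checks and comparisons.
#'
#' @return Named numeric vector.
#' @export
ubt_published_results <- function() {
  path <- system.file("extdata", "published_results.csv", package = "ubtcea",
                      mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stats::setNames(df$value, df$name)
}

#' Look up a parameter's base value
#'
#' @param ps parameter set.
#' @param name parameter name (vectorised).
#' @return Numeric vector of base values.
#' @export
param_value <- function(ps, name) {
  idx <- match(name, ps$name)
  if (anyNA(idx)) {
    stop("unresolved parameter reference: ",
         paste(name[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  stats::setNames(ps$value[idx], name)
}

# Named list mapping parameter name -> scalar base value.
param_lookup <- function(ps) {
  as.list(stats::setNames(ps$value, ps$name))
}

#' @export
print.ubt_params <- function(x, ...) {
  cat(sprintf("UBT model parameter set: %d parameters (%s)\n",
              nrow(x), attr(x, "provenance")))
  cat(sprintf("  groups: %s\n",
              paste(names(table(x$group)), table(x$group),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' Derive a sampling distribution from interval limits
#'
#' Probabilities, proportions and disability weights are assigned Beta
#' distributions; costs and resource counts Gamma distributions. Hyper
#' parameters come from the method of moments with mean equal to the base
#' value and standard deviation `(high - low) / 3.92`, i.e. the limits are
#' treated as a symmetric 95 percent interval. Degenerate intervals
#' (`low == high`) yield a fixed (point-mass) spec. Device-effectiveness
#' parameters carry a truncation ceiling of 0.983, the highest effectiveness
#' reported in the evidence base; draws above it are rejected and resampled.
#'
#' @param p a single-row parameter (one row of a [ubt_params] table), or a
#'   parameter set together with `name`.
#' @param name parameter name when `p` is a full parameter set.
#' @return A list of class `ubt_dist` with elements `family`, `hyper1`
#'   (Beta alpha / Gamma shape / fixed value), `hyper2` (Beta beta / Gamma
#'   scale), `truncation_high`, `mean`, `sd`, `name`.
#' @examples
#' ps <- ubt_reference_parameters()
#' derive_sampling_distribution(ps, "p_icu_controlled")
#' @export
derive_sampling_distribution <- function(p, name = NULL) {
  if (!is.null(name)) p <- p[p$name == name, , drop = FALSE]
  if (nrow(p) != 1L) stop("expected exactly one parameter row", call. = FALSE)
  nm <- p$name
  m <- p$value
  sdev <- (p$high - p$low) / 3.92
  trunc_high <- if (grepl("^p_eff_", nm)) EFFECTIVENESS_CEILING else NA_real_
  spec <- list(name = nm, family = "fixed", hyper1 = m, hyper2 = NA_real_,
               truncation_high = trunc_high, mean = m, sd = 0)
  if (p$family == "fixed" || p$high == p$low) {
    class(spec) <- "ubt_dist"
    return(spec)
  }
  if (p$family == "beta") {
    v <- sdev^2
    if (v >= m * (1 - m) || m <= 0 || m >= 1) {
      warning(sprintf(
        "%s: implied variance %.3g not attainable for a Beta with mean %.3g; using fixed value",
        nm, v, m), call. = FALSE)
      class(spec) <- "ubt_dist"
      return(spec)
    }
    k <- m * (1 - m) / v - 1
    spec$family <- "beta"
    spec$hyper1 <- m * k
    spec$hyper2 <- (1 - m) * k
    spec$sd <- sdev
  } else {
    spec$family <- "gamma"
    spec$hyper1 <- (m / sdev)^2           # shape
    spec$hyper2 <- sdev^2 / m             # scale
    spec$sd <- sdev
  }
  class(spec) <- "ubt_dist"
  spec
}

#' @export
print.ubt_dist <- function(x, ...) {
  cat(sprintf("%s: %s(%.6g, %.6g), mean %.6g, sd %.6g%s\n",
              x$name, x$family, x$hyper1,
              ifelse(is.na(x$hyper2), 0, x$hyper2), x$mean, x$sd,
              if (!is.na(x$truncation_high))
                sprintf(", truncated above %.3f", x$truncation_high) else ""))
  invisible(x)
}

#' Draw from a sampling distribution spec
#'
#' @param spec an `ubt_dist` from [derive_sampling_distribution()].
#' @param n number of draws.
#' @param truncation_mode how the ceiling is enforced: `"clamp"` (default)
#'   caps draws at the ceiling, leaving the distribution's mean essentially
#'   unchanged (the ceiling is a hard cap on attainable effectiveness, not
#'   a reshaping of belief below it); `"resample"` rejects and redraws,
#'   which redistributes the capped mass downward and shifts the mean.
#' @return Numeric vector of length `n`.
#' @export
sample_distribution <- function(spec, n,
                                truncation_mode = c("clamp", "resample")) {
  truncation_mode <- match.arg(truncation_mode)
  draw <- switch(spec$family,
    fixed = rep.int(spec$hyper1, n),
    beta  = stats::rbeta(n, spec$hyper1, spec$hyper2),
    gamma = stats::rgamma(n, shape = spec$hyper1, scale = spec$hyper2),
    stop("unknown family: ", spec$family)
  )
  if (!is.na(spec$truncation_high) && spec$family != "fixed") {
    if (truncation_mode == "clamp") {
      draw <- pmin(draw, spec$truncation_high)
    } else {
      bad <- which(draw > spec$truncation_high)
      guard <- 0L
      while (length(bad) > 0L && guard < 1000L) {
        draw[bad] <- switch(spec$family,
          beta  = stats::rbeta(length(bad), spec$hyper1, spec$hyper2),
          gamma = stats::rgamma(length(bad), shape = spec$hyper1,
                                scale = spec$hyper2))
        bad <- bad[draw[bad] > spec$truncation_high]
        guard <- guard + 1L
      }
      if (length(bad) > 0L) draw[bad] <- spec$truncation_high
    }
  }
  draw
}

#' Joint parameter draws for probabilistic analysis
#'
#' Samples every non-fixed parameter independently from its derived
#' distribution. Parameters named in `hold_fixed` are kept at their base
#' value (used for cohort sizes, which are shared between arms in
#' incremental comparisons).
#'
#' @param ps parameter set.
#' @param n number of joint draws.
#' @param seed integer seed; the draw matrix is deterministic given it.
#' @param hold_fixed character vector of parameter names to hold at base.
#' @return Numeric matrix, `n` rows by one column per parameter.
#' @export
sample_parameter_draws <- function(ps, n, seed = NULL,
                                   hold_fixed = character()) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  out <- matrix(NA_real_, nrow = n, ncol = nrow(ps),
                dimnames = list(NULL, ps$name))
  for (i in seq_len(nrow(ps))) {
    nm <- ps$name[i]
    if (nm %in% hold_fixed) {
      out[, i] <- ps$value[i]
    } else {
      spec <- suppressWarnings(derive_sampling_distribution(ps[i, ]))
      out[, i] <- sample_distribution(spec, n)
    }
  }
  out
}

#' Perturbed variant of a parameter set
#'
#' Replaces each non-fixed base value by a draw from its sampling
#' distribution shrunk by `scale` toward the mean
#' (`value + scale * (draw - value)`), shifting the limits by the same
#' offset (clamped to the group's domain). Used to generate valid randomized
#' parameter files for testing; deterministic given `seed`.
#'
#' @param ps parameter set.
#' @param scale shrinkage in (0, 1]; 0 is allowed and returns `ps` unchanged.
#' @param seed integer seed.
#' @return A new [ubt_params] object.
#' @export
perturb_parameters <- function(ps, scale, seed = NULL) {
  stopifnot(scale >= 0, scale <= 1)
  if (!is.null(seed)) set.seed(seed)
  df <- as.data.frame(ps)
  for (i in seq_len(nrow(df))) {
    r <- df[i, ]
    if (r$family == "fixed" || r$high == r$low || scale == 0) next
    spec <- suppressWarnings(derive_sampling_distribution(df[i, ]))
    if (spec$family == "fixed") next
    draw <- sample_distribution(spec, 1L)
    new_value <- r$value + scale * (draw - r$value)
    delta <- new_value - r$value
    new_low <- r$low + delta
    new_high <- r$high + delta
    if (r$group %in% BETA_GROUPS) {
      new_low <- max(0, new_low)
      new_high <- min(1, new_high)
      new_value <- min(max(new_value, new_low), new_high)
    } else {
      new_low <- max(0, new_low)
    }
    df$value[i] <- new_value
    df$low[i] <- new_low
    df$high[i] <- new_high
  }
  ubt_params(df, provenance = sprintf("%s (perturbed, scale %g)",
                                      attr(ps, "provenance"), scale))
}

#' Annual cohort eligible for UBT insertion
#'
#' Deliveries in public facilities times PPH incidence times the atonic
#' share times the share not controlled by uterotonics, rounded to a whole
#' number of women.
#'
#' @param ps parameter set.
#' @return Integer-valued count.
#' @examples
#' eligible_cohort(ubt_reference_parameters())  # 59962
#' @export
eligible_cohort <- function(ps) {
  v <- param_value(ps, c("deliveries_public", "p_pph_incidence",
                         "p_atonic_share", "p_uterotonic_failure"))
  round(prod(v))
}
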