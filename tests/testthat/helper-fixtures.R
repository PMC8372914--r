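# Shared fixtures: the reference registry (loaded once), an empty parameter
# set for literal-probability trees, and a random-tree generator used by the
# rollback-vs-enumeration oracle checks.

ref_params <- ubt_reference_parameters()

empty_params <- ubt_params(data.frame(
  name = character(), group = character(), value = numeric(),
  low = numeric(), high = numeric(), family = character(),
  units = character(), description = character(),
  stringsAsFactors = FALSE))

trivial_payload <- function(amount = 100) {
  terminal_payload(
    data.frame(label = "care", amount = as.character(amount),
               payer = "health_system", stringsAsFactors = FALSE),
    flags = character(), bleeding_status = "controlled")
}

# Random tree: chance nodes with 2-4 branches, literal probabilities from a
# Dirichlet draw with the last branch a complement, depth <= max_depth.
random_tree <- function(seed, max_depth = 4, max_branches = 4) {
  set.seed(seed)
  nodes <- list(); branches <- list(); payloads <- list()
  counter <- new.env(parent = emptyenv()); counter$i <- 0L
  new_id <- function() { counter$i <- counter$i + 1L; paste0("n", counter$i) }
  build <- function(depth) {
    id <- new_id()
    if (depth >= max_depth || (depth > 0 && stats::runif(1) < 0.35)) {
      nodes[[length(nodes) + 1L]] <<-
        data.frame(id = id, kind = "terminal", label = id)
      payloads[[id]] <<- trivial_payload(round(stats::runif(1, 10, 500)))
      return(id)
    }
    nodes[[length(nodes) + 1L]] <<-
      data.frame(id = id, kind = "chance", label = id)
    k <- sample(2:max_branches, 1)
    w <- stats::rgamma(k, 1) + 0.05
    p <- w / sum(w)
    for (j in seq_len(k)) {
      child <- build(depth + 1L)
      prob <- if (j == k) "~" else format(p[j], digits = 17)
      branches[[length(branches) + 1L]] <<-
        data.frame(parent = id, child = child, prob = prob)
    }
    id
  }
  root <- build(0L)
  decision_tree(root, do.call(rbind, nodes), do.call(rbind, branches),
                payloads)
}

# Evaluate a micro-model through the engine, shaped like its closed forms.
micro_engine_results <- function(mm) {
  td <- rollback_evaluate(mm$tree, mm$params, mm$cohort)
  ev <- compute_event_counts(td)
  dal <- compute_dalys(td, daly_params(mm$params,
                                       discount_method = "none"))
  list(patients_operated = ev$patients_operated,
       procedures = ev$procedures,
       hysterectomies = ev$hysterectomies,
       icu_admissions = ev$icu_admissions,
       total_societal_cost = accumulate_costs(td, "societal")$total,
       total_health_system_cost =
         accumulate_costs(td, "health_system")$total,
       total_daly = dal$daly)
}

# Reference parameter set with one value overridden (limits widened to keep
# the row valid).
override_param <- function(ps, name, value) {
  df <- as.data.frame(ps)
  i <- match(name, df$name)
  stopifnot(!is.na(i))
  df$value[i] <- value
  df$low[i] <- min(df$low[i], value)
  df$high[i] <- max(df$high[i], value)
  ubt_params(df, provenance = "override")
}
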