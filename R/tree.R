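# Decision-tree engine: chance/terminal node graphs, validation,
# expected-value cohort rollback, and an exhaustive path-enumeration oracle.
# Branch probabilities are symbolic (literal, parameter reference, or the
# complement marker "~") and resolve at evaluation time, so sensitivity
# analyses re-evaluate one structure under many parameter sets.

COMPLEMENT <- "~"

#' Terminal payload constructor
#'
#' The consequences attached to a terminal node: cost items with payer,
#' clinical event flags, and the bleeding status reached.
#'
#' @param cost_items data frame with columns `label`, `amount`, `payer`.
#'   `amount` may be numeric or a parameter name (resolved at evaluation);
#'   `payer` is `"health_system"` or `"household"`.
#' @param flags character vector over `ubt_only_control`, `devascularization`,
#'   `hysterectomy`, `icu`, `referred`.
#' @param bleeding_status `"controlled"` or `"uncontrolled"`.
#' @return Object of class `ubt_payload`.
#' @export
terminal_payload <- function(cost_items = NULL,
                             flags = character(),
                             bleeding_status = c("controlled", "uncontrolled")) {
  bleeding_status <- match.arg(bleeding_status)
  if (is.null(cost_items)) {
    cost_items <- data.frame(label = character(), amount = character(),
                             payer = character(), stringsAsFactors = FALSE)
  }
  stopifnot(all(c("label", "amount", "payer") %in% names(cost_items)))
  cost_items$label <- as.character(cost_items$label)
  cost_items$amount <- as.character(cost_items$amount)
  cost_items$payer <- as.character(cost_items$payer)
  bad_payer <- setdiff(unique(cost_items$payer), c("health_system", "household"))
  if (length(bad_payer) > 0L) {
    stop("unknown payer(s): ", paste(bad_payer, collapse = ", "),
         call. = FALSE)
  }
  valid_flags <- c("ubt_only_control", "devascularization", "hysterectomy",
                   "icu", "referred")
  bad <- setdiff(flags, valid_flags)
  if (length(bad) > 0L) {
    stop("unknown event flag(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(list(cost_items = cost_items, flags = flags,
                 bleeding_status = bleeding_status),
            class = "ubt_payload")
}

#' Decision tree constructor
#'
#' @param root id of the root node.
#' @param nodes data frame with columns `id`, `kind` (`"chance"` or
#'   `"terminal"`), `label`.
#' @param branches data frame with columns `parent`, `child`, `prob`.
#'   `prob` is a numeric literal, a parameter name, or `"~"` — the
#'   complement marker (1 minus the sum of the sibling branches).
#' @param payloads named list mapping terminal id to [terminal_payload()].
#' @return Object of class `ubt_tree`.
#' @export
decision_tree <- function(root, nodes, branches, payloads) {
  nodes$id <- as.character(nodes$id)
  nodes$kind <- as.character(nodes$kind)
  if (!"label" %in% names(nodes)) nodes$label <- nodes$id
  nodes$label <- as.character(nodes$label)
  branches$parent <- as.character(branches$parent)
  branches$child <- as.character(branches$child)
  branches$prob <- as.character(branches$prob)
  structure(list(root = as.character(root), nodes = nodes,
                 branches = branches, payloads = payloads),
            class = "ubt_tree")
}

#' @export
print.ubt_tree <- function(x, ...) {
  cat(sprintf("Decision tree: %d nodes (%d chance, %d terminal), %d branches, root '%s'\n",
              nrow(x$nodes), sum(x$nodes$kind == "chance"),
              sum(x$nodes$kind == "terminal"), nrow(x$branches), x$root))
  invisible(x)
}

# Resolve one branch-probability token against a lookup of numeric vectors.
# Returns a vector of length n (literals recycled). Complement handled by
# the caller, which sees all siblings at once.
resolve_prob_token <- function(token, lookup, n) {
  num <- suppressWarnings(as.numeric(token))
  if (!is.na(num)) return(rep.int(num, n))
  val <- lookup[[token]]
  if (is.null(val)) {
    stop("unresolved parameter reference in branch probability: ", token,
         call. = FALSE)
  }
  if (length(val) == 1L) rep.int(val, n) else val
}

# For every chance node, an n x k matrix of resolved sibling probabilities
# (complement filled in), in branch order.
resolve_node_probs <- function(tree, lookup, n) {
  out <- list()
  for (parent in unique(tree$branches$parent)) {
    idx <- which(tree$branches$parent == parent)
    toks <- tree$branches$prob[idx]
    m <- matrix(NA_real_, nrow = n, ncol = length(idx))
    comp <- which(toks == COMPLEMENT)
    if (length(comp) > 1L) {
      stop("node ", parent, " has more than one complement branch",
           call. = FALSE)
    }
    for (j in seq_along(toks)) {
      if (j %in% comp) next
      m[, j] <- resolve_prob_token(toks[j], lookup, n)
    }
    if (length(comp) == 1L) {
      m[, comp] <- 1 - rowSums(m[, -comp, drop = FALSE])
    }
    out[[parent]] <- m
  }
  out
}

#' Validate a decision tree
#'
#' Structural and numeric checks: unique node ids, reachability from the
#' root, at least two branches per chance node, a payload for every
#' terminal, at most one complement branch per node, and (when resolvable)
#' sibling probabilities summing to one within 1e-9 and lying in [0, 1].
#'
#' @param tree an `ubt_tree`.
#' @param params optional [ubt_params] used to resolve parameter references
#'   for the numeric checks; references that cannot be resolved are skipped
#'   structurally rather than reported.
#' @return Character vector of violations; empty when the tree is valid.
#' @export
validate_tree <- function(tree, params = NULL) {
  v <- character()
  nodes <- tree$nodes
  branches <- tree$branches
  if (anyDuplicated(nodes$id)) {
    v <- c(v, paste0("duplicate node id(s): ",
                     paste(unique(nodes$id[duplicated(nodes$id)]),
                           collapse = ", ")))
  }
  unknown <- setdiff(unique(c(branches$parent, branches$child, tree$root)),
                     nodes$id)
  if (length(unknown) > 0L) {
    v <- c(v, paste0("branch references unknown node(s): ",
                     paste(unknown, collapse = ", ")))
    return(v)
  }
  # reachability
  reached <- tree$root
  frontier <- tree$root
  while (length(frontier) > 0L) {
    nxt <- branches$child[branches$parent %in% frontier]
    frontier <- setdiff(nxt, reached)
    reached <- c(reached, frontier)
  }
  orphans <- setdiff(nodes$id, reached)
  if (length(orphans) > 0L) {
    v <- c(v, paste0("node(s) unreachable from root: ",
                     paste(orphans, collapse = ", ")))
  }
  for (id in nodes$id[nodes$kind == "chance"]) {
    k <- sum(branches$parent == id)
    if (k < 2L) {
      v <- c(v, sprintf("chance node %s has %d branch(es); needs >= 2", id, k))
    }
    toks <- branches$prob[branches$parent == id]
    if (sum(toks == COMPLEMENT) > 1L) {
      v <- c(v, sprintf("node %s has more than one complement branch", id))
    }
  }
  for (id in nodes$id[nodes$kind == "terminal"]) {
    if (sum(branches$parent == id) > 0L) {
      v <- c(v, sprintf("terminal node %s has outgoing branches", id))
    }
    if (!id %in% names(tree$payloads)) {
      v <- c(v, sprintf("terminal node %s has no payload", id))
    }
  }
  # numeric sum-to-one where resolvable
  lookup <- if (is.null(params)) list() else param_lookup(params)
  for (id in unique(branches$parent)) {
    toks <- branches$prob[branches$parent == id]
    if (sum(toks == COMPLEMENT) > 1L) next
    vals <- numeric(0)
    resolvable <- TRUE
    has_comp <- any(toks == COMPLEMENT)
    for (tok in toks[toks != COMPLEMENT]) {
      num <- suppressWarnings(as.numeric(tok))
      if (is.na(num)) {
        num <- lookup[[tok]]
        if (is.null(num)) { resolvable <- FALSE; break }
      }
      vals <- c(vals, num)
    }
    if (!resolvable) next
    if (any(vals < 0 | vals > 1)) {
      v <- c(v, sprintf("node %s: branch probability outside [0, 1]", id))
    }
    if (has_comp) {
      if (sum(vals) > 1 + 1e-9) {
        v <- c(v, sprintf(
          "node %s: explicit probabilities sum to %.12g > 1 with a complement branch",
          id, sum(vals)))
      }
    } else if (abs(sum(vals) - 1) > 1e-9) {
      v <- c(v, sprintf("node %s: sibling probabilities sum to %.12g, not 1",
                        id, sum(vals)))
    }
  }
  v
}

# Resolve a payload's cost items to numeric amounts under a lookup. Returns
# the payload with `amount` numeric (vectors of length n as matrix columns
# are not needed: base-case evaluation is scalar; multi-draw evaluation
# resolves amounts separately).
resolve_payload <- function(payload, lookup) {
  ci <- payload$cost_items
  if (nrow(ci) > 0L) {
    amt <- numeric(nrow(ci))
    for (i in seq_len(nrow(ci))) {
      num <- suppressWarnings(as.numeric(ci$amount[i]))
      if (is.na(num)) {
        val <- lookup[[ci$amount[i]]]
        if (is.null(val)) {
          stop("unresolved parameter reference in cost item: ", ci$amount[i],
               call. = FALSE)
        }
        num <- val[1L]
      }
      amt[i] <- num
    }
    if (any(amt < 0)) {
      stop("negative cost amount in payload item ",
           paste(ci$label[amt < 0], collapse = ", "), call. = FALSE)
    }
    ci$amount_value <- amt
  } else {
    ci$amount_value <- numeric(0)
  }
  payload$cost_items <- ci
  payload
}

#' Expected-value cohort rollback
#'
#' Propagates the cohort mass from the root through every chance node: each
#' terminal's expected count is the cohort times the product of resolved
#' branch probabilities along its unique root path. Implemented as iterative
#' forward mass propagation in topological order (not path enumeration; see
#' [enumerate_paths()] for the independent oracle).
#'
#' @param tree validated `ubt_tree`.
#' @param params [ubt_params] resolving all parameter references.
#' @param cohort cohort size (expected counts sum to it).
#' @return Object of class `ubt_terminal_dist`: a list with `rows` (data
#'   frame `terminal`, `path_prob`, `count`), `payloads` (resolved, numeric
#'   cost amounts) and `cohort`.
#' @export
rollback_evaluate <- function(tree, params, cohort) {
  violations <- validate_tree(tree, params)
  if (length(violations) > 0L) {
    stop("invalid tree:\n  ", paste(violations, collapse = "\n  "),
         call. = FALSE)
  }
  lookup <- param_lookup(params)
  probs <- resolve_node_probs(tree, lookup, 1L)
  mass <- stats::setNames(numeric(nrow(tree$nodes)), tree$nodes$id)
  mass[tree$root] <- 1
  # forward propagation; queue of nodes whose mass is final
  pending <- tree$root
  while (length(pending) > 0L) {
    id <- pending[1L]
    pending <- pending[-1L]
    idx <- which(tree$branches$parent == id)
    if (length(idx) == 0L) next
    p <- probs[[id]][1L, ]
    children <- tree$branches$child[idx]
    mass[children] <- mass[children] + mass[id] * p
    pending <- c(pending, children)
  }
  terminals <- tree$nodes$id[tree$nodes$kind == "terminal"]
  rows <- data.frame(terminal = terminals,
                     path_prob = unname(mass[terminals]),
                     count = unname(mass[terminals]) * cohort,
                     stringsAsFactors = FALSE)
  payloads <- lapply(tree$payloads[terminals], resolve_payload, lookup = lookup)
  structure(list(rows = rows, payloads = payloads, cohort = cohort),
            class = "ubt_terminal_dist")
}

#' @export
print.ubt_terminal_dist <- function(x, ...) {
  cat(sprintf("Terminal distribution: %d terminals, cohort %.6g (mass sums to %.9g)\n",
              nrow(x$rows), x$cohort, sum(x$rows$path_prob)))
  print(x$rows, row.names = FALSE)
  invisible(x)
}

#' Exhaustive path enumeration
#'
#' Depth-first enumeration of every root-to-terminal path, multiplying
#' resolved branch probabilities along the way. Serves as the independent
#' oracle for [rollback_evaluate()]; the two agree per terminal to 1e-12.
#'
#' @param tree an `ubt_tree`.
#' @param params [ubt_params].
#' @return Data frame `terminal`, `prob` (joint probability, summed over
#'   paths reaching the same terminal).
#' @export
enumerate_paths <- function(tree, params) {
  lookup <- param_lookup(params)
  probs <- resolve_node_probs(tree, lookup, 1L)
  acc <- new.env(parent = emptyenv())
  recurse <- function(id, p, stack) {
    if (id %in% stack) {
      stop("cycle detected through node ", id, call. = FALSE)
    }
    idx <- which(tree$branches$parent == id)
    if (length(idx) == 0L) {
      prev <- if (is.null(acc[[id]])) 0 else acc[[id]]
      acc[[id]] <- prev + p
      return(invisible(NULL))
    }
    bp <- probs[[id]][1L, ]
    for (j in seq_along(idx)) {
      recurse(tree$branches$child[idx[j]], p * bp[j], c(stack, id))
    }
    invisible(NULL)
  }
  recurse(tree$root, 1, character())
  terminals <- tree$nodes$id[tree$nodes$kind == "terminal"]
  data.frame(terminal = terminals,
             prob = vapply(terminals,
                           function(t) if (is.null(acc[[t]])) 0 else acc[[t]],
                           numeric(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

# Multi-draw evaluation: terminal path-probability matrix (n draws x
# terminals) plus per-draw resolved cost sums by payer for each terminal.
# `lookup` maps parameter name -> vector of length n. Used by the PSA.
evaluate_tree_draws <- function(tree, lookup, n) {
  probs <- resolve_node_probs(tree, lookup, n)
  mass <- list()
  for (id in tree$nodes$id) mass[[id]] <- numeric(n)
  mass[[tree$root]] <- rep.int(1, n)
  pending <- tree$root
  while (length(pending) > 0L) {
    id <- pending[1L]
    pending <- pending[-1L]
    idx <- which(tree$branches$parent == id)
    if (length(idx) == 0L) next
    m <- probs[[id]]
    for (j in seq_along(idx)) {
      child <- tree$branches$child[idx[j]]
      mass[[child]] <- mass[[child]] + mass[[id]] * m[, j]
    }
    pending <- c(pending, tree$branches$child[idx])
  }
  terminals <- tree$nodes$id[tree$nodes$kind == "terminal"]
  pm <- do.call(cbind, mass[terminals])
  colnames(pm) <- terminals
  # per-terminal, per-draw cost by payer
  cost_hs <- matrix(0, nrow = n, ncol = length(terminals),
                    dimnames = list(NULL, terminals))
  cost_hh <- cost_hs
  for (t in terminals) {
    ci <- tree$payloads[[t]]$cost_items
    for (i in seq_len(nrow(ci))) {
      num <- suppressWarnings(as.numeric(ci$amount[i]))
      amt <- if (!is.na(num)) rep.int(num, n) else {
        val <- lookup[[ci$amount[i]]]
        if (is.null(val)) stop("unresolved parameter reference in cost item: ",
                               ci$amount[i], call. = FALSE)
        if (length(val) == 1L) rep.int(val, n) else val
      }
      if (ci$payer[i] == "health_system") {
        cost_hs[, t] <- cost_hs[, t] + amt
      } else {
        cost_hh[, t] <- cost_hh[, t] + amt
      }
    }
  }
  list(path_prob = pm, cost_health_system = cost_hs, cost_household = cost_hh,
       terminals = terminals)
}

#' Serialize a decision tree to a plain-text document
#'
#' Writes nodes, branches and payloads in a line-oriented key-value format
#' sufficient to round-trip the tree with [read_tree()].
#'
#' @param tree an `ubt_tree`.
#' @param path output file path; when `NULL` the text is returned.
#' @return The serialized lines, invisibly when written to a file.
#' @export
write_tree <- function(tree, path = NULL) {
  lines <- c(sprintf("root\t%s", tree$root), "[nodes]")
  lines <- c(lines, sprintf("%s\t%s\t%s", tree$nodes$id, tree$nodes$kind,
                            tree$nodes$label))
  lines <- c(lines, "[branches]")
  lines <- c(lines, sprintf("%s\t%s\t%s", tree$branches$parent,
                            tree$branches$child, tree$branches$prob))
  lines <- c(lines, "[payloads]")
  for (t in names(tree$payloads)) {
    p <- tree$payloads[[t]]
    lines <- c(lines, sprintf("terminal\t%s\t%s\t%s", t, p$bleeding_status,
                              paste(p$flags, collapse = ",")))
    ci <- p$cost_items
    if (nrow(ci) > 0L) {
      lines <- c(lines, sprintf("cost\t%s\t%s\t%s\t%s", t, ci$label,
                                ci$amount, ci$payer))
    }
  }
  if (is.null(path)) return(lines)
  writeLines(lines, path, useBytes = TRUE)
  invisible(lines)
}

#' Read a serialized decision tree
#'
#' @param source path to a file written by [write_tree()], or its lines.
#' @return An `ubt_tree`.
#' @export
read_tree <- function(source) {
  lines <- if (length(source) == 1L && file.exists(source)) {
    readLines(source, encoding = "UTF-8")
  } else source
  section <- "header"
  root <- NULL
  nodes <- list(); branches <- list()
  term_meta <- list(); cost_rows <- list()
  for (ln in lines) {
    if (ln == "[nodes]") { section <- "nodes"; next }
    if (ln == "[branches]") { section <- "branches"; next }
    if (ln == "[payloads]") { section <- "payloads"; next }
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (section == "header" && f[1] == "root") root <- f[2]
    else if (section == "nodes") nodes[[length(nodes) + 1L]] <- f
    else if (section == "branches") branches[[length(branches) + 1L]] <- f
    else if (section == "payloads") {
      if (f[1] == "terminal") term_meta[[f[2]]] <- f
      else cost_rows[[length(cost_rows) + 1L]] <- f
    }
  }
  nodes_df <- data.frame(id = vapply(nodes, `[`, "", 1),
                         kind = vapply(nodes, `[`, "", 2),
                         label = vapply(nodes, `[`, "", 3),
                         stringsAsFactors = FALSE)
  branches_df <- data.frame(parent = vapply(branches, `[`, "", 1),
                            child = vapply(branches, `[`, "", 2),
                            prob = vapply(branches, `[`, "", 3),
                            stringsAsFactors = FALSE)
  payloads <- list()
  for (t in names(term_meta)) {
    f <- term_meta[[t]]
    flags <- if (length(f) >= 4L && nzchar(f[4]))
      strsplit(f[4], ",", fixed = TRUE)[[1]] else character()
    rows <- Filter(function(r) r[2] == t, cost_rows)
    ci <- data.frame(
      label = vapply(rows, `[`, "", 3),
      amount = vapply(rows, `[`, "", 4),
      payer = vapply(rows, `[`, "", 5),
      stringsAsFactors = FALSE)
    payloads[[t]] <- terminal_payload(ci, flags = flags,
                                      bleeding_status = f[3])
  }
  decision_tree(root, nodes_df, branches_df, payloads)
}
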