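two_branch_tree <- function(p1 = "0.3", p2 = "~") {
  decision_tree(
    "root",
    data.frame(id = c("root", "a", "b"),
               kind = c("chance", "terminal", "terminal"),
               label = c("root", "a", "b")),
    data.frame(parent = c("root", "root"), child = c("a", "b"),
               prob = c(p1, p2)),
    list(a = trivial_payload(), b = trivial_payload()))
}

test_that("complement branches resolve and validate", {
  expect_length(validate_tree(two_branch_tree()), 0L)
})

test_that("sum-to-one and reachability violations name the node", {
  bad <- two_branch_tree("0.6", "0.6")
  v <- validate_tree(bad)
  expect_true(any(grepl("root", v) & grepl("sum", v)))

  orphan <- decision_tree(
    "root",
    data.frame(id = c("root", "a", "b", "lost"),
               kind = c("chance", "terminal", "terminal", "terminal"),
               label = NA),
    data.frame(parent = c("root", "root"), child = c("a", "b"),
               prob = c("0.5", "~")),
    list(a = trivial_payload(), b = trivial_payload(),
         lost = trivial_payload()))
  expect_true(any(grepl("lost", validate_tree(orphan))))

  one_branch <- decision_tree(
    "root",
    data.frame(id = c("root", "a"), kind = c("chance", "terminal"),
               label = NA),
    data.frame(parent = "root", child = "a", prob = "1"),
    list(a = trivial_payload()))
  expect_true(any(grepl("needs >= 2", validate_tree(one_branch))))
})

test_that("rollback splits the cohort by branch probabilities", {
  td <- rollback_evaluate(two_branch_tree("0.2", "~"), empty_params, 100)
  counts <- setNames(td$rows$count, td$rows$terminal)
  expect_equal(unname(counts["a"]), 20)
  expect_equal(unname(counts["b"]), 80)
})

test_that("unresolved parameter references are reported by name", {
  t <- two_branch_tree("p_not_there", "~")
  expect_error(rollback_evaluate(t, empty_params, 10), "p_not_there")
})

test_that("rollback and exhaustive enumeration agree to 1e-12 on random trees", {
  for (seed in 1:25) {
    tr <- random_tree(seed)
    expect_length(validate_tree(tr), 0L)
    td <- rollback_evaluate(tr, empty_params, 1)
    en <- enumerate_paths(tr, empty_params)
    m <- merge(td$rows, en, by = "terminal")
    expect_true(all(abs(m$path_prob - m$prob) < 1e-12), label = seed)
    # conservation
    expect_equal(sum(td$rows$path_prob), 1, tolerance = 1e-9)
  }
})

test_that("expected counts always sum to the cohort", {
  for (seed in c(3, 14, 27)) {
    cohort <- 10^stats::runif(1, 1, 6)
    td <- rollback_evaluate(random_tree(seed), empty_params, cohort)
    expect_equal(sum(td$rows$count), cohort, tolerance = 1e-6 * cohort)
  }
})

test_that("degenerate 0/1 probabilities give a single unit-probability path", {
  t <- decision_tree(
    "root",
    data.frame(id = c("root", "mid", "a", "b", "c"),
               kind = c("chance", "chance", "terminal", "terminal",
                        "terminal"), label = NA),
    data.frame(parent = c("root", "root", "mid", "mid"),
               child = c("mid", "c", "a", "b"),
               prob = c("1", "~", "0", "~")),
    list(a = trivial_payload(), b = trivial_payload(),
         c = trivial_payload()))
  en <- enumerate_paths(t, empty_params)
  expect_equal(sort(en$prob), c(0, 0, 1))
})

test_that("enumeration detects cycles", {
  cyc <- decision_tree(
    "root",
    data.frame(id = c("root", "mid", "t"),
               kind = c("chance", "chance", "terminal"), label = NA),
    data.frame(parent = c("root", "root", "mid", "mid"),
               child = c("mid", "t", "root", "t"),
               prob = c("0.5", "~", "0.5", "~")),
    list(t = trivial_payload()))
  expect_error(enumerate_paths(cyc, empty_params), "cycle")
})

test_that("raising a branch probability moves mass monotonically", {
  build <- function(p) {
    decision_tree(
      "root",
      data.frame(id = c("root", "mid", "t1", "t2", "s"),
                 kind = c("chance", "chance", "terminal", "terminal",
                          "terminal"), label = NA),
      data.frame(parent = c("root", "root", "mid", "mid"),
                 child = c("mid", "s", "t1", "t2"),
                 prob = c(format(p), "~", "0.4", "~")),
      list(t1 = trivial_payload(), t2 = trivial_payload(),
           s = trivial_payload()))
  }
  lo <- rollback_evaluate(build(0.3), empty_params, 1000)
  hi <- rollback_evaluate(build(0.6), empty_params, 1000)
  get <- function(td, id) td$rows$count[td$rows$terminal == id]
  expect_gt(get(hi, "t1"), get(lo, "t1"))
  expect_gt(get(hi, "t2"), get(lo, "t2"))
  expect_lt(get(hi, "s"), get(lo, "s"))
})

test_that("tree serialization round-trips", {
  tr <- build_ubt_tree("esm", ref_params)
  lines <- write_tree(tr)
  back <- read_tree(lines)
  expect_equal(back$root, tr$root)
  expect_equal(back$nodes, tr$nodes, ignore_attr = TRUE)
  expect_equal(back$branches, tr$branches, ignore_attr = TRUE)
  expect_setequal(names(back$payloads), names(tr$payloads))
  for (t in names(tr$payloads)) {
    expect_equal(back$payloads[[t]]$flags, tr$payloads[[t]]$flags)
    expect_equal(back$payloads[[t]]$cost_items,
                 tr$payloads[[t]]$cost_items, ignore_attr = TRUE)
  }
  td1 <- rollback_evaluate(tr, ref_params, 100)
  td2 <- rollback_evaluate(back, ref_params, 100)
  expect_equal(td1$rows, td2$rows)
})
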