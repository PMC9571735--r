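test_that("best_split_for_cue finds separating rules and handles degenerate cues", {
  perfect <- best_split_for_cue(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(perfect$direction, ">")
  expect_equal(perfect$threshold, 2)
  expect_equal(perfect$goal, 1)
  constant <- best_split_for_cue(rep(7, 6), c(1, 0, 1, 0, 1, 0))
  expect_equal(constant$goal, 0.5)
  expect_error(best_split_for_cue(1:4, c(1, 1, 1, 1)), "both classes")
  expect_error(best_split_for_cue(c(1, NA, 3), c(0, 1, 1)), "missing")
})

test_that("best_split_for_cue equals exhaustive threshold enumeration", {
  for (s in 1:30) {
    set.seed(s)
    n <- sample(10:40, 1)
    v <- sample(c(rnorm(n), sample(0:3, n, TRUE)), n)
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    w <- sample(c(0.3, 0.5, 0.7), 1)
    got <- best_split_for_cue(v, y, weight = w)
    expect_equal(got$goal, oracle_best_rule(v, y, w)$goal, tolerance = 1e-12)
  }
})

test_that("rank_cues orders by marginal goal with alphabetical tie-breaks", {
  set.seed(2)
  d <- tibble::tibble(
    noise_a = rnorm(40), noise_b = rnorm(40),
    signal = rep(c(0, 1), each = 20), pod = rep(c(0L, 1L), each = 20)
  )
  ranked <- rank_cues(d)
  expect_equal(ranked$cue[1], "signal")
  expect_equal(ranked$goal[1], 1)
  # identical columns tie and fall back to name order
  d2 <- tibble::tibble(zeta = d$signal, alpha = d$signal, pod = d$pod)
  expect_equal(rank_cues(d2)$cue, c("alpha", "zeta"))
  # against the independent per-cue brute force
  for (s in 1:5) {
    set.seed(s + 100)
    dd <- tibble::tibble(
      a = sample(0:2, 40, TRUE), b = rnorm(40), c = sample(0:1, 40, TRUE),
      d = rnorm(40), e = sample(1:4, 40, TRUE), pod = rbinom(40, 1, 0.4)
    )
    if (length(unique(dd$pod)) < 2) next
    ranked <- rank_cues(dd)
    oracle <- vapply(letters[1:5],
                     function(cc) oracle_best_rule(dd[[cc]], dd$pod)$goal, 0)
    expect_equal(ranked$goal, unname(sort(oracle, decreasing = TRUE)),
                 tolerance = 1e-12)
  }
})

test_that("classify walks the tree with early exits and frugal lookups", {
  tree <- fftree(tibble::tibble(
    cue = c("a", "b", "c"), direction = c(">", "<=", ">"),
    threshold = c(0, 0, 0), exit = c("positive", "negative", "both")
  ))
  # all 2^3 binary patterns against a hand-walked truth table
  grid <- expand.grid(a = 0:1, b = 0:1, c = 0:1)
  got <- classify(grid, tree)
  expect_identical(got$decision, oracle_classify(tree$nodes, grid))
  # a > 0 exits positive at depth 1; a = 0, b = 0 exits negative at depth 2
  expect_equal(got$cues_used[grid$a == 1], rep(1L, 4))
  expect_equal(got$decision[grid$a == 1], rep(1L, 4))
  expect_equal(got$cues_used[grid$a == 0 & grid$b == 0], rep(2L, 2))
  expect_equal(got$decision[grid$a == 0 & grid$b == 0], rep(0L, 2))
  expect_identical(got$cues_used, got$exit_depth)
  expect_error(classify(data.frame(a = NA_real_, b = 1, c = 1), tree), "impute")
  # depth-1 tree uses exactly one cue everywhere
  t1 <- fftree(tibble::tibble(cue = "a", direction = ">",
                              threshold = 0, exit = "both"))
  expect_equal(classify(grid, t1)$cues_used, rep(1L, 8))
})

test_that("evaluate reproduces hand-tallied confusion counts and identities", {
  cohort <- toy_cohort()
  tree <- fftree(tibble::tibble(
    cue = c("cci", "frailty"), direction = c(">", ">"),
    threshold = c(1, 0), exit = c("positive", "both")
  ))
  stats <- evaluate(cohort, tree)
  # hand tally: cci>1 rows (1,3,4,7,9) all positive -> 5 hits at depth 1;
  # remainder decided by frailty>0: rows 6,10 false alarms, rows 2,5,8 correct
  expect_equal(stats[c("hi", "mi", "fa", "cr")],
               tibble::tibble(hi = 5L, mi = 0L, fa = 2L, cr = 3L),
               ignore_attr = TRUE)
  expect_equal(stats$sens, 1)
  expect_equal(stats$spec, 0.6)
  expect_equal(stats$bacc, 0.8)
  expect_equal(stats$acc, 0.8)
  expect_equal(stats$mcu, 1.5)
  expect_equal(stats$pci, 1 - 1.5 / 3)   # age counts as an available cue
})

test_that("build_ifan returns the exhaustive-fan optimum", {
  # single perfectly predictive cue -> depth-1 tree with training bacc 1
  d <- tibble::tibble(x = c(1, 2, 3, 4, 5, 6), noise = c(0, 1, 0, 1, 0, 1),
                      pod = c(0L, 0L, 0L, 1L, 1L, 1L))
  tree <- build_ifan(d)
  expect_equal(nrow(tree$nodes), 1)
  expect_equal(tree$nodes$cue, "x")
  expect_equal(tree$goal_value, 1)
  # fan completeness: 2^(k-1) candidates per depth k
  d5 <- generate_cohort(60, seed = 12)
  t5 <- build_ifan(d5, max_levels = 5)
  expect_equal(unname(table(t5$fan$depth)), c(1L, 2L, 4L, 8L, 16L),
               ignore_attr = TRUE)
  # oracle equivalence on random small instances
  for (s in 1:25) {
    inst <- random_binary_instance(s)
    cues <- setdiff(names(inst), "pod")
    got <- build_ifan(inst, max_levels = 3, cues = cues)
    expect_equal(got$goal_value,
                 oracle_ifan_goal(inst[cues], inst$pod, cues, 3),
                 tolerance = 1e-12)
  }
})

test_that("adding a strictly better cue never lowers the ifan training goal", {
  for (s in 1:10) {
    inst <- random_binary_instance(s + 500)
    cues <- setdiff(names(inst), "pod")
    base <- build_ifan(inst, max_levels = 3, cues = cues)$goal_value
    inst$oracle_cue <- inst$pod   # a perfect cue dominates every other
    expect_gte(build_ifan(inst, max_levels = 3,
                          cues = c(cues, "oracle_cue"))$goal_value, base)
  }
})

test_that("build_dfan matches an independent greedy re-derivation and truncates", {
  # truncation: a single perfect cue leaves nothing to improve
  d <- tibble::tibble(x = c(1, 2, 3, 4, 5, 6), z = c(0, 1, 1, 0, 1, 0),
                      pod = c(0L, 0L, 0L, 1L, 1L, 1L))
  tree <- build_dfan(d)
  expect_equal(nrow(tree$nodes), 1)
  expect_equal(tree$goal_value, 1)
  # dual-route check against the plain-R recursive oracle
  for (s in 1:25) {
    inst <- random_binary_instance(s + 1000)
    cues <- setdiff(names(inst), "pod")
    got <- build_dfan(inst, max_levels = 3, cues = cues)
    expect_equal(got$goal_value,
                 oracle_dfan_greedy_goal(inst[cues], inst$pod, cues, 3),
                 tolerance = 1e-12)
    # and the returned tree itself reproduces its reported goal
    expect_equal(oracle_goal_of(got$nodes, inst, inst$pod), got$goal_value,
                 tolerance = 1e-12)
  }
})

test_that("conditional re-ranking lets dfan exploit cues that ifan cannot", {
  # XOR-like pair: marginally useless, perfectly informative conditionally
  set.seed(9)
  a <- rbinom(400, 1, 0.5)
  b <- rbinom(400, 1, 0.5)
  m <- rbinom(400, 1, 0.5)
  y <- ifelse(m == 1, 1L, as.integer(xor(a, b)))
  d <- tibble::tibble(a = a, b = b, m = m, pod = y)
  expect_gte(build_dfan(d, max_levels = 3)$goal_value,
             build_ifan(d, max_levels = 3)$goal_value)
})

test_that("trees serialize to YAML and JSON and round-trip byte-stably", {
  tree <- build_ifan(generate_cohort(80, seed = 3), max_levels = 3)
  tree$fan <- NULL
  tree$ranking <- NULL
  for (ext in c(".yaml", ".json")) {
    path <- withr::local_tempfile(fileext = ext)
    write_fftree(tree, path)
    back <- read_fftree(path)
    expect_equal(back$nodes, tree$nodes)
    expect_equal(back$goal_value, tree$goal_value)
    expect_equal(back$weight, tree$weight)
    path2 <- withr::local_tempfile(fileext = ext)
    write_fftree(back, path2)
    expect_identical(readLines(path2), readLines(path))
  }
})

test_that("fftree validates its structural invariants", {
  nodes <- tibble::tibble(cue = c("a", "b"), direction = c(">", ">"),
                          threshold = c(0, 0), exit = c("positive", "both"))
  expect_s3_class(fftree(nodes), "fftree")
  bad_final <- nodes
  bad_final$exit <- c("positive", "negative")
  expect_error(fftree(bad_final), "both")
  dup <- nodes
  dup$cue <- c("a", "a")
  expect_error(fftree(dup), "twice")
  expect_error(fftree(nodes[0, ]), "at least one")
})
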