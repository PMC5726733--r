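test_that("selection size and membership follow the fixed-endpoint contract", {
  set.seed(1)
  # 20% of 115 residues -> 23 members including both endpoints
  sel <- sample_selection(115, 0.2, 3, 40)
  expect_equal(sel$k, 23L)
  expect_length(sel$members, 23)
  expect_true(all(c(3, 40) %in% sel$members))
  expect_false(anyDuplicated(sel$members) > 0)
  # 20% of 1530 residues -> 306 (MutS-sized case)
  expect_equal(sample_selection(1530, 0.2, 1, 2)$k, 306L)
  # k = 2 degenerates to the endpoints exactly
  expect_equal(sort(sample_selection(10, 0.2, 4, 9)$members), c(4L, 9L))
  expect_error(sample_selection(10, 0.2, 2, 2), class = "pathnull_input_error")
  expect_error(sample_selection(5, 0.2, 1, 2, k = 9), class = "pathnull_input_error")
})

test_that("non-endpoint residues are selected uniformly", {
  n <- 20; k <- 6; draws <- 1e5
  counts <- integer(n)
  set.seed(99)
  for (i in seq_len(draws)) {
    m <- sample_selection(n, start = 1, end = 2, k = k)$members
    counts[m] <- counts[m] + 1L
  }
  expect_equal(counts[1], draws)
  expect_equal(counts[2], draws)
  p <- (k - 2) / (n - 2)
  se <- sqrt(p * (1 - p) / draws)
  freq <- counts[3:n] / draws
  expect_true(all(abs(freq - p) < 4 * se))
})

test_that("trial rates hit the trivial cutoffs exactly", {
  dm <- build_distance_matrix(make_globule(30, seed = 5))
  set.seed(2)
  expect_equal(run_trial(dm, 0, 0.2, 1, 30, n_selections = 50)$rate, 0)
  expect_equal(run_trial(dm, max(dm$d), 0.2, 1, 30, n_selections = 50)$rate, 100)
  r1 <- run_trial(dm, 6, 0.2, 1, 30, n_selections = 1)$rate
  expect_true(r1 %in% c(0, 100))
})

test_that("exact enumeration matches the closed-form toy probability", {
  # 12-bead chain at 6 A has only consecutive edges; a path from bead 1 to
  # bead 4 exists iff beads 2 and 3 are both among the k = 6 selected, so
  # p = choose(8, 2) / choose(10, 4) = 2/15
  dm <- build_distance_matrix(bead_chain(12))
  p <- exact_success_probability(dm, 6, start = 1, end = 4, k = 6)
  expect_equal(p, 2 / 15, tolerance = 1e-12)
  # independent second route: enumeration via igraph connectivity
  ig <- igraph::graph_from_adj_list(neighbor_map(dm, 6)$adj, mode = "all")
  hits <- utils::combn(setdiff(1:12, c(1, 4)), 4, FUN = function(free) {
    sub <- igraph::induced_subgraph(ig, c(1, 4, free))
    igraph::distances(sub, v = "1", to = "4")[1, 1] < Inf
  })
  expect_equal(p, mean(hits))
  # degenerate bounds and the enumeration refusal
  expect_equal(exact_success_probability(dm, 0, start = 1, end = 4, k = 6), 0)
  expect_equal(exact_success_probability(dm, max(dm$d), start = 1, end = 12,
                                         k = 12), 1)
  expect_error(exact_success_probability(dm, 6, start = 1, end = 4, k = 6,
                                         limit = 10),
               class = "pathnull_enumeration_refusal")
})

test_that("Monte Carlo rate converges on the exact probability", {
  dm <- build_distance_matrix(bead_chain(12))
  p <- 2 / 15
  set.seed(11)
  tr <- run_trial(dm, 6, start = 1, end = 4, n_selections = 1e4, k = 6)
  se <- sqrt(p * (1 - p) / 1e4)
  expect_lt(abs(tr$rate / 100 - p), 3 * se)
})

test_that("experiments are reproducible and trial spread is binomial-like", {
  dm <- build_distance_matrix(make_globule(40, seed = 8))
  e1 <- run_experiment(dm, 6, 0.25, 1, 40, n_selections = 400, n_trials = 6,
                       base_seed = 42)
  e2 <- run_experiment(dm, 6, 0.25, 1, 40, n_selections = 400, n_trials = 6,
                       base_seed = 42)
  expect_identical(e1$trial_rates, e2$trial_rates)
  expect_equal(e1$mean_rate, mean(e1$trial_rates))
  expect_equal(e1$stdev_rate, sd(e1$trial_rates))
  # spread within a factor of 3 of the binomial prediction
  p <- e1$mean_rate / 100
  if (p > 0 && p < 1) {
    pred <- 100 * sqrt(p * (1 - p) / 400)
    expect_lt(e1$stdev_rate, 3 * pred)
    expect_gt(e1$stdev_rate, pred / 3)
  }
  expect_identical(e1$converged, isTRUE(e1$stdev_rate <= e1$tolerance))
})

test_that("fast-fail on neighbourless endpoints equals running the search", {
  g <- neighbor_map(build_distance_matrix(make_globule(40, seed = 14)), 5.5)
  coords <- g$rep_xyz
  set.seed(55)
  for (i in 1:400) {
    sel <- sample_selection(40, 0.2, 1, 40)
    mask <- logical(40); mask[sel$members] <- TRUE
    sub <- induced_subgraph(g, sel)
    full_search <- find_path_astar(sub, start = 1, end = 40)$found
    fast <- pathnull:::selection_success(g$adj, coords, mask, 1L, 40L)
    expect_identical(fast, full_search)
  }
})

test_that("per-seed success is monotone in the cutoff (common random numbers)", {
  dm <- build_distance_matrix(make_globule(50, seed = 3))
  cuts <- c(0, 3, 4.5, 6, 8, 12, max(dm$d) + 1)
  sw <- cutoff_sweep(dm, cuts, 0.2, 1, 50, n_selections = 300, n_trials = 2,
                     base_seed = 10)
  # exact monotonicity per trial, not just in the mean
  for (s in seq_along(sw$stats[[1]]$trial_rates)) {
    tr <- vapply(sw$stats, function(x) x$trial_rates[s], 1)
    expect_true(all(diff(tr) >= 0))
  }
})

test_that("experiment results serialise to CSV and JSON", {
  dm <- build_distance_matrix(make_globule(30, seed = 5))
  ex <- run_experiment(dm, 6, 0.2, 1, 30, n_selections = 100, n_trials = 3,
                       base_seed = 1)
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_experiment(ex, csv, js)
  tab <- read.csv(csv)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$rate_percent, ex$trial_rates)
  obj <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(obj$mean_rate_percent, ex$mean_rate)
  expect_equal(obj$params$n_selections, 100)
})
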