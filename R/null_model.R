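#' The random-selection null model
#'
#' The significance benchmark: fix the allosteric-site and active-site
#' residues, select a fraction (default 20%, commensurate with the size of
#' sequence-covariance "sector" predictions) of all residues uniformly at
#' random with the two endpoints always included, and ask whether the
#' induced contact subgraph contains any contiguous path between them. The
#' success rate over many selections, replicated over trials, estimates the
#' probability that a random residue subset would exhibit a pathway purely
#' by chance.
#'
#' @name pathnull-nullmodel
#' @keywords internal
NULL

selection_size <- function(n_residues, fraction) {
  # round half away from zero, so 0.2 * 115 residues -> 23 including endpoints
  as.integer(floor(fraction * n_residues + 0.5))
}

#' Draw one random residue selection with fixed endpoints
#'
#' The selection has `k = round(fraction * n)` members including the two
#' fixed endpoints; the remaining `k - 2` members are drawn uniformly
#' without replacement from the other `n - 2` residues, using R's global
#' RNG stream (seed it for reproducibility).
#'
#' @param n_residues total residue count n.
#' @param fraction selection fraction (default null model: 0.2).
#' @param start,end node indices of the fixed endpoints.
#' @param k override the selection size directly (used by toy systems);
#'   when given, `fraction` is ignored.
#' @return object of class `pn_selection`: list(k, members, start, end).
#' @export
sample_selection <- function(n_residues, fraction = 0.2, start, end, k = NULL) {
  if (is.null(k)) k <- selection_size(n_residues, fraction)
  k <- as.integer(k)
  if (start == end || start < 1L || end < 1L || start > n_residues ||
      end > n_residues)
    pn_stop("pathnull_input_error", "endpoints must be distinct valid indices")
  if (k < 2L || k > n_residues)
    pn_stop("pathnull_input_error",
            "selection size k = %d outside [2, %d]", k, n_residues)
  pool <- seq_len(n_residues)[-c(start, end)]
  members <- c(as.integer(start), as.integer(end),
               if (k > 2L) sample(pool, k - 2L) else integer(0))
  structure(list(k = k, members = members, start = as.integer(start),
                 end = as.integer(end)),
            class = "pn_selection")
}

# success of one selection: fast-fail when an endpoint has no selected
# neighbour (equivalent to running the search, since the other endpoint is
# itself selected), else A* existence on the masked graph
selection_success <- function(adj, coords, mask, start, end) {
  nbs <- adj[[start]]
  nbe <- adj[[end]]
  if (!any(mask[nbs]) || !any(mask[nbe])) return(FALSE)
  astar_core(adj, coords, start, end, mask = mask)$found
}

#' Pathway success rate over one trial of random selections
#'
#' Draws `n_selections` independent selections and reports the fraction
#' whose induced subgraph connects the endpoints (decided by A* search,
#' with an equivalent fast failure when either endpoint has no selected
#' neighbour). Uses the current RNG state; seed before calling or use
#' [run_experiment()] for managed seeding.
#'
#' @param dm a `pn_distmat`.
#' @param cutoff_c contact cutoff in Angstrom.
#' @param fraction selection fraction.
#' @param start,end endpoint node indices.
#' @param n_selections selections per trial.
#' @param k optional explicit selection size (see [sample_selection()]).
#' @param graph optional precomputed `pn_graph` at `cutoff_c`.
#' @return object of class `pn_trial`: list(n_selections, n_success, rate)
#'   with rate in percent.
#' @export
run_trial <- function(dm, cutoff_c, fraction = 0.2, start, end,
                      n_selections, k = NULL, graph = NULL) {
  if (is.null(graph)) graph <- neighbor_map(dm, cutoff_c)
  coords <- dm$rep_xyz
  adj <- graph$adj
  n <- dm$n
  if (is.null(k)) k <- selection_size(n, fraction)
  mask <- logical(n)
  succ <- 0L
  for (s in seq_len(n_selections)) {
    sel <- sample_selection(n, fraction, start, end, k = k)
    mask[] <- FALSE
    mask[sel$members] <- TRUE
    if (selection_success(adj, coords, mask, sel$start, sel$end))
      succ <- succ + 1L
  }
  structure(list(n_selections = as.integer(n_selections),
                 n_success = succ,
                 rate = 100 * succ / n_selections),
            class = "pn_trial")
}

#' Replicated Monte Carlo experiment with convergence check
#'
#' Runs `n_trials` independent trials of `n_selections` selections each;
#' trial t is seeded with a deterministic sub-seed derived from
#' `base_seed`, so the whole experiment is a pure function of its
#' arguments. The experiment is flagged converged when the sample standard
#' deviation of the trial rates is at or below `tolerance` (percentage
#' points).
#'
#' @inheritParams run_trial
#' @param n_trials number of independent trials.
#' @param base_seed integer seed for the whole experiment.
#' @param tolerance convergence tolerance on the trial-rate standard
#'   deviation, in percentage points (default 1).
#' @return object of class `pn_experiment`: trial_rates, trial_seeds,
#'   mean_rate, stdev_rate, converged, tolerance, params.
#' @export
run_experiment <- function(dm, cutoff_c, fraction = 0.2, start, end,
                           n_selections, n_trials, base_seed,
                           tolerance = 1, k = NULL) {
  if (n_trials < 1L) pn_stop("pathnull_input_error", "n_trials must be >= 1")
  graph <- neighbor_map(dm, cutoff_c)
  seeds <- vapply(seq_len(n_trials), function(t) sub_seed(base_seed, t), 1L)
  rates <- numeric(n_trials)
  for (t in seq_len(n_trials)) {
    rates[t] <- with_seed(seeds[t],
      run_trial(dm, cutoff_c, fraction, start, end, n_selections,
                k = k, graph = graph))$rate
  }
  stdev <- if (n_trials > 1L) sd(rates) else NA_real_
  structure(list(
    trial_rates = rates, trial_seeds = seeds,
    mean_rate = mean(rates), stdev_rate = stdev,
    converged = isTRUE(stdev <= tolerance), tolerance = tolerance,
    params = list(cutoff = cutoff_c, fraction = fraction, start = start,
                  end = end, n_selections = n_selections,
                  n_trials = n_trials, base_seed = base_seed, k = k)
  ), class = "pn_experiment")
}

#' @export
print.pn_experiment <- function(x, ...) {
  cat(sprintf(
    "<pn_experiment> cutoff %.2f A: mean rate %.2f%% (stdev %.3f pp over %d trials of %d selections)%s\n",
    x$params$cutoff, x$mean_rate, x$stdev_rate, x$params$n_trials,
    x$params$n_selections, if (x$converged) ", converged" else ""))
  invisible(x)
}

#' Exact pathway success probability by exhaustive enumeration
#'
#' For small systems, enumerates every possible selection (all
#' `choose(n-2, k-2)` placements of the free members) and evaluates
#' connectivity with the heuristic-free BFS oracle. This is the quantity
#' the Monte Carlo rate estimates.
#'
#' @inheritParams run_trial
#' @param limit refuse when the number of combinations exceeds this
#'   (default 1e6): use [run_experiment()] instead.
#' @return exact probability in [0, 1].
#' @export
exact_success_probability <- function(dm, cutoff_c, fraction = 0.2,
                                      start, end, k = NULL, limit = 1e6) {
  n <- dm$n
  if (is.null(k)) k <- selection_size(n, fraction)
  if (k < 2L || k > n)
    pn_stop("pathnull_input_error", "selection size k = %d outside [2, %d]", k, n)
  ncomb <- choose(n - 2L, k - 2L)
  if (ncomb > limit)
    pn_stop("pathnull_enumeration_refusal",
            "choose(%d, %d) = %.3g combinations exceeds the enumeration limit %g; use run_experiment() (Monte Carlo) instead",
            n - 2L, k - 2L, ncomb, limit)
  graph <- neighbor_map(dm, cutoff_c)
  adj <- graph$adj
  pool <- seq_len(n)[-c(start, end)]
  mask <- logical(n)
  start <- as.integer(start); end <- as.integer(end)
  if (k == 2L) {
    mask[c(start, end)] <- TRUE
    return(as.numeric(bfs_core(adj, start, end, mask = mask)$found))
  }
  hits <- combn(pool, k - 2L, FUN = function(free) {
    mask[] <- FALSE
    mask[c(start, end, free)] <- TRUE
    bfs_core(adj, start, end, mask = mask)$found
  })
  mean(hits)
}

#' Write experiment results as CSV (one row per trial) and a JSON summary
#'
#' @param experiment a `pn_experiment`.
#' @param csv_path,json_path output files (either may be NULL to skip).
#' @export
write_experiment <- function(experiment, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) {
    df <- data.frame(
      trial = seq_along(experiment$trial_rates),
      seed = experiment$trial_seeds,
      n_selections = experiment$params$n_selections,
      n_success = round(experiment$trial_rates / 100 *
                          experiment$params$n_selections),
      rate_percent = experiment$trial_rates
    )
    write.csv(df, csv_path, row.names = FALSE, quote = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(list(
      mean_rate_percent = experiment$mean_rate,
      stdev_rate_pp = experiment$stdev_rate,
      converged = experiment$converged,
      tolerance_pp = experiment$tolerance,
      trial_rates_percent = experiment$trial_rates,
      params = experiment$params,
      software = paste0("pathnull ",
                        as.character(utils::packageVersion("pathnull")))
    ), json_path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(experiment)
}
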