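#' Cutoff sweeps and asymmetric five-parameter logistic fits
#'
#' Success rate as a function of the contact cutoff follows a sigmoid: no
#' edges exist near zero cutoff and the graph saturates to complete beyond
#' the structure diameter. The curve is summarised by the asymmetric 5PL
#' form
#'   y = d + (a - d) / (1 + (x/c)^b)^m
#' where a is the value at x = 0, d the asymptote as x grows, c a location
#' scale (Angstrom), b a slope exponent and m an asymmetry exponent.
#' Published fits of this family can carry enormous m exponents, which make
#' the parameter tuple non-identifiable even when the predicted curve is
#' sharp; comparisons should therefore be made on predicted values
#' ([eval_5pl()]), never on parameter tuples.
#'
#' @name pathnull-sweepfit
#' @keywords internal
NULL

#' Success rate versus contact cutoff, with common random numbers
#'
#' Runs the null model at each cutoff using the same selection stream per
#' trial at every cutoff (common random numbers). Because an edge present
#' at a smaller cutoff is present at every larger one, success at cutoff
#' c1 implies success at c2 >= c1 for the same selection, so the rate
#' sequence is non-decreasing exactly, not just statistically.
#'
#' @inheritParams run_experiment
#' @param cutoffs strictly increasing vector of cutoffs in Angstrom.
#' @return object of class `pn_sweep`: cutoffs, rates (mean %, one per
#'   cutoff), stats (list of `pn_experiment`).
#' @export
cutoff_sweep <- function(dm, cutoffs, fraction = 0.2, start, end,
                         n_selections, n_trials, base_seed,
                         tolerance = 1, k = NULL) {
  if (!length(cutoffs) || any(cutoffs < 0))
    pn_stop("pathnull_input_error", "cutoffs must be non-empty, non-negative")
  if (is.unsorted(cutoffs, strictly = TRUE))
    pn_stop("pathnull_input_error", "cutoffs must be strictly increasing")
  n <- dm$n
  if (is.null(k)) k <- selection_size(n, fraction)
  graphs <- lapply(cutoffs, function(cc) neighbor_map(dm, cc))
  coords <- dm$rep_xyz
  nc <- length(cutoffs)
  seeds <- vapply(seq_len(n_trials), function(t) sub_seed(base_seed, t), 1L)
  rates <- matrix(NA_real_, n_trials, nc)
  mask <- logical(n)
  for (t in seq_len(n_trials)) {
    sels <- with_seed(seeds[t], lapply(seq_len(n_selections), function(s)
      sample_selection(n, fraction, start, end, k = k)))
    succ <- integer(nc)
    for (s in seq_len(n_selections)) {
      sel <- sels[[s]]
      mask[] <- FALSE
      mask[sel$members] <- TRUE
      # evaluate from the largest cutoff down: once a selection fails at
      # some cutoff it fails at every smaller one (edge sets are nested)
      for (ci in rev(seq_len(nc))) {
        if (selection_success(graphs[[ci]]$adj, coords, mask,
                              sel$start, sel$end))
          succ[ci] <- succ[ci] + 1L
        else break
      }
    }
    rates[t, ] <- 100 * succ / n_selections
  }
  stats <- lapply(seq_len(nc), function(ci) {
    r <- rates[, ci]
    stdev <- if (n_trials > 1L) sd(r) else NA_real_
    structure(list(
      trial_rates = r, trial_seeds = seeds, mean_rate = mean(r),
      stdev_rate = stdev, converged = isTRUE(stdev <= tolerance),
      tolerance = tolerance,
      params = list(cutoff = cutoffs[ci], fraction = fraction, start = start,
                    end = end, n_selections = n_selections,
                    n_trials = n_trials, base_seed = base_seed, k = k)
    ), class = "pn_experiment")
  })
  structure(list(cutoffs = as.numeric(cutoffs),
                 rates = vapply(stats, function(s) s$mean_rate, 1),
                 stats = stats),
            class = "pn_sweep")
}

#' @export
print.pn_sweep <- function(x, ...) {
  cat("<pn_sweep>\n")
  print(data.frame(cutoff_A = x$cutoffs, mean_rate_percent = x$rates))
  invisible(x)
}

log1pexp <- function(t) {
  out <- t
  lo <- t <= 33.3
  out[lo] <- log1p(exp(t[lo]))
  out
}

pl5_curve <- function(x, a, b, c, d, m) {
  y <- rep(a, length(x))
  pos <- x > 0
  if (any(pos)) {
    t <- b * (log(x[pos]) - log(c))
    # (a-d)/(1+(x/c)^b)^m computed in log space: stable for extreme m
    y[pos] <- d + (a - d) * exp(-m * log1pexp(t))
  }
  y
}

#' Fit the asymmetric 5PL curve to sweep data
#'
#' Least-squares fit of y = d + (a-d)/(1+(x/c)^b)^m with b, c, m kept
#' positive through a log-parameterisation, solved with
#' Levenberg-Marquardt ([minpack.lm::nls.lm]). Initialisation: a = min(y),
#' d = max(y), c = the x at which y first crosses the half range, b = 5,
#' m = 1. Deterministic given the data.
#'
#' @param xs strictly increasing cutoff values (>= 6 points).
#' @param ys rates in percent.
#' @return object of class `pn_5pl`: a, b, c, d, m, rss, degenerate flag.
#'   Constant data yields a flagged degenerate fit with a = d = mean(ys).
#' @export
fit_5pl <- function(xs, ys) {
  if (length(xs) != length(ys))
    pn_stop("pathnull_input_error", "xs and ys differ in length")
  if (length(xs) < 6L)
    pn_stop("pathnull_input_error",
            "need at least 6 points to fit 5 parameters (got %d)", length(xs))
  if (is.unsorted(xs, strictly = TRUE))
    pn_stop("pathnull_input_error", "xs must be strictly increasing")
  rng <- range(ys)
  if (diff(rng) < 1e-8) {
    return(structure(list(a = mean(ys), b = 1, c = max(xs[1], 1), d = mean(ys),
                          m = 1, rss = sum((ys - mean(ys))^2),
                          degenerate = TRUE),
                     class = "pn_5pl"))
  }
  half <- mean(rng)
  cross <- xs[which(ys >= half)[1]]
  if (is.na(cross) || cross <= 0) cross <- stats::median(xs[xs > 0])
  par0 <- c(a = rng[1], d = rng[2], lb = log(5), lc = log(cross), lm = log(1))
  resid_fn <- function(p) {
    ys - pl5_curve(xs, p[["a"]], exp(p[["lb"]]), exp(p[["lc"]]), p[["d"]],
                   exp(p[["lm"]]))
  }
  # convergence is diagnosed from fit$info below; minpack's own warning
  # about capped iterations would be redundant noise
  fit <- tryCatch(
    suppressWarnings(minpack.lm::nls.lm(par = par0, fn = resid_fn,
                       control = minpack.lm::nls.lm.control(maxiter = 500,
                                                            maxfev = 100000))),
    error = function(e)
      pn_stop("pathnull_fit_error", "5PL fit failed: %s", conditionMessage(e))
  )
  # info 1-4: converged by minpack's own criteria. Iteration-capped fits
  # (step-like data push m to infinity while the curve is already exact)
  # are accepted when the residual is negligible on the data scale.
  polished <- fit$deviance <= 1e-8 * max(1, sum(ys^2))
  if (!fit$info %in% 1:4 && !polished)
    pn_stop("pathnull_fit_error",
            "5PL fit did not converge (info %d: %s; rss %.4g)",
            fit$info, fit$message, fit$deviance)
  p <- fit$par
  structure(list(a = p[["a"]], b = exp(p[["lb"]]), c = exp(p[["lc"]]),
                 d = p[["d"]], m = exp(p[["lm"]]),
                 rss = fit$deviance, degenerate = FALSE),
            class = "pn_5pl")
}

#' @export
print.pn_5pl <- function(x, ...) {
  cat(sprintf(
    "<pn_5pl> y = %.4g + (%.4g - %.4g)/(1 + (x/%.4g)^%.4g)^%.4g  (rss %.4g%s)\n",
    x$d, x$a, x$d, x$c, x$b, x$m, x$rss,
    if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}

#' Evaluate a 5PL curve
#'
#' Numerically stable closed-form evaluation: the (1+(x/c)^b)^m factor is
#' computed as exp(m * log1p((x/c)^b)) in log space, which survives the
#' extreme asymmetry exponents (m ~ 1e7) that published fits of this family
#' can carry. At x = 0 the value is exactly `a`.
#'
#' @param fit a `pn_5pl`, or a list/vector with elements a, b, c, d, m.
#' @param x cutoff value(s), >= 0.
#' @return rate(s) in percent.
#' @export
eval_5pl <- function(fit, x) {
  if (any(x < 0)) pn_stop("pathnull_input_error", "x must be >= 0")
  p <- as.list(fit)[c("a", "b", "c", "d", "m")]
  if (any(vapply(p, is.null, TRUE)))
    pn_stop("pathnull_input_error", "fit must carry parameters a, b, c, d, m")
  pl5_curve(x, p$a, p$b, p$c, p$d, p$m)
}

#' Write sweep results as CSV and the fit as JSON
#' @param sweep a `pn_sweep`.
#' @param fit optional `pn_5pl`.
#' @param csv_path,json_path output files (NULL to skip).
#' @param grid evaluation grid for the fitted curve echoed into the JSON.
#' @export
write_sweep <- function(sweep, fit = NULL, csv_path = NULL, json_path = NULL,
                        grid = sweep$cutoffs) {
  if (!is.null(csv_path)) {
    df <- data.frame(
      cutoff_A = sweep$cutoffs,
      mean_rate_percent = sweep$rates,
      stdev_rate_pp = vapply(sweep$stats, function(s) s$stdev_rate, 1),
      converged = vapply(sweep$stats, function(s) s$converged, TRUE)
    )
    write.csv(df, csv_path, row.names = FALSE, quote = FALSE)
  }
  if (!is.null(json_path) && !is.null(fit)) {
    jsonlite::write_json(list(
      parameters = fit[c("a", "b", "c", "d", "m")],
      rss = fit$rss, degenerate = fit$degenerate,
      grid = data.frame(x = grid, y = eval_5pl(fit, grid))
    ), json_path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(sweep)
}
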