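#' Simulate a single Moran Bd trajectory
#'
#' Runs one faithful trajectory of the Birth-death process: parent chosen
#' proportional to fitness, a uniform out-neighbor replaced by the
#' parent's offspring. Steps count every Bd event, including lazy ones.
#' Identical `(seed, inputs)` give an identical trajectory.
#'
#' @param g A strongly connected [moran_graph()].
#' @param r Mutant relative fitness (> 0).
#' @param s0 Integer vector of initially mutant nodes.
#' @param seed Integer seed (optional; if `NULL` the current RNG stream is
#'   used).
#' @param step_cap Censor the run after this many steps (default `Inf`).
#' @return A list with `outcome` (`"fixed"`, `"extinct"` or `"censored"`)
#'   and `steps`.
#' @export
run_once <- function(g, r, s0, seed = NULL, step_cap = Inf) {
  est <- estimate(g, r, s0, n_runs = 1L, seed = seed, step_cap = step_cap)
  out <- if (est$n_fixed == 1L) "fixed" else
    if (est$n_extinct == 1L) "extinct" else "censored"
  list(outcome = out, steps = est$runs$steps[1L])
}

#' Monte Carlo estimate of fixation probability and times
#'
#' Aggregates `n_runs` independent trajectories started from `s0`. The
#' fixation probability estimate `fp_hat` is the proportion of fixed runs
#' among the uncensored ones; censored runs (those hitting `step_cap`) are
#' excluded rather than counted as extinctions, since stopping simulations
#' mid-way over-represents trajectories that quickly go extinct and biases
#' the average. Set `censored_as_extinct = TRUE` for the conservative
#' lower-bound convention instead. 95% intervals use the normal
#' approximation for `fp_hat` and a t-interval for the mean times.
#'
#' @inheritParams run_once
#' @param s0 Integer vector of initially mutant nodes, or `"uniform"` to
#'   start each run from a single uniformly drawn node.
#' @param n_runs Number of independent trajectories (>= 1).
#' @param censored_as_extinct Count censored runs as extinctions in
#'   `fp_hat` (default FALSE: excluded with a warning).
#' @return An object of class `moran_sim`: counts (`n_fixed`,
#'   `n_extinct`, `n_censored`), estimates (`fp_hat`, `t_hat` mean steps
#'   among fixating runs, `at_hat` mean steps among uncensored runs),
#'   95% CI half-widths (`ci_fp`, `ci_t`), the `seed`, and the per-run
#'   table `runs`.
#' @examples
#' est <- estimate(graph_complete(3), r = 2, s0 = 1, n_runs = 2000, seed = 1)
#' est$fp_hat  # near the closed-form 4/7
#' @export
estimate <- function(g, r, s0, n_runs, seed = NULL, step_cap = Inf,
                     censored_as_extinct = FALSE) {
  stopifnot(inherits(g, "moran_graph"))
  .check_params(r)
  .assert_strongly_connected(g)
  n_runs <- as.integer(n_runs)
  if (is.na(n_runs) || n_runs < 1L) stop("n_runs must be >= 1")
  stopifnot(step_cap >= 1)
  uniform <- identical(s0, "uniform")
  start0 <- integer(0)
  if (!uniform) {
    s0 <- as.integer(s0)
    stopifnot(all(s0 >= 1L), all(s0 <= g$n))
    start0 <- unique(s0) - 1L
  }
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
  }
  res <- cpp_simulate_runs(g$n, .adj0(g), r, start0, uniform, n_runs,
                           if (is.finite(step_cap)) step_cap else
                             .Machine$double.xmax)
  outcome <- res[, 1L]; steps <- res[, 2L]
  n_fixed <- sum(outcome == 1); n_extinct <- sum(outcome == 0)
  n_censored <- sum(outcome == -1)
  if (n_censored > 0L && !censored_as_extinct) {
    warning(n_censored, " run(s) censored at the step cap and excluded ",
            "from fp_hat; the estimate may be biased if censoring is ",
            "outcome-dependent", call. = FALSE)
  }
  if (censored_as_extinct) {
    denom <- n_runs
    fp_hat <- n_fixed / denom
  } else {
    denom <- n_fixed + n_extinct
    fp_hat <- if (denom > 0L) n_fixed / denom else NA_real_
  }
  ci_fp <- if (!is.na(fp_hat) && denom > 1L) {
    stats::qnorm(0.975) * sqrt(fp_hat * (1 - fp_hat) / denom)
  } else NA_real_
  t_fix <- steps[outcome == 1]
  t_hat <- if (length(t_fix)) mean(t_fix) else NA_real_
  ci_t <- if (length(t_fix) > 1L) {
    stats::qt(0.975, length(t_fix) - 1L) * stats::sd(t_fix) /
      sqrt(length(t_fix))
  } else NA_real_
  unc <- steps[outcome != -1]
  at_hat <- if (length(unc)) mean(unc) else NA_real_
  ci_at <- if (length(unc) > 1L) {
    stats::qt(0.975, length(unc) - 1L) * stats::sd(unc) / sqrt(length(unc))
  } else NA_real_
  structure(
    list(n_runs = n_runs, n_fixed = n_fixed, n_extinct = n_extinct,
         n_censored = n_censored, fp_hat = fp_hat, t_hat = t_hat,
         at_hat = at_hat, ci_fp = ci_fp, ci_t = ci_t, ci_at = ci_at,
         seed = seed, step_cap = step_cap, r = r,
         censored_as_extinct = censored_as_extinct,
         runs = data.frame(outcome = outcome, steps = steps)),
    class = "moran_sim"
  )
}

#' @export
print.moran_sim <- function(x, ...) {
  cat(sprintf("Moran Bd simulation: %d runs (r = %g%s)\n", x$n_runs, x$r,
              if (!is.null(x$seed)) paste0(", seed ", x$seed) else ""))
  cat(sprintf("  fixed %d / extinct %d / censored %d\n",
              x$n_fixed, x$n_extinct, x$n_censored))
  cat(sprintf("  fp_hat = %.4f +/- %.4f (95%% CI)\n", x$fp_hat, x$ci_fp))
  if (!is.na(x$t_hat)) {
    cat(sprintf("  mean fixation time = %.2f +/- %.2f steps\n",
                x$t_hat, x$ci_t))
  }
  if (!is.na(x$at_hat)) {
    cat(sprintf("  mean absorption time = %.2f +/- %.2f steps\n",
                x$at_hat, x$ci_at))
  }
  invisible(x)
}

#' Sampling plan for guaranteed-accuracy fixation probability estimates
#'
#' Builds the randomized approximation scheme sampling plan: a number of
#' runs and a step cap such that the Monte Carlo estimate `fp_hat` is
#' within `additive_error` of the true fixation probability with
#' probability at least `confidence`. The run count comes from Hoeffding's
#' inequality, `n_runs = ceil(log(2/delta) / (2 eps^2))` with
#' `delta = 1 - confidence` split evenly between sampling error and
#' censoring; the step cap comes from Markov's inequality applied to the
#' best available polynomial bound `B` on the expected absorption/fixation
#' time ([best_bound()]): `step_cap = ceil(B * 2 n_runs / delta)`, so the
#' probability that any run is censored is at most `delta / 2`. On
#' balanced graphs a finite `B` exists for every `r >= 1`, which makes
#' this a fully polynomial scheme; `relative_error` mode divides the
#' additive target by the balanced-graph lower bound `fp >= 1/N^2`.
#'
#' @inheritParams run_once
#' @param additive_error Target additive error `eps` for `fp_hat`.
#' @param confidence Target success probability (default 0.95).
#' @param relative_error If `TRUE` (balanced graphs only), interpret
#'   `additive_error` as a relative error and tighten it by the `1/N^2`
#'   fixation-probability lower bound.
#' @return An object of class `sample_plan`: `n_runs`, `step_cap`,
#'   `additive_error`, `confidence`, and the backing `time_bound`.
#' @examples
#' fpras_sample_plan(graph_star(4), r = 1, additive_error = 0.05)
#' @export
fpras_sample_plan <- function(g, r, additive_error, confidence = 0.95,
                              relative_error = FALSE) {
  stopifnot(inherits(g, "moran_graph"))
  stopifnot(additive_error > 0, confidence > 0, confidence < 1)
  bb <- best_bound(g, r)
  if (!bb$applicable) {
    stop("no finite fixation-time bound applies to this graph at r = ", r,
         "; use solve_exact() or supply a manual step cap to estimate()")
  }
  eps <- additive_error
  if (relative_error) {
    if (!is_balanced(g)) {
      stop("relative_error mode requires a balanced graph ",
           "(uses the fp >= 1/N^2 lower bound)")
    }
    eps <- additive_error / g$n^2
  }
  delta <- 1 - confidence
  n_runs <- ceiling(log(2 / delta) / (2 * eps^2))
  B <- if (!is.na(bb$at_bound)) bb$at_bound else bb$t_bound
  step_cap <- ceiling(B * 2 * n_runs / delta)
  structure(
    list(n_runs = as.integer(n_runs), step_cap = step_cap,
         additive_error = additive_error, confidence = confidence,
         relative_error = relative_error, time_bound_used = bb),
    class = "sample_plan"
  )
}

#' @export
print.sample_plan <- function(x, ...) {
  cat(sprintf("Sampling plan: %d runs, step cap %.6g\n",
              x$n_runs, x$step_cap))
  cat(sprintf("  target: |fp_hat - fp| <= %g %s with prob >= %g\n",
              x$additive_error,
              if (x$relative_error) "(relative)" else "(additive)",
              x$confidence))
  cat(sprintf("  backing bound: %s (T <= %.6g)\n",
              x$time_bound_used$theorem, x$time_bound_used$t_bound))
  invisible(x)
}

#' Run a sampling plan
#'
#' @param plan A [fpras_sample_plan()] result.
#' @inheritParams estimate
#' @return A `moran_sim` estimate produced under the plan's run count and
#'   step cap.
#' @export
run_plan <- function(plan, g, r, s0, seed = NULL) {
  stopifnot(inherits(plan, "sample_plan"))
  estimate(g, r, s0, n_runs = plan$n_runs, seed = seed,
           step_cap = plan$step_cap)
}
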