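# Polynomial upper bounds on absorption/fixation time, reported in steps
# of the discrete Bd process (lazy steps included), matching the solver.

.time_bound <- function(theorem, applicable, preconditions,
                        at_bound = NA_real_, t_bound = NA_real_,
                        epsilon = NA_real_, n = NA_integer_, r = NA_real_) {
  structure(
    list(theorem = theorem, applicable = applicable,
         preconditions = preconditions, at_bound = at_bound,
         t_bound = t_bound, epsilon = epsilon, n = n, r = r),
    class = "time_bound"
  )
}

#' @export
print.time_bound <- function(x, ...) {
  cat(sprintf("%s (N = %d, r = %g): %s\n", x$theorem, x$n, x$r,
              if (x$applicable) "applicable" else "not applicable"))
  for (nm in names(x$preconditions)) {
    cat(sprintf("  %-28s %s\n", nm,
                if (x$preconditions[[nm]]) "yes" else "no"))
  }
  if (x$applicable) {
    if (!is.na(x$at_bound)) cat(sprintf("  AT bound: %.6g steps\n", x$at_bound))
    if (!is.na(x$t_bound)) cat(sprintf("  T  bound: %.6g steps\n", x$t_bound))
    if (!is.na(x$epsilon)) cat(sprintf("  slack epsilon: %.6g\n", x$epsilon))
  }
  invisible(x)
}

#' Fixation-time upper bounds
#'
#' @description
#' Four efficiently computable upper bounds on the absorption time
#' `AT_r(G)` and the largest conditional fixation time `T_r(G)`
#' (see [fixation_time_max()]). Inapplicability is a result, not an
#' error: each function returns a `time_bound` report with an
#' `applicable` flag and the list of checked preconditions.
#'
#' * `bound_theorem1()`: strong selection. If `r >= N^2` then
#'   `AT <= 2 N^3` and `T <= 3 N^3`, on any strongly connected graph.
#' * `bound_theorem2()`: Eulerian graphs with degrees between `delta` and
#'   `Delta`. If `r >= (Delta/delta) (1 + eps)` for some `eps > 0` then
#'   `AT <= ((2 + eps)/eps) N^3` and
#'   `T <= ((1 + eps)(2 + eps)/eps^2) N^3`. The slack is set to the
#'   largest admissible value `eps = r delta / Delta - 1` (the bound is
#'   monotone decreasing in `eps`); `epsilon` can be overridden to
#'   reproduce intermediate values.
#' * `bound_theorem3()`: any graph, any `r >= 1`:
#'   `T <= N^6 / fp_min^4` where `fp_min` is the minimum neutral
#'   single-mutant fixation probability ([neutral_fp_vector()]).
#' * `bound_theorem4()`: balanced graphs ([is_balanced()]), any `r >= 1`:
#'   `T <= N^14` (graph-size-only bound).
#'
#' @param g A strongly connected [moran_graph()].
#' @param r Mutant relative fitness.
#' @param epsilon Optional override of the Theorem 2 slack (must satisfy
#'   `r >= (Delta/delta)(1 + epsilon)`).
#' @param nfp Optional precomputed [neutral_fp_vector()] result for `g`.
#' @return A `time_bound` object.
#' @examples
#' bound_theorem1(graph_cycle(4), r = 16)   # at_bound 128, t_bound 192
#' bound_theorem3(graph_star(4), r = 1)     # 4^6 / (1/10)^4
#' @export
bound_theorem1 <- function(g, r) {
  stopifnot(inherits(g, "moran_graph"))
  n <- g$n
  pre <- list("strongly connected" = is_strongly_connected(g),
              "r >= N^2" = r >= n^2)
  ok <- all(unlist(pre))
  .time_bound("T1", ok, pre,
              at_bound = if (ok) 2 * n^3 else NA_real_,
              t_bound = if (ok) 3 * n^3 else NA_real_,
              n = n, r = r)
}

#' @rdname bound_theorem1
#' @export
bound_theorem2 <- function(g, r, epsilon = NULL) {
  stopifnot(inherits(g, "moran_graph"))
  n <- g$n
  eul <- is_eulerian(g)
  ratio <- if (eul) max(g$indeg) / min(g$indeg) else NA_real_
  eps_max <- if (eul) r / ratio - 1 else NA_real_
  eps <- if (is.null(epsilon)) eps_max else epsilon
  pre <- list("strongly connected" = is_strongly_connected(g),
              "Eulerian" = eul,
              "r > Delta/delta" = isTRUE(eps_max > 0),
              "epsilon admissible" = isTRUE(eps > 0 && eps <= eps_max + 1e-15))
  ok <- all(unlist(pre))
  .time_bound("T2", ok, pre,
              at_bound = if (ok) (2 + eps) / eps * n^3 else NA_real_,
              t_bound = if (ok) (1 + eps) * (2 + eps) / eps^2 * n^3
                        else NA_real_,
              epsilon = if (ok) eps else NA_real_, n = n, r = r)
}

#' @rdname bound_theorem1
#' @export
bound_theorem3 <- function(g, r, nfp = NULL) {
  stopifnot(inherits(g, "moran_graph"))
  n <- g$n
  pre <- list("strongly connected" = is_strongly_connected(g),
              "r >= 1" = r >= 1)
  ok <- all(unlist(pre))
  tb <- NA_real_
  if (ok) {
    if (is.null(nfp)) nfp <- neutral_fp_vector(g)
    tb <- n^6 / nfp$fp_min^4
    if (!is.finite(tb)) {
      warning("fp_min underflows double precision; reporting +Inf bound",
              call. = FALSE)
      tb <- Inf
    }
  }
  .time_bound("T3", ok, pre, t_bound = tb, n = n, r = r)
}

#' @rdname bound_theorem1
#' @export
bound_theorem4 <- function(g, r) {
  stopifnot(inherits(g, "moran_graph"))
  n <- g$n
  pre <- list("strongly connected" = is_strongly_connected(g),
              "balanced" = is_balanced(g),
              "r >= 1" = r >= 1)
  ok <- all(unlist(pre))
  .time_bound("T4", ok, pre,
              t_bound = if (ok) n^14 else NA_real_, n = n, r = r)
}

#' Best applicable fixation-time bound
#'
#' Evaluates all four theorems and returns the applicable report with the
#' smallest finite fixation-time bound. All four reports are attached as
#' the `"audit"` attribute. If none applies (possible only for `r < 1` on
#' unbalanced non-Eulerian graphs below the strong-selection threshold), a
#' report with `applicable = FALSE` is returned.
#'
#' @inheritParams bound_theorem1
#' @return A `time_bound` object with attribute `audit` (list of all four
#'   reports).
#' @export
best_bound <- function(g, r, nfp = NULL) {
  audit <- list(T1 = bound_theorem1(g, r),
                T2 = bound_theorem2(g, r),
                T3 = bound_theorem3(g, r, nfp = nfp),
                T4 = bound_theorem4(g, r))
  tb <- vapply(audit, function(b) {
    if (b$applicable && is.finite(b$t_bound)) b$t_bound else Inf
  }, numeric(1))
  if (all(is.infinite(tb))) {
    out <- .time_bound("none", FALSE,
                       list("any theorem applicable" = FALSE),
                       n = g$n, r = r)
  } else {
    out <- audit[[which.min(tb)]]
  }
  attr(out, "audit") <- audit
  out
}

#' Table of all four bounds
#'
#' @inheritParams bound_theorem1
#' @return A data.frame with one row per theorem: applicability and the
#'   AT/T bounds.
#' @export
bounds_table <- function(g, r) {
  audit <- attr(best_bound(g, r), "audit")
  data.frame(
    theorem = vapply(audit, `[[`, "", "theorem"),
    applicable = vapply(audit, `[[`, NA, "applicable"),
    at_bound = vapply(audit, `[[`, NA_real_, "at_bound"),
    t_bound = vapply(audit, `[[`, NA_real_, "t_bound"),
    epsilon = vapply(audit, `[[`, NA_real_, "epsilon"),
    row.names = NULL
  )
}
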