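# Isomorphism-free enumeration of strongly connected digraphs and the
# census / landscape / scaling experiments run on top of it.

#' Canonical isomorphism key of a digraph
#'
#' The adjacency matrix read row-major as an `n*n`-bit integer, minimized
#' over all `n!` node permutations. Two digraphs on the same node count
#' are isomorphic iff their keys coincide.
#'
#' @param g A [moran_graph()] with at most 7 nodes.
#' @return The key as a double (exact integer value).
#' @export
canonical_key <- function(g) {
  stopifnot(inherits(g, "moran_graph"))
  cpp_canonical_key(g$n, g$edges - 1L)
}

#' Reconstruct the representative graph of a canonical key
#'
#' @param key Canonical key as returned by [canonical_key()] or
#'   [enumerate_strongly_connected()].
#' @param n Node count the key was computed for.
#' @return A [moran_graph()] whose adjacency matrix encodes `key`.
#' @export
key_to_graph <- function(key, n) {
  stopifnot(n >= 2, n <= 5 || key < 2^53)
  key <- as.numeric(key)
  from <- integer(0); to <- integer(0)
  for (u in 0:(n - 1L)) {
    for (v in 0:(n - 1L)) {
      if (key %% 2 == 1) { from <- c(from, u); to <- c(to, v) }
      key <- key %/% 2
    }
  }
  moran_graph(n, cbind(from + 1L, to + 1L))
}

#' Enumerate strongly connected digraphs up to isomorphism
#'
#' Iterates all `2^(n(n-1))` labeled digraphs on `n` nodes, keeps the
#' strongly connected ones, and reduces by isomorphism via canonical
#' adjacency bit-strings minimized over all `n!` node permutations. The
#' counts are 1, 5, 83 and 5048 classes for `n = 2, 3, 4, 5`.
#'
#' @param n Node count, 2 to 5 (`n = 6` only with `expensive = TRUE`;
#'   expect hours).
#' @param expensive Unlock `n = 6`.
#' @return A list of class `canonical_set`: `n`, `keys` (sorted canonical
#'   keys) and `graphs` (list of representative [moran_graph()]s in key
#'   order).
#' @examples
#' length(enumerate_strongly_connected(3)$graphs)  # 5
#' @export
enumerate_strongly_connected <- function(n, expensive = FALSE) {
  n <- as.integer(n)
  if (n < 2L || n > 6L) {
    stop("enumeration supports 2 <= n <= 6 only (capacity limit)")
  }
  if (n == 6L && !expensive) {
    stop("n = 6 enumerates 2^30 labeled digraphs; pass expensive = TRUE ",
         "if you really want this (expect hours)")
  }
  keys <- cpp_enumerate_scc(n)
  graphs <- lapply(keys, key_to_graph, n = n)
  structure(list(n = n, keys = keys, graphs = graphs),
            class = "canonical_set")
}

#' @export
print.canonical_set <- function(x, ...) {
  cat(sprintf(
    "%d isomorphism classes of strongly connected digraphs on %d nodes\n",
    length(x$keys), x$n))
  invisible(x)
}

# Memoized enumeration (the n = 5 scan takes a few seconds; experiments
# reuse it).
.enum_cache <- new.env(parent = emptyenv())
.enumerate_cached <- function(n) {
  key <- as.character(n)
  if (is.null(.enum_cache[[key]])) {
    .enum_cache[[key]] <- enumerate_strongly_connected(n)
  }
  .enum_cache[[key]]
}

#' Census of non-monotone fixation times over a fitness grid
#'
#' For each enumerated graph and each single-mutant start node, computes
#' the exact conditional fixation time `ft({v})` along a grid of fitness
#' values and flags the pair as `increased` when some grid value exceeds
#' the neutral (`r = 1`) value beyond a relative tolerance. On the 83
#' four-node graphs with the default grid, 182 of the 332 (graph, start)
#' pairs increase.
#'
#' The flagging criterion (grid search over `[r_lo, r_hi]` in steps of
#' `grid_step`, relative tolerance `tol`) is recorded in the output
#' attributes; halving the grid step does not change the four-node count.
#'
#' @param graphs A `canonical_set` (all graphs on one node count), or an
#'   integer node count (enumerated on the fly).
#' @param r_lo,r_hi Grid endpoints (the grid always includes `r = 1`).
#' @param grid_step Grid spacing (default 0.005).
#' @param tol Relative tolerance for calling an increase (default 1e-9).
#' @return A data.frame with one row per (graph, start node): `key`,
#'   `start`, `ft_neutral`, `ft_max` (largest grid value), `r_at_max`,
#'   `increased`. Attributes: `n_increased`, `r_grid`, `tol`.
#' @export
monotonicity_census <- function(graphs, r_lo = 1, r_hi = 1.3,
                                grid_step = 0.005, tol = 1e-9) {
  if (is.numeric(graphs) && length(graphs) == 1L) {
    graphs <- .enumerate_cached(graphs)
  }
  stopifnot(inherits(graphs, "canonical_set"))
  stopifnot(r_lo <= 1, r_hi > r_lo)
  r_grid <- sort(unique(c(1, seq(r_lo, r_hi, by = grid_step), r_hi)))
  n <- graphs$n
  rows <- vector("list", length(graphs$graphs))
  single_idx <- bitwShiftL(1L, 0:(n - 1L)) + 1L
  for (gi in seq_along(graphs$graphs)) {
    g <- graphs$graphs[[gi]]
    ft <- matrix(NA_real_, length(r_grid), n)
    for (ri in seq_along(r_grid)) {
      ft[ri, ] <- solve_exact(g, r_grid[ri])$ft[single_idx]
    }
    neutral <- ft[r_grid == 1, ]
    imax <- apply(ft, 2L, which.max)
    rows[[gi]] <- data.frame(
      key = graphs$keys[gi], start = seq_len(n),
      ft_neutral = neutral,
      ft_max = ft[cbind(imax, seq_len(n))],
      r_at_max = r_grid[imax],
      increased = ft[cbind(imax, seq_len(n))] > neutral * (1 + tol)
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_increased") <- sum(out$increased)
  attr(out, "r_grid") <- r_grid
  attr(out, "tol") <- tol
  out
}

#' Fitness value maximizing the star-graph leaf fixation time
#'
#' On the undirected star on `n` nodes, the conditional fixation time of a
#' single leaf mutant first rises with `r` above its neutral value and
#' only then decreases (stochastic slowdown). This locates the argmax of
#' the exact `ft({leaf})` over `[r_lo, r_hi]` by a fine grid followed by
#' golden-section refinement; for the 4-node star the peak sits near
#' `r = 1.023`.
#'
#' @param n Star size (default 4).
#' @param r_lo,r_hi Search interval (default `[1, 1.3]`).
#' @param tol Refinement width at which the search stops (default 1e-5).
#' @return A list: `r_peak` (argmax), `r_peak_3dp` (rounded to 3
#'   decimals), `ft_peak`, `ft_neutral`.
#' @export
star_peak_location <- function(n = 4, r_lo = 1, r_hi = 1.3, tol = 1e-5) {
  g <- graph_star(n)
  leaf_state <- .config_mask(2L, n) + 1L  # node 2 is a leaf
  f <- function(r) solve_exact(g, r)$ft[leaf_state]
  grid <- seq(r_lo, r_hi, length.out = 61L)
  vals <- vapply(grid, f, numeric(1))
  i <- which.max(vals)
  lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
  # golden-section search on the bracket (ft is unimodal on the interval,
  # checked empirically by the coarse grid)
  phi <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  x1 <- b - phi * (b - a); x2 <- a + phi * (b - a)
  f1 <- f(x1); f2 <- f(x2)
  while (b - a > tol) {
    if (f1 < f2) {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + phi * (b - a); f2 <- f(x2)
    } else {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - phi * (b - a); f1 <- f(x1)
    }
  }
  r_peak <- (a + b) / 2
  list(r_peak = r_peak, r_peak_3dp = round(r_peak, 3L),
       ft_peak = f(r_peak), ft_neutral = f(1))
}

#' Landscape scan: fixation probability and time under uniform
#' initialization
#'
#' For every enumerated graph, computes the single-mutant fixation
#' probability and conditional fixation time under uniform initialization
#' (the initial mutant node drawn uniformly):
#' `fp_uniform = mean_v fp({v})` and, by default, the fixation-weighted
#' time `t_uniform = sum_v fp({v}) ft({v}) / sum_v fp({v})` (the expected
#' conditional fixation time of the uniform mixture given fixation).
#' `weighting = "unweighted"` gives the plain mean of `ft({v})` instead.
#' Each graph is classified as `undirected`, `oriented` or
#' `other-directed`.
#'
#' @param graphs A `canonical_set` or a node count.
#' @param r Mutant relative fitness.
#' @param weighting `"fixation"` (default) or `"unweighted"`.
#' @return A data.frame: `key`, `fp_uniform`, `t_uniform`, `class`.
#' @export
landscape_scan <- function(graphs, r, weighting = c("fixation",
                                                    "unweighted")) {
  weighting <- match.arg(weighting)
  if (is.numeric(graphs) && length(graphs) == 1L) {
    graphs <- .enumerate_cached(graphs)
  }
  stopifnot(inherits(graphs, "canonical_set"))
  n <- graphs$n
  single_idx <- bitwShiftL(1L, 0:(n - 1L)) + 1L
  m <- length(graphs$graphs)
  fp_u <- numeric(m); t_u <- numeric(m); cls <- character(m)
  for (gi in seq_len(m)) {
    g <- graphs$graphs[[gi]]
    sol <- solve_exact(g, r)
    fp <- sol$fp[single_idx]; ft <- sol$ft[single_idx]
    fp_u[gi] <- mean(fp)
    t_u[gi] <- if (weighting == "fixation") {
      sum(fp * ft) / sum(fp)
    } else {
      mean(ft)
    }
    cls[gi] <- if (is_undirected_graph(g)) "undirected" else
      if (is_oriented(g)) "oriented" else "other-directed"
  }
  data.frame(key = graphs$keys, fp_uniform = fp_u, t_uniform = t_u,
             class = cls)
}

#' Fixation-time scaling of the fan and vortex families
#'
#' Simulates single-mutant (uniform start) fixation times on fan or
#' vortex graphs across sizes and fitness values, and fits a log-log
#' slope of mean fixation time against node count `N`. Empirically the
#' fixation time on both families grows roughly like `N^2`.
#'
#' @param family `"fan"` or `"vortex"`.
#' @param k_values Family size parameters to scan.
#' @param r_values Fitness values to scan.
#' @param n_runs Trajectories per (k, r) cell.
#' @param seed Integer master seed.
#' @param step_cap Censoring cap per run (default `Inf`).
#' @return A data.frame with one row per (k, r): `N`, `t_mean` (mean
#'   steps among fixating runs), `ci_t`, `n_fixed`. Attribute `slopes`:
#'   named vector of fitted log-log slopes per `r`.
#' @export
family_scaling <- function(family = c("fan", "vortex"), k_values, r_values,
                           n_runs = 1000L, seed = 1L, step_cap = Inf) {
  family <- match.arg(family)
  gen <- if (family == "fan") graph_fan else graph_vortex
  rows <- list()
  i <- 0L
  for (r in r_values) {
    for (k in k_values) {
      i <- i + 1L
      g <- gen(k)
      est <- estimate(g, r, "uniform", n_runs = n_runs,
                      seed = seed + 1000L * i, step_cap = step_cap)
      rows[[i]] <- data.frame(family = family, k = k, N = g$n, r = r,
                              t_mean = est$t_hat, ci_t = est$ci_t,
                              n_fixed = est$n_fixed)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  slopes <- vapply(r_values, function(r) {
    d <- out[out$r == r & is.finite(out$t_mean), ]
    if (nrow(d) < 2L) return(NA_real_)
    unname(stats::coef(stats::lm(log(t_mean) ~ log(N), data = d))[2L])
  }, numeric(1))
  names(slopes) <- as.character(r_values)
  attr(out, "slopes") <- slopes
  out
}
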