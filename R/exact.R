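# Configurations are bitmasks over nodes: bit (v-1) set  <=>  node v is a
# mutant. State index = mask + 1. The empty and full masks are absorbing.

.config_mask <- function(nodes, n) {
  nodes <- as.integer(nodes)
  if (length(nodes) == 0L) return(0L)
  stopifnot(all(nodes >= 1L), all(nodes <= n), !anyDuplicated(nodes))
  sum(bitwShiftL(1L, nodes - 1L))
}

.mask_nodes <- function(mask, n) {
  which(bitwAnd(bitwShiftR(mask, 0:(n - 1L)), 1L) == 1L)
}

.mask_size <- function(masks, n) {
  sz <- integer(length(masks))
  for (b in 0:(n - 1L)) sz <- sz + bitwAnd(bitwShiftR(masks, b), 1L)
  sz
}

.check_params <- function(r) {
  stopifnot(is.numeric(r), length(r) == 1L, is.finite(r), r > 0)
  if (r < 1) {
    warning("fitness advantage r < 1 (disadvantageous mutant); ",
            "polynomial-time guarantees assume r >= 1", call. = FALSE)
  }
  r
}

.adj0 <- function(g) lapply(g$adj, function(v) v - 1L)

#' One-step transition distribution of the Moran Bd process
#'
#' In each step of the process a parent is chosen with probability
#' proportional to fitness (mutants have fitness `r`, residents 1, total
#' `r|S| + (N - |S|)`), one of the parent's out-neighbors is chosen
#' uniformly at random, and the neighbor is replaced by a copy of the
#' parent. Lazy self-transitions (like replacing like) are included, so the
#' returned probabilities sum to 1.
#'
#' @param g A strongly connected [moran_graph()].
#' @param r Mutant relative fitness (> 0).
#' @param s Integer vector of mutant-occupied nodes (the configuration).
#' @return A data.frame with columns `mask` (successor configuration as a
#'   bitmask), `nodes` (list column of node ids) and `prob`.
#' @examples
#' step_distribution(graph_cycle(2), r = 1, s = 1)
#' @export
step_distribution <- function(g, r, s) {
  stopifnot(inherits(g, "moran_graph"))
  .check_params(r)
  .assert_strongly_connected(g)
  n <- g$n
  mask <- .config_mask(s, n)
  full <- bitwShiftL(1L, n) - 1L
  if (mask == 0L || mask == full) {
    out <- data.frame(mask = mask, prob = 1)
  } else {
    m <- length(.mask_nodes(mask, n))
    F <- r * m + (n - m)
    acc <- new.env(parent = emptyenv())
    for (u in seq_len(n)) {
      mu <- bitwAnd(bitwShiftR(mask, u - 1L), 1L) == 1L
      p_u <- (if (mu) r else 1) / F / g$outdeg[u]
      for (v in g$adj[[u]]) {
        tgt <- if (mu) bitwOr(mask, bitwShiftL(1L, v - 1L)) else
          bitwAnd(mask, bitwNot(bitwShiftL(1L, v - 1L)))
        key <- as.character(tgt)
        acc[[key]] <- (if (is.null(acc[[key]])) 0 else acc[[key]]) + p_u
      }
    }
    masks <- as.integer(ls(acc))
    out <- data.frame(mask = masks,
                      prob = vapply(as.character(masks),
                                    function(k) acc[[k]], numeric(1)))
    out <- out[order(out$mask), ]
    rownames(out) <- NULL
  }
  out$nodes <- lapply(out$mask, .mask_nodes, n = n)
  out[, c("mask", "nodes", "prob")]
}

.assert_strongly_connected <- function(g) {
  if (!is_strongly_connected(g)) {
    stop("graph must be strongly connected", call. = FALSE)
  }
  invisible(g)
}

#' Exact solution of the Moran Bd absorbing chain
#'
#' Solves the absorbing Markov chain over all `2^N` mutant configurations
#' for: the fixation probability `fp(S)`; the unconditional expected
#' absorption time `at(S)`; the expected fixation time `ft(S)` conditioned
#' on fixation; and the expected extinction time `ext(S)` conditioned on
#' extinction. Times are expected numbers of Bd steps, counting lazy
#' self-transitions (every Birth-death event is one step); set
#' `count_lazy = FALSE` to count only configuration-changing (active)
#' steps instead.
#'
#' The linear systems solved (over transient states, with absorbing
#' boundary) are `fp = P fp`, `at = 1 + P at`, and the conditioned-chain
#' systems for `h = fp * ft` (`h = fp + P h`) and `e = (1 - fp) * ext`
#' (`e = (1 - fp) + P e`). Conditional times are reported as `NA` where
#' the conditioning event has probability 0 (e.g. `ft` at the empty
#' configuration).
#'
#' @param g A strongly connected [moran_graph()].
#' @param r Mutant relative fitness (> 0; values below 1 are accepted with
#'   a warning).
#' @param max_nodes Capacity guard: refuse graphs with more than this many
#'   nodes (default 14, i.e. 16384 configurations).
#' @param count_lazy Count lazy self-transitions as steps (default TRUE).
#' @return An object of class `moran_exact`: list with vectors `fp`, `at`,
#'   `ft`, `ext` indexed by `mask + 1`, the scalar `t_max`
#'   (`max_S ft(S)` over non-empty `S`), plus `n`, `r` and the graph.
#' @examples
#' sol <- solve_exact(graph_complete(3), r = 2)
#' fixation_prob(sol, 1)  # single mutant: (1 - 1/2) / (1 - 1/2^3) = 4/7
#' @export
solve_exact <- function(g, r, max_nodes = 14L, count_lazy = TRUE) {
  stopifnot(inherits(g, "moran_graph"))
  .check_params(r)
  .assert_strongly_connected(g)
  n <- g$n
  if (n > max_nodes) {
    stop("graph has ", n, " nodes; the exact solver enumerates 2^N ",
         "configurations and is limited to N <= ", max_nodes,
         ". Use estimate() (Monte Carlo) for larger graphs.", call. = FALSE)
  }
  ns <- 2^n
  trip <- cpp_transition_triplets(n, .adj0(g), r)
  if (!count_lazy) trip <- .drop_lazy(trip, ns)
  transient <- 2:(ns - 1L)  # state indices (mask+1) excluding absorbing
  if (n == 1L) stop("graph must have at least 2 nodes")
  # P restricted to transient rows
  keep <- trip$i %in% transient
  i <- trip$i[keep]; j <- trip$j[keep]; x <- trip$x[keep]
  ti <- match(i, transient)
  full_idx <- ns
  # b_fp: probability of jumping straight to the full configuration
  b_fp <- numeric(length(transient))
  to_full <- j == full_idx
  if (any(to_full)) {
    agg <- tapply(x[to_full], ti[to_full], sum)
    b_fp[as.integer(names(agg))] <- agg
  }
  inq <- j %in% transient
  tj <- match(j[inq], transient)
  nt <- length(transient)
  use_dense <- n <= 10L
  if (use_dense) {
    A <- diag(nt)
    A[cbind(ti[inq], tj)] <- A[cbind(ti[inq], tj)] - x[inq]
    sol1 <- solve(A, cbind(b_fp, rep(1, nt)))
    fp_t <- sol1[, 1L]; at_t <- sol1[, 2L]
    sol2 <- solve(A, cbind(fp_t, 1 - fp_t))
  } else {
    Q <- Matrix::sparseMatrix(i = ti[inq], j = tj, x = x[inq],
                              dims = c(nt, nt))
    A <- Matrix::Diagonal(nt) - Q
    sol1 <- as.matrix(Matrix::solve(A, cbind(b_fp, rep(1, nt))))
    fp_t <- sol1[, 1L]; at_t <- sol1[, 2L]
    sol2 <- as.matrix(Matrix::solve(A, cbind(fp_t, 1 - fp_t)))
  }
  h_t <- sol2[, 1L]; e_t <- sol2[, 2L]
  fp <- numeric(ns); fp[full_idx] <- 1; fp[transient] <- fp_t
  at <- numeric(ns); at[transient] <- at_t
  ft <- rep(NA_real_, ns); ft[full_idx] <- 0
  ext <- rep(NA_real_, ns); ext[1L] <- 0
  pos <- fp_t > 0
  ft[transient[pos]] <- h_t[pos] / fp_t[pos]
  neg <- fp_t < 1
  ext[transient[neg]] <- e_t[neg] / (1 - fp_t[neg])
  t_max <- max(ft[-1L], na.rm = TRUE)
  structure(
    list(n = n, r = r, fp = fp, at = at, ft = ft, ext = ext,
         t_max = t_max, count_lazy = count_lazy, graph = g),
    class = "moran_exact"
  )
}

# Convert transition triplets to the embedded jump chain (no lazy
# self-transitions; rows renormalized). Absorbing rows keep their unit
# self-loop.
.drop_lazy <- function(trip, ns) {
  i <- trip$i; j <- trip$j; x <- trip$x
  lazy <- i == j & !(i %in% c(1L, ns))
  lazy_p <- numeric(ns)
  lazy_p[i[lazy]] <- x[lazy]
  keep <- !lazy
  i <- i[keep]; j <- j[keep]; x <- x[keep]
  x <- x / (1 - lazy_p[i])
  list(i = i, j = j, x = x)
}

#' @export
print.moran_exact <- function(x, ...) {
  cat(sprintf("Exact Moran Bd solution: N = %d, r = %g (%s steps)\n",
              x$n, x$r, if (x$count_lazy) "all" else "active"))
  cat(sprintf("  T_r(G) = max_S ft(S) = %.6g\n", x$t_max))
  print(summary(x))
  invisible(x)
}

#' @export
summary.moran_exact <- function(object, ...) {
  n <- object$n
  idx <- bitwShiftL(1L, 0:(n - 1L)) + 1L  # single-mutant states
  data.frame(start = seq_len(n),
             fp = object$fp[idx],
             at = object$at[idx],
             ft = object$ft[idx],
             ext = object$ext[idx])
}

#' Accessors for exact solutions
#'
#' Extract the fixation probability, absorption time, conditional fixation
#' time or conditional extinction time of a configuration from a
#' [solve_exact()] result.
#'
#' @param sol A `moran_exact` object.
#' @param s Integer vector of mutant-occupied nodes.
#' @return A single number (possibly `NA` for undefined conditional
#'   times).
#' @export
fixation_prob <- function(sol, s) {
  stopifnot(inherits(sol, "moran_exact"))
  sol$fp[.config_mask(s, sol$n) + 1L]
}

#' @rdname fixation_prob
#' @export
absorption_time <- function(sol, s) {
  stopifnot(inherits(sol, "moran_exact"))
  sol$at[.config_mask(s, sol$n) + 1L]
}

#' @rdname fixation_prob
#' @export
fixation_time <- function(sol, s) {
  stopifnot(inherits(sol, "moran_exact"))
  sol$ft[.config_mask(s, sol$n) + 1L]
}

#' @rdname fixation_prob
#' @export
extinction_time <- function(sol, s) {
  stopifnot(inherits(sol, "moran_exact"))
  sol$ext[.config_mask(s, sol$n) + 1L]
}

#' Largest conditional fixation time over all initial configurations
#'
#' `T_r(G) = max over non-empty S of ft(S)`; the full configuration
#' contributes 0. This is the quantity bounded by the polynomial
#' fixation-time theorems ([bound_theorem1()] and friends).
#'
#' @inheritParams solve_exact
#' @return A single number.
#' @export
fixation_time_max <- function(g, r, max_nodes = 14L) {
  solve_exact(g, r, max_nodes = max_nodes)$t_max
}

#' Neutral single-mutant fixation probabilities
#'
#' At `r = 1` the fixation probability is additive over the initial mutant
#' set, which reduces the `2^N`-state system to `N` equations: the vector
#' `x` with `x_v = fp_{r=1}(G, {v})` is the unique solution of
#' `(1/outdeg(u)) * sum_{u -> v} x_v = x_u * sum_{w -> u} 1/outdeg(w)`
#' for every node `u`, normalized to `sum_v x_v = 1` (the all-mutant set
#' fixes with probability 1). The minimum entry `fp_min` drives the
#' general fixation-time bound of [bound_theorem3()]; `fp_min <= 1/N`
#' always.
#'
#' @param g A strongly connected [moran_graph()].
#' @return A list with `fp` (length-`N` vector of neutral single-mutant
#'   fixation probabilities), `fp_min`, and `argmin` (a node attaining
#'   it).
#' @examples
#' neutral_fp_vector(graph_star(4))$fp  # center 1/10, leaves 3/10
#' @export
neutral_fp_vector <- function(g) {
  stopifnot(inherits(g, "moran_graph"))
  .assert_strongly_connected(g)
  n <- g$n
  M <- matrix(0, n, n)
  inv_outdeg_sum <- numeric(n)  # sum over predecessors w -> u of 1/outdeg(w)
  for (e in seq_len(nrow(g$edges))) {
    w <- g$edges[e, 1L]; u <- g$edges[e, 2L]
    inv_outdeg_sum[u] <- inv_outdeg_sum[u] + 1 / g$outdeg[w]
  }
  for (u in seq_len(n)) {
    M[u, g$adj[[u]]] <- M[u, g$adj[[u]]] + 1 / g$outdeg[u]
    M[u, u] <- M[u, u] - inv_outdeg_sum[u]
  }
  A <- rbind(M, rep(1, n))
  b <- c(numeric(n), 1)
  x <- qr.solve(A, b)
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop("neutral fixation system is singular or non-positive; ",
         "is the graph strongly connected?")
  }
  list(fp = x, fp_min = min(x), argmin = which.min(x))
}

#' Closed-form neutral fixation probability on balanced graphs
#'
#' On a balanced strongly connected graph the neutral single-mutant
#' fixation probability has the explicit form
#' `fp_{r=1}(G, {u}) = (1/indeg(u)) / sum_v 1/indeg(v)`,
#' which is always at least `1/N^2`.
#'
#' @param g A balanced, strongly connected [moran_graph()].
#' @param u Node id (1-based). If missing, the whole vector is returned.
#' @return Fixation probability of a single neutral mutant at `u` (or the
#'   length-`N` vector).
#' @examples
#' balanced_fp_formula(graph_star(4))  # c(1, 3, 3, 3)/10
#' @export
balanced_fp_formula <- function(g, u = NULL) {
  stopifnot(inherits(g, "moran_graph"))
  if (!is_balanced(g)) {
    stop("balanced_fp_formula requires a balanced graph ",
         "(see is_balanced()); for general graphs use neutral_fp_vector()")
  }
  x <- (1 / g$indeg) / sum(1 / g$indeg)
  if (is.null(u)) x else x[u]
}
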