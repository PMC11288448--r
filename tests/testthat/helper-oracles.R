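# Shared oracles and fixture helpers for the test suite.

# Closed-form single-mutant fixation probability of the well-mixed
# (complete-graph) Moran process: the 1-D biased birth-death chain.
moran_fp_complete <- function(n, r, i = 1) {
  if (r == 1) return(i / n)
  (1 - 1 / r^i) / (1 - 1 / r^n)
}

# Independent dense-R construction of the full transition matrix from the
# public step_distribution(), used to cross-check the compiled builder.
transition_matrix_R <- function(g, r) {
  n <- g$n
  ns <- 2^n
  P <- matrix(0, ns, ns)
  for (mask in 0:(ns - 1)) {
    s <- which(bitwAnd(bitwShiftR(mask, 0:(n - 1)), 1L) == 1L)
    d <- step_distribution(g, r, s)
    P[mask + 1, d$mask + 1] <- d$prob
  }
  P
}

# Exact absorption quantities from a dense transition matrix by direct
# linear algebra (independent of solve_exact's internals).
absorbing_solve_R <- function(P) {
  ns <- nrow(P)
  tr <- 2:(ns - 1)
  A <- diag(length(tr)) - P[tr, tr]
  fp <- solve(A, P[tr, ns])
  at <- solve(A, rep(1, length(tr)))
  h <- solve(A, fp)
  list(fp = fp, at = at, ft = h / fp)
}

# Deterministic pool of small strongly connected fixtures spanning
# structures: named families plus seeded random digraphs.
fixture_pool <- function(n_random = 20, n_max = 6) {
  fams <- list(graph_cycle(3), graph_complete(3), graph_star(4),
               graph_lollipop(), graph_cycle(5), graph_fan(2),
               graph_vortex(2), graph_complete(4))
  rand <- lapply(seq_len(n_random), function(s) {
    random_graph_fixture("strongly_connected", n = 3L + (s %% (n_max - 2L)),
                         density = 0.35, seed = s)
  })
  c(fams, rand)
}

# Enumerations are reused across test files through the package cache;
# this helper keeps test code terse.
enum4 <- function() enumerate_strongly_connected(4)
enum5 <- function() moranbd:::.enumerate_cached(5)
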