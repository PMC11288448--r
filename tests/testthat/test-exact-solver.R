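test_that("step distribution matches hand-computed cases", {
  # 2-cycle, r = 1, one mutant: each node selected w.p. 1/2, its sole
  # out-neighbor replaced
  d <- step_distribution(graph_cycle(2), 1, 1)
  expect_equal(d$mask, c(0L, 3L))
  expect_equal(d$prob, c(0.5, 0.5))

  # complete K3, r = 1, one mutant: extinct 1/3, lazy 1/3, grow 1/3
  d3 <- step_distribution(graph_complete(3), 1, 1)
  expect_equal(sum(d3$prob), 1)
  expect_equal(d3$prob[d3$mask == 0L], 1 / 3)
  expect_equal(d3$prob[d3$mask == 1L], 1 / 3)
  expect_equal(sum(d3$prob[d3$mask %in% c(3L, 5L)]), 1 / 3)

  # absorbing full configuration
  dv <- step_distribution(graph_star(4), 2, 1:4)
  expect_equal(dv$prob, 1)

  # rows of the compiled transition builder agree with the public
  # step_distribution on a directed fixture
  g <- random_graph_fixture("strongly_connected", 4, 0.4, seed = 9)
  P <- transition_matrix_R(g, 1.7)
  expect_equal(unname(rowSums(P)), rep(1, 16))
  sol_ref <- absorbing_solve_R(P)
  sol <- solve_exact(g, 1.7)
  expect_equal(sol$fp[2:15], unname(sol_ref$fp), tolerance = 1e-12)
  expect_equal(sol$at[2:15], unname(sol_ref$at), tolerance = 1e-12)
  expect_equal(sol$ft[2:15], unname(sol_ref$ft), tolerance = 1e-12)
})

test_that("exact solver reproduces closed forms", {
  # 2-cycle: absorption in exactly one step, fp = 1/2 at r = 1
  s <- solve_exact(graph_cycle(2), 1)
  expect_equal(fixation_prob(s, 1), 0.5)
  expect_equal(absorption_time(s, 1), 1)
  expect_equal(fixation_time(s, 1), 1)
  expect_equal(extinction_time(s, 1), 1)
  expect_equal(s$t_max, 1)
  s9 <- solve_exact(graph_cycle(2), 9)
  expect_equal(s9$t_max, 1)

  # complete K3 neutral: fp = 1/3, at = 3 (lumped 1-D walk)
  s3 <- solve_exact(graph_complete(3), 1)
  expect_equal(fixation_prob(s3, 1), 1 / 3, tolerance = 1e-12)
  expect_equal(absorption_time(s3, 1), 3, tolerance = 1e-12)

  # complete-graph fp matches the 1-D birth-death closed form
  for (n in 3:5) {
    for (r in c(1, 1.3, 2, 10)) {
      s <- solve_exact(graph_complete(n), r)
      expect_equal(fixation_prob(s, 1), moran_fp_complete(n, r),
                   tolerance = 1e-10)
    }
  }
})

test_that("absorption identity at = fp*ft + (1-fp)*ext holds on fixtures", {
  pool <- fixture_pool(n_random = 92)  # 100 graphs including families
  expect_length(pool, 100L)
  for (g in pool) {
    for (r in c(1, 1.1, 2, 10)) {
      s <- suppressWarnings(solve_exact(g, r))
      ns <- 2^s$n
      prop <- 2:(ns - 1)  # proper non-absorbing configurations
      lhs <- s$at[prop]
      rhs <- s$fp[prop] * s$ft[prop] + (1 - s$fp[prop]) * s$ext[prop]
      expect_equal(lhs, rhs, tolerance = 1e-10)
      expect_true(all(s$fp >= -1e-12 & s$fp <= 1 + 1e-12))
      expect_true(all(s$at >= 0))
    }
  }
})

test_that("neutral fixation probability is additive over configurations", {
  for (g in fixture_pool(n_random = 30)) {
    s <- solve_exact(g, 1)
    n <- g$n
    singles <- s$fp[bitwShiftL(1L, 0:(n - 1)) + 1L]
    for (mask in 0:(2^n - 1)) {
      nodes <- which(bitwAnd(bitwShiftR(mask, 0:(n - 1)), 1L) == 1L)
      expect_equal(s$fp[mask + 1L], sum(singles[nodes]), tolerance = 1e-10)
    }
  }
})

test_that("neutral N-equation system agrees with the 2^N-state solve", {
  for (g in fixture_pool(n_random = 30)) {
    nv <- neutral_fp_vector(g)
    s <- solve_exact(g, 1)
    singles <- s$fp[bitwShiftL(1L, 0:(g$n - 1)) + 1L]
    expect_equal(nv$fp, singles, tolerance = 1e-10)
    expect_equal(sum(nv$fp), 1, tolerance = 1e-10)
    expect_lte(nv$fp_min, 1 / g$n + 1e-12)
  }
})

test_that("balanced closed form: star values and agreement on balanced fixtures", {
  # undirected star on 4 nodes: indegrees (3,1,1,1) give center 1/10,
  # leaves 3/10
  s4 <- graph_star(4)
  expect_equal(balanced_fp_formula(s4), c(0.1, 0.3, 0.3, 0.3))
  expect_gte(balanced_fp_formula(s4, 1), 1 / 16)  # >= 1/N^2
  expect_equal(balanced_fp_formula(graph_cycle(5)), rep(0.2, 5))
  expect_error(balanced_fp_formula(graph_fan(2)), "balanced")

  for (seed in 1:20) {
    g <- random_graph_fixture("undirected", 5, 0.5, seed)
    expect_equal(balanced_fp_formula(g), neutral_fp_vector(g)$fp,
                 tolerance = 1e-10)
    expect_true(all(balanced_fp_formula(g) >= 1 / g$n^2))
  }
  expect_equal(balanced_fp_formula(graph_vortex(3)),
               neutral_fp_vector(graph_vortex(3))$fp, tolerance = 1e-10)
})

test_that("regular graphs are isothermal: complete-graph fixation probability", {
  for (seed in 1:10) {
    g <- random_graph_fixture("regular", 5, 0.5, seed)
    for (r in c(1, 1.4, 2)) {
      s <- solve_exact(g, r)
      expect_equal(fixation_prob(s, 1), moran_fp_complete(g$n, r),
                   tolerance = 1e-10)
    }
  }
})

test_that("fixation_time_max maximizes over all non-empty configurations", {
  s <- solve_exact(graph_star(4), 1)
  expect_equal(s$t_max, max(s$ft[-1], na.rm = TRUE))
  expect_equal(fixation_time_max(graph_star(4), 1), s$t_max)
  # the full configuration contributes 0, not the max
  expect_gt(s$t_max, 0)
})

test_that("conditional times are NA exactly where undefined", {
  s <- solve_exact(graph_lollipop(), 1.2)
  expect_true(is.na(s$ft[1]))        # ft undefined from extinction state
  expect_equal(s$ft[16], 0)          # already fixed
  expect_true(is.na(s$ext[16]))      # ext undefined from fixation state
  expect_equal(s$ext[1], 0)
  expect_false(anyNA(s$ft[-1]))
  expect_false(anyNA(s$ext[-16]))
})

test_that("disadvantageous fitness warns but solves; guards reject bad input", {
  expect_warning(s <- solve_exact(graph_cycle(3), 0.5), "r < 1")
  expect_lt(fixation_prob(s, 1), 1 / 3)
  expect_error(solve_exact(moran_graph(3, rbind(c(1, 2), c(2, 1))), 1),
               "strongly connected")
  expect_error(solve_exact(graph_cycle(16), 1, max_nodes = 14), "N <= 14")
})

test_that("active-step counting equals the lazy count scaled on the 2-cycle", {
  # the 2-cycle has no lazy transitions from proper states, so both
  # conventions agree there
  sa <- solve_exact(graph_cycle(2), 2, count_lazy = FALSE)
  sl <- solve_exact(graph_cycle(2), 2, count_lazy = TRUE)
  expect_equal(sa$at, sl$at)
  # on K3 the active count is strictly smaller
  ka <- solve_exact(graph_complete(3), 1, count_lazy = FALSE)
  kl <- solve_exact(graph_complete(3), 1, count_lazy = TRUE)
  expect_lt(absorption_time(ka, 1), absorption_time(kl, 1))
})
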