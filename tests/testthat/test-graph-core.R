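test_that("edge-list round trip, headers, and malformed input", {
  g <- moran_graph(2, rbind(c(1, 2), c(2, 1)))
  expect_equal(g$n, 2L)
  expect_true(is_strongly_connected(g))

  f <- tempfile(fileext = ".edges")
  writeLines(c("0 1", "1 0"), f)
  expect_equal(read_edge_list(f)$n, 2L)

  writeLines(c("# nodes=3", "0 1", "1 0"), f)
  g3 <- read_edge_list(f)
  expect_equal(g3$n, 3L)
  expect_false(is_strongly_connected(g3))  # node 2 is isolated

  writeLines("0 0", f)
  expect_error(read_edge_list(f), "self-loop")
  writeLines(c("0 1", "1 x"), f)
  expect_error(read_edge_list(f), "line 2")
  # duplicate lines collapse
  writeLines(c("0 1", "0 1", "1 0"), f)
  expect_equal(nrow(read_edge_list(f)$edges), 2L)

  # write/read round trip on assorted generated graphs
  for (g in list(graph_star(5), graph_fan(3), graph_four_column(2))) {
    write_edge_list(g, f)
    g2 <- read_edge_list(f)
    expect_equal(g2$edges, g$edges)
    expect_equal(g2$n, g$n)
  }
})

test_that("self-loops and out-of-range edges are rejected at construction", {
  expect_error(moran_graph(3, rbind(c(1, 1))), "self-loop")
  expect_error(moran_graph(3, rbind(c(1, 4))), "node ids")
})

test_that("structural predicates classify canonical examples", {
  expect_true(is_strongly_connected(graph_cycle(5)))
  out_star <- moran_graph(4, cbind(1L, 2:4))  # center -> leaves only
  expect_false(is_strongly_connected(out_star))
  expect_true(is_strongly_connected(graph_four_column(4)))

  s5 <- graph_star(5)
  expect_true(is_undirected_graph(s5))
  expect_false(is_oriented(s5))
  c3 <- graph_cycle(3)
  expect_false(is_undirected_graph(c3))
  expect_true(is_oriented(c3))
  mixed <- moran_graph(3, rbind(c(1, 2), c(2, 1), c(2, 3), c(3, 1)))
  expect_false(is_undirected_graph(mixed))
  expect_false(is_oriented(mixed))

  expect_true(is_regular_graph(graph_cycle(6)))
  expect_true(is_eulerian(graph_cycle(6)))
  expect_true(is_eulerian(s5))  # symmetric edges force equality
  two_cycles <- moran_graph(4, rbind(c(1, 2), c(2, 3), c(3, 1),
                                     c(1, 4), c(4, 1)))
  expect_true(is_eulerian(two_cycles))   # 3-cycle + 2-cycle through node 1
  expect_false(is_regular_graph(two_cycles))
})

test_that("balance predicate: undirected and regular pass, local imbalance fails", {
  expect_true(is_balanced(graph_star(4)))
  expect_true(is_balanced(graph_cycle(7)))
  expect_true(is_balanced(graph_complete(5)))
  # node 2 has outdegree 2 with successor indegrees 2 and 1, so its
  # successor side gives (1/2)(1/2 + 1/1) = 0.75, while its predecessor
  # side gives 1/outdeg(1) = 1: unbalanced
  g <- moran_graph(3, rbind(c(1, 2), c(2, 1), c(2, 3), c(3, 1)))
  expect_false(is_balanced(g))
  expect_error(is_balanced(moran_graph(2, rbind(c(1, 2)))), "indegree")
})

test_that("family generators match their closed-form node/edge counts", {
  g <- graph_four_column(4)
  expect_equal(g$n, 16L)
  f <- graph_fan(5)
  expect_equal(f$n, 11L)
  expect_equal(nrow(f$edges), 15L)
  v <- graph_vortex(3)
  expect_equal(v$n, 8L)
  expect_equal(nrow(v$edges), 12L)
  for (k in c(1, 2, 6)) {
    expect_equal(graph_four_column(k)$n, 4L * k)
    expect_equal(graph_fan(k)$n, 2L * k + 1L)
    expect_equal(nrow(graph_fan(k)$edges), 3L * k)
    expect_equal(graph_vortex(k)$n, 2L * k + 2L)
    expect_equal(nrow(graph_vortex(k)$edges), 4L * k)
  }
  ss <- graph_superstar(3, 2, 4)
  expect_equal(ss$n, 1L + 3L * (2L + 2L))
  mf <- graph_metafunnel(2, 2)
  expect_equal(mf$n, 7L)
  expect_true(all(vapply(
    list(g, f, v, ss, mf, graph_lollipop(),
         graph_cyclic_multipartite(c(2, 1, 3))),
    is_strongly_connected, NA)))
})

test_that("four-column wiring matches the frozen fixture", {
  path <- system.file("extdata", "four_column_k4.edges",
                      package = "moranbd")
  expect_equal(graph_four_column(4)$edges, read_edge_list(path)$edges)
})

test_that("random fixtures satisfy their requested predicate across seeds", {
  for (seed in 1:100) {
    expect_true(is_strongly_connected(
      random_graph_fixture("strongly_connected", 6, 0.3, seed)))
  }
  for (seed in 1:100) {
    ge <- random_graph_fixture("eulerian", 6, 0.3, seed)
    expect_true(is_eulerian(ge))
    expect_true(is_strongly_connected(ge))
  }
  for (seed in 1:50) {
    gu <- random_graph_fixture("undirected", 5, 0.5, seed)
    expect_true(is_undirected_graph(gu))
    gr <- random_graph_fixture("regular", 5 + seed %% 3, 0.5, seed)
    expect_true(is_regular_graph(gr))
    expect_true(is_strongly_connected(gr))
  }
})

test_that("predicate implications hold on randomized fixtures", {
  for (seed in 1:100) {
    gr <- random_graph_fixture("regular", 4 + seed %% 4, 0.45, seed)
    expect_true(is_eulerian(gr))   # regular => Eulerian
    expect_true(is_balanced(gr))   # regular => balanced
    gu <- random_graph_fixture("undirected", 4 + seed %% 4, 0.45, seed)
    expect_true(is_eulerian(gu))   # undirected => Eulerian
    expect_true(is_balanced(gu))   # undirected => balanced
  }
})

test_that("balance of named directed families", {
  # vortex and cyclic complete multipartite graphs satisfy the exact
  # balance equality for all tested parameters
  for (k in 1:4) expect_true(is_balanced(graph_vortex(k)))
  for (sz in list(c(1, 1, 3), c(2, 3, 2), c(1, 2), c(2, 2, 2, 2))) {
    expect_true(is_balanced(graph_cyclic_multipartite(sz)))
  }
  # single-lobe superstars and depth-1 metafunnels are balanced; wider
  # instances of the canonical wirings fail the exact equality at the
  # reservoir/outer layer (see the methods vignette)
  expect_true(is_balanced(graph_superstar(1, 3, 3)))
  expect_true(is_balanced(graph_superstar(1, 2, 5)))
  expect_true(is_balanced(graph_metafunnel(3, 1)))
  expect_false(is_balanced(graph_superstar(2, 2, 3)))
  expect_false(is_balanced(graph_metafunnel(2, 2)))
  expect_false(is_balanced(graph_fan(2)))
})

test_that("dot export and json descriptor are well formed", {
  g <- graph_star(4)
  f <- tempfile(fileext = ".dot")
  write_dot(g, f)
  expect_true(any(grepl("->", readLines(f))))
  d <- graph_descriptor(g)
  expect_equal(d$n_nodes, 4L)
  expect_equal(nrow(d$edges), 6L)
  expect_equal(d$family, "star")
})
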