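#' Named graph families
#'
#' Deterministic generators for the graph families used throughout the
#' package. All generated graphs are strongly connected (checked at
#' construction).
#'
#' @description
#' * `graph_complete(n)`: the well-mixed population; every ordered pair is
#'   an edge.
#' * `graph_cycle(n)`: directed n-cycle (regular with d = 1).
#' * `graph_star(n)`: undirected star; one center connected to `n - 1`
#'   leaves by two-way edges.
#' * `graph_lollipop()`: the 4-node lollipop; an undirected triangle with a
#'   pendant node attached by a two-way edge.
#' * `graph_four_column(k)`: the four-column tug-of-war graph on `N = 4k`
#'   nodes (see Details).
#' * `graph_fan(k)`: oriented fan with `k` blades; hub `h` plus blade pairs
#'   `(a_i, b_i)` wired `h -> a_i -> b_i -> h`; `N = 2k + 1` nodes and
#'   `3k` one-way edges.
#' * `graph_vortex(k)`: oriented vortex with batch size `k`; two relay
#'   nodes and two batches of `k` nodes in a one-way circulation
#'   `s -> A -> t -> B -> s`; `N = 2k + 2` nodes and `4k` edges.
#' * `graph_superstar(leaves, reservoir, path_len)`: superstar amplifier;
#'   each of `leaves` lobes has a reservoir of `reservoir` nodes feeding a
#'   directed chain of `path_len - 2` nodes into a global center, which
#'   feeds back to every reservoir node.
#' * `graph_metafunnel(arity, depth)`: layered funnel; layer `j` has
#'   `arity^j` nodes, each node points to its parent in the layer above,
#'   and the root feeds back to all deepest-layer nodes.
#' * `graph_cyclic_multipartite(sizes)`: parts arranged in a cycle, every
#'   node of part `i` pointing to every node of part `i + 1` (mod m).
#'
#' @details
#' The four-column graph consists of columns C1..C4 of `k` nodes each.
#' Each column is a vertical path of two-way edges; the two middle columns
#' are joined by two-way row edges; the side columns attach to their middle
#' column by a two-way edge in the bottom row and by one-way row edges
#' (side to middle) in all higher rows. With mutants seeded on the left
#' half, mutants advance up column C3 against one-way pressure from the
#' resident column C4 while residents advance up C2 against pressure from
#' C1, which makes fixation exponentially slow for small selective
#' advantage but fast for large `r`. The wiring is a documented design
#' choice; the `k = 4` edge set is frozen as a package fixture so the
#' generator cannot drift silently.
#'
#' @param n,k,leaves,reservoir,path_len,arity,depth,sizes Family
#'   parameters, positive integers (`sizes`: integer vector of part sizes,
#'   length >= 2).
#' @return A [moran_graph()] tagged with `family` and `params`.
#' @examples
#' graph_fan(5)     # 11 nodes, 15 edges
#' graph_vortex(3)  # 8 nodes, 12 edges
#' @name graph_families
NULL

.two_way <- function(u, v) rbind(cbind(u, v), cbind(v, u))

.check_family <- function(g) {
  if (!is_strongly_connected(g)) {
    stop("generated '", g$family, "' graph is not strongly connected; ",
         "invalid parameter combination")
  }
  g
}

#' @rdname graph_families
#' @export
graph_complete <- function(n) {
  stopifnot(n >= 2)
  e <- expand.grid(from = seq_len(n), to = seq_len(n))
  e <- as.matrix(e[e$from != e$to, ])
  .check_family(moran_graph(n, e, family = "complete", params = list(n = n)))
}

#' @rdname graph_families
#' @export
graph_cycle <- function(n) {
  stopifnot(n >= 2)
  e <- cbind(seq_len(n), c(seq_len(n)[-1L], 1L))
  .check_family(moran_graph(n, e, family = "cycle", params = list(n = n)))
}

#' @rdname graph_families
#' @export
graph_star <- function(n) {
  stopifnot(n >= 2)
  e <- .two_way(1L, 2:n)
  .check_family(moran_graph(n, e, family = "star", params = list(n = n)))
}

#' @rdname graph_families
#' @export
graph_lollipop <- function() {
  e <- rbind(.two_way(1L, 2L), .two_way(1L, 3L), .two_way(2L, 3L),
             .two_way(3L, 4L))
  .check_family(moran_graph(4L, e, family = "lollipop", params = list(n = 4L)))
}

#' @rdname graph_families
#' @export
graph_four_column <- function(k) {
  stopifnot(k >= 1)
  col <- function(j) ((j - 1L) * k + 1L):(j * k)  # column j, bottom to top
  C <- lapply(1:4, col)
  e <- NULL
  for (j in 1:4) {          # vertical two-way paths within each column
    if (k > 1L) e <- rbind(e, .two_way(C[[j]][-k], C[[j]][-1L]))
  }
  e <- rbind(e, .two_way(C[[2L]], C[[3L]]))       # middle rows, two-way
  e <- rbind(e, .two_way(C[[1L]][1L], C[[2L]][1L]),  # bottom row anchors
             .two_way(C[[4L]][1L], C[[3L]][1L]))
  if (k > 1L) {             # one-way side-to-middle pressure edges
    e <- rbind(e, cbind(C[[1L]][-1L], C[[2L]][-1L]),
               cbind(C[[4L]][-1L], C[[3L]][-1L]))
  }
  .check_family(moran_graph(4L * k, e, family = "four_column",
                            params = list(k = k)))
}

#' Left-half node set of the four-column graph
#'
#' Convenience accessor for the canonical initial condition of the
#' four-column experiment: all nodes of columns C1 and C2.
#'
#' @param k Column height.
#' @return Integer vector of node ids.
#' @export
four_column_left_half <- function(k) seq_len(2L * k)

#' @rdname graph_families
#' @export
graph_fan <- function(k) {
  stopifnot(k >= 1)
  h <- 1L
  a <- 1L + seq_len(k)
  b <- 1L + k + seq_len(k)
  e <- rbind(cbind(h, a), cbind(a, b), cbind(b, h))
  .check_family(moran_graph(2L * k + 1L, e, family = "fan",
                            params = list(k = k)))
}

#' @rdname graph_families
#' @export
graph_vortex <- function(k) {
  stopifnot(k >= 1)
  s <- 1L; t <- 2L
  A <- 2L + seq_len(k)
  B <- 2L + k + seq_len(k)
  e <- rbind(cbind(s, A), cbind(A, t), cbind(t, B), cbind(B, s))
  .check_family(moran_graph(2L * k + 2L, e, family = "vortex",
                            params = list(k = k)))
}

#' @rdname graph_families
#' @export
graph_superstar <- function(leaves, reservoir, path_len = 3L) {
  stopifnot(leaves >= 1, reservoir >= 1, path_len >= 2)
  m <- as.integer(reservoir); l <- as.integer(leaves)
  chain_len <- as.integer(path_len) - 2L
  n <- 1L + l * (m + chain_len)
  center <- 1L
  e <- NULL
  nxt <- 2L
  for (j in seq_len(l)) {
    res <- nxt:(nxt + m - 1L); nxt <- nxt + m
    e <- rbind(e, cbind(center, res))
    if (chain_len > 0L) {
      chain <- nxt:(nxt + chain_len - 1L); nxt <- nxt + chain_len
      e <- rbind(e, cbind(res, chain[1L]))
      if (chain_len > 1L) e <- rbind(e, cbind(chain[-chain_len], chain[-1L]))
      e <- rbind(e, cbind(chain[chain_len], center))
    } else {
      e <- rbind(e, cbind(res, center))
    }
  }
  .check_family(moran_graph(n, e, family = "superstar",
                            params = list(leaves = l, reservoir = m,
                                          path_len = as.integer(path_len))))
}

#' @rdname graph_families
#' @export
graph_metafunnel <- function(arity, depth) {
  stopifnot(arity >= 1, depth >= 1)
  a <- as.integer(arity); d <- as.integer(depth)
  sizes <- a^(0:d)
  offs <- cumsum(c(0L, sizes))
  layer <- function(j) offs[j + 1L] + seq_len(sizes[j + 1L])
  e <- NULL
  for (j in seq_len(d)) {   # child in layer j points to its parent in j - 1
    parents <- rep(layer(j - 1L), each = a)
    e <- rbind(e, cbind(layer(j), parents))
  }
  e <- rbind(e, cbind(1L, layer(d)))  # root feeds the deepest layer
  n <- sum(sizes)
  .check_family(moran_graph(n, e, family = "metafunnel",
                            params = list(arity = a, depth = d)))
}

#' @rdname graph_families
#' @export
graph_cyclic_multipartite <- function(sizes) {
  sizes <- as.integer(sizes)
  stopifnot(length(sizes) >= 2, all(sizes >= 1))
  m <- length(sizes)
  offs <- cumsum(c(0L, sizes))
  part <- function(i) offs[i] + seq_len(sizes[i])
  e <- NULL
  for (i in seq_len(m)) {
    j <- if (i == m) 1L else i + 1L
    e <- rbind(e, as.matrix(expand.grid(from = part(i), to = part(j))))
  }
  .check_family(moran_graph(sum(sizes), e, family = "cyclic_multipartite",
                            params = list(sizes = sizes)))
}

#' Generate a named family by id
#'
#' Dispatcher over the family generators, mainly for the command-line
#' interface. Family ids: `complete`, `cycle`, `star`, `lollipop`,
#' `four_column`, `fan`, `vortex`, `superstar`, `metafunnel`,
#' `cyclic_multipartite`.
#'
#' @param name Family id.
#' @param ... Parameters forwarded to the generator.
#' @return A [moran_graph()].
#' @export
make_family <- function(name, ...) {
  gen <- switch(name,
    complete = graph_complete,
    cycle = graph_cycle,
    star = graph_star,
    lollipop = graph_lollipop,
    four_column = graph_four_column,
    fan = graph_fan,
    vortex = graph_vortex,
    superstar = graph_superstar,
    metafunnel = graph_metafunnel,
    cyclic_multipartite = graph_cyclic_multipartite,
    stop("unknown graph family: ", name)
  )
  gen(...)
}

#' Random graph fixtures with a guaranteed structural property
#'
#' Seeded random digraph generators used as property-test fixtures. The
#' requested predicate holds by construction:
#' * `strongly_connected`: a random Hamiltonian cycle superposed on a
#'   random digraph;
#' * `eulerian`: a superposition of random directed cycles (cycles conserve
#'   in/out degree at every node);
#' * `undirected`: random symmetric edge set over a random Hamiltonian
#'   two-way cycle;
#' * `regular`: a circulant graph with random jump offsets (every node has
#'   indegree = outdegree = d).
#'
#' @param kind One of `"strongly_connected"`, `"eulerian"`, `"undirected"`,
#'   `"regular"`.
#' @param n Node count (>= 2).
#' @param density Approximate edge probability for the random part.
#' @param seed Integer seed fixing the draw.
#' @return A [moran_graph()] satisfying the requested predicate.
#' @export
random_graph_fixture <- function(kind = c("strongly_connected", "eulerian",
                                          "undirected", "regular"),
                                 n, density = 0.3, seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(n >= 2)
  n <- as.integer(n)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  g <- switch(kind,
    strongly_connected = {
      perm <- sample.int(n)
      e <- cbind(perm, c(perm[-1L], perm[1L]))
      extra <- which(matrix(stats::runif(n * n) < density, n, n) &
                       !diag(TRUE, n), arr.ind = TRUE)
      moran_graph(n, rbind(e, extra))
    },
    eulerian = {
      # superpose edge-disjoint random directed cycles on a Hamiltonian
      # cycle; each cycle conserves in/out degree at every node it visits
      em <- matrix(FALSE, n, n)
      perm <- sample.int(n)
      em[cbind(perm, c(perm[-1L], perm[1L]))] <- TRUE
      for (i in seq_len(max(1L, round(density * n * 2)))) {
        len <- sample(2:n, 1L)
        nodes <- sample.int(n, len)
        cyc <- cbind(nodes, c(nodes[-1L], nodes[1L]))
        if (!any(em[cyc])) em[cyc] <- TRUE
      }
      moran_graph(n, which(em, arr.ind = TRUE))
    },
    undirected = {
      perm <- sample.int(n)
      e <- .two_way(perm, c(perm[-1L], perm[1L]))
      pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
      keep <- pairs[stats::runif(nrow(pairs)) < density, , drop = FALSE]
      if (nrow(keep)) e <- rbind(e, .two_way(keep[, 1L], keep[, 2L]))
      moran_graph(n, e)
    },
    regular = {
      d <- max(1L, min(n - 1L, round(density * (n - 1L))))
      # jump 1 is always included so the circulant is strongly connected
      jumps <- if (d == 1L) 1L else c(1L, sample(2:(n - 1L), d - 1L))
      e <- NULL
      for (j in jumps) {
        from <- seq_len(n)
        e <- rbind(e, cbind(from, (from - 1L + j) %% n + 1L))
      }
      moran_graph(n, e)
    }
  )
  g$family <- paste0("random_", kind)
  g$params <- list(n = n, density = density, seed = seed)
  g
}

# Save/restore the global RNG state so fixture generation does not disturb
# the caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
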