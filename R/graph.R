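#' Directed graph for the Moran Birth-death process
#'
#' A `moran_graph` is a simple directed graph on `n` nodes: the spatial
#' population structure on which the process runs. Nodes are the integers
#' `1:n` (plain-text edge-list files use 0-based ids and are converted on
#' read/write). Self-loops are rejected and duplicate edges collapse to one.
#'
#' @param n Number of nodes (positive integer).
#' @param edges Two-column matrix (or data.frame) of directed edges
#'   `from -> to`, 1-based node ids. A two-way connection is represented by
#'   both one-way edges.
#' @param family,params Optional provenance tags set by the family
#'   generators.
#'
#' @return An object of class `moran_graph` with elements `n`, `edges`
#'   (ordered integer matrix), `adj` (out-adjacency lists), `indeg`,
#'   `outdeg`.
#' @examples
#' g <- moran_graph(2, rbind(c(1, 2), c(2, 1)))
#' is_strongly_connected(g)
#' @export
moran_graph <- function(n, edges, family = NULL, params = NULL) {
  n <- as.integer(n)
  stopifnot(length(n) == 1L, n >= 1L)
  edges <- as.matrix(edges)
  if (length(edges) == 0L) {
    edges <- matrix(integer(0), ncol = 2L)
  }
  if (ncol(edges) != 2L) stop("'edges' must have two columns (from, to)")
  storage.mode(edges) <- "integer"
  if (anyNA(edges)) stop("edges contain missing values")
  if (any(edges < 1L) || any(edges > n)) {
    stop("edge endpoints must be node ids in 1..", n)
  }
  if (any(edges[, 1L] == edges[, 2L])) {
    stop("self-loops are not allowed")
  }
  ord <- order(edges[, 1L], edges[, 2L])
  edges <- edges[ord, , drop = FALSE]
  dup <- duplicated(edges)
  if (any(dup)) edges <- edges[!dup, , drop = FALSE]
  dimnames(edges) <- list(NULL, c("from", "to"))
  adj <- split(edges[, 2L], factor(edges[, 1L], levels = seq_len(n)))
  adj <- lapply(adj, as.integer)
  outdeg <- lengths(adj)
  indeg <- tabulate(edges[, 2L], nbins = n)
  structure(
    list(n = n, edges = edges, adj = adj,
         indeg = as.integer(indeg), outdeg = as.integer(outdeg),
         family = family, params = params),
    class = "moran_graph"
  )
}

#' @export
print.moran_graph <- function(x, ...) {
  fam <- if (is.null(x$family)) "" else paste0(" [", x$family, "]")
  cat(sprintf("moran_graph%s: %d nodes, %d directed edges\n",
              fam, x$n, nrow(x$edges)))
  cat(sprintf("  strongly connected: %s; undirected: %s; Eulerian: %s\n",
              is_strongly_connected(x), is_undirected_graph(x),
              is_eulerian(x)))
  invisible(x)
}

#' @export
format.moran_graph <- function(x, ...) {
  sprintf("moran_graph(%d nodes, %d edges)", x$n, nrow(x$edges))
}

#' Convert to an igraph object
#'
#' @param g A [moran_graph()].
#' @return An [igraph::graph] with the same directed edge set.
#' @export
as_igraph <- function(g) {
  stopifnot(inherits(g, "moran_graph"))
  h <- igraph::make_empty_graph(n = g$n, directed = TRUE)
  if (nrow(g$edges) > 0L) h <- igraph::add_edges(h, t(g$edges))
  h
}

#' Node degrees
#'
#' In-degree is the number of incoming edges, out-degree the number of
#' outgoing edges. For Eulerian graphs the two coincide and are simply
#' called the degree.
#'
#' @param g A [moran_graph()].
#' @return A data.frame with columns `node`, `indeg`, `outdeg`.
#' @export
degree_profile <- function(g) {
  stopifnot(inherits(g, "moran_graph"))
  data.frame(node = seq_len(g$n), indeg = g$indeg, outdeg = g$outdeg)
}

# ---- structural predicates -------------------------------------------------

#' Structural graph predicates
#'
#' @description
#' * `is_strongly_connected()`: every node reaches every other node along
#'   directed edges. All process-facing computations require this.
#' * `is_undirected_graph()`: every edge is reciprocated (the edge set is
#'   symmetric).
#' * `is_oriented()`: no edge is reciprocated.
#' * `is_regular_graph()`: a single `d` exists with indegree = outdegree =
#'   `d` at every node.
#' * `is_eulerian()`: indegree equals outdegree at every node separately
#'   (a circulation).
#'
#' @param g A [moran_graph()].
#' @return A single logical.
#' @examples
#' is_regular_graph(graph_cycle(5))     # TRUE, d = 1
#' is_oriented(graph_cycle(3))          # TRUE
#' is_undirected_graph(graph_star(4))   # TRUE
#' @export
is_strongly_connected <- function(g) {
  stopifnot(inherits(g, "moran_graph"))
  if (g$n == 1L) return(TRUE)
  if (any(g$indeg == 0L) || any(g$outdeg == 0L)) return(FALSE)
  igraph::is_connected(as_igraph(g), mode = "strong")
}

#' @rdname is_strongly_connected
#' @export
is_undirected_graph <- function(g) {
  stopifnot(inherits(g, "moran_graph"))
  if (nrow(g$edges) == 0L) return(TRUE)
  key <- g$edges[, 1L] * (g$n + 1L) + g$edges[, 2L]
  rev <- g$edges[, 2L] * (g$n + 1L) + g$edges[, 1L]
  all(rev %in% key)
}

#' @rdname is_strongly_connected
#' @export
is_oriented <- function(g) {
  stopifnot(inherits(g, "moran_graph"))
  if (nrow(g$edges) == 0L) return(TRUE)
  key <- g$edges[, 1L] * (g$n + 1L) + g$edges[, 2L]
  rev <- g$edges[, 2L] * (g$n + 1L) + g$edges[, 1L]
  !any(rev %in% key)
}

#' @rdname is_strongly_connected
#' @export
is_regular_graph <- function(g) {
  stopifnot(inherits(g, "moran_graph"))
  d <- g$indeg[1L]
  all(g$indeg == d) && all(g$outdeg == d)
}

#' @rdname is_strongly_connected
#' @export
is_eulerian <- function(g) {
  stopifnot(inherits(g, "moran_graph"))
  all(g$indeg == g$outdeg)
}

# Exact rational arithmetic on reduced fractions stored as c(num, den).
# Degrees are small integers, so numerators/denominators stay well inside
# the exactly-representable double range.
.frac <- function(num, den) {
  g <- .gcd(num, den)
  c(num / g, den / g)
}
.gcd <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0) { t <- a %% b; a <- b; b <- t }
  if (a == 0) 1 else a
}
.frac_add <- function(f1, f2) {
  .frac(f1[1L] * f2[2L] + f2[1L] * f1[2L], f1[2L] * f2[2L])
}
.frac_eq <- function(f1, f2) {
  f1[1L] * f2[2L] == f2[1L] * f1[2L]
}

#' Balance predicate
#'
#' A strongly connected graph is *balanced* if at every node `v` the
#' degree-reciprocal sums over predecessors and successors agree exactly:
#' `(1/indeg(v)) * sum_{u -> v} 1/outdeg(u) =
#'  (1/outdeg(v)) * sum_{v -> w} 1/indeg(w)`.
#' The left side is the reciprocal-average outdegree of the predecessors of
#' `v`, the right side the reciprocal-average indegree of its successors.
#' Undirected graphs and regular graphs are always balanced; on balanced
#' graphs the neutral fixation probability has the closed form of
#' [balanced_fp_formula()] and fixation time is polynomially bounded
#' ([bound_theorem4()]).
#'
#' The equality is tested in exact rational arithmetic (integer numerators
#' and denominators, reduced at every addition), so there is no tolerance
#' parameter and no floating-point false positives.
#'
#' @param g A [moran_graph()] in which every node has indegree and outdegree
#'   at least 1.
#' @return A single logical.
#' @examples
#' is_balanced(graph_star(4))   # undirected => balanced
#' is_balanced(graph_cycle(6))  # regular    => balanced
#' @export
is_balanced <- function(g) {
  stopifnot(inherits(g, "moran_graph"))
  if (any(g$indeg == 0L) || any(g$outdeg == 0L)) {
    stop("is_balanced requires indegree and outdegree >= 1 at every node")
  }
  preds <- split(g$edges[, 1L], factor(g$edges[, 2L], levels = seq_len(g$n)))
  for (v in seq_len(g$n)) {
    lhs <- c(0, 1)
    for (u in preds[[v]]) lhs <- .frac_add(lhs, c(1, g$outdeg[u]))
    lhs <- .frac(lhs[1L], lhs[2L] * g$indeg[v])
    rhs <- c(0, 1)
    for (w in g$adj[[v]]) rhs <- .frac_add(rhs, c(1, g$indeg[w]))
    rhs <- .frac(rhs[1L], rhs[2L] * g$outdeg[v])
    if (!.frac_eq(lhs, rhs)) return(FALSE)
  }
  TRUE
}

# ---- input / output --------------------------------------------------------

#' Read and write plain-text edge lists
#'
#' The file format is one `u v` pair of whitespace-separated 0-based node
#' ids per line; `#` starts a comment. A `# nodes=N` header fixes the node
#' count when it exceeds `1 + max(id)` (e.g. to declare isolated nodes).
#' Node ids are shifted to 1-based on read and back to 0-based on write.
#' Duplicate edge lines collapse to a single edge.
#'
#' @param path File path.
#' @return `read_edge_list()` returns a [moran_graph()];
#'   `write_edge_list()` returns `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".edges")
#' write_edge_list(graph_cycle(3), f)
#' g <- read_edge_list(f)
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  n_declared <- NA_integer_
  hdr <- grepl("^\\s*#\\s*nodes\\s*=\\s*[0-9]+", lines)
  if (any(hdr)) {
    n_declared <- as.integer(sub(".*nodes\\s*=\\s*([0-9]+).*", "\\1",
                                 lines[which(hdr)[1L]]))
  }
  body <- sub("#.*$", "", lines)
  keep <- grepl("\\S", body)
  body <- body[keep]
  lineno <- which(keep)
  from <- integer(length(body)); to <- integer(length(body))
  for (i in seq_along(body)) {
    tok <- strsplit(trimws(body[i]), "\\s+")[[1L]]
    ids <- suppressWarnings(as.integer(tok))
    if (length(ids) != 2L || anyNA(ids)) {
      stop("malformed edge at line ", lineno[i], ": '", lines[lineno[i]], "'")
    }
    if (ids[1L] == ids[2L]) {
      stop("self-loop at line ", lineno[i], ": '", lines[lineno[i]], "'")
    }
    from[i] <- ids[1L]; to[i] <- ids[2L]
  }
  n <- if (length(from)) max(from, to) + 1L else 0L
  if (!is.na(n_declared)) n <- max(n, n_declared)
  moran_graph(n, cbind(from + 1L, to + 1L))
}

#' @rdname read_edge_list
#' @param g A [moran_graph()].
#' @export
write_edge_list <- function(g, path) {
  stopifnot(inherits(g, "moran_graph"))
  lines <- c(sprintf("# nodes=%d", g$n),
             sprintf("%d %d", g$edges[, 1L] - 1L, g$edges[, 2L] - 1L))
  writeLines(lines, path)
  invisible(path)
}

#' Export a graph in DOT format for visualization
#'
#' @param g A [moran_graph()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dot <- function(g, path) {
  stopifnot(inherits(g, "moran_graph"))
  igraph::write_graph(as_igraph(g), path, format = "dot")
  invisible(path)
}

#' JSON descriptor of a graph
#'
#' @param g A [moran_graph()].
#' @return A list `{n_nodes, edges, family, params}` (0-based edges),
#'   suitable for [jsonlite::toJSON()].
#' @export
graph_descriptor <- function(g) {
  stopifnot(inherits(g, "moran_graph"))
  list(n_nodes = g$n,
       edges = unname(g$edges) - 1L,
       family = if (is.null(g$family)) NA_character_ else g$family,
       params = g$params)
}
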