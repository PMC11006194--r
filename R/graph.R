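# Weighted undirected population structures.
#
# A `weighted_graph` stores the full symmetric weight matrix (populations
# here are small: exact solvers cap at N = 20 and lumped chains at a few
# thousand nodes), a cached directed-edge list used by the single-step
# kernels, weighted degrees, and optional family metadata (orbit structure
# of the node symmetries) that powers the lumped solvers.

new_weighted_graph <- function(W, family = "custom", meta = list()) {
  g <- structure(
    list(
      nodes = rownames(W),
      W = W,
      deg = rowSums(W),
      ed = NULL,
      family = family,
      meta = meta,
      connected = NA
    ),
    class = "weighted_graph"
  )
  validate_weighted_graph(g)
}

#' Build a weighted graph from an edge table
#'
#' @param edges A data frame with columns `from`, `to`, `weight`: one row
#'   per undirected edge. Node identifiers are coerced to character.
#' @param nodes Optional character vector fixing the node order; defaults
#'   to order of first appearance in `edges`.
#'
#' @details Validation enforces the population-structure contract: strictly
#'   positive symmetric weights, no self-loops, no duplicate edges, no
#'   isolated nodes, and at least two nodes. Connectivity is checked and
#'   recorded in the `$connected` field; fixation operations require it.
#'
#' @return An object of class `weighted_graph`.
#' @export
#' @examples
#' g <- weighted_graph(data.frame(from = c("a", "b"), to = c("b", "c"),
#'                                weight = c(1, 2)))
#' weighted_degree(g)
weighted_graph <- function(edges, nodes = NULL) {
  if (!is.data.frame(edges) || !all(c("from", "to", "weight") %in% names(edges))) {
    abort_validation("`edges` must be a data frame with columns from, to, weight")
  }
  from <- as.character(edges$from)
  to <- as.character(edges$to)
  w <- as.numeric(edges$weight)
  if (any(!is.finite(w)) || any(w <= 0)) {
    abort_validation("edge weights must be finite and strictly positive")
  }
  if (any(from == to)) abort_validation("self-loops are not allowed")
  key <- paste(pmin(from, to), pmax(from, to))
  if (anyDuplicated(key)) abort_validation("duplicate edges are not allowed")
  if (is.null(nodes)) nodes <- unique(c(rbind(from, to)))
  if (!all(c(from, to) %in% nodes)) abort_validation("`nodes` must cover all edge endpoints")
  n <- length(nodes)
  W <- matrix(0, n, n, dimnames = list(nodes, nodes))
  W[cbind(match(from, nodes), match(to, nodes))] <- w
  W[cbind(match(to, nodes), match(from, nodes))] <- w
  new_weighted_graph(W)
}

#' Validate a weighted graph
#'
#' Re-checks all structural invariants (symmetry, positivity, no
#' self-loops, size, no isolated nodes), refreshes the cached edge list and
#' degrees, and records connectivity.
#'
#' @param g A `weighted_graph`.
#' @return The validated graph, invisibly usable in pipelines.
#' @export
validate_weighted_graph <- function(g) {
  W <- g$W
  if (!is.matrix(W) || nrow(W) != ncol(W)) abort_validation("weight matrix must be square")
  n <- nrow(W)
  if (n < 2L) abort_validation("a population structure needs at least N = 2 nodes")
  if (is.null(rownames(W))) {
    rownames(W) <- colnames(W) <- paste0("v", seq_len(n))
    g$W <- W
    g$nodes <- rownames(W)
  }
  if (any(diag(W) != 0)) abort_validation("self-loops are not allowed")
  if (!isTRUE(all.equal(W, t(W), tolerance = 0, check.attributes = FALSE))) {
    abort_validation("weights must be symmetric: w(u,v) = w(v,u)")
  }
  off <- W[upper.tri(W)]
  if (any(!is.finite(off)) || any(off < 0)) {
    abort_validation("edge weights must be finite and nonnegative (zero = no edge)")
  }
  if (!any(off > 0)) abort_validation("graph has no edges")
  deg <- rowSums(W)
  if (any(deg == 0)) abort_validation("isolated nodes are not allowed")
  idx <- which(W > 0, arr.ind = TRUE)
  g$deg <- deg
  g$ed <- list(from = idx[, 1L], to = idx[, 2L], w = W[idx])
  ig <- igraph::graph_from_adjacency_matrix(W, mode = "undirected", weighted = TRUE)
  g$connected <- igraph::is_connected(ig)
  g
}

#' Number of nodes / undirected edges of a weighted graph
#'
#' @param g A `weighted_graph`.
#' @return An integer count.
#' @export
n_nodes <- function(g) length(g$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(g) length(g$ed$w) / 2L

node_index <- function(g, v) {
  i <- match(as.character(v), g$nodes)
  if (anyNA(i)) abort_lookup(sprintf("unknown node(s): %s",
                                     paste(v[is.na(i)], collapse = ", ")))
  i
}

require_connected <- function(g) {
  if (!isTRUE(g$connected)) {
    abort_validation("this operation requires a connected graph")
  }
  invisible(g)
}

#' @export
print.weighted_graph <- function(x, ...) {
  cat(sprintf("<weighted_graph> %d nodes, %d edges, family = %s, %s\n",
              n_nodes(x), n_edges(x), x$family,
              if (isTRUE(x$connected)) "connected" else "NOT connected"))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Constructors for the graph families under study
# ---------------------------------------------------------------------------

#' Complete graph \eqn{K_N}
#'
#' The unstructured, well-mixed population: all \eqn{N(N-1)/2} edges
#' present with unit weight. Serves as the baseline against which
#' amplifiers and suppressors are defined.
#'
#' @param N Population size (integer, at least 2).
#' @return A `weighted_graph` with family `"complete"`.
#' @export
#' @examples
#' make_complete(11)
make_complete <- function(N) {
  N <- check_scalar_count(N, "N", min = 2)
  nodes <- paste0("v", seq_len(N))
  W <- matrix(1, N, N, dimnames = list(nodes, nodes))
  diag(W) <- 0
  new_weighted_graph(W, family = "complete",
                     meta = list(orbits = list(singletons = integer(0),
                                               counts = list(all = seq_len(N)),
                                               pairs = list())))
}

#' Star graph \eqn{S_N}
#'
#' One center connected to \eqn{N - 1} mutually non-adjacent leaves, all
#' weights 1. The classic Birth-death amplifier.
#'
#' @param N Population size (integer, at least 2).
#' @return A `weighted_graph` with family `"star"`.
#' @export
make_star <- function(N) {
  N <- check_scalar_count(N, "N", min = 2)
  nodes <- c("center", paste0("leaf-", seq_len(N - 1L)))
  W <- matrix(0, N, N, dimnames = list(nodes, nodes))
  W[1L, -1L] <- 1
  W[-1L, 1L] <- 1
  new_weighted_graph(W, family = "star",
                     meta = list(orbits = list(singletons = c(center = 1L),
                                               counts = list(leaf = seq_len(N)[-1L]),
                                               pairs = list())))
}

#' Fan graph
#'
#' A center node plus `m` blades of two nodes each. Blade-internal edges
#' have weight 1; each blade node attaches to the center with weight
#' `hub_coupling`. Small couplings make the blades interact only rarely
#' with the hub, which is the regime in which large fans amplify
#' death-Birth selection. Total size is \eqn{N = 2m + 1}.
#'
#' @param m Number of blades (integer, at least 1).
#' @param hub_coupling Positive weight of each blade-center edge.
#' @return A `weighted_graph` with family `"fan"`.
#' @export
#' @examples
#' make_fan(5, hub_coupling = 0.01)  # the 11-node fan
make_fan <- function(m, hub_coupling = 0.01) {
  m <- check_scalar_count(m, "m", min = 1)
  hub_coupling <- check_scalar_positive(hub_coupling, "hub_coupling")
  N <- 2L * m + 1L
  nodes <- c("fan-center",
             as.vector(rbind(paste0("blade-", seq_len(m), "-a"),
                             paste0("blade-", seq_len(m), "-b"))))
  W <- matrix(0, N, N, dimnames = list(nodes, nodes))
  pairs <- cbind(2L * seq_len(m), 2L * seq_len(m) + 1L)
  for (i in seq_len(m)) {
    a <- pairs[i, 1L]; b <- pairs[i, 2L]
    W[a, b] <- W[b, a] <- 1
    W[1L, a] <- W[a, 1L] <- hub_coupling
    W[1L, b] <- W[b, 1L] <- hub_coupling
  }
  new_weighted_graph(W, family = "fan",
                     meta = list(hub_coupling = hub_coupling,
                                 orbits = list(singletons = c(center = 1L),
                                               counts = list(),
                                               pairs = list(blade = pairs))))
}

#' Composite simultaneous Bd/dB amplifier
#'
#' Builds the two-chunk weighted structure designed to amplify selection
#' under both update rules. One chunk (the Birth-death side) is a fan-like
#' graph with `a` hub nodes forming a unit-weight clique and `b` two-node
#' blades attached to every hub node by a weak coupling; the other chunk
#' (the death-Birth side) is a fan on `f` nodes. The two chunks are joined
#' by a single edge of weight \eqn{t^{-3}} between a designated hub node
#' `u` and the fan center `v`. After construction, `u`'s remaining
#' incident weights are rescaled to total \eqn{t^{-1}} and `v`'s remaining
#' incident weights to total 1, so that migration along the connecting
#' edge is strongly asymmetric: under Birth-death updating offspring flow
#' mostly from `u` to `v`, under death-Birth updating mostly from `v` to
#' `u`. Total size is \eqn{N = a + 2b + f}.
#'
#' @param a Hub size of the Birth-death chunk (at least 1).
#' @param b Number of two-node blades in the Birth-death chunk (at least 1).
#' @param f Node count of the fan chunk; must be odd and at least 3.
#' @param t Separation parameter (> 1); large `t` makes the chunks
#'   interact rarely. Default 100.
#' @param blade_coupling Weight of each blade-hub edge in the Birth-death
#'   chunk before rescaling; default `0.01 / a` so each blade node's total
#'   attachment to the hub is weak compared to its within-blade edge.
#' @param fan_coupling Blade-center coupling of the fan chunk; default
#'   `1 / (f - 1)` so `v`'s within-chunk weight totals 1 exactly.
#'
#' @return A `weighted_graph` with family `"an"`. The designated endpoint
#'   nodes are retrievable with [designated_nodes()].
#' @export
#' @examples
#' g <- make_amplifier_an(a = 5, b = 5, f = 11, t = 100)  # N = 26
#' designated_nodes(g)
make_amplifier_an <- function(a, b, f, t = 100,
                              blade_coupling = 0.01 / a,
                              fan_coupling = 1 / (f - 1)) {
  a <- check_scalar_count(a, "a", min = 1)
  b <- check_scalar_count(b, "b", min = 1)
  f <- check_scalar_count(f, "f", min = 3)
  if (f %% 2L == 0L) abort_validation("`f` must be odd (a fan has f = 2m + 1 nodes)")
  t <- check_scalar_positive(t, "t")
  if (t <= 1) abort_validation("`t` must exceed 1 (the chunks must interact rarely)")
  blade_coupling <- check_scalar_positive(blade_coupling, "blade_coupling")
  fan_coupling <- check_scalar_positive(fan_coupling, "fan_coupling")
  N <- a + 2L * b + f
  if (N < 4L) abort_validation("total size a + 2b + f must be at least 4")

  hub <- paste0("hub-", seq_len(a))
  ablades <- as.vector(rbind(paste0("ablade-", seq_len(b), "-a"),
                             paste0("ablade-", seq_len(b), "-b")))
  m <- (f - 1L) %/% 2L
  fnodes <- c("fan-center",
              as.vector(rbind(paste0("fblade-", seq_len(m), "-a"),
                              paste0("fblade-", seq_len(m), "-b"))))
  nodes <- c(hub, ablades, fnodes)
  W <- matrix(0, N, N, dimnames = list(nodes, nodes))

  ih <- seq_len(a)                       # hub nodes; u = hub-1
  iab <- a + seq_len(2L * b)             # blade nodes of the Bd chunk
  iu <- 1L
  iv <- a + 2L * b + 1L                  # fan center
  ifb <- iv + seq_len(f - 1L)            # fan blade nodes

  if (a > 1L) {
    W[ih, ih] <- 1
    diag(W)[ih] <- 0
  }
  apairs <- cbind(a + 2L * seq_len(b) - 1L, a + 2L * seq_len(b))
  for (i in seq_len(b)) {
    x <- apairs[i, 1L]; y <- apairs[i, 2L]
    W[x, y] <- W[y, x] <- 1
    W[ih, x] <- W[x, ih] <- blade_coupling
    W[ih, y] <- W[y, ih] <- blade_coupling
  }
  fpairs <- cbind(iv + 2L * seq_len(m) - 1L, iv + 2L * seq_len(m))
  for (i in seq_len(m)) {
    x <- fpairs[i, 1L]; y <- fpairs[i, 2L]
    W[x, y] <- W[y, x] <- 1
    W[iv, x] <- W[x, iv] <- fan_coupling
    W[iv, y] <- W[y, iv] <- fan_coupling
  }
  # Connecting edge and the weight-total contract at its endpoints:
  # w(u, v) = t^-3; u's other incident weight totals t^-1; v's totals 1.
  W[iu, iv] <- W[iv, iu] <- t^-3
  su <- sum(W[iu, -iv])
  W[iu, -iv] <- W[iu, -iv] * (t^-1 / su)
  W[-iv, iu] <- W[iu, -iv]
  sv <- sum(W[iv, -iu])
  W[iv, -iu] <- W[iv, -iu] / sv
  W[-iu, iv] <- W[iv, -iu]

  new_weighted_graph(
    W, family = "an",
    meta = list(
      params = list(a = a, b = b, f = f, t = t,
                    blade_coupling = blade_coupling,
                    fan_coupling = fan_coupling),
      u = iu, v = iv,
      bd_chunk = c(ih, iab), db_chunk = c(iv, ifb),
      orbits = list(
        singletons = c(u = iu, v = iv),
        counts = if (a > 1L) list(hub = ih[-1L]) else list(),
        pairs = list(ablade = apairs, fblade = fpairs)
      )
    )
  )
}

#' Designated endpoint nodes of a composite amplifier
#'
#' @param g A graph built by [make_amplifier_an()].
#' @return Named character vector with elements `u` (Birth-death chunk
#'   endpoint) and `v` (fan center).
#' @export
designated_nodes <- function(g) {
  if (!identical(g$family, "an")) abort_family("`g` must be built by make_amplifier_an()")
  c(u = g$nodes[g$meta$u], v = g$nodes[g$meta$v])
}

# Induced subgraph on a set of node indices; used by the chunk-coupling
# approximation to solve each chunk in isolation.
induced_subgraph <- function(g, idx) {
  new_weighted_graph(g$W[idx, idx, drop = FALSE])
}

# ---------------------------------------------------------------------------
# Structural quantities
# ---------------------------------------------------------------------------

#' Weighted degree
#'
#' \eqn{\deg(v) = \sum_{v'} w(v, v')}, the total weight of edges incident
#' to `v`.
#'
#' @param g A `weighted_graph`.
#' @param v Node label(s); default all nodes.
#' @return Named numeric vector of degrees.
#' @export
weighted_degree <- function(g, v = NULL) {
  if (is.null(v)) return(g$deg)
  g$deg[node_index(g, v)]
}

#' Node temperature
#'
#' \eqn{T(u) = \sum_{v \sim u} w(v, u) / \deg(v)}: the rate at which node
#' `u` is replaced by its neighbours in the neutral Birth-death process.
#' Temperatures average to 1, i.e. \eqn{\sum_u T(u) = N} on any graph.
#' Hot nodes (\eqn{T > 1}) are replaced often; a single mutant placed
#' there tends to die quickly under Birth-death updating.
#'
#' @param g A `weighted_graph`.
#' @param u Node label(s); default all nodes.
#' @return Named numeric vector of temperatures.
#' @export
#' @examples
#' node_temperature(make_star(4))  # center is hot, leaves are cold
node_temperature <- function(g, u = NULL) {
  Tall <- colSums(g$W / g$deg)
  names(Tall) <- g$nodes
  if (is.null(u)) return(Tall)
  Tall[node_index(g, u)]
}

# ---------------------------------------------------------------------------
# Edge-list interchange format
# ---------------------------------------------------------------------------

#' Write a graph as a tab-separated edge list
#'
#' Three columns `node_a  node_b  weight`, one line per undirected edge,
#' weights printed at full double precision so that a round trip through
#' [read_edge_list()] is exact.
#'
#' @param g A `weighted_graph`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(g, path) {
  up <- which(upper.tri(g$W) & g$W > 0, arr.ind = TRUE)
  lines <- c(
    "# weighted undirected edge list: node_a<TAB>node_b<TAB>weight",
    sprintf("%s\t%s\t%.17g", g$nodes[up[, 1L]], g$nodes[up[, 2L]], g$W[up])
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a weighted graph from a tab-separated edge list
#'
#' Accepts `#`-prefixed comment lines. Rejects duplicate edges,
#' self-loops, and non-positive weights.
#'
#' @param path Input file path.
#' @return A `weighted_graph`.
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) abort_validation(sprintf("file not found: %s", path))
  df <- tryCatch(
    read.table(path, sep = "\t", comment.char = "#", header = FALSE,
               col.names = c("from", "to", "weight"),
               colClasses = c("character", "character", "numeric"),
               quote = "", strip.white = TRUE),
    error = function(e) abort_validation(sprintf("malformed edge list: %s", conditionMessage(e)))
  )
  weighted_graph(df)
}

# ---------------------------------------------------------------------------
# Seeded random fixture generator
# ---------------------------------------------------------------------------

#' Random connected weighted graph
#'
#' Draws a uniform random spanning tree skeleton (each node attaches to a
#' uniformly chosen earlier node), adds each remaining pair independently
#' with probability `edge_density`, and assigns log-uniform weights. The
#' result is always connected and valid; identical seeds give identical
#' graphs. This is the fixture generator behind the property sweeps for
#' the neutral-fixation and first-step-bias impossibility checks.
#'
#' @param n Number of nodes (at least 2).
#' @param edge_density Probability in \[0, 1\] of including each non-tree
#'   pair.
#' @param weight_range Length-2 positive vector; weights are drawn
#'   log-uniformly between the two values.
#' @param seed Optional integer seed (caller's RNG state is preserved).
#' @return A connected `weighted_graph`.
#' @export
#' @examples
#' g1 <- random_connected_graph(6, seed = 42)
#' g2 <- random_connected_graph(6, seed = 42)
#' identical(g1$W, g2$W)
random_connected_graph <- function(n, edge_density = 0.3,
                                   weight_range = c(0.1, 10), seed = NULL) {
  n <- check_scalar_count(n, "n", min = 2)
  if (!is.numeric(edge_density) || length(edge_density) != 1L ||
      is.na(edge_density) || edge_density < 0 || edge_density > 1) {
    abort_validation("`edge_density` must be a probability in [0, 1]")
  }
  if (length(weight_range) != 2L || any(weight_range <= 0) ||
      weight_range[1L] > weight_range[2L]) {
    abort_validation("`weight_range` must be two positive increasing values")
  }
  with_preserved_seed(seed, {
    from <- integer(0); to <- integer(0)
    for (i in seq_len(n)[-1L]) {
      from <- c(from, if (i == 2L) 1L else sample.int(i - 1L, 1L))
      to <- c(to, i)
    }
    if (n > 2L) {
      cand <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
      key <- paste(cand[, 1L], cand[, 2L])
      tree_key <- paste(pmin(from, to), pmax(from, to))
      cand <- cand[!(key %in% tree_key), , drop = FALSE]
      take <- runif(nrow(cand)) < edge_density
      from <- c(from, cand[take, 1L])
      to <- c(to, cand[take, 2L])
    }
    w <- exp(runif(length(from), log(weight_range[1L]), log(weight_range[2L])))
    nodes <- paste0("v", seq_len(n))
    weighted_graph(data.frame(from = nodes[from], to = nodes[to], weight = w),
                   nodes = nodes)
  })
}
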