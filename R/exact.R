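# Exact fixation probabilities by sparse linear solve of the absorbing
# Markov chain on the full 2^N configuration space.
#
# Configurations are encoded as N-bit masks in node order. The absorption
# system is solved on the transient subspace after conditioning each row on
# a configuration-changing event (the embedded jump chain), which leaves
# fixation probabilities unchanged and keeps the system well conditioned
# even when edge weights span many orders of magnitude.

exact_chain_h <- function(g, process) {
  N <- n_nodes(g)
  r <- process$r
  bd <- process$kind == "Bd"
  S <- 2L^N - 2L
  masks <- as.numeric(seq_len(S))
  bits <- 2^(seq_len(N) - 1L)
  M <- outer(masks, bits, function(m, b) floor(m / b) %% 2 == 1)
  k <- rowSums(M)
  deg <- g$deg
  if (!bd) Wmut <- M %*% g$W
  ed <- g$ed
  ne <- length(ed$from)
  rowtot <- numeric(S)
  ti <- vector("list", ne); tj <- ti; tx <- ti
  for (e in seq_len(ne)) {
    u <- ed$from[e]; v <- ed$to[e]; w <- ed$w[e]
    ch <- which(M[, u] != M[, v])
    if (!length(ch)) next
    gain <- M[ch, u]
    fu <- ifelse(gain, r, 1)
    p <- if (bd) {
      fu * w / ((N + (r - 1) * k[ch]) * deg[u])
    } else {
      fu * w / (N * (deg[v] + (r - 1) * Wmut[ch, v]))
    }
    rowtot[ch] <- rowtot[ch] + p
    ti[[e]] <- ch
    tj[[e]] <- masks[ch] + ifelse(gain, bits[v], -bits[v])
    tx[[e]] <- p
  }
  i <- unlist(ti); j <- unlist(tj); x <- unlist(tx)
  x <- x / rowtot[i]
  full <- 2^N - 1
  b <- numeric(S)
  isfix <- j == full
  if (any(isfix)) {
    bf <- rowsum(x[isfix], i[isfix])
    b[as.integer(rownames(bf))] <- bf[, 1L]
  }
  keep <- !isfix & j != 0
  Q <- Matrix::sparseMatrix(i = i[keep], j = j[keep], x = x[keep], dims = c(S, S))
  A <- Matrix::Diagonal(S) - Q
  h <- as.numeric(Matrix::solve(A, b))
  residual <- max(abs(as.numeric(A %*% h) - b))
  list(h = c(0, h, 1), residual = residual)  # indexed by mask + 1
}

init_mask_index <- function(g, init) {
  bits <- 2^(seq_len(n_nodes(g)) - 1L)
  if (length(init) == 0L) return(1L)
  sum(bits[node_index(g, init)]) + 1
}

#' Exact fixation probability (full-state absorbing chain)
#'
#' Builds the \eqn{2^N}-configuration Markov chain from the one-step
#' replacement distribution and solves the linear absorption system with a
#' sparse direct solver. Uniform initialization averages the N
#' single-mutant solutions, \eqn{\rho(G) = \frac1N \sum_v \rho(G, \{v\})}.
#'
#' @param g A connected `weighted_graph`.
#' @param process A [moran_process()].
#' @param init `"uniform"`, or a character vector of node labels giving a
#'   fixed initial mutant set (the empty vector gives 0, the full node set
#'   gives 1).
#' @param n_max State-space cap: graphs with more than `n_max` nodes are
#'   refused with a capacity error pointing to the lumped and Monte Carlo
#'   backends. Default 20 (about a million states); memory grows as
#'   \eqn{2^N |E|}, so dense graphs near the cap need substantial RAM.
#' @return A `fixation_result` with `method = "exact"`; the linear-solver
#'   residual is reported in `$residual`.
#' @export
#' @examples
#' solve_fixation_exact(make_complete(3), moran_process("Bd", 2))  # 4/7
solve_fixation_exact <- function(g, process, init = "uniform", n_max = 20) {
  require_connected(g)
  N <- n_nodes(g)
  if (N > n_max) {
    abort_capacity(sprintf(
      "N = %d exceeds the full-state cap (%d): use solve_fixation_lumped() for a supported family or estimate_fixation_probability() for Monte Carlo",
      N, n_max))
  }
  ch <- exact_chain_h(g, process)
  p <- if (identical(init, "uniform")) {
    mean(ch$h[2^(seq_len(N) - 1L) + 1])
  } else {
    ch$h[init_mask_index(g, init)]
  }
  fixation_result(probability = p, method = "exact", residual = ch$residual,
                  kind = process$kind, r = process$r,
                  init = if (identical(init, "uniform")) "uniform" else paste(init, collapse = ","))
}

#' Fixation probability from each start node
#'
#' \eqn{\rho(G, \{v\})} for every node `v`, via one full-state (or lumped)
#' solve.
#'
#' @inheritParams solve_fixation_exact
#' @param method `"exact"` or `"lumped"`.
#' @param ... Passed to the backend solver.
#' @return Named numeric vector over nodes.
#' @export
fixation_by_node <- function(g, process, method = c("exact", "lumped"), ...) {
  method <- match.arg(method)
  require_connected(g)
  N <- n_nodes(g)
  if (method == "exact") {
    args <- list(...)
    n_max <- if (!is.null(args$n_max)) args$n_max else 20
    if (N > n_max) abort_capacity(sprintf("N = %d exceeds the full-state cap (%d)", N, n_max))
    ch <- exact_chain_h(g, process)
    setNames(ch$h[2^(seq_len(N) - 1L) + 1], g$nodes)
  } else {
    sol <- lumped_chain_solution(g, process, ...)
    setNames(sol$h_of_key[sol$node_keys], g$nodes)
  }
}
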