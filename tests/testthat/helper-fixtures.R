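# Fixture graphs built in code: regular graphs for isothermal checks and
# seeded random weighted graphs for the property sweeps.

cycle_graph <- function(n) {
  nodes <- paste0("c", seq_len(n))
  weighted_graph(data.frame(from = nodes, to = nodes[c(2:n, 1L)], weight = 1),
                 nodes = nodes)
}

# 3-regular graphs
cube_graph <- function() {
  # vertices = 3-bit strings, edges between strings differing in one bit
  v <- 0:7
  e <- do.call(rbind, lapply(v, function(x) {
    nb <- bitwXor(x, c(1L, 2L, 4L))
    nb <- nb[nb > x]
    data.frame(from = rep(x, length(nb)), to = nb)
  }))
  weighted_graph(data.frame(from = paste0("q", e$from), to = paste0("q", e$to),
                            weight = 1))
}

petersen_graph <- function() {
  outer_e <- data.frame(from = paste0("o", 1:5), to = paste0("o", c(2:5, 1)))
  spoke_e <- data.frame(from = paste0("o", 1:5), to = paste0("i", 1:5))
  inner_e <- data.frame(from = paste0("i", 1:5), to = paste0("i", c(3, 4, 5, 1, 2)))
  e <- rbind(outer_e, spoke_e, inner_e)
  e$weight <- 1
  weighted_graph(e)
}

k33_graph <- function() {
  e <- expand.grid(from = paste0("l", 1:3), to = paste0("r", 1:3),
                   stringsAsFactors = FALSE)
  e$weight <- 1
  weighted_graph(e)
}

random_fixture_set <- function(n_graphs, seed, n_range = 4:8) {
  lapply(seq_len(n_graphs), function(i) {
    n <- n_range[1L + (i - 1L) %% length(n_range)]
    random_connected_graph(n, edge_density = 0.2 + 0.6 * ((i * 7L) %% 10L) / 10,
                           weight_range = c(0.1, 10), seed = seed + i)
  })
}

expect_within <- function(object, expected, tol) {
  expect_true(abs(object - expected) <= tol,
              label = sprintf("|%g - %g| <= %g", object, expected, tol))
}
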