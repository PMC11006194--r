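test_that("one-step distributions are normalized, edge-supported and match hand calculations", {
  # two nodes, one mutant with r = 2: mutant reproduces w.p. f(u)/F = 2/3
  k2 <- make_complete(2)
  d <- replacement_distribution(k2, "v1", moran_process("Bd", 2))
  expect_equal(d$probability[d$source == "v1"], 2 / 3)
  expect_equal(sum(d$probability), 1)

  # neutral death-Birth: every node dies w.p. 1/N, neighbours fill
  # proportionally to w/deg
  g <- random_fixture_set(1, seed = 7)[[1]]
  n <- n_nodes(g)
  d <- replacement_distribution(g, g$nodes[1], moran_process("dB", 1))
  death_mass <- tapply(d$probability, d$target, sum)
  expect_equal(as.vector(death_mass[g$nodes]), rep(1 / n, n))
  for (v in g$nodes) {
    rows <- d[d$target == v, ]
    expect_equal(rows$probability,
                 unname(g$W[cbind(rows$source, v)] / (n * weighted_degree(g, v))),
                 tolerance = 1e-12)
  }

  # support only on edges; total mass 1 for random states under both rules
  set.seed(99)
  for (gg in random_fixture_set(5, seed = 500)) {
    mem <- logical(n_nodes(gg))
    mem[sample.int(n_nodes(gg), n_nodes(gg) %/% 2)] <- TRUE
    if (!any(mem)) mem[1] <- TRUE
    for (kind in c("Bd", "dB")) {
      d <- replacement_distribution(gg, gg$nodes[mem], moran_process(kind, 1.3))
      expect_within(sum(d$probability), 1, 1e-12)
      expect_true(all(gg$W[cbind(d$source, d$target)] > 0))
      expect_equal(attr(d, "no_change"), sum(d$probability[!d$changes]))
    }
  }
})

test_that("absorbing configurations are refused by the step kernels", {
  g <- make_complete(4)
  pr <- moran_process("Bd", 1.5)
  expect_error(replacement_distribution(g, character(0), pr),
               class = "moranamp_absorbing_error")
  expect_error(replacement_distribution(g, g$nodes, pr),
               class = "moranamp_absorbing_error")
  expect_error(moran_step(g, g$nodes, pr), class = "moranamp_absorbing_error")
})

test_that("trajectories are reproducible under a fixed seed and flip one node per step", {
  g <- random_fixture_set(1, seed = 21)[[1]]
  pr <- moran_process("dB", 1.2)
  run <- function() {
    set.seed(303)
    states <- list(cur <- g$nodes[1])
    while (length(cur) > 0 && length(cur) < n_nodes(g)) {
      nxt <- moran_step(g, cur, pr)
      expect_lte(length(setdiff(union(cur, nxt), intersect(cur, nxt))), 1L)
      states[[length(states) + 1L]] <- cur <- nxt
    }
    states
  }
  expect_identical(run(), run())

  # compiled engine: same seed, byte-identical outcome and step sequences
  e1 <- estimate_fixation_probability(g, "uniform", pr, replicates = 200, seed = 4)
  e2 <- estimate_fixation_probability(g, "uniform", pr, replicates = 200, seed = 4)
  expect_identical(e1$probability, e2$probability)
  expect_identical(e1$mean_steps, e2$mean_steps)
})

test_that("a full initial mutant set fixes with probability one", {
  g <- make_star(5)
  est <- estimate_fixation_probability(g, g$nodes, moran_process("Bd", 1),
                                       replicates = 50, seed = 1)
  expect_equal(est$probability, 1)
  expect_equal(est$capped, 0L)
})

test_that("Monte Carlo agrees with the exact solver on random graphs", {
  fixtures <- random_fixture_set(6, seed = 900, n_range = 5:7)
  for (i in seq_along(fixtures)) {
    g <- fixtures[[i]]
    kind <- if (i %% 2 == 0) "Bd" else "dB"
    pr <- moran_process(kind, 1.3)
    exact <- solve_fixation_exact(g, pr)$probability
    mc <- estimate_fixation_probability(g, "uniform", pr, replicates = 4000,
                                        seed = 1000 + i)
    expect_within(mc$probability, exact, 4 * mc$std_error)
  }
})

test_that("uniform-init estimates match the well-mixed closed form on K_10 and C_8", {
  k10 <- make_complete(10)
  mc <- estimate_fixation_probability(k10, "uniform", moran_process("Bd", 2),
                                      replicates = 1e5, seed = 77)
  expect_within(mc$probability, rho_complete(10, 2, "Bd"), 3 * mc$std_error)

  # regular graphs share the complete-graph Bd fixation probability
  c8 <- cycle_graph(8)
  mc2 <- estimate_fixation_probability(c8, "uniform", moran_process("Bd", 1.5),
                                       replicates = 2e4, seed = 78)
  expect_within(mc2$probability, rho_complete(8, 1.5, "Bd"), 3 * mc2$std_error)
})

test_that("neutral death-Birth fixation from a fixed node tracks relative degree", {
  g <- random_fixture_set(1, seed = 55, n_range = 6)[[1]]
  v <- g$nodes[3]
  expected <- unname(weighted_degree(g, v) / sum(weighted_degree(g)))
  mc <- estimate_fixation_probability(g, v, moran_process("dB", 1),
                                      replicates = 8000, seed = 5)
  expect_within(mc$probability, expected, 4 * mc$std_error)
})
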