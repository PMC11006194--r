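test_that("full-state solver reproduces hand-computed and closed-form values", {
  # K_3, Bd, r = 2: (1 - 1/2)/(1 - 1/8) = 4/7
  expect_within(solve_fixation_exact(make_complete(3), moran_process("Bd", 2))$probability,
                4 / 7, 1e-12)
  # absorbing inits
  g <- make_star(5)
  pr <- moran_process("dB", 1.3)
  expect_equal(solve_fixation_exact(g, pr, init = character(0))$probability, 0)
  expect_equal(solve_fixation_exact(g, pr, init = g$nodes)$probability, 1)
  # a fixed single node equals the per-node solution
  expect_equal(solve_fixation_exact(g, pr, init = "leaf-2")$probability,
               unname(fixation_by_node(g, pr)["leaf-2"]))
})

test_that("Bd fixation on regular graphs equals the complete-graph value", {
  for (r in c(0.9, 1.1, 1.5)) {
    pr <- moran_process("Bd", r)
    expect_within(solve_fixation_exact(cycle_graph(6), pr)$probability,
                  rho_complete(6, r, "Bd"), 1e-10)
    expect_within(solve_fixation_exact(cube_graph(), pr)$probability,
                  rho_complete(8, r, "Bd"), 1e-10)
  }
})

test_that("solver refuses oversized graphs with a capacity error", {
  g <- make_complete(6)
  expect_error(solve_fixation_exact(g, moran_process("Bd", 1.1), n_max = 5),
               class = "moranamp_capacity_error")
  expect_error(fixation_by_node(g, moran_process("Bd", 1.1), n_max = 5),
               class = "moranamp_capacity_error")
})

test_that("fixation probability is monotone in the initial mutant set", {
  for (g in random_fixture_set(4, seed = 1200, n_range = 5:6)) {
    n <- n_nodes(g)
    bits <- 2^(seq_len(n) - 1L)
    for (kind in c("Bd", "dB")) {
      h <- moranamp:::exact_chain_h(g, moran_process(kind, 1.2))$h
      for (mask in 0:(2^n - 2)) {
        for (v in which(bitwAnd(mask, bits) == 0)) {
          expect_gte(h[mask + bits[v] + 1], h[mask + 1] - 1e-12)
        }
      }
    }
  }
})

test_that("lumped chains equal the full-state solver on every family", {
  cases <- list(
    list(g = make_complete(8)),
    list(g = make_star(7)),
    list(g = make_fan(2, hub_coupling = 0.05)),
    list(g = make_fan(3, hub_coupling = 0.01)),
    list(g = make_amplifier_an(a = 1, b = 1, f = 5, t = 20)),   # N = 8
    list(g = make_amplifier_an(a = 2, b = 2, f = 3, t = 10))    # N = 9
  )
  for (cs in cases) {
    for (kind in c("Bd", "dB")) {
      for (r in c(1, 1.1, 1.5)) {
        pr <- moran_process(kind, r)
        pl <- solve_fixation_lumped(cs$g, pr)$probability
        pe <- solve_fixation_exact(cs$g, pr)$probability
        expect_within(pl, pe, 1e-10)
      }
    }
  }
  # fixed-set initialization goes through the same class machinery
  g <- make_fan(3)
  init <- c("fan-center", "blade-2-a")
  pr <- moran_process("dB", 1.2)
  expect_within(solve_fixation_lumped(g, pr, init = init)$probability,
                solve_fixation_exact(g, pr, init = init)$probability, 1e-10)
})

test_that("lumped star chain shows strict Bd amplification across the benchmark grid", {
  s11 <- make_star(11)
  for (r in seq(1.01, 1.1, by = 0.01)) {
    expect_gt(solve_fixation_lumped(s11, moran_process("Bd", r))$probability,
              rho_complete(11, r, "Bd"))
  }
})

test_that("lumped complete chain matches the closed form at N = 50", {
  expect_within(solve_fixation_lumped(make_complete(50), moran_process("Bd", 1.1))$probability,
                rho_complete(50, 1.1, "Bd"), 1e-10)
  expect_within(solve_fixation_lumped(make_complete(50), moran_process("dB", 1.1))$probability,
                rho_complete(50, 1.1, "dB"), 1e-10)
})

test_that("graphs without family structure are refused by the lumped backend", {
  g <- random_fixture_set(1, seed = 2)[[1]]
  expect_error(solve_fixation_lumped(g, moran_process("Bd", 1.1)),
               class = "moranamp_family_error")
})

test_that("neutral exact solutions equal the degree-based closed forms", {
  for (g in random_fixture_set(10, seed = 1500, n_range = 4:7)) {
    for (kind in c("Bd", "dB")) {
      exact <- fixation_by_node(g, moran_process(kind, 1))
      expect_true(max(abs(exact - neutral_fixation(g, kind = kind))) < 1e-8)
    }
  }
})

test_that("disconnected graphs are rejected by fixation operations", {
  e <- data.frame(from = c("a", "c"), to = c("b", "d"), weight = 1)
  g <- weighted_graph(e)
  expect_false(g$connected)
  expect_error(solve_fixation_exact(g, moran_process("Bd", 1.1)),
               class = "moranamp_validation_error")
  expect_error(estimate_fixation_probability(g, "uniform", moran_process("Bd", 1.1),
                                             replicates = 10),
               class = "moranamp_validation_error")
})
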