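test_that("complete-graph closed forms behave across N and r", {
  expect_equal(rho_complete(11, 1.1, "Bd"), (1 - 1 / 1.1) / (1 - 1.1^-11))
  # neutral limit is 1/N for both rules
  expect_equal(rho_complete(9, 1, "Bd"), 1 / 9)
  expect_equal(rho_complete(9, 1, "dB"), 1 / 9)
  expect_within(rho_complete(9, 1 + 1e-9, "Bd"), 1 / 9, 1e-8)
  expect_within(rho_complete(9, 1 + 1e-9, "dB"), 1 / 9, 1e-8)
  # death-Birth value is (N-1)/N times the Birth-death value one size down
  for (N in c(2:6, 20, 50, 200)) {
    r <- seq(0.5, 3, by = 0.25)
    expect_equal(rho_complete(N, r, "dB"),
                 if (N == 2) rep(1 / 2, length(r)) else (N - 1) / N * rho_complete(N - 1, r, "Bd"),
                 tolerance = 1e-12)
  }
  # strictly increasing in r
  grid <- rho_complete(12, seq(1.01, 2, by = 0.01), "Bd")
  expect_true(all(diff(grid) > 0))
})

test_that("first-step survival matches its closed forms and baselines", {
  # complete and regular graphs sit exactly at r/(r+1) under Bd
  for (g in list(make_complete(6), cycle_graph(7), cube_graph(), petersen_graph(), k33_graph())) {
    for (r in c(1, 1.2, 1.7)) {
      gr <- gamma_first_step(g, g$nodes[1], moran_process("Bd", r))
      expect_within(gr$gamma, r / (r + 1), 1e-12)
    }
  }
  # neutral death-Birth on the complete graph: 1/2
  gd <- gamma_first_step(make_complete(8), "v2", moran_process("dB", 1))
  expect_within(gd$gamma, 1 / 2, 1e-12)
  # generic conditioning equals the closed-form fast paths on random fixtures
  for (g in random_fixture_set(10, seed = 3000)) {
    u <- g$nodes[1 + (n_nodes(g) %% 3)]
    for (kind in c("Bd", "dB")) {
      for (r in c(1, 1.3)) {
        pr <- moran_process(kind, r)
        expect_within(gamma_first_step(g, u, pr, "generic")$gamma,
                      gamma_first_step(g, u, pr, "closed-form")$gamma, 1e-12)
      }
    }
  }
  # hot star center: gamma_Bd = r/(r + (N-1))
  gs <- gamma_first_step(make_star(9), "center", moran_process("Bd", 1.4))
  expect_within(gs$gamma, 1.4 / (1.4 + 8), 1e-12)
  expect_equal(gs$temperature, 8)
})

test_that("simulated first-event frequencies match the conditioned computation", {
  fixtures <- random_fixture_set(2, seed = 4000, n_range = 5:6)
  for (i in seq_along(fixtures)) {
    g <- fixtures[[i]]
    kind <- c("Bd", "dB")[i]
    pr <- moran_process(kind, 1.2)
    u <- g$nodes[2]
    gam <- gamma_first_step(g, u, pr)$gamma
    al <- moranamp:::adjacency_lists(g)
    reps <- 2e4
    surv <- withr::with_seed(10 + i, {
      moranamp:::mc_first_event_cpp(al$nbr, al$nbw, g$deg, kind == "Bd",
                                    1.2, which(g$nodes == u), reps)
    })
    phat <- mean(surv)
    se <- sqrt(gam * (1 - gam) / reps)
    expect_within(phat, gam, 4 * se)
  }
})

test_that("neutral closed forms give the known star values", {
  s4 <- make_star(4)
  expect_within(unname(neutral_fixation(s4, "leaf-1", "dB")), 1 / 6, 1e-12)
  expect_within(unname(neutral_fixation(s4, "leaf-1", "Bd")), 3 / 10, 1e-12)
  expect_equal(unname(neutral_fixation(make_complete(5), kind = "Bd")), rep(1 / 5, 5))
})

test_that("no start node beats the well-mixed baseline under both rules at neutrality", {
  expect_equal(check_theorem1(make_complete(6), "v3")$label, "both-equal")
  # star leaf: better than 1/N under Bd, worse under dB
  expect_equal(check_theorem1(make_star(4), "leaf-1")$label, "dB-below")
  # star center: the reverse
  expect_equal(check_theorem1(make_star(4), "center")$label, "Bd-below")
  for (g in random_fixture_set(100, seed = 5000)) {
    for (v in g$nodes) {
      expect_no_error(check_theorem1(g, v))
    }
  }
})

test_that("no node beats both first-step baselines; hot nodes lose under Bd", {
  # complete graph: exactly at both baselines
  expect_equal(check_theorem2(make_complete(6), "v2", 1.3)$label, "both-equal")
  # regular but incomplete: the Bd survival sits exactly at r/(r+1), while
  # the dB survival falls strictly below its complete-graph baseline
  cyc <- check_theorem2(cycle_graph(6), "c2", 1.3)
  expect_equal(cyc$label, "dB-below")
  expect_within(cyc$gamma_bd, 1.3 / 2.3, 1e-12)
  expect_lt(cyc$gamma_db, cyc$base_db)
  res <- check_theorem2(make_star(8), "center", 1.2)
  expect_equal(res$label, "Bd-below")
  expect_gt(res$temperature, 1)
  for (g in random_fixture_set(100, seed = 6000)) {
    u <- g$nodes[1]
    for (r in c(1, 1.1, 1.5)) {
      expect_no_error(check_theorem2(g, u, r))
    }
  }
})

test_that("classification recovers the known amplifier/suppressor pattern at N = 11", {
  expect_equal(classify_graph(make_complete(11), moran_process("Bd", 1.05))$verdict,
               "equivalent")
  expect_equal(classify_graph(make_star(11), moran_process("Bd", 1.05))$verdict,
               "amplifier")
  expect_equal(classify_graph(make_star(11), moran_process("dB", 1.05))$verdict,
               "suppressor")
  f11 <- make_fan(5, hub_coupling = 0.01)
  expect_equal(classify_graph(f11, moran_process("dB", 1.05))$verdict, "amplifier")
  expect_equal(classify_graph(f11, moran_process("Bd", 1.05))$verdict, "suppressor")
})

test_that("monte-carlo classification reports uncertainty instead of overclaiming", {
  g <- make_star(7)
  v <- classify_graph(g, moran_process("Bd", 1.01), method = "monte-carlo",
                      replicates = 500, seed = 9)
  expect_true(v$verdict %in% c("amplifier", "suppressor", "inconclusive"))
  expect_false(is.na(v$std_error))
  expect_length(v$ci, 2L)
})

test_that("fitness sweeps tabulate ratios and record failed points as NA rows", {
  sc <- scan_fitness_grid(make_complete(7), "Bd", c(1.02, 1.05, 1.1))
  expect_equal(sc$ratio, rep(1, 3))
  expect_named(sc, c("r", "rho_graph", "rho_complete", "ratio", "method", "std_error"))
  # the lumped backend cannot handle an arbitrary graph: rows survive as NA
  g <- random_fixture_set(1, seed = 77)[[1]]
  ws <- capture_warnings(sc2 <- scan_fitness_grid(g, "Bd", c(1.1, 1.2), method = "lumped"))
  expect_length(ws, 2L)  # one recorded warning per failed grid point
  expect_match(ws, "failed", all = TRUE)
  expect_equal(nrow(sc2), 2L)
  expect_true(all(is.na(sc2$rho_graph)))
  expect_error(scan_fitness_grid(make_complete(4), "Bd", numeric(0)),
               class = "moranamp_validation_error")
})

test_that("the coarse chunk-coupled chain behaves like a gambler's ruin", {
  sym <- list(entry = c(bd_chunk = 0.25, db_chunk = 0.25),
              cross = list(
                bd_chunk = list(lambda_mut = 1e-4, lambda_res = 1e-4, q_mut = 0.3, q_res = 0.3),
                db_chunk = list(lambda_mut = 1e-4, lambda_res = 1e-4, q_mut = 0.3, q_res = 0.3)))
  res <- chunk_coupling_approximation(sym)
  expect_equal(unname(res$p_fix_given_half), c(0.5, 0.5))
  expect_equal(res$probability, 0.25)
  # strongly asymmetric migration drives the half-done state to fixation
  t <- 1e6
  asym <- sym
  asym$cross$bd_chunk$lambda_mut <- t * asym$cross$bd_chunk$lambda_res
  expect_within(chunk_coupling_approximation(asym)$p_fix_given_half["bd_chunk"], 1, 1e-5)
  # invalid rates are rejected
  bad <- sym
  bad$cross$bd_chunk$lambda_mut <- 0
  expect_error(chunk_coupling_approximation(bad), class = "moranamp_validation_error")
})

test_that("migration asymmetry along the connecting edge flips with the update rule", {
  g <- make_amplifier_an(a = 3, b = 3, f = 7, t = 50)
  inp_bd <- an_chunk_inputs(g, moran_process("Bd", 1.1))
  inp_db <- an_chunk_inputs(g, moran_process("dB", 1.1))
  # Bd: offspring flow mostly u -> v (the Bd chunk is upstream), ratio ~ t
  ratio_bd <- inp_bd$cross$bd_chunk$lambda_mut / inp_bd$cross$bd_chunk$lambda_res
  expect_gt(ratio_bd, 50 / 3)
  # dB: flow reverses, v -> u dominates
  ratio_db <- inp_db$cross$db_chunk$lambda_mut / inp_db$cross$db_chunk$lambda_res
  expect_gt(ratio_db, 50 / 3)
})
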