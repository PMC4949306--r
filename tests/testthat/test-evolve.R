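test_that("single-group contests obey the micro-rules in edge cases", {
  p <- standard_params()
  # both over-threshold: a standing double kowtow, RHP never moves
  set.seed(1)
  expect_equal(play_group(c(1.5, 1.5), p, contests = 30), rep(log(10), 2))
  # two unconditional fighters, one contest: one wins, one loses
  set.seed(2)
  out <- play_group(c(0, 0), p, contests = 1)
  expect_equal(sort(out), sort(log(c(9, 11))))
  expect_error(play_group(c(-0.1, 0.5), p, 5), "non-negative")
  expect_error(play_group(0.5, p, 5), "at least two")
})

test_that("group simulation means agree with the exact long-horizon payoff", {
  g <- contest_game(V = 0.1, C = 0.1, T = 200, k_max = 2)
  sim <- simulate(g, nsim = 10000, seed = 7, k_x = 1, k_y = 1)
  exact <- expected_payoff(1, 1, game_params(V = 0.1, C = 0.1, T = 200))
  se <- sd(sim$payoff_x) / sqrt(nrow(sim))
  expect_lt(abs(mean(sim$payoff_x) - exact), 3 * se)
})

test_that("generation updates keep a valid frequency vector", {
  cfg <- evolution_config(N = 2, params = game_params(V = 0.1, C = 0.1),
                          n_groups = 100, contests = 10, n_generations = 5)
  set.seed(3)
  state <- list(p = rep(0.1, 10), generation = 0L)
  for (i in 1:5) {
    state <- run_generation(state, cfg)
    expect_equal(sum(state$p), 1, tolerance = 1e-12)
    expect_true(all(state$p >= 0))
  }
  # a monomorphic population is absorbing
  mono <- list(p = c(rep(0, 5), 1, rep(0, 4)), generation = 0L)
  after <- run_generation(mono, cfg)
  expect_equal(after$p, mono$p)
})

test_that("lost strategies never reappear without mutation", {
  cfg <- evolution_config(N = 2, params = game_params(V = 0.1, C = 0.1),
                          n_groups = 150, contests = 20, n_generations = 60)
  evo <- run_evolution(cfg, seed = 9)
  tr <- evo$trajectory
  for (k in seq_len(ncol(tr))) {
    gone <- which(tr[, k] == 0)
    if (length(gone) > 0) {
      expect_true(all(tr[seq(min(gone), nrow(tr)), k] == 0),
                  label = colnames(tr)[k])
    }
  }
})

test_that("identical seeds reproduce the trajectory bit for bit", {
  cfg <- evolution_config(N = 3, params = game_params(V = 0.15, C = 0.1),
                          n_groups = 80, contests = 15, n_generations = 20)
  e1 <- run_evolution(cfg, seed = 42)
  e2 <- run_evolution(cfg, seed = 42)
  expect_identical(e1$trajectory, e2$trajectory)
  expect_identical(e1$ess, e2$ess)
})

test_that("pairwise evolution recovers the exact-analysis ESS class", {
  # the exact two-player solution is the yardstick for the simulation;
  # contest horizon matched to the analysis horizon T = 20
  sets <- list(c(V = 0.1, C = 0.1), c(V = 0.2, C = 0.1), c(V = 0.1, C = 0.2))
  for (vc in sets) {
    exact <- find_pure_ess(build_payoff_matrix(
      1:8, game_params(V = vc["V"], C = vc["C"], T = 20)))
    cfg <- evolution_config(N = 2,
                            params = game_params(V = vc["V"], C = vc["C"]),
                            contests = 20, n_groups = 400,
                            n_generations = 250)
    evo <- suppressWarnings(run_evolution(cfg, seed = 1))
    sim_k <- class_from_theta(evo$ess_mode, vc[["V"]], vc[["C"]])$k
    expect_equal(sim_k, exact$ess$k,
                 label = sprintf("V=%g C=%g", vc["V"], vc["C"]))
  }
})

test_that("declared ESS follows the concentration rule", {
  cfg <- evolution_config(N = 2, params = game_params(V = 0.1, C = 0.1),
                          contests = 20, n_groups = 300, n_generations = 120)
  evo <- run_evolution(cfg, seed = 4)
  if (evo$concentration >= 0.5) {
    expect_identical(evo$ess, evo$ess_mode)
  } else {
    expect_identical(evo$ess, evo$ess_mean)
  }
  log <- capture.output(s <- summary(evo))
  expect_identical(s$ess, evo$ess)
  expect_equal(s$concentration, max(evo$p))
  expect_true(evo$ess >= 0.1 && evo$ess <= 1)
})
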