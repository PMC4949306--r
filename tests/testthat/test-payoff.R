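test_that("difference-based win probability matches the RHP share", {
  expect_equal(win_prob_from_diff(0, 0.1, 0.1), 0.5)
  expect_equal(win_prob_from_diff(1, 0.1, 0.1), 0.55)
  expect_equal(win_prob_from_diff(5, 0.2, 0.05) +
                 win_prob_from_diff(-5, 0.2, 0.05), 1)
  # agrees with win_probability on explicitly constructed RHPs
  expect_equal(win_prob_from_diff(3, 0.1, 0.1),
               win_probability(10 * 1.1^3, 10 * 0.9^3))
})

test_that("tiny horizons have hand-computable expected payoffs", {
  p1 <- game_params(V = 0.1, C = 0.1, T = 1)
  expect_equal(expected_payoff(1, 1, p1), 0.5 * log(11) + 0.5 * log(9))
  expect_equal(expected_payoff_bruteforce(1, 1, p1),
               0.5 * log(11) + 0.5 * log(9))
  # both players immediately retreating leaves RHP untouched
  p <- standard_params()
  expect_equal(expected_payoff(0, 0, p), log(10))
  # a lone fighter milks the retreater for T rounds
  expect_equal(expected_payoff(1, 0, p), log(10) + 20 * log(1.1))
  expect_equal(expected_payoff(0, 1, p), log(10))
})

test_that("dynamic programming agrees with brute-force enumeration", {
  fix <- make_fixtures(202, n = 6)$random
  fix$T <- pmin(fix$T, 10L)
  for (i in seq_len(nrow(fix))) {
    p <- game_params(V = fix$V[i], C = fix$C[i], T = fix$T[i])
    for (kx in 1:3) for (ky in 1:3) {
      expect_equal(expected_payoff(kx, ky, p),
                   expected_payoff_bruteforce(kx, ky, p),
                   tolerance = 1e-10,
                   label = sprintf("log V=%g C=%g T=%d k=(%d,%d)",
                                   fix$V[i], fix$C[i], fix$T[i], kx, ky))
      expect_equal(expected_payoff(kx, ky, p, payoff = "share"),
                   expected_payoff_bruteforce(kx, ky, p, payoff = "share"),
                   tolerance = 1e-10)
    }
  }
  expect_error(expected_payoff_bruteforce(1, 1, standard_params(T = 20)),
               "enumeration guard")
})

test_that("share payoffs are complementary and symmetric on the diagonal", {
  p <- standard_params()
  for (kx in c(1L, 3L, 5L)) {
    expect_identical(expected_payoff(kx, kx, p, payoff = "share"), 0.5)
  }
  for (pair in list(c(1, 2), c(2, 5), c(4, 7))) {
    expect_equal(expected_payoff(pair[1], pair[2], p, payoff = "share") +
                   expected_payoff(pair[2], pair[1], p, payoff = "share"),
                 1, tolerance = 1e-12)
  }
})

test_that("exact payoffs match Monte-Carlo contest simulation", {
  # independent stochastic route through the micro-rules
  fix <- make_fixtures(303, n = 3)$random
  for (i in seq_len(nrow(fix))) {
    p <- game_params(V = fix$V[i], C = fix$C[i], T = fix$T[i])
    g <- contest_game(V = fix$V[i], C = fix$C[i], T = fix$T[i])
    sim <- simulate(g, nsim = 20000, seed = 1000 + i, k_x = 2, k_y = 3)
    exact <- expected_payoff(2, 3, p)
    se <- sd(sim$payoff_x) / sqrt(nrow(sim))
    expect_lt(abs(mean(sim$payoff_x) - exact), 3 * se + 1e-9)
  }
})

test_that("pure winner effect favours fighting to the end", {
  # C = 0: losses are free, so payoff is non-decreasing in own class
  p <- game_params(V = 0.1, C = 0, T = 20)
  for (ky in 1:8) {
    col <- vapply(1:8, function(kx) expected_payoff(kx, ky, p), 0)
    expect_true(all(diff(col) >= -1e-12), label = sprintf("ky=%d", ky))
  }
})

test_that("pure loser effect favours immediate retreat", {
  # V = 0: winning earns nothing, fighting only risks injury
  p <- game_params(V = 0, C = 0.1, T = 20)
  for (ky in 0:8) {
    passive <- expected_payoff(0, ky, p)
    for (kx in 1:8) {
      expect_gte(passive + 1e-12, expected_payoff(kx, ky, p))
    }
  }
})

test_that("generalised presets are rejected by the exact analysis", {
  gen <- game_params(V1 = 0.1, V2 = 0.05, C1 = 0.1)
  expect_error(expected_payoff(1, 1, gen), "unsupported preset")
  gen2 <- game_params(V = 0.1, C = 0.1, C2 = 0.05)
  expect_error(expected_payoff(1, 1, gen2), "unsupported preset")
})
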