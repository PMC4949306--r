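test_that("the fight decision uses the inclusive RHP-ratio rule", {
  expect_equal(decide_action(10, 10, 0.91), "fight")
  expect_equal(decide_action(10, 10, 1.0), "fight")   # tie at theta = 1
  expect_equal(decide_action(9, 11, 0.91), "retreat") # 9/11 < 0.91
  expect_equal(decide_action(11, 9, 1.2), "fight")    # 11/9 > 1.2 fails? no:
  # 11/9 = 1.222 >= 1.2, so fight; and the mirror retreats
  expect_equal(decide_action(9, 11, 1.2), "retreat")
  expect_error(decide_action(-1, 10, 0.5), "positive")
  expect_error(decide_action(10, 10, -0.1), "non-negative")
})

test_that("win probability is the RHP share and complements sum to one", {
  expect_equal(win_probability(10, 10), 0.5)
  expect_equal(win_probability(11, 9), 0.55)
  expect_equal(win_probability(10 * 1.1^2, 10 * 0.9^2), 1.21 / 2.02)
  set.seed(11)
  x <- runif(50, 0.1, 100); y <- runif(50, 0.1, 100)
  expect_equal(win_probability(x, y) + win_probability(y, x), rep(1, 50))
  expect_error(win_probability(0, 1), "positive")
})

test_that("outcomes update both RHPs by exactly one multiplicative factor", {
  p <- game_params(V = 0.1, C = 0.1)
  expect_equal(apply_outcome(10, 10, "x_wins_fight", p), c(11, 9))
  expect_equal(apply_outcome(10, 10, "double_kowtow", p), c(10, 10))
  expect_equal(apply_outcome(11, 9, "y_fights_x_retreats", p), c(11, 9.9))
  expect_error(apply_outcome(10, 10, "coin_toss", p), "unknown outcome")

  # each update changes each log RHP by one of the four admissible increments
  gen <- game_params(V1 = 0.12, V2 = 0.07, C1 = 0.2, C2 = 0.05)
  incr <- c(log1p(0.12), log1p(0.07), log1p(-0.2), log1p(-0.05), 0)
  for (out in c("x_wins_fight", "y_wins_fight", "x_fights_y_retreats",
                "y_fights_x_retreats", "double_kowtow")) {
    after <- apply_outcome(10, 10, out, gen)
    expect_true(all(sapply(log(after) - log(10),
                           function(d) any(abs(d - incr) < 1e-12))),
                info = out)
  }
})

test_that("RHP from a win/loss record is path independent", {
  p <- game_params(V = 0.1, C = 0.1)
  expect_equal(rhp_from_record(0, 0, p), 10)
  expect_equal(rhp_from_record(1, 1, p), 9.9)
  expect_equal(rhp_from_record(20, 0, p), 10 * 1.1^20)

  # agreement with sequential application of the micro-rules, any order
  set.seed(5)
  for (rep in 1:10) {
    wins <- sample(0:6, 1); losses <- sample(0:6, 1)
    seqn <- sample(c(rep("x_wins_fight", wins), rep("y_wins_fight", losses)))
    rhp <- c(10, 10)
    for (out in seqn) rhp <- apply_outcome(rhp[1], rhp[2], out, p)
    expect_equal(rhp[1], rhp_from_record(wins, losses, p))
  }
})

test_that("retreating is free under the default preset", {
  p <- game_params(V = 0.1, C = 0.1)
  rhp <- c(10, 10)
  for (i in 1:15) rhp <- apply_outcome(rhp[1], rhp[2], "y_fights_x_retreats", p)
  expect_equal(rhp[1], 10)           # constant RHP for the serial retreater
  expect_equal(rhp[2], 10 * 1.1^15)
})

test_that("parameter validation rejects degenerate contests", {
  expect_error(game_params(V = 0.1, C = 1), "degenerate")
  expect_error(game_params(V = -0.1, C = 0.1), "non-negative")
  expect_error(game_params(V = 0.1, C = 0.1, T = 0), "T must")
  expect_error(game_params(V = 0.1, C = 0.1, rhp_initial = 0), "positive")
  expect_error(game_params(), "supply either")
  expect_true(game_params(V = 0.1, C = 0.1)$default_preset)
  expect_false(game_params(V1 = 0.1, V2 = 0.2, C1 = 0.1)$default_preset)
})
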