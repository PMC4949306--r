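#' Win probability as a function of the win-loss difference
#'
#' Under the default preset both RHPs are determined by the win-loss
#' difference `d` of the focal individual, and the fight-win probability
#' reduces to `r^d / (r^d + 1)` with `r = (1+V)/(1-C)`. Computed in log
#' space so large `|d|` cannot overflow.
#'
#' @param d integer win-loss difference (vectorised).
#' @param V,C default-preset gain and loss proportions.
#' @return Probability that the individual with difference `d` wins the next
#'   fight.
#' @export
win_prob_from_diff <- function(d, V, C) {
  if (C >= 1) stop("degenerate parameters: C = 1", call. = FALSE)
  lr <- log1p(V) - log1p(-C)
  1 / (1 + exp(-d * lr))
}

# ---------------------------------------------------------------------------
# Exact machinery. The mutual-fight phase of a two-player contest is an
# absorbing random walk on d = wins - losses of player x: interior while
# -k_x < d < k_y, step +1 with probability win_prob_from_diff(d). On
# absorption the loser's RHP freezes (retreating is free, C2 = 0) while the
# winner gains a factor (1 + V) in each remaining round. A forward pass over
# (t, d) replaces the 2^T sum over outcome sequences; cost O(T * (k_x+k_y)).
# ---------------------------------------------------------------------------

# First-passage decomposition of the mutual-fight walk.
# Returns absorption events (time, boundary, probability) and the mass still
# interior at the horizon, by interior state d.
walk_absorption <- function(k_x, k_y, V, C, T) {
  stopifnot(k_x >= 1L, k_y >= 1L)
  states <- seq.int(-k_x + 1L, k_y - 1L)
  W <- win_prob_from_diff(states, V, C)
  p <- numeric(length(states))
  p[match(0L, states)] <- 1
  n <- length(states)
  ev_t <- integer(0); ev_side <- integer(0); ev_p <- numeric(0)
  for (t in seq_len(T)) {
    up <- p * W
    dn <- p * (1 - W)
    if (up[n] > 0) {                       # absorbed at +k_y: y concedes
      ev_t <- c(ev_t, t); ev_side <- c(ev_side, 1L); ev_p <- c(ev_p, up[n])
    }
    if (dn[1L] > 0) {                      # absorbed at -k_x: x concedes
      ev_t <- c(ev_t, t); ev_side <- c(ev_side, -1L); ev_p <- c(ev_p, dn[1L])
    }
    p <- c(dn[-1L], 0) + c(0, up[-n])
    if (sum(p) == 0) break
  }
  list(events = data.frame(t = ev_t, side = ev_side, prob = ev_p),
       censored = p, states = states)
}

# terminal log RHPs of both players given an absorption event or a censored
# interior state; side: +1 y concedes, -1 x concedes, 0 censored at T
terminal_log_rhp <- function(t, d, side, V, C, rhp_initial, T) {
  lv <- log1p(V); lc <- log1p(-C); l0 <- log(rhp_initial)
  a <- (t + d) / 2; b <- (t - d) / 2   # x's fight wins / losses
  lx <- l0 + a * lv + b * lc + (side == 1L) * (T - t) * lv
  ly <- l0 + b * lv + a * lc + (side == -1L) * (T - t) * lv
  c(lx, ly)
}

#' Exact expected payoff of a two-player contest
#'
#' Computes the row player's expected payoff when individuals of concession
#' classes `k_x` and `k_y` meet for `T` rounds, by exact dynamic programming
#' over the mutual-fight random walk (no Monte Carlo error). Two payoff
#' currencies are supported:
#'
#' * `"log_rhp"` — the expectation of the final log RHP, appropriate when
#'   resources are plentiful and the absolute score matters;
#' * `"share"` — the expected share
#'   `ln(RHP_x) / (ln(RHP_x) + ln(RHP_y))` of a limited resource divided in
#'   proportion to log RHP (reproductive-skew reading). Shares of the two
#'   players sum to 1 path by path.
#'
#' Class `0` denotes immediate retreat (a threshold above 1).
#'
#' @param k_x,k_y integer concession classes (`>= 1`), or `0` for immediate
#'   retreat.
#' @param params a [game_params()] object in the default preset
#'   (`V1 = V2`, `C2 = 0`); other presets are rejected because the
#'   difference-only state reduction breaks when retreating changes RHP.
#' @param payoff `"log_rhp"` or `"share"`.
#' @return The exact expected payoff of the `k_x` player (a single number).
#' @examples
#' p <- game_params(V = 0.1, C = 0.1, T = 20)
#' expected_payoff(3, 3, p)                   # 2.89 (2 dp)
#' expected_payoff(1, 2, p, payoff = "share") # 0.459 (3 dp)
#' @export
expected_payoff <- function(k_x, k_y, params,
                            payoff = c("log_rhp", "share")) {
  payoff <- match.arg(payoff)
  stop_unless_default_preset(params)
  check_class_arg(k_x); check_class_arg(k_y)
  V <- params$V1; C <- params$C1; T <- params$T
  l0 <- log(params$rhp_initial)

  if (payoff == "share" && k_x == k_y) {
    # symmetric contest: shares are complementary path by path, so the
    # expectation is exactly one half (avoids summation round-off)
    if (k_x >= 1L) walk_absorption(k_x, k_y, V, C, 1L)  # parameter checks
    return(0.5)
  }
  if (k_x == 0L || k_y == 0L) {
    # no mutual fights ever happen: a retreater's RHP is constant (C2 = 0)
    # and a fighter facing a retreater gains (1 + V) every round
    lx <- l0 + (k_x >= 1L && k_y == 0L) * T * log1p(V)
    ly <- l0 + (k_y >= 1L && k_x == 0L) * T * log1p(V)
    return(payoff_from_pair(lx, ly, payoff))
  }

  w <- walk_absorption(k_x, k_y, V, C, T)
  total <- 0
  if (nrow(w$events)) {
    for (i in seq_len(nrow(w$events))) {
      side <- w$events$side[i]
      d <- if (side == 1L) k_y else -k_x
      lr <- terminal_log_rhp(w$events$t[i], d, side, V, C,
                             params$rhp_initial, T)
      total <- total + w$events$prob[i] *
        payoff_from_pair(lr[1L], lr[2L], payoff)
    }
  }
  for (i in seq_along(w$states)) {
    if (w$censored[i] > 0) {
      lr <- terminal_log_rhp(T, w$states[i], 0L, V, C, params$rhp_initial, T)
      total <- total + w$censored[i] *
        payoff_from_pair(lr[1L], lr[2L], payoff)
    }
  }
  total
}

payoff_from_pair <- function(lx, ly, payoff) {
  if (payoff == "log_rhp") return(lx)
  if (lx <= 0 || lx + ly <= 0) {
    stop("share payoff undefined: a reachable terminal log RHP is ",
         "non-positive (log RHP x = ", signif(lx, 6), ", y = ",
         signif(ly, 6), "); use the log_rhp payoff or a larger rhp_initial",
         call. = FALSE)
  }
  lx / (lx + ly)
}

check_class_arg <- function(k) {
  if (length(k) != 1L || !is.numeric(k) || k != as.integer(k) || k < 0) {
    stop("concession classes must be single integers >= 0 (0 = immediate ",
         "retreat)", call. = FALSE)
  }
}

#' Brute-force payoff by enumeration of all outcome sequences
#'
#' Test oracle for [expected_payoff()]: walks the full binary tree of fight
#' outcomes (up to `2^T` paths), scoring each terminal path directly from
#' the win/loss record. Deliberately shares no code with the forward
#' dynamic-programming pass. Refuses horizons above 14 rounds.
#'
#' @inheritParams expected_payoff
#' @return The exact expected payoff, identical to [expected_payoff()] up to
#'   floating-point error (`< 1e-10`).
#' @export
expected_payoff_bruteforce <- function(k_x, k_y, params,
                                       payoff = c("log_rhp", "share")) {
  payoff <- match.arg(payoff)
  stop_unless_default_preset(params)
  check_class_arg(k_x); check_class_arg(k_y)
  if (params$T > 14L) {
    stop("enumeration guard: T = ", params$T, " > 14 would require 2^T ",
         "paths; use expected_payoff()", call. = FALSE)
  }
  V <- params$V1; C <- params$C1; T <- params$T
  lv <- log1p(V); lc <- log1p(-C); l0 <- log(params$rhp_initial)

  score <- function(a, b, t, side) {
    lx <- l0 + a * lv + b * lc + if (side == 1L) (T - t) * lv else 0
    ly <- l0 + b * lv + a * lc + if (side == -1L) (T - t) * lv else 0
    payoff_from_pair(lx, ly, payoff)
  }
  if (k_x == 0L || k_y == 0L) {
    lx <- l0 + (k_x >= 1L && k_y == 0L) * T * lv
    ly <- l0 + (k_y >= 1L && k_x == 0L) * T * lv
    return(payoff_from_pair(lx, ly, payoff))
  }
  recurse <- function(a, b, t) {
    if (t == T) return(score(a, b, T, 0L))
    W <- win_prob_from_diff(a - b, V, C)
    # x wins round t+1
    aw <- a + 1L
    up <- if (aw - b >= k_y) score(aw, b, t + 1L, 1L) else recurse(aw, b, t + 1L)
    bl <- b + 1L
    dn <- if (a - bl <= -k_x) score(a, bl, t + 1L, -1L) else recurse(a, bl, t + 1L)
    W * up + (1 - W) * dn
  }
  recurse(0L, 0L, 0L)
}
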