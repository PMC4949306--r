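#' Decide whether to fight or retreat
#'
#' An individual plays Hawk (fights) whenever its RHP ratio to the opponent
#' is at least its aggression threshold `theta`, and retreats otherwise. The
#' inequality is inclusive, so `theta = 1` fights at the even initial state.
#'
#' @param rhp_self,rhp_opp positive RHP scores of the focal individual and
#'   its opponent.
#' @param theta non-negative aggression threshold; `theta = 0` never
#'   retreats, `theta > 1` retreats from an even start.
#' @return `"fight"` or `"retreat"` (vectorised over the inputs).
#' @examples
#' decide_action(10, 10, 0.91)  # fight
#' decide_action(9, 11, 0.91)   # retreat (9/11 < 0.91)
#' @export
decide_action <- function(rhp_self, rhp_opp, theta) {
  if (any(rhp_self <= 0) || any(rhp_opp <= 0)) {
    stop("RHP scores must be positive", call. = FALSE)
  }
  if (any(theta < 0)) stop("theta must be non-negative", call. = FALSE)
  ifelse(rhp_self / rhp_opp >= theta, "fight", "retreat")
}

#' Probability of winning an escalated fight
#'
#' When both individuals fight, the probability that `x` wins is its share
#' of the combined RHP, `rhp_x / (rhp_x + rhp_y)`, so that
#' `win_probability(x, y) + win_probability(y, x) = 1` exactly.
#'
#' @param rhp_x,rhp_y positive RHP scores.
#' @return The probability that the first individual wins.
#' @export
win_probability <- function(rhp_x, rhp_y) {
  if (any(rhp_x <= 0) || any(rhp_y <= 0)) {
    stop("RHP scores must be positive", call. = FALSE)
  }
  rhp_x / (rhp_x + rhp_y)
}

#' Apply the outcome of one interaction to both RHP scores
#'
#' Multiplicative winner/loser updates: the fight winner gains `1 + V1`, the
#' fight loser takes `1 - C1`; a fighter facing a retreater gains `1 + V2`
#' while the retreater takes `1 - C2`; in a double kowtow both take `1 - C2`.
#'
#' @param rhp_x,rhp_y positive RHP scores before the interaction.
#' @param outcome one of `"x_wins_fight"`, `"y_wins_fight"`,
#'   `"x_fights_y_retreats"`, `"y_fights_x_retreats"`, `"double_kowtow"`.
#' @param params a [game_params()] object.
#' @return Numeric vector `c(rhp_x, rhp_y)` after the update.
#' @examples
#' p <- game_params(V = 0.1, C = 0.1)
#' apply_outcome(10, 10, "x_wins_fight", p)  # c(11, 9)
#' @export
apply_outcome <- function(rhp_x, rhp_y, outcome, params) {
  stopifnot(inherits(params, "game_params"))
  if (rhp_x <= 0 || rhp_y <= 0) {
    stop("RHP scores must be positive", call. = FALSE)
  }
  f <- switch(outcome,
    x_wins_fight        = c(1 + params$V1, 1 - params$C1),
    y_wins_fight        = c(1 - params$C1, 1 + params$V1),
    x_fights_y_retreats = c(1 + params$V2, 1 - params$C2),
    y_fights_x_retreats = c(1 - params$C2, 1 + params$V2),
    double_kowtow       = c(1 - params$C2, 1 - params$C2),
    stop("unknown outcome: ", outcome, call. = FALSE)
  )
  c(rhp_x * f[1L], rhp_y * f[2L])
}

#' RHP implied by a win/loss record
#'
#' Under the default preset the order of outcomes does not matter: after `a`
#' fight wins and `b` fight losses the RHP is
#' `rhp_initial * (1 + V)^a * (1 - C)^b`, whatever the sequence.
#'
#' @param wins,losses non-negative integer counts of fight wins and losses.
#' @param params a [game_params()] object in the default preset.
#' @return The implied positive RHP score.
#' @export
rhp_from_record <- function(wins, losses, params) {
  stop_unless_default_preset(params)
  if (any(wins < 0) || any(losses < 0) ||
      any(wins != as.integer(wins)) || any(losses != as.integer(losses))) {
    stop("wins and losses must be non-negative integers", call. = FALSE)
  }
  # log space: large win counts overflow ratio space well before T does
  exp(log(params$rhp_initial) +
        wins * log1p(params$V1) + losses * log1p(-params$C1))
}
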