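#' Contest-rule parameters
#'
#' Bundle the constants that govern a winner-loser contest. After a fight the
#' winner's resource holding potential (RHP) is multiplied by `1 + V1` and the
#' loser's by `1 - C1`; when one individual fights and the other retreats the
#' fighter's RHP is multiplied by `1 + V2` and the retreater's by `1 - C2`;
#' when both retreat (a "double kowtow") both are multiplied by `1 - C2`.
#'
#' The default preset used throughout the exact analysis sets `V1 = V2 = V`,
#' `C1 = C` and `C2 = 0`: winning a fight and facing a retreating opponent
#' are equally rewarding, while retreating itself is free (only losing an
#' escalated fight is an injury). Supplying just `V` and `C` constructs this
#' preset.
#'
#' @param V proportional RHP gain, expands to `V1 = V2 = V` unless those are
#'   given explicitly. Dimensionless, `>= 0`.
#' @param C proportional RHP loss after losing a fight, expands to `C1 = C`.
#'   Must lie in `[0, 1)`.
#' @param rhp_initial positive initial RHP score shared by all individuals.
#' @param T integer contest horizon (number of interaction rounds), `>= 1`.
#' @param V1,V2,C1,C2 individual update factors; see Description. `C1` and
#'   `C2` must lie in `[0, 1)`: a multiplier of exactly zero would annihilate
#'   the RHP and make the log-RHP payoff undefined, so it is rejected as
#'   degenerate.
#'
#' @return An object of class `game_params`: a list with elements `V1`, `V2`,
#'   `C1`, `C2`, `rhp_initial`, `T`, and the logical `default_preset`
#'   (`TRUE` when `V1 == V2` and `C2 == 0`, the regime in which the exact
#'   two-player analysis applies).
#' @examples
#' game_params(V = 0.1, C = 0.1)             # the standard preset
#' game_params(V = 0.1, C = 0.1, T = 200)
#' @export
game_params <- function(V = NULL, C = NULL, rhp_initial = 10, T = 20,
                        V1 = V, V2 = V, C1 = C, C2 = 0) {
  if (is.null(V1) || is.null(V2) || is.null(C1)) {
    stop("supply either (V, C) or all of (V1, V2, C1)", call. = FALSE)
  }
  stopifnot(is.numeric(V1), is.numeric(V2), is.numeric(C1), is.numeric(C2),
            length(V1) == 1L, length(V2) == 1L, length(C1) == 1L,
            length(C2) == 1L)
  if (V1 < 0 || V2 < 0) {
    stop("V1 and V2 must be non-negative", call. = FALSE)
  }
  if (C1 < 0 || C2 < 0 || C1 > 1 || C2 > 1) {
    stop("C1 and C2 must lie in [0, 1]", call. = FALSE)
  }
  if (C1 >= 1 || C2 >= 1) {
    stop("degenerate parameters: C1 = 1 or C2 = 1 annihilates the RHP ",
         "and the log-RHP payoff is undefined", call. = FALSE)
  }
  if (!is.numeric(rhp_initial) || length(rhp_initial) != 1L ||
      rhp_initial <= 0) {
    stop("rhp_initial must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(T) || length(T) != 1L || T < 1 || T != as.integer(T)) {
    stop("T must be a single integer >= 1", call. = FALSE)
  }
  structure(
    list(V1 = V1, V2 = V2, C1 = C1, C2 = C2,
         rhp_initial = rhp_initial, T = as.integer(T),
         default_preset = (V1 == V2 && C2 == 0)),
    class = "game_params"
  )
}

#' @export
print.game_params <- function(x, ...) {
  cat("Winner-loser contest parameters\n")
  cat(sprintf("  win/lose a fight : RHP x (1 + %g) / x (1 - %g)\n",
              x$V1, x$C1))
  cat(sprintf("  fight a retreater: RHP x (1 + %g); retreating: x (1 - %g)\n",
              x$V2, x$C2))
  cat(sprintf("  initial RHP %g, horizon T = %d rounds\n",
              x$rhp_initial, x$T))
  if (x$default_preset) cat("  (default preset: V1 = V2, C2 = 0)\n")
  invisible(x)
}

# internal guard used by the exact machinery
stop_unless_default_preset <- function(params) {
  if (!inherits(params, "game_params")) {
    stop("params must be a game_params object", call. = FALSE)
  }
  if (!params$default_preset) {
    stop("unsupported preset: the exact analysis requires V1 = V2 and ",
         "C2 = 0 (retreating must not change RHP); use the Monte-Carlo ",
         "engine for generalised presets", call. = FALSE)
  }
  invisible(params)
}

# shared shorthand: V, C of the default preset
preset_VC <- function(params) c(V = params$V1, C = params$C1)
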