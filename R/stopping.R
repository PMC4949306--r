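#' Distribution of the contest stopping time
#'
#' The stopping time of a two-player contest is the round of the last mutual
#' fight: the first time either individual's win-loss difference reaches its
#' concession boundary (`-k` for itself). `stopping_distribution()` returns
#' its exact probability mass, truncated at the horizon `T`, together with
#' the probability that neither individual has conceded by `T`
#' (`censored_mass`).
#'
#' @param k_x,k_y integer concession classes, `>= 1`.
#' @param params a [game_params()] object in the default preset.
#' @return Object of class `stopping_distribution`: a data frame with
#'   columns `t` and `probability` (only rounds with positive mass), plus
#'   attributes `censored_mass`, `k_x`, `k_y` and `params`.
#' @examples
#' p <- game_params(V = 0.1, C = 0.1, T = 20)
#' stopping_distribution(1, 1, p)   # point mass at t = 1
#' @export
stopping_distribution <- function(k_x, k_y, params) {
  stop_unless_default_preset(params)
  check_class_arg(k_x); check_class_arg(k_y)
  if (k_x < 1L || k_y < 1L) {
    stop("stopping times are defined for classes >= 1 (class 0 never ",
         "fights)", call. = FALSE)
  }
  w <- walk_absorption(k_x, k_y, params$V1, params$C1, params$T)
  mass <- if (nrow(w$events)) {
    stats::aggregate(prob ~ t, data = w$events, FUN = sum)
  } else {
    data.frame(t = integer(0), prob = numeric(0))
  }
  out <- data.frame(t = mass$t, probability = mass$prob)
  structure(out,
            censored_mass = sum(w$censored),
            k_x = k_x, k_y = k_y, params = params,
            class = c("stopping_distribution", "data.frame"))
}

#' @export
print.stopping_distribution <- function(x, ...) {
  cat(sprintf("Stopping-time distribution, classes k_x = %d vs k_y = %d (T = %d)\n",
              attr(x, "k_x"), attr(x, "k_y"), attr(x, "params")$T))
  print.data.frame(x, row.names = FALSE)
  cat(sprintf("P(no concession by T) = %.6g\n", attr(x, "censored_mass")))
  invisible(x)
}

#' Closed-form support of the stopping time
#'
#' Which rounds can the stopping time land on? The walk moves by one per
#' round, so each player's own concession time has the parity of its class
#' and the combined support follows from a parity argument:
#'
#' * `k_x = k_y = 1`: the single interior state forces concession in round
#'   1 — a point mass at `t = 1`;
#' * `k_x + k_y` even (equal parities): all `t = min(k_x,k_y) + 2n`;
#' * `k_x + k_y` odd (mixed parities): every integer from
#'   `max(k_x,k_y)` upwards, plus the rounds in
#'   `[min(k_x,k_y), max(k_x,k_y))` sharing the parity of the smaller class.
#'
#' @param k_x,k_y integer concession classes, `>= 1`.
#' @return A predicate: a function mapping integer rounds to `TRUE` when the
#'   stopping time can occur there (vectorised).
#' @examples
#' stopping_support(2, 2)(1:6)  # FALSE TRUE FALSE TRUE FALSE TRUE
#' @export
stopping_support <- function(k_x, k_y) {
  check_class_arg(k_x); check_class_arg(k_y)
  if (k_x < 1L || k_y < 1L) {
    stop("support is defined for classes >= 1", call. = FALSE)
  }
  mn <- min(k_x, k_y); mx <- max(k_x, k_y)
  if (k_x == 1L && k_y == 1L) {
    return(function(t) t == 1L)
  }
  if ((k_x + k_y) %% 2L == 0L) {
    return(function(t) t >= mn & (t - mn) %% 2L == 0L)
  }
  function(t) (t >= mx) | (t >= mn & (t - mn) %% 2L == 0L)
}
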