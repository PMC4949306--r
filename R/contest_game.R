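#' Solve a two-player winner-loser contest game
#'
#' The central fitting-style constructor of the package: given the contest
#' rules `(V, C)`, a horizon `T` and a payoff currency, it computes the
#' exact payoff matrix over the concession-class grid, locates the pure ESS
#' by the diagonal rule, and attaches the stopping-time distribution of the
#' ESS-vs-ESS contest. The returned object supports `print()`, `summary()`,
#' `coef()` (the ESS class and threshold interval), `plot()` and
#' `simulate()` (Monte-Carlo replicates of a contest between chosen
#' classes).
#'
#' @param V,C proportional RHP gain and loss of an escalated fight
#'   (default preset: facing a retreater also pays `V`, retreating is free).
#' @param T integer contest horizon.
#' @param rhp_initial shared initial RHP.
#' @param k_max largest concession class on the strategy grid.
#' @param payoff `"log_rhp"` (plentiful resources) or `"share"` (limited
#'   resources divided in proportion to log RHP).
#' @param include_immediate_retreat prepend the never-fight class `0` to the
#'   grid; defaults to doing so exactly when `V = 0`, where fighting cannot
#'   pay.
#' @return An object of class `contest_game` with components `params`,
#'   `payoff`, `k_grid`, `matrix` (a [build_payoff_matrix()] result),
#'   `ess` (a [find_pure_ess()] result) and `stopping` (the
#'   ESS-vs-ESS [stopping_distribution()], or `NULL` without a fightable
#'   ESS).
#' @examples
#' g <- contest_game(V = 0.1, C = 0.1, T = 20)
#' g
#' coef(g)
#' @export
contest_game <- function(V, C, T = 20, rhp_initial = 10, k_max = 8,
                         payoff = c("log_rhp", "share"),
                         include_immediate_retreat = (V == 0)) {
  payoff <- match.arg(payoff)
  params <- game_params(V = V, C = C, rhp_initial = rhp_initial, T = T)
  k_grid <- if (include_immediate_retreat) c(0L, seq_len(k_max)) else seq_len(k_max)
  m <- build_payoff_matrix(k_grid, params, payoff)
  ess <- find_pure_ess(m)
  stopping <- NULL
  if (ess$kind == "pure" && any(ess$ess$k >= 1)) {
    k_star <- ess$ess$k[ess$ess$k >= 1][1L]
    stopping <- stopping_distribution(k_star, k_star, params)
  }
  structure(list(params = params, payoff = payoff, k_grid = k_grid,
                 matrix = m, ess = ess, stopping = stopping),
            class = "contest_game")
}

#' @export
print.contest_game <- function(x, ...) {
  p <- x$params
  cat(sprintf("Two-player winner-loser contest game (V = %g, C = %g, T = %d, initial RHP %g)\n",
              p$V1, p$C1, p$T, p$rhp_initial))
  cat(sprintf("Payoff: %s; class grid: %s\n", x$payoff,
              paste(x$k_grid, collapse = " ")))
  print(x$ess)
  invisible(x)
}

#' @export
summary.contest_game <- function(object, digits = 4, ...) {
  print(object$matrix, digits = digits)
  cat("\n")
  print(object$ess)
  if (!is.null(object$stopping)) {
    st <- object$stopping
    mean_ts <- sum(st$t * st$probability) + attr(st, "censored_mass") * NA
    cat(sprintf("\nESS vs ESS stopping time: P(concession by T) = %.4f",
                sum(st$probability)))
    if (attr(st, "censored_mass") < 1e-12) {
      cat(sprintf(", mean %.3f rounds", sum(st$t * st$probability)))
    }
    cat("\n")
  }
  invisible(object)
}

#' @export
coef.contest_game <- function(object, ...) {
  if (object$ess$kind == "none_found") {
    return(c(k = NA_real_, theta_rep = NA_real_,
             theta_min = NA_real_, theta_sup = NA_real_))
  }
  e <- object$ess$ess[1L, ]
  c(k = as.numeric(e$k), theta_rep = e$theta_rep,
    theta_min = e$theta_min, theta_sup = e$theta_sup)
}

#' Plot method for contest games
#'
#' Displays the payoff matrix as an image with the diagonal-rule ESS marked,
#' or the ESS-vs-ESS stopping-time mass.
#'
#' @param x a [contest_game()] object.
#' @param which `"matrix"` or `"stopping"`.
#' @param ... passed on to the underlying base-graphics call.
#' @return `x`, invisibly.
#' @export
plot.contest_game <- function(x, which = c("matrix", "stopping"), ...) {
  which <- match.arg(which)
  if (which == "matrix") {
    n <- length(x$k_grid)
    graphics::image(seq_len(n), seq_len(n), t(unclass(x$matrix))[, n:1],
                    col = grDevices::hcl.colors(25, "YlOrRd", rev = TRUE),
                    axes = FALSE, xlab = "opponent class k", ylab = "own class k",
                    main = sprintf("%s payoffs (row player)", x$payoff), ...)
    graphics::axis(1, at = seq_len(n), labels = x$k_grid)
    graphics::axis(2, at = seq_len(n), labels = rev(x$k_grid))
    if (x$ess$kind == "pure") {
      i <- match(x$ess$ess$k[1L], x$k_grid)
      graphics::points(i, n - i + 1, pch = 1, cex = 3, lwd = 2)
    }
  } else {
    if (is.null(x$stopping)) stop("no stopping distribution available")
    st <- x$stopping
    graphics::plot(st$t, st$probability, type = "h", lwd = 3,
                   xlab = "stopping time (round of last mutual fight)",
                   ylab = "probability", ...)
  }
  invisible(x)
}

#' Simulate contests from a solved game
#'
#' Monte-Carlo replicates of a single two-player contest under the game's
#' rules, played with the representative thresholds of the chosen classes.
#' Useful as an independent stochastic check on the exact expectations.
#'
#' @param object a [contest_game()] object.
#' @param nsim number of replicate contests.
#' @param seed optional integer seed.
#' @param k_x,k_y classes to pit against each other; default is the ESS
#'   against itself.
#' @param ... unused.
#' @return A data frame with `nsim` rows and columns `payoff_x`,
#'   `payoff_y`: terminal log RHPs (or shares, for a share game).
#' @importFrom stats simulate
#' @export
simulate.contest_game <- function(object, nsim = 1000, seed = NULL,
                                  k_x = NULL, k_y = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(k_x) || is.null(k_y)) {
    if (object$ess$kind != "pure") {
      stop("no pure ESS: supply k_x and k_y explicitly", call. = FALSE)
    }
    k_star <- object$ess$ess$k[1L]
    if (is.null(k_x)) k_x <- k_star
    if (is.null(k_y)) k_y <- k_star
  }
  p <- object$params
  th <- function(k) if (k == 0L) 1 / (1 - p$C1) + 1 else theta_rep(k, p$V1, p$C1)
  lr <- sim_contest_groups(
    theta = matrix(c(rep(th(k_x), nsim), rep(th(k_y), nsim)), nsim, 2),
    params = p, contests = p$T)
  out <- data.frame(payoff_x = lr[, 1L], payoff_y = lr[, 2L])
  if (object$payoff == "share") {
    s <- out$payoff_x / (out$payoff_x + out$payoff_y)
    out <- data.frame(payoff_x = s, payoff_y = 1 - s)
  }
  out
}
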