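# ---------------------------------------------------------------------------
# Monte-Carlo contest engine. Simulates many independent groups in parallel
# (vectorised across groups); each round one unordered pair per group is
# chosen uniformly, both members decide by the threshold rule against each
# other's current RHP, and the outcome updates log RHPs multiplicatively.
# Works for any preset (V1 != V2, C2 > 0 included). Three uniform draws per
# round per group are consumed regardless of the outcome, so trajectories
# are reproducible given a seed.
# ---------------------------------------------------------------------------
sim_contest_groups <- function(theta, params, contests) {
  stopifnot(inherits(params, "game_params"), is.matrix(theta))
  G <- nrow(theta); N <- ncol(theta)
  if (N < 2L) stop("groups need at least two individuals", call. = FALSE)
  lv1 <- log1p(params$V1); lc1 <- log1p(-params$C1)
  lv2 <- log1p(params$V2); lc2 <- log1p(-params$C2)
  lr <- matrix(log(params$rhp_initial), G, N)
  gidx <- seq_len(G)
  lth <- log(theta)                      # theta = 0 -> -Inf: always fights
  for (t in seq_len(contests)) {
    ii <- floor(stats::runif(G) * N) + 1L
    jj <- floor(stats::runif(G) * (N - 1L)) + 1L
    jj <- jj + (jj >= ii)
    xi <- cbind(gidx, ii); yi <- cbind(gidx, jj)
    rx <- lr[xi]; ry <- lr[yi]
    fx <- (rx - ry) >= lth[xi]
    fy <- (ry - rx) >= lth[yi]
    u <- stats::runif(G)
    both <- fx & fy
    xw <- both & (u < 1 / (1 + exp(ry - rx)))   # RHP-share win probability
    yw <- both & !xw
    dx <- numeric(G); dy <- numeric(G)
    dx[xw] <- lv1; dy[xw] <- lc1
    dx[yw] <- lc1; dy[yw] <- lv1
    only_x <- fx & !fy; only_y <- fy & !fx; neither <- !fx & !fy
    dx[only_x] <- lv2; dy[only_x] <- lc2
    dx[only_y] <- lc2; dy[only_y] <- lv2
    dx[neither] <- lc2; dy[neither] <- lc2
    lr[xi] <- rx + dx
    lr[yi] <- ry + dy
  }
  lr
}

#' Play one group of contests
#'
#' Simulates `contests` rounds within a single group: each round an
#' unordered pair is drawn uniformly, both members decide to fight or
#' retreat by the threshold rule, and RHPs are updated by the winner-loser
#' rules. Uses the session RNG; seed it for reproducibility.
#'
#' @param strategies numeric vector of the group members' aggression
#'   thresholds (length `N >= 2`).
#' @param params a [game_params()] object.
#' @param contests number of interaction rounds.
#' @return Numeric vector of final log RHPs, one per member.
#' @examples
#' set.seed(1)
#' play_group(c(0.6, 0.6), game_params(V = 0.1, C = 0.1), contests = 20)
#' @export
play_group <- function(strategies, params, contests) {
  if (any(strategies < 0)) stop("thresholds must be non-negative",
                                call. = FALSE)
  drop(sim_contest_groups(matrix(strategies, nrow = 1L), params, contests))
}

#' Configuration of an evolutionary run
#'
#' Collects the knobs of the frequency-dependent simulation: many groups of
#' `N` individuals play `contests` rounds each generation, individuals
#' credit their final log RHP to their strategy, and next generation's
#' strategy frequencies are proportional to the credited totals.
#'
#' `scale = "desk"` (default) uses 500 groups and 300 generations with early
#' stopping — small enough for interactive work while still concentrating on
#' the stable strategy. `scale = "paper"` uses the full 10,000 groups and
#' 10,000 generations with early stopping off; expect a long run.
#'
#' @param N group size, `>= 2`.
#' @param params a [game_params()] object (its `T` is not used here;
#'   `contests` plays that role).
#' @param theta_grid strictly increasing strategy grid; default
#'   `seq(0.1, 1, by = 0.1)`.
#' @param n_groups groups per generation.
#' @param contests interaction rounds per group per generation. Defaults to
#'   200. Note the strategic horizon matters: the stable threshold of the
#'   contest game depends on the number of rounds over which payoffs
#'   accumulate, so to compare with an exact `T`-round analysis set
#'   `contests = T`.
#' @param n_generations generations to run.
#' @param payoff_floor fitness floor: credited payoffs below it are clamped
#'   (with a warning) because the proportional update is undefined for
#'   negative totals. Never triggered under the default parameters.
#' @param converge_tol concentration tolerance for early stopping.
#' @param patience consecutive concentrated generations required to stop
#'   early (`Inf` disables early stopping).
#' @param scale `"desk"` or `"paper"`; presets for `n_groups`,
#'   `n_generations` and `patience`, overridden by explicit arguments.
#' @return A list of class `evolution_config`.
#' @export
evolution_config <- function(N = 2, params = game_params(V = 0.1, C = 0.1),
                             theta_grid = seq(0.1, 1, by = 0.1),
                             n_groups = NULL, contests = 200,
                             n_generations = NULL, payoff_floor = 0,
                             converge_tol = 1e-3, patience = NULL,
                             scale = c("desk", "paper")) {
  scale <- match.arg(scale)
  if (is.null(n_groups)) n_groups <- if (scale == "paper") 10000L else 500L
  if (is.null(n_generations)) {
    n_generations <- if (scale == "paper") 10000L else 300L
  }
  if (is.null(patience)) patience <- if (scale == "paper") Inf else 25L
  stopifnot(N >= 2, n_groups >= 1, contests >= 1, n_generations >= 1)
  if (any(diff(theta_grid) <= 0) || any(theta_grid <= 0)) {
    stop("theta_grid must be positive and strictly increasing",
         call. = FALSE)
  }
  structure(list(N = as.integer(N), params = params,
                 theta_grid = theta_grid, n_groups = as.integer(n_groups),
                 contests = as.integer(contests),
                 n_generations = as.integer(n_generations),
                 payoff_floor = payoff_floor, converge_tol = converge_tol,
                 patience = patience, scale = scale),
            class = "evolution_config")
}

#' Advance the population by one generation
#'
#' Samples `N` strategies per group i.i.d. from the current frequency
#' vector, plays every group, credits each individual's final log RHP to its
#' strategy's accumulator `H`, and replaces the frequencies by
#' `p_k = H_k / sum(H)`. Strategies that received no credit drop to
#' frequency zero and (absent mutation) never return.
#'
#' @param state list with elements `p` (frequency vector over the grid) and
#'   `generation`.
#' @param config an [evolution_config()].
#' @return The updated state (with the generation's `H` attached).
#' @export
run_generation <- function(state, config) {
  p <- state$p
  ng <- length(config$theta_grid)
  stopifnot(length(p) == ng, abs(sum(p) - 1) < 1e-9, all(p >= 0))
  si <- matrix(sample.int(ng, config$n_groups * config$N, replace = TRUE,
                          prob = p),
               config$n_groups, config$N)
  lr <- sim_contest_groups(matrix(config$theta_grid[si],
                                  config$n_groups, config$N),
                           config$params, config$contests)
  pay <- as.vector(lr)
  if (any(pay < config$payoff_floor)) {
    warning("credited payoffs below the fitness floor were clamped ",
            "(ln RHP < ", config$payoff_floor, ")")
    pay <- pmax(pay, config$payoff_floor)
  }
  idx <- as.vector(si)
  H <- vapply(seq_len(ng), function(k) sum(pay[idx == k]), numeric(1))
  total <- sum(H)
  if (total <= 0) {
    stop("degenerate fitness: total credited payoff is not positive; ",
         "raise rhp_initial or the fitness floor", call. = FALSE)
  }
  list(p = H / total, generation = state$generation + 1L, H = H)
}

#' Evolve aggression thresholds in groups of N individuals
#'
#' Runs the full frequency-dependent simulation: starting from a uniform
#' distribution over `theta_grid`, repeats [run_generation()] until the
#' configured number of generations, or earlier once the distribution has
#' stayed concentrated on one strategy (frequency `>= 1 - converge_tol`) for
#' `patience` consecutive generations.
#'
#' The declared ESS is the modal strategy when the final distribution is
#' concentrated (modal frequency at least one half), otherwise the
#' frequency-weighted mean threshold.
#'
#' @param config an [evolution_config()]; alternatively pass the arguments
#'   of [evolution_config()] via `...`.
#' @param seed optional integer seed (set it for reproducible runs).
#' @param ... used to build a config when `config` is missing.
#' @return An object of class `wl_evolution`: list with `p` (final
#'   frequencies), `trajectory` (generations x grid matrix), `ess`
#'   (declared), `ess_mode`, `ess_mean`, `concentration` (final modal
#'   frequency), `generations`, `converged`, `config`, `seed`.
#' @examples
#' \donttest{
#' res <- run_evolution(evolution_config(
#'   N = 2, params = game_params(V = 0.1, C = 0.1),
#'   contests = 20, n_groups = 200, n_generations = 100), seed = 1)
#' res$ess
#' }
#' @export
run_evolution <- function(config = NULL, seed = NULL, ...) {
  if (is.null(config)) config <- evolution_config(...)
  stopifnot(inherits(config, "evolution_config"))
  if (!is.null(seed)) set.seed(seed)
  ng <- length(config$theta_grid)
  state <- list(p = rep(1 / ng, ng), generation = 0L)
  traj <- matrix(NA_real_, config$n_generations, ng,
                 dimnames = list(NULL, config$theta_grid))
  streak <- 0L
  g <- 0L
  for (g in seq_len(config$n_generations)) {
    state <- run_generation(state, config)
    traj[g, ] <- state$p
    if (max(state$p) >= 1 - config$converge_tol) {
      streak <- streak + 1L
    } else {
      streak <- 0L
    }
    if (streak >= config$patience) break
  }
  traj <- traj[seq_len(g), , drop = FALSE]
  p <- state$p
  mode_theta <- config$theta_grid[which.max(p)]
  mean_theta <- sum(p * config$theta_grid)
  concentrated <- max(p) >= 0.5
  structure(list(
    p = stats::setNames(p, config$theta_grid),
    trajectory = traj,
    ess = if (concentrated) mode_theta else mean_theta,
    ess_mode = mode_theta,
    ess_mean = mean_theta,
    concentration = max(p),
    generations = g,
    converged = streak >= config$patience,
    config = config, seed = seed),
    class = "wl_evolution")
}

#' @export
print.wl_evolution <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Evolutionary simulation: N = %d, V = %g, C = %g, %d groups x %d contests\n",
              cfg$N, cfg$params$V1, cfg$params$C1, cfg$n_groups,
              cfg$contests))
  cat(sprintf("  %d generations run%s\n", x$generations,
              if (x$converged) " (early stop: concentrated)" else ""))
  cat(sprintf("  declared ESS theta = %.3g (mode %.2g, weighted mean %.3g, modal frequency %.3f)\n",
              x$ess, x$ess_mode, x$ess_mean, x$concentration))
  invisible(x)
}

#' Summary of an evolutionary run
#'
#' Reports the declared ESS, the full final frequency vector and a
#' concentration metric (the modal frequency).
#'
#' @param object a [run_evolution()] result.
#' @param ... unused.
#' @return A list with `ess`, `ess_mode`, `ess_mean`, `p`, `concentration`,
#'   `generations`, `converged`, returned invisibly after printing.
#' @export
summary.wl_evolution <- function(object, ...) {
  print(object)
  cat("  final strategy frequencies:\n")
  print(round(object$p, 4))
  invisible(list(ess = object$ess, ess_mode = object$ess_mode,
                 ess_mean = object$ess_mean, p = object$p,
                 concentration = object$concentration,
                 generations = object$generations,
                 converged = object$converged))
}

#' @export
plot.wl_evolution <- function(x, ...) {
  graphics::matplot(seq_len(nrow(x$trajectory)), x$trajectory, type = "l",
                    lty = 1, xlab = "generation", ylab = "frequency",
                    main = "strategy frequencies", ...)
  graphics::legend("topleft", legend = colnames(x$trajectory),
                   col = seq_len(ncol(x$trajectory)), lty = 1, cex = 0.7)
  invisible(x)
}
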