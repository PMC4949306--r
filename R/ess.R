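#' Payoff matrix over a grid of concession classes
#'
#' Entry `(i, j)` is the exact expected payoff of the row player using class
#' `k_grid[i]` against a column player using `k_grid[j]`, from
#' [expected_payoff()]. Share matrices satisfy
#' `M[i, j] + M[j, i] = 1` with an exactly 0.5 diagonal.
#'
#' @param k_grid vector of distinct integer classes (`0` allowed for
#'   immediate retreat).
#' @param params a [game_params()] object in the default preset.
#' @param payoff `"log_rhp"` or `"share"`.
#' @return A `payoff_matrix`: a numeric matrix with `k` values as dimnames
#'   and attributes `k_grid`, `payoff`, `params`.
#' @examples
#' p <- game_params(V = 0.1, C = 0.1, T = 20)
#' round(build_payoff_matrix(1:8, p), 2)
#' @export
build_payoff_matrix <- function(k_grid, params,
                                payoff = c("log_rhp", "share")) {
  payoff <- match.arg(payoff)
  if (length(k_grid) < 1L || anyDuplicated(k_grid)) {
    stop("k_grid must be a non-empty vector of distinct classes",
         call. = FALSE)
  }
  n <- length(k_grid)
  m <- matrix(NA_real_, n, n, dimnames = list(k_grid, k_grid))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      m[i, j] <- expected_payoff(k_grid[i], k_grid[j], params, payoff)
    }
  }
  structure(m, k_grid = as.integer(k_grid), payoff = payoff, params = params,
            class = c("payoff_matrix", "matrix", "array"))
}

#' @export
print.payoff_matrix <- function(x, digits = 4, ...) {
  p <- attr(x, "params")
  cat(sprintf("Expected %s payoffs (row player), V = %g, C = %g, T = %d\n",
              attr(x, "payoff"), p$V1, p$C1, p$T))
  print(round(unclass(x), digits))
  invisible(x)
}

#' Pure-ESS detection by the diagonal rule
#'
#' A pure strategy is an ESS if, when the whole population plays it, no rare
#' alternative earns more against it. On a payoff matrix this is the
#' diagonal rule: class `i` is an ESS when `M[i, i]` strictly exceeds every
#' other entry of column `i` (condition 1). When the column maximum is tied
#' with the diagonal (within `tol`), the second-order condition is checked
#' for every tying invader `j`: `M[i, j] > M[j, j]` (condition 2).
#'
#' @param m a [build_payoff_matrix()] result.
#' @param tol tolerance distinguishing genuine payoff ties from
#'   floating-point noise in the strict comparisons.
#' @return Object of class `ess_result`: list with `kind` (`"pure"` or
#'   `"none_found"`) and a data frame `ess` of the stable classes with their
#'   threshold interval and the condition that established them.
#' @export
find_pure_ess <- function(m, tol = 1e-9) {
  stopifnot(inherits(m, "payoff_matrix"))
  k_grid <- attr(m, "k_grid")
  p <- attr(m, "params")
  n <- nrow(m)
  hits <- list()
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    col <- m[, i]
    if (all(col[others] < col[i] - tol)) {
      hits[[length(hits) + 1L]] <- c(i = i, condition = 1)
      next
    }
    ties <- others[abs(col[others] - col[i]) <= tol]
    deficits <- others[col[others] > col[i] + tol]
    if (length(deficits) == 0L && length(ties) > 0L) {
      cond2 <- all(m[i, ties] > diag(m)[ties] + tol)
      if (cond2) hits[[length(hits) + 1L]] <- c(i = i, condition = 2)
    }
  }
  if (length(hits) == 0L) {
    return(structure(list(kind = "none_found",
                          ess = data.frame(), matrix = m, tol = tol),
                     class = "ess_result"))
  }
  idx <- vapply(hits, `[[`, numeric(1), "i")
  cond <- vapply(hits, `[[`, numeric(1), "condition")
  ks <- k_grid[idx]
  ratio <- (1 - p$C1) / (1 + p$V1)
  ess <- data.frame(
    k = ks,
    theta_rep = ifelse(ks >= 1, theta_rep(pmax(ks, 1L), p$V1, p$C1), NA_real_),
    theta_min = ifelse(ks >= 1, ratio^ks, 1),
    theta_sup = ifelse(ks >= 1, ratio^(ks - 1), Inf),
    condition = as.integer(cond)
  )
  structure(list(kind = "pure", ess = ess, matrix = m, tol = tol),
            class = "ess_result")
}

#' @export
print.ess_result <- function(x, ...) {
  if (x$kind == "none_found") {
    cat("No pure ESS found on the class grid",
        "(mixtures are not searched).\n")
    return(invisible(x))
  }
  cat("Pure ESS on the class grid:\n")
  for (i in seq_len(nrow(x$ess))) {
    e <- x$ess[i, ]
    if (e$k == 0) {
      cat(sprintf("  immediate retreat (theta > 1), via condition %d\n",
                  e$condition))
    } else {
      cat(sprintf("  k = %d, theta_rep = %.4f, interval [%.4f, %.4f), condition %d\n",
                  e$k, e$theta_rep, e$theta_min, e$theta_sup, e$condition))
    }
  }
  invisible(x)
}

#' Best response to a resident strategy
#'
#' Row indices attaining the maximum payoff in a given column of the payoff
#' matrix (ties returned together).
#'
#' @param m a [build_payoff_matrix()] result.
#' @param column column index (position in the grid) of the resident.
#' @param tol tie tolerance.
#' @return Integer vector of row indices, named by their `k` values.
#' @export
best_response <- function(m, column, tol = 1e-9) {
  stopifnot(inherits(m, "payoff_matrix"))
  col <- m[, column]
  idx <- which(col >= max(col) - tol)
  names(idx) <- attr(m, "k_grid")[idx]
  idx
}

#' ESS across a grid of V and C values
#'
#' Builds the payoff matrix and runs the diagonal rule for every combination
#' of `V_values` and `C_values`, returning one row per combination (and per
#' ESS, if several). When `V = 0` winning is worthless, so the
#' immediate-retreat class `0` is prepended to the grid for those
#' combinations. Degenerate `V = C = 0` pairs are skipped with a warning.
#'
#' @param V_values,C_values numeric vectors of gain/loss proportions.
#' @param T contest horizon.
#' @param rhp_initial initial RHP.
#' @param payoff `"log_rhp"` or `"share"`.
#' @param k_max largest concession class on the grid (the grid is
#'   `1:k_max`; the cut-off is arbitrary and should simply be large enough
#'   that the ESS lies strictly inside).
#' @return A data frame with columns `V`, `C`, `payoff`, `ess_k`,
#'   `theta_rep`, `theta_min`, `theta_sup` (`ess_k = NA` when no pure ESS
#'   exists, `ess_k = 0` for immediate retreat).
#' @export
ess_sweep <- function(V_values, C_values, T = 20, rhp_initial = 10,
                      payoff = c("log_rhp", "share"), k_max = 8) {
  payoff <- match.arg(payoff)
  rows <- list()
  for (V in V_values) {
    for (C in C_values) {
      if (V == 0 && C == 0) {
        warning("skipping degenerate combination V = C = 0")
        next
      }
      params <- game_params(V = V, C = C, rhp_initial = rhp_initial, T = T)
      grid <- if (V == 0) c(0L, seq_len(k_max)) else seq_len(k_max)
      res <- find_pure_ess(build_payoff_matrix(grid, params, payoff))
      if (res$kind == "none_found") {
        rows[[length(rows) + 1L]] <- data.frame(
          V = V, C = C, payoff = payoff, ess_k = NA_integer_,
          theta_rep = NA_real_, theta_min = NA_real_, theta_sup = NA_real_)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          V = V, C = C, payoff = payoff, ess_k = res$ess$k,
          theta_rep = res$ess$theta_rep, theta_min = res$ess$theta_min,
          theta_sup = res$ess$theta_sup)
      }
    }
  }
  do.call(rbind, rows)
}
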