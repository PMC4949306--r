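#' Critical win-loss deficit implied by a threshold
#'
#' Because RHP updates are multiplicative and both individuals start even,
#' the RHP ratio after `a` wins and `b` losses is `((1+V)/(1-C))^(a-b)`. A
#' threshold `theta` therefore translates into a critical value of the
#' win-loss difference,
#' `d = -ln(theta) / (ln(1+V) - ln(1-C))`,
#' below whose negative an individual retreats. `d` is negative for
#' `theta > 1` (concede from the even start) and `+Inf` for `theta = 0`
#' (never retreat).
#'
#' @param theta non-negative aggression threshold (vectorised).
#' @param V,C default-preset gain and loss proportions; at least one must be
#'   positive.
#' @return The real-valued critical difference `d`.
#' @export
d_value <- function(theta, V, C) {
  if (any(theta < 0)) stop("theta must be non-negative", call. = FALSE)
  if (V == 0 && C == 0) {
    stop("degenerate parameters: V = C = 0 leaves RHP constant and the ",
         "threshold mapping undefined", call. = FALSE)
  }
  denom <- log1p(V) - log1p(-C)
  ifelse(theta == 0, Inf, -log(theta) / denom)
}

#' Concession class of an aggression threshold
#'
#' Every threshold in an interval
#' `[((1-C)/(1+V))^k, ((1-C)/(1+V))^(k-1))` behaves identically: the
#' individual retreats exactly when its wins minus losses first reaches
#' `-k`. `class_from_theta()` maps a threshold to that integer class `k`,
#' together with the interval endpoints and the representative (midpoint)
#' threshold.
#'
#' The boundary convention follows the inclusive fight rule: a threshold
#' exactly on an interval endpoint belongs to the class that still fights
#' there, i.e. `k = floor(d) + 1` for the critical difference `d` (this
#' agrees with `ceiling(d)` at every non-integer `d`, and puts `theta = 1`
#' in class `k = 1`). Thresholds above 1 concede from the even start and are
#' reported as class `k = 0` ("immediate retreat").
#'
#' @param theta positive aggression threshold.
#' @inheritParams d_value
#' @return An object of class `threshold_class`: list with integer `k`
#'   (`0` = immediate retreat), `theta_min`, `theta_sup`, `theta_rep` and
#'   the generating `theta`, `V`, `C`.
#' @examples
#' class_from_theta(0.61, V = 0.1, C = 0.1)  # k = 3
#' class_from_theta(1.0,  V = 0.1, C = 0.1)  # k = 1
#' @export
class_from_theta <- function(theta, V, C) {
  stopifnot(length(theta) == 1L)
  if (theta <= 0) stop("theta must be positive here; theta = 0 never ",
                       "retreats and has no finite class", call. = FALSE)
  d <- d_value(theta, V, C)
  if (d < 0) {
    out <- list(k = 0L, theta_min = 1, theta_sup = Inf, theta_rep = NA_real_,
                theta = theta, V = V, C = C)
    return(structure(out, class = "threshold_class"))
  }
  # floor(d) + 1 with a 1e-9 fuzz so that representative thresholds map
  # back to their own class despite floating-point round-off
  k <- as.integer(floor(d + 1e-9)) + 1L
  ratio <- (1 - C) / (1 + V)
  structure(
    list(k = k,
         theta_min = ratio^k,
         theta_sup = ratio^(k - 1),
         theta_rep = theta_rep(k, V, C),
         theta = theta, V = V, C = C),
    class = "threshold_class"
  )
}

#' Representative threshold of a concession class
#'
#' The midpoint of the threshold interval for class `k`:
#' `((1-C)/(1+V))^k * (2+V-C) / (2(1-C))`. Used as the canonical label for
#' the class; for `V = C = 0.1` it gives the familiar ladder 0.91, 0.74,
#' 0.61, 0.50, 0.41, 0.33, 0.27, 0.22 for `k = 1, ..., 8`.
#'
#' @param k integer concession class, `>= 1` (vectorised).
#' @inheritParams d_value
#' @return The representative threshold(s).
#' @export
theta_rep <- function(k, V, C) {
  if (any(k < 1) || any(k != as.integer(k))) {
    stop("k must be an integer >= 1", call. = FALSE)
  }
  if (V == 0 && C == 0) {
    stop("degenerate parameters: V = C = 0", call. = FALSE)
  }
  ((1 - C) / (1 + V))^k * (2 + V - C) / (2 * (1 - C))
}

#' @export
print.threshold_class <- function(x, ...) {
  if (x$k == 0L) {
    cat(sprintf("Concession class: immediate retreat (theta = %g > 1)\n",
                x$theta))
  } else {
    cat(sprintf("Concession class k = %d (retreat when losses exceed wins by %d)\n",
                x$k, x$k))
    cat(sprintf("  theta interval [%.4f, %.4f), representative theta %.4f\n",
                x$theta_min, x$theta_sup, x$theta_rep))
  }
  invisible(x)
}

#' Rescale a threshold when V and C are scaled
#'
#' For small `V` and `C` the critical deficit satisfies
#' `d * (V + C) = -ln(theta)` approximately, so multiplying both `V` and `C`
#' by `alpha` maps an equivalent strategy to `theta^alpha`.
#'
#' @param theta positive threshold.
#' @param alpha positive scale factor applied to `V` and `C`.
#' @return `theta^alpha`.
#' @examples
#' scale_strategy(0.91, 1.5)  # 0.868
#' @export
scale_strategy <- function(theta, alpha) {
  if (any(theta <= 0)) stop("theta must be positive", call. = FALSE)
  if (any(alpha <= 0)) stop("alpha must be positive", call. = FALSE)
  theta^alpha
}

#' Check the approximate scaling invariance of concession classes
#'
#' Compares the concession class of `theta` under `(V, C)` with the class of
#' `theta^alpha` under `(alpha V, alpha C)`. The scaling law is a first-order
#' approximation in `V + C`; this report makes its accuracy explicit by
#' returning both exact critical differences and flagging a class change.
#'
#' @inheritParams scale_strategy
#' @inheritParams d_value
#' @return A list with `k_before`, `k_after`, `d_before`, `d_after`,
#'   `d_abs_diff` and the logical `class_preserved`.
#' @export
scaling_consistency <- function(theta, V, C, alpha) {
  if (alpha * C >= 1) {
    stop("scaled loss alpha * C >= 1 is out of range", call. = FALSE)
  }
  if (V + C > 0.3) {
    warning("scaling law derived for small V + C; V + C = ", V + C,
            " exceeds the documented validity range (<= 0.3)")
  }
  before <- class_from_theta(theta, V, C)
  after <- class_from_theta(scale_strategy(theta, alpha), alpha * V, alpha * C)
  list(
    k_before = before$k, k_after = after$k,
    d_before = d_value(theta, V, C),
    d_after = d_value(scale_strategy(theta, alpha), alpha * V, alpha * C),
    d_abs_diff = abs(d_value(theta, V, C) -
                       d_value(scale_strategy(theta, alpha),
                               alpha * V, alpha * C)),
    class_preserved = before$k == after$k
  )
}
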