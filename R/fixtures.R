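#' Deterministic parameter fixtures for property tests
#'
#' Generates a reproducible collection of valid contest-parameter sets:
#' random `(V, C, T)` triples inside documented ranges
#' (`V, C` in `[0.01, 0.3]`, `T` in `[4, 24]`), the named presets used in
#' the worked examples (`V = C = 0.1, T = 20` and `V = 0.02, C = 0.04`),
#' and the `(V, C)` grid of the group-size study.
#'
#' @param seed integer seed; the same seed always returns the same fixtures.
#' @param n number of random triples.
#' @return A list with data frames `random` (`V`, `C`, `T`), `presets` and
#'   `vc_grid`.
#' @export
make_fixtures <- function(seed, n = 20) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  random <- data.frame(
    V = round(stats::runif(n, 0.01, 0.3), 4),
    C = round(stats::runif(n, 0.01, 0.3), 4),
    T = sample(4:24, n, replace = TRUE)
  )
  presets <- data.frame(
    V = c(0.1, 0.02),
    C = c(0.1, 0.04),
    T = c(20L, 20L)
  )
  vc_grid <- expand.grid(
    V = c(0.01, 0.02, 0.03, 0.04, 0.05, 0.06, 0.07, 0.08, 0.09,
          0.1, 0.11, 0.12, 0.15, 0.18),
    C = c(0.025, 0.05, 0.075, 0.1, 0.125, 0.15)
  )
  list(random = random, presets = presets, vc_grid = vc_grid)
}
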