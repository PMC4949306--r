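# Output helpers: every CSV written by the package is paired with a JSON
# sidecar recording the effective parameters, so a run can be reproduced
# bit-identically from its outputs alone.

sidecar_path <- function(file) paste0(tools::file_path_sans_ext(file), ".json")

write_sidecar <- function(file, meta) {
  meta$package_version <- as.character(utils::packageVersion("wlgame"))
  jsonlite::write_json(meta, sidecar_path(file), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(sidecar_path(file))
}

params_meta <- function(params) {
  params[c("V1", "V2", "C1", "C2", "rhp_initial", "T")]
}

#' Export a payoff matrix as CSV with a JSON sidecar
#'
#' Rows are the focal (row player) classes, columns the opponent classes.
#'
#' @param m a [build_payoff_matrix()] result.
#' @param file output CSV path; the sidecar takes the same path with a
#'   `.json` extension.
#' @return `file`, invisibly.
#' @export
write_payoff_matrix <- function(m, file) {
  stopifnot(inherits(m, "payoff_matrix"))
  df <- data.frame(k_x = attr(m, "k_grid"), unclass(m), check.names = FALSE)
  names(df)[-1L] <- paste0("k_y=", attr(m, "k_grid"))
  utils::write.csv(df, file, row.names = FALSE)
  write_sidecar(file, list(kind = "payoff_matrix", payoff = attr(m, "payoff"),
                           k_grid = attr(m, "k_grid"),
                           params = params_meta(attr(m, "params"))))
  invisible(file)
}

#' Export a stopping-time distribution as CSV with a JSON sidecar
#'
#' @param sd a [stopping_distribution()] result.
#' @param file output CSV path.
#' @return `file`, invisibly.
#' @export
write_stopping_distribution <- function(sd, file) {
  stopifnot(inherits(sd, "stopping_distribution"))
  utils::write.csv(data.frame(t = sd$t, probability = sd$probability),
                   file, row.names = FALSE)
  write_sidecar(file, list(kind = "stopping_distribution",
                           k_x = attr(sd, "k_x"), k_y = attr(sd, "k_y"),
                           censored_mass = attr(sd, "censored_mass"),
                           params = params_meta(attr(sd, "params"))))
  invisible(file)
}

#' Export an evolutionary trajectory as CSV with a JSON summary sidecar
#'
#' One row per generation, one column per strategy on the grid.
#'
#' @param evo a [run_evolution()] result.
#' @param file output CSV path.
#' @return `file`, invisibly.
#' @export
write_trajectory <- function(evo, file) {
  stopifnot(inherits(evo, "wl_evolution"))
  df <- data.frame(generation = seq_len(nrow(evo$trajectory)),
                   evo$trajectory, check.names = FALSE)
  utils::write.csv(df, file, row.names = FALSE)
  cfg <- evo$config
  write_sidecar(file, list(
    kind = "evolution", ess = evo$ess, ess_mode = evo$ess_mode,
    ess_mean = evo$ess_mean, concentration = evo$concentration,
    generations = evo$generations, converged = evo$converged,
    seed = evo$seed,
    config = list(N = cfg$N, theta_grid = cfg$theta_grid,
                  n_groups = cfg$n_groups, contests = cfg$contests,
                  n_generations = cfg$n_generations, scale = cfg$scale,
                  params = params_meta(cfg$params))))
  invisible(file)
}

#' Read and write run configurations
#'
#' Round-trips a flat list of run settings through a YAML file. Used by the
#' command-line interface, where flags override file values.
#'
#' @param file YAML path.
#' @param config named list to write.
#' @return `read_run_config()` returns the named list; `write_run_config()`
#'   returns `file` invisibly.
#' @export
read_run_config <- function(file) yaml::read_yaml(file)

#' @rdname read_run_config
#' @export
write_run_config <- function(config, file) {
  yaml::write_yaml(config, file)
  invisible(file)
}
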