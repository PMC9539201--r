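## Trajectory/report serialization and scenario files.

#' Write a trajectory to CSV (with a JSON metadata sidecar)
#'
#' The CSV holds the `time` column plus one column per node at full
#' precision; a `<path>.json` sidecar records the network name/version,
#' clamp levels, schedules and gate parameters so a run can be identified
#' later. `read_trajectory()` reproduces the values exactly.
#'
#' @param traj A `fz_trajectory`.
#' @param path Output CSV path.
#' @param sidecar Write the JSON sidecar? Default `TRUE`.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, sidecar = TRUE) {
  stopifnot(inherits(traj, "fz_trajectory"))
  df <- as.data.frame(traj)
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  if (sidecar) {
    net <- trajectory_network(traj)
    env <- trajectory_env(traj)
    meta <- list(
      network = net$name, version = net$version,
      n_nodes = length(net$nodes),
      gate = as.list(attr(traj, "gate")),
      levels = as.list(env$levels),
      schedules = purrr::map(env$schedules, unclass),
      alpha_override = as.list(env$alpha_override),
      t_end = max(traj$time)
    )
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Read a trajectory CSV written by [write_trajectory()]
#'
#' @param path CSV path.
#' @return A tibble with `time` and node columns (plain data; network and
#'   environment attributes are not reattached).
#' @export
read_trajectory <- function(path) {
  tb <- tibble::as_tibble(utils::read.csv(path, check.names = FALSE))
  tb[] <- lapply(tb, as.numeric)
  tb
}

#' Write an attractor report to JSON
#'
#' @param report An `fz_attractor` tibble from [steady_state()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_attractor_json <- function(report, path) {
  stopifnot(inherits(report, "fz_attractor"))
  out <- list(window = attr(report, "window"),
              nodes = purrr::transpose(as.list(as.data.frame(report))))
  names(out$nodes) <- report$node
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a scenario file (YAML or JSON)
#'
#' A scenario file maps input names to clamp levels and may carry
#' `t_ctla4`, `t_end` and per-input `stimulus` overrides
#' (`A`, `D`, `T`, `beta_s`). Returns the assembled environment plus the
#' horizon.
#'
#' @param path Scenario file path.
#' @param manifest Role manifest for defaults.
#' @return A list with elements `env` (a `fz_env`) and `t_end`.
#' @export
read_scenario <- function(path, manifest = cd4_manifest()) {
  sc <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  lv <- unlist(sc$levels %||% list())
  stim <- purrr::map(sc$stimulus %||% list(), function(p) {
    do.call(step_stimulus, as.list(p))
  })
  env <- cd4_env(levels = lv, t_ctla4 = sc$t_ctla4 %||% 1,
                 stimulus = stim, manifest = manifest)
  list(env = env, t_end = sc$t_end %||% 30)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
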