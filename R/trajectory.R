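#' Trajectory container and run summaries
#'
#' Both simulation engines record one row per ancestor-descendant mapping:
#' the mapping index, total number of populations `n_total`, and the
#' count-weighted means `mean_y` and `mean_z` (NA once the metapopulation is
#' empty). Row 0 is the initial state. A run that hits its extinction
#' condition is truncated there, with the mapping index kept in the
#' `extinction_mapping` attribute.
#'
#' @name hgt_trajectory
NULL

new_trajectory <- function(mat, params, extinction_mapping, final_state,
                           seed = NULL) {
  df <- as.data.frame(mat)
  names(df) <- c("mapping", "n_total", "mean_y", "mean_z")
  structure(df,
            params = params,
            extinction_mapping = extinction_mapping,
            final_state = final_state,
            seed = seed,
            class = c("hgt_trajectory", "data.frame"))
}

#' @export
print.hgt_trajectory <- function(x, ...) {
  s <- run_summary(x)
  cat(sprintf("Trajectory over %d mapping(s)\n", max(x$mapping)))
  if (s$extinct) {
    cat(sprintf("  extinct at mapping %d\n", s$extinction_mapping))
  } else {
    cat(sprintf("  final N = %g (mean y = %.3f, mean z = %.3f)\n",
                s$final_n, s$final_mean_y, s$final_mean_z))
  }
  invisible(x)
}

#' Final state of a simulation run
#'
#' @param traj An `hgt_trajectory` returned by [run_expected()] or
#'   [run_stochastic()].
#' @return The terminal [metapop()] state.
#' @export
final_state <- function(traj) {
  attr(traj, "final_state")
}

#' Summarize a simulation run
#'
#' @param traj An `hgt_trajectory`.
#' @return A list with `extinct`, `extinction_mapping` (NA when not
#'   extinct), `final_n`, `final_mean_y`, `final_mean_z`, `seed` (NA for
#'   deterministic runs) and a `params` echo.
#' @export
run_summary <- function(traj) {
  stopifnot(inherits(traj, "hgt_trajectory"))
  last <- traj[nrow(traj), ]
  ext <- attr(traj, "extinction_mapping")
  seed <- attr(traj, "seed")
  list(
    extinct = !is.na(ext),
    extinction_mapping = if (is.na(ext)) NA_integer_ else as.integer(ext),
    final_n = as.numeric(last$n_total),
    final_mean_y = as.numeric(last$mean_y),
    final_mean_z = as.numeric(last$mean_z),
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
    params = unclass(attr(traj, "params"))
  )
}

#' Write a trajectory to CSV
#'
#' Comma-separated with a header row, `.` decimal separator, UTF-8, no row
#' names; reruns with identical inputs reproduce the file byte for byte.
#'
#' @param traj An `hgt_trajectory` (or the sweep table from [sweep_beta()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a run summary as JSON
#'
#' @param traj An `hgt_trajectory`.
#' @param path Output path (`.json`).
#' @return `path`, invisibly.
#' @export
write_summary <- function(traj, path) {
  jsonlite::write_json(run_summary(traj), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}
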