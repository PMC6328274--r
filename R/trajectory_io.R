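# Trajectory interchange: one CSV per trajectory (long format, fixed 9
# significant-digit formatting so identical runs are byte-identical) plus a
# JSON sidecar with the full config, seed, config hash, and versions.

traj_columns <- c("time_s", "cargo_id", "x_um", "y_um",
                  "n_bound", "n_free", "n_refractory")

fmt_num <- function(x) {
  out <- formatC(x, digits = 9, format = "g", flag = "-")
  trimws(out)
}

#' Convert a trajectory to the long tabular interchange format
#' @param x A `trajectory`.
#' @param ... Unused.
#' @return A data frame with columns `time_s, cargo_id, x_um, y_um, n_bound,
#'   n_free, n_refractory` (pool counts repeated across cargos of a record).
#' @export
as.data.frame.trajectory <- function(x, ...) {
  n_rec <- length(x$times)
  n_cargo <- x$n_cargo
  data.frame(
    time_s = rep(x$times, each = n_cargo),
    cargo_id = rep(seq_len(n_cargo), times = n_rec),
    x_um = as.vector(t(x$x)),
    y_um = as.vector(t(x$y)),
    n_bound = rep(x$pools$n_bound, each = n_cargo),
    n_free = rep(x$pools$n_free, each = n_cargo),
    n_refractory = rep(x$pools$n_refractory, each = n_cargo)
  )
}

#' Write a trajectory to a directory
#'
#' Writes `trajectory.csv` (schema above) and `metadata.json` (schema
#' version, software version, seed, config hash, full config). Two runs with
#' identical config and seed produce byte-identical files.
#'
#' @param traj A `trajectory`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_trajectory <- function(traj, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  df <- as.data.frame(traj)
  df$time_s <- fmt_num(df$time_s)
  df$x_um <- fmt_num(df$x_um)
  df$y_um <- fmt_num(df$y_um)
  lines <- c(paste(traj_columns, collapse = ","),
             do.call(paste, c(unname(df[traj_columns]), sep = ",")))
  writeLines(lines, file.path(dir, "trajectory.csv"))
  meta <- list(schema_version = traj$meta$schema_version,
               software_version = traj$meta$software_version,
               seed = traj$meta$seed,
               config_hash = traj$meta$config_hash,
               n_cargo = traj$n_cargo,
               overlap_warnings = traj$overlap_warnings,
               config = traj$meta$config)
  writeLines(as.character(jsonlite::toJSON(meta, auto_unbox = TRUE,
                                           digits = NA, null = "null",
                                           pretty = TRUE)),
             file.path(dir, "metadata.json"))
  invisible(dir)
}

#' Read a trajectory written by [write_trajectory()]
#'
#' @param dir Directory containing `trajectory.csv` and `metadata.json`.
#' @return A `trajectory`. Positions round-trip to better than 1e-9 um;
#'   metadata exactly.
#' @export
read_trajectory <- function(dir) {
  csv <- file.path(dir, "trajectory.csv")
  mj <- file.path(dir, "metadata.json")
  if (!file.exists(csv) || !file.exists(mj))
    stop("read_trajectory: missing trajectory.csv or metadata.json in ", dir)
  meta <- jsonlite::fromJSON(mj, simplifyVector = TRUE)
  if (!identical(meta$schema_version, SCHEMA_VERSION))
    stop("trajectory schema version mismatch: file has ",
         format(meta$schema_version), ", this package reads ", SCHEMA_VERSION)
  header <- strsplit(readLines(csv, n = 1), ",", fixed = TRUE)[[1]]
  if (!identical(header, traj_columns))
    stop("trajectory schema error: expected columns ",
         paste(traj_columns, collapse = ", "), " but found ",
         paste(header, collapse = ", "))
  df <- read.csv(csv, colClasses = c(time_s = "numeric", cargo_id = "integer",
                                     x_um = "numeric", y_um = "numeric",
                                     n_bound = "integer", n_free = "integer",
                                     n_refractory = "integer"))
  n_cargo <- meta$n_cargo
  n_rec <- nrow(df) / n_cargo
  if (n_rec != as.integer(n_rec))
    stop("trajectory schema error: row count is not a multiple of n_cargo")
  times <- df$time_s[seq(1, nrow(df), by = n_cargo)]
  X <- matrix(df$x_um, nrow = n_rec, ncol = n_cargo, byrow = TRUE)
  Y <- matrix(df$y_um, nrow = n_rec, ncol = n_cargo, byrow = TRUE)
  pools_mat <- cbind(df$n_bound[seq(1, nrow(df), by = n_cargo)],
                     df$n_free[seq(1, nrow(df), by = n_cargo)],
                     df$n_refractory[seq(1, nrow(df), by = n_cargo)])
  cfg <- rapply(meta$config, function(v) v, how = "replace")
  tr <- new_trajectory(times, X, Y, pools_mat, cfg, seed = meta$seed,
                       overlap_warnings = meta$overlap_warnings)
  tr$meta$schema_version <- meta$schema_version
  tr$meta$software_version <- meta$software_version
  tr$meta$config_hash <- meta$config_hash
  tr
}

#' Write an ensemble to a directory tree
#'
#' One subdirectory `traj_<seed>` per trajectory plus `ensemble.json` with
#' the summary statistics and per-trajectory records.
#'
#' @param ens An `ensemble_result` (with kept trajectories).
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_ensemble <- function(ens, dir) {
  if (any(vapply(ens$trajectories, is.null, TRUE)))
    stop("write_ensemble needs an ensemble run with keep_trajectories = TRUE")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(ens$n_trajectories))
    write_trajectory(ens$trajectories[[i]],
                     file.path(dir, paste0("traj_", ens$seeds[i])))
  summ <- list(n_trajectories = ens$n_trajectories, seeds = ens$seeds,
               master_seed = ens$master_seed,
               mean_nn = ens$mean_nn, sd_nn = ens$sd_nn,
               mean_pairwise = ens$mean_pairwise, sd_pairwise = ens$sd_pairwise,
               sd_degenerate = ens$sd_degenerate,
               labels = ens$labels, separation = ens$separation,
               config = ens$config)
  writeLines(as.character(jsonlite::toJSON(summ, auto_unbox = TRUE,
                                           digits = NA, null = "null",
                                           pretty = TRUE)),
             file.path(dir, "ensemble.json"))
  invisible(dir)
}
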