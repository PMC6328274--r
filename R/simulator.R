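#' Initialize a simulation state
#'
#' Places `n_cargo` carboxysomes uniformly at random within `cluster_radius`
#' of the domain centroid (resampled until pairwise non-overlapping and
#' inside the domain), and pre-equilibrates the cargo-free McdA chemistry for
#' `5 * tau_reset` of simulated time so the lattice starts at its bulk steady
#' state. No tethers exist initially. Uses the R RNG.
#'
#' @param config A `sim_config` (see [default_config()]).
#' @return `list(geom, lattice, pools, centers, config)` where `centers` is an
#'   `n_cargo` x 2 matrix.
#' @export
init_state <- function(config) {
  config <- validate_config(unclass(config))
  geom <- config_geometry(config)
  lattice <- build_lattice(geom, config$simulation$lattice_spacing)
  pools <- make_pools(config$chemistry$n_total)
  params <- chemistry_params(config$chemistry$k_on, config$chemistry$k_off_basal,
                             config$chemistry$tau_reset)
  eq <- chemistry_run(lattice, pools, params,
                      duration = 5 * config$chemistry$tau_reset)
  lattice <- eq$lattice; pools <- eq$pools

  n <- config$simulation$n_cargo
  R <- config$cargo$radius
  rc <- config$simulation$cluster_radius
  centers <- matrix(numeric(0), 0, 2)
  attempts <- 0L
  while (nrow(centers) < n) {
    if (attempts > 2000L * max(n, 1L))
      stop("could not place ", n, " non-overlapping cargos within ",
           "cluster_radius = ", rc, " um; increase the cluster radius")
    attempts <- attempts + 1L
    th <- runif(1, 0, 2 * pi); rr <- rc * sqrt(runif(1))
    p <- c(rr * cos(th), rr * sin(th))
    if (!geom_contains(geom, p[1], p[2])) next
    if (nrow(centers) > 0 &&
        any((centers[, 1] - p[1])^2 + (centers[, 2] - p[2])^2 < (2 * R)^2)) next
    centers <- rbind(centers, p)
  }
  dimnames(centers) <- NULL
  list(geom = geom, lattice = lattice, pools = pools, centers = centers,
       config = config)
}

new_trajectory <- function(times, x, y, pools_mat, config, seed,
                           final_lattice = NULL, tether_count = NULL,
                           snapshots = NULL, snapshot_times = NULL,
                           overlap_warnings = 0L) {
  structure(list(
    times = as.numeric(times),
    x = x, y = y,
    pools = data.frame(time_s = as.numeric(times),
                       n_bound = pools_mat[, 1], n_free = pools_mat[, 2],
                       n_refractory = pools_mat[, 3]),
    n_cargo = ncol(x),
    meta = list(config = unclass(config), seed = seed,
                config_hash = config_hash(config),
                schema_version = SCHEMA_VERSION,
                software_version = as.character(packageVersion("mcdpos"))),
    final_lattice = final_lattice,
    tether_count = tether_count,
    snapshots = snapshots, snapshot_times = snapshot_times,
    overlap_warnings = overlap_warnings), class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d cargos, %d records over %.4g s (seed %s)\n",
              x$n_cargo, length(x$times), max(x$times),
              format(x$meta$seed)))
  invisible(x)
}

#' Run one simulated trajectory
#'
#' The kinetic Monte Carlo stage of the model: a fixed-timestep loop coupling
#' tau-leaped McdA chemistry, per-cargo tether kinetics (with McdB-stimulated
#' release on every bond breakage), overdamped Langevin cargo motion with
#' reflective boundaries, and hard-disk cargo exclusion. Update order within a
#' step is chemistry, tethers, motion, exclusion; the cargo update order is
#' randomized each step. Fully reproducible from `(config, master_seed)`.
#'
#' @param config A `sim_config`.
#' @param pin_cargos Test hook: freeze all cargo motion (tether and chemistry
#'   kinetics still run), used to probe the self-generated depletion zone.
#' @return A `trajectory` object: `times`, position matrices `x`, `y`
#'   (records x cargos), `pools` data frame, per-record `tether_count`, the
#'   final lattice, and metadata (full config, seed, config hash, version).
#' @export
run_simulation <- function(config, pin_cargos = FALSE) {
  config <- validate_config(unclass(config))
  set.seed(config$simulation$master_seed)
  state <- init_state(config)
  si <- config$simulation
  snap_every <- if (si$field_snapshot_interval > 0)
    max(1L, as.integer(round(si$field_snapshot_interval / si$record_interval)))
  else 0L
  res <- cpp_run(state$geom$c, state$geom$r,
                 state$lattice$x, state$lattice$y,
                 state$lattice$i, state$lattice$j,
                 state$lattice$spacing,
                 as.integer(ifelse(state$lattice$occupied, 1L, 0L)),
                 config$chemistry$n_total, state$pools$n_free,
                 state$pools$n_refractory,
                 config$chemistry$k_on, config$chemistry$k_off_basal,
                 config$chemistry$tau_reset,
                 config$tethers$r_capture, config$tethers$k_attach,
                 config$tethers$k_detach, config$tethers$k_spring,
                 config$tethers$rest_length, config$cargo$n_mcdb,
                 config$cargo$radius, config$cargo$D_free,
                 config$motion$exclusion == "hard_disk",
                 state$centers[, 1], state$centers[, 2],
                 config$motion$dt, si$duration, si$record_interval,
                 snap_every, pin_cargos)
  lat <- state$lattice
  lat$occupied <- res$occ > 0L
  lat$tethered <- res$occ == 2L
  new_trajectory(res$times, res$x, res$y, res$pools, config,
                 seed = si$master_seed, final_lattice = lat,
                 tether_count = res$tether_count,
                 snapshots = if (length(res$snapshots)) res$snapshots,
                 snapshot_times = if (length(res$snapshots)) res$snapshot_times,
                 overlap_warnings = res$overlap_warnings)
}

#' Cargo positions at a given record
#' @param traj A `trajectory`.
#' @param time Time (s); defaults to the final record.
#' @return n x 2 matrix of centers.
#' @export
positions_at <- function(traj, time = NULL) {
  k <- if (is.null(time)) length(traj$times)
  else which.min(abs(traj$times - time))
  cbind(traj$x[k, ], traj$y[k, ])
}

#' Run an ensemble of independent trajectories
#'
#' Trajectory `i` (1-based) runs with seed `master_seed + i - 1`; the seed
#' derivation is part of the public contract so published ensembles are
#' reproducible. Summaries (mean and SD over trajectories of the final
#' mean nearest-neighbor and mean pairwise separations) are recomputable from
#' the stored per-trajectory records.
#'
#' @param config A `sim_config`.
#' @param n_trajectories Ensemble size (default 36).
#' @param master_seed Base seed (default from the config).
#' @param keep_trajectories Keep the full `trajectory` objects (default TRUE).
#' @return An `ensemble_result`: `seeds`, `finals` (list of final position
#'   matrices), `separation` data frame (per-trajectory mean_nn and
#'   mean_pairwise), `mean_nn`, `sd_nn`, `mean_pairwise`, `sd_pairwise`,
#'   `labels` (per-trajectory [classify_arrangement()] labels), and the
#'   trajectories themselves.
#' @export
run_ensemble <- function(config, n_trajectories = 36L,
                         master_seed = config$simulation$master_seed,
                         keep_trajectories = TRUE) {
  stopifnot(n_trajectories >= 1)
  config <- validate_config(unclass(config))
  geom <- config_geometry(config)
  seeds <- master_seed + seq_len(n_trajectories) - 1L
  trajs <- vector("list", n_trajectories)
  finals <- vector("list", n_trajectories)
  labels <- character(n_trajectories)
  sep <- data.frame(seed = seeds, mean_nn = NA_real_, mean_pairwise = NA_real_)
  for (i in seq_len(n_trajectories)) {
    cfg_i <- config_set(config, `simulation.master_seed` = seeds[i])
    tr <- run_simulation(cfg_i)
    finals[[i]] <- positions_at(tr)
    if (config$simulation$n_cargo >= 2) {
      ss <- separation_stats(finals[[i]])
      sep$mean_nn[i] <- ss$mean_nn
      sep$mean_pairwise[i] <- ss$mean_pairwise
      labels[i] <- classify_arrangement(finals[[i]], geom,
                                        thresholds = config$analysis_thresholds)$label
    } else labels[i] <- NA_character_
    trajs[[i]] <- if (keep_trajectories) tr
  }
  structure(list(
    n_trajectories = n_trajectories, seeds = seeds, finals = finals,
    separation = sep,
    mean_nn = mean(sep$mean_nn), sd_nn = sd(sep$mean_nn),
    mean_pairwise = mean(sep$mean_pairwise), sd_pairwise = sd(sep$mean_pairwise),
    sd_degenerate = n_trajectories == 1L,
    labels = labels, trajectories = trajs,
    config = unclass(config), master_seed = master_seed),
    class = "ensemble_result")
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat(sprintf("<ensemble_result> n = %d trajectories, %d cargos\n",
              x$n_trajectories, x$config$simulation$n_cargo))
  if (!is.na(x$mean_nn))
    cat(sprintf("  mean nearest-neighbor separation %.3f +/- %.3f um; mean pairwise %.3f +/- %.3f um\n",
                x$mean_nn, ifelse(x$sd_degenerate, 0, x$sd_nn),
                x$mean_pairwise, ifelse(x$sd_degenerate, 0, x$sd_pairwise)))
  if (!all(is.na(x$labels)))
    print(table(arrangement = x$labels))
  invisible(x)
}

#' Scan a parameter grid for motility regimes
#'
#' Evaluates the Cartesian product of the supplied parameter values; each
#' cell runs [run_ensemble()] with `n_per_cell` trajectories and classifies
#' every trajectory with [classify_motility()].
#'
#' @param base A `sim_config` to start from.
#' @param grid Named list mapping dotted parameter names
#'   (e.g. `"tethers.k_attach"`) to value vectors. An empty list means a
#'   single cell equal to the base configuration.
#' @param n_per_cell Trajectories per grid cell.
#' @return A data frame with one row per cell: the parameter values, the
#'   majority `regime` label, the per-cell mean and SD of the final mean
#'   nearest-neighbor separation, and the seeds used.
#' @export
scan_regime <- function(base, grid = list(), n_per_cell = 4L) {
  base <- validate_config(unclass(base))
  for (nm in names(grid)) # fail fast on unknown parameter names
    do.call(config_set, c(list(base), stats::setNames(list(grid[[nm]][1]), nm)))
  cells <- if (length(grid) == 0) data.frame(row.names = 1)
  else expand.grid(grid, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- vector("list", nrow(cells))
  for (r in seq_len(nrow(cells))) {
    cfg <- base
    if (ncol(cells) > 0)
      for (nm in names(cells))
        cfg <- do.call(config_set,
                       c(list(cfg), stats::setNames(list(cells[[nm]][r]), nm)))
    ens <- run_ensemble(cfg, n_trajectories = n_per_cell)
    regimes <- vapply(ens$trajectories, function(tr)
      classify_motility(tr, thresholds = cfg$analysis_thresholds)$label, "")
    maj <- names(sort(table(regimes), decreasing = TRUE))[1]
    row <- data.frame(regime = maj, mean_nn = ens$mean_nn,
                      sd_nn = ens$sd_nn,
                      seeds = paste(ens$seeds, collapse = ";"))
    if (ncol(cells) > 0) row <- cbind(cells[r, , drop = FALSE], row)
    out[[r]] <- row
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
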