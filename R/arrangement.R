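#' Separation statistics of a cargo configuration
#'
#' Two readings of "average distance between carboxysomes": the
#' nearest-neighbor distance averaged over cargos, and the mean over all
#' unordered pairs. Both are reported throughout because figure-level
#' "average distance" statistics are ambiguous between the two.
#'
#' @param positions n x 2 matrix (n >= 2) of cargo centers.
#' @return `list(mean_nn, mean_pairwise)` in um.
#' @export
separation_stats <- function(positions) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  if (n < 2) stop("separation_stats needs at least 2 positions")
  dm <- as.matrix(dist(positions))
  diag(dm) <- Inf
  list(mean_nn = mean(apply(dm, 1, min)),
       mean_pairwise = mean(dm[upper.tri(dm)]))
}

#' Default arrangement-classification thresholds
#'
#' The packing classes in the model output (and in micrographs) are visually
#' unambiguous in the ideal cases; these thresholds turn them into a
#' quantitative rule. `t_lin` is the maximum transverse spread (SD of y, um)
#' for a linear call; `alternation_min` the minimum fraction of consecutive
#' x-sorted pairs with opposite-sign y (about the mean) for a staggered call;
#' `clustered_nn_factor` times the cargo radius bounds the mean
#' nearest-neighbor distance of a cluster; `spacing_cv_max` bounds the
#' coefficient of variation of consecutive (x-sorted) neighbor distances a
#' staggered arrangement may have -- hexagonal packing means near-equidistant
#' neighbors, and this gate is what separates a true zig-zag from a random
#' configuration whose y signs happen to alternate.
#'
#' @param t_lin,alternation_min,clustered_nn_factor,spacing_cv_max,cargo_radius
#'   See description.
#' @return A named list.
#' @export
arrangement_thresholds <- function(t_lin = 0.05, alternation_min = 0.75,
                                   clustered_nn_factor = 2.5,
                                   spacing_cv_max = 0.25, cargo_radius = 0.0875) {
  list(t_lin = t_lin, alternation_min = alternation_min,
       clustered_nn_factor = clustered_nn_factor,
       spacing_cv_max = spacing_cv_max, cargo_radius = cargo_radius)
}

#' Classify a cargo arrangement as linear, staggered, clustered, or other
#'
#' Cargos are sorted by x. The configuration is `clustered` when the mean
#' nearest-neighbor distance falls below `clustered_nn_factor * cargo_radius`;
#' else `linear` when the transverse spread (SD of y) is at most `t_lin`;
#' else `staggered` (the zig-zag half of hexagonal packing) when consecutive
#' x-sorted cargos alternate sides of the long axis in at least
#' `alternation_min` of consecutive pairs *and* consecutive neighbors are
#' near-equidistant (coefficient of variation of consecutive-pair distances
#' at most `spacing_cv_max`); otherwise `other`. Alternation requires n >= 3. The staggering index is
#' the mean over consecutive pairs of `|y_i - y_{i+1}| / (2 * sd(y))`
#' (0 for collinear input by convention).
#'
#' @param positions n x 2 matrix (n >= 2) of centers inside `geom`.
#' @param geom A `nucleoid_geometry`.
#' @param thresholds See [arrangement_thresholds()]; a config
#'   `analysis_thresholds` section is also accepted.
#' @return An `arrangement_report`: `label`, `mean_nn_distance`,
#'   `mean_pairwise_distance`, `transverse_spread`, `staggering_index`,
#'   `alternation_fraction` (NA for n < 3).
#' @export
classify_arrangement <- function(positions, geom,
                                 thresholds = arrangement_thresholds()) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  if (n < 2) stop("classify_arrangement needs at least 2 positions")
  if (!all(geom_contains(geom, positions)))
    stop("classify_arrangement: positions outside the domain")
  th <- arrangement_thresholds()
  th[names(thresholds)[names(thresholds) %in% names(th)]] <-
    thresholds[names(thresholds) %in% names(th)]

  ord <- order(positions[, 1])
  xs <- positions[ord, 1]; ys <- positions[ord, 2]
  sep <- separation_stats(positions)
  spread <- sd(ys)
  yc <- ys - mean(ys)
  alt <- if (n >= 3) {
    s <- sign(yc)
    mean(s[-n] * s[-1] < 0)
  } else NA_real_
  stag <- if (spread > 0) mean(abs(diff(ys))) / (2 * spread) else 0
  cons <- sqrt(diff(xs)^2 + diff(ys)^2)
  spacing_cv <- if (n >= 3 && mean(cons) > 0) sd(cons) / mean(cons) else Inf

  label <-
    if (sep$mean_nn < th$clustered_nn_factor * th$cargo_radius) "clustered"
    else if (spread <= th$t_lin) "linear"
    else if (!is.na(alt) && alt >= th$alternation_min &&
             spacing_cv <= th$spacing_cv_max) "staggered"
    else "other"

  structure(list(label = label,
                 mean_nn_distance = sep$mean_nn,
                 mean_pairwise_distance = sep$mean_pairwise,
                 transverse_spread = spread,
                 staggering_index = stag,
                 alternation_fraction = alt,
                 n = n), class = "arrangement_report")
}

#' @export
print.arrangement_report <- function(x, ...) {
  cat(sprintf("<arrangement_report> %s (n = %d)\n", x$label, x$n))
  cat(sprintf("  mean nn %.3f um, mean pairwise %.3f um, transverse spread %.3f um\n",
              x$mean_nn_distance, x$mean_pairwise_distance, x$transverse_spread))
  cat(sprintf("  staggering index %.2f, alternation fraction %s\n",
              x$staggering_index, format(x$alternation_fraction)))
  invisible(x)
}

#' Earliest time after which all cargos stay put
#'
#' Returns the earliest recorded time `t*` such that within every subsequent
#' window of length `window`, no cargo moves more than `eps` between any two
#' records of the window; `NULL` if that never happens ("relatively
#' stationary" detection).
#'
#' @param traj A `trajectory`.
#' @param window Window length (s), default 60.
#' @param eps Displacement tolerance (um), default 0.05.
#' @return A time (s) or `NULL`.
#' @export
steady_state_time <- function(traj, window = 60, eps = 0.05) {
  times <- traj$times
  n_rec <- length(times)
  if (window >= max(times) - min(times))
    stop("steady_state_time: window must be shorter than the trajectory")
  # anchors whose window fits inside the record span; trailing partial
  # windows are subsets of the last full one, so checking these suffices
  anchors <- which(times <= max(times) - window)
  ok <- logical(length(anchors))
  for (k in anchors) {
    idx <- which(times >= times[k] & times <= times[k] + window)
    good <- TRUE
    for (m in seq_len(traj$n_cargo)) {
      xs <- traj$x[idx, m]; ys <- traj$y[idx, m]
      if ((max(xs) - min(xs))^2 + (max(ys) - min(ys))^2 > (eps * 1.0001)^2) {
        # cheap bound failed; check true max pairwise displacement
        dm <- max(dist(cbind(xs, ys)))
        if (dm > eps) { good <- FALSE; break }
      }
    }
    ok[k] <- good
  }
  holds <- rev(cumprod(rev(ok))) > 0 # ok from anchor k to the last anchor
  if (!any(holds)) return(NULL)
  times[anchors[which(holds)[1]]]
}

#' Local McdA depletion around a cargo
#'
#' Ratio of the occupied fraction in the annulus `r_inner < d <= r_outer`
#' around the cargo center to the occupied fraction in the bulk (all sites
#' farther than `r_outer`): 1 means no depletion, 0 full depletion.
#'
#' @param lattice An `mcda_lattice`.
#' @param center Length-2 cargo center, or a `carboxysome`.
#' @param r_inner,r_outer Annulus radii (um); defaults are the cargo radius
#'   and radius + 0.2.
#' @return Non-negative ratio.
#' @export
depletion_index <- function(lattice, center, r_inner = 0.0875,
                            r_outer = 0.0875 + 0.2) {
  if (inherits(center, "carboxysome")) center <- center$center
  stopifnot(r_inner < r_outer)
  d2 <- (lattice$x - center[1])^2 + (lattice$y - center[2])^2
  ann <- d2 > r_inner^2 & d2 <= r_outer^2
  bulk <- d2 > r_outer^2
  if (!any(ann)) stop("depletion_index: annulus contains no site")
  if (!any(bulk)) stop("depletion_index: bulk contains no site")
  fb <- occupancy_fraction(lattice, bulk)
  if (fb == 0) stop("depletion_index: bulk occupancy is zero")
  occupancy_fraction(lattice, ann) / fb
}

#' Classify the motility regime of a trajectory
#'
#' `directed_segregation` when a steady state is detected and the mean
#' pairwise separation gained more than `gain_threshold` um between the first
#' record and the steady state; `static` when the steady state starts at the
#' first record without such a gain; `diffusive` when no steady state exists
#' and the ensemble-averaged MSD grows as `t^alpha` with `alpha` in
#' `slope_range`; `other` otherwise.
#'
#' @param traj A `trajectory` with >= 2 cargos and >= 10 records (single-cargo
#'   trajectories are classified on displacement alone, with separation gain
#'   treated as zero).
#' @param thresholds Named list; recognized entries `gain_threshold` (um,
#'   default 0.3), `ss_window` (s, 60), `ss_eps` (um, 0.05), `slope_range`
#'   (default `c(0.8, 1.2)`). A config `analysis_thresholds` section works.
#' @return A `regime_label`: `label` plus supporting statistics
#'   (`separation_gain`, `steady_state_time`, `msd_slope`).
#' @export
classify_motility <- function(traj, thresholds = list()) {
  th <- list(gain_threshold = 0.3, ss_window = 60, ss_eps = 0.05,
             slope_range = c(0.8, 1.2))
  th[names(thresholds)[names(thresholds) %in% names(th)]] <-
    thresholds[names(thresholds) %in% names(th)]
  if (length(traj$times) < 10) stop("classify_motility needs >= 10 records")

  # for trajectories shorter than twice the arrest window, shrink the window
  span <- max(traj$times) - min(traj$times)
  window <- min(th$ss_window, span / 2)
  ss <- steady_state_time(traj, window = window, eps = th$ss_eps)
  gain <- if (traj$n_cargo >= 2) {
    t_ref <- if (is.null(ss)) max(traj$times) else ss
    separation_stats(positions_at(traj, t_ref))$mean_pairwise -
      separation_stats(positions_at(traj, traj$times[1]))$mean_pairwise
  } else 0

  # ensemble-averaged MSD over short lags (the pre-boundary regime: in a
  # confined domain the MSD saturates, so long lags bias the exponent down)
  n_rec <- length(traj$times)
  lags <- seq_len(min(30L, max(2L, n_rec %/% 4L)))
  msd <- vapply(lags, function(L) {
    dx <- traj$x[seq_len(n_rec - L) + L, , drop = FALSE] -
      traj$x[seq_len(n_rec - L), , drop = FALSE]
    dy <- traj$y[seq_len(n_rec - L) + L, , drop = FALSE] -
      traj$y[seq_len(n_rec - L), , drop = FALSE]
    mean(dx^2 + dy^2)
  }, 0)
  tau <- (traj$times[1 + lags] - traj$times[1])
  pos <- msd > 0 & tau > 0
  slope <- if (sum(pos) >= 2) unname(coef(lm(log(msd[pos]) ~ log(tau[pos])))[2])
  else NA_real_

  label <-
    if (!is.null(ss) && ss <= traj$times[1] + 1e-9 && gain <= th$gain_threshold)
      "static"
    else if (!is.null(ss) && gain > th$gain_threshold) "directed_segregation"
    else if (is.null(ss) && !is.na(slope) &&
             slope >= th$slope_range[1] && slope <= th$slope_range[2])
      "diffusive"
    else "other"

  structure(list(label = label, separation_gain = gain,
                 steady_state_time = ss, msd_slope = slope),
            class = "regime_label")
}

#' @export
print.regime_label <- function(x, ...) {
  cat(sprintf("<regime_label> %s (gain %.3f um, steady state %s, MSD slope %s)\n",
              x$label, x$separation_gain,
              if (is.null(x$steady_state_time)) "none"
              else sprintf("%.4g s", x$steady_state_time),
              if (is.na(x$msd_slope)) "NA" else sprintf("%.2f", x$msd_slope)))
  invisible(x)
}

#' Max-min-distance disk arrangements (packing oracle)
#'
#' Places `n` disks of radius `radius` fully inside the domain so as to
#' maximize the minimum over all pairwise center distances *and* twice each
#' center's clearance from the boundary -- the classic equal-disk packing
#' objective, in which the wall acts as a mirror neighbor. That is the right
#' oracle for cargo positioning on a nucleoid: the domain edge truncates a
#' cargo's local McdA supply exactly as a neighbor's depletion zone does, so
#' the boundary gap is equivalent to half an inter-cargo gap (for `n = 2` the
#' optimum is the familiar quarter/three-quarter positioning).
#'
#' Solved by multi-start stochastic relaxation: each point repeatedly steps
#' away from whichever is nearer -- its nearest neighbor or its wall image --
#' with a decaying step size, then is projected back into the radius-eroded
#' domain. Independent of the simulator; used to show that the optimal
#' packing switches from collinear to staggered as density grows.
#'
#' @param n Number of disks (>= 2).
#' @param geom A `nucleoid_geometry`.
#' @param radius Disk radius (um).
#' @param n_starts Random restarts.
#' @param n_iter Relaxation iterations per start.
#' @return `list(positions, min_distance)` for the best start;
#'   `min_distance` is the achieved objective (min of pair distances and
#'   doubled wall clearances).
#' @export
maxmin_arrangement <- function(n, geom, radius = 0.0875, n_starts = 24L,
                               n_iter = 1500L) {
  stopifnot(n >= 2)
  er <- geom$r - radius
  if (er <= 0) stop("disks do not fit: radius exceeds the domain half-width")
  project <- function(p) {
    cx <- pmin(pmax(p[, 1], -geom$c), geom$c)
    dx <- p[, 1] - cx; dy <- p[, 2]
    d <- sqrt(dx^2 + dy^2)
    out <- d > er
    if (any(out)) {
      f <- er / d[out]
      p[out, 1] <- cx[out] + dx[out] * f
      p[out, 2] <- dy[out] * f
    }
    p
  }
  objective <- function(p) {
    wall <- 2 * (geom$r - seg_dist(geom, p[, 1], p[, 2]))
    if (n >= 2) min(min(dist(p)), min(wall)) else min(wall)
  }
  best <- NULL; best_d <- -Inf
  xmax <- geom$c + er
  for (s in seq_len(n_starts)) {
    p <- project(cbind(runif(n, -xmax, xmax), runif(n, -er, er)))
    step <- 0.08
    for (it in seq_len(n_iter)) {
      dm <- as.matrix(dist(p)); diag(dm) <- Inf
      nn_d <- apply(dm, 1, min)
      nn <- apply(dm, 1, which.min)
      # wall image: twice the clearance, along the outward normal
      cx <- pmin(pmax(p[, 1], -geom$c), geom$c)
      vx <- p[, 1] - cx; vy <- p[, 2]
      sdist <- sqrt(vx^2 + vy^2)
      wall_d <- 2 * (geom$r - sdist)
      deg <- sdist < 1e-12
      if (any(deg)) { vx[deg] <- 0; vy[deg] <- 1; sdist[deg] <- 1 }
      v <- p - p[nn, , drop = FALSE]
      len <- sqrt(rowSums(v^2))
      zero <- len < 1e-12
      if (any(zero)) {
        th <- runif(sum(zero), 0, 2 * pi)
        v[zero, ] <- cbind(cos(th), sin(th)); len[zero] <- 1
      }
      v <- v / len
      # when the wall image is the closer "neighbor", step inward instead
      from_wall <- wall_d < nn_d
      if (any(from_wall)) {
        v[from_wall, 1] <- -vx[from_wall] / sdist[from_wall]
        v[from_wall, 2] <- -vy[from_wall] / sdist[from_wall]
      }
      p <- project(p + step * v)
      step <- step * 0.996
    }
    # phase 2 (tie-break): among configurations attaining this wall-limited
    # objective, spread the points to maximize the pairwise minimum
    j1 <- objective(p)
    er2 <- min(er, geom$r - j1 / 2 * 0.999)
    project2 <- function(q) {
      cx <- pmin(pmax(q[, 1], -geom$c), geom$c)
      dx <- q[, 1] - cx; dy <- q[, 2]
      d <- sqrt(dx^2 + dy^2)
      out <- d > er2
      if (any(out)) {
        f <- er2 / pmax(d[out], 1e-12)
        q[out, 1] <- cx[out] + dx[out] * f
        q[out, 2] <- dy[out] * f
      }
      q
    }
    step <- 0.04
    for (it in seq_len(n_iter %/% 2)) {
      dm <- as.matrix(dist(p)); diag(dm) <- Inf
      nn <- apply(dm, 1, which.min)
      v <- p - p[nn, , drop = FALSE]
      len <- sqrt(rowSums(v^2))
      zero <- len < 1e-12
      if (any(zero)) {
        th <- runif(sum(zero), 0, 2 * pi)
        v[zero, ] <- cbind(cos(th), sin(th)); len[zero] <- 1
      }
      p <- project2(p + step * v / len)
      step <- step * 0.995
    }
    score <- c(round(objective(p), 4), min(dist(p)))
    if (is.null(best) || score[1] > best_d[1] + 1e-9 ||
        (abs(score[1] - best_d[1]) <= 1e-9 && score[2] > best_d[2])) {
      best_d <- score; best <- p
    }
  }
  list(positions = best, min_distance = best_d[1],
       min_pairwise = best_d[2])
}
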