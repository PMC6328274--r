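# Ground-truth generators: idealized arrangements, occupancy fields with
# imposed depletion zones, and trajectories with known motility regimes.
# Everything the analysis layer computes can be validated against these
# without running the simulator.

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  force(expr)
}

#' Generate an idealized cargo arrangement
#'
#' Kinds: `linear` (equidistant along x at y = 0), `staggered` (equidistant
#' along x, y alternating `+/- stagger_amplitude`), `clustered` (all inside a
#' disk of radius `2 * cargo_radius` around the centroid), `uniform_random`
#' (hard-core rejection sampling at minimum distance `2 * cargo_radius`).
#' Transverse Gaussian noise of SD `noise_sd` is added to both coordinates
#' and points are kept inside the domain. Deterministic per seed.
#'
#' @param kind One of `"linear"`, `"staggered"`, `"clustered"`,
#'   `"uniform_random"`.
#' @param n Number of cargos.
#' @param geom A `nucleoid_geometry`.
#' @param noise_sd Gaussian jitter SD (um), default 0.02.
#' @param stagger_amplitude Alternating transverse offset (um), default 0.15.
#' @param cargo_radius Cargo radius (um).
#' @param seed Integer seed (optional; uses and restores the R RNG).
#' @return n x 2 matrix of positions inside `geom`.
#' @export
gen_arrangement <- function(kind = c("linear", "staggered", "clustered",
                                     "uniform_random"),
                            n, geom, noise_sd = 0.02, stagger_amplitude = 0.15,
                            cargo_radius = 0.0875, seed = NULL) {
  kind <- match.arg(kind)
  stopifnot(n >= 1, noise_sd >= 0)
  with_seed(seed, {
    margin <- cargo_radius + 3 * noise_sd
    xmax <- geom$c + geom$r - margin
    clamp_inside <- function(p) {
      # fold jittered points just inside the boundary
      d <- seg_dist(geom, p[, 1], p[, 2])
      out <- d > geom$r - 1e-9
      if (any(out)) {
        cx <- pmin(pmax(p[out, 1], -geom$c), geom$c)
        f <- (geom$r - 1e-9) / d[out]
        p[out, 1] <- cx + (p[out, 1] - cx) * f
        p[out, 2] <- p[out, 2] * f
      }
      p
    }
    p <- switch(kind,
      linear = {
        x <- if (n == 1) 0 else seq(-xmax, xmax, length.out = n)
        cbind(x, 0)
      },
      staggered = {
        x <- if (n == 1) 0 else seq(-xmax, xmax, length.out = n)
        cbind(x, stagger_amplitude * (-1)^(seq_len(n) - 1))
      },
      clustered = {
        rr <- 2 * cargo_radius * sqrt(runif(n))
        th <- runif(n, 0, 2 * pi)
        cbind(rr * cos(th), rr * sin(th))
      },
      uniform_random = {
        pts <- matrix(numeric(0), 0, 2)
        tries <- 0L
        while (nrow(pts) < n) {
          if (tries > 20000L)
            stop("gen_arrangement: hard-core placement of ", n,
                 " points is infeasible")
          tries <- tries + 1L
          cand <- c(runif(1, -(geom$c + geom$r), geom$c + geom$r),
                    runif(1, -geom$r, geom$r))
          if (seg_dist(geom, cand[1], cand[2]) > geom$r - cargo_radius) next
          if (nrow(pts) > 0 &&
              any((pts[, 1] - cand[1])^2 + (pts[, 2] - cand[2])^2 <
                  (2 * cargo_radius)^2)) next
          pts <- rbind(pts, cand)
        }
        pts
      })
    if (noise_sd > 0)
      p <- p + matrix(rnorm(2 * n, sd = noise_sd), n, 2)
    p <- clamp_inside(p)
    dimnames(p) <- NULL
    p
  })
}

#' Generate an McdA occupancy field with imposed depletion zones
#'
#' Each lattice site is occupied independently with probability
#' `bulk_occupancy`, or `depletion_occupancy` within `depletion_radius` of
#' any listed center. Ground truth for [depletion_index()] and
#' [occupancy_fraction()].
#'
#' @param geom A `nucleoid_geometry`.
#' @param spacing Lattice spacing (um).
#' @param bulk_occupancy,depletion_occupancy Occupancy probabilities in
#'   `[0, 1]`.
#' @param depletion_centers Optional m x 2 matrix of depletion-zone centers.
#' @param depletion_radius Zone radius (um).
#' @param seed Optional seed.
#' @return An `mcda_lattice`.
#' @export
gen_field <- function(geom, spacing = 0.02, bulk_occupancy = 0.5,
                      depletion_centers = NULL, depletion_radius = 0.2,
                      depletion_occupancy = 0, seed = NULL) {
  stopifnot(bulk_occupancy >= 0, bulk_occupancy <= 1,
            depletion_occupancy >= 0, depletion_occupancy <= 1)
  with_seed(seed, {
    lat <- build_lattice(geom, spacing)
    prob <- rep(bulk_occupancy, lat$n_sites)
    if (!is.null(depletion_centers)) {
      depletion_centers <- matrix(depletion_centers, ncol = 2)
      for (k in seq_len(nrow(depletion_centers))) {
        d2 <- (lat$x - depletion_centers[k, 1])^2 +
          (lat$y - depletion_centers[k, 2])^2
        prob[d2 <= depletion_radius^2] <- depletion_occupancy
      }
    }
    lat$occupied <- runif(lat$n_sites) < prob
    lat
  })
}

#' Generate a trajectory with a known motility regime
#'
#' Kinds: `pure_diffusion` (independent reflected Gaussian random walks with
#' diffusion coefficient `D`), `directed_then_static` (cargos move apart
#' deterministically along x to a target separation gain over `ramp_time`,
#' then freeze, with optional Gaussian jitter), `static` (constant
#' positions). Output has the exact structure of simulator trajectories
#' (pool columns are zero), so it round-trips through the IO layer.
#'
#' @param kind `"pure_diffusion"`, `"directed_then_static"`, or `"static"`.
#' @param geom A `nucleoid_geometry`.
#' @param n_cargo Number of cargos (default 2).
#' @param duration,record_interval Seconds (defaults 600 and 1).
#' @param D Diffusion coefficient (um^2/s) for `pure_diffusion`.
#' @param gain Target mean separation gain (um) for `directed_then_static`.
#' @param ramp_time Seconds over which the separation ramps.
#' @param jitter_sd Gaussian positional jitter SD (um) added to
#'   `directed_then_static` (default 0).
#' @param start Optional n x 2 matrix of starting positions (default: a tight
#'   cluster near the centroid).
#' @param seed Optional seed.
#' @return A `trajectory`.
#' @export
gen_trajectory <- function(kind = c("pure_diffusion", "directed_then_static",
                                    "static"),
                           geom, n_cargo = 2L, duration = 600,
                           record_interval = 1, D = 1e-3, gain = 1.0,
                           ramp_time = 200, jitter_sd = 0, start = NULL,
                           seed = NULL) {
  kind <- match.arg(kind)
  with_seed(seed, {
    times <- seq(0, duration, by = record_interval)
    n_rec <- length(times)
    if (is.null(start)) {
      ang <- seq(0, 2 * pi, length.out = n_cargo + 1)[seq_len(n_cargo)]
      start <- cbind(0.1 * cos(ang), 0.1 * sin(ang))
      if (n_cargo == 1) start <- matrix(0, 1, 2)
    }
    start <- matrix(start, ncol = 2)
    X <- matrix(NA_real_, n_rec, n_cargo)
    Y <- matrix(NA_real_, n_rec, n_cargo)
    X[1, ] <- start[, 1]; Y[1, ] <- start[, 2]
    if (kind == "static") {
      X <- matrix(start[, 1], n_rec, n_cargo, byrow = TRUE)
      Y <- matrix(start[, 2], n_rec, n_cargo, byrow = TRUE)
    } else if (kind == "pure_diffusion") {
      sig <- sqrt(2 * D * record_interval)
      for (k in 2:n_rec) for (m in seq_len(n_cargo)) {
        p <- reflect_into(geom, c(X[k - 1, m], Y[k - 1, m]),
                          c(X[k - 1, m] + rnorm(1, sd = sig),
                            Y[k - 1, m] + rnorm(1, sd = sig)))
        X[k, m] <- p[1]; Y[k, m] <- p[2]
      }
    } else { # directed_then_static
      # spread the cargos' x targets so mean pairwise distance grows by `gain`
      dir <- if (n_cargo == 1) 0 else
        (seq_len(n_cargo) - (n_cargo + 1) / 2) / ((n_cargo + 1) / 2 - 1 / 2)
      # scale so the mean pairwise x-spread increase equals `gain`
      base <- outer(dir, dir, function(a, b) abs(a - b))
      mb <- mean(base[upper.tri(base)])
      amp <- if (n_cargo >= 2 && mb > 0) gain / mb else 0
      frac <- pmin(times / ramp_time, 1)
      for (m in seq_len(n_cargo)) {
        X[, m] <- start[m, 1] + amp * dir[m] * frac
        Y[, m] <- start[m, 2]
      }
      if (jitter_sd > 0) {
        X <- X + matrix(rnorm(n_rec * n_cargo, sd = jitter_sd), n_rec)
        Y <- Y + matrix(rnorm(n_rec * n_cargo, sd = jitter_sd), n_rec)
      }
      for (k in seq_len(n_rec)) for (m in seq_len(n_cargo)) {
        if (!geom_contains(geom, X[k, m], Y[k, m])) {
          p <- reflect_into(geom, c(0, 0), c(X[k, m], Y[k, m]))
          X[k, m] <- p[1]; Y[k, m] <- p[2]
        }
      }
    }
    cfg <- default_config()
    cfg$simulation$n_cargo <- as.integer(n_cargo)
    cfg$simulation$duration <- duration
    cfg$simulation$record_interval <- record_interval
    if (!is.null(seed)) cfg$simulation$master_seed <- as.integer(seed)
    if (geom$kind == "circle") {
      cfg$geometry <- list(kind = "circle", length = NULL, width = NULL,
                           diameter = geom$diameter)
    } else {
      cfg$geometry$length <- geom$length; cfg$geometry$width <- geom$width
    }
    pools_mat <- matrix(0L, n_rec, 3)
    new_trajectory(times, X, Y, pools_mat, cfg,
                   seed = if (is.null(seed)) NA_integer_ else seed)
  })
}
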