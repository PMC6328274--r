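#' Construct a carboxysome cargo
#'
#' Carboxysomes are circular disks (default diameter 175 nm) moving on the
#' nucleoid surface. Each carries `n_mcdb` McdB tether slots; active tethers
#' are stored as lattice site indices on the cargo object.
#'
#' @param id Integer cargo id.
#' @param center Length-2 numeric center (um).
#' @param radius Disk radius in um (default 0.0875, i.e. 175 nm diameter).
#' @param n_mcdb Number of McdB tether slots.
#' @param D_free Free diffusion coefficient (um^2/s).
#' @return An object of class `carboxysome`.
#' @export
make_cargo <- function(id = 1L, center = c(0, 0), radius = 0.0875,
                       n_mcdb = 400L, D_free = 1e-6) {
  stopifnot(radius > 0, n_mcdb >= 0, D_free >= 0, length(center) == 2)
  structure(list(id = as.integer(id), center = as.numeric(center),
                 radius = radius, n_mcdb = as.integer(n_mcdb),
                 D_free = D_free, tethers = integer(0)),
            class = "carboxysome")
}

#' Tether kinetics and mechanics parameters
#'
#' Transient tethers are the McdA-McdB contacts: Hookean springs between the
#' cargo center and occupied lattice sites. Bond breakage is McdB-stimulated
#' hydrolysis, so every detachment releases the site's McdA into the
#' refractory pool.
#'
#' @param r_capture Maximum site distance from the cargo center for bond
#'   formation (um).
#' @param k_attach Attachment rate (1/s) per eligible (free slot, occupied
#'   site) pair.
#' @param k_detach Detachment rate (1/s) per tether.
#' @param k_spring Spring constant (kBT/um^2; the package works in kBT = 1
#'   units so forces are in kBT/um).
#' @param rest_length Spring rest length (um); force is zero inside it.
#' @return A list of class `tether_params`.
#' @export
tether_params <- function(r_capture = 0.3, k_attach = 10,
                          k_detach = 0.1, k_spring = 100, rest_length = 0) {
  stopifnot(r_capture >= 0, k_attach >= 0, k_detach >= 0, k_spring >= 0,
            rest_length >= 0)
  structure(list(r_capture = r_capture, k_attach = k_attach,
                 k_detach = k_detach, k_spring = k_spring,
                 rest_length = rest_length), class = "tether_params")
}

#' Sites a cargo could tether to
#'
#' Occupied, currently untethered lattice sites within `r_capture` of the
#' cargo center.
#'
#' @param cargo A [make_cargo()] object.
#' @param lattice An `mcda_lattice`.
#' @param params [tether_params()].
#' @return Integer vector of site indices.
#' @export
eligible_sites <- function(cargo, lattice, params) {
  d2 <- (lattice$x - cargo$center[1])^2 + (lattice$y - cargo$center[2])^2
  which(lattice$occupied & !lattice$tethered & d2 <= params$r_capture^2)
}

#' One tau-leaped step of tether kinetics for a cargo
#'
#' Each existing tether breaks with probability `1 - exp(-k_detach * dt)`;
#' every break calls [stimulated_release()] on its site (bond breakage =
#' hydrolysis = McdA leaves the nucleoid refractory). Then each eligible
#' (free McdB slot, occupied site) pair forms a tether with probability
#' `1 - exp(-k_attach * dt)`, in random order among candidates while free
#' slots remain.
#'
#' @inheritParams eligible_sites
#' @param pools `mcda_pools`.
#' @param dt Timestep (s); must satisfy `dt * max(k_attach, k_detach) <= 0.1`.
#' @return `list(cargo =, lattice =, pools =)`.
#' @export
tether_step <- function(cargo, lattice, pools, params, dt) {
  if (dt * max(params$k_attach, params$k_detach) > 0.1 + 1e-12)
    stop("tether timestep too large for tau-leaping: dt * max(k_attach, k_detach) > 0.1")
  if (length(cargo$tethers) > 0 && !all(lattice$occupied[cargo$tethers]))
    stop("tether references an empty site: bookkeeping bug")
  # detachment
  if (length(cargo$tethers) > 0 && params$k_detach > 0) {
    brk <- runif(length(cargo$tethers)) < 1 - exp(-params$k_detach * dt)
    for (s in cargo$tethers[brk]) {
      st <- stimulated_release(lattice, pools, s)
      lattice <- st$lattice; pools <- st$pools
    }
    cargo$tethers <- cargo$tethers[!brk]
  }
  # attachment
  slots <- cargo$n_mcdb - length(cargo$tethers)
  if (slots > 0 && params$k_attach > 0) {
    cand <- eligible_sites(cargo, lattice, params)
    if (length(cand) > 1) cand <- sample(cand)
    form <- cand[runif(length(cand)) < 1 - exp(-params$k_attach * dt)]
    form <- form[seq_len(min(length(form), slots))]
    if (length(form) > 0) {
      lattice$tethered[form] <- TRUE
      cargo$tethers <- c(cargo$tethers, form)
    }
  }
  list(cargo = cargo, lattice = lattice, pools = pools)
}

#' Net elastic force on a cargo from its tethers
#'
#' Sum of Hookean forces `k_spring * (|d| - rest_length)` directed from the
#' cargo center toward each anchor site (zero inside the rest length).
#'
#' @inheritParams eligible_sites
#' @return Length-2 force vector in kBT/um.
#' @export
net_tether_force <- function(cargo, lattice, params) {
  if (length(cargo$tethers) == 0) return(c(0, 0))
  dx <- lattice$x[cargo$tethers] - cargo$center[1]
  dy <- lattice$y[cargo$tethers] - cargo$center[2]
  if (params$rest_length > 0) {
    d <- sqrt(dx^2 + dy^2)
    f <- ifelse(d > params$rest_length,
                params$k_spring * (d - params$rest_length) / pmax(d, 1e-300), 0)
    c(sum(f * dx), sum(f * dy))
  } else {
    params$k_spring * c(sum(dx), sum(dy))
  }
}

#' One overdamped Langevin step for a cargo
#'
#' `center' = reflect_into(geom, center, center + D_free * F * dt +
#' sqrt(2 * D_free * dt) * xi)` with `xi` a pair of standard normals; in the
#' kBT = 1 convention the mobility equals `D_free` (Einstein relation).
#'
#' @param cargo A `carboxysome`.
#' @param force Length-2 force vector (kBT/um).
#' @param geom `nucleoid_geometry`.
#' @param dt Timestep (s).
#' @param noise Set `FALSE` to suppress the thermal term (test hook).
#' @param drift_limit Guard: the deterministic drift per step must stay below
#'   this length (um); default the canonical lattice spacing.
#' @return The cargo with an updated center.
#' @export
brownian_step <- function(cargo, force, geom, dt, noise = TRUE,
                          drift_limit = 0.02) {
  drift <- cargo$D_free * force * dt
  if (sum(abs(drift)) >= drift_limit)
    stop("drift per step (", signif(sum(abs(drift)), 3),
         " um) reaches the guard limit; reduce dt")
  xi <- if (noise) rnorm(2) else c(0, 0)
  target <- cargo$center + drift + sqrt(2 * cargo$D_free * dt) * xi
  cargo$center <- reflect_into(geom, cargo$center, target)
  cargo
}

#' Resolve hard-disk overlaps between cargos
#'
#' Iteratively pushes apart every pair closer than `2 * radius` along the
#' line of centers, symmetrically, re-reflecting displaced centers into the
#' domain, until no overlaps remain or the iteration cap is hit.
#'
#' @param centers n x 2 matrix of cargo centers.
#' @param radius Cargo radius (um).
#' @param geom `nucleoid_geometry`.
#' @param max_iter Iteration cap.
#' @return `list(centers =, converged = logical)`. Non-convergence is flagged,
#'   not fatal.
#' @export
resolve_exclusion <- function(centers, radius, geom, max_iter = 50L) {
  n <- nrow(centers)
  dmin <- 2 * radius
  converged <- TRUE
  if (n > 1) {
    for (it in seq_len(max_iter)) {
      moved <- FALSE
      for (a in seq_len(n - 1)) for (b in seq((a + 1), n)) {
        v <- centers[b, ] - centers[a, ]
        d <- sqrt(sum(v^2))
        if (d < dmin - 1e-12) {
          u <- if (d < 1e-12) { th <- runif(1, 0, 2 * pi); c(cos(th), sin(th)) } else v / d
          push <- (dmin - d) / 2 + 1e-12
          centers[a, ] <- reflect_into(geom, centers[a, ], centers[a, ] - push * u)
          centers[b, ] <- reflect_into(geom, centers[b, ], centers[b, ] + push * u)
          moved <- TRUE
        }
      }
      if (!moved) break
      if (it == max_iter) converged <- FALSE
    }
  }
  list(centers = centers, converged = converged)
}
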