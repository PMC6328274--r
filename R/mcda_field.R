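#' McdA pool bookkeeping
#'
#' McdA dimers are partitioned into three conserved pools: nucleoid-bound
#' (`n_bound`, equal to the number of occupied lattice sites), free cytosolic
#' binding-competent (`n_free`, well-mixed), and refractory (`n_refractory`:
#' post-hydrolysis McdA that cannot rebind DNA until it resets). The slow
#' reset is what turns local McdB-stimulated release into a persistent
#' depletion zone.
#'
#' @param n_total Total McdA dimer count.
#' @param n_bound,n_refractory Initial counts (default 0); `n_free` is the
#'   remainder.
#' @return An object of class `mcda_pools`.
#' @export
make_pools <- function(n_total, n_bound = 0L, n_refractory = 0L) {
  n_total <- as.integer(n_total); n_bound <- as.integer(n_bound)
  n_refractory <- as.integer(n_refractory)
  n_free <- n_total - n_bound - n_refractory
  if (n_total < 0 || n_bound < 0 || n_refractory < 0 || n_free < 0)
    stop("inconsistent McdA pools: counts must be non-negative and sum to n_total")
  structure(list(n_total = n_total, n_bound = n_bound, n_free = n_free,
                 n_refractory = n_refractory), class = "mcda_pools")
}

check_pools <- function(pools, lattice = NULL) {
  with(pools, {
    if (n_bound + n_free + n_refractory != n_total)
      stop("McdA conservation violated: pools do not sum to n_total")
    if (any(c(n_bound, n_free, n_refractory) < 0))
      stop("negative McdA pool count")
  })
  if (!is.null(lattice) && pools$n_bound != occupied_count(lattice))
    stop("n_bound does not match the lattice occupied count")
  invisible(pools)
}

#' McdA surface-chemistry parameters
#'
#' @param k_on Binding rate (1/s) per empty site at a fully free pool; the
#'   effective per-site propensity is `k_on * n_free / n_total`.
#' @param k_off_basal Basal (unstimulated) unbinding rate (1/s) per bound site;
#'   basally released McdA returns directly to the free pool.
#' @param tau_reset Mean refractory dwell time (s); per-dimer reset rate is
#'   `1 / tau_reset`.
#' @return A list of class `chemistry_params`.
#' @export
chemistry_params <- function(k_on = 1.0, k_off_basal = 0.01, tau_reset = 20) {
  stopifnot(k_on >= 0, k_off_basal >= 0, tau_reset > 0)
  structure(list(k_on = k_on, k_off_basal = k_off_basal, tau_reset = tau_reset),
            class = "chemistry_params")
}

chem_dt_guard <- function(params, dt) {
  rmax <- max(params$k_on, params$k_off_basal, 1 / params$tau_reset)
  if (dt * rmax > 0.1 + 1e-12)
    stop("chemistry timestep too large for tau-leaping: dt * max rate = ",
         signif(dt * rmax, 3), " > 0.1")
  invisible(TRUE)
}

#' One tau-leaped step of the McdA surface chemistry
#'
#' Each empty site binds a free McdA with probability
#' `1 - exp(-k_on * (n_free/n_total) * dt)` (total bindings capped at
#' `n_free`), each occupied untethered site unbinds basally with probability
#' `1 - exp(-k_off_basal * dt)`, and each refractory dimer resets to the free
#' pool with probability `1 - exp(-dt / tau_reset)`. Tethered sites are held
#' by their bond and are released only through [stimulated_release()].
#' McdA conservation is exact.
#'
#' Uses the R RNG; call `set.seed()` for reproducibility.
#'
#' @param lattice An `mcda_lattice`.
#' @param pools An `mcda_pools` consistent with the lattice.
#' @param params A [chemistry_params()] list.
#' @param dt Timestep (s); must satisfy `dt * max rate <= 0.1`.
#' @return `list(lattice =, pools =)` with updated state.
#' @export
chemistry_step <- function(lattice, pools, params, dt) {
  chem_dt_guard(params, dt)
  check_pools(pools, lattice)
  # resets
  n_res <- rbinom(1, pools$n_refractory, 1 - exp(-dt / params$tau_reset))
  pools$n_refractory <- pools$n_refractory - n_res
  pools$n_free <- pools$n_free + n_res
  # basal unbinding (untethered occupied sites only)
  unb_pool <- which(lattice$occupied & !lattice$tethered)
  if (length(unb_pool) > 0 && params$k_off_basal > 0) {
    go <- unb_pool[runif(length(unb_pool)) < 1 - exp(-params$k_off_basal * dt)]
    lattice$occupied[go] <- FALSE
    pools$n_bound <- pools$n_bound - length(go)
    pools$n_free <- pools$n_free + length(go)
  }
  # binding
  empty <- which(!lattice$occupied)
  if (length(empty) > 0 && pools$n_free > 0 && params$k_on > 0) {
    p <- 1 - exp(-params$k_on * (pools$n_free / pools$n_total) * dt)
    bind <- empty[runif(length(empty)) < p]
    if (length(bind) > pools$n_free)
      bind <- sample(bind, pools$n_free)
    lattice$occupied[bind] <- TRUE
    pools$n_bound <- pools$n_bound + length(bind)
    pools$n_free <- pools$n_free - length(bind)
  }
  check_pools(pools, lattice)
  list(lattice = lattice, pools = pools)
}

#' McdB-stimulated release of a bound McdA
#'
#' Cargo-bound McdB stimulates the ATPase activity of nucleoid-bound McdA,
#' which dissociates from the nucleoid into the refractory pool (it cannot
#' rebind until it resets its DNA-binding capability).
#'
#' @param lattice,pools Current state.
#' @param site_id Index of an occupied site.
#' @return `list(lattice =, pools =)`.
#' @export
stimulated_release <- function(lattice, pools, site_id) {
  stopifnot(length(site_id) == 1, site_id >= 1, site_id <= lattice$n_sites)
  if (!lattice$occupied[site_id])
    stop("stimulated_release on an empty site (id ", site_id,
         "): tether bookkeeping bug")
  lattice$occupied[site_id] <- FALSE
  lattice$tethered[site_id] <- FALSE
  pools$n_bound <- pools$n_bound - 1L
  pools$n_refractory <- pools$n_refractory + 1L
  check_pools(pools, lattice)
  list(lattice = lattice, pools = pools)
}

#' Fraction of occupied sites in a region
#'
#' @param lattice An `mcda_lattice`.
#' @param region Either a predicate `function(x, y)` returning a logical
#'   vector, or a logical/integer index into the sites.
#' @return Occupied fraction in `[0, 1]`.
#' @export
occupancy_fraction <- function(lattice, region) {
  idx <- if (is.function(region)) region(lattice$x, lattice$y) else region
  if (is.logical(idx)) idx <- which(idx)
  if (length(idx) == 0) stop("occupancy_fraction: region contains no site")
  mean(lattice$occupied[idx])
}

#' Run the tau-leaped chemistry alone for a stretch of simulated time
#'
#' Compiled loop over [chemistry_step()] semantics with no cargos; used for
#' lattice pre-equilibration and for validating the leap against the exact
#' Gillespie oracle.
#'
#' @inheritParams chemistry_step
#' @param duration Simulated seconds.
#' @param record_every Record the occupied fraction every this many seconds
#'   (0 = no recording).
#' @return `list(lattice, pools, occupied_fraction)` where
#'   `occupied_fraction` is the recorded time series.
#' @export
chemistry_run <- function(lattice, pools, params, duration, dt = NULL,
                          record_every = 0) {
  if (is.null(dt))
    dt <- 0.1 / max(params$k_on, params$k_off_basal, 1 / params$tau_reset)
  chem_dt_guard(params, dt)
  check_pools(pools, lattice)
  n_steps <- max(1L, as.integer(round(duration / dt)))
  rec <- if (record_every > 0) max(1L, as.integer(round(record_every / dt))) else 0L
  res <- cpp_chem_run(as.integer(ifelse(lattice$occupied, 1L, 0L)),
                      pools$n_total, pools$n_free, pools$n_refractory,
                      params$k_on, params$k_off_basal, params$tau_reset,
                      dt, n_steps, rec)
  lattice$occupied <- res$occ > 0L
  lattice$tethered[] <- FALSE
  pools <- make_pools(pools$n_total, n_bound = res$n_bound,
                      n_refractory = res$n_refractory)
  list(lattice = lattice, pools = pools,
       occupied_fraction = res$occupied_fraction)
}

#' Exact Gillespie simulation of the cargo-free McdA chemistry
#'
#' Independent event-driven oracle for the tau-leaped chemistry. With no
#' cargo every empty site is statistically equivalent, so the chemistry
#' reduces to a three-pool jump process with propensities
#' `a_bind = n_empty * k_on * n_free / n_total`,
#' `a_unbind = n_bound * k_off_basal`, `a_reset = n_refractory / tau_reset`,
#' simulated exactly with exponential waiting times.
#'
#' @param n_sites Number of lattice sites.
#' @param pools Initial [make_pools()] state.
#' @param params [chemistry_params()].
#' @param duration Simulated seconds.
#' @param n_batches Number of equal time bins for the batch means.
#' @return `list(pools, mean_occupancy, batch_means)`: `mean_occupancy` is
#'   the time-weighted mean occupied fraction over the whole run and
#'   `batch_means` the per-bin time-weighted means (for autocorrelation-aware
#'   standard errors).
#' @export
chemistry_gillespie <- function(n_sites, pools, params, duration,
                                n_batches = 50L) {
  t <- 0; nb <- pools$n_bound; nf <- pools$n_free; nr <- pools$n_refractory
  nt <- pools$n_total
  bin_w <- duration / n_batches
  bin_occ <- numeric(n_batches)
  add_time <- function(t0, t1, level) {
    # distribute level * dt over the time bins spanned by [t0, t1)
    b0 <- min(n_batches, 1L + floor(t0 / bin_w))
    b1 <- min(n_batches, 1L + floor((t1 - 1e-12) / bin_w))
    if (b0 == b1) bin_occ[b0] <<- bin_occ[b0] + level * (t1 - t0)
    else {
      bin_occ[b0] <<- bin_occ[b0] + level * (b0 * bin_w - t0)
      if (b1 > b0 + 1)
        bin_occ[(b0 + 1):(b1 - 1)] <<- bin_occ[(b0 + 1):(b1 - 1)] +
          level * bin_w
      bin_occ[b1] <<- bin_occ[b1] + level * (t1 - (b1 - 1) * bin_w)
    }
  }
  repeat {
    a1 <- (n_sites - nb) * params$k_on * nf / nt
    a2 <- nb * params$k_off_basal
    a3 <- nr / params$tau_reset
    a0 <- a1 + a2 + a3
    if (a0 <= 0) { add_time(t, duration, nb); break }
    tau <- rexp(1, a0)
    if (t + tau > duration) { add_time(t, duration, nb); break }
    add_time(t, t + tau, nb)
    t <- t + tau
    u <- runif(1) * a0
    if (u < a1) { nb <- nb + 1L; nf <- nf - 1L }
    else if (u < a1 + a2) { nb <- nb - 1L; nf <- nf + 1L }
    else { nr <- nr - 1L; nf <- nf + 1L }
  }
  batch_means <- bin_occ / (bin_w * n_sites)
  list(pools = make_pools(nt, n_bound = nb, n_refractory = nr),
       mean_occupancy = sum(bin_occ) / (duration * n_sites),
       batch_means = batch_means)
}

#' Deterministic steady-state occupancy of the cargo-free chemistry
#'
#' Solves the self-consistent balance
#' `(S - b) * k_on * (n_total - b) / n_total = b * k_off_basal`
#' for the bound count `b` (no refractory flux without cargo), giving the
#' mean-field fixed point the stochastic chemistry fluctuates around.
#'
#' @param n_sites Number of sites `S`.
#' @param n_total Total McdA count.
#' @param params [chemistry_params()].
#' @return `list(n_bound, occupancy)`.
#' @export
chemistry_fixed_point <- function(n_sites, n_total, params) {
  f <- function(b)
    (n_sites - b) * params$k_on * (n_total - b) / n_total - b * params$k_off_basal
  upper <- min(n_sites, n_total)
  if (params$k_on == 0) return(list(n_bound = 0, occupancy = 0))
  b <- uniroot(f, c(0, upper), tol = 1e-10)$root
  list(n_bound = b, occupancy = b / n_sites)
}
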