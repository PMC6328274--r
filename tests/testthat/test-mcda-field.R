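test_that("pools enforce conservation and non-negativity", {
  p <- make_pools(100, n_bound = 30, n_refractory = 10)
  expect_identical(p$n_free, 60L)
  expect_error(make_pools(10, n_bound = 11), "non-negative")
  expect_error(stimulated_release(manual_lattice(0, 0), make_pools(5), 1),
               "empty site")
})

test_that("chemistry with no reactions leaves the state unchanged", {
  lat <- build_lattice(geom_circle(), 0.1)
  lat$occupied[1:10] <- TRUE
  pools <- make_pools(100, n_bound = 10)
  out <- chemistry_step(lat, pools, chemistry_params(0, 0, tau_reset = 1), 0.01)
  expect_identical(out$lattice$occupied, lat$occupied)
  expect_identical(out$pools, pools)
})

test_that("chemistry timestep guard rejects too-coarse leaps", {
  lat <- build_lattice(geom_circle(), 0.1)
  expect_error(chemistry_step(lat, make_pools(10), chemistry_params(k_on = 5), 0.1),
               "tau-leap")
})

test_that("basal release counts match the binomial expectation", {
  # 1000 bound sites, k_off = 0.1/s, dt = 0.01 s: mean releases per step is
  # 1000 * (1 - exp(-1e-3)) ~ 0.9995
  lat0 <- build_lattice(geom_rod(), 0.02)
  lat0$occupied[seq_len(1000)] <- TRUE
  pools0 <- make_pools(1000, n_bound = 1000)
  params <- chemistry_params(k_on = 0, k_off_basal = 0.1)
  set.seed(11)
  n_rep <- 4000
  rel <- vapply(seq_len(n_rep), function(i) {
    out <- chemistry_step(lat0, pools0, params, 0.01)
    out$pools$n_free
  }, 0L)
  p1 <- 1 - exp(-0.1 * 0.01)
  se <- sqrt(1000 * p1 * (1 - p1) / n_rep)
  expect_lt(abs(mean(rel) - 1000 * p1), 3 * se)
})

test_that("stimulated release moves one McdA from bound to refractory", {
  lat <- manual_lattice(c(0, 0.02), c(0, 0), occupied = c(TRUE, TRUE))
  pools <- make_pools(10, n_bound = 2)
  out <- stimulated_release(lat, pools, 1)
  expect_false(out$lattice$occupied[1])
  expect_identical(out$pools$n_bound, 1L)
  expect_identical(out$pools$n_refractory, 1L)
  expect_error(stimulated_release(out$lattice, out$pools, 1), "empty site")
  # releasing every occupied site empties the lattice, conserving the total
  out2 <- stimulated_release(out$lattice, out$pools, 2)
  expect_identical(occupied_count(out2$lattice), 0L)
  expect_identical(out2$pools$n_refractory, 2L)
  expect_identical(out2$pools$n_total, 10L)
})

test_that("McdA is conserved exactly across random operation sequences", {
  set.seed(5)
  lat <- build_lattice(geom_circle(), 0.08)
  pools <- make_pools(200)
  params <- chemistry_params(k_on = 2, k_off_basal = 0.5, tau_reset = 2)
  for (step in 1:200) {
    out <- chemistry_step(lat, pools, params, 0.05)
    lat <- out$lattice; pools <- out$pools
    occ <- which(lat$occupied)
    if (length(occ) > 0 && runif(1) < 0.5) {
      out <- stimulated_release(lat, pools, sample(occ, 1))
      lat <- out$lattice; pools <- out$pools
    }
    expect_identical(pools$n_bound + pools$n_free + pools$n_refractory,
                     pools$n_total)
    expect_identical(pools$n_bound, occupied_count(lat))
  }
})

test_that("occupancy_fraction matches direct counting", {
  lat <- build_lattice(geom_circle(), 0.05)
  lat$occupied[] <- TRUE
  expect_equal(occupancy_fraction(lat, function(x, y) x^2 + y^2 < 0.25), 1.0)
  lat$occupied[] <- FALSE
  expect_equal(occupancy_fraction(lat, rep(TRUE, lat$n_sites)), 0.0)
  # checkerboard
  lat$occupied <- (lat$i + lat$j) %% 2L == 0L
  expect_equal(occupancy_fraction(lat, rep(TRUE, lat$n_sites)),
               mean((lat$i + lat$j) %% 2L == 0L))
  expect_error(occupancy_fraction(lat, function(x, y) x > 10), "no site")
})

test_that("long-run occupancy converges to the self-consistent fixed point", {
  lat <- build_lattice(geom_rod(), 0.05)     # ~570 sites
  pools <- make_pools(2000)
  params <- chemistry_params(k_on = 1, k_off_basal = 0.1, tau_reset = 20)
  set.seed(3)
  run <- chemistry_run(lat, pools, params, duration = 3000, dt = 0.02,
                       record_every = 2)
  occ <- run$occupied_fraction
  occ <- occ[(length(occ) %/% 2):length(occ)] # discard burn-in
  # exact stationary mean of the cargo-free chemistry: with no cargo the
  # bound count is a birth-death chain with rates
  # lambda_b = (S - b) k_on (N - b)/N and mu_b = b k_off; its stationary
  # law is the closed-form product measure
  S <- lat$n_sites; N <- 2000
  b_max <- min(S, N)
  logw <- cumsum(c(0, log(((S - 0:(b_max - 1)) * params$k_on *
                             (N - 0:(b_max - 1)) / N) /
                            ((1:b_max) * params$k_off_basal))))
  w <- exp(logw - max(logw))
  exact_mean <- sum((0:b_max) * w) / sum(w) / S
  # small slack beyond 3 SE for the residual O(dt) leaping bias
  expect_lt(abs(mean(occ) - exact_mean), 3 * batch_se(occ) + 1e-3)
  # the mean-field fixed point approximates the same quantity to ~1%
  fp <- chemistry_fixed_point(S, N, params)
  expect_equal(fp$occupancy, exact_mean, tolerance = 0.01)
  # pools consistent at the end
  expect_identical(run$pools$n_bound, occupied_count(run$lattice))
})

test_that("slower refractory resetting cannot shrink the refractory pool", {
  # driven toy: constant stimulated-release flux on a small lattice
  drive <- function(tau) {
    set.seed(42)
    lat <- build_lattice(geom_circle(), 0.08)
    pools <- make_pools(300)
    params <- chemistry_params(k_on = 1, k_off_basal = 0.01, tau_reset = tau)
    refr <- numeric(0)
    for (step in 1:600) {
      out <- chemistry_step(lat, pools, params, 0.1)
      lat <- out$lattice; pools <- out$pools
      occ <- which(lat$occupied)
      for (s in utils::head(occ, 3)) {  # release up to 3 per step
        out <- stimulated_release(lat, pools, s)
        lat <- out$lattice; pools <- out$pools
      }
      if (step > 300) refr <- c(refr, pools$n_refractory)
    }
    mean(refr)
  }
  expect_gt(drive(20), drive(10) - 1e-9)
})

test_that("exact Gillespie oracle reproduces the fixed point on a small system", {
  set.seed(9)
  out <- chemistry_gillespie(100, make_pools(150),
                             chemistry_params(1, 0.1, 20), duration = 2000)
  fp <- chemistry_fixed_point(100, 150, chemistry_params(1, 0.1, 20))
  expect_lt(abs(out$mean_occupancy - fp$occupancy), 0.05)
  expect_identical(out$pools$n_total, 150L)
})
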