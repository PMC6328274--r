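test_that("eligible sites are the occupied untethered sites within reach", {
  lat <- manual_lattice(c(0.05, 0.12, 0.2, 0.05), c(0, 0, 0, 0.02))
  cargo <- make_cargo(center = c(0, 0))
  par <- tether_params(r_capture = 0.15)
  expect_identical(eligible_sites(cargo, lat, par), integer(0))
  lat$occupied[] <- TRUE
  expect_setequal(eligible_sites(cargo, lat, par), c(1L, 2L, 4L))
  # boundary cases around r_capture
  lat2 <- manual_lattice(c(0.15 - 1e-6, 0.15 + 1e-6), c(0, 0),
                         occupied = c(TRUE, TRUE))
  expect_identical(eligible_sites(cargo, lat2, par), 1L)
  # tethered sites are excluded
  lat$tethered[1] <- TRUE
  expect_setequal(eligible_sites(cargo, lat, par), c(2L, 4L))
})

test_that("tether attachment honors the McdB slot cap and zero-rate limits", {
  lat <- manual_lattice(seq(0, 0.09, by = 0.01), rep(0, 10),
                        occupied = rep(TRUE, 10))
  pools <- make_pools(20, n_bound = 10)
  cargo <- make_cargo(center = c(0, 0), n_mcdb = 3L)
  par0 <- tether_params(r_capture = 0.15, k_attach = 0, k_detach = 0)
  out <- tether_step(cargo, lat, pools, par0, 0.01)
  expect_length(out$cargo$tethers, 0)
  # with a high attach probability the 3 slots fill but never overfill
  par1 <- tether_params(r_capture = 0.15, k_attach = 50, k_detach = 0)
  set.seed(2)
  st <- list(cargo = cargo, lattice = lat, pools = pools)
  for (i in 1:50) {
    st <- tether_step(st$cargo, st$lattice, st$pools, par1, 0.002)
    expect_lte(length(st$cargo$tethers), 3L)
  }
  expect_identical(length(st$cargo$tethers), 3L)
  expect_true(all(st$lattice$tethered[st$cargo$tethers]))
})

test_that("tether breakage rate matches the binomial expectation", {
  lat <- manual_lattice(seq(0, 0.09, by = 0.01), rep(0, 10),
                        occupied = rep(TRUE, 10))
  lat$tethered[] <- TRUE
  pools <- make_pools(20, n_bound = 10)
  cargo <- make_cargo(center = c(0, 0), n_mcdb = 10L)
  cargo$tethers <- 1:10
  par <- tether_params(r_capture = 0.15, k_attach = 0, k_detach = 1)
  set.seed(4)
  n_rep <- 2000
  breaks <- vapply(seq_len(n_rep), function(i)
    10L - length(tether_step(cargo, lat, pools, par, 0.01)$cargo$tethers), 0L)
  p1 <- 1 - exp(-0.01)
  se <- sqrt(10 * p1 * (1 - p1) / n_rep)
  expect_lt(abs(mean(breaks) - 10 * p1), 3 * se)
  # every break produced a refractory McdA
  out <- tether_step(cargo, lat, pools, par, 0.01)
  expect_identical(out$pools$n_refractory,
                   10L - length(out$cargo$tethers))
})

test_that("net tether force is Hookean toward the anchors", {
  lat <- manual_lattice(c(0.1, -0.1, 0, 0), c(0, 0, 0.1, -0.1),
                        occupied = rep(TRUE, 4))
  cargo <- make_cargo(center = c(0, 0))
  par <- tether_params(k_spring = 100, rest_length = 0)
  expect_equal(net_tether_force(cargo, lat, par), c(0, 0))
  cargo$tethers <- 1L
  expect_equal(net_tether_force(cargo, lat, par), c(10, 0))
  cargo$tethers <- 1:2
  expect_equal(net_tether_force(cargo, lat, par), c(0, 0))
  cargo$tethers <- 1:4
  expect_equal(net_tether_force(cargo, lat, par), c(0, 0))
  # rest length: no force inside it
  par2 <- tether_params(k_spring = 100, rest_length = 0.2)
  cargo$tethers <- 1L
  expect_equal(net_tether_force(cargo, lat, par2), c(0, 0))
  par3 <- tether_params(k_spring = 100, rest_length = 0.05)
  expect_equal(net_tether_force(cargo, lat, par3), c(100 * 0.05, 0))
})

test_that("Brownian step reduces to pure drift without noise", {
  g <- geom_rod()
  cargo <- make_cargo(center = c(0, 0), D_free = 0)
  set.seed(1)
  expect_equal(brownian_step(cargo, c(50, 50), g, 1e-3)$center, c(0, 0))
  cargo$D_free <- 1e-3
  out <- brownian_step(cargo, c(10, 0), g, 1e-3, noise = FALSE)
  expect_equal(out$center, c(1e-5, 0), tolerance = 1e-12)
  expect_error(brownian_step(cargo, c(1e6, 0), g, 1e-3), "guard")
})

test_that("free-cargo MSD follows the 2D diffusion law", {
  g <- geom_rod()
  set.seed(12)
  n <- 4000; D <- 1e-3; dt <- 1e-3
  d2 <- vapply(seq_len(n), function(i) {
    cargo <- make_cargo(center = c(0, 0), D_free = D)
    sum((brownian_step(cargo, c(0, 0), g, dt)$center)^2)
  }, 0)
  se <- sd(d2) / sqrt(n)
  expect_lt(abs(mean(d2) - 4 * D * dt), 3 * se)
})

test_that("static-anchor tethering gives the Gaussian stationary law", {
  # overdamped spring with kBT = 1: mean at the anchor centroid, variance
  # 1/(n k) per axis; adding tethers cannot increase the variance
  g <- geom_rod()
  lat <- manual_lattice(c(0.1, -0.1, 0, 0, 0.07, -0.07, 0, 0),
                        c(0, 0, 0.1, -0.1, 0.07, -0.07, 0.12, -0.12),
                        occupied = rep(TRUE, 8))
  par <- tether_params(k_spring = 100, rest_length = 0)
  sim_var <- function(tethers, n_steps = 60000, dt = 0.02) {
    cargo <- make_cargo(center = c(0, 0), D_free = 1e-3)
    cargo$tethers <- tethers
    xs <- matrix(NA_real_, n_steps, 2)
    for (i in seq_len(n_steps)) {
      f <- net_tether_force(cargo, lat, par)
      cargo <- brownian_step(cargo, f, g, dt)
      xs[i, ] <- cargo$center
    }
    xs <- xs[-(1:2000), ]
    c(var(xs[, 1]), var(xs[, 2]), colMeans(xs))
  }
  set.seed(21)
  v4 <- sim_var(1:4)
  expect_equal(mean(v4[1:2]), 1 / (4 * 100), tolerance = 0.2)
  expect_lt(max(abs(v4[3:4])), 0.01)
  v8 <- sim_var(1:8)
  expect_lt(mean(v8[1:2]), mean(v4[1:2]) * 1.1)
})

test_that("hard-disk exclusion separates overlapping cargos", {
  g <- geom_rod()
  r <- 0.0875
  p0 <- rbind(c(0, 0), c(0.3, 0))
  expect_equal(resolve_exclusion(p0, r, g)$centers, p0)
  p1 <- rbind(c(0, 0), c(0.1, 0))
  out <- resolve_exclusion(p1, r, g)
  expect_equal(dist(out$centers)[1], 2 * r, tolerance = 1e-9)
  expect_equal(colMeans(out$centers), colMeans(p1), tolerance = 1e-9)
  # three mutually overlapping cargos: all pairwise constraints satisfied,
  # centroid preserved (interior case), matching an independent sequential
  # projection oracle's feasibility
  set.seed(8)
  p3 <- rbind(c(0, 0), c(0.05, 0.02), c(-0.02, 0.06))
  out3 <- resolve_exclusion(p3, r, g)
  expect_true(out3$converged)
  expect_true(all(dist(out3$centers) >= 2 * r - 1e-6))
  expect_equal(colMeans(out3$centers), colMeans(p3), tolerance = 1e-6)
  oracle <- function(p, max_iter = 500) {
    for (it in seq_len(max_iter)) {
      done <- TRUE
      for (a in 1:(nrow(p) - 1)) for (b in (a + 1):nrow(p)) {
        v <- p[b, ] - p[a, ]; d <- sqrt(sum(v^2))
        if (d < 2 * r - 1e-9) {
          u <- v / d; push <- (2 * r - d) / 2
          p[a, ] <- p[a, ] - push * u; p[b, ] <- p[b, ] + push * u
          done <- FALSE
        }
      }
      if (done) break
    }
    p
  }
  ref <- oracle(p3)
  expect_true(all(dist(ref) >= 2 * r - 1e-6))
  # both solutions resolve the same overlap pattern to the same distances
  expect_equal(sort(as.vector(dist(out3$centers)))[1:2],
               sort(as.vector(dist(ref)))[1:2], tolerance = 0.05)
})
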