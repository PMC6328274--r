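test_that("initial state clusters non-overlapping cargos on an equilibrated lattice", {
  cfg <- tiny_config(`simulation.n_cargo` = 6L)
  set.seed(1)
  st <- init_state(cfg)
  expect_identical(nrow(st$centers), 6L)
  expect_true(all(sqrt(rowSums(st$centers^2)) <= 0.3 + 1e-9))
  expect_true(all(dist(st$centers) >= 2 * cfg$cargo$radius - 1e-12))
  expect_true(all(geom_contains(st$geom, st$centers)))
  expect_identical(st$pools$n_bound, occupied_count(st$lattice))
  expect_gt(st$pools$n_bound, 0L) # pre-equilibration populated the lattice
  # same RNG state twice gives the identical initial state
  set.seed(1)
  st2 <- init_state(cfg)
  expect_identical(st, st2)
  # infeasible packing is rejected
  expect_error(init_state(tiny_config(`simulation.n_cargo` = 30L,
                                      `simulation.cluster_radius` = 0.1)),
               "cluster")
})

test_that("a minimal run produces initial plus one record with exact conservation", {
  cfg <- tiny_config(`simulation.duration` = 1e-3,
                     `simulation.record_interval` = 1e-3)
  tr <- run_simulation(cfg)
  expect_identical(length(tr$times), 2L)
  expect_identical(tr$times, c(0, 1e-3))
  with(tr$pools, expect_true(all(n_bound + n_free + n_refractory ==
                                   cfg$chemistry$n_total)))
})

test_that("identical config and seed give bit-identical trajectories", {
  cfg <- tiny_config()
  tr1 <- run_simulation(cfg)
  tr2 <- run_simulation(cfg)
  expect_identical(tr1$x, tr2$x)
  expect_identical(tr1$y, tr2$y)
  expect_identical(tr1$pools, tr2$pools)
  expect_identical(tr1$final_lattice$occupied, tr2$final_lattice$occupied)
  tr3 <- run_simulation(config_set(cfg, `simulation.master_seed` = 99L))
  expect_false(identical(tr1$x, tr3$x))
})

test_that("trajectory invariants hold at every record", {
  cfg <- tiny_config(`simulation.n_cargo` = 4L, `simulation.duration` = 20)
  tr <- run_simulation(cfg)
  expect_true(all(diff(tr$times) > 0))
  g <- config_geometry(cfg)
  for (m in 1:4) expect_true(all(geom_contains(g, cbind(tr$x[, m], tr$y[, m]))))
  expect_true(all(tr$tether_count <= cfg$cargo$n_mcdb))
  expect_identical(sum(tr$final_lattice$tethered),
                   sum(tr$tether_count[length(tr$times), ]))
})

test_that("ensembles are seed-derived, summarized, and self-consistent", {
  cfg <- tiny_config(`simulation.duration` = 10)
  ens <- run_ensemble(cfg, n_trajectories = 3L, master_seed = 5L)
  expect_identical(ens$seeds, 5:7)
  expect_identical(ens$n_trajectories, 3L)
  # summary is recomputable from the per-trajectory records
  nn <- vapply(ens$finals, function(p) separation_stats(p)$mean_nn, 0)
  expect_equal(ens$mean_nn, mean(nn))
  expect_equal(ens$sd_nn, sd(nn))
  # each stored trajectory reproduces its record
  tr2 <- run_simulation(config_set(cfg, `simulation.master_seed` = 6L))
  expect_identical(positions_at(tr2), ens$finals[[2]])
  # n = 1 flags the degenerate SD
  e1 <- run_ensemble(cfg, n_trajectories = 1L, master_seed = 2L)
  expect_true(e1$sd_degenerate)
})

test_that("ensemble means from disjoint seed blocks agree statistically", {
  cfg <- tiny_config(`simulation.n_cargo` = 4L, `simulation.duration` = 20)
  e1 <- run_ensemble(cfg, n_trajectories = 8L, master_seed = 1L)
  e2 <- run_ensemble(cfg, n_trajectories = 8L, master_seed = 1000L)
  se <- sqrt(e1$sd_nn^2 / 8 + e2$sd_nn^2 / 8)
  expect_lt(abs(e1$mean_nn - e2$mean_nn), 3 * se + 1e-9)
})

test_that("regime scans cover the grid and label pure diffusion as diffusive", {
  cfg <- tiny_config(`simulation.duration` = 120,
                     `cargo.D_free` = 1e-3,
                     `tethers.k_attach` = 0)
  tab <- scan_regime(cfg, grid = list(`tethers.k_attach` = 0), n_per_cell = 2L)
  expect_identical(nrow(tab), 1L)
  expect_identical(tab$regime, "diffusive")
  # empty grid equals a single base-config cell
  tab0 <- scan_regime(tiny_config(`simulation.duration` = 10), n_per_cell = 2L)
  expect_identical(nrow(tab0), 1L)
  # 2x2 grid gives 4 reproducible rows
  tab2 <- scan_regime(tiny_config(`simulation.duration` = 12),
                      grid = list(`tethers.k_detach` = c(0.05, 0.1),
                                  `chemistry.tau_reset` = c(10, 20)),
                      n_per_cell = 2L)
  expect_identical(nrow(tab2), 4L)
  expect_error(scan_regime(cfg, grid = list(`tethers.bogus` = 1)), "unknown")
})

test_that("pinned cargos do not move while chemistry continues", {
  cfg <- tiny_config(`simulation.n_cargo` = 2L, `simulation.duration` = 10)
  tr <- run_simulation(cfg, pin_cargos = TRUE)
  expect_true(all(apply(tr$x, 2, function(v) diff(range(v))) == 0))
  expect_true(all(apply(tr$y, 2, function(v) diff(range(v))) == 0))
  expect_gt(max(tr$pools$n_refractory), 0L) # tether cycle still releases McdA
})
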