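test_that("separation statistics match hand-computed cases", {
  s <- separation_stats(rbind(c(0, 0), c(1, 0)))
  expect_equal(s$mean_nn, 1.0)
  expect_equal(s$mean_pairwise, 1.0)
  # 4 collinear points spaced 0.5
  s4 <- separation_stats(cbind(seq(0, 1.5, by = 0.5), 0))
  expect_equal(s4$mean_nn, 0.5)
  expect_equal(s4$mean_pairwise, (3 * 0.5 + 2 * 1.0 + 1 * 1.5) / 6)
  expect_error(separation_stats(rbind(c(0, 0))), "at least 2")
})

test_that("separation statistics equal brute-force recomputation", {
  brute <- function(p) {
    n <- nrow(p); nn <- rep(Inf, n); tot <- 0; cnt <- 0
    for (i in 1:n) for (j in 1:n) if (i != j) {
      d <- sqrt(sum((p[i, ] - p[j, ])^2))
      nn[i] <- min(nn[i], d)
      if (i < j) { tot <- tot + d; cnt <- cnt + 1 }
    }
    list(mean_nn = mean(nn), mean_pairwise = tot / cnt)
  }
  set.seed(10)
  for (rep in 1:50) {
    p <- matrix(runif(2 * sample(2:40, 1), -1, 1), ncol = 2)
    expect_equal(separation_stats(p), brute(p))
  }
})

test_that("ideal arrangements classify as constructed", {
  g <- geom_rod()
  th <- arrangement_thresholds()
  lin <- cbind(seq(-1, 1, length.out = 5), 0)
  expect_identical(classify_arrangement(lin, g, th)$label, "linear")
  stag <- cbind(seq(-1, 1, length.out = 6), 0.15 * (-1)^(0:5))
  rep_st <- classify_arrangement(stag, g, th)
  expect_identical(rep_st$label, "staggered")
  expect_equal(rep_st$alternation_fraction, 1.0)
  clus <- cbind(runif(6, -0.05, 0.05), runif(6, -0.05, 0.05))
  expect_identical(classify_arrangement(clus, g, th)$label, "clustered")
  expect_error(classify_arrangement(rbind(c(0, 0), c(5, 0)), g, th), "outside")
})

test_that("classification is invariant to x-translation, reflections, relabeling", {
  g <- geom_rod()
  set.seed(33)
  cases <- list(
    cbind(seq(-0.9, 0.9, length.out = 5), rnorm(5, 0, 0.01)),
    cbind(seq(-0.9, 0.9, length.out = 6), 0.12 * (-1)^(0:5) + rnorm(6, 0, 0.01)),
    gen_arrangement("uniform_random", 6, g, seed = 3))
  for (p in cases) {
    base <- classify_arrangement(p, g)$label
    expect_identical(classify_arrangement(cbind(p[, 1] + 0.2, p[, 2]), g)$label, base)
    expect_identical(classify_arrangement(cbind(-p[, 1], p[, 2]), g)$label, base)
    expect_identical(classify_arrangement(cbind(p[, 1], -p[, 2]), g)$label, base)
    expect_identical(classify_arrangement(p[sample(nrow(p)), ], g)$label, base)
  }
})

test_that("steady-state detection finds arrest times and ignores diffusion", {
  g <- geom_rod()
  # constant after t = 100 s
  tr <- gen_trajectory("directed_then_static", g, n_cargo = 2, gain = 1,
                       ramp_time = 100, duration = 600, seed = 1)
  t_star <- steady_state_time(tr)
  expect_false(is.null(t_star))
  expect_lte(t_star, 100 + 60)
  # all-constant trajectory arrests at the first record
  tr0 <- gen_trajectory("static", g, n_cargo = 2, duration = 300, seed = 1)
  expect_identical(steady_state_time(tr0), 0)
  # pure diffusion at D = 1e-3 does not arrest
  for (s in 1:10)
    expect_null(steady_state_time(gen_trajectory("pure_diffusion", g,
                                                 n_cargo = 2, D = 1e-3,
                                                 duration = 600, seed = s)))
  expect_error(steady_state_time(tr0, window = 1000), "window")
})

test_that("depletion index reads imposed depletion zones correctly", {
  g <- geom_rod()
  lat_full <- gen_field(g, 0.02, bulk_occupancy = 1)
  expect_equal(depletion_index(lat_full, c(0, 0)), 1.0)
  lat_dep <- gen_field(g, 0.02, bulk_occupancy = 1,
                       depletion_centers = c(0.3, 0), depletion_radius = 0.2875,
                       depletion_occupancy = 0, seed = 1)
  expect_equal(depletion_index(lat_dep, c(0.3, 0)), 0.0)
  # 50% annulus / 100% bulk within binomial noise of 0.5
  lat_half <- gen_field(g, 0.01, bulk_occupancy = 1,
                        depletion_centers = c(0, 0), depletion_radius = 0.2875,
                        depletion_occupancy = 0.5, seed = 2)
  expect_equal(depletion_index(lat_half, c(0, 0)), 0.5, tolerance = 0.05)
  expect_error(depletion_index(lat_full, c(0, 0), r_inner = 0.001,
                               r_outer = 0.002), "no site")
})

test_that("motility regimes classify by construction", {
  g <- geom_rod()
  tr_d <- gen_trajectory("directed_then_static", g, n_cargo = 2, gain = 1,
                         ramp_time = 200, duration = 600, seed = 2)
  expect_identical(classify_motility(tr_d)$label, "directed_segregation")
  tr_s <- gen_trajectory("static", g, n_cargo = 2, duration = 300, seed = 1)
  expect_identical(classify_motility(tr_s)$label, "static")
  expect_error(classify_motility(gen_trajectory("static", g, duration = 5)),
               ">= 10 records")
})

test_that("pure random walks are recognized as diffusive at a >= 95% rate", {
  g <- geom_rod()
  hits <- sum(vapply(1:100, function(s) {
    tr <- gen_trajectory("pure_diffusion", g, n_cargo = 2, D = 1e-3,
                         duration = 600, seed = s)
    classify_motility(tr)$label == "diffusive"
  }, TRUE))
  expect_gte(hits, 95)
})
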