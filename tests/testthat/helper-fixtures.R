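# Shared fixtures: a desk-scale configuration for structural/determinism
# tests (coarse lattice, short duration) and small statistical helpers.

tiny_config <- function(...) {
  cfg <- config_set(default_config(),
                    `simulation.lattice_spacing` = 0.04,
                    `chemistry.n_total` = 600L,
                    `cargo.n_mcdb` = 40L,
                    `simulation.duration` = 30,
                    `simulation.n_cargo` = 2L,
                    `simulation.cluster_radius` = 0.3)
  if (...length() > 0) cfg <- do.call(config_set, c(list(cfg), list(...)))
  cfg
}

# standard error of a (possibly autocorrelated) series by batch means
batch_se <- function(x, n_batches = 20) {
  n <- length(x)
  b <- max(1L, n %/% n_batches)
  means <- vapply(seq_len(n %/% b), function(i) mean(x[((i - 1) * b + 1):(i * b)]), 0)
  sd(means) / sqrt(length(means))
}

# manual lattice with chosen site coordinates (all treated as in-domain)
manual_lattice <- function(x, y, occupied = rep(FALSE, length(x)), spacing = 0.02) {
  structure(list(spacing = spacing, x = x, y = y,
                 i = as.integer(round(x / spacing)),
                 j = as.integer(round(y / spacing)),
                 occupied = occupied, tethered = rep(FALSE, length(x)),
                 n_sites = length(x)),
            class = "mcda_lattice")
}
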