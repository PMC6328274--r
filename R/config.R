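#' Default simulation configuration
#'
#' Returns the full configuration document with every default made explicit.
#' Sections: `geometry`, `chemistry`, `tethers`, `cargo`, `motion`,
#' `simulation`, `analysis_thresholds`. The shipped kinetic and mechanical
#' defaults place the system in the directed-segregation regime on the
#' default rod-shaped nucleoid (see the methods vignette for the rationale
#' behind each number).
#'
#' @return A nested list of class `sim_config`.
#' @export
default_config <- function() {
  cfg <- list(
    geometry = list(kind = "rounded_rectangle", length = 2.5, width = 0.6,
                    diameter = NULL),
    chemistry = list(n_total = 8000L, k_on = 1.0, k_off_basal = 0.01,
                     tau_reset = 20),
    tethers = list(r_capture = 0.3, k_attach = 10, k_detach = 0.1,
                   k_spring = 100, rest_length = 0),
    cargo = list(radius = 0.0875, n_mcdb = 400L, D_free = 1e-6),
    motion = list(dt = 1e-3, exclusion = "hard_disk"),
    simulation = list(n_cargo = 6L, duration = 600, record_interval = 1.0,
                      field_snapshot_interval = 0, master_seed = 1L,
                      cluster_radius = 0.3, lattice_spacing = 0.01),
    analysis_thresholds = list(t_lin = 0.05, alternation_min = 0.75,
                               clustered_nn_factor = 2.5, spacing_cv_max = 0.25,
                               ss_window = 60, ss_eps = 0.05,
                               gain_threshold = 0.3)
  )
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  for (sec in names(x)) {
    vals <- vapply(x[[sec]], function(v) if (is.null(v)) "NULL" else format(v), "")
    cat(" ", sec, ": ", paste(names(vals), vals, sep = "=", collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

# Merge user values over defaults, rejecting unknown sections/keys and
# validating invariants. Every error names the offending "section.key".
validate_config <- function(user) {
  cfg <- default_config()
  if (!is.list(user)) stop("config must be a list of sections")
  for (sec in names(user)) {
    if (!sec %in% names(cfg))
      stop("unknown config section: ", sec)
    if (is.null(user[[sec]])) next
    if (!is.list(user[[sec]]))
      stop("config section ", sec, " must be a mapping")
    for (key in names(user[[sec]])) {
      if (!key %in% names(cfg[[sec]]))
        stop("unknown config key: ", sec, ".", key)
      cfg[[sec]][[key]] <- user[[sec]][[key]]
    }
  }
  chk <- function(cond, key, msg) if (!cond) stop("invalid config: ", key, " ", msg)
  g <- cfg$geometry
  chk(g$kind %in% c("rounded_rectangle", "circle"), "geometry.kind",
      "must be rounded_rectangle or circle")
  if (g$kind == "rounded_rectangle") {
    chk(is.numeric(g$length) && g$length > 0, "geometry.length", "must be > 0")
    chk(is.numeric(g$width) && g$width > 0, "geometry.width", "must be > 0")
    chk(g$length >= g$width, "geometry.length", "must be >= geometry.width")
  } else {
    chk(is.numeric(g$diameter) && g$diameter > 0, "geometry.diameter", "must be > 0")
  }
  ch <- cfg$chemistry
  chk(ch$n_total >= 0, "chemistry.n_total", "must be >= 0")
  chk(is.numeric(ch$k_on) && ch$k_on >= 0, "chemistry.k_on", "must be >= 0")
  chk(is.numeric(ch$k_off_basal) && ch$k_off_basal >= 0,
      "chemistry.k_off_basal", "must be >= 0")
  chk(is.numeric(ch$tau_reset) && ch$tau_reset > 0, "chemistry.tau_reset",
      "must be > 0")
  te <- cfg$tethers
  for (k in names(te))
    chk(is.numeric(te[[k]]) && te[[k]] >= 0, paste0("tethers.", k), "must be >= 0")
  chk(te$r_capture >= cfg$cargo$radius, "tethers.r_capture",
      "must be >= cargo.radius")
  ca <- cfg$cargo
  chk(ca$radius > 0, "cargo.radius", "must be > 0")
  chk(ca$n_mcdb >= 0, "cargo.n_mcdb", "must be >= 0")
  chk(ca$D_free >= 0, "cargo.D_free", "must be >= 0")
  mo <- cfg$motion
  chk(is.numeric(mo$dt) && mo$dt > 0, "motion.dt", "must be > 0")
  chk(mo$exclusion %in% c("hard_disk", "none"), "motion.exclusion",
      "must be hard_disk or none")
  si <- cfg$simulation
  chk(si$n_cargo >= 0, "simulation.n_cargo", "must be >= 0")
  chk(si$duration > 0, "simulation.duration", "must be > 0")
  chk(si$record_interval > 0 && si$record_interval <= si$duration,
      "simulation.record_interval", "must be in (0, duration]")
  chk(si$field_snapshot_interval >= 0, "simulation.field_snapshot_interval",
      "must be >= 0")
  chk(si$cluster_radius > 0, "simulation.cluster_radius", "must be > 0")
  chk(si$lattice_spacing > 0, "simulation.lattice_spacing", "must be > 0")
  at <- cfg$analysis_thresholds
  for (k in names(at))
    chk(is.numeric(at[[k]]) && at[[k]] >= 0,
        paste0("analysis_thresholds.", k), "must be >= 0")
  cfg$chemistry$n_total <- as.integer(cfg$chemistry$n_total)
  cfg$cargo$n_mcdb <- as.integer(cfg$cargo$n_mcdb)
  cfg$simulation$n_cargo <- as.integer(cfg$simulation$n_cargo)
  cfg$simulation$master_seed <- as.integer(cfg$simulation$master_seed)
  class(cfg) <- "sim_config"
  cfg
}

#' Load a simulation configuration from a YAML file
#'
#' Unknown sections or keys are rejected by name; all physical parameters are
#' validated; every omitted value is filled with its documented default so
#' the returned object is fully explicit.
#'
#' @param path YAML file path.
#' @return A validated `sim_config`.
#' @seealso [save_config()], [default_config()]
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  validate_config(yaml::read_yaml(path))
}

#' Save a configuration as YAML
#'
#' `load_config(save_config(cfg, path))` is the identity.
#'
#' @param config A `sim_config` (or partial list; defaults are filled first).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  cfg <- validate_config(unclass(config))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Modify configuration values by dotted key
#'
#' @param config A `sim_config`.
#' @param ... Named values, e.g. `` `tethers.k_attach` = 20 ``.
#' @return The updated, revalidated `sim_config`.
#' @export
config_set <- function(config, ...) {
  vals <- list(...)
  cfg <- unclass(config)
  for (nm in names(vals)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    if (length(parts) != 2 || !parts[1] %in% names(cfg) ||
        !parts[2] %in% names(cfg[[parts[1]]]))
      stop("unknown config parameter: ", nm)
    cfg[[parts[1]]][[parts[2]]] <- vals[[nm]]
  }
  validate_config(cfg)
}

# 32-bit FNV-1a over the canonical (name-sorted) JSON of the config; used to
# stamp output metadata so runs are traceable to their exact parameters.
config_hash <- function(config) {
  canon <- function(x) {
    if (is.list(x)) {
      if (!is.null(names(x))) x <- x[order(names(x))]
      lapply(x, canon)
    } else x
  }
  txt <- jsonlite::toJSON(canon(unclass(config)), auto_unbox = TRUE,
                          digits = NA, null = "null")
  bytes <- utf8ToInt(as.character(txt))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Build geometry from the config's geometry section
#' @param config A `sim_config`.
#' @return A `nucleoid_geometry`.
#' @export
config_geometry <- function(config) {
  g <- config$geometry
  if (g$kind == "rounded_rectangle")
    make_geometry("rounded_rectangle", length = g$length, width = g$width)
  else make_geometry("circle", diameter = g$diameter)
}
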