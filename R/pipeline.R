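#' Run a declared analysis pipeline from a configuration
#'
#' Executes a sequence of named stages from a configuration (a YAML file
#' path or an equivalent nested list), with every source of randomness
#' seeded from the config so that re-running a config reproduces the
#' outputs exactly. Each stage yields a result record carrying the
#' operation name, an echo of its inputs, its outputs, the package
#' version, the seed and a timestamp.
#'
#' Available stages and their parameters:
#' \describe{
#'   \item{`torque_predictions`}{additive-torque predictions for two stator
#'     rings (`N_a`, `F_a`, `r_a`, `N_b`, `F_b`, `r_b`; defaults are the
#'     packaged motor constants) plus their ratio.}
#'   \item{`disk_rings`}{ring radii, protomer counts and increments of a
#'     [disk_lattice_model] (`R1`, `n1`, `spacing_ratio`, `n_rings`).}
#'   \item{`mesh_registry`}{cog mesh registry for (`n_small`, `m_teeth`).}
#'   \item{`simulate_bead`}{generate a stepping-bead trajectory (parameters
#'     of [simulate_stepping_trajectory()]); optional `out` CSV path.}
#'   \item{`detect_steps`}{dwell count from the trajectory of the preceding
#'     `simulate_bead` stage or from a `csv` path.}
#'   \item{`ring_phantom`}{generate a C_n ring phantom (parameters of
#'     [make_ring_phantom()]); optional `out` MRC path.}
#'   \item{`detect_symmetry`}{symmetry call on the preceding phantom or an
#'     `mrc` path (`r_min`, `r_max`, optional `z_min`, `z_max`, `k_max`).}
#' }
#'
#' @param config YAML file path or a list with elements `seed` (integer)
#'   and `stages` (list of lists, each with a `stage` name plus
#'   parameters).
#' @return list of result records (class `result_record`), one per stage.
#' @examples
#' cfg <- list(seed = 1, stages = list(list(stage = "torque_predictions")))
#' run_pipeline(cfg)
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop(sprintf("no such config: %s", config),
                                   call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("'config' must be a list or YAML path",
                             call. = FALSE)
  seed <- config$seed
  if (is.null(seed)) seed <- 1L
  check_scalar(seed, "config$seed", integerish = TRUE)
  stages <- config$stages
  if (is.null(stages)) stages <- list()
  state <- new.env(parent = emptyenv())
  records <- vector("list", length(stages))
  for (i in seq_along(stages)) {
    st <- stages[[i]]
    if (is.null(st$stage)) {
      stop(sprintf("stages[[%d]]: missing 'stage' name", i), call. = FALSE)
    }
    name <- st$stage
    params <- st[setdiff(names(st), "stage")]
    fn <- pipeline_stages[[name]]
    if (is.null(fn)) {
      stop(sprintf("stages[[%d]]: unknown stage '%s' (known: %s)",
                   i, name, paste(names(pipeline_stages), collapse = ", ")),
           call. = FALSE)
    }
    out <- fn(params, seed = as.integer(seed) + i, state = state)
    records[[i]] <- structure(
      list(operation = name, inputs = params, outputs = out,
           package_version = as.character(utils::packageVersion("flagmotor")),
           seed = as.integer(seed), timestamp = format(Sys.time(), tz = "UTC")),
      class = "result_record")
  }
  records
}

#' @export
print.result_record <- function(x, ...) {
  cat(sprintf("<result_record> %s (v%s, seed %d, %s)\n",
              x$operation, x$package_version, x$seed, x$timestamp))
  utils::str(x$outputs, max.level = 1, give.attr = FALSE)
  invisible(x)
}

#' Serialize a result record to JSON
#'
#' Stable JSON serialization; writing, re-reading and re-writing a record
#' is byte-identical.
#'
#' @param record a `result_record` (or list of them).
#' @param path optional file path; when omitted the JSON text is returned.
#' @return JSON text (invisibly when written to `path`).
#' @export
write_result_record <- function(record, path = NULL) {
  txt <- jsonlite::toJSON(unclass_records(record), auto_unbox = TRUE,
                          digits = NA, pretty = TRUE, null = "null")
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

unclass_records <- function(x) {
  if (inherits(x, "result_record")) return(lapply(unclass(x), unclass_records))
  if (is.list(x)) return(lapply(x, unclass_records))
  if (is.object(x)) return(unclass(x))
  x
}

default_param <- function(params, name, default) {
  if (!is.null(params[[name]])) params[[name]] else default
}

pipeline_stages <- list(
  torque_predictions = function(params, seed, state) {
    k <- motor_constants()
    ra <- stator_ring(default_param(params, "N_a", k$N_cj),
                      default_param(params, "F_a", k$F_stator_pN),
                      default_param(params, "r_a", k$r_cj_nm))
    rb <- stator_ring(default_param(params, "N_b", k$N_ec),
                      default_param(params, "F_b", k$F_stator_pN),
                      default_param(params, "r_b", k$r_ec_nm))
    cmp <- compare_motors(ra, rb)
    list(torque_a_pNnm = cmp$torque_a, torque_b_pNnm = cmp$torque_b,
         ratio = cmp$ratio, decomposition = as.list(cmp$decomposition))
  },
  disk_rings = function(params, seed, state) {
    k <- motor_constants()
    m <- disk_lattice_model(
      R1 = default_param(params, "R1", 180),
      n1 = default_param(params, "n1", k$disk_n1),
      spacing_ratio = default_param(params, "spacing_ratio",
                                    k$disk_spacing_ratio),
      n_rings = default_param(params, "n_rings", 5L))
    counts <- ring_protomer_counts(m)
    list(ring = seq_len(m$n_rings), radius_A = ring_radii(m),
         protomers = counts,
         increment = if (m$n_rings > 1) diff(counts) else integer(0))
  },
  mesh_registry = function(params, seed, state) {
    k <- motor_constants()
    mesh_registry(default_param(params, "n_small", k$N_cj),
                  default_param(params, "m_teeth", k$cring_teeth_cj))
  },
  simulate_bead = function(params, seed, state) {
    orbit <- orbit_ellipse(default_param(params, "orbit_a", 150),
                           default_param(params, "orbit_b", 90),
                           tilt = default_param(params, "orbit_tilt", 0))
    traj <- simulate_stepping_trajectory(
      n_steps_per_rev = default_param(params, "n_steps_per_rev", 26L),
      step_rate = default_param(params, "step_rate", 50),
      frames = default_param(params, "frames", 1e5),
      fps = default_param(params, "fps", 1000),
      orbit = orbit,
      noise_sd = default_param(params, "noise_sd", 20),
      back_step_prob = default_param(params, "back_step_prob", 0),
      seed = default_param(params, "seed", seed))
    state$trajectory <- traj
    if (!is.null(params$out)) write_trajectory(traj, params$out)
    list(frames = nrow(traj), seed = attr(traj, "seed"),
         out = params$out)
  },
  detect_steps = function(params, seed, state) {
    traj <- if (!is.null(params$csv)) read_trajectory(params$csv)
            else state$trajectory
    if (is.null(traj)) {
      stop("detect_steps: no trajectory (run simulate_bead first or give 'csv')",
           call. = FALSE)
    }
    call <- detect_bead_steps(
      traj, k_range = default_param(params, "k_min", 2):default_param(params, "k_max", 60))
    list(n_steps_spectral = call$n_steps_spectral,
         spectral_significance = call$spectral_significance,
         n_peaks_kde = call$n_peaks_kde, window = call$window)
  },
  ring_phantom = function(params, seed, state) {
    m <- make_ring_phantom(
      n_subunits = default_param(params, "n_subunits", 17L),
      ring_radius = default_param(params, "ring_radius", 150),
      subunit_sigma = default_param(params, "subunit_sigma", 12),
      grid_shape = default_param(params, "grid_shape", 128L),
      voxel_size = default_param(params, "voxel_size", 4))
    state$map <- m
    if (!is.null(params$out)) write_map(m, params$out)
    list(grid = dim(m$grid), voxel_size = m$voxel_size, out = params$out)
  },
  detect_symmetry = function(params, seed, state) {
    m <- if (!is.null(params$mrc)) read_map(params$mrc) else state$map
    if (is.null(m)) {
      stop("detect_symmetry: no map (run ring_phantom first or give 'mrc')",
           call. = FALSE)
    }
    r_band <- c(default_param(params, "r_min", 100),
                default_param(params, "r_max", 200))
    z_band <- if (!is.null(params$z_min)) c(params$z_min, params$z_max)
              else NULL
    call <- detect_cyclic_symmetry(m, r_band, z_band,
                                   k_range = 2:default_param(params, "k_max", 60))
    list(n_fold = call$n_fold, peak_power = call$peak_power,
         significance = call$significance)
  }
)
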