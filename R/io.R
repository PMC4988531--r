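## Pulse-package container (JSON), YAML run configuration with provenance,
## and helpers binding the pipeline together.

PULSE_SCHEMA_VERSION <- "1.0"

#' Write a pulse package
#'
#' Serializes a designed pulse and its gradient waveform into a single
#' JSON container with datasets `b_real` / `b_imag` (per channel,
#' microtesla), `G` (per axis, T/m), `dt` (s) and `meta`. Doubles are
#' written with 17 significant digits so that a write/read round trip
#' reproduces every array bit-exactly.
#'
#' @param file output path.
#' @param pulse an `rf_pulse_set`.
#' @param gradients a `gradient_set`.
#' @param meta optional named list of additional metadata.
#' @return Invisibly, `file`.
#' @export
write_pulse_package <- function(file, pulse, gradients, meta = list()) {
  if (nrow(pulse$b) != nrow(gradients$G))
    stop2("pulse and gradients must share the raster")
  obj <- list(schema_version = PULSE_SCHEMA_VERSION,
              b_real = unclass(Re(pulse$b)),
              b_imag = unclass(Im(pulse$b)),
              G = unclass(gradients$G),
              dt = pulse$dt,
              meta = meta)
  jsonlite::write_json(obj, file, digits = I(17), auto_unbox = TRUE)
  invisible(file)
}

#' Read a pulse package
#'
#' @param file path written by [write_pulse_package()].
#' @return List with `pulse` (`rf_pulse_set`), `gradients`
#'   (`gradient_set`) and `meta`. Missing datasets raise an error naming
#'   the absent field; an unknown schema version warns and reads
#'   best-effort.
#' @export
read_pulse_package <- function(file) {
  obj <- jsonlite::read_json(file, simplifyVector = TRUE)
  for (f in c("b_real", "b_imag", "G", "dt"))
    if (is.null(obj[[f]]))
      stop2("pulse package is missing required dataset: ", f)
  if (is.null(obj$schema_version) ||
      !identical(obj$schema_version, PULSE_SCHEMA_VERSION))
    warning("pulse package schema version mismatch; reading best-effort")
  br <- as.matrix(obj$b_real); bi <- as.matrix(obj$b_imag)
  b <- matrix(complex(real = br, imaginary = bi), nrow = nrow(br))
  G <- as.matrix(obj$G)
  dt <- obj$dt
  gs <- structure(list(G = G, dt = dt, duration = nrow(G) * dt,
                       k = NULL), class = "gradient_set")
  list(pulse = rf_pulse_set(b, dt), gradients = gs,
       meta = obj$meta)
}

## ---------------------------------------------------------------------------
## Run configuration

config_known_keys <- list(
  top = c("seed", "out_dir", "maps", "target", "trajectory", "design",
          "sequence"),
  maps = c("file_prefix", "grid_shape", "fov_mm", "n_channels",
           "b0_amplitude_hz", "uniform"),
  target = c("shape", "size_mm", "center_mm", "apodization_fwhm_mm",
             "flip_deg"),
  trajectory = c("type", "n_shells", "k_max", "radial_undersample",
                 "angular_undersample", "inter_shell_rotation", "fov_mm",
                 "resolution_mm", "undersample"),
  design = c("w_r", "lambda", "peak_ut", "attenuation_ut", "g_max", "s_max",
             "dt", "design_res_mm", "time_decimation", "max_iter",
             "use_girf"),
  sequence = c("asymptotic_angle", "n_echoes", "esp", "tissue", "n_dummy"))

check_keys <- function(block, name) {
  unknown <- setdiff(names(block), config_known_keys[[name]])
  if (length(unknown))
    stop2("unknown configuration key(s) in '", name, "': ",
          paste(unknown, collapse = ", "))
}

#' Run a design + verification pipeline from a configuration file
#'
#' Reads a YAML configuration describing field maps (a synthetic phantom
#' or files on disk), a target, a trajectory, design settings and an FSE
#' sequence; runs phantom generation, the re-VERSE design loop, a Bloch
#' simulation of the final pulse, the equivalent-flip-angle map and a
#' spatially resolved EPG prediction of the echo train; writes outputs and
#' a JSON provenance sidecar (seed, full parameter set, package and R
#' versions) sufficient to re-run the pipeline identically. Unknown
#' configuration keys are rejected.
#'
#' @param config path to a YAML file, or an equivalent named list.
#' @param out_dir output directory (overrides the configuration).
#' @return Invisibly, a list with the design result, flip-angle field, EPG
#'   images, suppression summary and the provenance record.
#' @export
run_config <- function(config, out_dir = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  check_keys(cfg, "top")
  for (blk in intersect(names(cfg), c("maps", "target", "trajectory",
                                      "design", "sequence")))
    check_keys(cfg[[blk]], blk)
  seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  out <- out_dir
  if (is.null(out)) out <- cfg$out_dir
  if (is.null(out)) out <- tempfile("cpmgpulse_run_")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)

  mc <- cfg$maps
  maps <- if (!is.null(mc$file_prefix)) {
    read_field_maps(mc$file_prefix)
  } else {
    make_phantom_maps(grid_shape = unlist(mc$grid_shape),
                      fov = unlist(mc$fov_mm %||% 220),
                      n_channels = mc$n_channels %||% 8,
                      b0_amplitude = mc$b0_amplitude_hz %||% 50,
                      uniform = isTRUE(mc$uniform), seed = seed)
  }

  tc <- cfg$trajectory
  curve <- if (identical(tc$type, "spiral_2d")) {
    spiral_2d(fov = tc$fov_mm %||% max(maps$fov_mm),
              resolution = tc$resolution_mm %||% 3.4,
              undersample = tc$undersample %||% 3.5)
  } else {
    shells_3d(n_shells = tc$n_shells %||% 6, k_max = tc$k_max %||% 280,
              radial_undersample = tc$radial_undersample %||% 1.75,
              angular_undersample = tc$angular_undersample %||% 3.21,
              inter_shell_rotation = tc$inter_shell_rotation %||% 30,
              fov_ref = tc$fov_mm %||% max(maps$fov_mm))
  }

  dc <- cfg$design %||% list()
  girf <- if (isTRUE(dc$use_girf)) girf_synthetic(dc$dt %||% 6.4e-6) else NULL
  tgt_args <- cfg$target %||% list(shape = "cube", size_mm = 60)
  names(tgt_args)[names(tgt_args) == "shape"] <- "shape"
  des <- design_pulse(
    maps, curve,
    target = tgt_args,
    w_r = dc$w_r %||% 0.25, lambda = dc$lambda %||% 0.01,
    limits = list(peak_ut = dc$peak_ut %||% 11,
                  attenuation_ut = dc$attenuation_ut %||% 8,
                  g_max = dc$g_max %||% 40, s_max = dc$s_max %||% 200),
    dt = dc$dt %||% 6.4e-6, design_res_mm = dc$design_res_mm %||% 5.5,
    time_decimation = dc$time_decimation %||% 4L, girf = girf,
    max_iter = dc$max_iter %||% 5L)

  mag <- bloch_simulate(des$pulse, des$gradients, des$design_maps)
  flip <- equivalent_flip(mag)

  sq <- cfg$sequence %||% list()
  tis <- tissue_params(sq$tissue %||% "csf")
  sweep <- pss_sweep(sq$asymptotic_angle %||% 35, sq$n_echoes %||% 100)
  epg <- spatial_epg(flip, sweep, T1 = tis$T1, T2 = tis$T2,
                     esp = sq$esp %||% 4, n_dummy = sq$n_dummy %||% 6)

  ## central-echo image and suppression summary
  win <- pmin(length(sweep$theta_deg), 46:55)
  echo_img <- array(0, des$design_maps$grid_shape)
  echo_img[epg$voxels] <- colMeans(Mod(epg$cpmg[win, , drop = FALSE]) +
                                     Mod(epg$noncpmg[win, , drop = FALSE]))
  sup <- tryCatch(
    suppression_ratio(echo_img, des$design_maps,
                      inner_center_mm = unlist(tgt_args$center_mm %||% c(0, 0, 0))),
    error = function(e) NULL)

  write_pulse_package(file.path(out, "pulse_package.json"), des$pulse,
                      des$gradients,
                      meta = list(seed = seed, w_r = dc$w_r %||% 0.25))
  prov <- list(seed = seed, config = cfg,
               package_version = as.character(utils::packageVersion("cpmgpulse")),
               r_version = R.version.string,
               timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(prov, file.path(out, "provenance.json"),
                       auto_unbox = TRUE, digits = I(17))

  invisible(list(design = des, flip = flip, epg = epg, suppression = sup,
                 provenance = prov, out_dir = out))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
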