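#' Run configuration for the batch pipeline
#'
#' One configuration document drives all pipeline stages. It round-trips
#' losslessly through YAML ([save_run_config()] / [load_run_config()]) and
#' its hash is recorded in every run manifest so a run can be reproduced
#' bit-for-bit from the manifest alone.
#'
#' @param movie_path,seeds_path,out_dir File paths (seeds CSV has columns
#'   `ring_id, x1, y1, x2, y2`).
#' @param pixel_size,frame_interval Calibration (um/px, s).
#' @param seed Integer seed for all stochastic stages.
#' @param ring_sim,sm_sim Named lists overriding [ring_sim_config()] /
#'   [sm_sim_config()] defaults for `run_simulate()`.
#' @param velocity Named list of [estimate_slope()] /
#'   [measure_ring_velocities()] overrides.
#' @param residence Named list of [detect_spots()] / [link_tracks()] /
#'   [fit_survival()] overrides (`threshold`, `link_radius`, `kp`,
#'   `b_bounds`, ...).
#' @return A `run_config` list.
#' @export
run_config <- function(movie_path = NULL, seeds_path = NULL, out_dir = ".",
                       pixel_size = 0.042, frame_interval = 1, seed = 1,
                       ring_sim = list(), sm_sim = list(),
                       velocity = list(), residence = list()) {
  structure(
    list(movie_path = movie_path, seeds_path = seeds_path, out_dir = out_dir,
         pixel_size = pixel_size, frame_interval = frame_interval,
         seed = as.integer(seed), ring_sim = ring_sim, sm_sim = sm_sim,
         velocity = velocity, residence = residence),
    class = "run_config"
  )
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("Config file not found: %s", path))
  raw <- yaml::read_yaml(path)
  cfg <- do.call(run_config, raw)
  cfg
}

#' @rdname run_config
#' @param config A `run_config`.
#' @export
save_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

config_hash <- function(config) rlang::hash(unclass(config))

write_manifest <- function(config, out_dir, stage, outputs) {
  manifest <- list(
    stage = stage,
    config = unclass(config),
    config_hash = config_hash(config),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("ztread")),
    outputs = outputs
  )
  path <- file.path(out_dir, paste0("manifest_", stage, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Simulate a ring movie and a single-molecule movie to disk
#'
#' Writes `ring.tif`, `sm.tif` (16-bit multi-page TIFF), the ground-truth
#' CSVs, a seeds CSV for the ring, and a manifest JSON recording the config
#' hash and seed. Identical config and seed give byte-identical TIFFs.
#'
#' @param config A [run_config()]; `config$ring_sim` / `config$sm_sim`
#'   override generator defaults, `config$seed` seeds both generators.
#' @param force Overwrite an existing run in `out_dir`?
#' @return Invisibly, a named list of output paths.
#' @export
run_simulate <- function(config, force = FALSE) {
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(out_dir, "manifest_simulate.json")
  if (file.exists(manifest_path) && !force)
    abort(sprintf("Output dir %s already holds a run (use force = TRUE).", out_dir))

  rcfg <- do.call(ring_sim_config, modifyList(list(seed = config$seed),
                                              config$ring_sim))
  scfg <- do.call(sm_sim_config, modifyList(list(seed = config$seed),
                                            config$sm_sim))
  ring <- simulate_ring_movie(rcfg)
  sm <- simulate_sm_movie(scfg)

  paths <- list(
    ring_movie = file.path(out_dir, "ring.tif"),
    sm_movie = file.path(out_dir, "sm.tif"),
    ring_truth = file.path(out_dir, "ring_truth.csv"),
    sm_truth = file.path(out_dir, "sm_truth.csv"),
    seeds = file.path(out_dir, "seeds.csv")
  )
  write_movie(ring$movie, paths$ring_movie)
  write_movie(sm$movie, paths$sm_movie)
  utils::write.csv(ring$truth, paths$ring_truth, row.names = FALSE)
  truth <- dplyr::transmute(sm$events,
                            event_id = .data$event_id,
                            birth_time_s = .data$birth_time_s,
                            dwell_s = .data$dwell_s,
                            cause = .data$cause,
                            x_px = .data$x_px, y_px = .data$y_px)
  utils::write.csv(truth, paths$sm_truth, row.names = FALSE)
  r <- ring$truth
  utils::write.csv(
    tibble(ring_id = 1L,
           x1 = r$cx - r$r_px, y1 = r$cy, x2 = r$cx + r$r_px, y2 = r$cy),
    paths$seeds, row.names = FALSE)
  write_manifest(config, out_dir, "simulate", paths)
  invisible(paths)
}

#' Measure ring velocities from a movie and a seeds CSV
#'
#' Runs preprocess, ring fitting, kymograph extraction and Fourier-phase
#' slope estimation for every seed pair and writes `velocity.csv` plus a
#' manifest. Rejected rings stay in the table with `accepted = FALSE` and a
#' `note` giving the reason.
#'
#' @param config A [run_config()] with `movie_path` and `seeds_path` set.
#' @return The per-ring velocity tibble, invisibly.
#' @export
run_velocity <- function(config) {
  if (is.null(config$movie_path) || !file.exists(config$movie_path))
    abort(sprintf("Movie file not found: %s", config$movie_path %||% "<missing>"))
  if (is.null(config$seeds_path) || !file.exists(config$seeds_path))
    abort(sprintf("Seeds file not found: %s", config$seeds_path %||% "<missing>"))
  seeds <- utils::read.csv(config$seeds_path)
  if (nrow(seeds) == 0) abort("Empty seeds CSV.")
  mov <- read_movie(config$movie_path, config$pixel_size,
                    config$frame_interval)
  res <- do.call(measure_ring_velocities,
                 c(list(mov = mov, seeds = seeds), config$velocity))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out_csv <- file.path(config$out_dir, "velocity.csv")
  utils::write.csv(res, out_csv, row.names = FALSE)
  write_manifest(config, config$out_dir, "velocity", list(velocity = out_csv))
  invisible(res)
}

#' Measure single-molecule residence times from a movie
#'
#' Runs spot detection, nearest-neighbour linking, residence collection and
#' the constrained survival fit; writes `spots.csv`, `tracks.csv` and
#' `fit.json` (parameters, kp mode and bounds, event counts) plus a
#' manifest.
#'
#' @param config A [run_config()] with `movie_path` set; `config$residence`
#'   may set `threshold`, `link_radius`, `kp`, `b_bounds`, `drop_censored`.
#' @return The `survival_fit`, invisibly.
#' @export
run_residence <- function(config) {
  if (is.null(config$movie_path) || !file.exists(config$movie_path))
    abort(sprintf("Movie file not found: %s", config$movie_path %||% "<missing>"))
  mov <- read_movie(config$movie_path, config$pixel_size,
                    config$frame_interval)
  p <- config$residence
  spots <- detect_spots(mov, threshold = p$threshold %||% NULL)
  if (nrow(spots) == 0) abort("no usable events")
  linked <- link_tracks(spots, link_radius = p$link_radius %||% 10)
  tracks <- track_summary(linked, n_frames(mov), mov$frame_interval)
  rs <- collect_residences(tracks, mov$frame_interval,
                           drop_censored = p$drop_censored %||% TRUE)
  fit <- fit_survival(rs, kp = p$kp %||% 0.031,
                      b_bounds = p$b_bounds %||% c(0.2, 0.25))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(spots = file.path(config$out_dir, "spots.csv"),
                tracks = file.path(config$out_dir, "tracks.csv"),
                fit = file.path(config$out_dir, "fit.json"))
  utils::write.csv(linked, paths$spots, row.names = FALSE)
  utils::write.csv(tracks, paths$tracks, row.names = FALSE)
  jsonlite::write_json(
    list(A = fit$A, B = fit$B, k = fit$k, kp = fit$kp, t_r = fit$t_r,
         kp_mode = fit$kp_mode,
         b_bounds = p$b_bounds %||% c(0.2, 0.25),
         n_events = fit$n_events, rss = fit$rss,
         r_squared = fit$r_squared),
    paths$fit, auto_unbox = TRUE, digits = NA)
  write_manifest(config, config$out_dir, "residence", paths)
  invisible(fit)
}
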