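#' Configuration for synthetic single-molecule movies
#'
#' Parameters of a sparse single-molecule TIRF channel in which fluorescently
#' tagged molecules appear on the membrane as a homogeneous Poisson process,
#' stay at a fixed position for an exponentially distributed dwell, and
#' disappear either by unbinding or by photobleaching. Disappearance is a
#' two-population mixture matching the double-exponential survival model
#' fitted downstream: a fraction `bleach_fraction` of molecules draws its
#' dwell from `Exponential(bleach_rate)` (bleach-limited) and the rest from
#' `Exponential(unbind_rate)`. A competing-risks mode, in which every
#' molecule races both clocks, is available via `mode = "competing"`.
#'
#' Defaults follow the nanobody-channel acquisition settings: 0.042 um
#' pixels, 1 frame/s, unbinding at `1/11.5` 1/s and photobleaching at
#' `0.031` 1/s with a bleach-limited fraction of 0.22. The spot SNR is
#' `spot_amplitude / noise_sd`.
#'
#' @param field_size Frame side length, px.
#' @param pixel_size Pixel size, um/px.
#' @param frame_interval Frame interval, s.
#' @param n_frames Number of frames.
#' @param appearance_rate Molecule appearances per second over the field.
#' @param unbind_rate Unbinding rate k, 1/s.
#' @param bleach_rate Photobleaching rate kp, 1/s.
#' @param bleach_fraction Fraction of molecules that are bleach-limited,
#'   in `[0, 1]`.
#' @param spot_amplitude Peak spot amplitude, A.U.
#' @param noise_sd Gaussian noise sd, A.U.; SNR = `spot_amplitude/noise_sd`.
#' @param psf_sigma Gaussian PSF sd, px.
#' @param mode `"mixture"` (default) or `"competing"` (per-molecule competing
#'   risks between unbinding and bleaching).
#' @param seed Integer seed.
#' @return An `sm_sim_config` list.
#' @export
sm_sim_config <- function(field_size = 64,
                          pixel_size = 0.042,
                          frame_interval = 1,
                          n_frames = 600,
                          appearance_rate = 2,
                          unbind_rate = 1 / 11.5,
                          bleach_rate = 0.031,
                          bleach_fraction = 0.22,
                          spot_amplitude = 50,
                          noise_sd = 10,
                          psf_sigma = 1.3,
                          mode = c("mixture", "competing"),
                          seed = 1) {
  mode <- match.arg(mode)
  cfg <- list(
    field_size = as.integer(field_size), pixel_size = pixel_size,
    frame_interval = frame_interval, n_frames = as.integer(n_frames),
    appearance_rate = appearance_rate, unbind_rate = unbind_rate,
    bleach_rate = bleach_rate, bleach_fraction = bleach_fraction,
    spot_amplitude = spot_amplitude, noise_sd = noise_sd,
    psf_sigma = psf_sigma, mode = mode, seed = as.integer(seed)
  )
  if (cfg$unbind_rate < 0 || cfg$bleach_rate < 0 || cfg$appearance_rate < 0)
    abort("Rates must be >= 0.")
  if (cfg$bleach_fraction < 0 || cfg$bleach_fraction > 1)
    abort("`bleach_fraction` must be in [0, 1].")
  eff_unbind <- (1 - cfg$bleach_fraction) * cfg$unbind_rate
  eff_bleach <- cfg$bleach_fraction * cfg$bleach_rate
  if (cfg$mode == "mixture" && eff_unbind == 0 && eff_bleach == 0)
    abort("No disappearance mechanism: all effective rates are zero.")
  if (cfg$mode == "competing" && cfg$unbind_rate == 0 && cfg$bleach_rate == 0)
    abort("No disappearance mechanism: all rates are zero.")
  structure(cfg, class = "sm_sim_config")
}

#' Draw ground-truth single-molecule appearance events
#'
#' Samples birth times (homogeneous Poisson over the movie duration),
#' positions (uniform with a PSF-sized margin) and true dwell times under
#' either the mixture or the competing-risks disappearance model of
#' [sm_sim_config()].
#'
#' @param cfg An [sm_sim_config()].
#' @param n_events Optional fixed number of events; by default the count is
#'   Poisson with mean `appearance_rate * duration`.
#' @return A tibble of ground-truth events: `event_id`, `birth_time_s`,
#'   `dwell_s`, `cause` (`"unbind"` or `"bleach"`), `x_px`, `y_px`.
#' @export
simulate_dwell_events <- function(cfg, n_events = NULL) {
  stopifnot(inherits(cfg, "sm_sim_config"))
  duration <- cfg$n_frames * cfg$frame_interval
  withr::with_seed(cfg$seed, {
    n <- if (is.null(n_events)) rpois(1, cfg$appearance_rate * duration)
         else as.integer(n_events)
    birth <- sort(runif(n, 0, duration))
    margin <- 3 * cfg$psf_sigma
    x <- runif(n, 1 + margin, cfg$field_size - margin)
    y <- runif(n, 1 + margin, cfg$field_size - margin)
    if (cfg$mode == "mixture") {
      is_bleach <- runif(n) < cfg$bleach_fraction
      dwell <- ifelse(is_bleach,
                      rexp(n, rate = max(cfg$bleach_rate, 1e-12)),
                      rexp(n, rate = max(cfg$unbind_rate, 1e-12)))
      cause <- ifelse(is_bleach, "bleach", "unbind")
    } else {
      t_u <- rexp(n, rate = max(cfg$unbind_rate, 1e-12))
      t_b <- rexp(n, rate = max(cfg$bleach_rate, 1e-12))
      if (cfg$unbind_rate == 0) t_u <- rep(Inf, n)
      if (cfg$bleach_rate == 0) t_b <- rep(Inf, n)
      dwell <- pmin(t_u, t_b)
      cause <- ifelse(t_u <= t_b, "unbind", "bleach")
    }
    tibble(event_id = seq_len(n), birth_time_s = birth, dwell_s = dwell,
           cause = cause, x_px = x, y_px = y)
  })
}

#' Convert true dwells into frame-sampled residence observations
#'
#' Mirrors what an ideal detector/tracker would record from a movie sampled
#' at `frame_interval`: a molecule is detected in every frame whose
#' acquisition time falls inside `[birth, birth + dwell)`; the observed
#' residence is `(n_frames_present - 1) * frame_interval` and an event is
#' censored when it touches the first or last movie frame.
#'
#' @param events Tibble from [simulate_dwell_events()] (or any table with
#'   `birth_time_s` and `dwell_s`).
#' @param frame_interval Sampling interval, s.
#' @param n_frames Number of movie frames; frame `f` is acquired at
#'   `(f - 1) * frame_interval`.
#' @return The events tibble with added `first_frame`, `last_frame`,
#'   `n_frames`, `residence_s`, `censored`; events never detected
#'   (zero frames) are dropped.
#' @export
discretize_dwells <- function(events, frame_interval, n_frames) {
  first_f <- pmax(1L, as.integer(ceiling(events$birth_time_s / frame_interval)) + 1L)
  ## last frame acquired strictly before birth + dwell
  last_f <- pmin(as.integer(n_frames),
                 as.integer(floor((events$birth_time_s + events$dwell_s) /
                                    frame_interval - 1e-12)) + 1L)
  keep <- last_f >= first_f
  out <- events[keep, , drop = FALSE]
  out$first_frame <- first_f[keep]
  out$last_frame <- last_f[keep]
  out$n_frames <- out$last_frame - out$first_frame + 1L
  out$residence_s <- (out$n_frames - 1L) * frame_interval
  out$censored <- out$first_frame == 1L | out$last_frame == n_frames
  as_tibble(out)
}

#' Simulate a single-molecule TIRF movie with ground truth
#'
#' Draws events with [simulate_dwell_events()] and renders each molecule as
#' an immobile 2-d Gaussian spot of amplitude `spot_amplitude` for the frames
#' spanned by its dwell, over a constant baseline with per-pixel Gaussian
#' noise of sd `noise_sd`.
#'
#' @param cfg An [sm_sim_config()].
#' @param noise Add Gaussian noise? `FALSE` gives noiseless renders.
#' @return A list with `movie` (a [movie()]) and `events`, the ground-truth
#'   table of [simulate_dwell_events()].
#' @export
simulate_sm_movie <- function(cfg, noise = TRUE) {
  stopifnot(inherits(cfg, "sm_sim_config"))
  events <- simulate_dwell_events(cfg)
  n <- cfg$field_size
  baseline <- 5 * cfg$noise_sd  # keeps noisy counts non-negative
  arr <- array(baseline, dim = c(cfg$n_frames, n, n))

  obs <- discretize_dwells(events, cfg$frame_interval, cfg$n_frames)
  half <- ceiling(3 * cfg$psf_sigma)
  for (i in seq_len(nrow(obs))) {
    x0 <- obs$x_px[i]; y0 <- obs$y_px[i]
    cx <- round(x0); cy <- round(y0)
    xs <- max(1, cx - half):min(n, cx + half)
    ys <- max(1, cy - half):min(n, cy + half)
    g <- cfg$spot_amplitude *
      exp(-(outer((ys - y0)^2, (xs - x0)^2, "+")) / (2 * cfg$psf_sigma^2))
    for (f in obs$first_frame[i]:obs$last_frame[i]) {
      arr[f, ys, xs] <- arr[f, ys, xs] + g
    }
  }
  if (noise) {
    ## noise seed offset from the event seed keeps the two draws independent
    withr::with_seed(cfg$seed + 10000L, {
      arr <- arr + array(rnorm(length(arr), sd = cfg$noise_sd), dim = dim(arr))
      arr[arr < 0] <- 0
    })
  }
  list(movie = movie(arr, cfg$pixel_size, cfg$frame_interval),
       events = events)
}

#' Mean dwell time of the mixture disappearance model
#'
#' Closed form `(1 - B)/k + B/kp` for the two-population mixture in which a
#' fraction `B` of molecules is bleach-limited.
#'
#' @param unbind_rate k, 1/s.
#' @param bleach_rate kp, 1/s.
#' @param bleach_fraction B, in `[0, 1]`.
#' @return Mean dwell, s.
#' @export
mixture_mean_dwell <- function(unbind_rate, bleach_rate, bleach_fraction) {
  (1 - bleach_fraction) / unbind_rate + bleach_fraction / bleach_rate
}
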