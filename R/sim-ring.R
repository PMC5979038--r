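#' Configuration for synthetic treadmilling-ring movies
#'
#' Defines the imaging and ground-truth parameters of a simulated TIRF movie
#' of a single ring-shaped polymer whose intensity pattern travels along the
#' circumference (treadmilling). Defaults emulate the experimental regime in
#' which ~1 um diameter rings rotate at tens of nm/s: 0.042 um pixels, 3 s
#' frames, a 0.5 um radius ring carrying three 390 nm filaments, and noise
#' levels giving a peak signal-to-noise ratio of about 3 (see [ring_snr()]).
#'
#' The sign of `linear_speed` encodes chirality in displayed-image
#' coordinates (row index increasing downwards): positive speed is clockwise.
#'
#' @param image_size Frame side length, pixels.
#' @param pixel_size Pixel size, um/px.
#' @param frame_interval Frame interval, s.
#' @param n_frames Number of frames (>= 2).
#' @param ring_center `(x, y)` centre in pixels; defaults to the frame centre.
#' @param ring_radius Ring radius, um.
#' @param linear_speed Signed treadmilling speed along the circumference,
#'   nm/s. Positive = clockwise, negative = counterclockwise, 0 = static.
#' @param n_filaments Number of filaments on the ring.
#' @param filament_length Filament arc length, nm.
#' @param psf_sigma Gaussian PSF standard deviation, px.
#' @param background_level Mean background, A.U.
#' @param photon_scale Signal scaling, A.U. per unit of line density; with
#'   the default PSF this sets the peak amplitude above background.
#' @param read_noise_sd Gaussian read-noise standard deviation, A.U.
#' @param seed Integer seed; the same config and seed give a bit-identical
#'   movie.
#'
#' @return A `ring_sim_config` list.
#' @export
#' @examples
#' cfg <- ring_sim_config(linear_speed = 34, seed = 7)
#' sim <- simulate_ring_movie(cfg)
#' sim$truth
ring_sim_config <- function(image_size = 48,
                            pixel_size = 0.042,
                            frame_interval = 3,
                            n_frames = 100,
                            ring_center = NULL,
                            ring_radius = 0.5,
                            linear_speed = 34,
                            n_filaments = 3,
                            filament_length = 390,
                            psf_sigma = 1.3,
                            background_level = 100,
                            photon_scale = 120,
                            read_noise_sd = 2,
                            seed = 1) {
  if (is.null(ring_center)) {
    ring_center <- c((image_size + 1) / 2, (image_size + 1) / 2)
  }
  cfg <- list(
    image_size = as.integer(image_size), pixel_size = pixel_size,
    frame_interval = frame_interval, n_frames = as.integer(n_frames),
    ring_center = as.numeric(ring_center), ring_radius = ring_radius,
    linear_speed = linear_speed, n_filaments = as.integer(n_filaments),
    filament_length = filament_length, psf_sigma = psf_sigma,
    background_level = background_level, photon_scale = photon_scale,
    read_noise_sd = read_noise_sd, seed = as.integer(seed)
  )
  if (cfg$ring_radius <= 0) abort("`ring_radius` must be > 0.")
  if (cfg$n_frames < 2L) abort("`n_frames` must be >= 2.")
  if (cfg$psf_sigma <= 0) abort("`psf_sigma` must be > 0.")
  if (cfg$pixel_size <= 0 || cfg$frame_interval <= 0)
    abort("Calibrations must be > 0.")
  if (cfg$n_filaments < 1L) abort("`n_filaments` must be >= 1.")
  structure(cfg, class = "ring_sim_config")
}

#' Simulate a treadmilling-ring TIRF movie with ground truth
#'
#' Renders `n_filaments` arcs of `filament_length` on the circle of
#' `ring_radius`, advancing each by `linear_speed * frame_interval` along the
#' circumference per frame (wrapping). Filament start angles are equally
#' spaced, so the noiseless render of speed `-v` is the exact mirror image
#' (column flip about the ring centre) of speed `+v`. The line-density map is
#' PSF-blurred, scaled by `photon_scale`, offset by the background, Poisson
#' sampled and finally perturbed by Gaussian read noise.
#'
#' @param cfg A [ring_sim_config()].
#' @param noise Add Poisson shot noise and Gaussian read noise? Set `FALSE`
#'   for noiseless expectation images (ground-truth checks).
#'
#' @return A list with elements `movie` (a [movie()]) and `truth`, a one-row
#'   tibble with the signed angular speed (rad/s), linear speed (nm/s),
#'   chirality, ring centre and radius (px).
#' @export
simulate_ring_movie <- function(cfg, noise = TRUE) {
  stopifnot(inherits(cfg, "ring_sim_config"))
  circumference_nm <- 2 * pi * cfg$ring_radius * 1000
  if (cfg$filament_length > circumference_nm)
    abort("`filament_length` exceeds the ring circumference; cannot place arcs.")
  r_px <- cfg$ring_radius / cfg$pixel_size
  omega <- cfg$linear_speed / (cfg$ring_radius * 1000)  # rad/s, signed
  ## Filament start angles: equally spaced, symmetric about pi/2, so that
  ## negating the speed mirrors the noiseless movie exactly and the pattern
  ## power concentrates in the n_filaments-th angular harmonic (a single
  ## sharp spectral line, as in experimental ring kymographs).
  theta0 <- pi / 2 + 2 * pi * (seq_len(cfg$n_filaments) - 1) / cfg$n_filaments
  half_arc <- cfg$filament_length / (cfg$ring_radius * 1000) / 2  # rad

  n <- cfg$image_size
  arr <- array(0, dim = c(cfg$n_frames, n, n))
  ## supersample points along each arc, ~10 per pixel of arc length
  arc_px <- cfg$filament_length / (cfg$pixel_size * 1000)
  n_pts <- max(2L, ceiling(arc_px * 10))
  rel <- seq(-half_arc, half_arc, length.out = n_pts)
  wt <- arc_px / n_pts  # density per deposit: integrates to arc length in px

  render_frame <- function(t_s) {
    dens <- matrix(0, n, n)
    for (th0 in theta0) {
      th <- th0 + omega * t_s + rel
      x <- cfg$ring_center[1] + r_px * cos(th)
      y <- cfg$ring_center[2] + r_px * sin(th)
      ## bilinear splatting: each point's weight is shared among its four
      ## neighbouring pixels, keeping the render exactly mirror-symmetric
      x0 <- floor(x); y0 <- floor(y)
      fx <- x - x0; fy <- y - y0
      for (k in seq_along(x)) {
        for (dd in list(c(0, 0, (1 - fx[k]) * (1 - fy[k])),
                        c(1, 0, fx[k] * (1 - fy[k])),
                        c(0, 1, (1 - fx[k]) * fy[k]),
                        c(1, 1, fx[k] * fy[k]))) {
          xi <- x0[k] + dd[1]; yi <- y0[k] + dd[2]
          if (xi >= 1 && xi <= n && yi >= 1 && yi <= n)
            dens[yi, xi] <- dens[yi, xi] + wt * dd[3]
        }
      }
    }
    cfg$background_level + cfg$photon_scale * gaussian_blur(dens, cfg$psf_sigma)
  }

  expected <- lapply(seq_len(cfg$n_frames) - 1L,
                     function(f) render_frame(f * cfg$frame_interval))
  if (noise) {
    withr::with_seed(cfg$seed, {
      for (f in seq_len(cfg$n_frames)) {
        mu <- expected[[f]]
        noisy <- rpois(length(mu), lambda = mu) +
          rnorm(length(mu), sd = cfg$read_noise_sd)
        arr[f, , ] <- pmax(matrix(noisy, n, n), 0)
      }
    })
  } else {
    for (f in seq_len(cfg$n_frames)) arr[f, , ] <- expected[[f]]
  }

  chir <- if (cfg$linear_speed > 0) "clockwise"
          else if (cfg$linear_speed < 0) "counterclockwise" else "static"
  list(
    movie = movie(arr, cfg$pixel_size, cfg$frame_interval),
    truth = tibble(
      omega_rad_s = omega,
      linear_speed_nm_s = cfg$linear_speed,
      chirality = chir,
      cx = cfg$ring_center[1], cy = cfg$ring_center[2],
      r_px = r_px,
      n_filaments = cfg$n_filaments
    )
  )
}

#' Estimate the peak signal-to-noise ratio of a ring-movie configuration
#'
#' SNR is defined as the peak filament amplitude above background divided by
#' the noise standard deviation at that intensity
#' (`sqrt(background + peak + read_noise_sd^2)`, Poisson + read noise). The
#' peak is measured on a noiseless render of the first frame.
#'
#' @param cfg A [ring_sim_config()].
#' @return A single number, the peak SNR.
#' @export
ring_snr <- function(cfg) {
  stopifnot(inherits(cfg, "ring_sim_config"))
  cfg2 <- cfg
  cfg2$n_frames <- 2L
  frame1 <- simulate_ring_movie(cfg2, noise = FALSE)$movie$data[1, , ]
  peak <- max(frame1) - cfg$background_level
  peak / sqrt(cfg$background_level + peak + cfg$read_noise_sd^2)
}

#' Simulate a membrane-adsorption time course
#'
#' Produces the frame-mean intensity trace of a protein-adsorption
#' experiment: a linear rise at `ramp_rate` that saturates at `plateau`,
#' with optional additive Gaussian noise. Used to exercise the time-zero
#' synchronisation rule ([synchronize_trace()]).
#'
#' @param ramp_rate Initial adsorption rate, A.U. per second.
#' @param plateau Saturation intensity, A.U. (> 0).
#' @param n_frames Number of time points.
#' @param frame_interval Time between points, s.
#' @param noise_sd Additive Gaussian noise sd, A.U.
#' @param seed Optional integer seed (required when `noise_sd > 0`).
#' @return A tibble with columns `frame`, `time_s`, `intensity`.
#' @export
simulate_adsorption_trace <- function(ramp_rate, plateau,
                                      n_frames = 200, frame_interval = 10,
                                      noise_sd = 0, seed = NULL) {
  if (plateau <= 0) abort("`plateau` must be > 0.")
  t_s <- (seq_len(n_frames) - 1) * frame_interval
  base <- pmin(ramp_rate * t_s, plateau)
  if (noise_sd > 0) {
    if (is.null(seed)) abort("Provide `seed` when `noise_sd > 0`.")
    base <- withr::with_seed(as.integer(seed),
                             base + rnorm(n_frames, sd = noise_sd))
  }
  tibble(frame = seq_len(n_frames), time_s = t_s, intensity = base)
}
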