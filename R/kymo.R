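#' Preprocess a movie: mean filter and drift correction
#'
#' Applies a square mean filter to every frame and, optionally, rigid
#' integer-pixel drift correction by phase correlation against the first
#' frame. Calibration is preserved.
#'
#' @param mov A [movie()].
#' @param mean_filter_size Odd side length of the mean filter; 1 disables
#'   filtering.
#' @param drift Estimate and remove whole-frame translation?
#' @return A [movie()] with the same dimensions. When drift correction is on,
#'   the per-frame shifts are attached as attribute `"drift"` (tibble with
#'   `frame`, `dx`, `dy`).
#' @export
preprocess <- function(mov, mean_filter_size = 3, drift = FALSE) {
  stopifnot(inherits(mov, "ztread_movie"))
  k <- as.integer(mean_filter_size)
  if (k < 1L || k %% 2L == 0L)
    abort("`mean_filter_size` must be odd and >= 1.")
  nf <- n_frames(mov)
  arr <- mov$data
  if (k > 1L) {
    kern <- matrix(1 / k^2, k, k)
    for (f in seq_len(nf)) {
      arr[f, , ] <- EBImage::filter2(arr[f, , ], kern)
    }
  }
  shifts <- NULL
  if (isTRUE(drift)) {
    nr <- dim(arr)[2]; nc <- dim(arr)[3]
    shifts <- tibble(frame = seq_len(nf), dx = 0, dy = 0)
    ## consecutive-frame correlation, accumulated: robust when the scene
    ## itself evolves slowly (e.g. a rotating ring) between distant frames
    raw <- arr
    acc <- c(dx = 0, dy = 0)
    for (f in 2:nf) {
      s <- phase_correlation_shift(raw[f - 1, , ], raw[f, , ]) + acc
      acc <- s
      if (abs(s["dx"]) > 0.25 * nc || abs(s["dy"]) > 0.25 * nr) {
        warn(sprintf("Frame %d drift (%d, %d) px exceeds 25%% of the frame; correction still applied.",
                     f, s["dx"], s["dy"]))
      }
      if (any(s != 0)) arr[f, , ] <- shift_matrix(arr[f, , ], s["dx"], s["dy"])
      shifts$dx[f] <- s[["dx"]]; shifts$dy[f] <- s[["dy"]]
    }
  }
  out <- movie(arr, mov$pixel_size, mov$frame_interval)
  if (!is.null(shifts)) attr(out, "drift") <- shifts
  out
}

#' Fit a circular ring ROI from two seed points
#'
#' The user supplies two points roughly on opposite sides of a ring. The
#' initial circle has the seed segment as diameter; it is then refined by
#' maximising the mean time-averaged intensity sampled along the circle,
#' over centre and radius within +/- 5 px of the initial guess.
#'
#' @param mov A [movie()].
#' @param p1,p2 Numeric `(x, y)` seed points, pixels.
#' @param search Half-width of the refinement box, px.
#' @return A `ring_roi`: list with `cx`, `cy`, `r_px`, `refined` (FALSE when
#'   refinement found no improvement or ran to the search-box edge) and the
#'   seed points.
#' @export
fit_ring <- function(mov, p1, p2, search = 5) {
  stopifnot(inherits(mov, "ztread_movie"))
  p1 <- as.numeric(p1); p2 <- as.numeric(p2)
  if (isTRUE(all.equal(p1, p2)))
    abort("Seed points are identical; cannot define a circle.")
  init <- c(cx = (p1[1] + p2[1]) / 2,
            cy = (p1[2] + p2[2]) / 2,
            r = sqrt(sum((p1 - p2)^2)) / 2)
  if (init["r"] < 3) abort("Seed circle radius below 3 px.")
  avg <- apply(mov$data, c(2, 3), mean)

  ring_mean <- function(par) {
    n <- max(8L, round(2 * pi * par[3]))
    th <- 2 * pi * (seq_len(n) - 1) / n
    mean(interp_bilinear(avg,
                         par[1] + par[3] * cos(th),
                         par[2] + par[3] * sin(th)))
  }
  lower <- init - search
  upper <- init + search
  lower["r"] <- max(lower["r"], 3)
  opt <- stats::optim(init, function(p) -ring_mean(p),
                      method = "L-BFGS-B", lower = lower, upper = upper)
  improved <- (-opt$value) > ring_mean(init) + 1e-9
  at_edge <- any(abs(opt$par - lower) < 1e-6) || any(abs(opt$par - upper) < 1e-6)
  refined <- improved && !at_edge
  par <- if (refined) opt$par else init
  structure(
    list(cx = unname(par[1]), cy = unname(par[2]), r_px = unname(par[3]),
         refined = refined, seed_points = rbind(p1, p2)),
    class = "ring_roi"
  )
}

#' @export
print.ring_roi <- function(x, ...) {
  cat(sprintf("<ring_roi> centre (%.2f, %.2f), r = %.2f px%s\n",
              x$cx, x$cy, x$r_px, if (x$refined) "" else " [not refined]"))
  invisible(x)
}

#' Extract a circular kymograph around a ring
#'
#' For every frame, intensity is sampled by bilinear interpolation at
#' `round(2*pi*r)` equally spaced angles on the three concentric circles of
#' radius `r - 1`, `r` and `r + 1` px, and the three angular profiles are
#' averaged. Rows index arc position (one sample is about one pixel of arc),
#' columns index time.
#'
#' @param mov A [movie()].
#' @param roi A `ring_roi` from [fit_ring()], or a list with `cx`, `cy`,
#'   `r_px`.
#' @return A `kymograph`: list with `values` (arc x time matrix), `arc_step`
#'   (nm per arc sample), `frame_interval` (s) and the source `roi`.
#' @export
extract_kymograph <- function(mov, roi) {
  stopifnot(inherits(mov, "ztread_movie"))
  r <- roi$r_px
  if (r < 3) abort("Ring radius must be >= 3 px (needs r-1, r, r+1 circles).")
  nr <- dim(mov$data)[2]; nc <- dim(mov$data)[3]
  if (roi$cx - (r + 1) < 1 || roi$cx + (r + 1) > nc ||
      roi$cy - (r + 1) < 1 || roi$cy + (r + 1) > nr)
    abort("Ring (r + 1 px) touches the image border.")
  n_arc <- round(2 * pi * r)
  th <- 2 * pi * (seq_len(n_arc) - 1) / n_arc
  nf <- n_frames(mov)
  vals <- matrix(0, n_arc, nf)
  for (f in seq_len(nf)) {
    m <- mov$data[f, , ]
    prof <- rep(0, n_arc)
    for (rho in c(r - 1, r, r + 1)) {
      prof <- prof + interp_bilinear(m, roi$cx + rho * cos(th),
                                     roi$cy + rho * sin(th))
    }
    vals[, f] <- prof / 3
  }
  structure(
    list(values = vals, arc_step = mov$pixel_size * 1000,
         frame_interval = mov$frame_interval, roi = roi),
    class = "kymograph"
  )
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("<kymograph> %d arc samples x %d frames | %.1f nm/sample | %.3g s/frame\n",
              nrow(x$values), ncol(x$values), x$arc_step, x$frame_interval))
  invisible(x)
}

#' Estimate treadmilling speed and chirality from a kymograph
#'
#' Implements Fourier-phase slope estimation with spectral quality gates.
#' The kymograph is Savitzky-Golay smoothed along the arc dimension
#' (order 2) and contrast-enhanced with CLAHE. The arc dimension is tiled
#' into blocks of `band_size` samples (a single all-rows block when fewer
#' than `2 * band_size` samples exist). Per block: the temporal FFT is taken
#' per arc row; the characteristic frequency `f*` is the non-DC bin (up to
#' 0.8x Nyquist) maximising the mean spectral magnitude; the FFT phase at `f*`,
#' unwrapped along arc position, is fitted with a least-squares line whose
#' slope `q` (rad/sample) and `R^2` are recorded. A block passes the quality
#' gates when the spectral peak is at least `peak_ratio_min` times the mean
#' non-DC magnitude and `R^2 >= r2_min`. Ring-level `f*` and `|q|` are
#' peak-ratio-weighted means over accepted blocks, and
#' `v = 2*pi*f* / |q| * arc_step` (nm/s) holds exactly by construction.
#' Positive phase slope (phase advancing with arc position) is called
#' clockwise, the rotation sense of C-terminally membrane-targeted FtsZ in
#' displayed-image orientation.
#'
#' @param kym A [extract_kymograph()] result.
#' @param band_size Arc samples per analysis block.
#' @param sg_window Savitzky-Golay window length (odd), arc samples.
#' @param sg_order Savitzky-Golay polynomial order.
#' @param peak_ratio_min Spectral peak / mean gate.
#' @param r2_min Phase-fit R^2 gate.
#' @param clahe_tiles,clahe_limit CLAHE tile grid and clip limit
#'   (EBImage parameterisation).
#' @return A one-row tibble (class `velocity_result`): `f_star_hz`,
#'   `q_rad_per_sample`, `r_squared`, `peak_ratio`, `v_nm_s` (unsigned),
#'   `omega_deg_s`, `chirality` (`"clockwise"`, `"counterclockwise"` or
#'   `"static/rejected"`), `accepted`, `n_blocks`, `n_blocks_accepted`.
#'   Per-block detail is attached as attribute `"blocks"`.
#' @export
estimate_slope <- function(kym, band_size = 50, sg_window = 7, sg_order = 2,
                           peak_ratio_min = 10, r2_min = 0.95,
                           clahe_tiles = 8, clahe_limit = 2) {
  stopifnot(inherits(kym, "kymograph"))
  V <- kym$values
  n_arc <- nrow(V); n_t <- ncol(V)
  if (n_t < 8) abort("Kymograph too short in time for spectral analysis.")

  reject <- function(reason) {
    res <- tibble(
      f_star_hz = NA_real_, q_rad_per_sample = NA_real_,
      r_squared = NA_real_, peak_ratio = 0, v_nm_s = NA_real_,
      omega_deg_s = NA_real_, chirality = "static/rejected",
      accepted = FALSE, n_blocks = 0L, n_blocks_accepted = 0L
    )
    class(res) <- c("velocity_result", class(res))
    attr(res, "reason") <- reason
    res
  }
  if (all(V == 0)) return(reject("all-zero kymograph"))

  ## Savitzky-Golay along the arc dimension, per time column: smooths shot
  ## noise across neighbouring arc samples without attenuating the temporal
  ## frequencies that carry the travelling pattern
  if (n_arc >= sg_window) {
    for (j in seq_len(n_t)) {
      V[, j] <- signal::sgolayfilt(V[, j], p = sg_order, n = sg_window)
    }
  }
  ## CLAHE on the [0, 1]-normalised kymograph
  rng <- range(V)
  if (diff(rng) > 0) {
    Vn <- (V - rng[1]) / diff(rng)
    Vc <- tryCatch(
      EBImage::clahe(Vn, nx = clahe_tiles, ny = clahe_tiles,
                     limit = clahe_limit),
      error = function(e) Vn)
    V <- as.matrix(Vc)
  }

  ## arc blocks
  blocks <- if (n_arc >= 2 * band_size) {
    n_b <- floor(n_arc / band_size)
    lapply(seq_len(n_b), function(b) ((b - 1) * band_size + 1):(b * band_size))
  } else {
    list(seq_len(n_arc))
  }

  n_half <- floor(n_t / 2)
  ## peak search: non-DC bins up to 0.8x Nyquist (the top of the band holds
  ## only frame-to-frame flicker, never a resolvable travelling pattern)
  cand <- 2:max(2, floor(0.8 * n_half) + 1)
  all_nondc <- 2:(n_half + 1)

  fit_block <- function(rows) {
    X <- V[rows, , drop = FALSE]
    X <- sweep(X, 1, rowMeans(X))          # remove per-row DC
    Fm <- mvfft(t(X))                      # freq x rows
    mag <- rowMeans(Mod(Fm))
    denom <- mean(mag[all_nondc])
    k <- cand[which.max(mag[cand])]
    peak_ratio <- if (denom > 0) mag[k] / denom else 0
    ## phase under the e^{+i 2 pi f t} travelling-wave convention, so that a
    ## clockwise pattern (advancing towards larger arc index) has q > 0
    phase <- -Arg(Fm[k, ])
    phase <- signal::unwrap(phase)
    idx <- seq_along(rows)
    fit <- lm(phase ~ idx)
    q <- unname(coef(fit)[2])
    r2 <- summary(fit)$r.squared
    f_star <- (k - 1) / (n_t * kym$frame_interval)
    tibble(f_star_hz = f_star, q = q, r_squared = r2,
           peak_ratio = peak_ratio,
           accepted = peak_ratio >= peak_ratio_min & r2 >= r2_min &
             abs(q) > .Machine$double.eps)
  }
  bl <- dplyr::bind_rows(lapply(blocks, fit_block))
  acc <- bl[bl$accepted, , drop = FALSE]

  if (nrow(acc) == 0) {
    res <- reject("no block passed the quality gates")
    res$n_blocks <- nrow(bl)
    res$peak_ratio <- max(bl$peak_ratio)
    res$r_squared <- bl$r_squared[which.max(bl$peak_ratio)]
    attr(res, "blocks") <- bl
    return(res)
  }
  w <- acc$peak_ratio / sum(acc$peak_ratio)
  f_star <- sum(w * acc$f_star_hz)
  q_abs <- sum(w * abs(acc$q))
  q_sign <- sign(sum(w * sign(acc$q)))
  if (q_sign == 0) q_sign <- sign(acc$q[which.max(acc$peak_ratio)])
  v <- 2 * pi * f_star / q_abs * kym$arc_step
  r_nm <- kym$roi$r_px * kym$arc_step
  omega_deg <- v / r_nm * 180 / pi
  res <- tibble(
    f_star_hz = f_star,
    q_rad_per_sample = q_sign * q_abs,
    r_squared = sum(w * acc$r_squared),
    peak_ratio = sum(w * acc$peak_ratio),
    v_nm_s = v,
    omega_deg_s = omega_deg,
    chirality = if (q_sign > 0) "clockwise" else "counterclockwise",
    accepted = TRUE,
    n_blocks = nrow(bl),
    n_blocks_accepted = nrow(acc)
  )
  class(res) <- c("velocity_result", class(res))
  attr(res, "blocks") <- bl
  res
}

#' Measure treadmilling velocity for seeded rings in a movie
#'
#' Convenience pipeline: [preprocess()] once, then per seed pair
#' [fit_ring()], [extract_kymograph()] and [estimate_slope()].
#'
#' @param mov A [movie()].
#' @param seeds Tibble with columns `ring_id`, `x1`, `y1`, `x2`, `y2`.
#' @param mean_filter_size,drift Passed to [preprocess()].
#' @param ... Passed to [estimate_slope()].
#' @return A tibble with one row per ring: `ring_id`, `cx`, `cy`, `r_px`
#'   and the [estimate_slope()] columns. Rings whose analysis fails
#'   (e.g. circle touching the border) are returned rejected with the error
#'   message in `note`.
#' @export
measure_ring_velocities <- function(mov, seeds, mean_filter_size = 3,
                                    drift = FALSE, ...) {
  stopifnot(all(c("ring_id", "x1", "y1", "x2", "y2") %in% names(seeds)))
  if (nrow(seeds) == 0) abort("Empty seeds table.")
  pp <- preprocess(mov, mean_filter_size = mean_filter_size, drift = drift)
  one <- function(row) {
    out <- tryCatch({
      roi <- fit_ring(pp, c(row$x1, row$y1), c(row$x2, row$y2))
      vr <- estimate_slope(extract_kymograph(pp, roi), ...)
      dplyr::bind_cols(
        tibble(ring_id = row$ring_id, cx = roi$cx, cy = roi$cy,
               r_px = roi$r_px, note = NA_character_),
        as_tibble(vr))
    }, error = function(e) {
      tibble(ring_id = row$ring_id, cx = NA_real_, cy = NA_real_,
             r_px = NA_real_, note = conditionMessage(e),
             f_star_hz = NA_real_, q_rad_per_sample = NA_real_,
             r_squared = NA_real_, peak_ratio = 0, v_nm_s = NA_real_,
             omega_deg_s = NA_real_, chirality = "static/rejected",
             accepted = FALSE, n_blocks = 0L, n_blocks_accepted = 0L)
    })
    out
  }
  dplyr::bind_rows(lapply(seq_len(nrow(seeds)), function(i) one(seeds[i, ])))
}
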