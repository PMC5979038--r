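#' Detect single-molecule spots in a movie
#'
#' Difference-of-Gaussians bandpass (removing low- and high-frequency noise)
#' followed by local-maximum detection above `threshold` and subpixel
#' refinement by brightness-weighted centroid over a window of radius 3 px
#' on the bandpassed image. The centroid iterates with a Gaussian mask
#' (sd `mask_sigma`) re-centred on the current estimate, which suppresses
#' window-edge noise and truncation bias while remaining a
#' brightness-weighted position estimate.
#'
#' @param mov A [movie()] (or a single matrix frame).
#' @param threshold Detection threshold on the bandpassed intensity, A.U.
#'   When `NULL`, set to `5 * mad` of the bandpassed first frame.
#' @param band_low_sigma,band_high_sigma Gaussian sigmas (px) of the
#'   difference-of-Gaussians bandpass; features between the two scales pass.
#' @param centroid_radius Half-width of the centroid window, px.
#' @param mask_sigma Gaussian mask sd for the iterative centroid, px.
#' @return A tibble of spots: `frame`, `x`, `y` (subpixel px), `brightness`
#'   (summed bandpassed intensity in the centroid window).
#' @export
detect_spots <- function(mov, threshold = NULL,
                         band_low_sigma = 1, band_high_sigma = 3,
                         centroid_radius = 3, mask_sigma = 1.6) {
  if (is.matrix(mov)) {
    frames <- list(mov)
  } else {
    stopifnot(inherits(mov, "ztread_movie"))
    frames <- lapply(seq_len(n_frames(mov)), function(i) mov$data[i, , ])
  }
  if (!is.null(threshold) && threshold <= 0) abort("`threshold` must be > 0.")

  bandpass <- function(m) {
    gaussian_blur(m, band_low_sigma) - gaussian_blur(m, band_high_sigma)
  }
  if (is.null(threshold)) {
    bp1 <- bandpass(frames[[1]])
    threshold <- 5 * mad(bp1)
  }

  r <- centroid_radius
  detect_one <- function(m, f) {
    bp <- bandpass(m)
    if (max(m) >= 65535) warn(sprintf("Frame %d contains saturated pixels.", f))
    nr <- nrow(bp); nc <- ncol(bp)
    ## local maxima: strictly greater than the 8-neighbourhood
    core <- bp[2:(nr - 1), 2:(nc - 1)]
    is_max <- core > threshold
    for (dy in -1:1) for (dx in -1:1) {
      if (dx == 0 && dy == 0) next
      is_max <- is_max & core >= bp[2:(nr - 1) + dy, 2:(nc - 1) + dx]
    }
    idx <- which(is_max, arr.ind = TRUE)
    if (nrow(idx) == 0) return(NULL)
    ys <- idx[, 1] + 1L; xs <- idx[, 2] + 1L
    keep <- ys > r & ys <= nr - r & xs > r & xs <= nc - r
    ys <- ys[keep]; xs <- xs[keep]
    if (length(ys) == 0) return(NULL)
    off <- -r:r
    out <- lapply(seq_along(ys), function(i) {
      x <- xs[i]; y <- ys[i]
      bright <- NA_real_
      for (it in 1:8) {
        cxi <- round(x); cyi <- round(y)
        if (cxi <= r || cxi > nc - r || cyi <= r || cyi > nr - r) break
        xw <- cxi + off; yw <- cyi + off
        w <- bp[yw, xw]
        w[w < 0] <- 0
        if (it == 1) bright <- sum(w)
        g <- exp(-(outer((yw - y)^2, (xw - x)^2, "+")) / (2 * mask_sigma^2))
        wg <- w * g
        s <- sum(wg)
        if (s <= 0) return(NULL)
        nx <- sum(wg * rep(xw, each = length(off))) / s
        ny <- sum(wg * rep(yw, times = length(off))) / s
        done <- abs(nx - x) < 1e-4 && abs(ny - y) < 1e-4
        x <- nx; y <- ny
        if (done) break
      }
      if (is.na(bright) || bright <= 0) return(NULL)
      tibble(frame = f, x = x, y = y, brightness = bright)
    })
    dplyr::bind_rows(out)
  }
  res <- dplyr::bind_rows(
    lapply(seq_along(frames), function(f) detect_one(frames[[f]], f)))
  if (nrow(res) == 0) {
    res <- tibble(frame = integer(), x = numeric(), y = numeric(),
                  brightness = numeric())
  }
  res
}

#' Link spots into tracks across consecutive frames
#'
#' Greedy nearest-neighbour assignment between consecutive frames: candidate
#' pairs within `link_radius` are matched closest-first, each spot used at
#' most once. An unmatched spot starts a new track; a track ends on the first
#' frame without a match (strict consecutive linking, no gap closing by
#' default).
#'
#' @param spots Tibble from [detect_spots()] (columns `frame`, `x`, `y`).
#' @param link_radius Maximum inter-frame displacement, px (default 10, the
#'   conventional search area at 0.042 um pixels).
#' @param gap_frames Frames a track may survive without a detection
#'   (default 0 = strict consecutive).
#' @return The spots tibble with an added `track_id` column.
#' @export
link_tracks <- function(spots, link_radius = 10, gap_frames = 0) {
  stopifnot(all(c("frame", "x", "y") %in% names(spots)))
  spots <- dplyr::arrange(spots, .data$frame)
  n <- nrow(spots)
  if (n == 0) return(dplyr::mutate(spots, track_id = integer()))
  track_id <- integer(n)
  next_id <- 1L
  ## active tracks: index of their last spot
  active <- integer(0)
  frames <- sort(unique(spots$frame))
  for (f in frames) {
    cur <- which(spots$frame == f)
    ## tracks eligible to continue
    if (length(active)) {
      last_f <- spots$frame[active]
      active <- active[f - last_f <= 1L + gap_frames & f - last_f >= 1L]
    }
    if (length(active) && length(cur)) {
      dx <- outer(spots$x[active], spots$x[cur], "-")
      dy <- outer(spots$y[active], spots$y[cur], "-")
      d <- sqrt(dx^2 + dy^2)
      d[d > link_radius] <- NA
      pairs <- which(!is.na(d), arr.ind = TRUE)
      if (nrow(pairs)) {
        ord <- order(d[pairs])
        used_a <- logical(length(active)); used_c <- logical(length(cur))
        for (p in ord) {
          i <- pairs[p, 1]; j <- pairs[p, 2]
          if (used_a[i] || used_c[j]) next
          used_a[i] <- TRUE; used_c[j] <- TRUE
          track_id[cur[j]] <- track_id[active[i]]
        }
      }
    }
    new_spots <- cur[track_id[cur] == 0L]
    if (length(new_spots)) {
      track_id[new_spots] <- next_id + seq_along(new_spots) - 1L
      next_id <- next_id + length(new_spots)
    }
    ## matched current spots replace their track's last index; unmatched old
    ## tracks are dropped next round by the frame-gap test
    active <- c(active[spots$frame[active] == f], cur)
    active <- active[!duplicated(track_id[active], fromLast = TRUE)]
  }
  dplyr::mutate(spots, track_id = track_id)
}

#' Summarise tracks
#'
#' @param linked Output of [link_tracks()].
#' @param n_movie_frames Total frames in the movie (for censoring).
#' @param frame_interval Frame interval, s.
#' @return One row per track: `track_id`, `start_frame`, `end_frame`,
#'   `n_frames`, `residence_s = (n_frames - 1) * frame_interval`, `censored`
#'   (track touches the first or last movie frame), mean position.
#' @export
track_summary <- function(linked, n_movie_frames, frame_interval) {
  stopifnot("track_id" %in% names(linked))
  dplyr::summarise(
    dplyr::group_by(linked, .data$track_id),
    start_frame = min(.data$frame),
    end_frame = max(.data$frame),
    n_frames = dplyr::n(),
    x = mean(.data$x), y = mean(.data$y),
    .groups = "drop"
  ) |>
    dplyr::mutate(
      residence_s = (.data$n_frames - 1) * frame_interval,
      censored = .data$start_frame == 1L | .data$end_frame == n_movie_frames
    )
}

#' Collect a residence-time sample from tracks
#'
#' Applies the standard exclusion rule: events detected in fewer than
#' `min_frames` (default 2) frames are below the method's accuracy and are
#' dropped. Censored tracks (present in the first or last movie frame) are
#' dropped by default because their dwell is only partially observed.
#'
#' @param tracks Tibble from [track_summary()] (or [discretize_dwells()]).
#' @param frame_interval Frame interval, s.
#' @param drop_censored Drop censored tracks?
#' @param min_frames Minimum number of frames for an event to count.
#' @return A `residence_set`: list with `residence_s` (numeric sample),
#'   `frame_interval`, `n_events`, and the exclusion bookkeeping.
#' @export
collect_residences <- function(tracks, frame_interval, drop_censored = TRUE,
                               min_frames = 2L) {
  stopifnot(all(c("n_frames", "residence_s", "censored") %in% names(tracks)))
  kept <- tracks[tracks$n_frames >= min_frames, , drop = FALSE]
  n_short <- nrow(tracks) - nrow(kept)
  n_cens <- sum(kept$censored)
  if (drop_censored) kept <- kept[!kept$censored, , drop = FALSE]
  if (nrow(kept) == 0) abort("no usable events")
  structure(
    list(residence_s = kept$residence_s, frame_interval = frame_interval,
         n_events = nrow(kept), n_excluded_short = n_short,
         n_censored = n_cens, drop_censored = drop_censored),
    class = "residence_set"
  )
}

#' @export
print.residence_set <- function(x, ...) {
  cat(sprintf("<residence_set> %d events | dt = %.3g s | mean = %.3g s (%d short excluded, %d censored%s)\n",
              x$n_events, x$frame_interval, mean(x$residence_s),
              x$n_excluded_short, x$n_censored,
              if (x$drop_censored) " dropped" else " kept"))
  invisible(x)
}

#' Empirical survival curve of a residence sample
#'
#' Fraction of events with residence strictly greater than `t`, evaluated at
#' integer frame multiples from 0 to the longest residence.
#'
#' @param rs A `residence_set`.
#' @return Tibble with `time_s` and `survival`.
#' @export
survival_curve <- function(rs) {
  stopifnot(inherits(rs, "residence_set"))
  tmax <- max(rs$residence_s)
  t_s <- seq(0, tmax, by = rs$frame_interval)
  tibble(time_s = t_s,
         survival = vapply(t_s, function(t) mean(rs$residence_s > t),
                           numeric(1)))
}

as_survival_df <- function(x) {
  if (inherits(x, "residence_set")) return(survival_curve(x))
  stopifnot(is.data.frame(x), all(c("time_s", "survival") %in% names(x)))
  as_tibble(x)
}

#' Fit the constrained double-exponential survival model
#'
#' Least-squares fit of `S(t) = A*exp(-k*t) + B*exp(-kp*t)` to the empirical
#' survival curve, with `A = 1 - B` (so `S(0) = 1`), `B` bounded in
#' `b_bounds`, and the photobleaching rate `kp` either fixed to an
#' independently calibrated value (default `0.031` 1/s, from immobilised
#' fluorophores) or co-fitted. `k` is the unbinding rate; the mean residence
#' time is `t_r = 1/k`.
#'
#' @param x A `residence_set`, or a data frame with `time_s` and `survival`
#'   (e.g. a noiseless model curve).
#' @param kp Fixed photobleaching rate (1/s), or `"free"` to co-fit it.
#' @param b_bounds Lower/upper bound on the bleach fraction `B`.
#' @return A `survival_fit`: list with `A`, `B`, `k`, `kp`, `t_r`,
#'   `kp_mode`, `n_events`, `rss`, `r_squared` and the fitted `curve`.
#' @export
fit_survival <- function(x, kp = 0.031, b_bounds = c(0.2, 0.25)) {
  df <- as_survival_df(x)
  n_events <- if (inherits(x, "residence_set")) x$n_events else NA_integer_
  if (!is.na(n_events) && n_events < 100)
    warn(sprintf("Only %d events; fits below ~100 events are unstable.", n_events))
  kp_free <- identical(kp, "free")
  if (!kp_free && (!is.numeric(kp) || kp < 0))
    abort("`kp` must be a non-negative rate or \"free\".")
  if (length(b_bounds) != 2 || b_bounds[1] > b_bounds[2])
    abort("`b_bounds` must be c(lower, upper).")

  k0 <- {
    m <- sum(df$survival) * mean(diff(df$time_s))  # integral of S ~ mean dwell
    if (m > 0) 1 / m else 1
  }
  b0 <- mean(b_bounds)
  nls_fit <- function() {
    if (kp_free) {
      minpack.lm::nlsLM(
        survival ~ (1 - B) * exp(-k * time_s) + B * exp(-kp * time_s),
        data = df, start = list(k = k0, B = b0, kp = 0.03),
        lower = c(k = 1e-8, B = b_bounds[1], kp = 1e-8),
        upper = c(k = Inf, B = b_bounds[2], kp = Inf),
        control = minpack.lm::nls.lm.control(maxiter = 500))
    } else {
      kp_fix <- kp
      minpack.lm::nlsLM(
        survival ~ (1 - B) * exp(-k * time_s) + B * exp(-kp_fix * time_s),
        data = df, start = list(k = k0, B = b0),
        lower = c(k = 1e-8, B = b_bounds[1]),
        upper = c(k = Inf, B = b_bounds[2]),
        control = minpack.lm::nls.lm.control(maxiter = 500))
    }
  }
  ## direct bounded least squares; covers starts where the Levenberg-
  ## Marquardt jacobian is singular (degenerate mixtures with kp -> k)
  optim_fit <- function() {
    rss_of <- function(p) {
      kpv <- if (kp_free) p[3] else kp
      pred <- (1 - p[2]) * exp(-p[1] * df$time_s) + p[2] * exp(-kpv * df$time_s)
      sum((df$survival - pred)^2)
    }
    par0 <- if (kp_free) c(k0, b0, 0.03) else c(k0, b0)
    lo <- if (kp_free) c(1e-8, b_bounds[1], 1e-8) else c(1e-8, b_bounds[1])
    hi <- if (kp_free) c(1e3, b_bounds[2], 1e3) else c(1e3, b_bounds[2])
    o <- stats::optim(par0, rss_of, method = "L-BFGS-B", lower = lo,
                      upper = hi,
                      control = list(maxit = 1000, factr = 1e3,
                                     parscale = abs(par0)))
    if (o$convergence != 0)
      abort(sprintf("Survival fit did not converge (optim code %d, n = %d points, k0 = %.3g).",
                    o$convergence, nrow(df), k0))
    cf <- c(k = o$par[1], B = o$par[2])
    if (kp_free) cf <- c(cf, kp = o$par[3])
    cf
  }
  rss_at <- function(cf) {
    kpv <- if (kp_free) unname(cf["kp"]) else kp
    pred <- (1 - cf["B"]) * exp(-cf["k"] * df$time_s) +
      cf["B"] * exp(-kpv * df$time_s)
    sum((df$survival - pred)^2)
  }
  ## LM can stall on its box projection at a B bound; take the better of the
  ## two bounded least-squares routes
  cands <- list()
  cands$lm <- tryCatch(coef(nls_fit()), error = function(e) NULL)
  cands$opt <- tryCatch(optim_fit(),
                        error = function(e) if (is.null(cands$lm)) abort(conditionMessage(e)) else NULL)
  cands <- Filter(Negate(is.null), cands)
  if (length(cands) == 0) abort("Survival fit did not converge.")
  cf <- cands[[which.min(vapply(cands, rss_at, numeric(1)))]]
  k_hat <- unname(cf["k"])
  if (k_hat <= 0) abort("Fitted unbinding rate k <= 0.")
  B_hat <- unname(cf["B"])
  kp_hat <- if (kp_free) unname(cf["kp"]) else kp
  if (kp_free && abs(kp_hat - k_hat) < 0.05 * k_hat)
    warn("kp ~ k at the optimum: the mixture is degenerate (single-exponential data?).")
  pred <- (1 - B_hat) * exp(-k_hat * df$time_s) + B_hat * exp(-kp_hat * df$time_s)
  rss <- sum((df$survival - pred)^2)
  tss <- sum((df$survival - mean(df$survival))^2)
  structure(
    list(A = 1 - B_hat, B = B_hat, k = k_hat, kp = kp_hat, t_r = 1 / k_hat,
         kp_mode = if (kp_free) "free" else "fixed",
         n_events = n_events, rss = rss,
         r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
         curve = dplyr::mutate(df, fitted = pred)),
    class = "survival_fit"
  )
}

#' @export
print.survival_fit <- function(x, ...) {
  cat(sprintf("<survival_fit> t_r = %.3g s (k = %.4g 1/s), B = %.3f, kp = %.4g 1/s [%s]\n",
              x$t_r, x$k, x$B, x$kp, x$kp_mode))
  invisible(x)
}

#' Calibrate the photobleaching rate from an immobilised control
#'
#' Single-exponential fit `S(t) = C * exp(-kp * t)` to the survival curve of
#' a control acquisition of immobilised fluorophores, whose only loss channel
#' is photobleaching. A fit with `R^2 < 0.9` triggers a warning (e.g. a
#' contaminated, multi-rate control).
#'
#' @param x A `residence_set` or a data frame with `time_s`, `survival`.
#' @return A `bleach_calibration`: list with `kp` (1/s), `timescale_s`
#'   (`1/kp`), `r_squared` (computed on log survival, where departures from
#'   a single rate appear as curvature) and the fitted curve.
#' @export
calibrate_photobleaching <- function(x) {
  df <- as_survival_df(x)
  m <- sum(df$survival) * mean(diff(df$time_s))
  k0 <- if (m > 0) 1 / m else 1
  fit <- minpack.lm::nlsLM(
    survival ~ C * exp(-kp * time_s), data = df,
    start = list(C = 1, kp = k0),
    lower = c(C = 1e-6, kp = 1e-8),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  cf <- coef(fit)
  pred <- cf["C"] * exp(-cf["kp"] * df$time_s)
  ## fit quality judged on log survival, where a second rate shows up as
  ## curvature instead of hiding under the early-time decay
  pos <- df$survival > 0 & pred > 0
  ls <- log(df$survival[pos]); lp <- log(pred[pos])
  tss <- sum((ls - mean(ls))^2)
  r2 <- if (tss > 0) 1 - sum((ls - lp)^2) / tss else NA_real_
  if (!is.na(r2) && r2 < 0.9)
    warn(sprintf("Single-exponential bleach fit is poor (R^2 = %.3f); control may contain multiple rates.", r2))
  structure(
    list(kp = unname(cf["kp"]), timescale_s = 1 / unname(cf["kp"]),
         r_squared = r2, curve = dplyr::mutate(df, fitted = pred)),
    class = "bleach_calibration"
  )
}

#' @export
print.bleach_calibration <- function(x, ...) {
  cat(sprintf("<bleach_calibration> kp = %.4g 1/s (timescale %.3g s), R^2 = %.3f\n",
              x$kp, x$timescale_s, x$r_squared))
  invisible(x)
}
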