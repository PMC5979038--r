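test_that("a symmetric noiseless spot is localised exactly at its pixel", {
  m <- spot_frame(x0 = 16, y0 = 16, noise_sd = 0)
  sp <- detect_spots(m, threshold = 5)
  expect_equal(nrow(sp), 1L)
  expect_equal(sp$x, 16, tolerance = 1e-6)
  expect_equal(sp$y, 16, tolerance = 1e-6)
})

test_that("subpixel localisation error stays below 0.15 px at SNR 5", {
  ex <- ey <- numeric(0)
  for (s in 1:100) {
    m <- spot_frame(x0 = 10.3, y0 = 7.6, amplitude = 50, noise_sd = 10,
                    seed = s)
    sp <- detect_spots(m, threshold = 10)
    sp <- sp[which.max(sp$brightness), ]
    ex <- c(ex, sp$x - 10.3); ey <- c(ey, sp$y - 7.6)
  }
  expect_equal(length(ex), 100L)
  expect_lt(mean(abs(ex)), 0.15)
  expect_lt(mean(abs(ey)), 0.15)
})

test_that("detection recall reaches 0.95 for a 50-spot field at SNR 2", {
  set.seed(42)
  n <- 128
  xs <- runif(50, 8, n - 8); ys <- runif(50, 8, n - 8)
  ## keep spots separated so ground truth is unambiguous
  keep <- rep(TRUE, 50)
  for (i in 2:50) {
    if (min(sqrt((xs[i] - xs[1:(i - 1)])^2 +
                   (ys[i] - ys[1:(i - 1)])^2)) < 8) keep[i] <- FALSE
  }
  m <- matrix(50, n, n)
  for (i in which(keep)) {
    m <- m + 20 * exp(-(outer((1:n - ys[i])^2, (1:n - xs[i])^2, "+")) /
                        (2 * 1.3^2))
  }
  m <- m + rnorm(n * n, sd = 10)
  sp <- detect_spots(matrix(m, n, n), threshold = 7)
  hits <- vapply(which(keep), function(i)
    any(sqrt((sp$x - xs[i])^2 + (sp$y - ys[i])^2) < 2), logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("one immobile molecule yields one track with the right residence", {
  spots <- tibble::tibble(frame = 3:12, x = 20 + rnorm(10, sd = 0.05),
                          y = 15 + rnorm(10, sd = 0.05), brightness = 100)
  linked <- link_tracks(spots, link_radius = 10)
  expect_equal(length(unique(linked$track_id)), 1L)
  tr <- track_summary(linked, n_movie_frames = 50, frame_interval = 2)
  expect_equal(tr$n_frames, 10L)
  expect_equal(tr$residence_s, 9 * 2)
  expect_false(tr$censored)
})

test_that("well-separated molecules are never merged", {
  spots <- dplyr::bind_rows(
    tibble::tibble(frame = 1:8, x = 10, y = 10, brightness = 1),
    tibble::tibble(frame = 1:8, x = 40, y = 10, brightness = 1))
  linked <- link_tracks(spots, link_radius = 10)
  expect_equal(length(unique(linked$track_id)), 2L)
  by_track <- split(linked$x, linked$track_id)
  expect_true(all(vapply(by_track, function(x) length(unique(x)) == 1,
                         logical(1))))
})

test_that("tracking a simulated sparse field recovers ground-truth dwells", {
  ## sparse enough that a 10-px link radius rarely bridges the death of one
  ## molecule and the birth of a neighbour in consecutive frames
  cfg <- sm_sim_config(field_size = 128, n_frames = 500,
                       appearance_rate = 0.15, seed = 9)
  sim <- simulate_sm_movie(cfg)
  spots <- detect_spots(sim$movie, threshold = 10)
  linked <- link_tracks(spots, link_radius = 10)
  tracks <- track_summary(linked, cfg$n_frames, cfg$frame_interval)
  truth <- discretize_dwells(sim$events, cfg$frame_interval, cfg$n_frames)
  truth <- truth[truth$n_frames >= 2, ]
  matched <- vapply(seq_len(nrow(truth)), function(i) {
    cand <- tracks[sqrt((tracks$x - truth$x_px[i])^2 +
                          (tracks$y - truth$y_px[i])^2) < 2, ]
    any(abs(cand$n_frames - truth$n_frames[i]) <= 1 &
          abs(cand$start_frame - truth$first_frame[i]) <= 1)
  }, logical(1))
  expect_gte(mean(matched), 0.95)
})

test_that("the residence collection applies the two-frame exclusion rule", {
  tracks <- tibble::tibble(
    track_id = 1:3, start_frame = c(5, 10, 20), end_frame = c(5, 11, 24),
    n_frames = c(1L, 2L, 5L), x = 0, y = 0,
    residence_s = c(0, 1, 4), censored = FALSE)
  rs <- collect_residences(tracks, frame_interval = 1)
  expect_equal(rs$n_events, 2L)
  expect_setequal(rs$residence_s, c(1, 4))
  expect_equal(rs$n_excluded_short, 1L)

  all_censored <- dplyr::mutate(tracks, censored = TRUE)
  expect_error(collect_residences(all_censored, 1), "no usable events")
})

test_that("the survival fit recovers exact model curves to tolerance", {
  ## generating parameters (B = 0.22, k = 0.087, kp = 0.031)
  df <- model_survival(k = 0.087, kp = 0.031, B = 0.22)
  fit <- fit_survival(df, kp = 0.031)
  expect_equal(fit$k, 0.087, tolerance = 1e-4)
  expect_equal(fit$B, 0.22, tolerance = 1e-3)
  expect_equal(fit$A + fit$B, 1)
  expect_equal(fit$t_r, 1 / 0.087, tolerance = 1e-4)

  free <- fit_survival(df, kp = "free")
  expect_equal(free$k, 0.087, tolerance = 1e-3)
  expect_equal(free$kp, 0.031, tolerance = 1e-2)
})

test_that("survival fits recover simulated mixtures within 10 percent", {
  fit <- residence_harness(k_true = 1 / 11.5, frame_interval = 1,
                           n_events = 5000, seed = 11)
  expect_lt(abs(fit$t_r - 11.5) / 11.5, 0.10)
  expect_gte(fit$B, 0.2); expect_lte(fit$B, 0.25)
})

test_that("the empirical survival curve is monotone and starts at 1", {
  fit <- residence_harness(k_true = 1 / 8, frame_interval = 1,
                           n_events = 800, seed = 12)
  S <- fit$curve$survival
  expect_equal(S[1], 1)
  expect_true(all(diff(S) <= 0))
  ## model S(0) = A + B = 1 by construction
  expect_equal(fit$curve$fitted[1], 1, tolerance = 1e-9)
})

test_that("single-exponential data reproduce the closed-form mean dwell", {
  ## kp = k and B pinned: the model collapses to exp(-k t); compare with
  ## the exponential MLE (the sample mean of the true dwells)
  k <- 1 / 10
  set.seed(21)
  dwells <- rexp(8000, k)
  ev <- tibble::tibble(event_id = seq_along(dwells),
                       birth_time_s = runif(8000, 0, 4000),
                       dwell_s = dwells, cause = "unbind", x_px = 0, y_px = 0)
  obs <- discretize_dwells(ev, frame_interval = 0.5, n_frames = 9000)
  rs <- collect_residences(obs, 0.5)
  fit <- fit_survival(rs, kp = k, b_bounds = c(0.2, 0.25))
  expect_lt(abs(fit$t_r - mean(dwells)) / mean(dwells), 0.05)
})

test_that("the exclusion rule biases the naive mean but not the fitted rate", {
  k <- 0.2
  set.seed(22)
  dwells <- rexp(6000, k)
  ev <- tibble::tibble(event_id = seq_along(dwells),
                       birth_time_s = runif(6000, 0, 30000),
                       dwell_s = dwells, cause = "unbind", x_px = 0, y_px = 0)
  obs <- discretize_dwells(ev, frame_interval = 1, n_frames = 40000)
  rs <- collect_residences(obs, 1)
  expect_gt(mean(rs$residence_s), 1 / k)  # naive mean biased upward
  fit <- fit_survival(rs, kp = k)         # degenerate kp = k: single exp
  expect_lt(abs(fit$k - k) / k, 0.10)     # fitted rate stays consistent
})

test_that("fits at 1 and 3 frames per second agree for slow unbinding", {
  f1 <- residence_harness(k_true = 1 / 15, frame_interval = 1,
                          n_events = 4000, seed = 13)
  f3 <- residence_harness(k_true = 1 / 15, frame_interval = 1 / 3,
                          n_events = 4000, seed = 14)
  expect_lt(abs(f1$t_r - f3$t_r) / f3$t_r, 0.10)
})

test_that("photobleaching calibration recovers the control rate", {
  df <- model_survival(k = 0.031, kp = 0.031, B = 0.2, t_max = 200)
  cal <- calibrate_photobleaching(df)
  expect_equal(cal$kp, 0.031, tolerance = 1e-6)
  expect_equal(cal$timescale_s, 1 / 0.031, tolerance = 1e-4)

  ## simulated immobilised control, bleaching only
  cfg <- sm_sim_config(unbind_rate = 0, bleach_rate = 0.031,
                       bleach_fraction = 1, frame_interval = 1,
                       n_frames = 3000, seed = 15)
  ev <- simulate_dwell_events(cfg, n_events = 3000)
  rs <- collect_residences(discretize_dwells(ev, 1, 3000), 1)
  cal2 <- calibrate_photobleaching(rs)
  expect_lt(abs(cal2$kp - 0.031) / 0.031, 0.10)

  ## contaminated two-rate control triggers the quality warning
  t <- seq(0, 60, by = 1)
  bad <- tibble::tibble(time_s = t,
                        survival = 0.6 * exp(-0.12 * t) + 0.4 * exp(-0.01 * t))
  expect_warning(calibrate_photobleaching(bad), "poor")
})

test_that("degenerate free-kp fits warn about the collapsed mixture", {
  cfg <- sm_sim_config(unbind_rate = 1 / 10, bleach_rate = 1 / 10,
                       bleach_fraction = 0.2, n_frames = 5000, seed = 2)
  ev <- simulate_dwell_events(cfg, n_events = 3000)
  rs <- collect_residences(discretize_dwells(ev, 1, 5000), 1)
  expect_warning(fit_survival(rs, kp = "free"), "degenerate")
})

test_that("small samples trigger the low-event warning", {
  set.seed(30)
  ev <- tibble::tibble(event_id = 1:50, birth_time_s = runif(50, 0, 500),
                       dwell_s = rexp(50, 0.1), cause = "unbind",
                       x_px = 0, y_px = 0)
  rs <- collect_residences(discretize_dwells(ev, 1, 1000), 1)
  expect_warning(fit_survival(rs, kp = 0.031), "events")
})
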