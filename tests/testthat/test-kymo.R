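test_that("preprocess is the identity for filter size 1 without drift", {
  sim <- simulate_ring_movie(ring_sim_config(n_frames = 3, seed = 1))
  out <- preprocess(sim$movie, mean_filter_size = 1, drift = FALSE)
  expect_equal(out$data, sim$movie$data)
  expect_error(preprocess(sim$movie, mean_filter_size = 2), "odd")
})

test_that("mean filtering leaves constant frames unchanged", {
  mov <- movie(array(7, dim = c(3, 16, 16)), 0.042, 3)
  out <- preprocess(mov, mean_filter_size = 5)
  expect_equal(out$data, mov$data, tolerance = 1e-12)
})

test_that("drift correction recovers an injected whole-frame shift", {
  sim <- simulate_ring_movie(ring_sim_config(n_frames = 6, seed = 2),
                             noise = FALSE)
  arr <- sim$movie$data
  ## translate the last three frames by (dx = 3, dy = -2)
  for (f in 4:6) {
    m <- arr[f, , ]
    shifted <- matrix(median(m), nrow(m), ncol(m))
    shifted[1:(nrow(m) - 2), 4:ncol(m)] <- m[3:nrow(m), 1:(ncol(m) - 3)]
    arr[f, , ] <- shifted
  }
  out <- preprocess(movie(arr, 0.042, 3), mean_filter_size = 1, drift = TRUE)
  shifts <- attr(out, "drift")
  expect_equal(shifts$dx[4:6], rep(-3, 3))
  expect_equal(shifts$dy[4:6], rep(2, 3))
  ## correction restores the original (pre-injection) frames in the core
  core <- 10:38
  expect_equal(out$data[5, core, core],
               sim$movie$data[5, core, core], tolerance = 1e-10)
})

test_that("fit_ring recovers a synthetic ring within half a pixel", {
  sim <- simulate_ring_movie(ring_sim_config(n_frames = 4, seed = 3),
                             noise = FALSE)
  tr <- sim$truth
  roi <- fit_ring(sim$movie, c(tr$cx - tr$r_px, tr$cy),
                  c(tr$cx + tr$r_px, tr$cy))
  expect_lt(abs(roi$r_px - tr$r_px), 0.5)
  expect_lt(abs(roi$cx - tr$cx), 0.5)
  expect_lt(abs(roi$cy - tr$cy), 0.5)

  ## off-centre seeds still land on the ring
  roi2 <- fit_ring(sim$movie, c(tr$cx - tr$r_px + 1.5, tr$cy + 1),
                   c(tr$cx + tr$r_px + 1.5, tr$cy - 1))
  expect_lt(abs(roi2$r_px - tr$r_px), 0.7)
})

test_that("degenerate and featureless ring fits are flagged", {
  sim <- simulate_ring_movie(ring_sim_config(n_frames = 3, seed = 4))
  expect_error(fit_ring(sim$movie, c(10, 10), c(10, 10)), "identical")
  flat <- movie(array(5, dim = c(2, 48, 48)), 0.042, 3)
  roi <- fit_ring(flat, c(12, 24), c(36, 24))
  expect_false(roi$refined)
})

test_that("a static ring yields time-invariant kymograph columns", {
  sim <- simulate_ring_movie(ring_sim_config(linear_speed = 0, n_frames = 5),
                             noise = FALSE)
  tr <- sim$truth
  kym <- extract_kymograph(sim$movie,
                           list(cx = tr$cx, cy = tr$cy, r_px = tr$r_px))
  for (j in 2:5) expect_equal(kym$values[, j], kym$values[, 1])
  expect_equal(nrow(kym$values), round(2 * pi * tr$r_px))
})

test_that("rotation shifts the kymograph by the expected arc samples", {
  ## one filament rotating at a known rate: the angular profile at frame f
  ## is the frame-1 profile circularly shifted by omega * dt * f in samples
  cfg <- ring_sim_config(linear_speed = 55, frame_interval = 3, n_frames = 12,
                         n_filaments = 1, filament_length = 250)
  sim <- simulate_ring_movie(cfg, noise = FALSE)
  tr <- sim$truth
  kym <- extract_kymograph(sim$movie,
                           list(cx = tr$cx, cy = tr$cy, r_px = tr$r_px))
  n_arc <- nrow(kym$values)
  step_samples <- tr$omega_rad_s * 3 / (2 * pi) * n_arc
  for (f in c(4, 9)) {
    shift <- round(step_samples * (f - 1)) %% n_arc
    ## profile at frame f equals the frame-1 profile advanced by `shift`
    idx <- ((seq_len(n_arc) - 1 - shift) %% n_arc) + 1
    expect_gt(cor(kym$values[, f], kym$values[idx, 1]), 0.98)
  }
})

test_that("a rotating ring's kymograph is periodic with the rotation period", {
  ## 30-frame rotation period: omega = 2 pi / 90 s at 3-s frames
  r_um <- 0.25
  v <- 2 * pi / 90 * r_um * 1000
  cfg <- ring_sim_config(ring_radius = r_um, linear_speed = v,
                         frame_interval = 3, n_frames = 40, n_filaments = 1,
                         filament_length = 200)
  sim <- simulate_ring_movie(cfg, noise = FALSE)
  tr <- sim$truth
  kym <- extract_kymograph(sim$movie,
                           list(cx = tr$cx, cy = tr$cy, r_px = tr$r_px))
  expect_gt(cor(kym$values[, 1], kym$values[, 31]), 0.999)
  expect_lt(cor(kym$values[, 1], kym$values[, 16]), 0.5)
})

test_that("circles touching the border are refused", {
  sim <- simulate_ring_movie(ring_sim_config(n_frames = 3))
  expect_error(
    extract_kymograph(sim$movie, list(cx = 5, cy = 24, r_px = 8)),
    "border")
})

test_that("a constructed travelling wave is recovered exactly", {
  f_true <- 0.02; q_true <- 0.25
  dt <- 3; n_t <- 100; n_arc <- 75
  s <- seq_len(n_arc); t <- (seq_len(n_t) - 1) * dt
  vals <- outer(s, t, function(s, t) cos(2 * pi * f_true * t - q_true * s))
  kym <- structure(list(values = vals, arc_step = 42, frame_interval = dt,
                        roi = list(cx = 0, cy = 0, r_px = n_arc / (2 * pi))),
                   class = "kymograph")
  res <- estimate_slope(kym)
  expect_true(res$accepted)
  expect_equal(res$f_star_hz, f_true, tolerance = 1e-9)
  expect_equal(res$q_rad_per_sample, q_true, tolerance = 0.02)
  expect_equal(res$v_nm_s, 2 * pi * f_true / q_true * 42, tolerance = 0.03)
  expect_identical(res$chirality, "clockwise")

  ## time reversal flips chirality, |v| unchanged
  kym_rev <- kym
  kym_rev$values <- vals[, n_t:1]
  res_rev <- estimate_slope(kym_rev)
  expect_identical(res_rev$chirality, "counterclockwise")
  expect_equal(res_rev$v_nm_s, res$v_nm_s, tolerance = 0.02)
})

test_that("static and all-zero kymographs are rejected by the quality gates", {
  n_arc <- 75; n_t <- 60
  static <- structure(
    list(values = matrix(rep(runif(n_arc), n_t), n_arc, n_t),
         arc_step = 42, frame_interval = 3,
         roi = list(cx = 0, cy = 0, r_px = 12)),
    class = "kymograph")
  res <- estimate_slope(static)
  expect_false(res$accepted)
  expect_identical(res$chirality, "static/rejected")

  zero <- static
  zero$values <- matrix(0, n_arc, n_t)
  res0 <- estimate_slope(zero)
  expect_false(res0$accepted)
  expect_equal(res0$peak_ratio, 0)
})

test_that("accepted results satisfy v = 2 pi f* / |q| * arc_step exactly", {
  sim <- simulate_ring_movie(ring_sim_config(linear_speed = 34, seed = 6))
  res <- measure_ring_velocities(sim$movie, seeds_for(sim))
  expect_true(res$accepted)
  expect_equal(res$v_nm_s,
               2 * pi * res$f_star_hz / abs(res$q_rad_per_sample) * 42,
               tolerance = 1e-12)
})

test_that("mirroring a movie flips the recovered chirality, not the speed", {
  sim <- simulate_ring_movie(ring_sim_config(linear_speed = 34, seed = 8))
  res <- measure_ring_velocities(sim$movie, seeds_for(sim))
  flipped_data <- sim$movie$data[, , rev(seq_len(dim(sim$movie$data)[3]))]
  mirrored <- movie(flipped_data, sim$movie$pixel_size,
                    sim$movie$frame_interval)
  n <- dim(flipped_data)[3]
  seeds_m <- seeds_for(sim)
  seeds_m$x1 <- n + 1 - seeds_m$x1
  seeds_m$x2 <- n + 1 - seeds_m$x2
  res_m <- measure_ring_velocities(mirrored, seeds_m)
  expect_true(res$accepted && res_m$accepted)
  expect_identical(res$chirality, "clockwise")
  expect_identical(res_m$chirality, "counterclockwise")
  expect_equal(res_m$v_nm_s, res$v_nm_s, tolerance = 0.05)
})
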