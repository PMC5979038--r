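## Shared fixtures, all generated in code.

## Seed-pair table pointing at a simulated ring's true diameter endpoints.
seeds_for <- function(sim) {
  tr <- sim$truth
  tibble::tibble(ring_id = 1L,
                 x1 = tr$cx - tr$r_px, y1 = tr$cy,
                 x2 = tr$cx + tr$r_px, y2 = tr$cy)
}

## Exact survival curve of the double-exponential model on a frame lattice.
model_survival <- function(k, kp, B, dt = 1, t_max = 120) {
  t <- seq(0, t_max, by = dt)
  tibble::tibble(time_s = t,
                 survival = (1 - B) * exp(-k * t) + B * exp(-kp * t))
}

## Single Gaussian spot on a constant baseline, optional noise.
spot_frame <- function(n = 32, x0 = 16, y0 = 16, amplitude = 50,
                       psf_sigma = 1.3, baseline = 50, noise_sd = 0,
                       seed = NULL) {
  m <- baseline + amplitude *
    exp(-(outer((1:n - y0)^2, (1:n - x0)^2, "+")) / (2 * psf_sigma^2))
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    m <- m + rnorm(n * n, sd = noise_sd)
  }
  matrix(m, n, n)
}

## Event-level residence-time recovery harness: true dwells -> frame
## sampling -> exclusion rule -> constrained survival fit.
residence_harness <- function(k_true, frame_interval, n_events = 5000,
                              seed = 11, kp = 0.031, B = 0.22,
                              duration_frames = 20000) {
  cfg <- sm_sim_config(frame_interval = frame_interval,
                       n_frames = duration_frames,
                       unbind_rate = k_true, bleach_rate = kp,
                       bleach_fraction = B, seed = seed)
  ev <- simulate_dwell_events(cfg, n_events = n_events)
  obs <- discretize_dwells(ev, frame_interval, duration_frames)
  rs <- collect_residences(obs, frame_interval)
  fit_survival(rs, kp = kp)
}
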