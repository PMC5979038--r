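# ztread

Quantitative analysis of treadmilling dynamics in ring-shaped cytoskeletal
polymers imaged by TIRF microscopy.

FtsZ, the tubulin homologue that organises bacterial cell division, forms
dynamic rings on supported lipid bilayers when given a membrane anchor, GTP
and Mg²⁺. The rings do not rotate as rigid bodies: filaments treadmill —
subunits add at the leading edge and leave at the trailing edge — so the
intensity pattern travels around the circumference at tens of nm/s with a
defined chirality, while single molecules stay put and turn over within
seconds. `ztread` implements the two measurements that characterise this
system, plus the synthetic-data generators needed to validate them against
known ground truth:

* **Ring velocity and chirality from circular kymographs.** Around a
  user-seeded, circle-fitted ring ROI, intensity is sampled on three
  concentric circles (radii *r − 1*, *r*, *r + 1* px) and averaged into an
  arc-position × time kymograph. A travelling pattern
  *I(s, t) ≈ G(qs − 2πf\*t)* appears as tilted stripes: the temporal FFT per
  arc row has a peak at the characteristic frequency *f\**, and the phase at
  *f\** grows linearly with arc position with slope *q* (rad/sample). The
  speed is

  *v = 2π f\* / |q| · Δs*  (nm/s),

  with Δs the arc step, and the sign of *q* gives the rotation sense.
  Estimates are accepted only when the spectral peak is ≥ 10× the mean
  magnitude and the phase fit has *R² ≥ 0.95*; static rings fail these gates.

* **Single-molecule residence times with photobleaching correction.**
  Spots are detected by difference-of-Gaussians bandpass and localised by
  iterative brightness-weighted centroid, linked across consecutive frames
  within a 10 px radius, and tracks shorter than 2 frames are excluded. The
  survival function of the residence times is fitted with the constrained
  double exponential

  *S(t) = A e^(−kt) + B e^(−k_p t)*,  *A = 1 − B*, *B ∈ [0.2, 0.25]*,

  where *k_p* is the photobleaching rate (fixed to an independently
  calibrated 0.031 s⁻¹ by default) and *t_r = 1/k* is the mean residence
  time freed of bleaching.

Derived quantities connect the two measurements: the mean treadmilling
filament length *⟨l⟩ = v · t_r* (and its monomer count at 5 nm/monomer),
linear ↔ angular speed conversion, surface-density regime classification
and adsorption-trace synchronisation.

## Worked example

Simulate a treadmilling ring with known ground truth and measure it back:

```r
library(ztread)

cfg <- ring_sim_config(ring_radius = 0.5, linear_speed = 34,
                       frame_interval = 3, n_frames = 100, seed = 3)
sim <- simulate_ring_movie(cfg)
seeds <- tibble::tibble(ring_id = 1,
                        x1 = sim$truth$cx - sim$truth$r_px, y1 = sim$truth$cy,
                        x2 = sim$truth$cx + sim$truth$r_px, y2 = sim$truth$cy)
measure_ring_velocities(sim$movie, seeds)
#> # A tibble: 1 × 15
#>   ring_id    cx    cy  r_px note  f_star_hz q_rad_per_sample r_squared
#>     <dbl> <dbl> <dbl> <dbl> <chr>     <dbl>            <dbl>     <dbl>
#> 1       1  24.4  24.5  11.7 NA       0.0333            0.254      1.00
#> # ... v_nm_s 34.6, omega_deg_s 4.02, chirality "clockwise", accepted TRUE
```

The 34 nm/s ground truth is recovered as 34.6 nm/s (4.0°/s at this radius),
called clockwise, and accepted by both quality gates. A static ring
(`linear_speed = 0`) is rejected with `chirality = "static/rejected"`.

Residence times from simulated disappearance events:

```r
cfg <- sm_sim_config(unbind_rate = 1 / 11.5, bleach_rate = 0.031,
                     bleach_fraction = 0.22, frame_interval = 1,
                     n_frames = 20000, seed = 11)
ev  <- simulate_dwell_events(cfg, n_events = 5000)
obs <- discretize_dwells(ev, 1, 20000)
rs  <- collect_residences(obs, 1)
fit <- fit_survival(rs, kp = 0.031)
fit
#> <survival_fit> t_r = 11.6 s (k = 0.08613 1/s), B = 0.213, kp = 0.031 1/s [fixed]
generics::glance(fit)
filament_length(34, fit$t_r)   # mean filament length, nm and monomers
```

The generating mean residence time of 11.5 s is recovered within 1%
despite the 2-frame exclusion rule and the bleaching admixture.
`autoplot(fit)` shows the empirical and fitted survival curves;
`autoplot()` on a kymograph and `plot_velocity_population()` cover the
other result types.

Batch processing of movies on disk goes through `run_simulate()`,
`run_velocity()` and `run_residence()` (TIFF + seed CSV in, CSV/JSON out,
with a reproducibility manifest), or the thin CLI wrapper in
`inst/cli/ztread.R`.

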