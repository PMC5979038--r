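---
title: "Methods: quantifying treadmilling rings and single-molecule turnover"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying treadmilling rings and single-molecule turnover}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ztread)
```

## The system and the two measurements

Membrane-targeted FtsZ polymerises on supported lipid bilayers into
ring-shaped structures about 1 µm across. The rings are built from curved,
polar filaments that treadmill: GTP-loaded subunits add at the leading end
while GDP-loaded subunits dissociate at the trailing end, so the intensity
pattern travels along the circumference although no subunit moves. Two
complementary observables characterise the dynamics:

1. the **speed and rotation sense (chirality)** of the travelling pattern,
   measured on the ring as a whole, and
2. the **residence time of single subunits** on the membrane, measured by
   sparse labelling, which sets the turnover rate of the filament ends.

Their product `v * t_r` estimates the mean treadmilling filament length:
the distance the growing tip advances during the lifetime of one subunit.

## Velocity from the Fourier phase of a circular kymograph

A ring is specified by two user-supplied seed points; the circle with the
seed segment as diameter is refined by maximising the mean time-averaged
intensity on the circle over centre and radius within ±5 px (`fit_ring()`).
If the optimiser finds no improvement, or runs to the edge of the search
box, the initial circle is returned with a `not refined` flag rather than
an extrapolated one.

`extract_kymograph()` samples each frame by bilinear interpolation at
`round(2*pi*r)` equally spaced angles on the circles of radius `r - 1`,
`r`, `r + 1` px and averages the three profiles. One arc sample therefore
corresponds to about one pixel of arc, and the arc step in physical units
is the pixel size. Averaging three concentric circles suppresses
single-pixel noise without blurring the angular structure.

For a pattern travelling at angular rate `omega`, the kymograph is
`I(s, t) = G(s*dtheta - omega*t)`: every temporal frequency `k*omega/(2*pi)`
present in the profile `G` carries a phase that is **linear in arc
position** with slope `k*dtheta`. `estimate_slope()` exploits this:

* Savitzky–Golay smoothing (order 2, window 7) is applied **along the arc
  dimension**. Smoothing along time would act as a low-pass filter on
  exactly the axis that carries the signal: at 3-s frames a 7-point
  temporal window attenuates a 0.1 Hz pattern (the fast, FtsA-anchored
  regime) below the spectral quality gate, while arc-direction smoothing
  removes shot noise and leaves all temporal frequencies untouched.
* CLAHE (8×8 tiles, clip limit 2 in the EBImage parameterisation)
  equalises slow intensity gradients around the ring so that bright
  segments do not dominate the spectrum.
* The arc dimension is tiled into blocks of 50 samples; when the ring is
  too small to supply two full blocks (a 0.5 µm ring has ~75 samples) a
  single block spanning all rows is used. Tiling, rather than a sliding
  window, keeps the per-block statistics independent.
* Per block, the temporal FFT is taken per arc row and the characteristic
  frequency `f*` is the non-DC bin, up to 0.8× Nyquist, maximising the
  mean magnitude. The top fifth of the band is excluded because a
  travelling pattern sampled that close to Nyquist is not resolvable and
  the bins there carry only frame-to-frame flicker; capping at half
  Nyquist instead would discard the legitimate spectral line of fast
  rings (0.103 Hz at 3-s frames).
* The FFT phase at `f*` is unwrapped along arc position (standard 2π jump
  correction) and fitted by least squares; the slope `q` (rad/sample) and
  its `R²` are recorded. The phase is taken in the travelling-wave sign
  convention, so a pattern advancing towards larger arc index — clockwise
  in displayed-image coordinates, where the row index grows downwards —
  has `q > 0`.
* **Quality gates**: a block is accepted only if the spectral peak is at
  least 10× the mean non-DC magnitude and `R² >= 0.95`. Static rings and
  pure noise fail the peak gate; disordered phase fails the `R²` gate. An
  all-zero kymograph reports `peak_ratio = 0` and is rejected.
* Ring-level `f*` and `|q|` are peak-ratio-weighted means over accepted
  blocks, and the speed is *defined* as `v = 2*pi*f*/|q| * arc_step`, so
  the internal consistency identity holds exactly. Chirality comes from
  the weighted sign of `q`; ties fall back to the strongest block.

Drift correction (optional in `preprocess()`) estimates integer-pixel
shifts by phase correlation of Hann-windowed consecutive frames and
accumulates them, which stays robust when the scene itself evolves slowly;
shifts above 25% of the frame are applied but flagged with a warning.

## Residence times from constrained double-exponential survival fits

`detect_spots()` band-passes each frame with a difference of Gaussians
(sigmas 1 and 3 px), takes local maxima above a threshold, and refines each
position with a brightness-weighted centroid over a radius-3 window. The
centroid iterates with a Gaussian mask (sd 1.6 px) re-centred on the
current estimate; the mask suppresses window-edge noise and truncation
bias, bringing the per-coordinate error at SNR 5 below 0.15 px while
remaining a plain weighted-mean position estimate. The detection threshold
is user-set (as in the original routine); when omitted it defaults to five
times the robust noise scale of the band-passed first frame.

`link_tracks()` performs greedy nearest-neighbour assignment between
consecutive frames: candidate pairs within the 10 px link radius are
matched closest-first, each spot used once. At single-molecule densities
greedy and globally optimal matching coincide; the option `gap_frames`
exists but defaults to 0 (strict consecutive linking). A track's residence
time is `(n_frames - 1) * frame_interval`, events detected in fewer than 2
frames are excluded as below the method's accuracy, and tracks touching
the first or last movie frame are censored and dropped by default since
their dwell is only partially observed.

The empirical survival function `S(t)` (fraction of residences longer than
`t`, evaluated at frame multiples) is fitted with
`S(t) = A*exp(-k*t) + B*exp(-kp*t)`. Design choices:

* **Survival, not the rising cumulative curve.** A sum of decaying
  exponentials can only describe the complement of the CDF; fitting
  `1 - CDF` matches the stated functional form without an ad-hoc offset.
* **`A = 1 - B`.** `S(0) = 1` for any probability model; constraining only
  `B ∈ [0.2, 0.25]` (the photobleaching contribution) then fixes `A`.
* **`kp` fixed by default** to 0.031 s⁻¹, the value calibrated from
  immobilised fluorophores whose only loss channel is bleaching
  (`calibrate_photobleaching()`, a free-amplitude single-exponential fit
  whose quality is judged on *log* survival so that a second rate shows up
  as curvature; `R² < 0.9` warns of a contaminated control). `kp = "free"`
  co-fits it, and warns when `kp → k` (degenerate mixture).
* The least squares problem is solved by Levenberg–Marquardt with box
  constraints, with a direct bounded quasi-Newton minimisation as a
  fallback and cross-check; the better residual wins. This covers the
  degenerate single-exponential corner where the LM Jacobian is singular.

The frame-sampling of dwells is worth noting: for exponential dwells the
lattice-sampled survival is exactly proportional to `exp(-k * t)` at frame
multiples, so the `< 2`-frame exclusion biases the naive sample mean
upward but leaves the fitted `k` consistent — the package's tests assert
both halves of this statement.

## The synthetic-data generators

The generators are first-class, seeded, and return full ground truth; they
define the conditions under which the estimators are validated.

**Ring movies** (`simulate_ring_movie()`): `n_filaments` arcs of uniform
linear density (1 px wide before blurring) advance along the circle by
`linear_speed * frame_interval` per frame. Filament start angles are
equally spaced and symmetric about π/2, so negating the speed mirrors the
noiseless movie exactly and the pattern power concentrates in a single
sharp spectral line, as in experimental kymographs. Density is deposited
with bilinear splatting (exactly mirror-symmetric), PSF-blurred, scaled,
Poisson-sampled and perturbed with Gaussian read noise. Defaults are the
acquisition settings of the system being emulated: 0.042 µm pixels, 3-s
frames, 0.5 µm radius, three 390 nm filaments, and noise levels giving a
peak SNR near 3 (`ring_snr()` reports it). Peak SNR is defined as the
filament amplitude above background over the noise sd at the peak
(`sqrt(background + peak + read_noise_sd²)`).

**Single-molecule movies** (`simulate_sm_movie()`): molecules appear as a
homogeneous Poisson process, sit immobile at subpixel positions, and
disappear after an exponential dwell. Disappearance is a **two-population
mixture** — a fraction `B` is bleach-limited (`Exponential(kp)`), the rest
unbinding-limited (`Exponential(k)`) — matching the fitted sum of
exponentials; a competing-risks mode (`mode = "competing"`, every molecule
racing both clocks) is available for sensitivity analysis. Molecules are
immobile so that the 10-px link radius is tested against localisation
noise only; diffusion is out of scope. `discretize_dwells()` converts
ground-truth dwells into what an ideal tracker would record, which lets
parameter-recovery studies run at large N without rendering movies.

**Adsorption traces** (`simulate_adsorption_trace()`): a linear ramp
saturating at a plateau with additive Gaussian noise — the minimal shape
against which the time-zero synchronisation rule (first crossing of
200 A.U., `synchronize_trace()`) is tested.

What the generators deliberately do **not** emulate: filament nucleation,
fragmentation and ring assembly; nematic bundling at high density; mobile
or blinking fluorophores; camera fixed-pattern noise; intensity
calibration drift. Passing the recovery tests therefore shows the
estimators are correct for movies obeying the stated model, not that real
acquisitions meet those assumptions.

## Derived metrics and conventions

* `angular_to_linear()` / `linear_to_angular()`: `v = omega * r`, exact in
  both directions (machine-precision involution).
* `filament_length()`: `l = v * t_r`, monomer count `round(l / 5 nm)`; the
  5 nm monomer length is exposed as a parameter.
* `classify_density()`: surface mean intensity below 450 A.U. is the
  low-density regime, 450–1000 A.U. (closed interval) the ring-forming
  regime, above 1000 A.U. the bundled regime. The A.U. scale is
  instrument-specific; the thresholds are configurable defaults meaningful
  under the emulated acquisition settings.
* `synchronize_trace()`: time zero is the first frame at or above
  200 A.U.; "around 200" is made exact at 200 and configurable.
* Intensity units are arbitrary throughout; TIFF IO stores 16-bit counts.

## Problem sizes and tolerances

The validation studies use: 120 rings (20 per speed × chirality condition
at 25/34/108 nm/s, SNR ≈ 3, 100 frames at 3 s) plus 20 static controls for
the velocity estimator — accepted rings show ~2% median speed error, 100%
correct chirality, and static rings are rejected by the gates; 5,000
simulated disappearance events per condition for the survival fit, which
recovers `t_r = 11.5 s` within 10% at 1 fps and `t_r = 1.72 s` within 15%
at 3 fps (the shorter dwell spans fewer frames, so its estimate is
noisier); 140 fitted rings for the diameter statistics; 100 seeded renders
for the localisation benchmark. These sizes give the Monte-Carlo error a
comfortable margin below the assertion tolerances while keeping the whole
suite inside a few minutes.

## Known limitations

* The velocity estimator assumes one dominant travelling pattern per ring;
  rings with mixed-chirality segments yield a weighted compromise, and
  overlapping rings should be seeded separately.
* Sub-integer drift is not corrected (integer-pixel phase correlation);
  at 0.042 µm pixels this bounds residual drift at ~21 nm, well below the
  arc step.
* Greedy linking merges a dying molecule with a neighbour born within the
  link radius on the next frame; at the sparse densities the assay is
  designed for this affects a few percent of tracks at most, but dense
  fields need a smaller radius or a global matcher.
* The survival fit conditions on detection in ≥ 2 frames; for dwells much
  shorter than the frame interval most events are never observed and the
  recovered `k` reflects only the observable tail.
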