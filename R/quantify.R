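#' Convert between linear and angular treadmilling speed
#'
#' Exact closed-form conversion `v = omega * r` with `omega` in rad/s.
#' At a 500 nm ring radius, 3.9 deg/s corresponds to 34 nm/s.
#'
#' @param omega_deg_s Angular speed, degrees/s.
#' @param v_nm_s Linear speed along the circumference, nm/s.
#' @param radius_nm Ring radius, nm (> 0).
#' @return The converted speed (nm/s or deg/s).
#' @export
#' @examples
#' angular_to_linear(3.9, 500)   # ~34 nm/s
#' linear_to_angular(34, 500)    # ~3.9 deg/s
angular_to_linear <- function(omega_deg_s, radius_nm) {
  if (any(radius_nm <= 0)) abort("`radius_nm` must be > 0.")
  omega_deg_s * pi / 180 * radius_nm
}

#' @rdname angular_to_linear
#' @export
linear_to_angular <- function(v_nm_s, radius_nm) {
  if (any(radius_nm <= 0)) abort("`radius_nm` must be > 0.")
  v_nm_s / radius_nm * 180 / pi
}

#' Mean treadmilling filament length from speed and residence time
#'
#' In steady-state treadmilling the mean filament length is the distance a
#' growing tip travels during one subunit's residence: `l = v * t_r`. The
#' monomer count is `round(l / monomer_length)` (5 nm per monomer by
#' default, so 34 nm/s x 11.5 s gives ~390 nm, 78 monomers).
#'
#' @param v_nm_s Treadmilling speed, nm/s (>= 0).
#' @param t_r_s Mean residence time, s (> 0).
#' @param monomer_length Monomer length, nm.
#' @return A one-row tibble: `length_nm`, `n_monomers`, `v_nm_s`, `t_r_s`,
#'   `monomer_length`.
#' @export
filament_length <- function(v_nm_s, t_r_s, monomer_length = 5) {
  if (any(v_nm_s < 0)) abort("`v_nm_s` must be >= 0.")
  if (any(t_r_s <= 0)) abort("`t_r_s` must be > 0.")
  l <- v_nm_s * t_r_s
  tibble(length_nm = l, n_monomers = round(l / monomer_length),
         v_nm_s = v_nm_s, t_r_s = t_r_s, monomer_length = monomer_length)
}

#' Classify the surface protein-density regime
#'
#' Surface mean intensity is a proxy for protein density on the bilayer.
#' Dynamic rings form in an intermediate regime; below it only transient
#' filaments are seen and above it filaments jam into static bundles.
#' Boundary values belong to the interval written `low_max`-`ring_max`:
#' intensity `>= low_max` and `<= ring_max` is ring-forming.
#'
#' @param mean_intensity Surface mean intensity, A.U. (vectorised, >= 0).
#' @param low_max Lower boundary of the ring-forming regime, A.U.
#' @param ring_max Upper boundary of the ring-forming regime, A.U.
#' @return A factor with levels `low`, `ring-forming`, `bundled`.
#' @export
#' @examples
#' classify_density(c(300, 880, 1500))
classify_density <- function(mean_intensity, low_max = 450, ring_max = 1000) {
  if (low_max >= ring_max) abort("`low_max` must be < `ring_max`.")
  if (any(mean_intensity < 0)) abort("Intensity must be >= 0.")
  cut(mean_intensity, breaks = c(-Inf, low_max, ring_max, Inf),
      labels = c("low", "ring-forming", "bundled"), right = FALSE) |>
    ## right = FALSE puts 450 in ring-forming; move 1000 back down
    (\(f) {
      f[mean_intensity == ring_max] <- "ring-forming"
      f
    })()
}

#' Synchronise a time-lapse to the adsorption threshold crossing
#'
#' Acquisitions are aligned by defining time zero as the first frame whose
#' surface mean intensity reaches `sync_threshold` (default 200 A.U.).
#'
#' @param trace A tibble with `intensity` (and optionally `time_s`), or a
#'   numeric vector of frame-mean intensities.
#' @param sync_threshold Intensity defining time zero, A.U.
#' @return A list: `t0_index` (0-based frame offset of the crossing),
#'   `t0_frame` (1-based frame), `t0_time_s` (when `time_s` is available).
#' @export
synchronize_trace <- function(trace, sync_threshold = 200) {
  intensity <- if (is.data.frame(trace)) trace$intensity else as.numeric(trace)
  if (length(intensity) == 0) abort("Empty trace.")
  hit <- which(intensity >= sync_threshold)
  if (length(hit) == 0) abort("threshold never reached")
  f <- hit[1]
  list(t0_index = f - 1L, t0_frame = f,
       t0_time_s = if (is.data.frame(trace) && "time_s" %in% names(trace))
         trace$time_s[f] else NA_real_)
}

#' Ring diameter statistics
#'
#' @param rois A list of `ring_roi` objects or a tibble with an `r_px`
#'   column.
#' @param pixel_size Pixel size, um/px.
#' @return A one-row tibble: `mean_um`, `sd_um` (sample sd, `NA` for a
#'   single ring), `n`; the diameters are attached as attribute
#'   `"diameters_um"`.
#' @export
ring_size_stats <- function(rois, pixel_size) {
  r_px <- if (is.data.frame(rois)) rois$r_px
          else vapply(rois, function(r) r$r_px, numeric(1))
  if (length(r_px) < 1) abort("Need at least one ROI.")
  d <- 2 * r_px * pixel_size
  out <- tibble(mean_um = mean(d),
                sd_um = if (length(d) > 1) sd(d) else NA_real_,
                n = length(d))
  attr(out, "diameters_um") <- d
  out
}

#' Population summary of ring velocities
#'
#' Summarises accepted per-ring velocity estimates, optionally split by
#' chirality, and returns histogram counts for plotting/export.
#'
#' @param results Tibble of [estimate_slope()] /
#'   [measure_ring_velocities()] rows.
#' @param by_chirality Split the summary by chirality class?
#' @param binwidth Histogram bin width, nm/s.
#' @return A tibble with `mean_v_nm_s`, `sd_v_nm_s` (`NA` for a single
#'   ring), `n` (and `chirality` when split); histogram counts
#'   (`bin_left`, `bin_right`, `count`) attached as attribute
#'   `"histogram"`.
#' @export
velocity_population <- function(results, by_chirality = FALSE, binwidth = 5) {
  acc <- results[results$accepted %in% TRUE, , drop = FALSE]
  if (nrow(acc) == 0) abort("No accepted velocity results.")
  summarise_v <- function(df) {
    tibble(mean_v_nm_s = mean(df$v_nm_s),
           sd_v_nm_s = if (nrow(df) > 1) sd(df$v_nm_s) else NA_real_,
           n = nrow(df))
  }
  out <- if (by_chirality) {
    dplyr::group_by(acc, .data$chirality) |>
      dplyr::group_modify(~ summarise_v(.x)) |>
      dplyr::ungroup()
  } else {
    summarise_v(acc)
  }
  breaks <- seq(floor(min(acc$v_nm_s) / binwidth) * binwidth,
                ceiling(max(acc$v_nm_s) / binwidth) * binwidth + binwidth,
                by = binwidth)
  h <- graphics::hist(acc$v_nm_s, breaks = breaks, plot = FALSE)
  attr(out, "histogram") <- tibble(bin_left = head(h$breaks, -1),
                                   bin_right = tail(h$breaks, -1),
                                   count = h$counts)
  out
}
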