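#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a survival fit
#'
#' @param x A `survival_fit`.
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate`, `constraint`.
#' @export
tidy.survival_fit <- function(x, ...) {
  tibble(
    term = c("A", "B", "k", "kp", "t_r"),
    estimate = c(x$A, x$B, x$k, x$kp, x$t_r),
    constraint = c("1 - B", "bounded", "free",
                   if (x$kp_mode == "fixed") "fixed" else "free", "1 / k")
  )
}

#' @rdname tidy.survival_fit
#' @export
glance.survival_fit <- function(x, ...) {
  tibble(t_r_s = x$t_r, k = x$k, kp = x$kp, B = x$B,
         kp_mode = x$kp_mode, n_events = x$n_events,
         rss = x$rss, r_squared = x$r_squared)
}

#' @rdname tidy.survival_fit
#' @export
tidy.bleach_calibration <- function(x, ...) {
  tibble(term = c("kp", "timescale_s"),
         estimate = c(x$kp, x$timescale_s),
         constraint = c("free", "1 / kp"))
}

#' @rdname tidy.survival_fit
#' @export
glance.bleach_calibration <- function(x, ...) {
  tibble(kp = x$kp, timescale_s = x$timescale_s, r_squared = x$r_squared)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a kymograph as an arc-position x time raster
#'
#' Tilted stripes indicate a travelling (treadmilling) pattern; their slope
#' encodes the rotation speed and its sign the chirality.
#'
#' @param object A `kymograph`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.kymograph <- function(object, ...) {
  df <- tidyr::expand_grid(
    arc = seq_len(nrow(object$values)),
    t = seq_len(ncol(object$values))
  )
  df$intensity <- object$values[cbind(df$arc, df$t)]
  df$time_s <- (df$t - 1) * object$frame_interval
  df$arc_nm <- (df$arc - 1) * object$arc_step
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$arc_nm,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "A.U.") +
    ggplot2::labs(x = "time (s)", y = "arc position (nm)") +
    ggplot2::theme_minimal()
}

#' Plot an empirical survival curve and its fitted model
#'
#' @param object A `survival_fit` or `bleach_calibration`.
#' @param ... Unused.
#' @return A ggplot on a log survival axis.
#' @export
autoplot.survival_fit <- function(object, ...) {
  df <- object$curve
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$survival)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "red") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time (s)", y = "fraction surviving") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.survival_fit
#' @export
autoplot.bleach_calibration <- autoplot.survival_fit

#' Histogram of accepted ring velocities
#'
#' @param results Tibble from [measure_ring_velocities()].
#' @param binwidth Bin width, nm/s.
#' @return A ggplot, faceted by chirality when both senses are present.
#' @export
plot_velocity_population <- function(results, binwidth = 5) {
  acc <- results[results$accepted %in% TRUE, , drop = FALSE]
  if (nrow(acc) == 0) abort("No accepted velocity results.")
  p <- ggplot2::ggplot(acc, ggplot2::aes(.data$v_nm_s)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            fill = "steelblue", colour = "white") +
    ggplot2::labs(x = "treadmilling speed (nm/s)", y = "rings") +
    ggplot2::theme_minimal()
  if (length(unique(acc$chirality)) > 1)
    p <- p + ggplot2::facet_wrap(~chirality)
  p
}
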