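#' Time-lapse movie container
#'
#' A `ztread_movie` bundles a `(time x row x column)` intensity array with its
#' physical calibration. TIFF metadata for pixel size and frame interval is
#' unreliable in practice, so both are supplied explicitly and carried through
#' every processing step.
#'
#' Coordinates follow the displayed-image convention: `x` indexes columns and
#' `y` indexes rows, both 1-based with pixel centres at integer positions, and
#' `y` increases downwards.
#'
#' @param data Numeric array with dimensions `(frames, rows, columns)`.
#' @param pixel_size Pixel size in micrometres per pixel.
#' @param frame_interval Time between frames, in seconds.
#'
#' @return A `ztread_movie` object.
#' @export
#' @examples
#' mov <- movie(array(0, dim = c(3, 16, 16)), pixel_size = 0.042,
#'              frame_interval = 3)
#' n_frames(mov)
movie <- function(data, pixel_size, frame_interval) {
  if (!is.array(data) || length(dim(data)) != 3L)
    abort("`data` must be a 3-d array (frames x rows x columns).")
  if (dim(data)[1] < 2L)
    abort("A movie needs at least 2 frames.")
  if (!is.numeric(pixel_size) || pixel_size <= 0)
    abort("`pixel_size` must be a positive number (um/px).")
  if (!is.numeric(frame_interval) || frame_interval <= 0)
    abort("`frame_interval` must be a positive number (s).")
  structure(
    list(data = data, pixel_size = pixel_size,
         frame_interval = frame_interval),
    class = "ztread_movie"
  )
}

#' @rdname movie
#' @param x A `ztread_movie`.
#' @export
n_frames <- function(x) dim(x$data)[1]

#' @rdname movie
#' @param i Frame index.
#' @export
frame_matrix <- function(x, i) {
  stopifnot(inherits(x, "ztread_movie"), i >= 1, i <= n_frames(x))
  x$data[i, , ]
}

#' @export
print.ztread_movie <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<ztread_movie> %d frames of %d x %d px | %.3f um/px | %.3g s/frame\n",
    d[1], d[2], d[3], x$pixel_size, x$frame_interval))
  invisible(x)
}

#' @export
dim.ztread_movie <- function(x) dim(x$data)

#' Read / write movies as multi-page TIFF
#'
#' Movies are stored as 16-bit unsigned multi-page TIFF. Intensities are
#' mapped linearly onto the 16-bit range on write using a fixed `scale`
#' (A.U. per full range), and mapped back on read, so arbitrary-unit values
#' round-trip to within quantisation error.
#'
#' @param path File path.
#' @param pixel_size,frame_interval Calibration attached to the movie on read.
#' @param scale Intensity corresponding to the 16-bit maximum (default 65535,
#'   i.e. intensities are stored as-is).
#' @return `read_movie()` returns a [movie()]; `write_movie()` returns `path`
#'   invisibly.
#' @export
read_movie <- function(path, pixel_size, frame_interval, scale = 65535) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) < 2L) abort("TIFF has fewer than 2 pages.")
  d <- dim(pages[[1]])
  arr <- array(0, dim = c(length(pages), d[1], d[2]))
  for (i in seq_along(pages)) arr[i, , ] <- pages[[i]] * scale
  movie(arr, pixel_size = pixel_size, frame_interval = frame_interval)
}

#' @rdname read_movie
#' @param mov A [movie()].
#' @export
write_movie <- function(mov, path, scale = 65535) {
  stopifnot(inherits(mov, "ztread_movie"))
  pages <- lapply(seq_len(n_frames(mov)), function(i) {
    m <- mov$data[i, , ] / scale
    m[m < 0] <- 0
    m[m > 1] <- 1
    m
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

## --- shared image helpers ------------------------------------------------

## Bilinear interpolation of matrix `m` at (x = column, y = row), vectorised.
## Points outside the grid are clamped to the border.
interp_bilinear <- function(m, x, y) {
  nr <- nrow(m); nc <- ncol(m)
  x <- pmin(pmax(x, 1), nc)
  y <- pmin(pmax(y, 1), nr)
  x0 <- pmin(floor(x), nc - 1L); y0 <- pmin(floor(y), nr - 1L)
  fx <- x - x0; fy <- y - y0
  i00 <- (x0 - 1) * nr + y0        # linear index of (y0, x0)
  v00 <- m[i00];      v10 <- m[i00 + 1]
  v01 <- m[i00 + nr]; v11 <- m[i00 + nr + 1]
  (1 - fx) * ((1 - fy) * v00 + fy * v10) + fx * ((1 - fy) * v01 + fy * v11)
}

## Integer-pixel translation estimate between two frames by phase correlation.
## Returns c(dx, dy) such that shifting `b` by (dx, dy) aligns it onto `a`.
## A Hann window suppresses the spurious peaks that the periodic FFT
## boundary otherwise produces.
phase_correlation_shift <- function(a, b) {
  hann <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  w <- outer(hann(nrow(a)), hann(ncol(a)))
  a <- (a - mean(a)) * w
  b <- (b - mean(b)) * w
  fa <- fft(a); fb <- fft(b)
  cross <- fa * Conj(fb)
  mag <- Mod(cross)
  mag[mag < .Machine$double.eps] <- 1
  corr <- Re(fft(cross / mag, inverse = TRUE))
  idx <- which.max(corr)
  nr <- nrow(a); nc <- ncol(a)
  dy <- (idx - 1) %% nr
  dx <- (idx - 1) %/% nr
  if (dy > nr / 2) dy <- dy - nr
  if (dx > nc / 2) dx <- dx - nc
  c(dx = dx, dy = dy)
}

## Shift a matrix by integer (dx, dy), filling vacated pixels with the
## matrix median (neutral background).
shift_matrix <- function(m, dx, dy) {
  out <- matrix(median(m), nrow(m), ncol(m))
  nr <- nrow(m); nc <- ncol(m)
  src_r <- seq_len(nr) - dy
  src_c <- seq_len(nc) - dx
  ok_r <- src_r >= 1 & src_r <= nr
  ok_c <- src_c >= 1 & src_c <= nc
  out[which(ok_r), which(ok_c)] <- m[src_r[ok_r], src_c[ok_c]]
  out
}

## 2-d isotropic Gaussian blur that preserves total intensity. The kernel
## radius is capped so small images remain blurrable.
gaussian_blur <- function(m, sigma) {
  r <- 2 * ceiling(3 * sigma) + 1
  r_max <- min(dim(m))
  if (r_max %% 2 == 0) r_max <- r_max - 1
  EBImage::gblur(m, sigma = sigma, radius = min(r, r_max))
}
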