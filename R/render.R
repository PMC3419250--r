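#' Time-ordered image stack with physical metadata
#'
#' @param frames list of equally sized numeric matrices (row 1 = top of the
#'   image, intensities nominally in `[0, 1]`).
#' @param pixel_size um per pixel (> 0).
#' @param times_min per-frame timestamps (min), strictly increasing.
#' @return An object of class `image_sequence`.
#' @export
image_sequence <- function(frames, pixel_size, times_min) {
  if (!is.list(frames) || !length(frames))
    stop("'frames' must be a non-empty list of matrices")
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all frames must have the same shape")
  stop_if_not_scalar_num(pixel_size, "pixel_size", positive = TRUE)
  if (length(times_min) != length(frames))
    stop("'times_min' must have one entry per frame")
  if (length(times_min) > 1 && any(diff(times_min) <= 0))
    stop("timestamps must be strictly increasing")
  structure(list(frames = frames, pixel_size = pixel_size,
                 time_min = as.numeric(times_min)),
            class = "image_sequence")
}

#' @export
print.image_sequence <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<image_sequence> %d frames of %d x %d px at %.3g um/px\n",
              length(x$frames), d[1], d[2], x$pixel_size))
  invisible(x)
}

# Physical (x, y) in um of pixel centers; 0-based indices, y up:
# x = (col + 0.5) * px, y = (n_rows - row - 0.5) * px.
pixel_centers_x <- function(ncol_px, pixel_size) (seq_len(ncol_px) - 0.5) * pixel_size
pixel_centers_y <- function(nrow_px, pixel_size) (nrow_px - seq_len(nrow_px) + 0.5) * pixel_size

# Even-odd scanline fill of a closed polygon onto a pixel grid.
# Returns a logical matrix (TRUE strictly inside).
rasterize_polygon <- function(v, nrow_px, ncol_px, pixel_size) {
  mask <- matrix(FALSE, nrow_px, ncol_px)
  if (is.null(v)) return(mask)
  x1 <- v[, 1]; y1 <- v[, 2]
  x2 <- c(x1[-1], x1[1]); y2 <- c(y1[-1], y1[1])
  keep <- !(y1 == y2)   # horizontal edges contribute no crossings
  x1 <- x1[keep]; y1 <- y1[keep]; x2 <- x2[keep]; y2 <- y2[keep]
  ys <- pixel_centers_y(nrow_px, pixel_size)
  xs <- pixel_centers_x(ncol_px, pixel_size)
  rows <- which(ys >= min(c(y1, y2)) & ys <= max(c(y1, y2)))
  for (i in rows) {
    y <- ys[i]
    # half-open rule: edge covers [min(y1,y2), max(y1,y2))
    hit <- (y1 <= y & y2 > y) | (y2 <= y & y1 > y)
    if (!any(hit)) next
    xc <- x1[hit] + (y - y1[hit]) / (y2[hit] - y1[hit]) * (x2[hit] - x1[hit])
    xc <- sort(xc)
    if (length(xc) < 2) next
    for (p in seq.int(1, 2 * (length(xc) %/% 2) - 1, by = 2)) {
      sel <- xs > xc[p] & xs < xc[p + 1]
      mask[i, sel] <- TRUE
    }
  }
  mask
}

#' Render a contour series into a synthetic image stack
#'
#' Emulates the appearance of label-free interference-contrast recordings:
#' the adhesion footprint (contour interior) is darker than the
#' surrounding background, with optional additive Gaussian noise. Geometry
#' is preserved to one-pixel tolerance.
#'
#' @param series a [contour_series()]; frames with `NULL` vertices render
#'   as uniform background.
#' @param pixel_size um per pixel.
#' @param frame_shape c(n_rows, n_cols) in pixels.
#' @param noise_sd additive Gaussian intensity noise (0 disables).
#' @param background_level,cell_level intensities in `[0, 1]`;
#'   `cell_level < background_level` is required (dark footprint).
#' @param seed RNG seed for the noise (NULL uses the current stream).
#' @return An [image_sequence()] with the series' timestamps.
#' @export
render_frames <- function(series, pixel_size, frame_shape = c(256, 256),
                          noise_sd = 0, background_level = 0.8,
                          cell_level = 0.2, seed = NULL) {
  if (!inherits(series, "contour_series"))
    stop("'series' must be a contour_series")
  stop_if_not_scalar_num(pixel_size, "pixel_size", positive = TRUE)
  if (cell_level >= background_level)
    stop("'cell_level' must be below 'background_level' (dark footprint)")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  nr <- frame_shape[1]; nc <- frame_shape[2]
  xmax <- nc * pixel_size; ymax <- nr * pixel_size
  with_seed(seed, {
    frames <- vector("list", length(series$vertices))
    for (j in seq_along(frames)) {
      v <- series$vertices[[j]]
      if (!is.null(v) &&
          (min(v[, 1]) < 0 || max(v[, 1]) > xmax ||
           min(v[, 2]) < 0 || max(v[, 2]) > ymax))
        stop(sprintf("contour exceeds frame bounds at frame %d", j))
      f <- matrix(background_level, nr, nc)
      if (!is.null(v)) {
        inside <- rasterize_polygon(v, nr, nc, pixel_size)
        f[inside] <- cell_level
      }
      if (noise_sd > 0) f <- f + matrix(rnorm(nr * nc, 0, noise_sd), nr, nc)
      frames[[j]] <- f
    }
    image_sequence(frames, pixel_size, series$time_min)
  })
}
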