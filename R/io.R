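#' Write a contour series to CSV (with optional ground-truth sidecar)
#'
#' Long format, one row per vertex: frame, time_min, vertex_index, x_um,
#' y_um. Vertices survive a write/read round trip to better than 1e-6 um.
#' If the series carries a `ground_truth` attribute (generator output) it
#' is written to `<path>.json`.
#'
#' @param series a [contour_series()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_contour_csv <- function(series, path) {
  if (!inherits(series, "contour_series"))
    stop("'series' must be a contour_series")
  rows <- lapply(seq_along(series$vertices), function(j) {
    v <- series$vertices[[j]]
    if (is.null(v)) return(NULL)
    data.frame(frame = j, time_min = series$time_min[j],
               vertex_index = seq_len(nrow(v)) - 1L,
               x_um = v[, 1], y_um = v[, 2])
  })
  df <- do.call(rbind, rows)
  write.csv(format(df, digits = 15, scientific = FALSE, trim = TRUE),
            path, row.names = FALSE, quote = FALSE)
  gt <- attr(series, "ground_truth")
  if (!is.null(gt))
    jsonlite::write_json(gt, paste0(path, ".json"), digits = NA,
                         dataframe = "columns")
  invisible(path)
}

#' Read a contour series from CSV
#'
#' @param path CSV written by [write_contour_csv()] (columns frame,
#'   time_min, vertex_index, x_um, y_um).
#' @return A [contour_series()] (centers recomputed as area centroids).
#' @export
read_contour_csv <- function(path) {
  df <- read.csv(path)
  need <- c("frame", "time_min", "vertex_index", "x_um", "y_um")
  if (!all(need %in% names(df)))
    stop("contour CSV must have columns: ", paste(need, collapse = ", "))
  for (col in need) df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  bad <- which(Reduce(`|`, lapply(df[need], function(v) !is.finite(v))))
  if (length(bad))
    stop(sprintf("malformed contour CSV row at line %d of %s",
                 bad[1] + 1L, path))
  frames <- sort(unique(df$frame))
  contours <- lapply(frames, function(f) {
    sub <- df[df$frame == f, ]
    sub <- sub[order(sub$vertex_index), ]
    cbind(x = sub$x_um, y = sub$y_um)
  })
  times <- vapply(frames, function(f) df$time_min[df$frame == f][1],
                  numeric(1))
  contour_series(contours, times)
}

#' Write an image sequence as multi-page TIFF plus JSON sidecar
#'
#' Intensities are clipped to `[0, 1]` and stored as 16-bit; pixel size
#' and timestamps go to `<path>.json`.
#'
#' @param seq an [image_sequence()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(seq, path) {
  if (!inherits(seq, "image_sequence")) stop("'seq' must be an image_sequence")
  frames <- lapply(seq$frames, function(f) pmin(pmax(f, 0), 1))
  tiff::writeTIFF(frames, path, bits.per.sample = 16)
  jsonlite::write_json(list(pixel_size_um = seq$pixel_size,
                            time_min = seq$time_min),
                       paste0(path, ".json"), digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a multi-page TIFF stack with physical metadata
#'
#' Metadata comes from the `<path>.json` sidecar written by
#' [write_stack_tiff()], or from the explicit arguments; without either,
#' reading fails rather than guessing.
#'
#' @param path TIFF path.
#' @param pixel_size um/px (overrides the sidecar).
#' @param frame_interval min between frames (overrides the sidecar;
#'   timestamps start at 0).
#' @return An [image_sequence()].
#' @export
read_stack <- function(path, pixel_size = NULL, frame_interval = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  frames <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]
    as.matrix(p)
  })
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar,
                                                        simplifyVector = TRUE)
          else NULL
  if (is.null(pixel_size)) pixel_size <- meta$pixel_size_um
  times <- if (!is.null(frame_interval))
    (seq_along(frames) - 1) * frame_interval else meta$time_min
  if (is.null(pixel_size))
    stop("no pixel size: supply 'pixel_size' or a metadata sidecar")
  if (is.null(times))
    stop("no frame timing: supply 'frame_interval' or a metadata sidecar")
  image_sequence(frames, pixel_size, times)
}

#' Write an amplitude or correlation map as a CSV matrix
#'
#' First column carries the angular axis, remaining columns one time (or
#' time-lag) point each; the header row states the time axis and the
#' angle convention (0 deg = laboratory vertical, counterclockwise).
#'
#' @param x an `amplitude_map` or `correlation_map`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_map_csv <- function(x, path) {
  if (inherits(x, "amplitude_map")) {
    m <- x$delta_r; ax <- x$theta_deg; cols <- x$time_min
    lab <- c("theta_deg", paste0("t_min_", cols))
  } else if (inherits(x, "correlation_map")) {
    m <- x$g; ax <- x$dtheta_deg; cols <- x$dt_min
    lab <- c("dtheta_deg", paste0("dt_min_", cols))
  } else stop("'x' must be an amplitude_map or correlation_map")
  df <- data.frame(ax, m)
  names(df) <- lab
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# angle convention: 0 deg = laboratory vertical (+y), counterclockwise",
             con)
  write.csv(format(df, digits = 12, scientific = FALSE, trim = TRUE),
            con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Heatmap of an amplitude map
#'
#' @param x an `amplitude_map`.
#' @param ... passed to [graphics::image()].
#' @export
plot.amplitude_map <- function(x, ...) {
  graphics::image(x$time_min, x$theta_deg, t(x$delta_r),
                  xlab = "t (min)", ylab = expression(theta ~ "(deg)"),
                  main = expression(Delta * R(theta, t) ~ "(um)"),
                  col = grDevices::hcl.colors(64, "RdBu", rev = TRUE), ...)
  invisible(x)
}

#' Heatmap of a correlation map
#'
#' @param x a `correlation_map`.
#' @param ... passed to [graphics::image()].
#' @export
plot.correlation_map <- function(x, ...) {
  graphics::image(x$dt_min, x$dtheta_deg, t(x$g),
                  xlab = expression(Delta * t ~ "(min)"),
                  ylab = expression(Delta * theta ~ "(deg)"),
                  main = expression(G(Delta * theta, Delta * t)),
                  col = grDevices::hcl.colors(64, "RdBu", rev = TRUE), ...)
  invisible(x)
}
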