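#' Per-frame closed cell contours with derived geometry
#'
#' A `contour_series` is the package's central container: one closed cell
#' boundary per frame, in physical micrometres with y increasing upward,
#' together with the per-frame reference center, area, perimeter and
#' timestamp. Frames without a cell carry `NULL` vertices.
#'
#' @param contours list with one entry per frame; each entry is either
#'   `NULL` (no cell) or an n x 2 matrix of vertex coordinates (x, y in um)
#'   describing a closed polygon (last vertex implicitly joined to the
#'   first).
#' @param times_min numeric vector of frame timestamps in minutes,
#'   strictly increasing.
#' @param centers optional n_frames x 2 matrix of reference centers (um).
#'   Defaults to the area centroid of each polygon. Generator output stores
#'   the true generative center here instead.
#' @return An object of class `contour_series`: a list with elements
#'   `vertices` (list of matrices), `time_min`, `center` (n x 2 matrix),
#'   `area_um2`, `perimeter_um`.
#' @export
contour_series <- function(contours, times_min, centers = NULL) {
  if (!is.list(contours)) stop("'contours' must be a list of vertex matrices")
  n <- length(contours)
  if (length(times_min) != n)
    stop("'times_min' must have one timestamp per frame")
  if (n > 1 && any(diff(times_min) <= 0))
    stop("timestamps must be strictly increasing")
  contours <- lapply(contours, function(v) {
    if (is.null(v)) return(NULL)
    v <- as.matrix(v)
    if (ncol(v) != 2 || nrow(v) < 3)
      stop("each contour must be an n x 2 matrix with n >= 3")
    colnames(v) <- c("x", "y")
    v
  })
  geom <- t(vapply(contours, function(v) {
    if (is.null(v)) return(c(NA_real_, NA_real_, NA_real_, NA_real_))
    c(polygon_centroid(v), polygon_area(v), polygon_perimeter(v))
  }, numeric(4)))
  if (is.null(centers)) {
    centers <- geom[, 1:2, drop = FALSE]
  } else {
    centers <- as.matrix(centers)
    if (!all(dim(centers) == c(n, 2)))
      stop("'centers' must be an n_frames x 2 matrix")
  }
  colnames(centers) <- c("x", "y")
  structure(list(
    vertices = contours,
    time_min = as.numeric(times_min),
    center = centers,
    area_um2 = geom[, 3],
    perimeter_um = geom[, 4]
  ), class = "contour_series")
}

#' @export
print.contour_series <- function(x, ...) {
  n <- length(x$vertices)
  present <- sum(!vapply(x$vertices, is.null, logical(1)))
  cat(sprintf("<contour_series> %d frames (%d with a cell), t = %.1f..%.1f min\n",
              n, present,
              if (n) min(x$time_min) else NA, if (n) max(x$time_min) else NA))
  if (present) {
    a <- x$area_um2[!is.na(x$area_um2)]
    cat(sprintf("  area %.1f-%.1f um^2, mean perimeter %.1f um\n",
                min(a), max(a), mean(x$perimeter_um, na.rm = TRUE)))
  }
  invisible(x)
}

#' @export
length.contour_series <- function(x) length(x$vertices)

#' Build a contour series from a polar radius function
#'
#' Samples `radius_fun(theta_deg, t_min)` on a uniform vertex grid and
#' assembles the closed contours. Useful for scripted morphodynamic
#' scenarios (e.g. a cell that elongates, rounds up, and re-elongates along
#' the perpendicular axis) with exact ground truth.
#'
#' @param radius_fun function of (theta_deg, time_min) returning radii (um);
#'   must be vectorized over theta. Angles follow the lab convention:
#'   0 deg = vertical (+y), increasing counterclockwise.
#' @param times_min frame timestamps (min).
#' @param center fixed center (x, y) in um, or an n_frames x 2 matrix.
#' @param n_vertices vertices per contour (default 512).
#' @return A [contour_series()] whose per-frame centers are the supplied
#'   generative centers.
#' @export
contour_series_from_polar <- function(radius_fun, times_min,
                                      center = c(0, 0), n_vertices = 512) {
  n <- length(times_min)
  if (is.matrix(center)) {
    centers <- center
  } else {
    centers <- matrix(rep(as.numeric(center), each = n), ncol = 2)
  }
  theta <- seq(0, 360, length.out = n_vertices + 1)[-(n_vertices + 1)]
  u <- angle_to_unit(theta)
  contours <- vector("list", n)
  for (j in seq_len(n)) {
    r <- radius_fun(theta, times_min[j])
    if (any(!is.finite(r)) || any(r <= 0))
      stop(sprintf("radius_fun produced non-positive radii at frame %d", j))
    contours[[j]] <- cbind(x = centers[j, 1] + r * u[, "x"],
                           y = centers[j, 2] + r * u[, "y"])
  }
  contour_series(contours, times_min, centers = centers)
}
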