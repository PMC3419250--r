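#' Polar radius profile of a closed contour
#'
#' Casts rays from the reference center at uniformly spaced angles and
#' records the distance to the contour. Angles follow the laboratory
#' convention: 0 deg is the vertical (+y) direction, increasing
#' counterclockwise. For non-star-shaped contours the farthest
#' intersection along each ray is used (with a message).
#'
#' @param contour n x 2 vertex matrix (um).
#' @param center reference point (x, y) um, strictly inside the contour.
#' @param n_bins number of angular bins over `[0, 360)` (>= 36,
#'   default 180, i.e. 2 deg).
#' @return list of class `polar_profile`: `theta_deg`, `r_um`, `center`.
#' @export
polar_profile <- function(contour, center, n_bins = 180) {
  contour <- as.matrix(contour)
  if (n_bins < 36) stop("'n_bins' must be >= 36")
  if (!point_in_polygon(center[1], center[2], contour))
    stop("center lies outside the contour")
  theta <- (seq_len(n_bins) - 1) * 360 / n_bins
  r <- ray_distances(contour, center, theta)
  if (any(!is.finite(r)))
    stop("a ray found no contour intersection (contour not closed?)")
  structure(list(theta_deg = theta, r_um = r, center = center),
            class = "polar_profile")
}

# Even-odd point-in-polygon test.
point_in_polygon <- function(px, py, v) {
  x1 <- v[, 1]; y1 <- v[, 2]
  x2 <- c(x1[-1], x1[1]); y2 <- c(y1[-1], y1[1])
  hit <- (y1 <= py & y2 > py) | (y2 <= py & y1 > py)
  if (!any(hit)) return(FALSE)
  xc <- x1[hit] + (py - y1[hit]) / (y2[hit] - y1[hit]) * (x2[hit] - x1[hit])
  sum(xc > px) %% 2 == 1
}

# Distance from center to the polygon along each ray direction, taking
# the farthest boundary crossing. Crossings are assigned to edges by a
# half-open rule on the vertex polar angles, so a ray passing exactly
# through a vertex is counted once (robust to the vertex/ray grids
# sharing angles).
ray_distances <- function(v, center, theta_deg) {
  q <- sweep(v, 2, center)                 # vertex - center, V x 2
  a1 <- vector_to_angle(q[, 1], q[, 2])    # vertex polar angles (deg)
  a2 <- c(a1[-1], a1[1])
  delta <- wrap_angle(a2 - a1)             # signed angular span per edge
  d1 <- wrap_angle(outer(theta_deg, a1, "-"))   # n_bins x V
  cover <- sweep(d1 >= 0, 2, delta > 0, `&`) &
    sweep(d1, 2, delta, `<`) |
    sweep(d1 <= 0, 2, delta < 0, `&`) &
    sweep(d1, 2, delta, `>`)
  u <- angle_to_unit(theta_deg)
  e <- rbind(diff(v), v[1, ] - v[nrow(v), ])    # edge vectors, V x 2
  uxe <- outer(u[, 1], e[, 2]) - outer(u[, 2], e[, 1])
  qxe <- q[, 1] * e[, 2] - q[, 2] * e[, 1]
  tt <- sweep(1 / uxe, 2, qxe, `*`)
  valid <- cover & is.finite(tt) & tt > 0
  tt[!valid] <- -Inf
  r <- apply(tt, 1, max)
  # crossings clearly inside the farthest one mark a non-star-shaped ray
  # (a vertex shared between two edges yields coincident radii, not two)
  inner <- valid & tt < r * (1 - 1e-9)
  if (any(rowSums(inner) > 0))
    message(sprintf("non-star-shaped contour: %d rays with multiple crossings; using the farthest",
                    sum(rowSums(inner) > 0)))
  r
}

#' Amplitude map of radial shape fluctuations
#'
#' For each frame, the polar radius profile about the per-frame center is
#' reduced to its fluctuation `dR(theta, t) = r(theta, t) - Rbar(t)`,
#' where `Rbar(t)` is the angular mean radius of that frame. The angular
#' mean of every column is therefore zero by construction.
#'
#' @param series a [contour_series()] with at least 2 frames.
#' @param n_bins angular bins (default 180).
#' @return Object of class `amplitude_map`: `delta_r` (n_bins x n_frames
#'   matrix, um), `theta_deg`, `time_min`, `r_bar_um`.
#' @export
amplitude_map <- function(series, n_bins = 180) {
  if (!inherits(series, "contour_series"))
    stop("'series' must be a contour_series")
  keep <- which(!vapply(series$vertices, is.null, logical(1)))
  if (length(keep) < 2) stop("need at least 2 frames with a contour")
  n_f <- length(keep)
  dr <- matrix(NA_real_, n_bins, n_f)
  rbar <- numeric(n_f)
  theta <- (seq_len(n_bins) - 1) * 360 / n_bins
  for (jj in seq_along(keep)) {
    j <- keep[jj]
    v <- series$vertices[[j]]
    ctr <- series$center[j, ]
    if (!point_in_polygon(ctr[1], ctr[2], v))
      stop(sprintf("center outside contour at frame %d", j))
    r <- ray_distances(v, ctr, theta)
    rbar[jj] <- mean(r)
    dr[, jj] <- r - rbar[jj]
  }
  structure(list(delta_r = dr, theta_deg = theta,
                 time_min = series$time_min[keep], r_bar_um = rbar),
            class = "amplitude_map")
}

#' @export
print.amplitude_map <- function(x, ...) {
  cat(sprintf("<amplitude_map> %d angular bins x %d frames, |dR| up to %.2f um\n",
              nrow(x$delta_r), ncol(x$delta_r), max(abs(x$delta_r))))
  invisible(x)
}

#' Spatio-temporal autocorrelation of an amplitude map
#'
#' Computes `G(dtheta, dt) = <dR(theta, t) dR(theta + dtheta, t + dt)>`,
#' averaging over all angles (with periodic wrap) and all overlapping
#' frame pairs, each time lag divided by its own pair count so long lags
#' are unbiased, and globally normalized by the zero-lag value so that
#' `G(0, 0) = 1`. The map satisfies `G(-dtheta, -dt) = G(dtheta, dt)`
#' exactly and is periodic in `dtheta` with period 360 deg.
#'
#' @param map an [amplitude_map()] with a uniform frame interval
#'   (non-uniform timestamps are linearly resampled onto the modal
#'   interval first).
#' @param max_lag_min largest temporal lag (min); truncated to the series
#'   duration with a warning when it exceeds it. Default: half the
#'   duration.
#' @return Object of class `correlation_map`: `g` (n_dtheta x n_dt
#'   matrix), `dtheta_deg` (ascending, in `(-180, 180]`), `dt_min`
#'   (symmetric about 0).
#' @export
autocorrelation <- function(map, max_lag_min = NULL) {
  if (!inherits(map, "amplitude_map"))
    stop("'map' must be an amplitude_map")
  dr <- map$delta_r
  tt <- map$time_min
  n_t <- ncol(dr)
  if (n_t < 2) stop("need at least 2 frames")
  dts <- diff(tt)
  interval <- as.numeric(names(sort(table(dts), decreasing = TRUE))[1])
  if (max(abs(dts - interval)) > 1e-9 * max(interval, 1)) {
    grid <- seq(tt[1], tt[n_t], by = interval)
    dr <- t(apply(dr, 1, function(row) approx(tt, row, xout = grid)$y))
    n_t <- length(grid)
  }
  duration <- (n_t - 1) * interval
  if (is.null(max_lag_min)) max_lag_min <- duration / 2
  if (max_lag_min > duration) {
    warning("max_lag_min exceeds the series duration; truncating")
    max_lag_min <- duration
  }
  m_max <- min(floor(max_lag_min / interval), n_t - 1)
  n_b <- nrow(dr)
  g_half <- matrix(0, n_b, m_max + 1)
  for (m in 0:m_max) {
    a <- dr[, 1:(n_t - m), drop = FALSE]
    b <- dr[, (1 + m):n_t, drop = FALSE]
    cc <- Re(mvfft(Conj(mvfft(a)) * mvfft(b), inverse = TRUE)) / n_b
    g_half[, m + 1] <- rowSums(cc) / (n_b * (n_t - m))
  }
  g0 <- g_half[1, 1]
  # fluctuations below 1e-4 of the mean radius (sub-nm on a 10 um cell,
  # far below optical resolution) are discretization ripple, not shape
  # dynamics: report a flat (all-zero) correlation
  if (g0 <= (1e-4 * mean(map$r_bar_um))^2) {
    warning("flat amplitude map: correlation undefined, returning zeros")
    g_half[] <- 0
    g0 <- 1
  }
  g_half <- g_half / g0
  # reorder circular angular lags 0..(n_b-1) to ascending (-180, 180]
  binw <- 360 / n_b
  lag_deg <- wrap_angle((seq_len(n_b) - 1) * binw)
  ord <- order(lag_deg)
  dtheta <- lag_deg[ord]
  g_pos <- g_half[ord, , drop = FALSE]
  # negative time lags by the point symmetry G(-dtheta, -dt) = G(dtheta, dt):
  # reverse the (circular) angular axis. Index of -dtheta in 'dtheta':
  neg_idx <- vapply(dtheta, function(d) which.min(abs(wrap_angle(-d) - dtheta)),
                    integer(1))
  g_neg <- if (m_max > 0) g_pos[neg_idx, (m_max + 1):2, drop = FALSE] else NULL
  structure(list(g = cbind(g_neg, g_pos),
                 dtheta_deg = dtheta,
                 dt_min = seq(-m_max, m_max) * interval),
            class = "correlation_map")
}

#' @export
print.correlation_map <- function(x, ...) {
  cat(sprintf("<correlation_map> %d angular lags x %d time lags (dt up to %.0f min)\n",
              length(x$dtheta_deg), length(x$dt_min), max(x$dt_min)))
  invisible(x)
}

#' Locate angular correlation peaks at a fixed time lag
#'
#' Finds local maxima of the `G(dtheta)` slice at the time lag nearest
#' `at_lag_min`, treating the angular axis as circular so that a maximum
#' at +/-180 deg is reported once (at +180). Plateaus of equal values
#' yield a single peak.
#'
#' @param corr a [autocorrelation()] result.
#' @param min_height minimum peak height (in `[0, 1)`, default 0.1).
#' @param at_lag_min time-lag slice (min, default 0).
#' @return numeric vector of peak positions (deg), sorted ascending;
#'   empty for a flat slice.
#' @export
locate_peaks <- function(corr, min_height = 0.1, at_lag_min = 0) {
  if (!inherits(corr, "correlation_map"))
    stop("'corr' must be a correlation_map")
  if (min_height < 0 || min_height >= 1)
    stop("'min_height' must lie in [0, 1)")
  col <- which.min(abs(corr$dt_min - at_lag_min))
  g <- corr$g[, col]
  n <- length(g)
  left <- g[c(n, 1:(n - 1))]
  right <- g[c(2:n, 1)]
  is_peak <- g > left & g >= right & g >= min_height
  sort(corr$dtheta_deg[is_peak])
}

#' Peak-ridge slope: rotation rate from a correlation map
#'
#' Follows the correlation peak nearest `dtheta = 0` outward through
#' successive positive time lags (nearest-peak continuation) and fits a
#' line through the tracked positions. For a rigidly rotating shape the
#' slope recovers the rotation rate in deg/min.
#'
#' @param corr a [autocorrelation()] result.
#' @param max_lag_min largest time lag to track (default: half the
#'   available positive range).
#' @param min_height peak threshold passed to the slice search.
#' @return list: `slope_deg_min`, `ridge` (data.frame dt_min, dtheta_deg).
#' @export
ridge_slope <- function(corr, max_lag_min = NULL, min_height = 0.2) {
  pos_lags <- corr$dt_min[corr$dt_min >= 0]
  if (is.null(max_lag_min)) max_lag_min <- max(pos_lags) / 2
  lags <- pos_lags[pos_lags <= max_lag_min]
  pos <- numeric(0); used <- numeric(0)
  current <- 0
  for (lag in lags) {
    pk <- locate_peaks(corr, min_height = min_height, at_lag_min = lag)
    if (!length(pk)) next
    # nearest peak to the running position, on the circle
    d <- abs(wrap_angle(pk - current))
    current <- pk[which.min(d)]
    pos <- c(pos, current); used <- c(used, lag)
  }
  if (length(used) < 3) stop("too few trackable peaks for a ridge fit")
  # unwrap the tracked positions so the fit crosses +/-180 cleanly
  unwrapped <- cumsum(c(pos[1], wrap_angle(diff(pos))))
  fit <- lm(unwrapped ~ used)
  list(slope_deg_min = unname(coef(fit)[2]),
       ridge = data.frame(dt_min = used, dtheta_deg = pos))
}
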