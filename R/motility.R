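#' Center-of-mass trajectory of a contour series
#'
#' @param series a [contour_series()] with at least 2 frames.
#' @return A `trajectory` data.frame (frame, time_min, x_um, y_um, step_um)
#'   with attribute `gaps`: indices of steps whose time spacing exceeds
#'   1.5x the median frame interval (missed frames are flagged, never
#'   silently interpolated).
#' @export
track_centers <- function(series) {
  if (!inherits(series, "contour_series"))
    stop("'series' must be a contour_series")
  n <- length(series$vertices)
  if (n < 2) stop("need at least 2 frames to track")
  xy <- series$center
  step <- c(NA, sqrt(rowSums(diff(xy)^2)))
  dts <- diff(series$time_min)
  gaps <- which(dts > 1.5 * median(dts))
  traj <- data.frame(frame = seq_len(n), time_min = series$time_min,
                     x_um = xy[, 1], y_um = xy[, 2], step_um = step)
  structure(traj, gaps = gaps, class = c("trajectory", "data.frame"))
}

#' Mean migration speed at a fixed sampling interval
#'
#' Resamples the trajectory onto a regular `dt_min` grid (nearest frame)
#' and averages the per-interval displacement magnitudes, reported in
#' um/h. The default 30-min interval matches the standard read-out for
#' slowly migrating adherent cells.
#'
#' @param traj a `trajectory` (from [track_centers()] or
#'   [simulate_prw()]).
#' @param dt_min sampling interval (min, default 30). The trajectory must
#'   span at least one interval.
#' @return list: `mean_um_h`, `sd_mean_um_h` (standard deviation of the
#'   mean), `n_samples`, `speeds_um_h`.
#' @export
mean_velocity <- function(traj, dt_min = 30) {
  if (!inherits(traj, "trajectory")) stop("'traj' must be a trajectory")
  tt <- traj$time_min
  duration <- tt[length(tt)] - tt[1]
  if (duration < dt_min)
    stop(sprintf("trajectory spans %.1f min < dt = %.1f min", duration, dt_min))
  grid <- seq(tt[1], tt[length(tt)], by = dt_min)
  idx <- vapply(grid, function(g) which.min(abs(tt - g)), integer(1))
  x <- traj$x_um[idx]; y <- traj$y_um[idx]
  disp <- sqrt(diff(x)^2 + diff(y)^2)
  speeds <- disp / dt_min * 60
  n <- length(speeds)
  list(mean_um_h = mean(speeds),
       sd_mean_um_h = if (n > 1) sd(speeds) / sqrt(n) else NA_real_,
       n_samples = n, speeds_um_h = speeds)
}

# Per-frame motion direction from the centered displacement over a dt
# window; NA where the displacement is below the noise floor or the
# window is unavailable.
motion_directions <- function(traj, dt_min, noise_floor_um) {
  tt <- traj$time_min
  n <- length(tt)
  dir <- rep(NA_real_, n)
  for (j in seq_len(n)) {
    t0 <- tt[j] - dt_min / 2; t1 <- tt[j] + dt_min / 2
    if (t0 < tt[1] || t1 > tt[n]) next
    i0 <- which.min(abs(tt - t0)); i1 <- which.min(abs(tt - t1))
    dx <- traj$x_um[i1] - traj$x_um[i0]
    dy <- traj$y_um[i1] - traj$y_um[i0]
    if (sqrt(dx^2 + dy^2) < noise_floor_um) next
    dir[j] <- vector_to_angle(dx, dy)
  }
  dir
}

#' Joint distribution of contour deformation and motility direction
#'
#' For every frame whose centered displacement over a `dt_min` window
#' exceeds the noise floor, the radial fluctuation profile
#' `dR(theta) = r(theta) - Rbar` is rotated into the motility frame
#' (0 deg = instantaneous motion direction) and accumulated into a joint
#' histogram of (deformation dR in um, relative angle in deg), normalized
#' to total mass 1. The "degree of deformation" axis is the radial
#' fluctuation itself, which carries the um scale on which directional
#' protrusions appear as off-center sub-peaks.
#'
#' @param series a [contour_series()].
#' @param traj matching `trajectory`; defaults to [track_centers()] of the
#'   series.
#' @param dt_min displacement window for the motion direction (default 30).
#' @param noise_floor_um minimum displacement defining a directed frame
#'   (default 0.5).
#' @param d_bin_um deformation bin width (default 1).
#' @param angle_bin_deg angular bin width (default 10).
#' @param n_theta angular samples per contour (default 180).
#' @return Object of class `deformation_pdf`: `pdf` (deformation x angle
#'   matrix, total mass 1), `d_um` (bin centers), `rel_angle_deg` (bin
#'   centers), `marginal` (data.frame d_um, mass: distribution of dR
#'   sampled within one polar bin of the motion axis, normalized to 1),
#'   `n_contours`.
#' @export
deformation_direction_pdf <- function(series, traj = NULL, dt_min = 30,
                                      noise_floor_um = 0.5, d_bin_um = 1,
                                      angle_bin_deg = 10, n_theta = 180) {
  if (!inherits(series, "contour_series"))
    stop("'series' must be a contour_series")
  if (is.null(traj)) traj <- track_centers(series)
  dirs <- motion_directions(traj, dt_min, noise_floor_um)
  usable <- which(!is.na(dirs) &
                    !vapply(series$vertices, is.null, logical(1)))
  if (!length(usable)) stop("no directed frames above the motion noise floor")
  theta <- (seq_len(n_theta) - 1) * 360 / n_theta
  theta_bin <- 360 / n_theta
  n_ab <- round(360 / angle_bin_deg)
  d_vals <- numeric(0); a_bins <- integer(0); axis_vals <- numeric(0)
  for (j in usable) {
    r <- ray_distances(series$vertices[[j]], series$center[j, ], theta)
    dr <- r - mean(r)
    rel <- wrap_angle(theta - dirs[j])
    ab <- floor((rel + 180) / angle_bin_deg) %% n_ab + 1L
    d_vals <- c(d_vals, dr); a_bins <- c(a_bins, ab)
    axis_vals <- c(axis_vals, dr[abs(rel) <= theta_bin])
  }
  d_lim <- max(1, ceiling(max(abs(d_vals)) / d_bin_um)) * d_bin_um
  d_edges <- seq(-d_lim, d_lim, by = d_bin_um)
  d_idx <- pmin(pmax(findInterval(d_vals, d_edges, rightmost.closed = TRUE),
                     1L), length(d_edges) - 1L)
  h <- matrix(0, length(d_edges) - 1L, n_ab)
  for (i in seq_along(d_vals)) h[d_idx[i], a_bins[i]] <- h[d_idx[i], a_bins[i]] + 1
  pdf <- h / sum(h)
  d_centers <- d_edges[-length(d_edges)] + d_bin_um / 2
  a_centers <- seq(-180 + angle_bin_deg / 2, 180 - angle_bin_deg / 2,
                   by = angle_bin_deg)
  # motion-axis marginal at the contour's angular resolution (relative
  # angle within one polar bin of 0), so narrow protrusions keep their
  # peak deformation instead of being averaged over a coarse angle bin
  a_idx <- pmin(pmax(findInterval(axis_vals, d_edges, rightmost.closed = TRUE),
                     1L), length(d_edges) - 1L)
  marg <- tabulate(a_idx, nbins = length(d_edges) - 1L)
  if (sum(marg) > 0) marg <- marg / sum(marg)
  structure(list(pdf = pdf, d_um = d_centers, rel_angle_deg = a_centers,
                 marginal = data.frame(d_um = d_centers, mass = marg),
                 n_contours = length(usable),
                 d_bin_um = d_bin_um, angle_bin_deg = angle_bin_deg),
            class = "deformation_pdf")
}

#' @export
print.deformation_pdf <- function(x, ...) {
  cat(sprintf("<deformation_pdf> %d x %d bins from %d contour lines\n",
              nrow(x$pdf), ncol(x$pdf), x$n_contours))
  invisible(x)
}

#' Symmetry-break offset of the deformation distribution
#'
#' Location (um) of the most prominent non-central local mode of the
#' motion-axis marginal; 0 when no such mode reaches the prominence
#' threshold relative to the central mode. A displaced mode signals
#' polarized, directional migration; ties between equally heavy modes are
#' broken toward the motion direction (positive deformation), then toward
#' the larger mass.
#'
#' @param pdf a [deformation_direction_pdf()] result.
#' @param min_contours minimum number of contributing contour lines
#'   (default 55).
#' @param prominence minimum sub-peak mass as a fraction of the central
#'   mode's mass (default 0.1).
#' @return offset in um (0 for a central unimodal distribution).
#' @export
symmetry_break_offset <- function(pdf, min_contours = 55, prominence = 0.1) {
  if (!inherits(pdf, "deformation_pdf"))
    stop("'pdf' must be a deformation_pdf")
  if (pdf$n_contours < min_contours)
    stop(sprintf("only %d contour lines (< %d required)", pdf$n_contours,
                 min_contours))
  m <- pdf$marginal$mass
  d <- pdf$marginal$d_um
  if (!sum(m)) stop("empty marginal distribution")
  n <- length(m)
  left <- c(-Inf, m[-n]); right <- c(m[-1], -Inf)
  is_mode <- m > left & m >= right & m > 0
  central <- abs(d) <= pdf$d_bin_um
  central_mass <- if (any(is_mode & central)) max(m[is_mode & central])
                  else max(m[central], 0)
  cand <- which(is_mode & !central)
  if (!length(cand)) return(0)
  ok <- m[cand] >= prominence * central_mass
  cand <- cand[ok]
  if (!length(cand)) return(0)
  # prefer larger mass; among equals prefer positive (motion-direction) d
  best_mass <- max(m[cand])
  best <- cand[m[cand] >= best_mass - 1e-15]
  if (length(best) > 1) {
    pos <- best[d[best] > 0]
    best <- if (length(pos)) pos[which.min(d[pos])] else best[1]
  }
  d[best]
}
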