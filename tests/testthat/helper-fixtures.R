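# Shared fixtures and independent brute-force oracles. Everything here is
# deliberately written from scratch (no calls into package internals) so
# the oracles stay independent of the code paths they check.

# Closed polygon of a circle, vertices counterclockwise in math coords.
circle_polygon <- function(radius, center = c(0, 0), n = 256) {
  a <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(x = center[1] + radius * cos(a), y = center[2] + radius * sin(a))
}

# Axis-aligned ellipse (semi-axes a >= b), optionally rotated (deg, CCW).
ellipse_polygon <- function(a, b, center = c(0, 0), rot_deg = 0, n = 512) {
  t <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  x <- a * cos(t); y <- b * sin(t)
  r <- rot_deg * pi / 180
  cbind(x = center[1] + x * cos(r) - y * sin(r),
        y = center[2] + x * sin(r) + y * cos(r))
}

# Crossing-number point-in-polygon, straightforward per-point loop form.
oracle_point_in_polygon <- function(px, py, v) {
  n <- nrow(v)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((v[i, 2] > py) != (v[j, 2] > py)) {
      xint <- v[j, 1] + (py - v[j, 2]) / (v[i, 2] - v[j, 2]) * (v[i, 1] - v[j, 1])
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

# Brute-force count of pixel centers inside a polygon, using the same
# physical pixel-center convention as the package (0-based, y up).
oracle_pixel_count <- function(v, nrow_px, ncol_px, pixel_size) {
  count <- 0
  for (i in seq_len(nrow_px)) {
    y <- (nrow_px - i + 0.5) * pixel_size
    for (j in seq_len(ncol_px)) {
      x <- (j - 0.5) * pixel_size
      if (oracle_point_in_polygon(x, y, v)) count <- count + 1
    }
  }
  count
}

# Brute-force farthest ray/segment intersection distance, solving the
# 2x2 linear system edge by edge. Lab angle convention: 0 = +y, CCW.
oracle_ray_distance <- function(v, center, theta_deg) {
  t <- theta_deg * pi / 180
  u <- c(-sin(t), cos(t))
  n <- nrow(v)
  best <- -Inf
  for (i in seq_len(n)) {
    p1 <- v[i, ]; p2 <- v[if (i == n) 1 else i + 1, ]
    m <- cbind(u, p1 - p2)
    if (abs(det(m)) < 1e-12) next
    sol <- solve(m, p1 - center)
    if (sol[2] >= -1e-9 && sol[2] <= 1 + 1e-9 && sol[1] > 1e-9)
      best <- max(best, sol[1])
  }
  best
}

# Dense-grid second-moment axis ratio of a polygon interior.
oracle_axis_ratio <- function(v, n_grid = 400) {
  xr <- range(v[, 1]); yr <- range(v[, 2])
  xs <- seq(xr[1], xr[2], length.out = n_grid)
  ys <- seq(yr[1], yr[2], length.out = n_grid)
  pts <- expand.grid(x = xs, y = ys)
  keep <- vapply(seq_len(nrow(pts)), function(i)
    oracle_point_in_polygon(pts$x[i], pts$y[i], v), logical(1))
  m <- cov(pts[keep, ])
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  sqrt(ev[2] / ev[1])
}

# Polar radius of an ellipse about its center, angle from the major axis.
ellipse_radius <- function(a, b, angle_from_major_deg) {
  t <- angle_from_major_deg * pi / 180
  a * b / sqrt((b * cos(t))^2 + (a * sin(t))^2)
}

# Single-mode simulated cell, the workhorse fixture.
mode_cell <- function(k, a, n_frames = 50, rotation_rate = 0, phase = 10,
                      base_radius = 12, frame_interval = 10, ...) {
  p <- cell_sim_params(base_radius = base_radius,
                       fourier_modes = data.frame(k = k, a = a,
                                                  phase_deg = phase),
                       rotation_rate = rotation_rate, ...)
  simulate_cell(p, n_frames = n_frames, frame_interval = frame_interval)
}
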