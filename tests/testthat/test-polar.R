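test_that("polar profiles match closed forms for circles and ellipses", {
  pp <- polar_profile(circle_polygon(5, c(2, -3), 512), c(2, -3), 72)
  expect_equal(pp$r_um, rep(5, 72), tolerance = 1e-3)
  # centered ellipse: r(theta) = ab / sqrt(b^2 cos^2 t' + a^2 sin^2 t')
  # major axis along lab 0 deg (vertical) -> rotate the ellipse by 90
  v <- ellipse_polygon(8, 5, rot_deg = 90, n = 2048)
  pp2 <- polar_profile(v, c(0, 0), 120)
  expected <- ellipse_radius(8, 5, pp2$theta_deg)
  expect_equal(pp2$r_um, expected, tolerance = 1e-3)
  expect_error(polar_profile(circle_polygon(5), c(10, 0), 72), "outside")
  expect_error(polar_profile(circle_polygon(5), c(0, 0), 10), ">= 36")
})

test_that("non-convex contours match the brute-force ray oracle", {
  # deep 5-fold star: rays in the concavities cross the boundary 3 times
  a <- seq(0, 2 * pi, length.out = 201)[-201]
  r <- 10 * (1 + 0.45 * cos(5 * a)) + 2 * sin(17 * a)
  v <- cbind(r * cos(a), r * sin(a))
  ctr <- c(0.5, 0.2)
  suppressMessages(pp <- polar_profile(v, ctr, 90))
  oracle <- vapply(pp$theta_deg, function(th) oracle_ray_distance(v, ctr, th),
                   numeric(1))
  expect_equal(pp$r_um, oracle, tolerance = 1e-9)
})

test_that("amplitude maps remove the per-frame mean radius", {
  # circle at all frames: dR identically zero (vertices on the bin grid
  # so the polygon chords do not alias into the profile)
  s <- contour_series_from_polar(function(th, t) rep(7, length(th)),
                                 c(0, 10, 20), n_vertices = 360)
  am <- amplitude_map(s)
  expect_lt(max(abs(am$delta_r)), 1e-9)
  expect_equal(am$r_bar_um, rep(7, 3), tolerance = 1e-4)
  # static two-fold mode: dR = 0.2 R0 cos(2 theta)
  s2 <- contour_series_from_polar(function(th, t)
    10 * (1 + 0.2 * cos(2 * th * pi / 180)), c(0, 10, 20))
  am2 <- amplitude_map(s2)
  expect_equal(am2$delta_r[, 2], 2 * cos(2 * am2$theta_deg * pi / 180),
               tolerance = 1e-3)
  # construction invariant: angular means vanish for any input
  s3 <- mode_cell(k = 3, a = 0.3, n_frames = 30, mode_noise_sd = 1, seed = 6)
  am3 <- amplitude_map(s3)
  expect_lt(max(abs(colMeans(am3$delta_r))), 1e-9)
})

test_that("autocorrelation of a static pure harmonic is cos(k dtheta)", {
  s <- contour_series_from_polar(function(th, t)
    10 * (1 + 0.25 * cos(3 * th * pi / 180)), seq(0, 90, by = 10))
  g <- autocorrelation(amplitude_map(s))
  slice <- g$g[, g$dt_min == 0]
  expect_equal(slice, cos(3 * g$dtheta_deg * pi / 180), tolerance = 1e-3)
  expect_equal(sort(locate_peaks(g)), c(-120, 0, 120))
})

test_that("correlation maps are normalized and point-symmetric", {
  s <- mode_cell(k = 2, a = 0.25, n_frames = 60, rotation_rate = 0.3,
                 mode_noise_sd = 0.5, seed = 12)
  g <- autocorrelation(amplitude_map(s))
  i0 <- which(g$dtheta_deg == 0); j0 <- which(g$dt_min == 0)
  expect_equal(g$g[i0, j0], 1)
  expect_equal(max(g$g), 1)
  # G(-dtheta, -dt) = G(dtheta, dt) exactly (with -180 identified as +180)
  neg <- vapply(g$dtheta_deg, function(d) {
    nd <- (-d) %% 360; if (nd > 180) nd <- nd - 360
    which.min(abs(nd - g$dtheta_deg))
  }, integer(1))
  expect_equal(g$g, g$g[neg, rev(seq_along(g$dt_min))], tolerance = 1e-12)
  expect_warning(autocorrelation(amplitude_map(s), max_lag_min = 1e6),
                 "truncating")
})

test_that("single-mode contours give k maxima spaced 360/k apart", {
  for (k in c(2, 3, 4, 6)) {
    s <- mode_cell(k = k, a = 0.2, n_frames = 40)
    pk <- locate_peaks(autocorrelation(amplitude_map(s)))
    expect_length(pk, k)
    expect_equal(unique(round(diff(pk), 6)), 360 / k)
  }
})

test_that("the ridge slope of a rigidly rotating shape recovers omega", {
  omega <- 0.2
  s <- mode_cell(k = 3, a = 0.3, n_frames = 150, rotation_rate = omega,
                 mode_noise_sd = 0.3, seed = 21)
  g <- autocorrelation(amplitude_map(s))
  sl <- ridge_slope(g, max_lag_min = 250)$slope_deg_min
  expect_lt(abs(sl - omega) / omega, 0.05)
})

test_that("elongate-round-reelongate scripts shift the peak by 90 deg", {
  amp_a <- function(t) if (t <= 790) 0.3 else if (t < 1190) 0.3 * (1190 - t) / 400 else 0
  amp_b <- function(t) if (t < 1200) 0 else 0.3
  rfun <- function(th, t) 12 * (1 + amp_a(t) * cos(2 * th * pi / 180) +
                                  amp_b(t) * cos(2 * (th - 90) * pi / 180))
  s <- contour_series_from_polar(rfun, seq(0, 1990, by = 10))
  g <- autocorrelation(amplitude_map(s), max_lag_min = 1500)
  early <- locate_peaks(g, at_lag_min = 0)
  late_slice <- g$g[, which.min(abs(g$dt_min - 1300))]
  late_pk <- g$dtheta_deg[which.max(late_slice)]
  shift <- min(abs(late_pk - early) %% 180, 180 - abs(late_pk - early) %% 180)
  expect_equal(min(shift), 90, tolerance = 2 / 90)
})

test_that("mode-free noisy contours decorrelate between frames", {
  s <- simulate_cell(cell_sim_params(base_radius = 12, mode_noise_sd = 1,
                                     seed = 9), 200, 10)
  g <- autocorrelation(amplitude_map(s))
  expect_lt(max(abs(g$g[, g$dt_min != 0])), 0.2)
})

test_that("peak detection handles flat slices and matches grid argmax", {
  s <- contour_series_from_polar(function(th, t) rep(5, length(th)),
                                 c(0, 10, 20))
  g <- suppressWarnings(autocorrelation(amplitude_map(s)))
  expect_length(locate_peaks(g), 0)
  # noisy two-fold: detected peak equals exhaustive argmax within one bin
  s2 <- mode_cell(k = 2, a = 0.25, n_frames = 80, mode_noise_sd = 0.8,
                  seed = 31)
  g2 <- autocorrelation(amplitude_map(s2))
  slice <- g2$g[, g2$dt_min == 0]
  grid_argmax <- g2$dtheta_deg[which.max(slice)]
  pk <- locate_peaks(g2)
  expect_true(any(abs(pk - grid_argmax) <= 2))
})
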