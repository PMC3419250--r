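straight_line_traj <- function(speed_um_h, n = 25, dt = 10) {
  tt <- (seq_len(n) - 1) * dt
  structure(data.frame(frame = seq_len(n), time_min = tt,
                       x_um = 0, y_um = tt * speed_um_h / 60),
            gaps = integer(0), class = c("trajectory", "data.frame"))
}

test_that("center tracking reports displacements and flags gaps", {
  s <- contour_series_from_polar(function(th, t) rep(8, length(th)),
                                 c(0, 10, 20, 30))
  tr <- track_centers(s)
  expect_true(all(tr$step_um[-1] == 0))
  expect_length(attr(tr, "gaps"), 0)
  # a missing frame shows up as a flagged gap, not silent interpolation
  s_gap <- contour_series_from_polar(function(th, t) rep(8, length(th)),
                                     c(0, 10, 20, 60, 70))
  expect_equal(attr(track_centers(s_gap), "gaps"), 3L)
  expect_error(track_centers(contour_series_from_polar(
    function(th, t) rep(8, length(th)), 0)), "at least 2")
})

test_that("straight-line speed is exact and sampling-interval consistent", {
  tr <- straight_line_traj(5, n = 25, dt = 5)
  for (dt in c(10, 15, 30))
    expect_equal(mean_velocity(tr, dt)$mean_um_h, 5)
  tr0 <- straight_line_traj(0)
  expect_equal(mean_velocity(tr0, 30)$mean_um_h, 0)
  expect_error(mean_velocity(straight_line_traj(5, n = 3, dt = 5), 30),
               "spans")
})

test_that("persistent-random-walk speed is recovered within 5%", {
  # 1000 replicate walks, 40 velocity samples each, persistence >> dt
  est <- vapply(seq_len(1000), function(i) {
    tr <- simulate_prw(5, persistence_min = 2000, n_steps = 41, dt_min = 30,
                       seed = 20000 + i)
    mean_velocity(tr, 30)$mean_um_h
  }, numeric(1))
  expect_lt(abs(mean(est) - 5) / 5, 0.05)
})

test_that("rotation-only cells stay at the tracking noise floor", {
  s <- mode_cell(k = 3, a = 0.25, n_frames = 13, rotation_rate = 1,
                 base_radius = 10, frame_interval = 10)
  shifted <- contour_series(lapply(s$vertices, function(v)
    sweep(v, 2, c(20, 20), `+`)), s$time_min)
  img <- render_frames(shifted, pixel_size = 0.5, frame_shape = c(80, 80),
                       noise_sd = 0.03, seed = 3)
  # a stationary cell contaminates a temporal-median background (its
  # core is the median), so this assay supplies the known blank level
  tracked <- suppressMessages(segment_sequence(img, background = 0.8))
  v <- mean_velocity(track_centers(tracked), 30)
  expect_lt(v$mean_um_h, 0.5)
})

test_that("deformation histograms are normalized and isotropy is central", {
  p <- cell_sim_params(base_radius = 12, mode_noise_sd = 1, speed = 3,
                       persistence_time = 60, seed = 3)
  s <- simulate_cell(p, 500, 10)
  pdf <- deformation_direction_pdf(s)
  expect_equal(sum(pdf$pdf), 1, tolerance = 1e-12)
  expect_equal(sum(pdf$marginal$mass), 1, tolerance = 1e-12)
  # isotropic cell: single central mode within one bin of zero
  mode_at <- pdf$marginal$d_um[which.max(pdf$marginal$mass)]
  expect_lt(abs(mode_at), 1)
  expect_equal(symmetry_break_offset(pdf), 0)
})

test_that("re-seeding leaves the isotropic deformation PDF invariant", {
  mk <- function(seed) {
    p <- cell_sim_params(base_radius = 12, mode_noise_sd = 1, speed = 3,
                         persistence_time = 60, seed = seed)
    deformation_direction_pdf(simulate_cell(p, 500, 10))
  }
  p1 <- mk(3); p2 <- mk(4)
  nd <- max(nrow(p1$pdf), nrow(p2$pdf))
  pad <- function(x) {
    k <- (nd - nrow(x$pdf)) / 2
    rbind(matrix(0, k, ncol(x$pdf)), x$pdf, matrix(0, k, ncol(x$pdf)))
  }
  tv <- 0.5 * sum(abs(pad(p1) - pad(p2)))
  expect_lt(tv, 0.05)
})

test_that("an aligned protrusion creates the expected off-center sub-peak", {
  p <- cell_sim_params(base_radius = 12, mode_noise_sd = 0.5, speed = 5,
                       persistence_time = 3000, protrusion_amplitude = 8,
                       protrusion_alignment = 1, seed = 11)
  s <- simulate_cell(p, 120, 10)
  pdf <- deformation_direction_pdf(s)
  expect_gte(pdf$n_contours, 55)
  offset <- symmetry_break_offset(pdf)
  expect_lte(abs(offset - 8), 1)
  expect_gt(offset, 0)
})

test_that("speed and protrusion amplitude are jointly recovered on a cohort", {
  speeds <- numeric(10); offsets <- numeric(10)
  for (i in 1:10) {
    p <- cell_sim_params(base_radius = 12, mode_noise_sd = 0.5, speed = 5,
                         persistence_time = 3000, protrusion_amplitude = 8,
                         protrusion_alignment = 1, seed = 100 + i)
    s <- simulate_cell(p, 100, 10)
    tr <- track_centers(s)
    speeds[i] <- mean_velocity(tr, 30)$mean_um_h
    offsets[i] <- symmetry_break_offset(deformation_direction_pdf(s, tr))
  }
  expect_lt(abs(mean(speeds) - 5) / 5, 0.05)
  # a width-60-deg raised-cosine bump of height A sits A/12 above the
  # angular mean, so the planted sub-peak lies at 8 - 8/12 um
  expect_lte(abs(mean(offsets) - (8 - 8 / 12)), 1)
})

test_that("symmetry-break tie between +/- modes prefers the motion direction", {
  # synthetic marginal with equal sub-peaks at +6 and -6 um
  d <- seq(-10.5, 10.5, by = 1)
  mass <- rep(0.002, length(d))
  mass[d == 0.5] <- 0.5
  mass[d == 6.5] <- 0.2; mass[d == -6.5] <- 0.2
  mass <- mass / sum(mass)
  pdf <- structure(list(pdf = matrix(mass, ncol = 1), d_um = d,
                        rel_angle_deg = 0,
                        marginal = data.frame(d_um = d, mass = mass),
                        n_contours = 60, d_bin_um = 1, angle_bin_deg = 10),
                   class = "deformation_pdf")
  expect_equal(symmetry_break_offset(pdf), 6.5)
  # brute-force mode scan agrees on the candidate set
  modes <- d[which(mass > c(0, mass[-length(mass)]) &
                     mass >= c(mass[-1], 0))]
  expect_true(6.5 %in% modes && -6.5 %in% modes)
})

test_that("undirected series raise the documented errors", {
  s <- contour_series_from_polar(function(th, t) rep(8, length(th)),
                                 seq(0, 200, by = 10))
  expect_error(deformation_direction_pdf(s), "no directed frames")
  p <- cell_sim_params(base_radius = 12, speed = 5, persistence_time = 3000,
                       mode_noise_sd = 0.3, seed = 2)
  s2 <- simulate_cell(p, 40, 10)
  pdf <- deformation_direction_pdf(s2)
  expect_error(symmetry_break_offset(pdf, min_contours = 55), "< 55")
})
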