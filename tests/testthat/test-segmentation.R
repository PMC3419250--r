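make_disk_image <- function(radius = 10, center = c(32, 32), px = 0.5,
                            shape = c(128, 128), noise = 0, seed = 1) {
  s <- contour_series_from_polar(function(th, t) rep(radius, length(th)),
                                 0, center = center)
  render_frames(s, pixel_size = px, frame_shape = shape, noise_sd = noise,
                seed = seed)
}

test_that("segmentation recovers the generator mask (IoU >= 0.95)", {
  img <- make_disk_image(noise = 0.05, seed = 7)
  truth <- make_disk_image(noise = 0)$frames[[1]] < 0.5
  mask <- segment_frame(img$frames[[1]], background = 0.8, pixel_size = 0.5)
  iou <- sum(mask & truth) / sum(mask | truth)
  expect_gte(iou, 0.95)
})

test_that("blank and constant frames yield empty masks, not errors", {
  blank <- matrix(0.8, 64, 64)
  expect_warning(m <- segment_frame(blank, background = 0.8, pixel_size = 0.5),
                 "constant")
  expect_false(any(m))
  # background-only noise: everything below the minimum footprint area
  set.seed(2)
  noisy <- matrix(0.8 + rnorm(64 * 64, 0, 0.02), 64, 64)
  expect_warning(m2 <- segment_frame(noisy, background = 0.8,
                                     pixel_size = 0.5), "contrast")
  expect_false(any(m2))
})

test_that("two disjoint cells give exactly two components", {
  s <- contour_series(list(rbind(circle_polygon(6, c(15, 20), 128),
                                 NULL)), 0)
  s2 <- contour_series(list(circle_polygon(6, c(45, 20), 128)), 0)
  img1 <- render_frames(s, pixel_size = 0.5, frame_shape = c(80, 120))
  img2 <- render_frames(s2, pixel_size = 0.5, frame_shape = c(80, 120))
  both <- pmin(img1$frames[[1]], img2$frames[[1]])
  mask <- segment_frame(both, background = 0.8, pixel_size = 0.5)
  expect_equal(max(EBImage::bwlabel(mask)), 2)
})

test_that("extract_contour recovers circle area, perimeter and center", {
  img <- make_disk_image(radius = 10, center = c(15, 15), px = 0.1,
                         shape = c(300, 300))
  ec <- extract_contour(img$frames[[1]] < 0.5, pixel_size = 0.1)
  expect_lt(abs(ec$area_um2 - pi * 100) / (pi * 100), 0.02)
  expect_lt(abs(ec$perimeter_um - 2 * pi * 10) / (2 * pi * 10), 0.02)
  expect_lt(sqrt(sum((ec$center_of_mass - c(15, 15))^2)), 0.5 * 0.1)
  # circularity from the extracted geometry stays below 1 + tolerance
  expect_lte(circularity(ec$area_um2, ec$perimeter_um), 1.02)
})

test_that("interior holes are filled before area and center computation", {
  img <- make_disk_image(radius = 10, center = c(16, 16), px = 0.25,
                         shape = c(128, 128))
  full <- img$frames[[1]] < 0.5
  holed <- full
  holed[60:68, 60:68] <- FALSE
  ec_full <- extract_contour(full, 0.25)
  ec_holed <- extract_contour(holed, 0.25)
  # pixel-count oracle: filled area must match the hole-free mask
  expect_equal(ec_holed$area_um2, ec_full$area_um2)
  expect_equal(ec_holed$center_of_mass, ec_full$center_of_mass)
})

test_that("empty masks raise a distinct no-cell condition", {
  expect_error(extract_contour(matrix(FALSE, 10, 10), 0.5),
               class = "contourdyn_no_cell")
})

test_that("area and perimeter scale correctly with pixel size", {
  img <- make_disk_image()
  m <- img$frames[[1]] < 0.5
  e1 <- extract_contour(m, 0.5)
  e2 <- extract_contour(m, 1.0)
  expect_equal(e2$area_um2, 4 * e1$area_um2)
  expect_equal(e2$perimeter_um, 2 * e1$perimeter_um, tolerance = 1e-9)
})

test_that("adhered_fraction validates and computes per-frame ratios", {
  expect_equal(adhered_fraction(3, 10), 0.3)
  expect_equal(adhered_fraction(c(0, 5), c(10, 10)), c(0, 0.5))
  expect_error(adhered_fraction(11, 10), "exceeds")
  expect_error(adhered_fraction(1, 0), "> 0")
})

test_that("measured adhesion curve converges to the generator plateau", {
  prm <- adhesion_sim_params(5000, 0.7, attachment_halftime = 20,
                             frame_interval = 10, n_frames = 40, seed = 8)
  a <- simulate_adhesion_series(prm)
  frac <- adhered_fraction(a$n_adhered, a$n_total)
  ci <- qbinom(c(0.005, 0.995), 5000, 0.7) / 5000
  late <- frac[a$time_min >= 8 * 20]
  expect_true(all(late >= ci[1] & late <= ci[2]))
})
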