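test_that("peak prominences match the frozen reference values", {
  # reference prominences computed independently with scipy.signal
  y <- c(0.2, 0.5, 1.4, 3.0, 1.9, 0.8, 1.1, 2.2, 5.1, 2.0, 0.6, 0.9, 2.6,
         1.5, 1.2, 0.3)
  pk <- condensia:::find_local_maxima(y)
  expect_equal(pk, c(4L, 9L, 13L))
  prom <- vapply(pk, function(i) condensia:::peak_prominence(y, i), numeric(1))
  expect_equal(prom, c(2.2, 4.8, 2.0))
})

test_that("FWHM of a noiseless Gaussian profile equals 2*sqrt(2*log(2))*sigma", {
  ps <- 0.5
  pos <- seq(0.25, 400, by = ps)
  for (sigma in c(8, 15, 30)) {
    prof <- gaussian_profile(pos, 200, sigma, 1)
    det <- detect_condensations(prof, min_prominence = 0.2)
    expect_equal(nrow(det), 1L)
    expect_equal(det$fwhm_um, 2 * sqrt(2 * log(2)) * sigma, tolerance = 2 * ps /
                   (2 * sqrt(2 * log(2)) * sigma))
    expect_equal(det$position_um, 200, tolerance = ps)
  }
})

test_that("FWHM of a symmetric triangular peak on zero baseline is half its base", {
  ps <- 1
  pos <- seq(0.5, 200, by = ps)
  b <- 60  # base width
  y <- pmax(0, 1 - abs(pos - 100) / (b / 2))
  prof <- structure(list(positions = pos, intensities = y, axis = "major",
                         pixel_size = ps), class = "axial_profile")
  det <- detect_condensations(prof, min_prominence = 0.5)
  expect_equal(nrow(det), 1L)
  expect_equal(det$fwhm_um, b / 2, tolerance = 0.05)
})

test_that("peaks below the prominence threshold are excluded", {
  pos <- seq(0.5, 500, by = 1)
  sigma <- 10
  prof <- gaussian_profile(pos, c(150, 150 + 4 * sigma, 400), c(sigma, sigma, sigma),
                           c(1, 0.9, 0.05))
  det <- detect_condensations(prof, min_prominence = 0.2)
  expect_equal(nrow(det), 2L)
  expect_equal(sort(det$position_um), c(150, 190), tolerance = 2)
})

test_that("scaling condensation amplitudes scales prominences proportionally", {
  gs <- generate_groove_series(groove_series_spec(
    n_timepoints = 1, noise_sd = 0, background_level = 0,
    condensations = data.frame(center_um = c(120, 320), final_length_um = 70,
                               final_width_um = 60, t_mid_h = -20, rate_per_h = 0.5,
                               amp_start = c(0.6, 1.0), amp_end = c(0.6, 1.0)),
    seed = 1))
  f1 <- gs$stack[, , 1]
  c_scale <- 2.5
  p1 <- detect_condensations(axial_profile(f1, gs$roi, "major"), 0.05)
  p2 <- detect_condensations(axial_profile(f1 * c_scale, gs$roi, "major"),
                             0.05 * c_scale)
  expect_equal(p2$prominence, c_scale * p1$prominence, tolerance = 1e-10)
})

test_that("axial profiles average correctly over the perpendicular axis", {
  roi <- groove_roi(1, 1, 200, 50, nominal_width = 50, pixel_size = 1)
  # uniform frame -> flat profile at that level
  u <- matrix(0.37, 50, 200)
  prof <- axial_profile(u, roi, "major")
  expect_true(all(abs(prof$intensities - 0.37) < 1e-12))
  expect_equal(length(prof$intensities), 200L)
  expect_equal(prof$positions[1], 0.5)
  # Gaussian ridge at x0: argmax within 1 px
  xs <- matrix(rep(1:200 - 0.5, each = 50), 50, 200)  # column positions in um
  ridge <- exp(-(xs - 77.5)^2 / (2 * 9^2))
  prof2 <- axial_profile(ridge, roi, "major")
  expect_lt(abs(prof2$positions[which.max(prof2$intensities)] - 77.5), 1)
  # noise averaging: profile variance ~ noise_sd^2 / n_rows
  set.seed(3)
  nz <- matrix(rnorm(50 * 200, sd = 0.1), 50, 200)
  prof3 <- axial_profile(nz, roi, "major")
  expect_equal(var(prof3$intensities), 0.1^2 / 50, tolerance = 0.3)
  # ROI outside the image errors
  expect_error(axial_profile(u, groove_roi(1, 1, 300, 50), "major"), "outside")
})

test_that("length and width are recovered for isotropic and anisotropic blobs", {
  mk <- function(L, W) generate_groove_series(groove_series_spec(
    groove_width = 100, groove_length = 400, n_timepoints = 1, noise_sd = 0.005,
    condensations = data.frame(center_um = 200, final_length_um = L,
                               final_width_um = W, t_mid_h = -20, rate_per_h = 0.5,
                               amp_start = 1, amp_end = 1),
    seed = 4))
  iso <- mk(60, 60)
  m <- measure_groove_frame(iso$stack[, , 1], iso$roi)
  expect_equal(nrow(m), 1L)
  expect_equal(m$width_um / m$length_um, 1, tolerance = 0.05)
  aniso <- mk(80, 40)
  m2 <- measure_groove_frame(aniso$stack[, , 1], aniso$roi)
  expect_equal(m2$length_um, 80, tolerance = 0.05 * 80)
  expect_equal(m2$width_um, 40, tolerance = 0.05 * 40)
})

test_that("measured width is clipped at the groove's short-axis extent", {
  gs <- generate_groove_series(groove_series_spec(
    groove_width = 50, groove_length = 300, n_timepoints = 1, noise_sd = 0,
    condensations = data.frame(center_um = 150, final_length_um = 80,
                               final_width_um = 50, t_mid_h = -20, rate_per_h = 0.5,
                               amp_start = 1, amp_end = 1),
    seed = 5))
  m <- measure_groove_frame(gs$stack[, , 1], gs$roi)
  expect_lte(m$width_um, gs$roi$minor_extent_um)
  expect_true(m$clipped_width)
})

test_that("aspect ratio follows the constrained / unconstrained convention", {
  meas <- data.frame(position_um = c(100, 200), length_um = c(40, 40),
                     width_um = c(20, 50), prominence = 1, height = 1,
                     clipped_length = FALSE, clipped_width = FALSE,
                     width_missing = FALSE)
  roi100 <- groove_roi(1, 1, 500, 100, nominal_width = 100)
  dm <- derive_metrics(meas, roi100)
  expect_equal(dm$measurements$aspect_ratio, c(2.0, 0.8))  # constrained: can be < 1
  roi300 <- groove_roi(1, 1, 500, 300, nominal_width = 300)
  dm300 <- derive_metrics(meas, roi300)
  expect_equal(dm300$measurements$aspect_ratio, c(2.0, 1.25))  # longest / shortest
  expect_true(all(dm300$measurements$aspect_ratio >= 1))
  roitcp <- groove_roi(1, 1, 500, 400, nominal_width = "TCP")
  expect_equal(derive_metrics(meas, roitcp)$measurements$aspect_ratio[2], 1.25)
  # density: 18 condensations in a 500 um groove -> 3.6 per 100 um
  meas18 <- meas[rep(1, 18), ]
  expect_equal(derive_metrics(meas18, roi100)$count_per_100um, 3.6)
})

test_that("zero or missing width flags the aspect ratio as missing", {
  meas <- data.frame(position_um = 100, length_um = 40, width_um = NA_real_,
                     prominence = 1, height = 1, clipped_length = FALSE,
                     clipped_width = NA, width_missing = TRUE)
  dm <- derive_metrics(meas, groove_roi(1, 1, 500, 100, nominal_width = 100))
  expect_true(is.na(dm$measurements$aspect_ratio))
})

test_that("marker-positive fractions count nuclei above the marker threshold", {
  set.seed(8)
  nuc <- matrix(0, 60, 60)
  pts <- cbind(row = seq(10, 50, length.out = 10), col = seq(8, 52, length.out = 10))
  nuc[round(pts)] <- 1
  marker <- matrix(0, 60, 60)
  marker[round(pts[1:5, , drop = FALSE])] <- 1  # 5 of 10 marked
  region <- matrix(TRUE, 60, 60)
  expect_equal(marker_positive_fraction(nuc, marker, region, 0.5, 0.5), 0.5)
  allm <- matrix(1, 60, 60)
  expect_equal(marker_positive_fraction(nuc, allm, region, 0.5, 0.5), 1.0)
  none <- matrix(0, 60, 60)
  expect_equal(marker_positive_fraction(nuc, none, region, 0.5, 0.5), 0.0)
  empty_region <- matrix(FALSE, 60, 60)
  expect_warning(v <- marker_positive_fraction(nuc, marker, empty_region, 0.5, 0.5),
                 "no nuclei")
  expect_true(is.na(v))
})
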