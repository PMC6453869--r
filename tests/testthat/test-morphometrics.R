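test_that("moment ellipse matches analytic axes and eccentricity", {
  # disk: equal axes, eccentricity ~ 0
  disk <- rasterize_disk(30)
  e <- ellipse_from_moments(disk)
  expect_lt(e$eccentricity, 0.05)
  expect_equal(e$major_axis, 60, tolerance = 0.02)
  # 2:1 ellipse: e = sqrt(3)/2
  ell <- rasterize_ellipse(40, 20)
  e2 <- ellipse_from_moments(ell)
  expect_equal(e2$eccentricity, sqrt(3) / 2, tolerance = 0.02)
  expect_equal(e2$major_axis, 80, tolerance = 0.02)
  expect_equal(e2$minor_axis, 40, tolerance = 0.02)
  # thin 100 x 2 bar: eccentricity -> 1
  bar <- matrix(FALSE, 10, 110); bar[5:6, 6:105] <- TRUE
  expect_gt(ellipse_from_moments(bar)$eccentricity, 0.99)
  expect_error(ellipse_from_moments(matrix(FALSE, 5, 5)), "empty")
})

test_that("roundness is 1 for a disk, 0.5 for a 2:1 ellipse, small for a thin bar", {
  disk <- rasterize_disk(50)
  e <- ellipse_from_moments(disk)
  expect_equal(roundness(sum(disk), e$major_axis), 1.0, tolerance = 0.03)
  # continuous substitution: Area = 2*pi*b^2, Major = 4b -> 0.5 exactly
  b <- 10
  expect_equal(roundness(2 * pi * b^2, 4 * b), 0.5)
  # rasterized 100 x 4 rectangle via its moment major axis
  rect <- matrix(FALSE, 12, 108); rect[5:8, 5:104] <- TRUE
  er <- ellipse_from_moments(rect)
  expect_lt(roundness(sum(rect), er$major_axis), 0.1)
  expect_error(roundness(0, 10), "positive")
})

test_that("roughness is 1 for convex regions and below 1 for concave ones", {
  rect <- matrix(FALSE, 70, 130); rect[6:65, 6:125] <- TRUE
  expect_equal(roughness(rect), 1.0, tolerance = 0.02)
  disk <- rasterize_disk(50)
  expect_equal(roughness(disk), 1.0, tolerance = 0.02)
  # plus / cross shape is concave
  plus <- matrix(FALSE, 100, 100)
  plus[40:60, 10:90] <- TRUE
  plus[10:90, 40:60] <- TRUE
  expect_lt(roughness(plus), 0.9)
  # single pixel: defined as convex
  px <- matrix(FALSE, 5, 5); px[3, 3] <- TRUE
  expect_equal(roughness(px), 1)
})

test_that("star roughness agrees with the independent polygon oracle", {
  # 4-armed star with 2:1 arm geometry: outer radius 60, inner 30
  ang_out <- 2 * pi * (0:3) / 4 + 0.3
  ang_in <- ang_out + pi / 4
  xs <- as.vector(rbind(60 * cos(ang_out), 30 * cos(ang_in))) + 70
  ys <- as.vector(rbind(60 * sin(ang_out), 30 * sin(ang_in))) + 70
  orc <- polygon_oracle(xs, ys)
  mask <- rasterize_polygon(xs, ys)
  expect_gt(sum(mask), 500)
  expect_equal(roughness(mask), orc$roughness, tolerance = 0.05)
  expect_lt(roughness(mask), 1)
})

test_that("occupancy matches analytic values for disk, segment and half-disk", {
  disk <- rasterize_disk(40)
  expect_equal(occupancy(disk), 1.0, tolerance = 0.03)
  # 1-px straight segment of length d: ~ 4 / (pi * d)
  d <- 60
  seg <- matrix(FALSE, 9, d + 9); seg[5, 5:(5 + d)] <- TRUE
  expect_equal(occupancy(seg), 4 / (pi * d), tolerance = 0.1)
  # half-disk: diametral circle is the full disk, half filled
  half <- rasterize_disk(40)
  ctr <- 40 + 3 + 1
  half[(ctr + 1):nrow(half), ] <- FALSE
  expect_equal(occupancy(half), 0.5, tolerance = 0.03)
  # degenerate cases
  px <- matrix(FALSE, 5, 5); px[3, 3] <- TRUE
  expect_warning(v <- occupancy(px), "single-pixel")
  expect_true(is.na(v))
})

test_that("mean 4-nearest-neighbour distance follows the worked examples", {
  # square corners (side 2) + centre
  pts <- rbind(c(0, 0), c(2, 0), c(0, 2), c(2, 2), c(1, 1))
  d <- mean_nn_distance(pts, k = 4)
  expect_equal(d[5], sqrt(2))                       # centre: four half-diagonals
  expect_equal(d[1], (sqrt(2) + 2 + 2 + 2 * sqrt(2)) / 4)  # corner
  # 3 collinear points: middle averages its 2 available neighbours
  col3 <- cbind(c(0, 1, 2), c(0, 0, 0))
  expect_equal(mean_nn_distance(col3, k = 4)[2], 1)
  expect_warning(v <- mean_nn_distance(cbind(1, 1), k = 4), "single")
  expect_true(is.na(v))
})

test_that("descriptor table has one row per label and scales with calibration", {
  sc <- generate_micromass_scene(micromass_scene_spec(n_objects = 7, seed = 71))
  d1 <- descriptor_table(sc$labels, calibration = 1)
  expect_equal(nrow(d1), 7L)
  expect_true(all(d1$n_condensations == 7))
  expect_equal(attr(d1, "n_condensations"), 7L)
  d2 <- descriptor_table(sc$labels, calibration = 2)
  expect_equal(d2$area, 4 * d1$area)
  for (m in c("perimeter", "minor_axis", "major_axis", "distance"))
    expect_equal(d2[[m]], 2 * d1[[m]])
  for (m in c("eccentricity", "aspect_ratio", "roundness", "roughness", "occupancy"))
    expect_equal(d2[[m]], d1[[m]])
  # empty label map -> empty table
  d0 <- descriptor_table(new_label_map(matrix(0L, 10, 10)))
  expect_equal(nrow(d0), 0L)
  expect_equal(attr(d0, "n_condensations"), 0L)
})

test_that("segmented descriptor areas agree with generator ground truth", {
  sc <- generate_micromass_scene(micromass_scene_spec(n_objects = 6, seed = 81,
                                                      area_range = c(400, 800)))
  labs <- segment_micromass(sc$image)
  expect_equal(n_objects(labs), 6L)
  d <- descriptor_table(labs)
  # match segmented objects to truth by centroid proximity
  regs <- condensia:::region_coords(labs)
  for (i in seq_along(regs)) {
    cy <- mean(regs[[i]][, "row"]); cx <- mean(regs[[i]][, "col"])
    j <- which.min((sc$truth$cy_px - cy)^2 + (sc$truth$cx_px - cx)^2)
    expect_lt(abs(d$area[i] - sc$truth$area_px[j]) / sc$truth$area_px[j], 0.05)
  }
})

test_that("dimensionless descriptors are rotation invariant within tolerance", {
  a <- rasterize_ellipse(50, 25, 0)
  b <- rasterize_ellipse(50, 25, 37 * pi / 180)
  da <- suppressWarnings(descriptor_table(mask_label_map(a)))
  db <- suppressWarnings(descriptor_table(mask_label_map(b)))
  for (m in c("area", "perimeter", "eccentricity", "roundness", "roughness",
              "occupancy")) {
    expect_lt(abs(da[[m]] - db[[m]]) / abs(da[[m]]), 0.03)
  }
})

test_that("bounded descriptors stay within [0, 1] plus estimator tolerance", {
  for (s in 1:5) {
    sc <- generate_micromass_scene(
      micromass_scene_spec(n_objects = 6, seed = 100 + s,
                           shape_family = if (s %% 2) "ellipse" else "branched",
                           axis_ratio_range = c(1, 3)))
    d <- descriptor_table(sc$labels)
    expect_true(all(d$eccentricity >= 0 & d$eccentricity <= 1.02))
    expect_true(all(d$roughness > 0 & d$roughness <= 1.02))
    expect_true(all(d$occupancy > 0 & d$occupancy <= 1.02))
    expect_true(all(d$aspect_ratio >= 1))
  }
})

test_that("standardization gives zero mean, unit sd, and is idempotent", {
  sc <- generate_micromass_scene(micromass_scene_spec(n_objects = 10, seed = 91))
  d <- descriptor_table(sc$labels)
  z <- standardize(d, columns = setdiff(descriptor_names(), "n_condensations"))
  expect_true(all(abs(colMeans(z)) < 1e-9))
  expect_true(all(abs(apply(z, 2, sd) - 1) < 1e-9))
  z2 <- standardize(z)
  expect_equal(z2, z, ignore_attr = TRUE, tolerance = 1e-12)
  # constant column is an error naming the descriptor
  d$occupancy <- 0.5
  expect_error(standardize(d), "occupancy")
})

test_that("discriminant weights are antisymmetric under class swap", {
  pops <- generate_two_class_shapes(
    micromass_scene_spec(n_objects = 5, axis_ratio_range = c(1, 1.3)),
    micromass_scene_spec(n_objects = 5, axis_ratio_range = c(2, 3)),
    n_per_class = 30, seed = 23)
  f1 <- fit_discriminant(pops$a, pops$b)
  f2 <- fit_discriminant(pops$b, pops$a)
  expect_equal(f2$weights, -f1$weights, tolerance = 1e-8)
  expect_identical(f2$ranking, f1$ranking)
  expect_equal(sort(f1$ranking), sort(descriptor_names()))
  expect_error(fit_discriminant(pops$a[1, , drop = FALSE], pops$b), "at least 2")
})

test_that("discriminant direction agrees with the reference LDA implementation", {
  skip_if_not_installed("MASS")
  set.seed(5)
  p <- 6; n <- 80
  xa <- matrix(rnorm(n * p), n, p) ; xa[, 2] <- xa[, 2] + 1.5
  xb <- matrix(rnorm(n * p), n, p)
  colnames(xa) <- colnames(xb) <- paste0("v", 1:p)
  fit <- fit_discriminant(as.data.frame(xa), as.data.frame(xb),
                          descriptors = colnames(xa))
  z <- standardize(rbind(xa, xb))
  ref <- MASS::lda(z, grouping = rep(c("a", "b"), each = n))
  cosang <- abs(sum(fit$weights * ref$scaling)) /
    (sqrt(sum(fit$weights^2)) * sqrt(sum(ref$scaling^2)))
  expect_gt(cosang, 0.999)
})

test_that("null classes give low separation; a single shifted descriptor ranks first", {
  set.seed(7)
  p <- 11; n <- 200
  nm <- descriptor_names()
  xa <- matrix(rnorm(n * p), n, p); xb <- matrix(rnorm(n * p), n, p)
  colnames(xa) <- colnames(xb) <- nm
  f0 <- fit_discriminant(as.data.frame(xa), as.data.frame(xb), descriptors = nm)
  expect_lt(f0$separation, 0.5)
  xa[, "area"] <- xa[, "area"] + 3
  f1 <- fit_discriminant(as.data.frame(xa), as.data.frame(xb), descriptors = nm)
  expect_identical(f1$ranking[1], "area")
})
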