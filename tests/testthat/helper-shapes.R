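# Shape fixtures and an independent continuous-geometry oracle.
# Everything here is computed from polygon vertex lists with closed-form
# formulas (shoelace area, Green's-theorem second moments, hull
# perimeter), never through the package's pixel-based code paths.

# Rasterize a polygon by even-odd scanline filling; pixel centres sit at
# integer (row = y, col = x) coordinates.
rasterize_polygon <- function(xs, ys, pad = 3) {
  xmin <- floor(min(xs)) - pad; ymin <- floor(min(ys)) - pad
  xs <- xs - xmin + 1; ys <- ys - ymin + 1
  W <- ceiling(max(xs)) + pad; H <- ceiling(max(ys)) + pad
  mask <- matrix(FALSE, H, W)
  n <- length(xs)
  for (r in seq_len(H)) {
    xint <- numeric()
    j <- n
    for (i in seq_len(n)) {
      if ((ys[j] <= r) != (ys[i] <= r)) {
        xint <- c(xint, xs[j] + (r - ys[j]) / (ys[i] - ys[j]) * (xs[i] - xs[j]))
      }
      j <- i
    }
    xint <- sort(xint)
    if (length(xint) >= 2) {
      for (k in seq(1, length(xint) - 1, by = 2)) {
        c0 <- ceiling(xint[k]); c1 <- floor(xint[k + 1])
        if (c0 <= c1) mask[r, c0:c1] <- TRUE
      }
    }
  }
  mask
}

rasterize_disk <- function(radius, pad = 3) {
  n <- 2 * (radius + pad) + 1
  ctr <- radius + pad + 1
  xy <- expand.grid(r = seq_len(n), c = seq_len(n))
  matrix((xy$r - ctr)^2 + (xy$c - ctr)^2 <= radius^2, n, n)
}

rasterize_ellipse <- function(a, b, theta = 0, pad = 3) {
  n <- 2 * ceiling(a + pad) + 1
  ctr <- ceiling(a + pad) + 1
  xy <- expand.grid(r = seq_len(n), c = seq_len(n))
  u <- (xy$c - ctr) * cos(theta) + (xy$r - ctr) * sin(theta)
  v <- -(xy$c - ctr) * sin(theta) + (xy$r - ctr) * cos(theta)
  matrix((u / a)^2 + (v / b)^2 <= 1, n, n)
}

regular_polygon <- function(n_sides, R, rot = 0) {
  ang <- rot + 2 * pi * (seq_len(n_sides) - 1) / n_sides
  list(xs = R * cos(ang), ys = R * sin(ang))
}

# Closed-form polygon properties (continuous geometry).
polygon_oracle <- function(xs, ys) {
  n <- length(xs)
  i2 <- c(seq_len(n)[-1], 1L)
  cross <- xs * ys[i2] - xs[i2] * ys
  A <- sum(cross) / 2
  if (A < 0) { xs <- rev(xs); ys <- rev(ys)
    i2 <- c(seq_len(n)[-1], 1L); cross <- xs * ys[i2] - xs[i2] * ys; A <- -A }
  cx <- sum((xs + xs[i2]) * cross) / (6 * A)
  cy <- sum((ys + ys[i2]) * cross) / (6 * A)
  Ix <- sum((ys^2 + ys * ys[i2] + ys[i2]^2) * cross) / 12
  Iy <- sum((xs^2 + xs * xs[i2] + xs[i2]^2) * cross) / 12
  Ixy <- sum((xs * ys[i2] + 2 * xs * ys + 2 * xs[i2] * ys[i2] + xs[i2] * ys) * cross) / 24
  uxx <- Iy / A - cx^2; uyy <- Ix / A - cy^2; uxy <- Ixy / A - cx * cy
  common <- sqrt((uxx - uyy)^2 + 4 * uxy^2)
  l1 <- (uxx + uyy + common) / 2; l2 <- (uxx + uyy - common) / 2
  major <- 4 * sqrt(l1); minor <- 4 * sqrt(max(l2, 0))
  per <- sum(sqrt((xs[i2] - xs)^2 + (ys[i2] - ys)^2))
  h <- chull(xs, ys)
  hx <- xs[h]; hy <- ys[h]
  h2 <- c(seq_along(h)[-1], 1L)
  hull_per <- sum(sqrt((hx[h2] - hx)^2 + (hy[h2] - hy)^2))
  # occupancy only when the polygon provably sits inside its diametral circle
  D <- outer(xs, xs, "-")^2 + outer(ys, ys, "-")^2
  ij <- which(D == max(D), arr.ind = TRUE)[1, ]
  r <- sqrt(max(D)) / 2
  ocx <- (xs[ij[1]] + xs[ij[2]]) / 2; ocy <- (ys[ij[1]] + ys[ij[2]]) / 2
  contained <- all((xs - ocx)^2 + (ys - ocy)^2 <= r^2 + 1e-6)
  list(area = A, perimeter = per, convex_perimeter = hull_per,
       major_axis = major, minor_axis = minor,
       eccentricity = sqrt(max(1 - (minor / major)^2, 0)),
       roundness = 4 * A / (pi * major^2),
       roughness = hull_per / per,
       occupancy = if (contained) A / (pi * r^2) else NA_real_)
}

# Label map from a single logical mask (ground-truth labelling).
mask_label_map <- function(mask) {
  new_label_map(matrix(as.integer(mask), nrow(mask), ncol(mask)))
}

# Synthetic 1-D Gaussian profile as an axial_profile object.
gaussian_profile <- function(positions, centers, sigmas, amps, baseline = 0) {
  y <- rep(baseline, length(positions))
  for (i in seq_along(centers))
    y <- y + amps[i] * exp(-(positions - centers[i])^2 / (2 * sigmas[i]^2))
  structure(list(positions = positions, intensities = y, axis = "major",
                 pixel_size = positions[2] - positions[1]),
            class = "axial_profile")
}
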