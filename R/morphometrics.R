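#' The eleven condensation shape descriptors
#'
#' Column names of the descriptor set, in canonical order: `area`,
#' `perimeter`, `eccentricity`, `minor_axis`, `major_axis`,
#' `aspect_ratio`, `roundness`, `n_condensations`, `roughness`,
#' `distance`, `occupancy`.
#' @return Character vector of length 11.
#' @export
descriptor_names <- function() {
  c("area", "perimeter", "eccentricity", "minor_axis", "major_axis",
    "aspect_ratio", "roundness", "n_condensations", "roughness",
    "distance", "occupancy")
}

## Accept a region as a logical mask or a 2-column (row, col) matrix.
as_region_coords <- function(region) {
  if (is.matrix(region) && ncol(region) == 2L && !is.logical(region))
    return(cbind(row = region[, 1], col = region[, 2]))
  if (is.logical(region) || all(region %in% c(0, 1))) {
    idx <- which(region != 0)
    if (length(idx) == 0L) stop("empty region")
    return(cbind(row = ((idx - 1L) %% nrow(region)) + 1L,
                 col = ((idx - 1L) %/% nrow(region)) + 1L))
  }
  stop("region must be a logical mask or a 2-column (row, col) matrix")
}

#' Moment-equivalent ellipse of a region
#'
#' Axis lengths and eccentricity of the ellipse with the same normalized
#' second central moments as the region (the regionprops convention,
#' including the 1/12 per-pixel variance correction). Eccentricity is the
#' ratio of the distance between the foci to the major axis length: 0 for
#' a circle, approaching 1 for a line segment.
#'
#' @param region logical mask or 2-column (row, col) pixel matrix.
#' @return List with `major_axis`, `minor_axis`, `eccentricity`,
#'   `orientation` (radians) and `centroid` (`c(x, y)` = `c(col, row)`).
#' @export
ellipse_from_moments <- function(region) {
  p <- as_region_coords(region)
  if (nrow(p) < 1L) stop("empty region")
  x <- p[, "col"]; y <- p[, "row"]
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  uxx <- sum((x - mx)^2) / n + 1 / 12
  uyy <- sum((y - my)^2) / n + 1 / 12
  uxy <- sum((x - mx) * (y - my)) / n
  common <- sqrt((uxx - uyy)^2 + 4 * uxy^2)
  major <- 2 * sqrt(2) * sqrt(uxx + uyy + common)
  minor <- 2 * sqrt(2) * sqrt(pmax(uxx + uyy - common, 0))
  ecc <- sqrt(pmax(1 - (minor / major)^2, 0))
  theta <- 0.5 * atan2(2 * uxy, uxx - uyy)
  list(major_axis = major, minor_axis = minor, eccentricity = ecc,
       orientation = theta, centroid = c(x = mx, y = my))
}

## Traced boundary of a single region as an (x, y) polygon through pixel
## centres, ordered. Returns NULL for regions too small to trace.
region_contour <- function(p) {
  r0 <- min(p[, "row"]); c0 <- min(p[, "col"])
  sub <- matrix(0, max(p[, "row"]) - r0 + 3L, max(p[, "col"]) - c0 + 3L)
  sub[cbind(p[, "row"] - r0 + 2L, p[, "col"] - c0 + 2L)] <- 1
  oc <- EBImage::ocontour(t(sub))  # EBImage is [x, y]; transpose so dim1 = x
  if (length(oc) == 0L) return(NULL)
  ct <- oc[[1L]]
  if (nrow(ct) < 3L) return(NULL)
  ## 0-based within padded submask -> image coordinates
  cbind(x = ct[, 1L] + c0 - 1L, y = ct[, 2L] + r0 - 1L)
}

## Boundary perimeter and convex-hull perimeter of one region.
## The traced pixel contour is smoothed with a circular moving average
## (window `smooth`) before measuring, which removes the staircase bias
## of chain-code perimeters (raw tracing overestimates a circle's
## circumference by ~5%). The hull of the smoothed contour keeps
## convex-perimeter <= perimeter exactly.
region_perimeters <- function(p, smooth = 5L) {
  ct <- region_contour(p)
  if (is.null(ct)) {
    ## tiny region: treat as convex, side length from its pixel count
    n <- nrow(p)
    return(list(perimeter = 4 * sqrt(n), convex_perimeter = 4 * sqrt(n),
                traceable = FALSE))
  }
  sc <- smooth_closed_contour(ct, smooth)
  per <- polygon_perimeter(sc)
  hull <- sc[chull(sc), , drop = FALSE]
  list(perimeter = per, convex_perimeter = polygon_perimeter(hull),
       traceable = TRUE)
}

#' Roundness of a region
#'
#' `4 * Area / (pi * MajorAxis^2)` with the major axis taken from the
#' moment-equivalent ellipse. 1.0 indicates a perfect circle; values
#' approach 0 for increasingly elongated shapes.
#'
#' @param area region area (px^2 or um^2).
#' @param major_axis moment-ellipse major axis length (same length unit).
#' @return Dimensionless roundness.
#' @export
roundness <- function(area, major_axis) {
  if (any(area <= 0) || any(major_axis <= 0))
    stop("area and major_axis must be positive")
  4 * area / (pi * major_axis^2)
}

#' Boundary roughness of a region
#'
#' Convex perimeter divided by perimeter: 1 for a convex object, below 1
#' for objects with irregular (non-convex) boundaries. Computed from the
#' traced boundary polygon; regions too small to trace (single pixels,
#' short lines) are defined as convex (roughness 1).
#'
#' @param region logical mask or 2-column (row, col) pixel matrix.
#' @return Dimensionless roughness in `(0, 1]`.
#' @export
roughness <- function(region) {
  p <- as_region_coords(region)
  pr <- region_perimeters(p)
  if (!pr$traceable) return(1)
  pr$convex_perimeter / pr$perimeter
}

#' Occupancy of the circumscribing circle
#'
#' The circle whose diameter joins the two most distant pixels of the
#' region is constructed; occupancy is the fraction of that circle's
#' pixels that belong to the region. Close to 1 for a filled disk, about
#' `4 / (pi * d)` for a thin segment of length `d`.
#'
#' @param region logical mask or 2-column (row, col) pixel matrix
#'   (>= 2 pixels).
#' @return Dimensionless occupancy in `(0, 1]` (up to discretization).
#' @export
occupancy <- function(region) {
  p <- as_region_coords(region)
  if (nrow(p) < 2L) {
    warning("occupancy undefined for a single-pixel region")
    return(NA_real_)
  }
  x <- p[, "col"]; y <- p[, "row"]
  ## farthest pair: restrict to hull vertices when the region is large
  cand <- if (nrow(p) > 400L) {
    h <- unique(p[chull(x, y), , drop = FALSE])
    h
  } else p
  hx <- cand[, "col"]; hy <- cand[, "row"]
  d2 <- outer(hx, hx, "-")^2 + outer(hy, hy, "-")^2
  ij <- which(d2 == max(d2), arr.ind = TRUE)[1L, ]
  d <- sqrt(max(d2))
  if (d == 0) stop("degenerate region: all pixels coincident")
  cx <- (hx[ij[1]] + hx[ij[2]]) / 2
  cy <- (hy[ij[1]] + hy[ij[2]]) / 2
  ## discretization correction: the extreme pixel centres sit on average
  ## about a quarter pixel inside the continuous extremes at each end
  r <- d / 2 + 0.25
  inside <- sum((x - cx)^2 + (y - cy)^2 <= r^2)
  gx <- seq(floor(cx - r), ceiling(cx + r))
  gy <- seq(floor(cy - r), ceiling(cy + r))
  total <- sum(outer(gy - cy, gx - cx, function(a, b) a^2 + b^2) <= r^2)
  inside / total
}

#' Mean distance to the 4 nearest neighbouring condensations
#'
#' For each region, the mean Euclidean centroid-to-centroid distance to
#' its `k` nearest neighbours. When fewer than `k` neighbours exist the
#' mean is taken over all available neighbours; a single region yields
#' `NA` with a warning.
#'
#' @param centroids numeric matrix, one row per region, columns `(x, y)`.
#' @param k number of neighbours to average over (default 4).
#' @return Numeric vector, one value per region.
#' @export
mean_nn_distance <- function(centroids, k = 4L) {
  n <- nrow(centroids)
  if (is.null(n) || n < 1L) stop("no centroids given")
  if (n == 1L) {
    warning("nearest-neighbour distance undefined for a single region")
    return(NA_real_)
  }
  D <- as.matrix(dist(centroids))
  vapply(seq_len(n), function(i) {
    d <- sort(D[i, -i])
    mean(d[seq_len(min(k, length(d)))])
  }, numeric(1))
}

#' Shape descriptor table for a segmented image
#'
#' Computes the eleven shape descriptors for every labelled condensation:
#' area, perimeter, eccentricity, minor/major moment-ellipse axes, aspect
#' ratio (major/minor, always >= 1), roundness, number of condensations
#' in the image, boundary roughness, mean 4-nearest-neighbour centroid
#' distance and circumscribed-circle occupancy.
#'
#' Lengths scale linearly and areas quadratically with the pixel
#' calibration; dimensionless descriptors are unaffected.
#'
#' @param labels a `label_map` (or integer matrix of labels).
#' @param calibration pixel size in um/px (default 1 reports pixel units).
#' @return A data frame of class `descriptor_table`, one row per
#'   condensation, columns `label_id` plus [descriptor_names()], with
#'   attribute `n_condensations`.
#' @examples
#' sc <- generate_micromass_scene(micromass_scene_spec(n_objects = 5, seed = 2))
#' d <- descriptor_table(sc$labels)
#' d$roundness
#' @export
descriptor_table <- function(labels, calibration = 1) {
  stopifnot(calibration > 0)
  regions <- region_coords(labels)
  n <- length(regions)
  if (n == 0L) {
    out <- data.frame(label_id = integer())
    for (nm in descriptor_names()) out[[nm]] <- numeric()
    attr(out, "n_condensations") <- 0L
    class(out) <- c("descriptor_table", class(out))
    return(out)
  }
  cents <- t(vapply(regions, function(p) c(mean(p[, "col"]), mean(p[, "row"])),
                    numeric(2)))
  dist4 <- if (n >= 2L) mean_nn_distance(cents, 4L) else {
    warning("single condensation: distance descriptor is NA")
    NA_real_
  }
  rows <- lapply(seq_len(n), function(i) {
    p <- regions[[i]]
    ell <- ellipse_from_moments(p)
    pr <- region_perimeters(p)
    occ <- if (nrow(p) >= 2L) occupancy(p) else {
      warning("single-pixel region: occupancy is NA"); NA_real_
    }
    data.frame(
      label_id = i,
      area = nrow(p) * calibration^2,
      perimeter = pr$perimeter * calibration,
      eccentricity = ell$eccentricity,
      minor_axis = ell$minor_axis * calibration,
      major_axis = ell$major_axis * calibration,
      aspect_ratio = ell$major_axis / ell$minor_axis,
      roundness = roundness(nrow(p), ell$major_axis),
      n_condensations = n,
      roughness = if (pr$traceable) pr$convex_perimeter / pr$perimeter else 1,
      distance = dist4[i] * calibration,
      occupancy = occ)
  })
  out <- do.call(rbind, rows)
  attr(out, "n_condensations") <- n
  class(out) <- c("descriptor_table", class(out))
  out
}

#' Write a descriptor table as CSV
#'
#' Columns are written in the canonical order `area, perimeter,
#' eccentricity, minor_axis, major_axis, aspect_ratio, roundness,
#' n_condensations, roughness, distance, occupancy` (preceded by
#' `label_id` and followed by any extra columns such as `class`).
#'
#' @param table a `descriptor_table`.
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
write_descriptor_csv <- function(table, path) {
  extra <- setdiff(names(table), c("label_id", descriptor_names()))
  cols <- c("label_id", descriptor_names(), extra)
  write.csv(table[, cols, drop = FALSE], path, row.names = FALSE)
  invisible(path)
}
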