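#' Groove region of interest
#'
#' A rectangular groove region in image coordinates (1-based, inclusive;
#' `x` = column, `y` = row) with its nominal width class, orientation and
#' pixel calibration. The long (major) axis of the groove must be at
#' least as long as the short (minor) axis.
#'
#' @param x0,y0,x1,y1 rectangle bounds (1-based, inclusive).
#' @param nominal_width groove width class in um (25, 50, 100, 200, 300)
#'   or `"TCP"` for an unconstrained tissue-culture-plate field.
#' @param long_axis `"horizontal"` (major axis along x) or `"vertical"`.
#' @param pixel_size calibration in um/px.
#' @return An object of class `groove_roi`.
#' @export
groove_roi <- function(x0, y0, x1, y1,
                       nominal_width = 100,
                       long_axis = c("horizontal", "vertical"),
                       pixel_size = 1) {
  long_axis <- match.arg(long_axis)
  if (pixel_size <= 0) stop("calibration error: pixel_size must be > 0 um/px")
  stopifnot(x1 >= x0, y1 >= y0)
  wx <- x1 - x0 + 1L; wy <- y1 - y0 + 1L
  major_px <- if (long_axis == "horizontal") wx else wy
  minor_px <- if (long_axis == "horizontal") wy else wx
  if (major_px < minor_px)
    stop("long-axis extent must be at least the short-axis extent")
  if (!(identical(nominal_width, "TCP") ||
        (is.numeric(nominal_width) && nominal_width > 0)))
    stop("nominal_width must be a positive width in um or \"TCP\"")
  structure(list(x0 = as.integer(x0), y0 = as.integer(y0),
                 x1 = as.integer(x1), y1 = as.integer(y1),
                 nominal_width = nominal_width, long_axis = long_axis,
                 pixel_size = pixel_size,
                 major_extent_um = major_px * pixel_size,
                 minor_extent_um = minor_px * pixel_size),
            class = "groove_roi")
}

## Crop a frame to the ROI and orient it so rows = minor axis (y),
## cols = major axis (x).
crop_oriented <- function(frame, roi) {
  if (roi$y1 > nrow(frame) || roi$x1 > ncol(frame) || roi$x0 < 1L || roi$y0 < 1L)
    stop("ROI extends outside the image")
  sub <- frame[roi$y0:roi$y1, roi$x0:roi$x1, drop = FALSE]
  if (roi$long_axis == "vertical") sub <- t(sub)
  sub
}

#' Axis-averaged intensity profile of a groove
#'
#' Averages fluorescence across one groove axis to produce a 1-D profile
#' along the other: the major-axis profile (intensity averaged over the
#' minor axis at each position along the groove) locates condensations
#' and measures their length; the minor-axis profile (averaged over the
#' major axis, optionally restricted to one condensation's extent)
#' measures their width.
#'
#' @param frame numeric image matrix (rows = y).
#' @param roi a [groove_roi()].
#' @param axis `"major"` or `"minor"`: the axis along which the profile
#'   runs (averaging happens over the other axis).
#' @param restrict optional length-2 interval in um along the
#'   *perpendicular* axis restricting the averaging band (e.g. a
#'   condensation's half-max interval when measuring its width).
#' @return An object of class `axial_profile`: list with `positions`
#'   (um, pixel centres from the ROI edge), `intensities`, `axis` and
#'   `pixel_size`.
#' @export
axial_profile <- function(frame, roi, axis = c("major", "minor"),
                          restrict = NULL) {
  axis <- match.arg(axis)
  sub <- crop_oriented(frame, roi)
  ps <- roi$pixel_size
  if (!is.null(restrict)) {
    stopifnot(length(restrict) == 2L)
    perp_n <- if (axis == "major") nrow(sub) else ncol(sub)
    lo <- max(1L, floor(min(restrict) / ps + 0.5))
    hi <- min(perp_n, ceiling(max(restrict) / ps + 0.5))
    if (lo > hi) stop("restrict interval lies outside the ROI")
    if (axis == "major") sub <- sub[lo:hi, , drop = FALSE]
    else sub <- sub[, lo:hi, drop = FALSE]
  }
  v <- if (axis == "major") colMeans(sub) else rowMeans(sub)
  structure(list(positions = (seq_along(v) - 0.5) * ps,
                 intensities = as.numeric(v),
                 axis = axis, pixel_size = ps),
            class = "axial_profile")
}

#' Measure one condensation's length, width and prominence
#'
#' Given a peak detected on the groove's major-axis profile, measures the
#' condensation width as the FWHM of the minor-axis profile averaged over
#' the peak's half-max interval (the condensation's length extent). The
#' length, position and prominence are those of the major-axis peak.
#'
#' @param frame numeric image matrix.
#' @param roi a [groove_roi()].
#' @param peak a one-row data frame from [detect_condensations()] run on
#'   the major-axis profile.
#' @param min_prominence threshold for the width peak; default as in
#'   [detect_condensations()].
#' @param baseline background intensity used as the FWHM reference for
#'   the width peak (normally estimated from the major-axis profile,
#'   where background between condensations is visible; the restricted
#'   minor-axis window may contain no background at all).
#' @return One-row data frame: `position_um`, `length_um`, `width_um`,
#'   `prominence`, `height`, `clipped_length`, `clipped_width`,
#'   `width_missing`.
#' @export
measure_condensation <- function(frame, roi, peak, min_prominence = NULL,
                                 baseline = NULL) {
  stopifnot(nrow(peak) == 1L)
  wprof <- axial_profile(frame, roi, "minor",
                         restrict = c(peak$left_um, peak$right_um))
  wp <- detect_condensations(wprof, min_prominence, baseline = baseline)
  if (nrow(wp) == 0L) {
    width <- NA_real_; wclip <- NA; missing <- TRUE
  } else {
    best <- wp[which.max(wp$prominence), ]
    ## a condensation cannot be wider than the groove
    width <- min(best$fwhm_um, roi$minor_extent_um)
    wclip <- best$clipped || best$fwhm_um > roi$minor_extent_um
    missing <- FALSE
  }
  data.frame(position_um = peak$position_um,
             length_um = peak$fwhm_um,
             width_um = width,
             prominence = peak$prominence,
             height = peak$height,
             clipped_length = peak$clipped,
             clipped_width = wclip,
             width_missing = missing)
}

#' Measure all condensations in one frame of a groove
#'
#' Convenience composition: major-axis profile, background estimation,
#' peak detection, and per-peak width measurement. The groove background
#' is estimated as the 10th percentile of the major-axis profile (the
#' level between condensations, which also tracks any stain-accumulation
#' offset) and used as the half-maximum reference for both length and
#' width.
#'
#' @inheritParams measure_condensation
#' @param min_prominence detection threshold (default: 6 x robust noise).
#' @return Data frame with one row per condensation (possibly 0 rows).
#' @export
measure_groove_frame <- function(frame, roi, min_prominence = NULL) {
  prof <- axial_profile(frame, roi, "major")
  bg <- unname(quantile(prof$intensities, 0.1))
  peaks <- detect_condensations(prof, min_prominence, baseline = bg)
  if (nrow(peaks) == 0L)
    return(data.frame(position_um = numeric(), length_um = numeric(),
                      width_um = numeric(), prominence = numeric(),
                      height = numeric(), clipped_length = logical(),
                      clipped_width = logical(), width_missing = logical()))
  do.call(rbind, lapply(seq_len(nrow(peaks)), function(i)
    measure_condensation(frame, roi, peaks[i, ], min_prominence, baseline = bg)))
}

#' Aspect ratios and density for one groove at one timepoint
#'
#' Aspect ratio follows the constraint convention: in constrained grooves
#' (nominal width below 300 um) it is `length / width` (and may drop
#' below 1 when a condensation grows wider than long); in 300 um grooves
#' and on unconstrained tissue culture plastic (`"TCP"`), where no axis
#' is privileged, it is `longest / shortest` and is always >= 1. Density
#' is the number of condensations per 100 um of groove length.
#'
#' @param measurements data frame from [measure_groove_frame()].
#' @param roi a [groove_roi()].
#' @return List with `measurements` (input plus `aspect_ratio` column)
#'   and `count_per_100um`.
#' @export
derive_metrics <- function(measurements, roi) {
  m <- measurements
  unconstrained <- identical(roi$nominal_width, "TCP") ||
    (is.numeric(roi$nominal_width) && roi$nominal_width >= 300)
  if (nrow(m) > 0L) {
    ar <- ifelse(is.na(m$width_um) | m$width_um <= 0, NA_real_,
                 if (unconstrained)
                   pmax(m$length_um, m$width_um) / pmin(m$length_um, m$width_um)
                 else m$length_um / m$width_um)
    m$aspect_ratio <- ar
  } else m$aspect_ratio <- numeric()
  list(measurements = m,
       count_per_100um = nrow(m) / roi$major_extent_um * 100)
}

#' Fraction of marker-positive nuclei within condensation regions
#'
#' Nuclei are detected as local maxima of the nuclear channel above a
#' detection threshold; within each condensation region the fraction of
#' those nuclei whose marker-channel intensity reaches
#' `marker_threshold` is reported (e.g. the ratio of Sox9-positive to
#' total nuclei).
#'
#' @param nuclei_frame,marker_frame registered numeric image matrices.
#' @param regions a `label_map`, a list of logical masks, or a single
#'   logical mask.
#' @param marker_threshold intensity above which a nucleus counts as
#'   marker-positive.
#' @param detect_threshold nuclear detection threshold; default is Otsu's
#'   threshold of the nuclear frame.
#' @return Numeric vector, one fraction in `[0, 1]` per region (`NA`
#'   with a warning where no nuclei are detected).
#' @export
marker_positive_fraction <- function(nuclei_frame, marker_frame, regions,
                                     marker_threshold,
                                     detect_threshold = NULL) {
  stopifnot(all(dim(nuclei_frame) == dim(marker_frame)))
  if (is.null(detect_threshold))
    detect_threshold <- EBImage::otsu(t(rescale01(nuclei_frame)), range = c(0, 1)) *
      diff(range(nuclei_frame)) + min(nuclei_frame)
  mx <- local_maxima_2d(nuclei_frame) & (nuclei_frame >= detect_threshold)
  if (inherits(regions, "label_map") || (is.matrix(regions) && !is.logical(regions))) {
    n <- max(regions)
    masks <- lapply(seq_len(n), function(i) regions == i)
  } else if (is.list(regions)) {
    masks <- regions
  } else {
    masks <- list(regions)
  }
  vapply(masks, function(msk) {
    idx <- which(mx & msk)
    if (length(idx) == 0L) {
      warning("no nuclei detected in region")
      return(NA_real_)
    }
    mean(marker_frame[idx] >= marker_threshold)
  }, numeric(1))
}

## Strict local maxima over the 8-neighbourhood.
local_maxima_2d <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  pad <- matrix(-Inf, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- img
  out <- matrix(TRUE, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    nb <- pad[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dc]
    out <- out & (img > nb)
  }
  out
}
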