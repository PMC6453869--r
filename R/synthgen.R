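#' Specification of a synthetic micromass scene
#'
#' Describes a brightfield-like scene: dark condensation-shaped objects on
#' a bright noisy background, with controlled size, elongation and
#' spacing. Used by [generate_micromass_scene()] to render images with
#' exact ground truth for validating segmentation and morphometrics.
#'
#' @param image_size integer vector `c(height, width)` in pixels.
#' @param n_objects number of condensations to place (may be 0).
#' @param shape_family `"ellipse"` for compact elliptical condensations or
#'   `"branched"` for unions of overlapping ellipses emulating the
#'   branched morphology of facial condensations.
#' @param area_range numeric length-2, target object area in px^2.
#' @param axis_ratio_range numeric length-2, major/minor axis ratio (>= 1).
#' @param background_level,object_level background and object intensities
#'   in `[0, 1]`; objects must be darker than the background
#'   (brightfield polarity).
#' @param noise_sd standard deviation of additive Gaussian noise.
#' @param noise_model `"gaussian"` (additive) or `"poisson"` (shot noise
#'   at `photons` expected counts per unit intensity).
#' @param photons photon scale for the Poisson noise model.
#' @param min_gap minimum gap between object envelopes in px (0 permits
#'   touching objects).
#' @param seed integer seed; identical seeds give bit-identical scenes.
#' @return An object of class `micromass_scene_spec`.
#' @seealso [generate_micromass_scene()]
#' @export
micromass_scene_spec <- function(image_size = c(256L, 256L),
                                 n_objects = 10L,
                                 shape_family = c("ellipse", "branched"),
                                 area_range = c(300, 800),
                                 axis_ratio_range = c(1.2, 2),
                                 background_level = 0.8,
                                 object_level = 0.3,
                                 noise_sd = 0.02,
                                 noise_model = c("gaussian", "poisson"),
                                 photons = 1000,
                                 min_gap = 5,
                                 seed = NULL) {
  shape_family <- match.arg(shape_family)
  noise_model <- match.arg(noise_model)
  stopifnot(length(image_size) == 2L, all(image_size >= 16),
            n_objects >= 0, length(area_range) == 2L,
            all(area_range > 0), diff(area_range) >= 0,
            length(axis_ratio_range) == 2L, all(axis_ratio_range >= 1),
            noise_sd >= 0, min_gap >= 0, photons > 0)
  if (object_level >= background_level)
    stop("object_level must be below background_level (dark objects on bright background)")
  if (max(area_range) > 0.25 * prod(image_size))
    stop("area_range exceeds image capacity")
  structure(list(image_size = as.integer(image_size), n_objects = as.integer(n_objects),
                 shape_family = shape_family, area_range = area_range,
                 axis_ratio_range = axis_ratio_range,
                 background_level = background_level, object_level = object_level,
                 noise_sd = noise_sd, noise_model = noise_model, photons = photons,
                 min_gap = min_gap, seed = seed),
            class = "micromass_scene_spec")
}

## Pixel-centre rasterization of one object into logical mask over the
## whole image. Ellipse: centre (cy, cx), semi-axes (a major, b minor),
## orientation theta (radians, from +x axis). Branched objects are unions
## of a core ellipse and 2-3 overlapping arm ellipses.
rasterize_object <- function(image_size, cy, cx, a, b, theta, family = "ellipse",
                             arms = NULL) {
  H <- image_size[1]; W <- image_size[2]
  parts <- list(c(cy, cx, a, b, theta))
  if (family == "branched" && !is.null(arms)) parts <- c(parts, arms)
  mask <- matrix(FALSE, H, W)
  for (p in parts) {
    yc <- p[1]; xc <- p[2]; pa <- p[3]; pb <- p[4]; th <- p[5]
    r0 <- max(1L, floor(yc - pa)); r1 <- min(H, ceiling(yc + pa))
    c0 <- max(1L, floor(xc - pa)); c1 <- min(W, ceiling(xc + pa))
    if (r0 > r1 || c0 > c1) next
    rows <- r0:r1; cols <- c0:c1
    dy <- outer(rows - yc, rep(1, length(cols)))
    dx <- outer(rep(1, length(rows)), cols - xc)
    u <- dx * cos(th) + dy * sin(th)
    v <- -dx * sin(th) + dy * cos(th)
    mask[rows, cols] <- mask[rows, cols] | ((u / pa)^2 + (v / pb)^2 <= 1)
  }
  mask
}

#' Render a synthetic micromass scene with ground truth
#'
#' Places `n_objects` dark objects (ellipses or branched unions of
#' ellipses) on a bright noisy background, subject to a minimum gap
#' between object envelopes, and returns the image together with the
#' ground-truth label map and per-object truth table.
#'
#' @param spec a [micromass_scene_spec()].
#' @return A list with elements:
#'   \describe{
#'     \item{image}{numeric matrix (rows = y), intensities in `[0, 1]`.}
#'     \item{labels}{ground-truth label map (integer matrix).}
#'     \item{truth}{data frame with one row per object: `object_id`,
#'       centroid `cy_px`/`cx_px`, `area_px` (rendered pixel count),
#'       `major_px`/`minor_px` (true axis lengths `2a`/`2b`),
#'       `axis_ratio`, `theta`, `class_label`.}
#'   }
#' @examples
#' sc <- generate_micromass_scene(micromass_scene_spec(n_objects = 3, seed = 1))
#' nrow(sc$truth)
#' @export
generate_micromass_scene <- function(spec) {
  stopifnot(inherits(spec, "micromass_scene_spec"))
  with_seed(spec$seed, {
    H <- spec$image_size[1]; W <- spec$image_size[2]
    n <- spec$n_objects
    placed <- list()
    if (n > 0L) {
      max_tries <- 500L * n
      tries <- 0L
      while (length(placed) < n) {
        tries <- tries + 1L
        if (tries > max_tries)
          stop("placement failure: cannot place ", n, " objects at min_gap = ",
               spec$min_gap, " in a ", H, "x", W, " image")
        area <- runif(1, spec$area_range[1], spec$area_range[2])
        q <- runif(1, spec$axis_ratio_range[1], spec$axis_ratio_range[2])
        a <- sqrt(area * q / pi); b <- a / q
        theta <- runif(1, 0, pi)
        arms <- NULL
        rb <- a  # bounding radius of the envelope
        if (spec$shape_family == "branched") {
          n_arm <- sample(2:3, 1)
          arms <- vector("list", n_arm)
          for (k in seq_len(n_arm)) {
            phi <- runif(1, 0, 2 * pi)
            la <- a * runif(1, 0.6, 0.9)     # arm semi-major
            lb <- max(1.2, la / runif(1, 2.5, 3.5))
            off <- a * runif(1, 0.5, 0.8)
            arms[[k]] <- c(off * sin(phi), off * cos(phi), la, lb, phi)
          }
          rb <- a * 1.8
        }
        margin <- rb + 3  # keep clear of the border-suppression zone
        if (2 * margin >= min(H, W)) next
        cy <- runif(1, margin + 1, H - margin)
        cx <- runif(1, margin + 1, W - margin)
        ok <- TRUE
        for (p in placed) {
          if (sqrt((cy - p$cy)^2 + (cx - p$cx)^2) < rb + p$rb + spec$min_gap) {
            ok <- FALSE; break
          }
        }
        if (!ok) next
        if (!is.null(arms))
          arms <- lapply(arms, function(v) c(cy + v[1], cx + v[2], v[3], v[4], v[5]))
        placed[[length(placed) + 1L]] <-
          list(cy = cy, cx = cx, a = a, b = b, theta = theta, rb = rb, arms = arms)
      }
    }
    labels <- matrix(0L, H, W)
    for (i in seq_along(placed)) {
      p <- placed[[i]]
      m <- rasterize_object(spec$image_size, p$cy, p$cx, p$a, p$b, p$theta,
                            spec$shape_family, p$arms)
      labels[m] <- i
    }
    image <- matrix(spec$background_level, H, W)
    image[labels > 0L] <- spec$object_level
    if (spec$noise_model == "gaussian") {
      if (spec$noise_sd > 0) image <- image + rnorm(H * W, sd = spec$noise_sd)
    } else {
      image <- rpois(H * W, lambda = pmax(image, 0) * spec$photons) / spec$photons
      dim(image) <- c(H, W)
    }
    image <- pmin(pmax(image, 0), 1)
    truth <- if (length(placed) == 0L) {
      data.frame(object_id = integer(), cy_px = numeric(), cx_px = numeric(),
                 area_px = numeric(), major_px = numeric(), minor_px = numeric(),
                 axis_ratio = numeric(), theta = numeric(), class_label = character(),
                 stringsAsFactors = FALSE)
    } else {
      do.call(rbind, lapply(seq_along(placed), function(i) {
        p <- placed[[i]]
        idx <- which(labels == i)
        rr <- ((idx - 1L) %% H) + 1L; cc <- ((idx - 1L) %/% H) + 1L
        data.frame(object_id = i, cy_px = mean(rr), cx_px = mean(cc),
                   area_px = length(idx), major_px = 2 * p$a, minor_px = 2 * p$b,
                   axis_ratio = p$a / p$b, theta = p$theta, class_label = NA_character_,
                   stringsAsFactors = FALSE)
      }))
    }
    list(image = image, labels = new_label_map(labels), truth = truth)
  })
}

#' Generate two labelled descriptor populations from synthetic scenes
#'
#' Renders scenes from two specifications and computes the full shape
#' descriptor table for each rendered object (from the ground-truth label
#' maps, so descriptor differences reflect the generating distributions,
#' not segmentation error). The number of objects per scene is drawn as
#' `max(2, Poisson(n_objects))` so that the image-level
#' `n_condensations` descriptor varies across rows, as it does across
#' replicate culture images.
#'
#' @param class_a_spec,class_b_spec [micromass_scene_spec()] objects; they
#'   may be identical (null case) or differ in any distributional
#'   parameter.
#' @param n_per_class number of condensations per class (>= 2).
#' @param seed integer seed for both classes.
#' @param class_labels character length-2 labels, default `c("a", "b")`.
#' @return A list with descriptor tables `a` and `b` (see
#'   [descriptor_table()]), each with a `class` column.
#' @export
generate_two_class_shapes <- function(class_a_spec, class_b_spec, n_per_class,
                                      seed = NULL, class_labels = c("a", "b")) {
  stopifnot(inherits(class_a_spec, "micromass_scene_spec"),
            inherits(class_b_spec, "micromass_scene_spec"))
  if (n_per_class < 2) stop("n_per_class must be >= 2 (discriminant analysis needs >= 2 per class)")
  with_seed(seed, {
    one_class <- function(spec, lab) {
      rows <- list()
      got <- 0L
      guard <- 0L
      while (got < n_per_class) {
        guard <- guard + 1L
        if (guard > 10L * n_per_class) stop("failed to accumulate descriptor rows")
        sp <- spec
        sp$n_objects <- max(2L, rpois(1, spec$n_objects))
        sp$seed <- NULL  # inherit the outer stream
        sc <- generate_micromass_scene(sp)
        dt <- descriptor_table(sc$labels)
        if (nrow(dt) == 0L) next
        dt$class <- lab
        rows[[length(rows) + 1L]] <- dt
        got <- got + nrow(dt)
      }
      out <- do.call(rbind, rows)
      out[seq_len(n_per_class), , drop = FALSE]
    }
    list(a = one_class(class_a_spec, class_labels[1]),
         b = one_class(class_b_spec, class_labels[2]))
  })
}

#' Specification of a synthetic groove fluorescence time series
#'
#' Describes a live-imaging series of one microgroove: condensations are
#' rendered as additive 2-D anisotropic Gaussians whose length and width
#' (full width at half maximum, FWHM) follow logistic growth in time and
#' whose peak amplitude ramps linearly across the series (emulating the
#' increase in cell density as condensations mature).
#'
#' @param groove_width groove width in um (the constrained, minor axis).
#' @param groove_length groove length in um (the free, major axis).
#' @param pixel_size calibration in um/px (> 0).
#' @param n_timepoints number of frames (>= 1).
#' @param frame_interval hours between frames (default 0.5 h, i.e. one
#'   frame every 30 min).
#' @param condensations data frame with one row per condensation:
#'   `center_um` (position along the groove), `final_length_um`,
#'   `final_width_um` (asymptotic FWHMs; width must not exceed
#'   `groove_width`), `t_mid_h` (logistic growth midpoint, h),
#'   `rate_per_h` (logistic rate, 1/h), `amp_start`, `amp_end`
#'   (peak amplitude at first/last frame; equal values give a constant
#'   amplitude). Optional `cy_um` (transverse position, default groove
#'   centre). `NULL` gives a default population: one condensation per
#'   100 um, final length 80 um, final width capped at 80% of the groove
#'   width, midpoint 8 h and rate 0.25/h so that size enters its +/-10%
#'   plateau band around 17 h.
#' @param background_level,noise_sd background intensity and Gaussian
#'   noise standard deviation.
#' @param seed integer seed.
#' @return An object of class `groove_series_spec`.
#' @export
groove_series_spec <- function(groove_width = 100,
                               groove_length = 500,
                               pixel_size = 1,
                               n_timepoints = 72L,
                               frame_interval = 0.5,
                               condensations = NULL,
                               background_level = 0.05,
                               noise_sd = 0.01,
                               seed = NULL) {
  if (pixel_size <= 0) stop("calibration error: pixel_size must be > 0 um/px")
  stopifnot(groove_width > 0, groove_length > 0, n_timepoints >= 1,
            frame_interval > 0, noise_sd >= 0)
  if (is.null(condensations)) {
    n <- max(1L, round(groove_length / 100))
    centers <- (seq_len(n) - 0.5) / n * groove_length
    condensations <- data.frame(
      center_um = centers,
      final_length_um = 80,
      final_width_um = min(80, 0.8 * groove_width),
      t_mid_h = 8, rate_per_h = 0.25,
      amp_start = 0.5, amp_end = 1.0)
  }
  need <- c("center_um", "final_length_um", "final_width_um",
            "t_mid_h", "rate_per_h", "amp_start", "amp_end")
  if (!all(need %in% names(condensations)))
    stop("condensations must have columns: ", paste(need, collapse = ", "))
  if (!("cy_um" %in% names(condensations)))
    condensations$cy_um <- groove_width / 2
  if (any(condensations$final_width_um > groove_width))
    stop("final_width_um must not exceed groove_width")
  if (any(condensations$final_length_um <= 0) || any(condensations$final_width_um <= 0))
    stop("final FWHMs must be positive")
  structure(list(groove_width = groove_width, groove_length = groove_length,
                 pixel_size = pixel_size, n_timepoints = as.integer(n_timepoints),
                 frame_interval = frame_interval, condensations = condensations,
                 background_level = background_level, noise_sd = noise_sd,
                 seed = seed),
            class = "groove_series_spec")
}

#' Logistic growth law used by the groove generator
#'
#' FWHM at time `t` growing logistically towards `final`:
#' `final / (1 + exp(-rate * (t - t_mid)))`.
#' @param final asymptotic FWHM (um).
#' @param t time (h).
#' @param t_mid growth midpoint (h).
#' @param rate growth rate (1/h).
#' @return FWHM at `t` (um).
#' @export
logistic_fwhm <- function(final, t, t_mid, rate) {
  final / (1 + exp(-rate * (t - t_mid)))
}

#' Render a synthetic groove time series with ground truth
#'
#' Each frame contains the additive 2-D Gaussian condensations that
#' `spec` defines at that timepoint plus Gaussian background noise. Frame `k`
#' corresponds to time `(k - 1) * frame_interval` hours.
#'
#' @param spec a [groove_series_spec()].
#' @return A list with:
#'   \describe{
#'     \item{stack}{numeric array `[rows (y, minor axis), cols (x, major
#'       axis), frames]`.}
#'     \item{truth}{data frame, one row per condensation per timepoint:
#'       `object_id`, `t_h`, `cx_um`, `cy_um`, `length_fwhm_um`,
#'       `width_fwhm_um`, `amplitude`.}
#'     \item{roi}{the [groove_roi()] covering the full groove.}
#'   }
#' @export
generate_groove_series <- function(spec) {
  stopifnot(inherits(spec, "groove_series_spec"))
  with_seed(spec$seed, {
    H <- max(3L, round(spec$groove_width / spec$pixel_size))
    W <- max(3L, round(spec$groove_length / spec$pixel_size))
    xs <- (seq_len(W) - 0.5) * spec$pixel_size
    ys <- (seq_len(H) - 0.5) * spec$pixel_size
    Tn <- spec$n_timepoints
    cp <- spec$condensations
    k2s <- 1 / (2 * sqrt(2 * log(2)))  # FWHM -> sigma
    stack <- array(0, dim = c(H, W, Tn))
    truth <- vector("list", Tn)
    for (k in seq_len(Tn)) {
      t_h <- (k - 1) * spec$frame_interval
      frame <- matrix(spec$background_level, H, W)
      amp_frac <- if (Tn == 1L) 1 else (k - 1) / (Tn - 1)
      rows <- vector("list", nrow(cp))
      for (i in seq_len(nrow(cp))) {
        L <- logistic_fwhm(cp$final_length_um[i], t_h, cp$t_mid_h[i], cp$rate_per_h[i])
        Wd <- logistic_fwhm(cp$final_width_um[i], t_h, cp$t_mid_h[i], cp$rate_per_h[i])
        amp <- cp$amp_start[i] + (cp$amp_end[i] - cp$amp_start[i]) * amp_frac
        sx <- L * k2s; sy <- Wd * k2s
        gx <- exp(-(xs - cp$center_um[i])^2 / (2 * sx^2))
        gy <- exp(-(ys - cp$cy_um[i])^2 / (2 * sy^2))
        frame <- frame + amp * (gy %o% gx)
        rows[[i]] <- data.frame(object_id = i, t_h = t_h,
                                cx_um = cp$center_um[i], cy_um = cp$cy_um[i],
                                length_fwhm_um = L, width_fwhm_um = Wd,
                                amplitude = amp)
      }
      if (spec$noise_sd > 0)
        frame <- frame + rnorm(H * W, sd = spec$noise_sd)
      stack[, , k] <- frame
      truth[[k]] <- do.call(rbind, rows)
    }
    roi <- groove_roi(x0 = 1L, y0 = 1L, x1 = W, y1 = H,
                      nominal_width = spec$groove_width,
                      long_axis = "horizontal", pixel_size = spec$pixel_size)
    list(stack = stack, truth = do.call(rbind, truth), roi = roi)
  })
}

#' Write a groove series and its truth table to disk
#'
#' The stack is written as a multi-page TIFF (one page per timepoint) and
#' the truth table as a CSV.
#'
#' @param series result of [generate_groove_series()].
#' @param tiff_path,truth_path output paths; `NULL` skips that output.
#' @return Invisibly, the paths written.
#' @export
write_groove_series <- function(series, tiff_path = NULL, truth_path = NULL) {
  if (!is.null(tiff_path)) write_image_stack(series$stack, tiff_path)
  if (!is.null(truth_path))
    write.csv(series$truth, truth_path, row.names = FALSE)
  invisible(c(tiff = tiff_path, truth = truth_path))
}
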