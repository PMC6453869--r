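## Image and configuration I/O. All in-memory images are numeric
## matrices with rows = y (image row) and cols = x; multi-frame stacks
## are [y, x, t] arrays. EBImage stores images as [x, y(, frame)], so
## every call transposes on the way in and out.

#' Read a grayscale or RGB image
#' @param path TIFF or PNG file.
#' @return Numeric matrix (grayscale) or H x W x 3 array (RGB).
#' @export
read_image <- function(path) {
  img <- EBImage::readImage(path)
  d <- dim(img)
  if (length(d) == 2L) return(t(as.matrix(img)))
  aperm(as.array(img), c(2L, 1L, 3L))
}

#' Read a multi-page TIFF stack
#' @param path multi-page TIFF, one page per timepoint.
#' @return Array `[y, x, t]` (single-page input gives t = 1).
#' @export
read_image_stack <- function(path) {
  img <- tryCatch(EBImage::readImage(path, all = TRUE),
                  error = function(e) stop("failed to read stack '", path,
                                           "': ", conditionMessage(e)))
  a <- as.array(img)
  if (length(dim(a)) == 2L) dim(a) <- c(dim(a), 1L)
  aperm(a, c(2L, 1L, 3L))
}

#' Write an image matrix to TIFF or PNG
#' @param image numeric matrix, values clamped to `[0, 1]` on write.
#' @param path output path (format from extension).
#' @return Invisibly, `path`.
#' @export
write_image <- function(image, path) {
  EBImage::writeImage(t(pmin(pmax(image, 0), 1)), path)
  invisible(path)
}

#' Write a stack as a multi-page TIFF (one page per timepoint)
#' @param stack array `[y, x, t]`.
#' @param path output TIFF path.
#' @return Invisibly, `path`.
#' @export
write_image_stack <- function(stack, path) {
  if (length(dim(stack)) == 2L) dim(stack) <- c(dim(stack), 1L)
  img <- EBImage::Image(aperm(pmin(pmax(stack, 0), 1), c(2L, 1L, 3L)))
  EBImage::writeImage(img, path)
  invisible(path)
}

#' Write / read a label map as 16-bit TIFF
#'
#' Labels are stored as `label / 65535` so that up to 65535 objects
#' round-trip exactly through the 16-bit container.
#' @param labels a `label_map`.
#' @param path TIFF path.
#' @return Invisibly `path` / the `label_map`.
#' @export
write_label_map <- function(labels, path) {
  if (max(labels) > 65535L) stop("more than 65535 labels cannot be stored in 16 bits")
  m <- matrix(as.numeric(labels), nrow(labels), ncol(labels))
  EBImage::writeImage(t(m) / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_label_map
#' @export
read_label_map <- function(path) {
  m <- t(as.matrix(EBImage::readImage(path)))
  new_label_map(matrix(as.integer(round(m * 65535)), nrow(m), ncol(m)))
}

#' Write a segmentation QC overlay
#'
#' Paints object boundaries over the grayscale image and writes a PNG.
#' @param image grayscale matrix in `[0, 1]`.
#' @param labels a `label_map`.
#' @param path output PNG path.
#' @return Invisibly, `path`.
#' @export
write_overlay_png <- function(image, labels, path) {
  g <- t(pmin(pmax(image, 0), 1))
  rgb <- EBImage::rgbImage(g, g, g)
  ov <- EBImage::paintObjects(EBImage::Image(t(labels)), rgb, col = "#FF0000")
  EBImage::writeImage(ov, path)
  invisible(path)
}

#' Read groove ROI definitions from YAML
#'
#' Expects a top-level `grooves:` list; each entry has `x0, y0, x1, y1`,
#' `nominal_width` (um or `"TCP"`), optional `long_axis` and
#' `pixel_size` (entry values override the `default_pixel_size`).
#'
#' @param path YAML file.
#' @param default_pixel_size calibration applied where an entry gives
#'   none (um/px).
#' @return List of [groove_roi()] objects.
#' @export
read_rois_yaml <- function(path, default_pixel_size = 1) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$grooves)) stop("ROI file has no 'grooves:' list")
  lapply(doc$grooves, function(g) {
    groove_roi(x0 = g$x0, y0 = g$y0, x1 = g$x1, y1 = g$y1,
               nominal_width = if (is.null(g$nominal_width)) "TCP" else g$nominal_width,
               long_axis = if (is.null(g$long_axis)) "horizontal" else g$long_axis,
               pixel_size = if (is.null(g$pixel_size)) default_pixel_size else g$pixel_size)
  })
}

## Canonical ground-truth CSV columns shared by both generators.
truth_csv_columns <- function() {
  c("object_id", "t_h", "cx_um", "cy_um", "length_fwhm_um", "width_fwhm_um",
    "area_px", "major_px", "minor_px", "class_label")
}

#' Write a ground-truth table in the canonical column layout
#'
#' Fills columns that do not apply to the generator at hand with `NA`.
#' @param truth truth data frame from a generator.
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
write_truth_csv <- function(truth, path) {
  out <- truth
  for (cn in truth_csv_columns()) if (!cn %in% names(out)) out[[cn]] <- NA
  write.csv(out[, truth_csv_columns(), drop = FALSE], path, row.names = FALSE)
  invisible(path)
}

write_manifest <- function(out_dir, seed, extra = list()) {
  man <- c(list(tool = "condensia",
                version = as.character(packageVersion("condensia")),
                seed = if (is.null(seed)) NA else seed),
           extra)
  jsonlite::write_json(man, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run the micromass pipeline end to end
#'
#' Segments every image, extracts descriptor tables per class, writes
#' per-class CSVs and QC overlays, and -- when exactly two classes each
#' yield at least two condensations -- ranks the descriptors by linear
#' discriminant analysis on the jointly standardized pooled tables.
#'
#' @param images named list of classes; each class is a character vector
#'   of image paths or a list of image matrices. A single unnamed class
#'   yields descriptors only (no discriminant).
#' @param out_dir output directory (created if needed); `NULL` skips all
#'   file output.
#' @param config a [segmentation_config()].
#' @param calibration pixel size in um/px.
#' @param seed recorded in the manifest (the pipeline itself is
#'   deterministic).
#' @return List with `descriptors` (named list of `descriptor_table`s)
#'   and `discriminant` (a `discriminant_result` or `NULL`).
#' @export
run_micromass_analysis <- function(images, out_dir = NULL,
                                   config = segmentation_config(),
                                   calibration = 1, seed = NULL) {
  if (!is.list(images) || length(images) == 0L) stop("images must be a non-empty list")
  if (is.null(names(images)) || any(names(images) == ""))
    names(images) <- paste0("class_", seq_along(images))
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tables <- list()
  for (cls in names(images)) {
    set <- images[[cls]]
    if (is.character(set)) set <- lapply(set, read_image)
    if (!is.list(set)) set <- list(set)
    per_img <- lapply(seq_along(set), function(i) {
      labs <- segment_micromass(set[[i]], config)
      dt <- descriptor_table(labs, calibration)
      if (nrow(dt) > 0L) dt$image_id <- i
      if (!is.null(out_dir) && n_objects(labs) > 0L)
        write_overlay_png(rescale01(to_gray(set[[i]])), labs,
                          file.path(out_dir, sprintf("overlay_%s_%02d.png", cls, i)))
      dt
    })
    per_img <- per_img[vapply(per_img, nrow, integer(1)) > 0L]
    tab <- if (length(per_img) > 0L) do.call(rbind, per_img) else
      descriptor_table(new_label_map(matrix(0L, 1, 1)), calibration)
    tab$class <- cls
    tables[[cls]] <- tab
    if (!is.null(out_dir))
      write_descriptor_csv(tab, file.path(out_dir, paste0("descriptors_", cls, ".csv")))
  }
  fit <- NULL
  if (length(tables) == 2L &&
      all(vapply(tables, nrow, integer(1)) >= 2L)) {
    ## drop descriptors that are constant across the pooled rows (e.g.
    ## n_condensations when every image holds the same object count):
    ## they carry no discriminative information and break standardization
    pooled <- rbind(tables[[1L]][, descriptor_names(), drop = FALSE],
                    tables[[2L]][, descriptor_names(), drop = FALSE])
    sds <- vapply(pooled, sd, numeric(1))
    keep <- descriptor_names()[sds > .Machine$double.eps^0.5 *
                                 pmax(abs(colMeans(pooled)), 1)]
    if (length(keep) < length(descriptor_names()))
      message("constant descriptor(s) excluded from the discriminant: ",
              paste(setdiff(descriptor_names(), keep), collapse = ", "))
    fit <- fit_discriminant(tables[[1L]], tables[[2L]], descriptors = keep)
    if (!is.null(out_dir))
      write_discriminant_json(fit, file.path(out_dir, "discriminant.json"))
  } else if (length(tables) == 2L) {
    message("a class yielded fewer than 2 condensations; discriminant analysis skipped")
  }
  if (!is.null(out_dir))
    write_manifest(out_dir, seed,
                   list(mode = "micromass", calibration = calibration,
                        config = unclass(config),
                        classes = names(tables),
                        n_condensations = lapply(tables, nrow)))
  list(descriptors = tables, discriminant = fit)
}

#' Run the groove pipeline end to end
#'
#' For every groove ROI and frame: axis-averaged profile, peak detection,
#' per-condensation length/width/prominence and aspect ratio. With more
#' than one frame, condensations are tracked backwards from the final
#' frame and per-timepoint summaries (with plateau times) are computed
#' per groove-width class; a single frame gives endpoint measurements
#' only.
#'
#' @param stack array `[y, x, t]`, a single-frame matrix, or a TIFF path.
#' @param rois list of [groove_roi()] or a YAML path
#'   (see [read_rois_yaml()]).
#' @param out_dir output directory; `NULL` skips file output.
#' @param frame_interval hours between frames (default 0.5).
#' @param times explicit frame times in hours (overrides
#'   `frame_interval`).
#' @param min_prominence peak threshold (default 3 x robust noise per
#'   profile).
#' @param gate_floor_um tracking gate floor, see [track_backwards()].
#' @param seed recorded in the manifest.
#' @return List with `measurements` (all grooves/frames), `tracks`
#'   (`NULL` for single-frame input), `summaries` (per width class) and
#'   `density` (per groove and frame, condensations per 100 um).
#' @export
run_groove_analysis <- function(stack, rois, out_dir = NULL,
                                frame_interval = 0.5, times = NULL,
                                min_prominence = NULL, gate_floor_um = 10,
                                seed = NULL) {
  if (is.character(stack)) stack <- read_image_stack(stack)
  if (is.matrix(stack)) dim(stack) <- c(dim(stack), 1L)
  Tn <- dim(stack)[3L]
  if (is.character(rois)) rois <- read_rois_yaml(rois)
  if (inherits(rois, "groove_roi")) rois <- list(rois)
  if (length(rois) == 0L) stop("no ROIs given")
  if (is.null(times)) times <- (seq_len(Tn) - 1) * frame_interval
  stopifnot(length(times) == Tn)
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  all_meas <- list(); all_tracks <- list(); density <- list()
  per_groove_tracks <- list()
  for (g in seq_along(rois)) {
    roi <- rois[[g]]
    frames <- lapply(seq_len(Tn), function(k) {
      m <- measure_groove_frame(stack[, , k], roi, min_prominence)
      derive_metrics(m, roi)
    })
    meas_list <- lapply(frames, `[[`, "measurements")
    for (k in seq_len(Tn)) {
      mk <- meas_list[[k]]
      if (nrow(mk) > 0L) {
        mk$t_h <- times[k]; mk$groove_id <- g
        all_meas[[length(all_meas) + 1L]] <- mk
      }
      density[[length(density) + 1L]] <-
        data.frame(groove_id = g, t_h = times[k],
                   nominal_width = as.character(roi$nominal_width),
                   count_per_100um = frames[[k]]$count_per_100um)
    }
    if (Tn > 1L) {
      tr <- track_backwards(meas_list, times, gate_floor_um)
      if (nrow(tr) > 0L) {
        tr$groove_id <- g
        tr$nominal_width <- as.character(roi$nominal_width)
        all_tracks[[length(all_tracks) + 1L]] <- tr
      }
      per_groove_tracks[[g]] <- tr
    }
  }
  measurements <- if (length(all_meas) > 0L) do.call(rbind, all_meas) else NULL
  tracks <- if (length(all_tracks) > 0L) do.call(rbind, all_tracks) else NULL
  summaries <- NULL
  if (!is.null(tracks)) {
    summaries <- lapply(split(tracks, tracks$nominal_width), summarize_series)
  }
  density <- do.call(rbind, density)
  if (!is.null(out_dir)) {
    if (!is.null(measurements))
      write.csv(measurements, file.path(out_dir, "measurements.csv"), row.names = FALSE)
    if (!is.null(tracks))
      write.csv(as.data.frame(tracks), file.path(out_dir, "tracks.csv"),
                row.names = FALSE)
    write.csv(density, file.path(out_dir, "density.csv"), row.names = FALSE)
    if (!is.null(summaries)) {
      for (w in names(summaries))
        write.csv(summaries[[w]]$summary,
                  file.path(out_dir, paste0("summary_w", w, ".csv")),
                  row.names = FALSE)
    }
    write_manifest(out_dir, seed,
                   list(mode = "grooves", n_frames = Tn,
                        n_grooves = length(rois),
                        frame_interval = if (is.null(times)) frame_interval else NA,
                        gate_floor_um = gate_floor_um))
  }
  list(measurements = measurements, tracks = tracks,
       summaries = summaries, density = density)
}
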