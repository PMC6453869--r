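#' Segmentation configuration
#'
#' Parameters of the micromass segmentation pipeline. Defaults follow the
#' pipeline's reference settings; all stages are configurable.
#'
#' @param clahe_tile nominal CLAHE tile size in px; the image is divided
#'   into roughly `dim / clahe_tile` tiles per side (at least 1, at most
#'   16). 0 disables CLAHE.
#' @param clahe_clip CLAHE contrast limit (multiples of the uniform
#'   histogram height; higher = stronger enhancement).
#' @param lowpass_sigma Gaussian low-pass standard deviation in px (0
#'   disables smoothing).
#' @param open_radius,close_radius disc radii (px) for morphological
#'   opening (removes small foreground specks) and closing (fills small
#'   holes); 0 disables the operation.
#' @param min_object_px connected components with fewer than this many
#'   pixels are removed (strictly fewer; a component of exactly
#'   `min_object_px` pixels is kept). Default 24.
#' @param minima_depth_h depth threshold (in distance-transform units,
#'   px) below which local minima are filtered out before the watershed
#'   (minima imposition); larger values merge shallow basins and prevent
#'   over-segmentation.
#' @param border_suppress suppress structures connected to the image
#'   border (lighter than their surroundings in the original polarity).
#' @param min_separability minimum Otsu separability (between-class over
#'   total variance, in `[0, 1]`) for the threshold to be considered
#'   meaningful. A unimodal noise image cannot exceed about 0.64
#'   (the Gaussian limit), while images that genuinely contain dark
#'   objects score well above 0.85; below the cutoff the image is
#'   treated as object-free. Set to 0 to disable.
#' @param polarity `"dark"` if condensations are darker than the
#'   background (brightfield default) or `"bright"` for inverted-polarity
#'   inputs. Handled by [preprocess()] so that the downstream pipeline
#'   always sees dark objects.
#' @return An object of class `segmentation_config`.
#' @export
segmentation_config <- function(clahe_tile = 32,
                                clahe_clip = 2,
                                lowpass_sigma = 2,
                                open_radius = 2,
                                close_radius = 2,
                                min_object_px = 24L,
                                minima_depth_h = 2,
                                border_suppress = TRUE,
                                polarity = c("dark", "bright"),
                                min_separability = 0.75) {
  polarity <- match.arg(polarity)
  stopifnot(min_object_px >= 1, lowpass_sigma >= 0, minima_depth_h > 0,
            clahe_tile >= 0, clahe_clip > 0, open_radius >= 0, close_radius >= 0,
            min_separability >= 0, min_separability <= 1)
  structure(list(clahe_tile = clahe_tile, clahe_clip = clahe_clip,
                 lowpass_sigma = lowpass_sigma, open_radius = open_radius,
                 close_radius = close_radius, min_object_px = as.integer(min_object_px),
                 minima_depth_h = minima_depth_h, border_suppress = border_suppress,
                 polarity = polarity, min_separability = min_separability),
            class = "segmentation_config")
}

#' Label map constructor
#'
#' An integer matrix the shape of the source image; 0 is background and
#' 1..N are condensation labels (8-connected components, consecutively
#' numbered).
#' @param m integer matrix of labels.
#' @return `m` with class `label_map`.
#' @export
new_label_map <- function(m) {
  storage.mode(m) <- "integer"
  structure(m, class = c("label_map", class(matrix())))
}

#' @export
print.label_map <- function(x, ...) {
  cat("<label_map> ", nrow(x), "x", ncol(x), ", ", max(x), " object(s)\n", sep = "")
  invisible(x)
}

#' Number of objects in a label map
#' @param labels a `label_map`.
#' @return integer count of labels.
#' @export
n_objects <- function(labels) max(0L, max(labels))

#' Preprocess a brightfield micromass image
#'
#' Converts RGB input to grayscale (Rec.709 luma), rescales to `[0, 1]`,
#' normalizes polarity so that condensations are dark, enhances local
#' contrast by contrast-limited adaptive histogram equalization (CLAHE)
#' and removes constant-power additive noise with a Gaussian low-pass
#' filter.
#'
#' @param image numeric matrix (grayscale) or H x W x 3 array (RGB).
#' @param config a [segmentation_config()].
#' @return Numeric matrix, same height/width, intensities in `[0, 1]`,
#'   condensations dark.
#' @export
preprocess <- function(image, config = segmentation_config()) {
  if (length(image) == 0L) stop("empty image")
  x <- to_gray(image)
  x <- rescale01(x)
  if (config$polarity == "bright") x <- 1 - x
  if (config$clahe_tile > 0 && diff(range(x)) > .Machine$double.eps) {
    nx <- max(1L, min(16L, round(ncol(x) / config$clahe_tile)))
    ny <- max(1L, min(16L, round(nrow(x) / config$clahe_tile)))
    ## EBImage images are indexed [x, y]; transpose in and out.
    x <- t(EBImage::clahe(t(x), nx = nx, ny = ny, limit = config$clahe_clip))
  }
  if (config$lowpass_sigma > 0) {
    x <- t(as.matrix(EBImage::gblur(t(x), sigma = config$lowpass_sigma,
                                    boundary = "replicate")))
  }
  rescale01(x)
}

#' Binarize a preprocessed image and clean the mask
#'
#' Thresholds with Otsu's method (global), takes the dark class as
#' foreground (condensations; [preprocess()] has normalized polarity),
#' then applies morphological opening (removes small specks), closing
#' (fills small holes), removes components with fewer than
#' `min_object_px` pixels and suppresses structures connected to the
#' image border.
#'
#' @param image preprocessed grayscale matrix in `[0, 1]`.
#' @param config a [segmentation_config()].
#' @return Logical matrix; `TRUE` = condensation foreground.
#' @export
binarize_and_clean <- function(image, config = segmentation_config()) {
  if (length(image) == 0L) stop("empty image")
  if (diff(range(image)) < 1e-8)
    stop("degenerate threshold: image is uniform, Otsu's method is undefined")
  thr <- EBImage::otsu(t(image), range = c(0, 1))
  fg <- image < thr  # dark objects are foreground
  ## Otsu separability guard: a threshold through unimodal noise explains
  ## little of the variance; treat such images as object-free.
  if (config$min_separability > 0 && any(fg) && !all(fg)) {
    w0 <- mean(fg)
    eta <- w0 * (1 - w0) * (mean(image[fg]) - mean(image[!fg]))^2 /
      var(as.numeric(image))
    if (eta < config$min_separability)
      return(matrix(FALSE, nrow(image), ncol(image)))
  }
  m <- matrix(as.numeric(fg), nrow(fg), ncol(fg))
  if (config$open_radius > 0)
    m <- as.matrix(EBImage::opening(m, disc_brush(config$open_radius)))
  if (config$close_radius > 0)
    m <- as.matrix(EBImage::closing(m, disc_brush(config$close_radius)))
  lab <- label_components(m > 0)
  lab <- filter_small_components(lab, config$min_object_px)
  mask <- lab > 0L
  if (config$border_suppress) mask <- clear_border_components(mask)
  matrix(mask, nrow(image), ncol(image))
}

#' Split touching condensations by watershed with minima imposition
#'
#' Computes the Euclidean distance transform of the mask and applies a
#' watershed in which basins are seeded only at extended minima deeper
#' than `minima_depth_h` (shallow minima are filtered out and no minima
#' may occur at the filtered locations), which prevents the
#' over-segmentation a plain watershed produces.
#'
#' @param mask logical matrix from [binarize_and_clean()].
#' @param config a [segmentation_config()].
#' @return A [new_label_map()]; empty mask gives an all-zero map.
#' @export
split_touching <- function(mask, config = segmentation_config()) {
  m <- matrix(as.numeric(mask != 0), nrow(mask), ncol(mask))
  if (!any(m > 0)) return(new_label_map(matrix(0L, nrow(mask), ncol(mask))))
  dm <- EBImage::distmap(t(m))
  ws <- EBImage::watershed(dm, tolerance = config$minima_depth_h, ext = 1L)
  lab <- t(as.matrix(ws))
  storage.mode(lab) <- "integer"
  ## watershed can leave fragments below the size floor; drop and renumber
  lab <- filter_small_components(lab, config$min_object_px)
  new_label_map(lab)
}

#' Segment condensations in a brightfield micromass image
#'
#' Full pipeline: [preprocess()] (grayscale, CLAHE, low-pass),
#' [binarize_and_clean()] (Otsu, morphology, size and border filters) and
#' [split_touching()] (distance-transform watershed with minima
#' imposition). Deterministic for a fixed input and configuration.
#'
#' @param image raw brightfield image (matrix or RGB array).
#' @param config a [segmentation_config()].
#' @return A `label_map` of individual condensations.
#' @examples
#' sc <- generate_micromass_scene(micromass_scene_spec(n_objects = 4, seed = 7))
#' labs <- segment_micromass(sc$image)
#' n_objects(labs)
#' @export
segment_micromass <- function(image, config = segmentation_config()) {
  pre <- preprocess(image, config)
  mask <- binarize_and_clean(pre, config)
  if (!any(mask)) return(new_label_map(matrix(0L, nrow(pre), ncol(pre))))
  split_touching(mask, config)
}
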