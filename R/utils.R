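## Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so generators are
#' reproducible without clobbering the session's random stream.
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

## Min-max rescale to [0,1]; constant input is returned clamped, unchanged
## in shape, so that flat images survive the preprocessing contract.
rescale01 <- function(x) {
  r <- range(x, finite = TRUE)
  if (!all(is.finite(r))) stop("image contains no finite values")
  if (diff(r) < .Machine$double.eps) return(pmin(pmax(x, 0), 1))
  (x - r[1]) / diff(r)
}

## RGB (H x W x 3) to grayscale by Rec.709 luma; 2-D input passes through.
to_gray <- function(image) {
  if (is.matrix(image)) return(image)
  d <- dim(image)
  if (length(d) == 3L && d[3] %in% c(3L, 4L)) {
    w <- c(0.2126, 0.7152, 0.0722)
    return(image[, , 1L] * w[1] + image[, , 2L] * w[2] + image[, , 3L] * w[3])
  }
  if (length(d) == 3L && d[3] == 1L) return(image[, , 1L])
  stop("expected a 2-D matrix or an H x W x 3 RGB array")
}

#' Label connected components of a binary mask
#'
#' 8-connected labelling built on top of 4-connected flood fill: labels
#' from [EBImage::bwlabel()] that touch diagonally are merged.
#'
#' @param mask logical or 0/1 matrix.
#' @return integer matrix; 0 background, 1..N consecutive labels.
#' @noRd
label_components <- function(mask) {
  m <- matrix(as.numeric(mask != 0), nrow(mask), ncol(mask))
  lab <- EBImage::bwlabel(m)
  lab <- matrix(as.integer(lab), nrow(lab), ncol(lab))
  n <- max(lab)
  if (n <= 1L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  ## diagonal neighbour pairs (both diagonals)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]     # down-right
  a2 <- lab[-nr, -1];  b2 <- lab[-1, -nc]    # down-left
  keep1 <- a1 > 0L & b1 > 0L & a1 != b1
  keep2 <- a2 > 0L & b2 > 0L & a2 != b2
  pairs <- unique(rbind(cbind(a1[keep1], b1[keep1]), cbind(a2[keep2], b2[keep2])))
  if (nrow(pairs) > 0L) {
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
    for (k in seq_len(nrow(pairs))) {
      ra <- find(pairs[k, 1L]); rb <- find(pairs[k, 2L])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
    root <- vapply(seq_len(n), find, integer(1))
    relab <- match(root, sort(unique(root)))
    lab[lab > 0L] <- relab[lab[lab > 0L]]
  }
  lab
}

## Drop foreground components connected to the image border (the classic
## border-clearing operator: structures lighter than their surroundings
## that touch the border are suppressed from the foreground).
clear_border_components <- function(mask) {
  lab <- label_components(mask)
  if (max(lab) == 0L) return(mask & FALSE)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border <- border[border > 0L]
  out <- lab > 0L & !(lab %in% border)
  matrix(out, nrow(mask), ncol(mask))
}

## Remove components smaller than min_px (strict <); relabels consecutively.
filter_small_components <- function(lab, min_px) {
  if (max(lab) == 0L) return(lab)
  sizes <- tabulate(lab[lab > 0L], nbins = max(lab))
  keep <- which(sizes >= min_px)
  relab <- integer(max(lab))
  relab[keep] <- seq_along(keep)
  lab[lab > 0L] <- relab[lab[lab > 0L]]
  lab
}

## Per-label pixel coordinates as a list of cbind(row, col) matrices.
region_coords <- function(labels) {
  n <- max(labels)
  if (n == 0L) return(list())
  idx <- which(labels > 0L)
  rr <- ((idx - 1L) %% nrow(labels)) + 1L
  cc <- ((idx - 1L) %/% nrow(labels)) + 1L
  f <- factor(labels[idx], levels = seq_len(n))
  Map(function(r, c) cbind(row = r, col = c), split(rr, f), split(cc, f))
}

## Odd-sized disc structuring element of the given radius (0 = identity).
disc_brush <- function(radius) {
  if (radius <= 0) return(NULL)
  EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
}

## Perimeter of a closed polygon given as a 2-column coordinate matrix.
polygon_perimeter <- function(p) {
  if (is.null(dim(p)) || nrow(p) < 2L) return(0)
  q <- rbind(p, p[1L, , drop = FALSE])
  sum(sqrt(rowSums(diff(q)^2)))
}

## Circular moving average of a closed contour (w odd); suppresses the
## staircase bias of pixel-traced boundaries before measuring length.
smooth_closed_contour <- function(p, w = 5L) {
  n <- nrow(p)
  if (w <= 1L || n < w) return(p)
  k <- (w - 1L) %/% 2L
  out <- p
  for (j in seq(-k, k)) {
    if (j == 0L) next
    out <- out + p[((seq_len(n) + j - 1L) %% n) + 1L, , drop = FALSE]
  }
  out / w
}
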