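# Foreground/background separation.
#
# The cell sheet is located by thresholding the gradient magnitude image:
# flat background produces near-zero gradients while cell texture, membranes
# and the sheet edge produce a heavy upper tail. The threshold is placed
# empirically where that upper tail separates from the dominant low-gradient
# mode of the gradient histogram (see `egt_threshold`), then small spurious
# objects are removed and enclosed holes are filled.

#' Foreground-detection parameters
#'
#' @param min_object_area Connected foreground components smaller than this
#'   (pixels) are discarded as specks. Default 100.
#' @param min_hole_area Background holes enclosed by foreground and smaller
#'   than this are filled. Default `NULL` = 10% of the image area.
#' @param threshold_adjustment Offset, in percentile points of the gradient
#'   distribution, added to the automatically chosen threshold. Positive
#'   values shrink the foreground. Default 0.
#' @return A list of class `foreground_params`.
#' @export
foreground_params <- function(min_object_area = 100, min_hole_area = NULL,
                              threshold_adjustment = 0) {
  if (min_object_area < 0 || (!is.null(min_hole_area) && min_hole_area < 0))
    stop("areas must be non-negative", call. = FALSE)
  structure(list(min_object_area = min_object_area,
                 min_hole_area = min_hole_area,
                 threshold_adjustment = threshold_adjustment),
            class = "foreground_params")
}

#' Sobel gradient magnitude
#'
#' 3x3 Sobel operator with replicated borders; returns the Euclidean norm of
#' the two directional responses. Zero everywhere for a constant image.
#'
#' @param img Numeric matrix, at least 3x3.
#' @return Non-negative numeric matrix of the same shape.
#' @export
gradient_magnitude <- function(img) {
  assert_gray(img)
  if (nrow(img) < 3 || ncol(img) < 3)
    stop("image smaller than the 3x3 gradient stencil", call. = FALSE)
  pad <- rbind(img[1, , drop = FALSE], img, img[nrow(img), , drop = FALSE])
  pad <- cbind(pad[, 1, drop = FALSE], pad, pad[, ncol(pad), drop = FALSE])
  nr <- nrow(img); nc <- ncol(img)
  sh <- function(dr, dc) pad[1 + dr + seq_len(nr), 1 + dc + seq_len(nc)]
  # gx: horizontal derivative (columns), gy: vertical (rows)
  gx <- (sh(-1, 1) + 2 * sh(0, 1) + sh(1, 1)) -
        (sh(-1, -1) + 2 * sh(0, -1) + sh(1, -1))
  gy <- (sh(1, -1) + 2 * sh(1, 0) + sh(1, 1)) -
        (sh(-1, -1) + 2 * sh(-1, 0) + sh(-1, 1))
  sqrt(gx^2 + gy^2)
}

# Empirical threshold on the gradient-magnitude distribution: histogram the
# gradients, find the dominant (background / flat-texture) mode, and place
# the cut at the first bin past the mode where the density falls below 5% of
# the mode's density, i.e. where the foreground tail separates from the
# background mode. The result is converted to a percentile so that
# `threshold_adjustment` operates on a scale-free axis. Returns Inf when the
# distribution has no upper tail (e.g. constant images).
egt_threshold <- function(g, threshold_adjustment = 0) {
  rng <- range(g)
  if (diff(rng) == 0) return(Inf)
  nbins <- 1000L
  cuts <- seq(rng[1], rng[2], length.out = nbins + 1L)
  counts <- tabulate(findInterval(g, cuts, rightmost.closed = TRUE,
                                  all.inside = TRUE), nbins)
  mode_bin <- which.max(counts)
  after <- which(counts[seq(mode_bin, nbins)] < 0.05 * counts[mode_bin])
  if (length(after) == 0) return(Inf)
  thr0 <- cuts[mode_bin + after[1] - 1]
  q <- 100 * mean(g <= thr0)
  q <- min(100, max(0, q + threshold_adjustment))
  if (q >= 100) return(Inf)
  pctl(g, q)
}

#' Empirical-gradient-threshold foreground mask
#'
#' Separates the cell sheet (region of interest) from background: pixels with
#' gradient magnitude above an empirically chosen threshold form the raw
#' mask, then enclosed holes below `min_hole_area` are filled and components
#' below `min_object_area` are dropped. Invariant to adding a constant to the
#' image. A constant image yields an empty mask.
#'
#' @param img Numeric matrix.
#' @param params A [foreground_params()] object.
#' @param connectivity Component connectivity (default 8).
#' @return Logical matrix, `TRUE` = foreground.
#' @export
egt_foreground <- function(img, params = foreground_params(), connectivity = 8L) {
  assert_gray(img)
  g <- gradient_magnitude(img)
  thr <- egt_threshold(g, params$threshold_adjustment)
  mask <- g > thr
  if (!any(mask)) return(mask)
  hole_max <- if (is.null(params$min_hole_area)) 0.1 * length(img)
              else params$min_hole_area
  mask <- fill_holes(mask, hole_max)
  drop_small(mask, params$min_object_area, connectivity)
}

# Fill background components that do not touch the image border and are
# smaller than max_area. Background connectivity is the complement (4) of
# the 8-connected foreground convention.
fill_holes <- function(mask, max_area) {
  bg <- label_components(!mask, connectivity = 4L)
  if (max(bg) == 0) return(mask)
  border <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  sizes <- tabulate(bg[bg > 0], nbins = max(bg))
  fill <- setdiff(which(sizes < max_area), border)
  mask[bg %in% fill] <- TRUE
  mask
}

drop_small <- function(mask, min_area, connectivity = 8L) {
  if (min_area <= 0 || !any(mask)) return(mask)
  lab <- label_components(mask, connectivity)
  sizes <- tabulate(lab[lab > 0], nbins = max(lab))
  mask[lab %in% which(sizes < min_area)] <- FALSE
  mask
}
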