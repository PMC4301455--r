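# Geodesic traversability mask and geodesic distances.
#
# Cell membranes image as thin high-intensity ridges; pixels above a chosen
# intensity percentile of the region of interest are declared non-traversable
# obstacles. Distances between pixels are then shortest-path lengths on the
# pixel adjacency graph restricted to traversable pixels, so two pixels on
# opposite sides of a membrane are far apart (or disconnected) even when
# spatially adjacent.

#' Build a geodesic traversability mask
#'
#' Within the region of interest, pixels whose intensity exceeds the
#' `boundary_percentile` of ROI intensities (for `polarity = "bright"`; falls
#' below the `100 - boundary_percentile` point for `"dark"`) are marked as
#' boundaries that cannot be traversed. Everything outside the ROI is also
#' non-traversable.
#'
#' @param img Numeric intensity matrix.
#' @param roi Logical foreground mask, same shape.
#' @param boundary_percentile Percentile in \[0, 100\] of ROI intensities at
#'   which boundaries start; default 85.
#' @param polarity `"bright"` for membranes brighter than the cell interior
#'   (phase contrast), `"dark"` for dark-boundary modalities.
#' @return An object of class `geodesic_mask`: a list with `traversable`
#'   (logical matrix), `roi`, `cutoff` (the intensity threshold used),
#'   `boundary_percentile` and `polarity`.
#' @export
build_geodesic_mask <- function(img, roi, boundary_percentile = 85,
                                polarity = c("bright", "dark")) {
  assert_gray(img)
  assert_mask(roi, img, "roi")
  polarity <- match.arg(polarity)
  if (boundary_percentile < 0 || boundary_percentile > 100)
    stop("`boundary_percentile` must be in [0, 100]", call. = FALSE)
  if (!any(roi)) stop("empty ROI", call. = FALSE)
  vals <- img[roi]
  if (polarity == "bright") {
    cutoff <- pctl(vals, boundary_percentile)
    blocked <- roi & img > cutoff
  } else {
    cutoff <- pctl(vals, 100 - boundary_percentile)
    blocked <- roi & img < cutoff
  }
  structure(list(traversable = roi & !blocked, roi = roi, cutoff = cutoff,
                 boundary_percentile = boundary_percentile,
                 polarity = polarity),
            class = "geodesic_mask")
}

as_traversable <- function(mask) {
  if (inherits(mask, "geodesic_mask")) mask$traversable
  else { assert_mask(mask); mask }
}

#' Geodesic distance map from source pixels
#'
#' Exact shortest-path length (number of steps; diagonal steps cost
#' `diag_cost`) from the nearest source pixel, on the adjacency graph
#' restricted to traversable pixels. Pixels not connected to any source get
#' `Inf`, matching the convention that disconnected pixels are infinitely
#' far apart.
#'
#' @param mask A `geodesic_mask` or plain logical traversability matrix.
#' @param sources Two-column matrix of (row, col) source pixels, 1-based;
#'   all must be traversable.
#' @param connectivity 4 or 8 (default 8).
#' @param diag_cost Cost of a diagonal step under 8-connectivity: 1 (default,
#'   pure step counting) or `sqrt(2)` for Euclidean-weighted chains.
#' @return Numeric matrix of distances; 0 exactly on sources, `Inf` where
#'   unreachable (including non-traversable pixels).
#' @export
geodesic_distance <- function(mask, sources, connectivity = 8L, diag_cost = 1) {
  trav <- as_traversable(mask)
  sources <- as_coord_matrix(sources)
  if (nrow(sources) == 0) stop("empty source set", call. = FALSE)
  bad <- !trav[sources]
  if (any(bad)) stop("sources must be traversable pixels", call. = FALSE)
  lab <- matrix(0L, nrow(trav), ncol(trav))
  lab[sources] <- 1L
  res <- grow_assign_cpp(trav, lab, diag_cost, check_connectivity(connectivity))
  d <- res$dist
  d[d < 0] <- Inf
  d
}

as_coord_matrix <- function(x) {
  if (is.matrix(x) && ncol(x) == 2) {
    storage.mode(x) <- "integer"
    return(x)
  }
  stop("coordinates must be a two-column (row, col) matrix", call. = FALSE)
}

#' Assign candidate pixels to the nearest seed
#'
#' Each candidate pixel receives the label of the seed object whose current
#' pixel set is nearest, under either the geodesic metric (paths through
#' traversable pixels only) or the Euclidean metric (straight-line distance
#' to the nearest seed boundary pixel, ignoring obstacles). Equidistant
#' candidates go to the smaller label. Candidates unreachable under the
#' geodesic metric are left unassigned (label 0).
#'
#' @param candidates Two-column (row, col) matrix of unassigned pixels.
#' @param seeds Integer label matrix of current seed/cell objects.
#' @param mask A `geodesic_mask` or logical traversability matrix.
#' @param metric `"geodesic"` (default) or `"euclidean"`.
#' @param connectivity 4 or 8.
#' @param diag_cost Diagonal step cost for the geodesic metric.
#' @return Integer vector of labels, one per candidate row; 0 = unassigned.
#' @export
nearest_seed_assignment <- function(candidates, seeds, mask,
                                    metric = c("geodesic", "euclidean"),
                                    connectivity = 8L, diag_cost = 1) {
  metric <- match.arg(metric)
  assert_labels(seeds, "seeds")
  candidates <- as_coord_matrix(candidates)
  if (max(seeds) == 0) stop("no seeds", call. = FALSE)
  storage.mode(seeds) <- "integer"
  if (metric == "euclidean")
    return(nearest_label_euclid_cpp(seeds, candidates))
  trav <- as_traversable(mask)
  res <- grow_assign_cpp(trav, seeds, diag_cost, check_connectivity(connectivity))
  res$label[candidates]
}
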