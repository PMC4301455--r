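# FogBank-style single-cell segmentation: grow one region per seed through
# the percentile-quantized intensity levels, assigning each newly admitted
# pixel to the seed with the nearest boundary under the geodesic metric, so
# that regions cannot flow across high-intensity membrane obstacles.

#' Segmentation parameters
#'
#' @param boundary_percentile Intensity percentile of the ROI above which
#'   pixels form non-traversable cell boundaries (default 85).
#' @param boundary_polarity `"bright"` (phase contrast membranes) or
#'   `"dark"`.
#' @param seed_method `"nucleoli"` (default; biological modeling) or
#'   `"histogram"` (percentile quantization with size constraint).
#' @param seed_params Parameters for the chosen seed method; defaults to
#'   [nucleoli_seed_params()] or [histogram_seed_params()] accordingly.
#' @param grow_direction `"ascending"` admits dark pixels first so that
#'   bright membranes are reached last (phase contrast); `"descending"` is
#'   the mirror image for dark-boundary modalities.
#' @param grow_metric `"geodesic"` (default) or `"euclidean"` pixel-to-seed
#'   distance during growth.
#' @param quantize If `TRUE` (default), growth proceeds over the 100
#'   percentile bins; if `FALSE`, every distinct intensity is its own level.
#'   `quantize = FALSE` together with `grow_metric = "euclidean"` reproduces
#'   the "wopg" ablation (no percentile quantization, no geodesic distance).
#' @param mitotic Detect bright round mitotic cells and overlay them
#'   (default `TRUE`).
#' @param mitotic_percentile Intensity percentile for mitotic thresholding
#'   (default 97; must exceed 50).
#' @param mitotic_circularity Minimum roundness of a mitotic body
#'   (default 0.5).
#' @param mitotic_min_size Minimum mitotic body area, pixels (default 30).
#' @param connectivity Pixel adjacency, 4 or 8 (default 8).
#' @param diag_cost Diagonal step cost for geodesic paths (default 1).
#' @return A list of class `fogbank_params`.
#' @export
fogbank_params <- function(boundary_percentile = 85,
                           boundary_polarity = c("bright", "dark"),
                           seed_method = c("nucleoli", "histogram"),
                           seed_params = NULL,
                           grow_direction = c("ascending", "descending"),
                           grow_metric = c("geodesic", "euclidean"),
                           quantize = TRUE,
                           mitotic = TRUE,
                           mitotic_percentile = 97,
                           mitotic_circularity = 0.5,
                           mitotic_min_size = 30,
                           connectivity = 8L,
                           diag_cost = 1) {
  seed_method <- match.arg(seed_method)
  if (is.null(seed_params))
    seed_params <- if (seed_method == "nucleoli") nucleoli_seed_params()
                   else histogram_seed_params()
  if (boundary_percentile < 0 || boundary_percentile > 100)
    stop("`boundary_percentile` must be in [0, 100]", call. = FALSE)
  if (mitotic_percentile <= 50 || mitotic_percentile > 100)
    stop("`mitotic_percentile` must be in (50, 100]", call. = FALSE)
  structure(list(boundary_percentile = boundary_percentile,
                 boundary_polarity = match.arg(boundary_polarity),
                 seed_method = seed_method,
                 seed_params = seed_params,
                 grow_direction = match.arg(grow_direction),
                 grow_metric = match.arg(grow_metric),
                 quantize = isTRUE(quantize),
                 mitotic = isTRUE(mitotic),
                 mitotic_percentile = mitotic_percentile,
                 mitotic_circularity = mitotic_circularity,
                 mitotic_min_size = mitotic_min_size,
                 connectivity = check_connectivity(connectivity),
                 diag_cost = diag_cost),
            class = "fogbank_params")
}

#' Grow single-cell regions from seeds
#'
#' Starting from the seed objects, pixels are admitted level by level (the
#' 100 percentile bins of the traversable ROI intensities, or every distinct
#' intensity when `quantize = FALSE`) and each admitted pixel is assigned to
#' the seed whose current boundary is nearest — geodesic paths run only
#' through already-assigned pixels and pixels of the current level, so
#' growth respects membrane obstacles. Within one level all pixels are
#' assigned simultaneously by multi-source distance; equidistant pixels go
#' to the smaller label. After all levels, remaining foreground pixels
#' (non-traversable membrane pixels, and pockets walled off from every
#' seed) are assigned to the nearest cell ignoring obstacles, so the final
#' mask has no unlabeled foreground reachable within the ROI.
#'
#' @param img Numeric intensity matrix.
#' @param seeds Integer label matrix of seed objects (positive labels).
#' @param geo A `geodesic_mask` from [build_geodesic_mask()].
#' @param params A [fogbank_params()] object.
#' @return Integer label matrix; the set of positive labels equals the set
#'   of seed labels.
#' @export
fogbank_grow <- function(img, seeds, geo, params = fogbank_params()) {
  assert_gray(img)
  assert_labels(seeds, "seeds")
  storage.mode(seeds) <- "integer"
  if (max(seeds) == 0) stop("no seeds", call. = FALSE)
  if (!inherits(geo, "geodesic_mask"))
    stop("`geo` must be a geodesic_mask", call. = FALSE)
  conn <- params$connectivity
  roi <- geo$roi
  euclid <- params$grow_metric == "euclidean"
  # under the Euclidean metric the traversability mask plays no role
  work <- if (euclid) roi else geo$traversable

  seed_labels <- sort(unique(seeds[seeds > 0]))
  out <- seeds
  out[!work] <- 0L
  lost <- setdiff(seed_labels, out[out > 0])
  if (length(lost) > 0)
    stop("seed(s) entirely outside the traversable ROI: ",
         paste(lost, collapse = ", "), call. = FALSE)

  vals <- img[work]
  thresholds <- if (params$quantize) pctl(vals, 1:100)
                else sort(unique(vals))
  asc <- params$grow_direction == "ascending"
  if (!asc) thresholds <- rev(thresholds)

  unassigned <- work & out == 0L
  for (thr in thresholds) {
    if (!any(unassigned)) break
    sel <- unassigned & (if (asc) img <= thr else img >= thr)
    cand <- which(sel, arr.ind = TRUE)
    if (nrow(cand) == 0) next
    lab <- if (euclid) {
      nearest_label_euclid_cpp(out, cand)
    } else {
      step_trav <- (out > 0L) | sel
      res <- grow_assign_cpp(step_trav, out, params$diag_cost, conn)
      res$label[cand]
    }
    hit <- lab > 0L
    if (any(hit)) {
      out[cand[hit, , drop = FALSE]] <- lab[hit]
      unassigned[cand[hit, , drop = FALSE]] <- FALSE
    }
  }

  # final pass: membrane pixels and walled-off pockets join the nearest
  # cell, measured ignoring obstacles but staying inside the ROI
  rest <- roi & out == 0L
  if (any(rest)) {
    res <- grow_assign_cpp(roi, out, params$diag_cost, conn)
    fill <- which(rest & res$label > 0L)
    out[fill] <- res$label[fill]
  }
  out
}

#' Detect mitotic cells
#'
#' Mitotic cells image as very bright round bodies: pixels above the
#' `mitotic_percentile` of ROI intensities are thresholded and the resulting
#' clusters are kept when both large enough and round enough.
#'
#' @param img Numeric intensity matrix.
#' @param roi Logical foreground mask.
#' @param params A [fogbank_params()] object (uses the `mitotic_*` fields).
#' @return Integer label matrix of mitotic objects (possibly all zero).
#' @export
detect_mitotic <- function(img, roi, params = fogbank_params()) {
  assert_gray(img)
  assert_mask(roi, img, "roi")
  if (!any(roi)) return(matrix(0L, nrow(img), ncol(img)))
  thr <- pctl(img[roi], params$mitotic_percentile)
  comp <- label_components(img > thr & roi, params$connectivity)
  ncomp <- max(comp)
  if (ncomp == 0) return(comp)
  sizes <- tabulate(comp[comp > 0], nbins = ncomp)
  keep <- which(sizes >= params$mitotic_min_size)
  keep <- keep[vapply(keep, function(k)
    circularity(which(comp == k, arr.ind = TRUE)) >= params$mitotic_circularity,
    logical(1))]
  out <- matrix(0L, nrow(img), ncol(img))
  for (i in seq_along(keep)) out[comp == keep[i]] <- i
  out
}

#' Overlay mitotic objects onto a cell segmentation
#'
#' Each mitotic object receives a fresh label that overwrites the cell
#' labels beneath it; all other pixels are unchanged. Output labels are
#' renumbered contiguously 1..K.
#'
#' @param cells Integer label matrix of grown cells.
#' @param mitotic Integer label matrix of mitotic objects, same shape.
#' @return Integer label matrix.
#' @export
merge_mitotic <- function(cells, mitotic) {
  assert_labels(cells, "cells")
  assert_labels(mitotic, "mitotic")
  if (!identical(dim(cells), dim(mitotic)))
    stop("shape mismatch between cells and mitotic masks", call. = FALSE)
  out <- cells
  storage.mode(out) <- "integer"
  base <- max(out)
  sel <- mitotic > 0
  out[sel] <- base + as.integer(mitotic[sel])
  relabel_contiguous(out)
}

#' Full single-cell segmentation pipeline
#'
#' Orchestrates the five stages: (1) foreground/background separation,
#' (2) geodesic boundary mask, (3) seed detection, (4) region growing from
#' the seeds over percentile levels, (5) mitotic cell detection and overlay.
#' Deterministic for fixed inputs and parameters. Images in which no seed is
#' found fall back to one label per foreground component.
#'
#' @param img Numeric intensity matrix.
#' @param params A [fogbank_params()] object.
#' @param fg_params A [foreground_params()] object.
#' @param roi Optional precomputed foreground mask; skips stage 1.
#' @return Integer label matrix (0 = background).
#' @export
fogbank_segment <- function(img, params = fogbank_params(),
                            fg_params = foreground_params(), roi = NULL) {
  assert_gray(img)
  if (is.null(roi)) roi <- egt_foreground(img, fg_params, params$connectivity)
  empty <- matrix(0L, nrow(img), ncol(img))
  if (!any(roi)) return(empty)
  geo <- build_geodesic_mask(img, roi, params$boundary_percentile,
                             params$boundary_polarity)
  seeds <- switch(params$seed_method,
    nucleoli = nucleoli_seeds(img, roi, params$seed_params, geo,
                              params$connectivity),
    histogram = histogram_quantization_seeds(img, roi, params$seed_params,
                                             geo, params$connectivity))
  cells <- if (max(seeds) == 0) {
    label_components(roi, params$connectivity) # zero-seed fallback
  } else {
    fogbank_grow(img, seeds, geo, params)
  }
  if (params$mitotic) {
    mit <- detect_mitotic(img, roi, params)
    cells <- merge_mitotic(cells, mit)
  } else {
    cells <- relabel_contiguous(cells)
  }
  cells
}
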