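# Seed-point detection: one labeled object per cell, found either by
# histogram percentile quantization with a size constraint, or by nucleoli
# modeling (dark round intranuclear bodies, filtered by size and circularity
# and clustered by centroid distance).

#' Percentile table of ROI intensities
#'
#' The 101 values p(0)...p(100), where p(i) is the intensity below which i%
#' of ROI pixels fall (linear interpolation, the package-wide percentile
#' convention). Quantizing intensities into the bins (p(i-1), p(i)] yields
#' 100 levels, each holding 1% of the pixels when values are distinct.
#'
#' @param img Numeric intensity matrix.
#' @param roi Logical mask of pixels to include.
#' @return Numeric vector of length 101, monotone non-decreasing.
#' @export
percentile_table <- function(img, roi) {
  assert_gray(img)
  assert_mask(roi, img, "roi")
  if (!any(roi)) stop("empty ROI", call. = FALSE)
  pctl(img[roi], 0:100)
}

#' Histogram-quantization seed parameters
#'
#' @param S_T Minimum seed size in pixels (>= 1).
#' @param direction `"ascending"` detects seeds from low intensity upward
#'   (dark basins first), `"descending"` from high intensity downward.
#' @param source Detect on the `"intensity"` image or its `"gradient"`
#'   magnitude.
#' @return A list of class `histogram_seed_params`.
#' @export
histogram_seed_params <- function(S_T = 20, direction = c("ascending", "descending"),
                                  source = c("intensity", "gradient")) {
  if (S_T < 1) stop("S_T must be >= 1", call. = FALSE)
  structure(list(S_T = S_T, direction = match.arg(direction),
                 source = match.arg(source)),
            class = "histogram_seed_params")
}

#' Seed detection by histogram percentile quantization
#'
#' Thresholds the image at each of its 100 percentile levels (ascending:
#' keep pixels strictly below p(i) for i = 1..100; descending: strictly
#' above p(i) for i = 99..0) inside the traversable ROI, labels the
#' connected components at
#' each level, and accepts as a new seed every component of at least `S_T`
#' pixels that contains no previously accepted seed. A component containing
#' exactly one existing seed extends that seed's provisional extent; a
#' component bridging two or more seeds freezes them (seed identities are
#' immutable, so distinct basins are never flooded together).
#'
#' @param img Numeric intensity matrix.
#' @param roi Logical foreground mask.
#' @param params A [histogram_seed_params()] object.
#' @param geo Optional `geodesic_mask`; seeds are confined to its
#'   traversable pixels.
#' @param connectivity 4 or 8.
#' @return Integer label matrix of seed objects (possibly all zero).
#' @export
histogram_quantization_seeds <- function(img, roi, params = histogram_seed_params(),
                                         geo = NULL, connectivity = 8L) {
  assert_gray(img)
  assert_mask(roi, img, "roi")
  work <- if (is.null(geo)) roi else roi & as_traversable(geo)
  if (!any(work)) return(matrix(0L, nrow(img), ncol(img)))
  src <- if (params$source == "gradient") gradient_magnitude(img) else img
  pt <- percentile_table(src, work)
  seeds <- matrix(0L, nrow(img), ncol(img))
  n_seeds <- 0L
  # strict comparisons: at the extreme level nothing strictly exceeds the
  # range, so the full work region never becomes a single degenerate seed
  levels <- if (params$direction == "ascending") 1:100 else 99:0
  for (i in levels) {
    bw <- if (params$direction == "ascending") src < pt[i + 1] else src > pt[i + 1]
    comp <- label_components(bw & work, connectivity)
    if (max(comp) == 0) next
    upd <- accumulate_seeds(comp, seeds, n_seeds, params$S_T)
    seeds <- upd$seeds; n_seeds <- upd$n_seeds
  }
  seeds
}

# One quantization level: components containing no seed and of size >= S_T
# become new seeds; components containing exactly one seed extend it;
# components containing several seeds leave them frozen.
accumulate_seeds <- function(comp, seeds, n_seeds, S_T) {
  pos <- which(comp > 0)
  if (length(pos) == 0) return(list(seeds = seeds, n_seeds = n_seeds))
  by_comp <- split(pos, comp[pos]) # component ids in ascending (scan) order
  for (idx in by_comp) {
    inside <- unique(seeds[idx])
    inside <- inside[inside > 0]
    if (length(inside) == 1L) {
      seeds[idx] <- inside
    } else if (length(inside) == 0L && length(idx) >= S_T) {
      n_seeds <- n_seeds + 1L
      seeds[idx] <- n_seeds
    }
  }
  list(seeds = seeds, n_seeds = n_seeds)
}

#' Circularity of a connected pixel component
#'
#' `C = 4 * pi * area / perimeter^2` with area the pixel count and perimeter
#' the length of the traced outer boundary chain (axial steps count 1,
#' diagonal steps `sqrt(2)`). An ideal disk scores near 1, elongated shapes
#' near 0. Single-pixel components return 1 by convention.
#'
#' @param component Two-column (row, col) matrix of pixel coordinates, or a
#'   logical mask of one connected component.
#' @return Circularity value in (0, ~1\] (slightly above 1 possible for very
#'   small shapes, an artifact of discrete perimeters).
#' @export
circularity <- function(component) {
  if (is.matrix(component) && is.logical(component)) {
    component <- which(component, arr.ind = TRUE)
  }
  component <- as_coord_matrix(component)
  area <- nrow(component)
  if (area == 0) stop("empty component", call. = FALSE)
  if (area == 1) return(1)
  per <- boundary_chain_length(component)
  if (per <= 0) return(1)
  4 * pi * area / per^2
}

# Length of the outer boundary chain, by Moore (8-neighborhood) boundary
# tracing with backtracking start. Holes are ignored; 1-pixel-wide arms are
# traversed in both directions, as expected of a closed outer contour.
boundary_chain_length <- function(coords) {
  rmin <- min(coords[, 1]) - 1L; cmin <- min(coords[, 2]) - 1L
  nr <- max(coords[, 1]) - rmin + 2L; nc <- max(coords[, 2]) - cmin + 2L
  m <- matrix(FALSE, nr, nc)
  m[cbind(coords[, 1] - rmin, coords[, 2] - cmin)] <- TRUE
  # Moore neighborhood in clockwise order starting from W
  dr <- c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L)
  dc <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
  step_len <- ifelse(dr != 0L & dc != 0L, sqrt(2), 1)
  # start: uppermost-leftmost pixel (column-major first), entered from W
  start <- which(m)[1]
  sr <- (start - 1L) %% nr + 1L; sc <- (start - 1L) %/% nr + 1L
  total <- 0
  cr <- sr; cc <- sc
  backtrack <- 1L # index of the neighbor we came from (W for the start)
  first_dir <- NA_integer_
  repeat {
    found <- FALSE
    for (s in 1:8) {
      k <- ((backtrack - 1L + s - 1L) %% 8L) + 1L
      qr <- cr + dr[k]; qc <- cc + dc[k]
      if (qr >= 1 && qr <= nr && qc >= 1 && qc <= nc && m[qr, qc]) {
        total <- total + step_len[k]
        # new backtrack: direction pointing back toward the previous pixel,
        # advanced one position clockwise
        backtrack <- ((k + 4L - 1L + 1L) %% 8L) + 1L
        cr <- qr; cc <- qc
        if (is.na(first_dir)) first_dir <- k
        found <- TRUE
        break
      }
    }
    if (!found) return(0) # isolated pixel (area 1 handled by caller)
    if (cr == sr && cc == sc && total > 1.5) break
    if (total > 8 * (nr + nc) * 4) break # safety stop
  }
  total
}

#' Nucleoli seed parameters
#'
#' @param t Percentile threshold of ROI intensities defining candidate
#'   nucleolus pixels; default 2 (the bottom 2% of intensities, appropriate
#'   for dark nucleoli in phase contrast).
#' @param S_T Minimum nucleolus size in pixels.
#' @param C_T Circularity threshold in \[0, 1\]; rounder than this survives.
#' @param D_N Approximate nucleus diameter in pixels: nucleoli whose
#'   centroids lie closer than `D_N` belong to the same nucleus.
#' @param cluster_metric `"euclidean"` or `"geodesic"` centroid distance.
#' @param polarity `"dark"` thresholds `I <= p(t)`, `"bright"` thresholds
#'   `I >= p(t)`.
#' @return A list of class `nucleoli_seed_params`.
#' @export
nucleoli_seed_params <- function(t = 2, S_T = 10, C_T = 0.5, D_N = 15,
                                 cluster_metric = c("euclidean", "geodesic"),
                                 polarity = c("dark", "bright")) {
  if (t < 0 || t > 100) stop("t must be in [0, 100]", call. = FALSE)
  if (C_T < 0 || C_T > 1) stop("C_T must be in [0, 1]", call. = FALSE)
  if (D_N <= 0) stop("D_N must be positive", call. = FALSE)
  if (S_T < 1) stop("S_T must be >= 1", call. = FALSE)
  structure(list(t = t, S_T = S_T, C_T = C_T, D_N = D_N,
                 cluster_metric = match.arg(cluster_metric),
                 polarity = match.arg(polarity)),
            class = "nucleoli_seed_params")
}

#' Seed detection by nucleoli modeling
#'
#' Thresholds once at the percentile `t` of ROI intensities (dark polarity:
#' `I <= p(t)`), keeps connected components that are both large enough
#' (`>= S_T` pixels) and round enough (circularity `>= C_T`), then
#' single-linkage clusters the survivors: nucleoli whose centroids are
#' closer than the nucleus diameter `D_N` (Euclidean or geodesic, per
#' `cluster_metric`) receive the same label, giving one seed per nucleus.
#'
#' @inheritParams histogram_quantization_seeds
#' @param params A [nucleoli_seed_params()] object.
#' @return Integer label matrix: one label per nucleolus cluster. A label's
#'   pixel set may comprise several disjoint nucleoli of one nucleus.
#' @export
nucleoli_seeds <- function(img, roi, params = nucleoli_seed_params(),
                           geo = NULL, connectivity = 8L) {
  assert_gray(img)
  assert_mask(roi, img, "roi")
  work <- if (is.null(geo)) roi else roi & as_traversable(geo)
  empty <- matrix(0L, nrow(img), ncol(img))
  if (!any(work)) return(empty)
  pt <- percentile_table(img, roi)
  thr <- pt[params$t + 1]
  bw <- if (params$polarity == "dark") img <= thr else img >= thr
  comp <- label_components(bw & work, connectivity)
  ncomp <- max(comp)
  if (ncomp == 0) return(empty)
  sizes <- tabulate(comp[comp > 0], nbins = ncomp)
  keep <- which(sizes >= params$S_T)
  keep <- keep[vapply(keep, function(k)
    circularity(which(comp == k, arr.ind = TRUE)) >= params$C_T, logical(1))]
  if (length(keep) == 0) return(empty)

  cents <- t(vapply(keep, function(k) {
    ix <- which(comp == k, arr.ind = TRUE)
    c(mean(ix[, 1]), mean(ix[, 2]))
  }, numeric(2)))
  d <- centroid_distances(cents, params$cluster_metric, work, connectivity)
  cl <- single_linkage(d, params$D_N)

  # canonical cluster numbering: order clusters by the column-major position
  # of their first pixel, so the labeling is independent of enumeration order
  out <- empty
  for (i in seq_along(keep)) out[comp == keep[i]] <- cl[i]
  relabel_contiguous(out)
}

centroid_distances <- function(cents, metric, trav, connectivity) {
  n <- nrow(cents)
  if (metric == "euclidean" || n == 1) return(as.matrix(stats::dist(cents)))
  # geodesic: measure between the traversable pixels nearest each centroid
  tix <- which(trav, arr.ind = TRUE)
  anchor <- t(vapply(seq_len(n), function(i) {
    d2 <- (tix[, 1] - cents[i, 1])^2 + (tix[, 2] - cents[i, 2])^2
    tix[which.min(d2), ]
  }, integer(2)))
  d <- matrix(Inf, n, n)
  for (i in seq_len(n)) {
    dm <- geodesic_distance(trav, anchor[i, , drop = FALSE],
                            connectivity = connectivity)
    d[i, ] <- dm[anchor]
  }
  diag(d) <- 0
  d
}

# Transitive chaining of components at distance < D_N: connected components
# of the thresholded distance graph (single linkage), via union-find.
single_linkage <- function(d, D_N) {
  n <- nrow(d)
  parent <- seq_len(n)
  findr <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j > i && is.finite(d[i, j]) && d[i, j] < D_N) {
      ri <- findr(i); rj <- findr(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  roots <- vapply(seq_len(n), findr, integer(1))
  match(roots, unique(roots))
}
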