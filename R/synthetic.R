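# Synthetic confluent-sheet phantoms with exact ground truth.
#
# The generator emulates the phenomenology of a phase-contrast confluent
# epithelial sheet: a blob-shaped colony tessellated into polygonal cells by
# thin bright membrane ridges, mid-gray textured cell interiors, small dark
# round nucleoli near each cell center, optional very bright round mitotic
# bodies, additive Gaussian noise, and a flat mid-gray background. Intensities
# are quantized to the 0..255 range of an 8-bit camera. The ground-truth
# label image is the exact Voronoi tessellation (ridge pixels keep the label
# of their own Voronoi cell), so metric tests against it are exact.

#' Synthetic sheet specification
#'
#' Default values describe a realistic 8-bit phase-contrast scene: membranes
#' at 210 counts over a 110-count cell interior (texture sd 5), nucleoli at
#' 35 counts (the darkest objects in the field, as in phase contrast),
#' background a flat mid-gray 95, no noise.
#'
#' @param n_cells Number of cells (>= 1).
#' @param size Image size `c(rows, cols)`.
#' @param membrane_intensity Ridge intensity (bright), counts.
#' @param membrane_width Full ridge width in pixels.
#' @param cell_texture_mean,cell_texture_sd Interior intensity distribution.
#' @param nucleoli_per_cell Number of dark nucleoli per cell.
#' @param nucleolus_radius Nucleolus radius, pixels.
#' @param nucleolus_intensity Nucleolus intensity (dark), counts.
#' @param nucleus_jitter Maximum offset of each nucleolus center from the
#'   cell anchor point, pixels; keeps sibling nucleoli within one nucleus
#'   diameter of each other.
#' @param n_mitotic Number of bright round mitotic bodies (placed in
#'   distinct cells, which then carry no nucleoli).
#' @param mitotic_intensity Mitotic body intensity, counts.
#' @param mitotic_radius Mitotic body radius, pixels.
#' @param background_level Background intensity, counts.
#' @param noise_std Additive Gaussian noise sd, counts.
#' @param rng_seed Integer seed; the whole phantom is reproducible from it.
#' @return A list of class `sheet_spec`.
#' @export
sheet_spec <- function(n_cells = 10, size = c(200, 200),
                       membrane_intensity = 210, membrane_width = 2,
                       cell_texture_mean = 110, cell_texture_sd = 5,
                       nucleoli_per_cell = 2, nucleolus_radius = 3,
                       nucleolus_intensity = 35, nucleus_jitter = 3,
                       n_mitotic = 0, mitotic_intensity = 245,
                       mitotic_radius = 5,
                       background_level = 95, noise_std = 0,
                       rng_seed = 1L) {
  if (n_cells < 1) stop("n_cells must be >= 1", call. = FALSE)
  if (any(size < 32)) stop("image too small", call. = FALSE)
  if (membrane_width < 1 || nucleolus_radius < 1)
    stop("sizes must be positive", call. = FALSE)
  structure(as.list(environment()), class = "sheet_spec")
}

#' Disk-shaped binary mask
#'
#' Pixels within Euclidean distance `radius` of `center`; parts of the disk
#' outside the image are clipped.
#'
#' @param radius Disk radius (>= 0.5 for a single pixel).
#' @param center `c(row, col)` center.
#' @param size Image size `c(rows, cols)`.
#' @return Logical matrix.
#' @export
make_disk <- function(radius, center, size) {
  rows <- matrix(seq_len(size[1]), size[1], size[2])
  cols <- matrix(seq_len(size[2]), size[1], size[2], byrow = TRUE)
  (rows - center[1])^2 + (cols - center[2])^2 <= radius^2
}

#' Generate a confluent-sheet phantom
#'
#' See [sheet_spec()] for the scene model. Cell centers are placed by
#' Poisson-disk (minimum spacing) sampling inside the colony so that no
#' degenerate sliver cells arise; the colony is an ellipse covering roughly
#' half of the frame.
#'
#' @param spec A [sheet_spec()] object.
#' @return A list with `image` (numeric matrix, 0..255 integer counts),
#'   `truth` (integer label matrix, the exact Voronoi tessellation of the
#'   colony), `centers` (one (row, col) anchor per cell), `mitotic_truth`
#'   (integer label matrix of the planted mitotic bodies), and `spec`.
#' @export
make_confluent_sheet <- function(spec = sheet_spec()) {
  stopifnot(inherits(spec, "sheet_spec"))
  with_seed(spec$rng_seed, {
    nr <- spec$size[1]; nc <- spec$size[2]
    rows <- matrix(seq_len(nr), nr, nc)
    cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    colony <- ((rows - nr / 2) / (0.40 * nr))^2 +
              ((cols - nc / 2) / (0.44 * nc))^2 <= 1

    margin <- max(10, min(14, floor(min(spec$size) / 12)))
    centers <- poisson_disk_centers(colony, spec$n_cells, margin = margin)

    # Voronoi tessellation of the colony (Euclidean, ties to lower label)
    d2 <- vapply(seq_len(spec$n_cells), function(k)
      as.numeric((rows - centers[k, 1])^2 + (cols - centers[k, 2])^2),
      numeric(nr * nc))
    truth <- matrix(max.col(-d2, ties.method = "first"), nr, nc)
    truth[!colony] <- 0L
    storage.mode(truth) <- "integer"

    # spatially correlated interior texture (organelle-scale structure, not
    # per-pixel camera noise): box-blurred Gaussian field rescaled to the
    # requested sd
    img <- matrix(spec$background_level, nr, nc)
    tex <- box_blur(matrix(rnorm(nr * nc), nr, nc), 2L)
    tex <- tex / stats::sd(tex) * spec$cell_texture_sd
    img[colony] <- spec$cell_texture_mean + tex[colony]

    # membrane ridges along cell-cell interfaces and the sheet edge
    ridge <- interface_mask_cpp(truth, as.integer(ceiling(spec$membrane_width / 2)),
                                TRUE)
    img[ridge] <- spec$membrane_intensity

    # mitotic bodies first: their host cells carry no nucleoli
    mitotic_truth <- matrix(0L, nr, nc)
    n_mit <- min(spec$n_mitotic, spec$n_cells)
    mit_cells <- if (n_mit > 0) sample(spec$n_cells, n_mit) else integer(0)
    for (i in seq_along(mit_cells)) {
      ctr <- centers[mit_cells[i], ]
      disk <- make_disk(spec$mitotic_radius, ctr, spec$size) &
        truth == mit_cells[i] & !ridge
      img[disk] <- spec$mitotic_intensity
      mitotic_truth[disk] <- i
    }

    # nucleoli: distinct non-overlapping bodies on a small ring around the
    # cell anchor, all within one nucleus diameter of each other
    for (k in setdiff(seq_len(spec$n_cells), mit_cells)) {
      m <- spec$nucleoli_per_cell
      if (m == 0) next
      base <- runif(1, 0, 2 * pi)
      ring <- if (m == 1) 0 else spec$nucleolus_radius + 1.5
      for (j in seq_len(m)) {
        ang <- base + 2 * pi * (j - 1) / m
        ctr <- centers[k, ] + ring * c(cos(ang), sin(ang)) +
          runif(2, -spec$nucleus_jitter / 3, spec$nucleus_jitter / 3)
        disk <- make_disk(spec$nucleolus_radius, ctr, spec$size) &
          truth == k & !ridge
        img[disk] <- spec$nucleolus_intensity
      }
    }

    if (spec$noise_std > 0)
      img <- img + rnorm(length(img), 0, spec$noise_std)
    img <- pmin(pmax(round(img), 0), 255) # 8-bit camera
    img <- matrix(as.numeric(img), nr, nc)

    list(image = img, truth = truth, centers = centers,
         mitotic_truth = mitotic_truth, spec = spec)
  })
}

# Separable 1-D running-mean blur of half-width w in both directions.
box_blur <- function(m, w) {
  k <- 2L * w + 1L
  smooth1 <- function(x) {
    n <- length(x)
    cs <- cumsum(c(0, x))
    lo <- pmax(seq_len(n) - w, 1L); hi <- pmin(seq_len(n) + w, n)
    (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
  m <- apply(m, 2, smooth1)
  t(apply(m, 1, smooth1))
}

# Rejection sampling of n points inside the colony, at least `margin` pixels
# from its edge and pairwise at least 0.6 * sqrt(area / n) apart.
poisson_disk_centers <- function(colony, n, margin = 14) {
  area <- sum(colony)
  d_min <- 0.6 * sqrt(area / n)
  core <- colony & !interface_mask_cpp(colony + 0L, as.integer(margin), TRUE)
  ix <- which(core, arr.ind = TRUE)
  if (nrow(ix) < n) stop("n_cells too large for the image area", call. = FALSE)
  pts <- matrix(0, n, 2)
  placed <- 0
  for (try in seq_len(400 * n)) {
    cand <- ix[sample(nrow(ix), 1), ]
    if (placed > 0) {
      d2 <- (pts[seq_len(placed), 1] - cand[1])^2 +
            (pts[seq_len(placed), 2] - cand[2])^2
      if (min(d2) < d_min^2) next
    }
    placed <- placed + 1
    pts[placed, ] <- cand
    if (placed == n) break
  }
  if (placed < n) stop("n_cells too large for the image area", call. = FALSE)
  colnames(pts) <- c("row", "col")
  pts
}
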