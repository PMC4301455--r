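# Shared validation and small numeric helpers.

assert_gray <- function(img, arg = "img") {
  if (!is.matrix(img) || !is.numeric(img))
    stop(sprintf("`%s` must be a numeric matrix", arg), call. = FALSE)
  if (any(!is.finite(img)))
    stop(sprintf("`%s` contains non-finite values", arg), call. = FALSE)
  invisible(img)
}

assert_mask <- function(mask, img = NULL, arg = "mask") {
  if (!is.matrix(mask) || !is.logical(mask))
    stop(sprintf("`%s` must be a logical matrix", arg), call. = FALSE)
  if (anyNA(mask))
    stop(sprintf("`%s` contains NA", arg), call. = FALSE)
  if (!is.null(img) && !identical(dim(mask), dim(img)))
    stop(sprintf("`%s` shape does not match the image", arg), call. = FALSE)
  invisible(mask)
}

assert_labels <- function(labels, arg = "labels") {
  if (!is.matrix(labels) || !is.numeric(labels))
    stop(sprintf("`%s` must be an integer-valued matrix", arg), call. = FALSE)
  if (anyNA(labels) || any(labels < 0) || any(labels != round(labels)))
    stop(sprintf("`%s` must hold non-negative integers", arg), call. = FALSE)
  invisible(labels)
}

check_connectivity <- function(connectivity) {
  if (!connectivity %in% c(4L, 8L))
    stop("`connectivity` must be 4 or 8", call. = FALSE)
  as.integer(connectivity)
}

#' Label connected components of a binary mask
#'
#' Deterministic flood-fill labeling; components are numbered by the
#' column-major position of their first pixel.
#'
#' @param mask Logical matrix.
#' @param connectivity Pixel adjacency, 4 or 8 (default 8, the package-wide
#'   convention for cell masks).
#' @return Integer matrix of the same shape; 0 = background.
#' @export
label_components <- function(mask, connectivity = 8L) {
  assert_mask(mask)
  cc_label_cpp(mask, check_connectivity(connectivity))
}

# Percentile with the package-wide convention: linear interpolation
# (stats::quantile type 7) over the supplied pixel values.
pctl <- function(values, p) {
  stats::quantile(values, p / 100, type = 7, names = FALSE)
}

# Renumber positive labels to 1..K, preserving the order of label values.
relabel_contiguous <- function(labels) {
  u <- sort(unique(labels[labels > 0]))
  if (length(u) == 0L) return(matrix(0L, nrow(labels), ncol(labels)))
  out <- labels
  out[labels > 0] <- match(labels[labels > 0], u)
  storage.mode(out) <- "integer"
  out
}

# Run `expr` under a seeded RNG stream, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
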