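# Segmentation evaluation against a reference labeled mask: contingency
# table over foreground pixels, Adjusted Rand Index with background
# discarded, and cell-level matching (TP / FP / FN, over- and
# under-segmentation, cell count accuracy CCA = TP / (N + FP)).

#' Contingency table between two labeled masks
#'
#' Overlap pixel counts between reference cells and test cells, computed
#' over the pixels that are foreground in at least one mask. Pixels that are
#' background in exactly one of the two masks are retained as singleton
#' clusters on that side (each such pixel is its own group), so the row and
#' column sums reconcile with the total `T`; background-background pixels
#' are discarded entirely.
#'
#' @param ref Integer label matrix (reference).
#' @param seg Integer label matrix (test), same shape.
#' @return A list of class `contingency_table`: `tab` (matrix of overlap
#'   counts between positive labels, rownames = reference labels, colnames =
#'   test labels), `ref_only` (per reference label, pixels where the test
#'   mask is background), `seg_only` (per test label, pixels where the
#'   reference is background), `a` (reference cell sizes over counted
#'   pixels), `b` (test cell sizes), and `T` (total counted pixels).
#' @export
contingency <- function(ref, seg) {
  assert_labels(ref, "ref")
  assert_labels(seg, "seg")
  if (!identical(dim(ref), dim(seg)))
    stop("shape mismatch between ref and seg", call. = FALSE)
  idx <- which(ref > 0 | seg > 0)
  r <- ref[idx]; s <- seg[idx]
  rl <- sort(unique(r[r > 0])); sl <- sort(unique(s[s > 0]))
  both <- r > 0 & s > 0
  tab <- matrix(0, length(rl), length(sl), dimnames = list(rl, sl))
  if (any(both)) {
    cnt <- table(factor(r[both], levels = rl), factor(s[both], levels = sl))
    tab[] <- as.numeric(cnt)
  }
  ref_only <- vapply(rl, function(i) sum(r == i & s == 0), numeric(1))
  seg_only <- vapply(sl, function(j) sum(s == j & r == 0), numeric(1))
  a <- rowSums(tab) + ref_only
  b <- colSums(tab) + seg_only
  structure(list(tab = tab, ref_only = ref_only, seg_only = seg_only,
                 a = a, b = b, T = length(idx)),
            class = "contingency_table")
}

choose2 <- function(n) n * (n - 1) / 2

#' Adjusted Rand Index between two labeled masks
#'
#' Chance-corrected pixel-pair agreement between the two labelings,
#' evaluated on the contingency table over foreground pixels (background
#' discarded; pixels foreground in only one mask count as singleton
#' disagreements). Bounded above by 1 (identical partitions). When both
#' partitions are trivial the index is 1 by convention.
#'
#' @inheritParams contingency
#' @return Scalar ARI.
#' @export
adjusted_rand_index <- function(ref, seg) {
  ct <- contingency(ref, seg)
  if (ct$T == 0) stop("both masks are empty", call. = FALSE)
  sum_nij <- sum(choose2(ct$tab)) # singleton clusters contribute C(1,2) = 0
  sum_a <- sum(choose2(ct$a))
  sum_b <- sum(choose2(ct$b))
  tot <- choose2(ct$T)
  expected <- sum_a * sum_b / tot
  denom <- (sum_a + sum_b) / 2 - expected
  if (denom == 0) return(1) # both partitions trivial: perfect agreement
  (sum_nij - expected) / denom
}

#' Cell-level matching between reference and test masks
#'
#' Mutual-majority matching: a reference cell is a true positive when a
#' single test cell covers more than `overlap_fraction` of its pixels and
#' that test cell in turn lies (by the same fraction) mostly inside this
#' reference cell. Complementary counts: a reference cell claimed by two or
#' more test cells (each lying mostly inside it) is over-segmented; a test
#' cell covering the majority of two or more reference cells is
#' under-segmenting; reference cells touched by no majority test cell and
#' claimed by none are false negatives; test cells mostly outside every
#' reference cell (and not under-segmenting) are false positives.
#'
#' @inheritParams contingency
#' @param overlap_fraction Majority threshold in (0, 1\]; default 0.5.
#' @return A list with `TP`, `FP`, `FN`, `over`, `under`, and `N` (number of
#'   reference cells).
#' @export
match_cells <- function(ref, seg, overlap_fraction = 0.5) {
  if (overlap_fraction <= 0 || overlap_fraction > 1)
    stop("`overlap_fraction` must be in (0, 1]", call. = FALSE)
  ct <- contingency(ref, seg)
  tab <- ct$tab
  nref <- nrow(tab); nseg <- ncol(tab)
  N <- nref
  if (nseg == 0)
    return(list(TP = 0L, FP = 0L, FN = N, over = 0L, under = 0L, N = N))
  f <- overlap_fraction
  # test cell j lies mostly inside reference major_ref(j)
  claims <- matrix(FALSE, nref, nseg) # [i, j]: j claims i
  for (j in seq_len(nseg)) {
    i <- which.max(tab[, j])
    if (tab[i, j] > f * ct$b[j]) claims[i, j] <- TRUE
  }
  # reference cell i is majority-covered by test major_test(i)
  covers <- integer(nref) # index of covering test cell, 0 = none
  for (i in seq_len(nref)) {
    j <- which.max(tab[i, ])
    if (tab[i, j] > f * ct$a[i]) covers[i] <- j
  }
  n_claims <- rowSums(claims)
  TP <- sum(vapply(seq_len(nref), function(i)
    covers[i] > 0 && claims[i, covers[i]], logical(1)))
  over <- sum(n_claims >= 2)
  under_j <- vapply(seq_len(nseg), function(j)
    sum(tab[, j] > f * ct$a) >= 2, logical(1))
  under <- sum(under_j)
  FN <- sum(covers == 0 & n_claims == 0)
  FP <- sum(colSums(claims) == 0 & !under_j)
  list(TP = as.integer(TP), FP = as.integer(FP), FN = as.integer(FN),
       over = as.integer(over), under = as.integer(under), N = as.integer(N))
}

#' Cell count accuracy
#'
#' `CCA = TP / (N + FP)`: 1 only when every reference cell is correctly
#' detected and no spurious cell is produced.
#'
#' @param TP True positive count.
#' @param N Reference cell count (>= 1).
#' @param FP False positive count.
#' @return Scalar in \[0, 1\].
#' @export
cell_count_accuracy <- function(TP, N, FP) {
  if (N < 1) stop("N must be >= 1", call. = FALSE)
  TP / (N + FP)
}

#' Full segmentation scorecard
#'
#' Convenience wrapper computing cell matching, CCA and ARI in one call.
#'
#' @inheritParams match_cells
#' @return A list of class `segmentation_metrics` with fields `N`, `TP`,
#'   `FP`, `FN`, `over`, `under`, `CCA`, `ARI`.
#' @export
segmentation_metrics <- function(ref, seg, overlap_fraction = 0.5) {
  m <- match_cells(ref, seg, overlap_fraction)
  cca <- if (m$N >= 1) cell_count_accuracy(m$TP, m$N, m$FP) else NA_real_
  ari <- adjusted_rand_index(ref, seg)
  structure(c(m, list(CCA = cca, ARI = ari)), class = "segmentation_metrics")
}

#' @export
print.segmentation_metrics <- function(x, ...) {
  cat(sprintf("cells (reference): %d\n", x$N))
  cat(sprintf("TP %d | FP %d | FN %d | over %d | under %d\n",
              x$TP, x$FP, x$FN, x$over, x$under))
  cat(sprintf("CCA %.4f | ARI %.4f\n", x$CCA, x$ARI))
  invisible(x)
}
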