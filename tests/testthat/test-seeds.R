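# Seed detection: percentile table structure, histogram-quantization seeds,
# circularity calibration, nucleoli filtering and clustering.

test_that("percentile table partitions ranks as stated", {
  # ROI holding 1..100 once each: table is monotone and spans the range
  img <- matrix(sample(1:100), 10, 10)
  pt <- percentile_table(img, matrix(TRUE, 10, 10))
  expect_length(pt, 101)
  expect_true(all(diff(pt) >= 0))
  expect_equal(pt[1], 1); expect_equal(pt[101], 100)

  # constant image degenerates to one effective level, not an error
  ptc <- percentile_table(matrix(4, 6, 6), matrix(TRUE, 6, 6))
  expect_true(all(ptc == 4))

  # 10,000 distinct values: each bin (p(i-1), p(i)] holds exactly 100 pixels
  set.seed(1)
  vals <- sample(seq_len(10^6), 10^4)
  img <- matrix(vals, 100, 100)
  pt <- percentile_table(img, matrix(TRUE, 100, 100))
  counts <- vapply(1:100, function(i)
    sum(vals > pt[i] & vals <= pt[i + 1]), numeric(1))
  counts[1] <- counts[1] + sum(vals <= pt[1])
  expect_true(all(counts == 100))

  expect_error(percentile_table(img, matrix(FALSE, 100, 100)), "empty ROI")
})

test_that("histogram seeds: two blobs, size constraint, single bowl", {
  tb <- two_blob_image()
  p <- histogram_seed_params(S_T = 20, direction = "ascending")
  seeds <- histogram_quantization_seeds(tb$image, tb$roi, p)
  expect_equal(max(seeds), 2)
  # each blob hosts exactly one seed
  expect_equal(length(unique(seeds[tb$blobs[[1]] & seeds > 0])), 1)
  expect_equal(length(unique(seeds[tb$blobs[[2]] & seeds > 0])), 1)

  # S_T above either blob size: zero seeds
  big <- histogram_seed_params(S_T = 500, direction = "ascending")
  expect_equal(max(histogram_quantization_seeds(tb$image, tb$roi, big)), 0)

  # single-minimum bowl: exactly one seed
  bowl <- outer(1:40, 1:40, function(r, c) (r - 20)^2 + (c - 20)^2)
  s1 <- histogram_quantization_seeds(bowl, matrix(TRUE, 40, 40),
                                     histogram_seed_params(S_T = 10))
  expect_equal(max(s1), 1)
})

test_that("histogram seed count is non-increasing in S_T", {
  sh <- make_confluent_sheet(sheet_spec(n_cells = 5, size = c(120, 120),
                                        rng_seed = 2))
  roi <- sh$truth > 0
  counts <- vapply(c(5, 20, 60, 200), function(st)
    max(histogram_quantization_seeds(sh$image, roi,
        histogram_seed_params(S_T = st))), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("circularity calibration on canonical shapes", {
  # digital disk r = 15: frozen value from the boundary-chain estimator
  disk <- which(make_disk(15, c(20, 20), c(40, 40)), arr.ind = TRUE)
  expect_equal(circularity(disk), 0.9106697, tolerance = 1e-6)
  expect_gt(circularity(disk), 0.9)

  # 1x50 line of pixels scores very low
  expect_lt(circularity(cbind(5L, 1:50)), 0.3)

  # large square tends to pi/4 under the exact side-length perimeter
  sq <- which(matrix(TRUE, 60, 60), arr.ind = TRUE)
  expect_equal(circularity(sq), 4 * pi * 60^2 / (4 * 59)^2, tolerance = 1e-6)

  expect_equal(circularity(cbind(3L, 3L)), 1) # single pixel, by convention
  expect_error(circularity(matrix(0L, 0, 2)), "empty")
})

test_that("nucleoli seeds: clustering by D_N and circularity rejection", {
  # dark pixels kept at >= 2% of the field so the bottom-2% rule captures
  # the nucleoli exactly
  mk <- function(centers, radius = 5, extra = NULL) {
    img <- matrix(120, 80, 80)
    for (i in seq_len(nrow(centers)))
      img[make_disk(radius, centers[i, ], c(80, 80))] <- 20
    if (!is.null(extra)) img[extra] <- 20
    img
  }
  roi <- matrix(TRUE, 80, 80)
  pars <- nucleoli_seed_params(t = 2, S_T = 10, C_T = 0.5, D_N = 16)

  # two blobs 3 * D_N apart: two seeds
  s2 <- nucleoli_seeds(mk(rbind(c(20, 20), c(20, 68))), roi, pars)
  expect_equal(max(s2), 2)

  # three disjoint blobs at mutual distance ~ 0.6 * D_N: one nucleus
  tri <- rbind(c(40, 40), c(40, 50), c(48, 45))
  s1 <- nucleoli_seeds(mk(tri, radius = 4), roi, pars)
  expect_equal(max(s1), 1)
  expect_equal(max(label_components(s1 > 0)), 3) # three separate nucleoli

  # a round blob plus an elongated streak below C_T: one seed
  streak <- matrix(FALSE, 80, 80)
  streak[70:71, 21:60] <- TRUE
  se <- nucleoli_seeds(mk(rbind(c(20, 20)), extra = streak), roi, pars)
  expect_equal(max(se), 1)
  expect_true(all(se[streak] == 0))
})

test_that("nucleoli seed count is monotone in the filter parameters", {
  sh <- make_confluent_sheet(sheet_spec(n_cells = 6, rng_seed = 4))
  roi <- sh$truth > 0
  count <- function(...) max(nucleoli_seeds(sh$image, roi,
                                            nucleoli_seed_params(...)))
  # S_T up -> count non-increasing
  expect_true(all(diff(vapply(c(5, 15, 40), function(s)
    count(S_T = s), numeric(1))) <= 0))
  # C_T up -> count non-increasing
  expect_true(all(diff(vapply(c(0.2, 0.6, 0.95), function(ct)
    count(C_T = ct), numeric(1))) <= 0))
  # D_N up -> clusters only merge, count non-increasing
  expect_true(all(diff(vapply(c(4, 15, 60), function(dn)
    count(D_N = dn), numeric(1))) <= 0))
})

test_that("seed objects are disjoint and respect the traversable ROI", {
  sh <- make_confluent_sheet(sheet_spec(n_cells = 6, rng_seed = 4))
  roi <- sh$truth > 0
  geo <- build_geodesic_mask(sh$image, roi)
  for (seeds in list(
    nucleoli_seeds(sh$image, roi, nucleoli_seed_params(), geo),
    histogram_quantization_seeds(sh$image, roi, histogram_seed_params(S_T = 20), geo))) {
    expect_true(all(seeds[!geo$traversable] == 0))
    ks <- setdiff(unique(as.vector(seeds)), 0L)
    expect_equal(sort(ks), seq_along(ks)) # contiguous labels, one per object
  }
})
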