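# Region growing, mitotic detection/overlay and the assembled pipeline.

test_that("one seed floods the whole reachable ROI", {
  img <- matrix(50, 20, 20)
  roi <- matrix(FALSE, 20, 20); roi[3:18, 3:18] <- TRUE
  geo <- build_geodesic_mask(img, roi, 100) # constant: everything traversable
  seeds <- matrix(0L, 20, 20); seeds[10, 10] <- 1L
  out <- fogbank_grow(img, seeds, geo)
  expect_true(all(out[roi] == 1L))
  expect_true(all(out[!roi] == 0L))
})

test_that("a bright ridge above the boundary percentile separates two seeds", {
  img <- matrix(50, 21, 21)
  img[, 11] <- 200 # ridge column
  roi <- matrix(TRUE, 21, 21)
  geo <- build_geodesic_mask(img, roi, 90)
  expect_true(all(!geo$traversable[, 11]))
  seeds <- matrix(0L, 21, 21); seeds[11, 4] <- 1L; seeds[11, 18] <- 2L
  out <- fogbank_grow(img, seeds, geo)
  expect_true(all(out[, 1:10] == 1L))
  expect_true(all(out[, 12:21] == 2L))
  # ridge pixels were assigned in the final pass, none left unlabeled
  expect_true(all(out[, 11] > 0L))
})

test_that("grow conserves the seed label set and partitions the ROI", {
  sh <- make_confluent_sheet(sheet_spec(n_cells = 7, rng_seed = 12))
  roi <- egt_foreground(sh$image)
  geo <- build_geodesic_mask(sh$image, roi)
  seeds <- nucleoli_seeds(sh$image, roi, nucleoli_seed_params(), geo)
  out <- fogbank_grow(sh$image, seeds, geo)
  expect_setequal(unique(as.vector(out[out > 0])),
                  unique(as.vector(seeds[seeds > 0])))
  expect_true(all(out[roi] > 0L)) # ROI fully covered (colony is connected)
  expect_true(all(out[!roi] == 0L))
  # determinism: bit-identical rerun
  expect_identical(out, fogbank_grow(sh$image, seeds, geo))
})

test_that("quantized and unquantized growth coincide on few-valued images", {
  img <- matrix(rep(c(10, 20, 30, 40), each = 100), 20, 20)
  img[8:12, 8:12] <- 5
  roi <- matrix(TRUE, 20, 20)
  geo <- build_geodesic_mask(img, roi, 100)
  seeds <- matrix(0L, 20, 20); seeds[10, 10] <- 1L; seeds[2, 2] <- 2L
  a <- fogbank_grow(img, seeds, geo, fogbank_params(quantize = TRUE))
  b <- fogbank_grow(img, seeds, geo, fogbank_params(quantize = FALSE))
  expect_identical(a, b)
})

test_that("mitotic detection keeps bright round bodies only", {
  # bright objects total ~2% of the field, below the 97th-percentile cut
  img <- matrix(100, 100, 100)
  img[make_disk(6, c(30, 30), c(100, 100))] <- 240  # round and bright
  img[70:71, 20:60] <- 240                          # bright but elongated
  roi <- matrix(TRUE, 100, 100)
  p <- fogbank_params(mitotic_min_size = 30, mitotic_circularity = 0.5)
  mit <- detect_mitotic(img, roi, p)
  expect_equal(max(mit), 1)
  expect_true(all(mit[70:71, 20:60] == 0))
  expect_true(all(mit[make_disk(5, c(30, 30), c(100, 100))] == 1))

  # only sub-threshold specks above p(97): nothing detected
  set.seed(1)
  img2 <- matrix(100, 100, 100) + matrix(runif(1e4), 100, 100)
  img2[5, 5] <- 250
  expect_equal(max(detect_mitotic(img2, roi, p)), 0)
})

test_that("merge_mitotic overwrites hosts and renumbers", {
  cells <- matrix(1L, 20, 20); cells[, 11:20] <- 2L
  # empty mitotic mask: unchanged up to renumbering
  expect_identical(merge_mitotic(cells, matrix(0L, 20, 20)), cells)

  # mitotic object strictly inside cell 1
  mit <- matrix(0L, 20, 20); mit[5:8, 3:6] <- 1L
  out <- merge_mitotic(cells, mit)
  expect_equal(max(out), 3)
  expect_true(all(out[5:8, 3:6] == 3L))
  expect_true(all(out[cells == 1L & mit == 0L] == 1L))

  # mitotic object straddling both cells: both hosts shrink
  mit2 <- matrix(0L, 20, 20); mit2[9:12, 9:13] <- 1L
  out2 <- merge_mitotic(cells, mit2)
  expect_equal(max(out2), 3)
  expect_true(all(out2[9:12, 9:13] == 3L))
  expect_equal(sum(out2 == 1L), sum(cells == 1L) - sum(mit2[, 1:10] > 0))

  expect_error(merge_mitotic(cells, matrix(0L, 5, 5)), "shape")
})

test_that("fogbank_segment: blank image, exact recovery, planted mitotic", {
  expect_true(all(fogbank_segment(matrix(9, 50, 50)) == 0L))

  sh <- make_confluent_sheet(sheet_spec(n_cells = 6, rng_seed = 21))
  seg <- fogbank_segment(sh$image)
  expect_equal(max(seg), 6)
  m <- segmentation_metrics(sh$truth, seg)
  expect_gte(m$ARI, 0.8)
  expect_equal(m$CCA, 1)

  # a planted mitotic body adds exactly one (round, bright) object
  shm <- make_confluent_sheet(sheet_spec(n_cells = 6, n_mitotic = 1,
                                         rng_seed = 21))
  segm <- fogbank_segment(shm$image)
  mit <- detect_mitotic(shm$image, shm$truth > 0, fogbank_params())
  expect_equal(max(mit), 1)
  expect_gte(sum(mit > 0 & shm$mitotic_truth > 0) / sum(shm$mitotic_truth > 0),
             0.8)
})

test_that("histogram-seed pipeline also recovers cells on textured sheets", {
  # S_T is set to a sizable fraction of the cell area, so only basins
  # spanning most of one membrane-bounded cell qualify as seeds — the
  # paper's intended regime for this method
  sh <- make_confluent_sheet(sheet_spec(n_cells = 5, nucleoli_per_cell = 1,
                                        size = c(160, 160), rng_seed = 31))
  p <- fogbank_params(seed_method = "histogram",
                      seed_params = histogram_seed_params(S_T = 800))
  seg <- fogbank_segment(sh$image, p)
  expect_equal(max(seg), 5)
  expect_gte(segmentation_metrics(sh$truth, seg)$ARI, 0.8)
})
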