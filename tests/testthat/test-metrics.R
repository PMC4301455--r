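# Evaluation metrics: contingency bookkeeping, ARI against the all-pairs
# oracle, cell matching, and CCA.

test_that("contingency: identical masks give a diagonal table", {
  lab <- matrix(0L, 12, 12)
  lab[2:5, 2:5] <- 1L; lab[8:11, 2:6] <- 2L; lab[3:6, 8:11] <- 3L
  ct <- contingency(lab, lab)
  expect_equal(dim(ct$tab), c(3, 3))
  expect_equal(sum(ct$tab) , sum(diag(ct$tab)))
  expect_equal(unname(diag(ct$tab)), unname(tabulate(lab[lab > 0])))
  expect_equal(ct$T, sum(lab > 0))
})

test_that("contingency: a split cell spreads its row", {
  ref <- matrix(0L, 10, 10); ref[2:9, 2:9] <- 1L
  seg <- ref; seg[2:9, 6:9] <- 2L
  ct <- contingency(ref, seg)
  expect_equal(unname(ct$tab["1", ]), c(32, 32))
  expect_equal(unname(ct$a["1"]), 64)
})

test_that("contingency row/col sums reconcile with a brute-force loop", {
  set.seed(11)
  for (rep in 1:5) {
    ref <- random_label_image(16, 16, 3)
    seg <- random_label_image(16, 16, 4)
    ct <- contingency(ref, seg)
    # brute-force double loop over pixels
    for (i in rownames(ct$tab)) for (j in colnames(ct$tab)) {
      n <- 0
      for (p in seq_along(ref))
        if (ref[p] == as.integer(i) && seg[p] == as.integer(j)) n <- n + 1
      expect_equal(unname(ct$tab[i, j]), n)
    }
    expect_equal(unname(ct$a), unname(rowSums(ct$tab) + ct$ref_only))
    expect_equal(unname(ct$b), unname(colSums(ct$tab) + ct$seg_only))
    expect_equal(sum(ct$tab) + sum(ct$ref_only) + sum(ct$seg_only), ct$T)
    expect_error(contingency(ref, seg[1:8, ]), "shape")
  }
})

test_that("ARI: self-comparison and label permutation give 1", {
  set.seed(5)
  for (rep in 1:5) {
    m <- random_label_image(14, 14, 4)
    expect_equal(adjusted_rand_index(m, m), 1)
    perm <- sample(10)
    m2 <- m; m2[m > 0] <- perm[m[m > 0]]
    expect_equal(adjusted_rand_index(m, m2), 1)
    expect_equal(adjusted_rand_index(m, m2), adjusted_rand_index(m2, m))
  }
})

test_that("ARI matches the all-pairs agreement oracle", {
  # 4x4 two-cell toy pair, then randomized small instances
  ref <- matrix(c(1, 1, 0, 0, 1, 1, 0, 0, 0, 0, 2, 2, 0, 0, 2, 2), 4, 4)
  seg <- matrix(c(1, 1, 0, 0, 1, 0, 0, 0, 0, 2, 2, 2, 0, 0, 2, 2), 4, 4)
  expect_equal(adjusted_rand_index(ref, seg), ari_pairs_oracle(ref, seg))

  set.seed(23)
  for (rep in 1:10) {
    a <- random_label_image(10, 10, sample(2:4, 1))
    b <- random_label_image(10, 10, sample(2:4, 1))
    if (all(a == 0) && all(b == 0)) next
    expect_equal(adjusted_rand_index(a, b), ari_pairs_oracle(a, b))
  }
})

test_that("match_cells: identity, split-in-half, empty segmentation", {
  lab <- matrix(0L, 12, 12)
  lab[2:5, 2:5] <- 1L; lab[8:11, 2:6] <- 2L; lab[3:6, 8:11] <- 3L
  m <- match_cells(lab, lab)
  expect_equal(m[c("TP", "FP", "FN", "over", "under")],
               list(TP = 3L, FP = 0L, FN = 0L, over = 0L, under = 0L))

  # one cell split exactly in half: no TP under the strict majority rule,
  # counted as over-segmentation
  ref <- matrix(0L, 10, 10); ref[2:9, 2:9] <- 1L
  seg <- ref; seg[2:9, 6:9] <- 2L
  ms <- match_cells(ref, seg)
  expect_equal(ms$TP, 0L)
  expect_equal(ms$over, 1L)

  # empty segmentation: all reference cells are missed
  me <- match_cells(lab, matrix(0L, 12, 12))
  expect_equal(me$TP, 0L)
  expect_equal(me$FN, 3L)
  expect_equal(cell_count_accuracy(me$TP, me$N, me$FP), 0)

  # one test cell engulfing two reference cells: under-segmentation
  ref2 <- matrix(0L, 10, 10); ref2[2:9, 2:5] <- 1L; ref2[2:9, 6:9] <- 2L
  seg2 <- matrix(0L, 10, 10); seg2[2:9, 2:9] <- 1L
  mu <- match_cells(ref2, seg2)
  expect_equal(mu$under, 1L)
  expect_equal(mu$TP, 0L)
})

test_that("CCA formula and monotonicity in FP", {
  expect_equal(cell_count_accuracy(5, 5, 0), 1)
  expect_equal(cell_count_accuracy(3, 4, 1), 0.6)
  expect_equal(cell_count_accuracy(0, 7, 3), 0)
  cca <- vapply(0:5, function(fp) cell_count_accuracy(4, 6, fp), numeric(1))
  expect_true(all(diff(cca) < 0))
  expect_error(cell_count_accuracy(1, 0, 0), "N")
})

test_that("segmentation_metrics bundles the scorecard", {
  sh <- make_confluent_sheet(sheet_spec(n_cells = 5, size = c(120, 120),
                                        rng_seed = 6))
  m <- segmentation_metrics(sh$truth, sh$truth)
  expect_equal(m$CCA, 1)
  expect_equal(m$ARI, 1)
  expect_equal(m$N, 5L)
  expect_output(print(m), "CCA 1.0000")
})
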