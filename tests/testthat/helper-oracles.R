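# Independent oracles and small fixture builders used across the suite.
# The oracles deliberately share no code with the implementation paths they
# check: plain-R breadth-first search on the explicit pixel graph, and
# all-pairs agreement counting for the Adjusted Rand Index.

# Textbook BFS over the adjacency graph restricted to traversable pixels.
# Unit cost per move (diagonals included under 8-connectivity). Returns a
# distance matrix with Inf where unreachable.
bfs_oracle <- function(trav, sources, connectivity = 8L) {
  nr <- nrow(trav); nc <- ncol(trav)
  offs <- if (connectivity == 8L)
    cbind(c(-1, 1, 0, 0, -1, -1, 1, 1), c(0, 0, -1, 1, -1, 1, -1, 1))
  else cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  dist <- matrix(Inf, nr, nc)
  queue <- sources
  dist[sources] <- 0
  while (nrow(queue) > 0) {
    nxt <- NULL
    for (i in seq_len(nrow(queue))) {
      p <- queue[i, ]
      for (k in seq_len(nrow(offs))) {
        q <- p + offs[k, ]
        if (q[1] < 1 || q[1] > nr || q[2] < 1 || q[2] > nc) next
        if (!trav[q[1], q[2]] || is.finite(dist[q[1], q[2]])) next
        dist[q[1], q[2]] <- dist[p[1], p[2]] + 1
        nxt <- rbind(nxt, q)
      }
    }
    queue <- if (is.null(nxt)) matrix(0L, 0, 2) else nxt
  }
  dist
}

# All-pairs agreement ARI: enumerate every pixel pair among the pixels
# foreground in at least one mask (background side of a mismatched pixel is
# its own singleton group), count pair agreements, and apply the standard
# pair-counting form of the index.
ari_pairs_oracle <- function(ref, seg) {
  idx <- which(ref > 0 | seg > 0)
  r <- ref[idx]; s <- seg[idx]
  # unique negative ids for background-side singletons
  rz <- r == 0; sz <- s == 0
  r[rz] <- -seq_len(sum(rz))
  s[sz] <- -seq_len(sum(sz))
  n <- length(idx)
  a <- b <- cc <- d <- 0
  for (i in seq_len(n - 1)) {
    same_r <- r[(i + 1):n] == r[i]
    same_s <- s[(i + 1):n] == s[i]
    a <- a + sum(same_r & same_s)
    b <- b + sum(same_r & !same_s)
    cc <- cc + sum(!same_r & same_s)
    d <- d + sum(!same_r & !same_s)
  }
  num <- 2 * (a * d - b * cc)
  den <- (a + b) * (b + d) + (a + cc) * (cc + d)
  if (den == 0) return(1)
  num / den
}

# Two dark round blobs on a bright field; returns image, roi, blob masks.
two_blob_image <- function(size = c(60, 60), centers = rbind(c(18, 18), c(42, 42)),
                           radius = 5, dark = 30, bright = 120) {
  img <- matrix(bright, size[1], size[2])
  blobs <- lapply(seq_len(nrow(centers)), function(i)
    make_disk(radius, centers[i, ], size))
  for (b in blobs) img[b] <- dark
  list(image = img, roi = matrix(TRUE, size[1], size[2]), blobs = blobs)
}

# Small random label image with `k` blocky cells for metric tests.
random_label_image <- function(nr, nc, k) {
  lab <- matrix(0L, nr, nc)
  for (i in seq_len(k)) {
    r0 <- sample(nr, 1); c0 <- sample(nc, 1)
    h <- sample(2:max(2, nr %/% 2), 1); w <- sample(2:max(2, nc %/% 2), 1)
    lab[r0:min(nr, r0 + h), c0:min(nc, c0 + w)] <- i
  }
  lab
}

expect_same_labeling <- function(a, b) {
  expect_equal(dim(a), dim(b))
  expect_true(all((a > 0) == (b > 0)))
  if (any(a > 0)) {
    map <- tapply(b[a > 0], a[a > 0], function(x) unique(x))
    expect_true(all(lengths(map) == 1))
    expect_equal(length(unique(unlist(map))), length(map))
  }
}

local_tempdir <- function() {
  d <- tempfile("fogbankr-test-")
  dir.create(d)
  d
}
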