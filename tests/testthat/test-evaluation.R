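test_that("adjusted Rand index matches pair counting and external oracle", {
  a <- c(1, 1, 2, 2, 3, 3)
  expect_equal(adjustedRand(a, a), 1)
  expect_equal(adjustedRand(a, c(2, 2, 1, 1, 3, 3)), 1)  # relabeling
  expect_error(adjustedRand(a, 1:3), "differ in length")

  # brute-force pair-counting oracle on random partitions
  set.seed(50)
  for (rep in 1:5) {
    x <- sample(3, 25, replace = TRUE)
    y <- sample(4, 25, replace = TRUE)
    agree <- disagree <- 0
    n11 <- n00 <- n10 <- n01 <- 0
    for (i in 1:24) for (j in (i + 1):25) {
      sx <- x[i] == x[j]; sy <- y[i] == y[j]
      if (sx && sy) n11 <- n11 + 1
      else if (!sx && !sy) n00 <- n00 + 1
      else if (sx) n10 <- n10 + 1
      else n01 <- n01 + 1
    }
    np <- choose(25, 2)
    expected <- (n11 - (n11 + n10) * (n11 + n01) / np) /
      ((n11 + n10 + n11 + n01) / 2 - (n11 + n10) * (n11 + n01) / np)
    expect_equal(adjustedRand(x, y), expected, tolerance = 1e-12)
    skip_if_not_installed("mclust")
    expect_equal(adjustedRand(x, y), mclust::adjustedRandIndex(x, y),
      tolerance = 1e-12)
  }
})

test_that("normalized mutual information matches the igraph oracle", {
  a <- c(1, 1, 2, 2, 3, 3)
  expect_equal(normalizedMutualInfo(a, a), 1)
  expect_equal(normalizedMutualInfo(a, c(3, 3, 1, 1, 2, 2)), 1)
  set.seed(51)
  x <- sample(3, 40, replace = TRUE)
  y <- sample(3, 40, replace = TRUE)
  expect_gte(normalizedMutualInfo(x, y), 0)
  skip_if_not_installed("igraph")
  expect_equal(normalizedMutualInfo(x, y),
    igraph::compare(x, y, method = "nmi"), tolerance = 1e-10)
})

test_that("mean silhouette follows its per-point definition", {
  # well-separated tight blobs approach 1
  set.seed(52)
  pts <- rbind(matrix(rnorm(30, 0, 0.1), 15, 2),
    matrix(rnorm(30, 10, 0.1), 15, 2))
  lab <- rep(1:2, each = 15)
  expect_gt(silhouetteMean(pts, lab), 0.9)

  # coincident points in two forced clusters: defined as 0
  expect_equal(silhouetteMean(matrix(1, 4, 2), c(1, 1, 2, 2)), 0)

  # 6-point worked case against the explicit double loop
  x6 <- matrix(c(0, 0, 1, 0, 0, 1, 4, 4, 5, 4, 9, 9), 6, 2, byrow = TRUE)
  l6 <- c(1, 1, 1, 2, 2, 3)
  D <- as.matrix(dist(x6))
  svals <- numeric(6)
  for (i in 1:6) {
    own <- which(l6 == l6[i] & seq_len(6) != i)
    if (!length(own)) { svals[i] <- 0; next }
    a <- mean(D[i, own])
    b <- min(vapply(setdiff(unique(l6), l6[i]),
      function(c) mean(D[i, l6 == c]), numeric(1)))
    svals[i] <- (b - a) / max(a, b)
  }
  expect_equal(silhouetteMean(x6, l6), mean(svals), tolerance = 1e-12)
  skip_if_not_installed("cluster")
  # cross-check against cluster::silhouette (it scores singletons 0 too)
  sil <- cluster::silhouette(l6, dist(x6))
  expect_equal(silhouetteMean(x6, l6), mean(sil[, "sil_width"]),
    tolerance = 1e-12)
})

test_that("silhouette is invariant under isometries", {
  set.seed(53)
  pts <- matrix(rnorm(40), 20, 2)
  lab <- rep(1:2, 10)
  theta <- 0.7
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  moved <- pts %*% R + matrix(c(5, -3), 20, 2, byrow = TRUE)
  expect_equal(silhouetteMean(moved, lab), silhouetteMean(pts, lab),
    tolerance = 1e-10)
  expect_error(silhouetteMean(pts, rep(1, 20)), "single cluster")

  # a precomputed distance matrix reproduces the coordinate-based value
  expect_equal(silhouetteMean(NULL, lab, distances = dist(pts)),
    silhouetteMean(pts, lab), tolerance = 1e-12)
  expect_error(silhouetteMean(NULL, lab, distances = matrix(1, 20, 19)),
    "symmetric square")
})

test_that("clusterComparison bundles the metrics", {
  set.seed(54)
  pts <- rbind(matrix(rnorm(20, 0, 0.2), 10, 2),
    matrix(rnorm(20, 6, 0.2), 10, 2))
  truth <- rep(1:2, each = 10)
  cc <- clusterComparison(truth, truth, points = pts)
  expect_equal(cc$ari, 1)
  expect_equal(cc$nmi, 1)
  expect_gt(cc$silhouette, 0.9)
})
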