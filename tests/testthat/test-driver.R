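test_that("the joint objective matches a term-wise recomputation", {
  set.seed(40)
  pr <- randProblem(t = 2, n = 10, ms = c(12, 14))
  n <- pr$n
  Zs <- replicate(2, randSimilarity(n), simplify = FALSE)
  S <- randSimilarity(n)
  Fm <- randOrthonormal(n, 3)
  eps <- c(0.4, 0.9)
  alpha <- 0.7; beta <- 1.2; lam <- 0.5

  got <- mrfmscObjective(pr$views, Zs, S, Fm, eps, pr$Llist, alpha, beta, lam)
  # independent term-by-term recomputation
  expected <- 0
  for (v in 1:2) {
    X <- viewValues(pr$views[[v]])
    L <- laplacianValues(pr$Llist[[v]])
    expected <- expected + sum((X - X %*% Zs[[v]])^2) +
      alpha * sum(diag(Zs[[v]] %*% L %*% t(Zs[[v]]))) +
      beta * eps[v] * sum((S - Zs[[v]])^2)
  }
  Ssym <- (S + t(S)) / 2
  LS <- diag(rowSums(Ssym)) - Ssym
  expected <- expected + lam * sum(diag(t(Fm) %*% LS %*% Fm))
  expect_equal(got, expected, tolerance = 1e-10)

  # switch-offs
  zeros <- replicate(2, matrix(0, n, n), simplify = FALSE)
  xnorm <- sum(vapply(pr$views, function(v) sum(viewValues(v)^2), numeric(1)))
  expect_equal(mrfmscObjective(pr$views, zeros, matrix(0, n, n), Fm, eps,
    pr$Llist, 1, 1, 1), xnorm, tolerance = 1e-10)
  expect_equal(mrfmscObjective(pr$views, Zs, S, Fm, eps, pr$Llist, 0, 0, 0),
    sum(vapply(1:2, function(v) reconstructionError(pr$views[[v]], Zs[[v]]),
      numeric(1))), tolerance = 1e-10)
})

test_that("identical views get equal weights and view order does not matter", {
  sim <- makeMultiview(n = 40, k = 2, dims = c(30, 30), seed = 41)
  v <- sim$views[[1]]
  twin <- OmicsView(viewValues(v), "copy")
  fit <- mrfmsc(list(v, twin), k = 2, K = 8, seed = 1)
  expect_equal(epsTrace(fit)[, 1], epsTrace(fit)[, 2], tolerance = 1e-10)
  expect_equal(epsTrace(fit)[1, ], c(0.5, 0.5), ignore_attr = TRUE)

  sim2 <- makeMultiview(n = 40, k = 2, dims = c(30, 20), seed = 42)
  f12 <- mrfmsc(sim2$views, k = 2, K = 8, seed = 1)
  f21 <- mrfmsc(rev(sim2$views), k = 2, K = 8, seed = 1)
  expect_identical(clusterLabels(f12), clusterLabels(f21))
})

test_that("iteration cap and convergence flags behave as documented", {
  sim <- makeMultiview(n = 40, k = 2, dims = c(30, 20), seed = 43)
  one <- mrfmsc(sim$views, k = 2, K = 8, maxIter = 1, tol = 1e-12, seed = 1)
  expect_identical(one@nIter, 1L)
  expect_false(one@converged)
  expect_length(objectiveTrace(one), 1L)

  fit <- mrfmsc(sim$views, k = 2, K = 8, seed = 1)
  expect_true(fit@converged)
  expect_lt(fit@sChangeTrace[fit@nIter], 1e-3)
  # weight trace stays positive and finite throughout
  expect_true(all(is.finite(epsTrace(fit))) && all(epsTrace(fit) > 0))
  # fixed seed reproduces labels bit-identically
  refit <- mrfmsc(sim$views, k = 2, K = 8, seed = 1)
  expect_identical(clusterLabels(fit), clusterLabels(refit))

  expect_error(mrfmsc(sim$views, k = 40, K = 8), "k < n")
  misaligned <- list(sim$views[[1]],
    sim$views[[2]][, rev(sampleIds(sim$views[[2]]))])
  expect_error(mrfmsc(misaligned, k = 2), "alignViews")
})

test_that("each block update descends the exact objective", {
  # sylvester solves, no clipping, frozen weights: textbook coordinate descent
  set.seed(44)
  for (rep in 1:3) {
    pr <- randProblem(t = 2, n = 12, ms = c(15, 18))
    n <- pr$n; k <- 3
    alpha <- runif(1, 0.2, 2); beta <- runif(1, 0.5, 2)
    lam <- runif(1, 0.2, 2)
    eps <- rep(0.5, 2)
    grams <- lapply(pr$views, function(v) crossprod(viewValues(v)))
    S <- diag(1, n)
    Fm <- embeddingBasis(updateF(S, k))
    Zs <- replicate(2, diag(1, n), simplify = FALSE)
    obj <- function() mrfmscObjective(pr$views, Zs, S, Fm, eps, pr$Llist,
      alpha, beta, lam)
    prev <- obj()
    for (it in 1:4) {
      for (v in 1:2)
        Zs[[v]] <- smoothValues(updateZ(pr$views[[v]], S, pr$Llist[[v]],
          eps[v], alpha, beta, mode = "sylvester", clip = FALSE,
          gram = grams[[v]]))
      afterZ <- obj()
      expect_lte(afterZ, prev + 1e-8 * abs(prev))
      G <- pairwiseEmbeddingDists(Fm)
      S <- fusedValues(updateS(Zs, eps, G, beta, lam, clip = FALSE))
      afterS <- obj()
      expect_lte(afterS, afterZ + 1e-8 * abs(afterZ))
      Fm <- embeddingBasis(updateF(S, k))
      afterF <- obj()
      expect_lte(afterF, afterS + 1e-8 * abs(afterS))
      prev <- afterF
    }
  }
})

test_that("grid search screens the number of clusters by silhouette", {
  sim <- makeMultiview(n = 60, k = 3, dims = c(60, 40), seed = 45)
  gs <- mrfmscGrid(sim$views, k = 2:4, K = 10, seed = 1)
  expect_identical(gs$params$k, 3L)
  expect_identical(nrow(gs$scores), 3L)
  expect_true(all(is.finite(gs$scores$silhouette)))

  # scoring in fused-graph distances agrees on well-separated data
  gsF <- mrfmscGrid(sim$views, k = 2:4, K = 10, seed = 1,
    silhouetteSpace = "fused")
  expect_identical(gsF$params$k, 3L)

  single <- mrfmscGrid(sim$views, k = 3, K = 10, seed = 1)
  expect_s4_class(single$best, "MRFMSCResult")
  expect_identical(single$params$k, 3L)

  # degenerate input: every sample identical, no usable fit anywhere
  flat <- OmicsView(matrix(1, 20, 10) + 0, "flat")
  expect_error(suppressWarnings(mrfmscGrid(list(flat), k = 2:3)),
    "all grid fits failed")
})
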