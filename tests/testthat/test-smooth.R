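test_that("clipping is the elementwise positive part and is idempotent", {
  expect_equal(clipNonneg(matrix(c(-1, 0, 2, -3), 2)),
    matrix(c(0, 0, 2, 0), 2))
  z <- matrix(runif(9), 3)
  expect_identical(clipNonneg(z), z)
  expect_equal(clipNonneg(-abs(z)), matrix(0, 3, 3))
  sr <- new("SmoothRepresentation", Z = matrix(c(-1, 2, 0, 1), 2),
    viewName = "v")
  expect_equal(smoothValues(clipNonneg(sr)), matrix(c(0, 2, 0, 1), 2))
})

test_that("Z update reduces to the identity when unregularized", {
  set.seed(10)
  X <- matrix(rnorm(6 * 4), 6, 4)       # X^T X invertible (m > n)
  S <- diag(1, 4)
  L <- laplacianValues(graphLaplacian(randSimilarity(4)))
  # beta = 0 removes the fusion pull; eps only scales a vanished term
  Z <- smoothValues(updateZ(X, S, L, epsV = 1, alpha = 0, beta = 0))
  expect_equal(Z, diag(1, 4), ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("both Z solvers agree when the Laplacian term vanishes", {
  set.seed(11)
  X <- matrix(rnorm(7 * 5), 7, 5)
  S <- randSimilarity(5)
  L <- laplacianValues(graphLaplacian(randSimilarity(5)))
  for (beta in c(0.5, 3)) {
    Za <- smoothValues(updateZ(X, S, L, 0.4, alpha = 0, beta = beta,
      mode = "as_printed", clip = FALSE))
    Zs <- smoothValues(updateZ(X, S, L, 0.4, alpha = 0, beta = beta,
      mode = "sylvester", clip = FALSE))
    expect_equal(Za, Zs, tolerance = 1e-10)
  }
})

test_that("each Z solver matches its own oracle", {
  set.seed(12)
  for (rep in 1:5) {
    X <- matrix(rnorm(8 * 5), 8, 5)
    S <- diag(1, 5)
    L <- laplacianValues(graphLaplacian(randSimilarity(5)))
    alpha <- 1; beta <- 1; epsV <- 0.2
    A <- crossprod(X)

    # sylvester mode: the Sylvester stationarity residual vanishes
    Zs <- smoothValues(updateZ(X, S, L, epsV, alpha, beta,
      mode = "sylvester", clip = FALSE))
    resid <- (A + beta * epsV * diag(5)) %*% Zs + alpha * Zs %*% L -
      A - beta * epsV * S
    expect_lt(norm(resid, "F"), 1e-8)

    # as-printed mode: literal one-shot formula by an independent solve
    Za <- smoothValues(updateZ(X, S, L, epsV, alpha, beta,
      mode = "as_printed", clip = FALSE))
    Zlit <- qr.solve(A + beta * epsV * diag(5) + alpha * L,
      A + beta * epsV * S)
    expect_equal(Za, Zlit, tolerance = 1e-10)
  }
})

test_that("duplicated samples receive identical similarity profiles", {
  # grouping effect: x_i = x_j forces z_i = z_j at the exact minimizer,
  # provided the graph and the fusion target treat i and j symmetrically
  set.seed(13)
  for (rep in 1:5) {
    n <- 9
    X <- matrix(rnorm(14 * n), 14, n)
    X[, 6] <- X[, 3]
    W <- suppressWarnings(knnAffinity(X, K = n - 1, kernel = "heat"))
    L <- graphLaplacian(W)
    Z <- smoothValues(updateZ(X, matrix(0, n, n), L, epsV = 0.5,
      alpha = 1.5, beta = 1, mode = "sylvester", clip = FALSE))
    expect_lt(sqrt(sum((Z[, 3] - Z[, 6])^2)), 1e-6 * sqrt(sum(Z^2)))
  }
})

test_that("the sylvester update is the exact block minimizer", {
  set.seed(14)
  n <- 7
  X <- matrix(rnorm(10 * n), 10, n)
  S <- randSimilarity(n)
  Lm <- laplacianValues(graphLaplacian(randSimilarity(n)))
  alpha <- 0.8; beta <- 1.3; epsV <- 0.6
  blockObj <- function(Z)
    sum((X - X %*% Z)^2) + alpha * sum((Z %*% Lm) * Z) +
      beta * epsV * sum((S - Z)^2)
  Zstar <- smoothValues(updateZ(X, S, Lm, epsV, alpha, beta,
    mode = "sylvester", clip = FALSE))
  f0 <- blockObj(Zstar)
  for (rep in 1:20) {
    pert <- matrix(rnorm(n * n, sd = 1e-3), n, n)
    expect_gte(blockObj(Zstar + pert), f0 - 1e-10 * abs(f0))
  }
})

test_that("Z is pulled onto S as the fusion weight grows", {
  set.seed(15)
  n <- 6
  X <- matrix(rnorm(9 * n), 9, n)
  S <- randSimilarity(n)
  L <- laplacianValues(graphLaplacian(randSimilarity(n)))
  gaps <- vapply(c(1, 1e2, 1e4), function(beta)
    norm(smoothValues(updateZ(X, S, L, 1, alpha = 1, beta = beta,
      mode = "sylvester", clip = FALSE)) - S, "F"), numeric(1))
  expect_true(all(diff(gaps) < 0))
  expect_lt(gaps[3], 1e-2)
})

test_that("penalty and reconstruction terms match their summation oracles", {
  set.seed(16)
  W <- randSimilarity(5)
  L <- laplacianValues(graphLaplacian(W))

  # identical columns: perfectly smooth, zero penalty
  Zflat <- matrix(rep(rnorm(5), 5), 5, 5)
  expect_equal(smoothnessPenalty(Zflat, L), 0, tolerance = 1e-10)

  # two-node hand computation: 1/2 * 2 * ||(1,0) - (0,1)||^2 = 2
  L2 <- laplacianValues(graphLaplacian(matrix(c(0, 1, 1, 0), 2)))
  expect_equal(smoothnessPenalty(diag(1, 2), L2), 2)

  # trace form equals the pairwise-sum form
  Z <- matrix(rnorm(25), 5)
  pairSum <- 0
  for (i in 1:5) for (j in 1:5)
    pairSum <- pairSum + 0.5 * W[i, j] * sum((Z[, i] - Z[, j])^2)
  expect_equal(smoothnessPenalty(Z, L), pairSum, tolerance = 1e-10)

  X <- matrix(rnorm(12), 3, 4)
  expect_equal(reconstructionError(X, diag(1, 4)), 0)
  expect_equal(reconstructionError(X, matrix(0, 4, 4)), sum(X^2))
  Z4 <- matrix(rnorm(16), 4)
  R <- X - X %*% Z4
  bySummation <- sum(vapply(seq_len(nrow(R)),
    function(i) sum(R[i, ]^2), numeric(1)))
  expect_equal(reconstructionError(X, Z4), bySummation, tolerance = 1e-12)

  expect_error(smoothnessPenalty(matrix(0, 3, 3), L), "incompatible")
  expect_error(reconstructionError(X, matrix(0, 3, 3)), "incompatible")
})

test_that("a truly singular system is reported, advising regularization", {
  X <- matrix(c(1, 1, 2, 2), 1, 4)     # rank-1 Gram
  S <- diag(1, 4)
  L <- matrix(0, 4, 4)
  expect_error(updateZ(X, S, L, 1, alpha = 0, beta = 0), "beta > 0")
})
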