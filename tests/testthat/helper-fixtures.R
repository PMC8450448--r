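# fixture builders shared across test files; all randomness is seeded locally

randOrthonormal <- function(n, k) {
  qr.Q(qr(matrix(rnorm(n * k), n, k)))
}

# symmetric nonnegative similarity with zero diagonal and a connected graph
randSimilarity <- function(n) {
  S <- matrix(runif(n * n), n, n)
  S <- (S + t(S)) / 2
  diag(S) <- 0
  S
}

# symmetric sparse 0/1 adjacency (possibly disconnected) for component tests
randSparseAdjacency <- function(n, p = 0.08) {
  A <- matrix(rbinom(n * n, 1, p), n, n)
  A <- pmax(A, t(A))
  diag(A) <- 0
  A
}

# a small multi-view problem with graphs and Grams precomputed
randProblem <- function(t = 2, n = 12, ms = c(15, 18), K = 5) {
  views <- lapply(seq_len(t), function(v)
    OmicsView(matrix(rnorm(ms[v] * n), ms[v], n), sprintf("v%d", v)))
  Llist <- lapply(views, function(v)
    graphLaplacian(suppressWarnings(knnAffinity(v, K = K))))
  list(views = views, Llist = Llist, n = n, t = t)
}

# graph component count by traversal (independent of any eigen machinery)
componentsByTraversal <- function(A) {
  n <- nrow(A)
  seen <- rep(FALSE, n)
  comps <- 0L
  for (start in seq_len(n)) {
    if (seen[start]) next
    comps <- comps + 1L
    queue <- start
    seen[start] <- TRUE
    while (length(queue)) {
      u <- queue[1L]; queue <- queue[-1L]
      nb <- which(A[u, ] > 0 & !seen)
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
  }
  comps
}

writeTempView <- function(m, ext = ".tsv") {
  f <- tempfile(fileext = ext)
  writeViewMatrix(m, f)
  f
}
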