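#' Laplacian of the fused graph
#'
#' The column-wise S update does not guarantee symmetry, so the Laplacian is
#' always built from the symmetrized \eqn{(S + S^T)/2}.
#'
#' @param S [FusedGraph-class] or n x n matrix.
#' @return A [GraphLaplacian-class].
#' @export
fusedLaplacian <- function(S) {
  Sm <- asSquareMatrix(S)
  Sym <- (Sm + t(Sm)) / 2
  new("GraphLaplacian",
    values = diag(rowSums(Sym), nrow(Sym)) - Sym)
}

#' Spectral embedding from the k smallest Laplacian eigenvalues
#'
#' Solves the embedding block of the joint objective: over orthonormal
#' \eqn{F}, \eqn{tr(F^T L_S F)} is minimized by the eigenvectors of
#' \eqn{L_S} for its k smallest eigenvalues, and the attained value equals
#' the sum of those eigenvalues (Ky Fan). Driving that sum towards zero is
#' what constrains the fused graph towards exactly k connected components.
#'
#' @param S [FusedGraph-class] or n x n nonnegative matrix.
#' @param k number of clusters, \eqn{2 \le k < n}.
#' @return A [SpectralEmbedding-class] with eigenvalues sorted ascending.
#' @export
updateF <- function(S, k) {
  Sm <- asSquareMatrix(S)
  n <- nrow(Sm)
  k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2")
  if (k >= n) stop(sprintf("k = %d but only %d samples; need k < n", k, n))
  eg <- eigen(fusedLaplacian(Sm)@values, symmetric = TRUE)
  idx <- seq.int(n, n - k + 1L)      # eigen() sorts decreasing
  basis <- eg$vectors[, idx, drop = FALSE]
  rownames(basis) <- rownames(Sm)
  new("SpectralEmbedding", basis = basis, eigenvalues = eg$values[idx])
}

#' Multiplicity of the zero eigenvalue of the fused-graph Laplacian
#'
#' For a nonnegative similarity matrix this equals the number of connected
#' components of the graph with edges \eqn{s_{ij} > 0} — the structural fact
#' that links the Laplacian rank constraint to an exactly-k-cluster graph.
#'
#' @param S [FusedGraph-class] or nonnegative n x n matrix.
#' @param tol eigenvalues below this count as zero; default \eqn{10^{-8} n}.
#' @return integer count.
#' @export
zeroEigenMultiplicity <- function(S, tol = NULL) {
  Sm <- asSquareMatrix(S)
  if (is.null(tol)) tol <- 1e-8 * nrow(Sm)
  ev <- eigen(fusedLaplacian(Sm)@values, symmetric = TRUE,
    only.values = TRUE)$values
  sum(ev < tol)
}

# k-means++ center selection on rows of x
kmeansppCenters <- function(x, k) {
  n <- nrow(x)
  centers <- integer(k)
  centers[1L] <- sample.int(n, 1L)
  d2 <- rowSums((x - matrix(x[centers[1L], ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1L)) {
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[j + 1L] <- sample.int(n, 1L, prob = p)
    nd <- rowSums((x - matrix(x[centers[j + 1L], ], n, ncol(x),
      byrow = TRUE))^2)
    d2 <- pmin(d2, nd)
  }
  x[centers, , drop = FALSE]
}

#' Cluster labels by K-means on the embedding rows
#'
#' Each row of the final spectral embedding is the new representation of one
#' sample; K-means on those rows produces the cluster labels. Runs
#' \code{restarts} independent k-means++-seeded starts and keeps the solution
#' with the smallest within-cluster sum of squares. Deterministic for a fixed
#' seed; the caller's RNG state is left untouched.
#'
#' @param F [SpectralEmbedding-class] or numeric matrix, samples in rows.
#' @param k number of clusters.
#' @param restarts number of seeded restarts (default 50).
#' @param seed RNG seed (default 1).
#' @return integer vector of labels in 1..k, named by row names when present.
#' @export
kmeansLabels <- function(F, k, restarts = 50L, seed = 1L) {
  Fm <- asEmbeddingMatrix(F)
  k <- as.integer(k)
  if (restarts < 1L) stop("restarts must be at least 1")
  ndistinct <- nrow(unique(Fm))
  if (k > ndistinct)
    stop(sprintf("k = %d exceeds the %d distinct embedding rows", k,
      ndistinct))
  withSeed(seed, {
    best <- NULL
    for (r in seq_len(restarts)) {
      centers <- kmeansppCenters(Fm, k)
      fit <- suppressWarnings(stats::kmeans(Fm, centers = centers,
        iter.max = 100L))
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
    labels <- as.integer(best$cluster)
    names(labels) <- rownames(Fm)
    labels
  })
}
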