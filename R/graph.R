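#' K-nearest-neighbour affinity graph between samples
#'
#' Builds the per-view sample similarity graph \eqn{W} used by the smoothness
#' regularizer. Euclidean distances are computed between sample columns; an
#' edge i-j is kept when j is among i's K nearest neighbours or i among j's
#' (symmetrization by element-wise max, preserving connectivity). Ties at the
#' K-th neighbour distance are broken by sample index, so the graph is
#' deterministic.
#'
#' Edge weights: the default self-tuning heat kernel sets
#' \eqn{w_{ij} = \exp(-d_{ij}^2/(\sigma_i \sigma_j))} with \eqn{\sigma_i} the
#' mean distance from i to its K neighbours, so each sample's bandwidth adapts
#' to its local density; \code{kernel = "binary"} keeps weight 1 on every kept
#' edge, discarding distance information (useful for ablation).
#'
#' @param x an [OmicsView-class] or a features-by-samples matrix.
#' @param K neighbour count, \eqn{1 \le K \le n - 1}; values outside the
#'   customary search range \[5, 50\] trigger a warning only. Default 20.
#' @param kernel \code{"heat"} (default) or \code{"binary"}.
#' @return An [AffinityGraph-class].
#' @examples
#' v <- makeMultiview(n = 30, k = 2, dims = 40, seed = 1)$views[[1]]
#' knnAffinity(v, K = 5)
#' @export
knnAffinity <- function(x, K = 20L, kernel = c("heat", "binary")) {
  kernel <- match.arg(kernel)
  m <- asViewMatrix(x)
  n <- ncol(m)
  K <- as.integer(K)
  if (K < 1L) stop("K must be at least 1")
  if (K >= n) stop(sprintf("K = %d but only %d samples; need K <= n - 1", K, n))
  if (K < 5L || K > 50L)
    warning(sprintf("K = %d is outside the customary range [5, 50]", K))
  D <- as.matrix(stats::dist(t(m)))
  # directed KNN mask; order() breaks distance ties by index
  mask <- matrix(FALSE, n, n)
  sigma <- numeric(n)
  for (i in seq_len(n)) {
    ord <- order(D[i, ])            # self (distance 0) sorts first
    nb <- setdiff(ord, i)[seq_len(K)]
    mask[i, nb] <- TRUE
    sigma[i] <- mean(D[i, nb])
  }
  if (kernel == "binary") {
    W <- (mask | t(mask)) * 1
  } else {
    sigma[sigma <= 0] <- 1          # duplicated points: any bandwidth, d = 0
    Wdir <- exp(-D^2 / outer(sigma, sigma)) * mask
    W <- pmax(Wdir, t(Wdir))
  }
  diag(W) <- 0
  dimnames(W) <- list(colnames(m), colnames(m))
  new("AffinityGraph", weights = W, K = K)
}

#' Combinatorial graph Laplacian L = D - W
#'
#' @param W an [AffinityGraph-class] or a symmetric nonnegative matrix.
#' @return A [GraphLaplacian-class]; rows sum to zero and all eigenvalues are
#'   nonnegative, with the multiplicity of eigenvalue 0 equal to the number of
#'   connected components of the graph.
#' @examples
#' L <- graphLaplacian(matrix(c(0, 1, 1, 0), 2))
#' laplacianValues(L)
#' @export
graphLaplacian <- function(W) {
  Wm <- asSquareMatrix(W)
  if (max(abs(Wm - t(Wm))) > 1e-8)
    stop("affinity matrix must be symmetric")
  L <- diag(rowSums(Wm), nrow(Wm)) - Wm
  dimnames(L) <- dimnames(Wm)
  new("GraphLaplacian", values = L)
}
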