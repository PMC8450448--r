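#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement computed from the contingency table of the two
#' labelings; 1 for identical partitions up to relabeling, about 0 for
#' independent random partitions.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return scalar in \[-1, 1\].
#' @export
adjustedRand <- function(a, b) {
  if (length(a) != length(b))
    stop(sprintf("label vectors differ in length (%d vs %d)",
      length(a), length(b)))
  n <- length(a)
  tab <- table(a, b)
  sumnij <- sum(choose(tab, 2))
  sumai <- sum(choose(rowSums(tab), 2))
  sumbj <- sum(choose(colSums(tab), 2))
  expected <- sumai * sumbj / choose(n, 2)
  maxindex <- (sumai + sumbj) / 2
  if (maxindex == expected) return(1)   # both partitions trivial
  (sumnij - expected) / (maxindex - expected)
}

#' Normalized mutual information between two partitions
#'
#' Mutual information of the two labelings normalized by the mean of their
#' entropies (\eqn{2 I / (H_a + H_b)}); 1 for identical partitions, 0 for
#' independent ones.
#'
#' @param a,b label vectors of equal length.
#' @return scalar in \[0, 1\].
#' @export
normalizedMutualInfo <- function(a, b) {
  if (length(a) != length(b))
    stop(sprintf("label vectors differ in length (%d vs %d)",
      length(a), length(b)))
  n <- length(a)
  tab <- table(a, b) / n
  pa <- rowSums(tab); pb <- colSums(tab)
  nz <- tab > 0
  mi <- sum(tab[nz] * log(tab[nz] / outer(pa, pb)[nz]))
  ha <- -sum(pa[pa > 0] * log(pa[pa > 0]))
  hb <- -sum(pb[pb > 0] * log(pb[pb > 0]))
  if (ha + hb == 0) return(1)           # both partitions trivial
  2 * mi / (ha + hb)
}

#' Mean silhouette width of a clustering
#'
#' For each sample, a is its mean distance to the other members of its own
#' cluster and b the smallest mean distance to any other cluster; the
#' silhouette is \eqn{(b - a)/\max(a, b)}, with the conventions that
#' coincident points (a = b = 0) score 0 and singleton clusters score 0. The
#' mean over samples screens candidate numbers of clusters: higher means
#' tighter, better-separated clusters.
#'
#' @param points numeric matrix, samples in rows (typically the rows of the
#'   spectral embedding), or a [SpectralEmbedding-class]. Ignored when
#'   \code{distances} is given.
#' @param labels cluster labels, one per row; at least two clusters.
#' @param distances optional precomputed symmetric distance matrix (or
#'   \code{dist} object), e.g. a similarity matrix turned into distances, in
#'   place of Euclidean distances between the rows of \code{points}.
#' @return scalar in \[-1, 1\].
#' @export
silhouetteMean <- function(points, labels, distances = NULL) {
  if (!is.null(distances)) {
    D <- as.matrix(distances)
    if (nrow(D) != ncol(D) || max(abs(D - t(D))) > 1e-8)
      stop("'distances' must be a symmetric square matrix")
    return(silhouetteFromDist(D, labels))
  }
  x <- asEmbeddingMatrix(points)
  n <- nrow(x)
  silhouetteFromDist(as.matrix(stats::dist(x)), labels)
}

silhouetteFromDist <- function(D, labels) {
  n <- nrow(D)
  if (n < 3L) stop("need at least 3 samples")
  if (length(labels) != n)
    stop("one label per row required")
  labels <- as.integer(factor(labels))
  kl <- max(labels)
  if (kl < 2L) stop("silhouette undefined for a single cluster")
  sizes <- tabulate(labels, kl)
  # mean distance from each point to each cluster (including itself for own)
  M <- sapply(seq_len(kl), function(c) rowSums(D[, labels == c, drop = FALSE]))
  s <- numeric(n)
  for (i in seq_len(n)) {
    ci <- labels[i]
    if (sizes[ci] == 1L) { s[i] <- 0; next }
    a <- M[i, ci] / (sizes[ci] - 1L)
    b <- min(M[i, -ci] / sizes[-ci])
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}

#' Compare two partitions and score a clustering geometry
#'
#' Bundles the agreement metrics (ARI, NMI) with the mean silhouette of the
#' first labeling on the supplied coordinates.
#'
#' @param a,b label vectors of equal length.
#' @param points optional coordinate matrix for the silhouette of \code{a}.
#' @return named list with \code{ari}, \code{nmi} and (when \code{points} is
#'   given) \code{silhouette}.
#' @export
clusterComparison <- function(a, b, points = NULL) {
  out <- list(ari = adjustedRand(a, b), nmi = normalizedMutualInfo(a, b))
  if (!is.null(points)) out$silhouette <- silhouetteMean(points, a)
  out
}
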