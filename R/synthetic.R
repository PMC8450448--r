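#' Generate a multi-view dataset with known cluster structure
#'
#' Emulates the multi-omics regime the method targets: few samples, many
#' features per view (\eqn{m_v \gg n}), a cluster partition shared across
#' views but expressed with view-specific signal strength and noise, and
#' optionally uninformative (pure-noise) views.
#'
#' Cluster sizes are as equal as possible. For an informative view, each
#' cluster gets a mean vector drawn diffusely across all features and the set
#' of mean vectors is rescaled so that the average pairwise distance between
#' cluster means equals \code{separation * noiseSd[v]}; samples are that mean
#' plus i.i.d. Gaussian noise of sd \code{noiseSd[v]} (optionally
#' heavy-tailed, a scaled Student t with 3 df, for robustness studies).
#' Views listed in \code{uninformativeViews} are pure noise drawn from one
#' global distribution for all samples.
#'
#' @param n number of samples (default 150).
#' @param k number of clusters (default 3); needs \eqn{n \ge 2k}.
#' @param dims integer vector of feature counts per view (default
#'   \code{c(500, 400, 100)}).
#' @param separation between-cluster mean distance in units of within-cluster
#'   sd (default 20, a strongly separated regime).
#' @param noiseSd noise sd per view (recycled; default 1).
#' @param uninformativeViews indices of views generated with no cluster
#'   signal (default none).
#' @param heavyTail use t(3) noise scaled to the same sd (default FALSE).
#' @param seed RNG seed; output is bit-identical for identical seeds, and the
#'   caller's RNG state is untouched.
#' @return list with \code{views} (list of [OmicsView-class], shared sample
#'   ids) and \code{labels} (integer cluster labels named by sample id).
#' @examples
#' sim <- makeMultiview(n = 30, k = 2, dims = c(40, 20), seed = 7)
#' table(sim$labels)
#' @export
makeMultiview <- function(n = 150L, k = 3L, dims = c(500L, 400L, 100L),
    separation = 20, noiseSd = 1, uninformativeViews = integer(0),
    heavyTail = FALSE, seed = 1L) {
  n <- as.integer(n); k <- as.integer(k)
  if (n < 2L * k) stop("need n >= 2 * k")
  if (any(dims < 1L)) stop("each view needs at least one feature")
  if (separation < 0) stop("separation must be nonnegative")
  t <- length(dims)
  noiseSd <- rep_len(noiseSd, t)
  labels <- rep(seq_len(k), length.out = n)
  labels <- sort(labels)                       # sizes as equal as possible
  ids <- sprintf("S%03d", seq_len(n))
  names(labels) <- ids

  withSeed(seed, {
    views <- lapply(seq_len(t), function(v) {
      m <- dims[v]
      # t(3) has sd sqrt(3); rescale so both noise models share noiseSd[v]
      noise <- if (heavyTail)
        matrix(stats::rt(m * n, df = 3) / sqrt(3) * noiseSd[v], m, n)
      else matrix(stats::rnorm(m * n, sd = noiseSd[v]), m, n)
      if (v %in% uninformativeViews || separation == 0) {
        x <- noise
      } else {
        mu <- matrix(stats::rnorm(m * k), m, k)
        pd <- stats::dist(t(mu))
        target <- separation * noiseSd[v]
        if (mean(pd) > 0) mu <- mu * (target / mean(pd))
        x <- mu[, labels, drop = FALSE] + noise
      }
      dimnames(x) <- list(sprintf("view%d_f%d", v, seq_len(m)), ids)
      OmicsView(x, sprintf("view%d", v))
    })
    list(views = views, labels = labels)
  })
}

#' Block-structured similarity matrix fixture
#'
#' A fused-graph fixture with known component structure for exercising the
#' Laplacian-rank machinery: \code{within} on all off-diagonal entries inside
#' each block, \code{between} everywhere else, zero diagonal. With
#' \code{between = 0} the graph has exactly \code{length(sizes)} connected
#' components.
#'
#' @param sizes integer vector of block sizes.
#' @param within edge weight inside blocks (> between).
#' @param between edge weight across blocks (default 0).
#' @return A [FusedGraph-class].
#' @examples
#' zeroEigenMultiplicity(makeBlockSimilarity(c(3, 4), 1))
#' @export
makeBlockSimilarity <- function(sizes, within = 1, between = 0) {
  if (within <= between || between < 0)
    stop("need within > between >= 0")
  n <- sum(sizes)
  block <- rep(seq_along(sizes), sizes)
  S <- matrix(between, n, n)
  same <- outer(block, block, "==")
  S[same] <- within
  diag(S) <- 0
  new("FusedGraph", S = S)
}
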