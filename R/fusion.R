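#' Pairwise squared distances between embedding rows
#'
#' \eqn{g_{ij} = \lVert f_i - f_j\rVert_2^2} for rows of the spectral
#' embedding; the columns \eqn{g_i} of the result enter the fused-graph update
#' as the spectral pull that shrinks similarity between samples far apart in
#' the embedding.
#'
#' @param F a [SpectralEmbedding-class] or numeric matrix with samples in rows.
#' @return symmetric n x n matrix, zero diagonal, entries \eqn{\ge 0}.
#' @export
pairwiseEmbeddingDists <- function(F) {
  Fm <- asEmbeddingMatrix(F)
  sq <- rowSums(Fm^2)
  G <- outer(sq, sq, "+") - 2 * tcrossprod(Fm)
  G <- pmax((G + t(G)) / 2, 0)
  diag(G) <- 0
  G
}

#' Update the fused similarity graph S
#'
#' Column-wise closed-form minimizer of the fusion objective holding the
#' smooth representations, the view weights and the spectral embedding fixed:
#' \deqn{s_i = \frac{\sum_v \epsilon^v z_i^v - \lambda g_i / (4\beta)}
#'   {\sum_v \epsilon^v}}
#' i.e. a weight-averaged consensus of the per-view similarity columns, pushed
#' down where the current embedding places samples far apart. Negative entries
#' are then clipped to zero (default) so the Laplacian of S is a valid graph
#' Laplacian — the rank/connected-component argument presupposes nonnegative
#' edge weights.
#'
#' @param Zlist list of [SmoothRepresentation-class] (or n x n matrices).
#' @param eps [ViewWeights-class] or positive numeric vector, one per view.
#' @param G n x n matrix of squared embedding distances
#'   ([pairwiseEmbeddingDists()]); use 0 before an embedding exists.
#' @param beta fusion hyperparameter, > 0.
#' @param lam spectral hyperparameter \eqn{\lambda \ge 0}.
#' @param clip clip negative entries (default TRUE); disable to inspect the
#'   exact unconstrained minimizer.
#' @return A [FusedGraph-class].
#' @export
updateS <- function(Zlist, eps, G, beta, lam, clip = TRUE) {
  if (beta <= 0) stop("beta must be positive")
  if (lam < 0) stop("lam must be nonnegative")
  e <- if (is(eps, "ViewWeights")) eps@eps else as.numeric(eps)
  if (length(e) != length(Zlist))
    stop("one weight per view required")
  if (sum(e) <= 0) stop("view weights must sum to a positive value")
  Zs <- lapply(Zlist, asSquareMatrix)
  acc <- Reduce(`+`, Map(`*`, Zs, e))
  if (is.matrix(G) || (length(G) == 1 && G != 0)) {
    S <- (acc - lam * G / (4 * beta)) / sum(e)
  } else {
    S <- acc / sum(e)
  }
  if (clip) S <- pmax(S, 0)
  new("FusedGraph", S = S)
}

#' Self-tuned view weights
#'
#' \eqn{\epsilon^v = 1/(2\lVert S - Z^v\rVert_F)}: the weight of each view is
#' the reciprocal (halved) distance of its smooth representation from the
#' consensus, so views agreeing with the fused graph dominate and
#' uninformative views are automatically down-weighted — no extra
#' hyperparameter. A guard \eqn{\delta} keeps the weight finite when a view
#' coincides with S.
#'
#' @param S [FusedGraph-class] or n x n matrix.
#' @param Zlist list of [SmoothRepresentation-class] (or matrices).
#' @param guard lower bound \eqn{\delta} on the norm (default 1e-10).
#' @return A [ViewWeights-class].
#' @export
updateWeights <- function(S, Zlist, guard = 1e-10) {
  Sm <- asSquareMatrix(S)
  eps <- vapply(Zlist, function(Z)
    1 / (2 * max(fnorm(Sm - asSquareMatrix(Z)), guard)), numeric(1))
  nms <- vapply(Zlist, function(Z)
    if (is(Z, "SmoothRepresentation")) Z@viewName else NA_character_,
    character(1))
  if (!anyNA(nms)) names(eps) <- nms
  new("ViewWeights", eps = eps)
}
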