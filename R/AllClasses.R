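#' @import methods
NULL

#' OmicsView: one omics feature-by-sample matrix
#'
#' Container for a single omics layer (a "view"): an \eqn{m_v \times n} numeric
#' matrix of measurements for \eqn{m_v} features on \eqn{n} shared samples,
#' with feature identifiers as row names and sample identifiers as column
#' names.
#'
#' @slot values numeric matrix, features in rows, samples in columns; dimnames
#'   carry the feature and sample identifiers.
#' @slot viewName single string naming the layer (e.g. \code{"mrna"}).
#'
#' @seealso [readViewMatrix()], [alignViews()], [makeMultiview()]
#' @exportClass OmicsView
setClass("OmicsView",
  representation(values = "matrix", viewName = "character"))

setValidity("OmicsView", function(object) {
  x <- object@values
  msgs <- character(0)
  if (!is.numeric(x))
    msgs <- c(msgs, "'values' must be a numeric matrix")
  if (nrow(x) < 1L || ncol(x) < 2L)
    msgs <- c(msgs, "need at least 1 feature and 2 samples")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    msgs <- c(msgs, "'values' must have feature row names and sample column names")
  if (!is.null(colnames(x)) && anyDuplicated(colnames(x)))
    msgs <- c(msgs, "duplicate sample identifiers")
  if (anyNA(x) || any(!is.finite(x)))
    msgs <- c(msgs, "missing or non-finite values; reject or impute at load time")
  if (length(object@viewName) != 1L)
    msgs <- c(msgs, "'viewName' must be a single string")
  if (length(msgs)) msgs else TRUE
})

#' Construct an OmicsView
#'
#' @param values numeric matrix (features x samples). Row and column names are
#'   used as feature and sample identifiers; defaults are generated if absent.
#' @param viewName single string naming the layer.
#' @return An [OmicsView-class] object.
#' @examples
#' v <- OmicsView(matrix(rnorm(12), 3, 4), "mrna")
#' nSamples(v)
#' @export
OmicsView <- function(values, viewName = "view") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("f%d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("s%d", seq_len(ncol(values)))
  new("OmicsView", values = values, viewName = as.character(viewName))
}

#' AffinityGraph: symmetric KNN sample-similarity graph
#'
#' Nonnegative symmetric \eqn{n \times n} weight matrix \eqn{W} over samples,
#' zero on the diagonal, built from K-nearest-neighbour relations.
#'
#' @slot weights symmetric nonnegative numeric matrix with zero diagonal.
#' @slot K integer, the neighbour count used to build the graph.
#' @seealso [knnAffinity()], [graphLaplacian()]
#' @exportClass AffinityGraph
setClass("AffinityGraph",
  representation(weights = "matrix", K = "integer"))

setValidity("AffinityGraph", function(object) {
  W <- object@weights
  msgs <- character(0)
  if (nrow(W) != ncol(W))
    msgs <- c(msgs, "'weights' must be square")
  if (any(W < 0))
    msgs <- c(msgs, "weights must be nonnegative")
  if (max(abs(W - t(W))) > 1e-8)
    msgs <- c(msgs, "weights must be symmetric")
  if (any(abs(diag(W)) > 0))
    msgs <- c(msgs, "diagonal must be zero")
  if (nrow(W) > 1L && any(apply(W, 1L, max) <= 0))
    msgs <- c(msgs, "every sample needs at least one positive edge")
  if (length(msgs)) msgs else TRUE
})

#' GraphLaplacian: combinatorial Laplacian L = D - W
#'
#' Symmetric positive semi-definite matrix with zero row sums; the smoothness
#' regularizer of the per-view representation is \eqn{tr(Z L Z^T)}.
#'
#' @slot values symmetric numeric matrix with zero row sums.
#' @seealso [graphLaplacian()], [smoothnessPenalty()]
#' @exportClass GraphLaplacian
setClass("GraphLaplacian", representation(values = "matrix"))

setValidity("GraphLaplacian", function(object) {
  L <- object@values
  msgs <- character(0)
  if (nrow(L) != ncol(L))
    msgs <- c(msgs, "must be square")
  if (max(abs(L - t(L))) > 1e-8)
    msgs <- c(msgs, "must be symmetric")
  if (max(abs(rowSums(L))) > 1e-6 * max(1, max(abs(L))))
    msgs <- c(msgs, "row sums must be zero")
  if (length(msgs)) msgs else TRUE
})

#' SmoothRepresentation: self-expressive sample-similarity matrix Z
#'
#' Nonnegative \eqn{n \times n} coefficient matrix of the self-expression
#' X = X Z for one view; entry \eqn{z_{ij}} acts as a learned similarity
#' between samples i and j. Entries may be transiently negative when the
#' clipping step is disabled for analysis.
#'
#' @slot Z numeric n x n matrix of finite reals.
#' @slot viewName string naming the view the representation belongs to.
#' @seealso [updateZ()], [clipNonneg()]
#' @exportClass SmoothRepresentation
setClass("SmoothRepresentation",
  representation(Z = "matrix", viewName = "character"))

setValidity("SmoothRepresentation", function(object) {
  if (nrow(object@Z) != ncol(object@Z)) return("'Z' must be square")
  if (any(!is.finite(object@Z))) return("'Z' must be finite")
  TRUE
})

#' FusedGraph: consensus similarity graph S across views
#'
#' The fused \eqn{n \times n} similarity matrix learned from the per-view
#' smooth representations. After each update negative entries are clipped to
#' zero so that its Laplacian is a valid graph Laplacian; the Laplacian is
#' always built from the symmetrized \eqn{(S + S^T)/2}.
#'
#' @slot S numeric n x n matrix of finite reals.
#' @seealso [updateS()], [fusedLaplacian()], [updateF()]
#' @exportClass FusedGraph
setClass("FusedGraph", representation(S = "matrix"))

setValidity("FusedGraph", function(object) {
  if (nrow(object@S) != ncol(object@S)) return("'S' must be square")
  if (any(!is.finite(object@S))) return("'S' must be finite")
  TRUE
})

#' ViewWeights: adaptive per-view fusion weights
#'
#' Positive weights \eqn{\epsilon^v = 1/(2\lVert S - Z^v\rVert_F)}; views whose
#' smooth representation sits closer to the consensus get larger weight.
#'
#' @slot eps positive finite numeric vector, one entry per view.
#' @seealso [updateWeights()]
#' @exportClass ViewWeights
setClass("ViewWeights", representation(eps = "numeric"))

setValidity("ViewWeights", function(object) {
  if (any(!is.finite(object@eps)) || any(object@eps <= 0))
    return("weights must be positive and finite")
  TRUE
})

#' SpectralEmbedding: rank-constrained spectral coordinates
#'
#' Columns are orthonormal eigenvectors of the fused-graph Laplacian for its k
#' smallest eigenvalues; rows are the spectral coordinates of the samples that
#' feed the final K-means step.
#'
#' @slot basis numeric n x k matrix with orthonormal columns.
#' @slot eigenvalues the k smallest Laplacian eigenvalues, sorted ascending.
#' @seealso [updateF()], [kmeansLabels()]
#' @exportClass SpectralEmbedding
setClass("SpectralEmbedding",
  representation(basis = "matrix", eigenvalues = "numeric"))

setValidity("SpectralEmbedding", function(object) {
  Fm <- object@basis
  msgs <- character(0)
  if (ncol(Fm) != length(object@eigenvalues))
    msgs <- c(msgs, "one eigenvalue per column")
  if (max(abs(crossprod(Fm) - diag(ncol(Fm)))) > 1e-8)
    msgs <- c(msgs, "columns must be orthonormal")
  if (is.unsorted(object@eigenvalues))
    msgs <- c(msgs, "eigenvalues must be sorted ascending")
  if (length(msgs)) msgs else TRUE
})

#' MRFMSCResult: output of the alternating optimization
#'
#' Holds everything the fit produces: the final cluster labels, the fused graph
#' S, the spectral embedding F, the per-view smooth representations, and the
#' traces of the view weights and of the joint objective across iterations.
#'
#' @slot labels integer cluster labels (1-based), named by sample id.
#' @slot S [FusedGraph-class].
#' @slot F [SpectralEmbedding-class].
#' @slot Z list of [SmoothRepresentation-class], one per view.
#' @slot epsTrace numeric matrix, one row per iteration (row 1 is the uniform
#'   initialization 1/t), one column per view.
#' @slot objectiveTrace numeric vector of joint-objective values per iteration.
#' @slot sChangeTrace numeric vector of relative Frobenius changes of S.
#' @slot nIter integer, iterations performed.
#' @slot converged logical, whether the relative change of S fell below tol.
#' @slot hyperparams named list of the hyperparameters used.
#' @seealso [mrfmsc()]
#' @exportClass MRFMSCResult
setClass("MRFMSCResult",
  representation(labels = "integer", S = "FusedGraph", F = "SpectralEmbedding",
    Z = "list", epsTrace = "matrix", objectiveTrace = "numeric",
    sChangeTrace = "numeric", nIter = "integer", converged = "logical",
    hyperparams = "list"))

setValidity("MRFMSCResult", function(object) {
  if (any(!is.finite(object@objectiveTrace)))
    return("objective trace must be finite")
  if (any(!is.finite(object@epsTrace)) || any(object@epsTrace <= 0))
    return("weight trace must be positive and finite")
  TRUE
})
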