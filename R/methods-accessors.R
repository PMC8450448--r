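#' @rdname OmicsView-class
setMethod("viewValues", "OmicsView", function(object) object@values)

#' @rdname OmicsView-class
setMethod("viewName", "OmicsView", function(object) object@viewName)

#' @rdname OmicsView-class
setMethod("sampleIds", "OmicsView", function(object) colnames(object@values))

#' @rdname OmicsView-class
setMethod("featureIds", "OmicsView", function(object) rownames(object@values))

#' @rdname OmicsView-class
setMethod("nSamples", "OmicsView", function(object) ncol(object@values))

#' @rdname OmicsView-class
setMethod("nFeatures", "OmicsView", function(object) nrow(object@values))

#' @rdname OmicsView-class
#' @param i,j,drop,... row (feature) and column (sample) subscripts, as for
#'   matrices; \code{drop} is ignored, the result is always an OmicsView
setMethod("[", "OmicsView", function(x, i, j, ..., drop = FALSE) {
  v <- x@values
  if (!missing(i)) v <- v[i, , drop = FALSE]
  if (!missing(j)) v <- v[, j, drop = FALSE]
  new("OmicsView", values = v, viewName = x@viewName)
})

setMethod("show", "OmicsView", function(object) {
  cat(sprintf("OmicsView '%s': %d features x %d samples\n",
    object@viewName, nrow(object@values), ncol(object@values)))
  cat("  samples:", paste(utils::head(colnames(object@values), 4L),
    collapse = ", "),
    if (ncol(object@values) > 4L) "..." else "", "\n")
})

#' @rdname AffinityGraph-class
setMethod("graphWeights", "AffinityGraph", function(object) object@weights)

#' @rdname AffinityGraph-class
setMethod("neighborCount", "AffinityGraph", function(object) object@K)

setMethod("show", "AffinityGraph", function(object) {
  W <- object@weights
  cat(sprintf("AffinityGraph: %d samples, K = %d, %d edges\n",
    nrow(W), object@K, sum(W[upper.tri(W)] > 0)))
})

#' @rdname GraphLaplacian-class
setMethod("laplacianValues", "GraphLaplacian", function(object) object@values)

setMethod("show", "GraphLaplacian", function(object) {
  cat(sprintf("GraphLaplacian: %d x %d\n",
    nrow(object@values), ncol(object@values)))
})

#' @rdname SmoothRepresentation-class
setMethod("smoothValues", "SmoothRepresentation", function(object) object@Z)

setMethod("show", "SmoothRepresentation", function(object) {
  cat(sprintf("SmoothRepresentation '%s': %d x %d, %.1f%% nonzero\n",
    object@viewName, nrow(object@Z), ncol(object@Z),
    100 * mean(object@Z != 0)))
})

#' @rdname FusedGraph-class
setMethod("fusedValues", "FusedGraph", function(object) object@S)

setMethod("show", "FusedGraph", function(object) {
  cat(sprintf("FusedGraph: %d samples, %.1f%% nonzero entries\n",
    nrow(object@S), 100 * mean(object@S != 0)))
})

#' @rdname ViewWeights-class
setMethod("viewEps", "ViewWeights", function(object) object@eps)

setMethod("show", "ViewWeights", function(object) {
  cat("ViewWeights:", paste(sprintf("%s=%.4g",
    if (is.null(names(object@eps))) seq_along(object@eps) else
      names(object@eps), object@eps), collapse = ", "), "\n")
})

#' @rdname SpectralEmbedding-class
setMethod("embeddingBasis", "SpectralEmbedding", function(object) object@basis)

#' @rdname SpectralEmbedding-class
setMethod("embeddingEigenvalues", "SpectralEmbedding",
  function(object) object@eigenvalues)

setMethod("show", "SpectralEmbedding", function(object) {
  cat(sprintf("SpectralEmbedding: %d samples x %d components\n",
    nrow(object@basis), ncol(object@basis)))
  cat("  eigenvalues:", paste(signif(object@eigenvalues, 4), collapse = ", "),
    "\n")
})

#' @rdname MRFMSCResult-class
setMethod("clusterLabels", "MRFMSCResult", function(object) object@labels)

#' @rdname MRFMSCResult-class
setMethod("fusedGraph", "MRFMSCResult", function(object) object@S)

#' @rdname MRFMSCResult-class
setMethod("spectralEmbedding", "MRFMSCResult", function(object) object@F)

#' @rdname MRFMSCResult-class
setMethod("smoothRepresentations", "MRFMSCResult", function(object) object@Z)

#' @rdname MRFMSCResult-class
setMethod("epsTrace", "MRFMSCResult", function(object) object@epsTrace)

#' @rdname MRFMSCResult-class
setMethod("objectiveTrace", "MRFMSCResult",
  function(object) object@objectiveTrace)

setMethod("show", "MRFMSCResult", function(object) {
  k <- length(unique(object@labels))
  cat(sprintf(
    "MRFMSCResult: %d samples in %d clusters (%s after %d iterations)\n",
    length(object@labels), k,
    if (object@converged) "converged" else "not converged", object@nIter))
  cat("  cluster sizes:", paste(tabulate(object@labels), collapse = ", "), "\n")
  cat("  final view weights:",
    paste(signif(object@epsTrace[nrow(object@epsTrace), ], 4),
      collapse = ", "), "\n")
})
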