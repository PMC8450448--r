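#' @rdname OmicsView-class
#' @param object,x an object of the documented class
#' @export
setGeneric("viewValues", function(object) standardGeneric("viewValues"))

#' @rdname OmicsView-class
#' @export
setGeneric("viewName", function(object) standardGeneric("viewName"))

#' @rdname OmicsView-class
#' @export
setGeneric("sampleIds", function(object) standardGeneric("sampleIds"))

#' @rdname OmicsView-class
#' @export
setGeneric("featureIds", function(object) standardGeneric("featureIds"))

#' @rdname OmicsView-class
#' @export
setGeneric("nSamples", function(object) standardGeneric("nSamples"))

#' @rdname OmicsView-class
#' @export
setGeneric("nFeatures", function(object) standardGeneric("nFeatures"))

#' @rdname AffinityGraph-class
#' @param object an object of the documented class
#' @export
setGeneric("graphWeights", function(object) standardGeneric("graphWeights"))

#' @rdname AffinityGraph-class
#' @export
setGeneric("neighborCount", function(object) standardGeneric("neighborCount"))

#' @rdname GraphLaplacian-class
#' @param object an object of the documented class
#' @export
setGeneric("laplacianValues", function(object) standardGeneric("laplacianValues"))

#' @rdname SmoothRepresentation-class
#' @param object an object of the documented class
#' @export
setGeneric("smoothValues", function(object) standardGeneric("smoothValues"))

#' @rdname FusedGraph-class
#' @param object an object of the documented class
#' @export
setGeneric("fusedValues", function(object) standardGeneric("fusedValues"))

#' @rdname ViewWeights-class
#' @param object an object of the documented class
#' @export
setGeneric("viewEps", function(object) standardGeneric("viewEps"))

#' @rdname SpectralEmbedding-class
#' @param object an object of the documented class
#' @export
setGeneric("embeddingBasis", function(object) standardGeneric("embeddingBasis"))

#' @rdname SpectralEmbedding-class
#' @export
setGeneric("embeddingEigenvalues",
  function(object) standardGeneric("embeddingEigenvalues"))

#' @rdname MRFMSCResult-class
#' @param object an object of the documented class
#' @export
setGeneric("clusterLabels", function(object) standardGeneric("clusterLabels"))

#' @rdname MRFMSCResult-class
#' @export
setGeneric("fusedGraph", function(object) standardGeneric("fusedGraph"))

#' @rdname MRFMSCResult-class
#' @export
setGeneric("spectralEmbedding",
  function(object) standardGeneric("spectralEmbedding"))

#' @rdname MRFMSCResult-class
#' @export
setGeneric("smoothRepresentations",
  function(object) standardGeneric("smoothRepresentations"))

#' @rdname MRFMSCResult-class
#' @export
setGeneric("epsTrace", function(object) standardGeneric("epsTrace"))

#' @rdname MRFMSCResult-class
#' @export
setGeneric("objectiveTrace", function(object) standardGeneric("objectiveTrace"))
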