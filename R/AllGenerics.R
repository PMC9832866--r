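#' @rdname TimeCourseSet
#' @param object,x an object.
#' @export
setGeneric("tpm", function(object) standardGeneric("tpm"))

#' @rdname TimeCourseSet
#' @export
setGeneric("geneLengths", function(object) standardGeneric("geneLengths"))

#' @rdname TimeCourseSet
#' @export
setGeneric("timePoints", function(object) standardGeneric("timePoints"))

#' @rdname TimeCourseSet
#' @export
setGeneric("replicates", function(object) standardGeneric("replicates"))

#' @rdname TOGCN-class
#' @export
setGeneric("edgeTable", function(object) standardGeneric("edgeTable"))

#' @rdname TOGCN-class
#' @export
setGeneric("levelMap", function(object) standardGeneric("levelMap"))

#' @rdname TOGCN-class
#' @export
setGeneric("networkNodes", function(object) standardGeneric("networkNodes"))

#' @rdname TOGCN-class
#' @export
setGeneric("networkSeed", function(object) standardGeneric("networkSeed"))

#' @rdname GeneCatalog
#' @export
setGeneric("isTF", function(object, genes) standardGeneric("isTF"))

#' @rdname GeneCatalog
#' @export
setGeneric("tfGenes", function(object) standardGeneric("tfGenes"))

#' @rdname GeneCatalog
#' @export
setGeneric("pathwayGenes", function(object, pathways) standardGeneric("pathwayGenes"))

#' @rdname motifModel
#' @export
setGeneric("motifWidth", function(object) standardGeneric("motifWidth"))

#' @rdname motifModel
#' @export
setGeneric("motifConsensus", function(object) standardGeneric("motifConsensus"))

#' @rdname TruthRegulome-class
#' @param object a [TruthRegulome].
#' @param cutoff correlation cutoff (inclusive).
#' @param species 1 or 2.
#' @export
setGeneric("latentEdges", function(object, cutoff = 0.81, species = 1L)
    standardGeneric("latentEdges"))
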