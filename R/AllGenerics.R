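#' @rdname ExpressionMatrix-class
#' @param object an object.
#' @export
setGeneric("geneIds", function(object) standardGeneric("geneIds"))

#' @rdname ExpressionMatrix-class
#' @export
setGeneric("sampleIds", function(object) standardGeneric("sampleIds"))

#' @rdname ExpressionMatrix-class
#' @export
setGeneric("exprValues", function(object) standardGeneric("exprValues"))

#' @rdname EdgeList-class
#' @param object an object.
#' @export
setGeneric("edges", function(object) standardGeneric("edges"))

#' @rdname EdgeList-class
#' @export
setGeneric("nodeIds", function(object) standardGeneric("nodeIds"))

#' @rdname EdgeList-class
#' @export
setGeneric("tfIds", function(object) standardGeneric("tfIds"))

#' @rdname EdgeList-class
#' @export
setGeneric("edgeCount", function(object) standardGeneric("edgeCount"))

#' @rdname FactorModelFit-class
#' @param object an object.
#' @export
setGeneric("factorLoadings", function(object) standardGeneric("factorLoadings"))

#' @rdname FactorModelFit-class
#' @export
setGeneric("noiseVariances", function(object) standardGeneric("noiseVariances"))

#' @rdname FactorModelFit-class
#' @export
setGeneric("numFactors", function(object) standardGeneric("numFactors"))

#' @rdname FactorModelFit-class
#' @export
setGeneric("loglikTrace", function(object) standardGeneric("loglikTrace"))

#' @rdname PriorScale-class
#' @param object an object.
#' @export
setGeneric("scaleMatrix", function(object) standardGeneric("scaleMatrix"))

#' @rdname PriorScale-class
#' @export
setGeneric("jitterValue", function(object) standardGeneric("jitterValue"))

#' Degrees of freedom of a Wishart prior or posterior
#' @param object a [WishartPrior-class] or [WishartPosterior-class].
#' @return a single numeric value.
#' @export
setGeneric("dof", function(object) standardGeneric("dof"))

#' Extract a network as an [EdgeList-class]
#' @param object an object holding a network.
#' @param ... passed to methods.
#' @export
setGeneric("asEdgeList", function(object, ...) standardGeneric("asEdgeList"))

#' Binary adjacency matrix of a network
#' @param object an object holding a network.
#' @export
setGeneric("adjacencyMatrix",
           function(object) standardGeneric("adjacencyMatrix"))
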