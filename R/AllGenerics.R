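#' @importFrom methods setGeneric setMethod setClass new validObject is slot
NULL

#' @rdname fpkm
#' @export
setGeneric("fpkm", function(object, lengths) standardGeneric("fpkm"))

#' @rdname floorLog2
#' @export
setGeneric("floorLog2", function(object) standardGeneric("floorLog2"))

#' @rdname dropAllZero
#' @export
setGeneric("dropAllZero", function(object) standardGeneric("dropAllZero"))

#' @rdname tauScores
#' @export
setGeneric("tauScores", function(object) standardGeneric("tauScores"))

#' @rdname pcaExpression
#' @export
setGeneric("pcaExpression", function(object, k = 2L, scale. = FALSE)
  standardGeneric("pcaExpression"))

#' @rdname ExpressionMatrix-class
#' @export
setGeneric("exprValues", function(object) standardGeneric("exprValues"))

#' @rdname ExpressionMatrix-class
#' @export
setGeneric("exprState", function(object) standardGeneric("exprState"))

#' @rdname HomologClusterSet-class
#' @export
setGeneric("clusterMembers", function(object) standardGeneric("clusterMembers"))

#' @rdname HomologClusterSet-class
#' @export
setGeneric("clusterRepresentatives", function(object)
  standardGeneric("clusterRepresentatives"))
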