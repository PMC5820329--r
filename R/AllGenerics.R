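#' @include AllGenerics.R
NULL

#' Node identifiers of a network object
#'
#' @param x a \linkS4class{SimilarityMatrix} or other drugFlow object.
#' @return Character vector of node ids.
#' @export
setGeneric("nodeIds", function(x) standardGeneric("nodeIds"))

#' Numeric values of a matrix-backed object
#'
#' @param x a drugFlow matrix object.
#' @return The underlying numeric matrix, with dimnames set to the node ids.
#' @export
setGeneric("simValues", function(x) standardGeneric("simValues"))

#' Unknown-entry mask of a bipartite association matrix
#'
#' @param x a \linkS4class{BipartiteMatrix}.
#' @return 0/1 matrix; 1 marks an untested (unknown) pair.
#' @export
setGeneric("unknownMask", function(x) standardGeneric("unknownMask"))

#' Prediction score matrix of a propagation result
#'
#' @param x a \linkS4class{PropagationResult}.
#' @return Numeric cell line x drug matrix of propagation scores.
#' @export
setGeneric("predictionScores", function(x) standardGeneric("predictionScores"))
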