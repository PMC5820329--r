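#' @include AllGenerics.R
NULL

.checkSquareNamed <- function(m, what) {
  msgs <- character()
  if (!is.matrix(m) || !is.numeric(m))
    return(sprintf("%s must be a numeric matrix", what))
  if (nrow(m) != ncol(m))
    msgs <- c(msgs, sprintf("%s must be square (got %d x %d)", what, nrow(m), ncol(m)))
  if (any(!is.finite(m)))
    msgs <- c(msgs, sprintf("%s contains non-finite values", what))
  msgs
}

#' SimilarityMatrix: a sparsified intra-type similarity network
#'
#' Symmetric matrix of signed Pearson correlations between nodes of one type
#' (cell lines, drugs or target genes), with unit diagonal and off-diagonal
#' entries zeroed unless they pass the rank/p-value filter applied by
#' \code{\link{buildSimilarity}}.
#'
#' @slot nodeIds character, ordered node identifiers.
#' @slot values numeric square matrix; symmetric, diagonal 1, entries in
#'   \eqn{[-1, 1]}.
#' @slot kind one of \code{"cell"}, \code{"drug"}, \code{"target"}.
#'
#' @seealso \code{\link{buildSimilarity}}, \code{\link{buildTargetSimilarity}}
#' @export
setClass("SimilarityMatrix",
  representation(nodeIds = "character", values = "matrix", kind = "character"))

setValidity("SimilarityMatrix", function(object) {
  m <- object@values
  msgs <- .checkSquareNamed(m, "values")
  if (length(msgs) == 0L) {
    if (length(object@nodeIds) != nrow(m))
      msgs <- c(msgs, "nodeIds length does not match matrix dimension")
    if (anyDuplicated(object@nodeIds))
      msgs <- c(msgs, "duplicate node ids")
    if (max(abs(m - t(m))) > 1e-12)
      msgs <- c(msgs, "matrix is not symmetric (tolerance 1e-12)")
    if (nrow(m) > 0 && max(abs(diag(m) - 1)) > 1e-12)
      msgs <- c(msgs, "diagonal must equal 1")
    if (nrow(m) > 0 && max(abs(m)) > 1 + 1e-12)
      msgs <- c(msgs, "entries must lie in [-1, 1]")
  }
  if (!(length(object@kind) == 1L && object@kind %in% c("cell", "drug", "target")))
    msgs <- c(msgs, "kind must be one of 'cell', 'drug', 'target'")
  if (length(msgs)) msgs else TRUE
})

#' Construct a SimilarityMatrix
#'
#' @param values symmetric numeric matrix with unit diagonal.
#' @param nodeIds node identifiers (default: rownames of \code{values}).
#' @param kind node type: \code{"cell"}, \code{"drug"} or \code{"target"}.
#' @return a validated \linkS4class{SimilarityMatrix}.
#' @export
SimilarityMatrix <- function(values, nodeIds = rownames(values), kind = "cell") {
  dimnames(values) <- list(nodeIds, nodeIds)
  new("SimilarityMatrix", nodeIds = as.character(nodeIds), values = values,
      kind = kind)
}

#' @describeIn SimilarityMatrix node identifiers
#' @param x a SimilarityMatrix
#' @export
setMethod("nodeIds", "SimilarityMatrix", function(x) x@nodeIds)

#' @describeIn SimilarityMatrix underlying matrix with dimnames
#' @export
setMethod("simValues", "SimilarityMatrix", function(x) {
  m <- x@values
  dimnames(m) <- list(x@nodeIds, x@nodeIds)
  m
})

setMethod("show", "SimilarityMatrix", function(object) {
  n <- nrow(object@values)
  off <- n * (n - 1L)
  nz <- if (off > 0) sum(object@values[row(object@values) != col(object@values)] != 0) else 0L
  cat(sprintf("SimilarityMatrix (%s): %d nodes, %.1f%% of off-diagonal entries retained\n",
              object@kind, n, if (off > 0) 100 * nz / off else 0))
})

#' BipartiteMatrix: 0/1 association matrix between two node types
#'
#' Holds the cell line x drug sensitivity matrix \eqn{A_{cd}} (with an unknown
#' mask for untested pairs) or the drug x target interaction matrix
#' \eqn{A_{dt}}. Unknown entries carry value 0, matching the convention that
#' resistant and unknown pairs both enter the propagation as 0.
#'
#' @slot rowIds,colIds character identifiers for rows and columns.
#' @slot values 0/1 numeric matrix.
#' @slot unknownMask 0/1 numeric matrix of the same shape (all-zero when no
#'   entry is unknown, as for drug-target interactions).
#'
#' @seealso \code{\link{binarizeResponses}}, \code{\link{buildDrugTarget}}
#' @export
setClass("BipartiteMatrix",
  representation(rowIds = "character", colIds = "character",
                 values = "matrix", unknownMask = "matrix"))

setValidity("BipartiteMatrix", function(object) {
  msgs <- character()
  v <- object@values; u <- object@unknownMask
  if (length(object@rowIds) != nrow(v) || length(object@colIds) != ncol(v))
    msgs <- c(msgs, "id lengths do not match matrix shape")
  if (anyDuplicated(object@rowIds) || anyDuplicated(object@colIds))
    msgs <- c(msgs, "duplicate row or column ids")
  if (!all(v %in% c(0, 1)))
    msgs <- c(msgs, "values must be 0/1")
  if (!identical(dim(v), dim(u)))
    msgs <- c(msgs, "unknownMask shape differs from values")
  else {
    if (!all(u %in% c(0, 1)))
      msgs <- c(msgs, "unknownMask must be 0/1")
    if (any(v == 1 & u == 1))
      msgs <- c(msgs, "unknown entries must have value 0")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a BipartiteMatrix
#'
#' @param values 0/1 numeric matrix.
#' @param rowIds,colIds identifiers (default: dimnames of \code{values}).
#' @param unknownMask 0/1 matrix of the same shape; defaults to all-known.
#' @return a validated \linkS4class{BipartiteMatrix}.
#' @export
BipartiteMatrix <- function(values, rowIds = rownames(values),
                            colIds = colnames(values),
                            unknownMask = matrix(0, nrow(values), ncol(values))) {
  dimnames(values) <- list(rowIds, colIds)
  dimnames(unknownMask) <- list(rowIds, colIds)
  new("BipartiteMatrix", rowIds = as.character(rowIds),
      colIds = as.character(colIds), values = values, unknownMask = unknownMask)
}

#' @describeIn BipartiteMatrix the 0/1 matrix with dimnames
#' @param x a BipartiteMatrix
#' @export
setMethod("simValues", "BipartiteMatrix", function(x) {
  m <- x@values
  dimnames(m) <- list(x@rowIds, x@colIds)
  m
})

#' @describeIn BipartiteMatrix the unknown-pair mask
#' @export
setMethod("unknownMask", "BipartiteMatrix", function(x) {
  m <- x@unknownMask
  dimnames(m) <- list(x@rowIds, x@colIds)
  m
})

setMethod("show", "BipartiteMatrix", function(object) {
  cat(sprintf("BipartiteMatrix: %d x %d, %d positive, %d unknown\n",
              nrow(object@values), ncol(object@values),
              sum(object@values == 1), sum(object@unknownMask == 1)))
})

#' HeterogeneousNetwork: the assembled five sub-network object
#'
#' Bundles the three similarity networks and the two bipartite association
#' matrices with mutually consistent index maps: the drug axis is shared by
#' \code{simDD}, the columns of \code{acd0} and the rows of \code{adt0}; the
#' gene axis is shared by \code{simTT} and the columns of \code{adt0}; the
#' cell axis by \code{simCC} and the rows of \code{acd0}.
#'
#' @slot simCC,simDD \linkS4class{SimilarityMatrix} for cell lines and drugs.
#' @slot simTT numeric square target-gene similarity matrix (fused, in [0,1]
#'   by default).
#' @slot acd0 \linkS4class{BipartiteMatrix}, initial cell-drug sensitivities.
#' @slot adt0 \linkS4class{BipartiteMatrix}, drug-target interactions.
#'
#' @seealso \code{\link{buildNetwork}}, \code{\link{propagate}}
#' @export
setClass("HeterogeneousNetwork",
  representation(simCC = "SimilarityMatrix", simDD = "SimilarityMatrix",
                 simTT = "matrix", acd0 = "BipartiteMatrix",
                 adt0 = "BipartiteMatrix"))

setValidity("HeterogeneousNetwork", function(object) {
  msgs <- character()
  cells <- object@simCC@nodeIds
  drugs <- object@simDD@nodeIds
  genes <- rownames(object@simTT)
  if (is.null(genes))
    msgs <- c(msgs, "simTT must carry gene ids as dimnames")
  msgs <- c(msgs, .checkSquareNamed(object@simTT, "simTT"))
  if (!identical(object@acd0@rowIds, cells))
    msgs <- c(msgs, "cell axis of acd0 does not match simCC")
  if (!identical(object@acd0@colIds, drugs))
    msgs <- c(msgs, "drug axis of acd0 does not match simDD")
  if (!identical(object@adt0@rowIds, drugs))
    msgs <- c(msgs, "drug axis of adt0 does not match simDD")
  if (!is.null(genes) && !identical(object@adt0@colIds, as.character(genes)))
    msgs <- c(msgs, "gene axis of adt0 does not match simTT")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "HeterogeneousNetwork", function(object) {
  cat(sprintf(paste0("HeterogeneousNetwork: %d cell lines, %d drugs, %d target genes\n",
                     "  %d sensitive associations, %d drug-target links, %d unknown pairs\n"),
              length(object@simCC@nodeIds), length(object@simDD@nodeIds),
              nrow(object@simTT), sum(object@acd0@values == 1),
              sum(object@adt0@values == 1), sum(object@acd0@unknownMask == 1)))
})

#' PropagationResult: converged scores with provenance
#'
#' @slot scores numeric cell x drug matrix, the final \eqn{A_{cd}^{k+1}}.
#' @slot adtFinal numeric drug x gene matrix, the final \eqn{A_{dt}} iterate.
#' @slot alpha restart-mixing weight used.
#' @slot iterations number of update steps taken.
#' @slot residual final sum of absolute changes in the score matrix.
#' @slot residualTrace residual after each iteration (for convergence
#'   diagnostics).
#' @slot converged logical; FALSE when the iteration cap was hit.
#' @export
setClass("PropagationResult",
  representation(scores = "matrix", adtFinal = "matrix", alpha = "numeric",
                 iterations = "integer", residual = "numeric",
                 residualTrace = "numeric", converged = "logical"))

#' @describeIn PropagationResult final score matrix
#' @param x a PropagationResult
#' @export
setMethod("predictionScores", "PropagationResult", function(x) x@scores)

setMethod("show", "PropagationResult", function(object) {
  cat(sprintf("PropagationResult: %d x %d scores, alpha = %g, %d iterations, residual %.3g%s\n",
              nrow(object@scores), ncol(object@scores), object@alpha,
              object@iterations, object@residual,
              if (object@converged) "" else " (iteration cap reached)"))
})
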