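#' @include AllClasses.R
NULL

#' Assemble the heterogeneous network
#'
#' Bundles the five sub-networks into a validated
#' \linkS4class{HeterogeneousNetwork}, checking that the shared axes (cells,
#' drugs, genes) carry identical id vectors across all members. Assembly is
#' by id, never by position: a mismatch is an error, not a silent reorder.
#'
#' @param simCC,simDD \linkS4class{SimilarityMatrix} objects for cell lines
#'   and drugs.
#' @param simTT square numeric gene similarity matrix with gene-id dimnames
#'   (e.g. \code{buildTargetSimilarity(...)$simTT}).
#' @param acd0 cell x drug \linkS4class{BipartiteMatrix}.
#' @param adt0 drug x gene \linkS4class{BipartiteMatrix}.
#' @return a \linkS4class{HeterogeneousNetwork}.
#' @export
buildNetwork <- function(simCC, simDD, simTT, acd0, adt0) {
  new("HeterogeneousNetwork", simCC = simCC, simDD = simDD, simTT = simTT,
      acd0 = acd0, adt0 = adt0)
}

#' Replace the initial cell-drug associations of a network
#'
#' Used by cross-validation to mask a held-out association without rebuilding
#' the similarity layers.
#'
#' @param net a \linkS4class{HeterogeneousNetwork}.
#' @param values replacement 0/1 matrix, same shape and ids as the current
#'   association matrix.
#' @return the updated network.
#' @export
setAssociations <- function(net, values) {
  net@acd0 <- BipartiteMatrix(values, net@acd0@rowIds, net@acd0@colIds,
                              net@acd0@unknownMask)
  methods::validObject(net)
  net
}
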