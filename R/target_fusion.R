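#' @include AllClasses.R
NULL

#' Degree-normalize a PPI confidence matrix
#'
#' Scales each interaction confidence by the geometric mean of the two
#' incident row sums:
#' \deqn{\bar W(i,j) = W(i,j) / \sqrt{D(i,i)\,D(j,j)},}
#' where \eqn{D(i,i)} is the sum of row i. Rows with zero sum (isolated
#' genes) yield all-zero entries (0/0 is taken as 0).
#'
#' @param wPpi square nonnegative matrix of confidences, zero diagonal
#'   permitted.
#' @return square matrix, symmetric when the input is.
#' @export
normalizePPI <- function(wPpi) {
  if (!is.matrix(wPpi) || nrow(wPpi) != ncol(wPpi))
    stop("wPpi must be a square matrix")
  if (any(wPpi < 0)) stop("PPI confidences must be nonnegative")
  d <- rowSums(wPpi)
  denom <- sqrt(outer(d, d))
  out <- ifelse(denom > 0, wPpi / denom, 0)
  dimnames(out) <- dimnames(wPpi)
  out
}

#' Noisy-OR fusion of two gene-gene weight matrices
#'
#' Combines the co-expression weights with the normalized PPI weights
#' elementwise as
#' \deqn{S(i,j) = 1 - (1 - W_{corr}(i,j))(1 - \bar W_{ppi}(i,j)),}
#' so that evidence from either source raises the fused similarity and a 1
#' in either source is absorbing. By default negative co-expression weights
#' are clamped to 0 before fusing: the noisy-OR form presumes [0, 1] inputs,
#' and a negative weight would otherwise push the fused value above 1.
#'
#' @param wCorr square matrix of (filtered) co-expression correlations.
#' @param wPpiNorm square matrix from \code{\link{normalizePPI}}; same shape
#'   and gene order.
#' @param signedCorr if TRUE, skip the clamping of negative wCorr entries.
#' @return square fused matrix; in [0, 1] for [0, 1] inputs.
#' @export
fuseSimilarities <- function(wCorr, wPpiNorm, signedCorr = FALSE) {
  if (!identical(dim(wCorr), dim(wPpiNorm)))
    stop("shape mismatch between wCorr and wPpiNorm")
  if (!signedCorr) wCorr <- pmax(wCorr, 0)
  out <- 1 - (1 - wCorr) * (1 - wPpiNorm)
  dimnames(out) <- dimnames(wCorr)
  out
}

#' Build the target-gene similarity network
#'
#' Constructs SIM_tt from two evidence layers over a common gene universe:
#' (1) PPI confidences, cut at \code{confidenceCut} and degree-normalized
#' (\code{\link{normalizePPI}}); (2) gene co-expression, computed from a
#' gene x sample expression matrix with the same rank/p-value sparsification
#' used for the other similarity networks (optionally disabled). The two
#' layers are fused by noisy-OR and the diagonal is set to 1, consistent
#' with the cell and drug similarity matrices.
#'
#' Genes of the universe missing from either layer simply contribute zero
#' rows in that layer, keeping the drug-target gene universe intact.
#'
#' @param ppiEdges weighted edge data.frame (\code{\link{readEdgeList}}).
#' @param geneExpr numeric gene x sample matrix, or NULL to use PPI only.
#' @param geneIds gene universe; defaults to the union of edge and
#'   expression genes.
#' @param confidenceCut PPI edges below this confidence are dropped before
#'   normalization (default 0.4).
#' @param filterCorr apply the rank/p-value filter to the co-expression
#'   layer (default TRUE).
#' @param topFraction,pCut filter parameters, as in
#'   \code{\link{buildSimilarity}}.
#' @param signedCorr passed to \code{\link{fuseSimilarities}}.
#' @return list with components \code{simTT} (fused matrix, unit diagonal),
#'   \code{wPpiNorm}, \code{wCorr} and \code{geneIds}.
#' @export
buildTargetSimilarity <- function(ppiEdges, geneExpr = NULL, geneIds = NULL,
                                  confidenceCut = 0.4, filterCorr = TRUE,
                                  topFraction = 0.5, pCut = 0.01,
                                  signedCorr = FALSE) {
  if (is.null(geneIds)) {
    geneIds <- sort(unique(c(ppiEdges$from, ppiEdges$to,
                             if (!is.null(geneExpr)) rownames(geneExpr))))
  }
  geneIds <- as.character(geneIds)
  l <- length(geneIds)
  kept <- if (nrow(ppiEdges)) {
    ppiEdges[ppiEdges$weight >= confidenceCut, , drop = FALSE]
  } else ppiEdges
  wRaw <- edgeListToAdjacency(kept, geneIds)
  wPpiNorm <- normalizePPI(wRaw)
  wCorr <- matrix(0, l, l, dimnames = list(geneIds, geneIds))
  if (!is.null(geneExpr)) {
    common <- intersect(geneIds, rownames(geneExpr))
    if (length(common) >= 3L && ncol(geneExpr) >= 3L) {
      sub <- geneExpr[common, , drop = FALSE]
      if (filterCorr) {
        sm <- buildSimilarity(sub, topFraction, pCut, kind = "target")
        wc <- simValues(sm)
      } else {
        wc <- stats::cor(t(sub))
      }
      diag(wc) <- 0   # diagonal handled after fusion
      wCorr[common, common] <- wc
    }
  }
  simTT <- fuseSimilarities(wCorr, wPpiNorm, signedCorr = signedCorr)
  diag(simTT) <- 1
  list(simTT = simTT, wPpiNorm = wPpiNorm, wCorr = wCorr, geneIds = geneIds)
}
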