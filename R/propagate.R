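#' @include AllClasses.R
NULL

#' Degree normalization of a weight matrix
#'
#' Divides each entry by the geometric mean of its row and column sums,
#' \deqn{N(i,j) = W(i,j) / \sqrt{\textstyle\sum_k W(i,k)\sum_k W(k,j)},}
#' computed from the current matrix. Entries whose row-sum/column-sum
#' product is zero or negative map to 0 (0/0 is taken as 0; a negative
#' product, possible only under signed similarities, has no real square
#' root and contributes nothing).
#'
#' @param w numeric matrix (square or rectangular), finite entries.
#' @return matrix of the same shape.
#' @examples
#' degreeNormalize(matrix(1, 2, 2))  # all entries 0.5
#' @export
degreeNormalize <- function(w) {
  if (any(!is.finite(w))) stop("non-finite entries")
  rs <- rowSums(w)
  cs <- colSums(w)
  prod <- outer(rs, cs)
  out <- matrix(0, nrow(w), ncol(w), dimnames = dimnames(w))
  ok <- prod > 0
  out[ok] <- w[ok] / sqrt(prod[ok])
  out
}

.netMatrices <- function(net, normalizeSims = FALSE) {
  m <- list(simCC = net@simCC@values, simDD = net@simDD@values,
            simTT = net@simTT, acd0 = net@acd0@values, adt0 = net@adt0@values)
  if (normalizeSims) {
    m$simCC <- degreeNormalize(m$simCC)
    m$simDD <- degreeNormalize(m$simDD)
    m$simTT <- degreeNormalize(m$simTT)
  }
  m
}

#' One propagation step over the heterogeneous network
#'
#' Performs the coupled Jacobi-style update that mixes the current scores,
#' smoothed through the network, with the initial associations:
#' \deqn{A_{cd}^{k+1} = \alpha\, A_{cd}^{k}\, N(S_{dd} A_{dt}^{k} S_{tt} A_{dt}^{k\top})
#'       + (1-\alpha) A_{cd}^{0}}
#' \deqn{A_{dt}^{k+1} = \alpha\, N(A_{cd}^{k\top} S_{cc} A_{cd}^{k} S_{dd})\, A_{dt}^{k}
#'       + (1-\alpha) A_{dt}^{0}}
#' where \eqn{N} is \code{\link{degreeNormalize}} applied to the bracketed
#' drug x drug product each step (the similarity matrices themselves enter
#' unnormalized). Both updates read the iteration-k matrices; an optional
#' Gauss-Seidel mode lets the second update consume the freshly updated
#' \eqn{A_{cd}^{k+1}}.
#'
#' @param net a \linkS4class{HeterogeneousNetwork}.
#' @param acdK,adtK current iterates (numeric matrices).
#' @param alpha mixing weight in [0, 1); at 0 a single step returns the
#'   initial associations exactly.
#' @param gaussSeidel sequential instead of simultaneous update.
#' @param normalizeSims degree-normalize the three similarity matrices
#'   before use (a sensitivity-analysis option; by default similarity
#'   matrices enter unnormalized and only the bracketed products are
#'   normalized, each iteration).
#' @return list with elements \code{acd} and \code{adt}.
#' @export
propagationStep <- function(net, acdK, adtK, alpha, gaussSeidel = FALSE,
                            normalizeSims = FALSE) {
  m <- .netMatrices(net, normalizeSims)
  if (!identical(dim(acdK), dim(m$acd0)) || !identical(dim(adtK), dim(m$adt0)))
    stop("iterate shapes do not match the network")
  bracketCD <- m$simDD %*% adtK %*% m$simTT %*% t(adtK)
  acdNext <- alpha * (acdK %*% degreeNormalize(bracketCD)) + (1 - alpha) * m$acd0
  acdForDT <- if (gaussSeidel) acdNext else acdK
  bracketDT <- t(acdForDT) %*% m$simCC %*% acdForDT %*% m$simDD
  adtNext <- alpha * (degreeNormalize(bracketDT) %*% adtK) + (1 - alpha) * m$adt0
  list(acd = acdNext, adt = adtNext)
}

#' Propagate information flow to convergence
#'
#' Iterates \code{\link{propagationStep}} from the initial associations until
#' the sum of absolute entrywise changes in the cell-drug score matrix falls
#' below \code{tol} (the drug-target iterate is reported as-is at exit), or
#' until \code{maxIter} steps, whichever comes first. The final score matrix
#' ranks every cell line-drug pair; a training sensitive pair retains at
#' least its restart floor \eqn{(1-\alpha)} under nonnegative similarities.
#'
#' @param net a \linkS4class{HeterogeneousNetwork}.
#' @param alpha mixing weight; in (0, 1) for real use, 0 is admitted as a
#'   degenerate boundary (scores equal the initial associations).
#' @param tol convergence threshold on the summed absolute change
#'   (default 1e-4).
#' @param maxIter iteration cap (default 1000); reaching it logs a warning
#'   and still returns the last iterate.
#' @param gaussSeidel,normalizeSims passed to \code{\link{propagationStep}}.
#' @return a \linkS4class{PropagationResult}.
#' @examples
#' net <- generateSynthetic(syntheticConfig(nCells = 12, nDrugs = 4,
#'                                          nGenes = 10, seed = 1))$network
#' res <- propagate(net, alpha = 0.4)
#' res
#' @export
propagate <- function(net, alpha = 0.4, tol = 1e-4, maxIter = 1000L,
                      gaussSeidel = FALSE, normalizeSims = FALSE) {
  if (alpha < 0 || alpha >= 1) stop("alpha must lie in [0, 1)")
  m <- .netMatrices(net)
  acd <- m$acd0
  adt <- m$adt0
  residuals <- numeric(0)
  converged <- FALSE
  iter <- 0L
  while (iter < maxIter) {
    iter <- iter + 1L
    nxt <- propagationStep(net, acd, adt, alpha, gaussSeidel, normalizeSims)
    if (any(!is.finite(nxt$acd)) || any(!is.finite(nxt$adt)))
      stop("non-finite values at iteration ", iter)
    resid <- sum(abs(nxt$acd - acd))
    residuals <- c(residuals, resid)
    acd <- nxt$acd
    adt <- nxt$adt
    if (resid < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("propagation did not converge within ", maxIter,
            " iterations (residual ", signif(residuals[iter], 3), ")")
  dimnames(acd) <- list(net@acd0@rowIds, net@acd0@colIds)
  dimnames(adt) <- list(net@adt0@rowIds, net@adt0@colIds)
  new("PropagationResult", scores = acd, adtFinal = adt, alpha = alpha,
      iterations = iter, residual = residuals[iter],
      residualTrace = residuals, converged = converged)
}
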