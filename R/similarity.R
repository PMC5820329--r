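#' @include AllClasses.R
NULL

#' Pearson correlation between two feature vectors
#'
#' The similarity score between two nodes is the Pearson correlation
#' coefficient of their feature vectors,
#' \deqn{r = \frac{\sum (X-\bar X)(Y-\bar Y)}
#'               {\sqrt{\sum (X-\bar X)^2 \sum (Y-\bar Y)^2}}.}
#'
#' @param x,y numeric vectors of equal length (at least 3), each with
#'   nonzero variance.
#' @return correlation in [-1, 1].
#' @examples
#' pearsonCor(c(1, 2, 3, 4), c(1, 3, 2, 4))  # 0.8
#' @export
pearsonCor <- function(x, y) {
  if (length(x) != length(y)) stop("vectors differ in length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("non-finite values")
  if (stats::var(x) == 0) stop("constant vector: x has zero variance")
  if (stats::var(y) == 0) stop("constant vector: y has zero variance")
  dx <- x - mean(x); dy <- y - mean(y)
  r <- sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
  min(1, max(-1, r))
}

#' Two-sided t-test p-value for a Pearson correlation
#'
#' Tests r = 0 using \eqn{t = r\sqrt{n-2}/\sqrt{1-r^2}} on n - 2 degrees of
#' freedom. Perfect correlation (|r| = 1) maps to p = 0.
#'
#' @param r correlation in [-1, 1].
#' @param n number of paired observations (>= 3).
#' @return two-sided p-value in [0, 1].
#' @export
pearsonPValue <- function(r, n) {
  if (any(n < 3)) stop("need n >= 3")
  if (any(abs(r) > 1 + 1e-12)) stop("|r| must not exceed 1")
  r <- pmin(1, pmax(-1, r))
  p <- ifelse(abs(r) >= 1, 0, {
    t <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, .Machine$double.xmin))
    2 * stats::pt(-abs(t), df = n - 2)
  })
  p
}

#' Build a sparsified Pearson similarity network
#'
#' Computes all-pairs Pearson correlations between the rows of a node x
#' feature matrix, then keeps an off-diagonal entry (with its signed value)
#' only if its absolute correlation ranks in the top \code{topFraction} of
#' all distinct off-diagonal pairs AND its t-test p-value is below
#' \code{pCut}; every other off-diagonal entry is set to 0 and the diagonal
#' to 1. Ties at the rank cutoff are all retained, which keeps the result
#' deterministic and independent of node order.
#'
#' @param features numeric node x feature matrix with dimnames (see
#'   \code{\link{readFeatureMatrix}}); at least 3 nodes and 3 features.
#' @param topFraction fraction of off-diagonal pairs eligible by rank
#'   (default 0.5).
#' @param pCut p-value threshold (default 0.01, uncorrected).
#' @param kind node type label for the result.
#' @param clampNegative replace retained negative correlations by 0
#'   (default FALSE: signed similarities are kept).
#' @return a \linkS4class{SimilarityMatrix}.
#' @examples
#' set.seed(1)
#' m <- matrix(rnorm(40), 4, 10, dimnames = list(paste0("c", 1:4), paste0("g", 1:10)))
#' buildSimilarity(m, kind = "cell")
#' @export
buildSimilarity <- function(features, topFraction = 0.5, pCut = 0.01,
                            kind = c("cell", "drug", "target"),
                            clampNegative = FALSE) {
  kind <- match.arg(kind)
  if (nrow(features) < 3L) stop("need at least 3 nodes")
  if (ncol(features) < 3L) stop("need at least 3 features per node")
  if (topFraction < 0 || topFraction > 1) stop("topFraction must be in [0, 1]")
  validateFeatureMatrix(features)
  n <- nrow(features)
  r <- stats::cor(t(features))
  r[r > 1] <- 1; r[r < -1] <- -1
  p <- pearsonPValue(r, ncol(features))
  up <- upper.tri(r)
  absUp <- abs(r[up])
  nPairs <- length(absUp)
  k <- floor(topFraction * nPairs)
  keep <- matrix(FALSE, n, n)
  if (k >= 1L) {
    cutoff <- sort(absUp, decreasing = TRUE)[k]
    keep <- abs(r) >= cutoff & p < pCut
  }
  out <- ifelse(keep, r, 0)
  if (clampNegative) out[out < 0] <- 0
  out <- (out + t(out)) / 2   # numerically enforce symmetry
  diag(out) <- 1
  SimilarityMatrix(out, rownames(features), kind)
}
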