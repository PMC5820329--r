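#' @include AllClasses.R
NULL

#' Leave-one-out cross-validation over sensitive associations
#'
#' Each known sensitive cell-drug pair is held out in turn: its entry in the
#' initial association matrix is set to 0, the propagation is re-run, and
#' only that pair's score is recorded. Scores for resistant pairs — needed to
#' draw a ROC but never masked — come from a single propagation on the
#' unmodified training matrix; their initial entries are already 0, so no
#' label leaks. Unknown pairs are never scored for evaluation.
#'
#' @param net a \linkS4class{HeterogeneousNetwork}.
#' @param alpha,tol,maxIter,normalizeSims passed to \code{\link{propagate}}.
#' @param verbose report progress every 50 folds.
#' @return list with \code{heldOut} (cell x drug matrix, NA except at the
#'   held-out sensitive entries), \code{full} (score matrix of the single
#'   full-training run), and \code{folds} (number of held-out pairs).
#' @export
runLOOCV <- function(net, alpha = 0.4, tol = 1e-4, maxIter = 1000L,
                     normalizeSims = FALSE, verbose = FALSE) {
  acd0 <- net@acd0@values
  sens <- which(acd0 == 1, arr.ind = TRUE)
  if (nrow(sens) < 1L) stop("no sensitive associations to hold out")
  full <- predictionScores(propagate(net, alpha, tol, maxIter,
                                     normalizeSims = normalizeSims))
  heldOut <- matrix(NA_real_, nrow(acd0), ncol(acd0),
                    dimnames = list(net@acd0@rowIds, net@acd0@colIds))
  for (f in seq_len(nrow(sens))) {
    i <- sens[f, 1L]; j <- sens[f, 2L]
    masked <- acd0
    masked[i, j] <- 0
    foldNet <- setAssociations(net, masked)
    res <- propagate(foldNet, alpha, tol, maxIter,
                     normalizeSims = normalizeSims)
    heldOut[i, j] <- predictionScores(res)[i, j]
    if (verbose && f %% 50L == 0L)
      message("LOOCV fold ", f, " / ", nrow(sens))
  }
  list(heldOut = heldOut, full = full, folds = nrow(sens))
}

#' Per-drug ranked predictions for evaluation
#'
#' For each drug, assembles the cells with a KNOWN association (unknown
#' pairs excluded), labels them sensitive (1) or resistant (0), and attaches
#' the evaluation score: the held-out LOOCV score for sensitive pairs, the
#' full-training score for resistant pairs. Cells are ordered by descending
#' score; ties keep the stable order of cell ids.
#'
#' @param cv result of \code{\link{runLOOCV}}.
#' @param net the network the CV was run on.
#' @return named list (one element per drug) of data.frames with columns
#'   \code{cell}, \code{score}, \code{label}.
#' @export
rankedPredictions <- function(cv, net) {
  acd0 <- net@acd0@values
  mask <- net@acd0@unknownMask
  drugs <- net@acd0@colIds
  cells <- net@acd0@rowIds
  out <- vector("list", length(drugs))
  names(out) <- drugs
  for (j in seq_along(drugs)) {
    known <- which(mask[, j] == 0)
    label <- acd0[known, j]
    score <- ifelse(label == 1, cv$heldOut[known, j], cv$full[known, j])
    ord <- order(-score)   # stable: ties stay in cell-id order
    out[[j]] <- data.frame(cell = cells[known][ord], score = score[ord],
                           label = label[ord], row.names = NULL)
  }
  out
}

#' Area under the ROC curve
#'
#' Computed in the rank (Mann-Whitney) formulation: the probability that a
#' random positive outscores a random negative, with tied scores counting
#' one half. Equal to trapezoidal integration of the empirical ROC curve.
#'
#' @param labels 0/1 vector.
#' @param scores numeric vector aligned to \code{labels}.
#' @return AUC in [0, 1].
#' @examples
#' rocAUC(c(1, 1, 0, 0), c(0.9, 0.8, 0.3, 0.1))  # 1
#' @export
rocAUC <- function(labels, scores) {
  if (length(labels) != length(scores)) stop("length mismatch")
  P <- sum(labels == 1); N <- sum(labels == 0)
  if (P == 0L || N == 0L)
    stop("AUC undefined: need at least one positive and one negative")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - P * (P + 1) / 2) / (P * N)
}

#' AUC for each drug's ranked predictions
#'
#' @param rankings output of \code{\link{rankedPredictions}}.
#' @return named numeric vector; NA (with a warning) for drugs lacking both
#'   classes. The unweighted mean over the non-NA drugs is the summary AUC.
#' @export
perDrugAUC <- function(rankings) {
  out <- vapply(rankings, function(rk) {
    if (sum(rk$label == 1) == 0L || sum(rk$label == 0) == 0L) NA_real_
    else rocAUC(rk$label, rk$score)
  }, numeric(1))
  if (anyNA(out))
    warning(sum(is.na(out)), " drug(s) lacked both classes and were skipped")
  out
}

#' True positives retrieved within top score percentiles
#'
#' Counts the sensitive pairs found among the top \code{ceiling(p * N)}
#' ranked entries for each percentile p. At p = 1 the count equals the total
#' number of positives.
#'
#' @param labels 0/1 vector.
#' @param scores numeric vector aligned to \code{labels}.
#' @param percentiles fractions in (0, 1], default
#'   \code{c(0.01, 0.02, 0.05, 0.10, 1.0)}.
#' @return named integer vector of counts, non-decreasing in p.
#' @export
retrievalAtPercentiles <- function(labels, scores,
                                   percentiles = c(0.01, 0.02, 0.05, 0.10, 1)) {
  if (any(percentiles <= 0 | percentiles > 1))
    stop("percentiles must lie in (0, 1]")
  ord <- order(-scores)
  lab <- labels[ord]
  n <- length(lab)
  counts <- vapply(percentiles, function(p) sum(lab[seq_len(ceiling(p * n))] == 1),
                   numeric(1))
  stats::setNames(as.integer(counts), paste0(100 * percentiles, "%"))
}

#' Tissue-stratified mean AUC
#'
#' Restricts each drug's ranking to the cell lines of one tissue, computes
#' the AUC where both classes remain, and averages (unweighted) over drugs
#' within each tissue. Drugs with a single class in a tissue are omitted;
#' tissues with no evaluable drug are dropped with a warning.
#'
#' @param rankings output of \code{\link{rankedPredictions}}.
#' @param tissue named character vector mapping cell ids to tissue labels;
#'   must cover every evaluated cell.
#' @return named numeric vector of per-tissue mean AUCs.
#' @export
stratifiedAUC <- function(rankings, tissue) {
  cellsSeen <- unique(unlist(lapply(rankings, `[[`, "cell")))
  missing <- setdiff(cellsSeen, names(tissue))
  if (length(missing))
    stop("no tissue label for cell(s): ", paste(missing, collapse = ", "))
  tissues <- sort(unique(tissue[cellsSeen]))
  out <- stats::setNames(rep(NA_real_, length(tissues)), tissues)
  for (tt in tissues) {
    aucs <- unlist(lapply(rankings, function(rk) {
      sub <- rk[tissue[rk$cell] == tt, , drop = FALSE]
      if (sum(sub$label == 1) >= 1L && sum(sub$label == 0) >= 1L)
        rocAUC(sub$label, sub$score)
      else NULL
    }))
    if (length(aucs)) out[tt] <- mean(aucs)
  }
  if (anyNA(out)) {
    warning("tissue(s) with no two-class drug omitted: ",
            paste(names(out)[is.na(out)], collapse = ", "))
    out <- out[!is.na(out)]
  }
  out
}
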