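#' @include AllClasses.R
NULL

#' Binarize IC50 responses into the cell-drug association matrix
#'
#' Applies the per-drug threshold: a measured IC50 strictly above the drug's
#' threshold marks the pair resistant (0); at or below the threshold marks it
#' sensitive (1). Missing measurements become value 0 with the unknown mask
#' set, so unknown and resistant pairs are indistinguishable to the
#' propagation (both 0) but distinguishable to the evaluation, which must
#' exclude unknown pairs from the ranking.
#'
#' @param responses a \linkS4class{ResponseTable}.
#' @return a \linkS4class{BipartiteMatrix} (cells x drugs) with unknown mask.
#' @examples
#' rt <- ResponseTable(matrix(c(-1, 3, 5, NA), 2, 2,
#'                            dimnames = list(c("c1", "c2"), c("d1", "d2"))),
#'                     thresholds = c(d1 = 0, d2 = 4))
#' binarizeResponses(rt)
#' @export
binarizeResponses <- function(responses) {
  ic <- responses@ic50
  thr <- responses@thresholds[responses@drugIds]
  sens <- sweep(ic, 2L, thr, "<=")
  vals <- ifelse(!is.na(ic) & sens, 1, 0)
  mask <- ifelse(is.na(ic), 1, 0)
  BipartiteMatrix(vals, responses@cellIds, responses@drugIds, mask)
}

#' Build the drug-target interaction matrix
#'
#' Turns a two-column drug-target pair list into a 0/1 matrix over given drug
#' and gene universes. Duplicate pairs are idempotent. Pairs naming unknown
#' ids either raise an error (strict mode, default) or are dropped with a
#' warning.
#'
#' @param pairs data.frame with columns \code{from} (drug) and \code{to}
#'   (gene), e.g. from \code{\link{readEdgeList}(weighted = FALSE)}.
#' @param drugIds,geneIds the axis universes.
#' @param strict error on unknown ids instead of dropping them.
#' @return a \linkS4class{BipartiteMatrix} (drugs x genes), no unknown mask.
#' @export
buildDrugTarget <- function(pairs, drugIds, geneIds, strict = TRUE) {
  drugIds <- as.character(drugIds); geneIds <- as.character(geneIds)
  vals <- matrix(0, length(drugIds), length(geneIds),
                 dimnames = list(drugIds, geneIds))
  if (nrow(pairs)) {
    known <- pairs$from %in% drugIds & pairs$to %in% geneIds
    if (any(!known)) {
      offenders <- unique(c(pairs$from[!pairs$from %in% drugIds],
                            pairs$to[!pairs$to %in% geneIds]))
      if (strict)
        stop("unknown id(s) in drug-target pairs: ",
             paste(offenders, collapse = ", "))
      warning("dropping ", sum(!known), " pair(s) with unknown id(s): ",
              paste(offenders, collapse = ", "))
    }
    p <- pairs[known, , drop = FALSE]
    vals[cbind(p$from, p$to)] <- 1
  }
  BipartiteMatrix(vals, drugIds, geneIds)
}
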