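#' @include AllClasses.R
NULL

#' ResponseTable: continuous drug-response measurements with thresholds
#'
#' Log-normalized IC50 values for cell line x drug pairs (NA where untested)
#' together with the per-drug binarization threshold. Thresholds are an input
#' column, not derived here: they come from an external per-drug calibration.
#'
#' @slot cellIds,drugIds character identifiers.
#' @slot ic50 numeric matrix (cells x drugs), NA allowed, otherwise finite.
#' @slot thresholds named numeric vector, one finite value per drug.
#' @seealso \code{\link{binarizeResponses}}, \code{\link{readResponseTable}}
#' @export
setClass("ResponseTable",
  representation(cellIds = "character", drugIds = "character",
                 ic50 = "matrix", thresholds = "numeric"))

setValidity("ResponseTable", function(object) {
  msgs <- character()
  if (length(object@cellIds) != nrow(object@ic50) ||
      length(object@drugIds) != ncol(object@ic50))
    msgs <- c(msgs, "id lengths do not match ic50 shape")
  if (anyDuplicated(object@cellIds) || anyDuplicated(object@drugIds))
    msgs <- c(msgs, "duplicate cell or drug ids")
  if (any(is.infinite(object@ic50) | is.nan(object@ic50)))
    msgs <- c(msgs, "ic50 entries must be finite where present")
  if (length(object@thresholds) != length(object@drugIds))
    msgs <- c(msgs, "one threshold per drug required")
  else if (any(!is.finite(object@thresholds)))
    msgs <- c(msgs, "thresholds must all be finite")
  if (length(msgs)) msgs else TRUE
})

#' Construct a ResponseTable
#'
#' @param ic50 numeric cells x drugs matrix, NA for untested pairs.
#' @param thresholds numeric vector, named by drug or aligned to columns.
#' @param cellIds,drugIds identifiers (default: dimnames of \code{ic50}).
#' @return a validated \linkS4class{ResponseTable}.
#' @export
ResponseTable <- function(ic50, thresholds, cellIds = rownames(ic50),
                          drugIds = colnames(ic50)) {
  dimnames(ic50) <- list(cellIds, drugIds)
  if (is.null(names(thresholds))) names(thresholds) <- drugIds
  thresholds <- thresholds[drugIds]
  if (any(is.na(thresholds)))
    stop("missing threshold for drug(s): ",
         paste(drugIds[is.na(thresholds)], collapse = ", "))
  new("ResponseTable", cellIds = as.character(cellIds),
      drugIds = as.character(drugIds), ic50 = ic50, thresholds = thresholds)
}

setMethod("show", "ResponseTable", function(object) {
  cat(sprintf("ResponseTable: %d cell lines x %d drugs, %d measured, %d missing\n",
              nrow(object@ic50), ncol(object@ic50),
              sum(!is.na(object@ic50)), sum(is.na(object@ic50))))
})

.sep <- function(format) switch(match.arg(format, c("tsv", "csv")),
                                tsv = "\t", csv = ",")

#' Read a node x feature matrix from a delimited table
#'
#' Reads a TSV (or CSV) with a header row and a leading index column into a
#' validated numeric matrix: node ids on rows, feature ids on columns. Used
#' for cell line expression profiles, drug chemical descriptors, and
#' gene x cell expression for target co-expression.
#'
#' @param path file path.
#' @param format \code{"tsv"} (default) or \code{"csv"}.
#' @param rowsAreNodes if FALSE the table is transposed after reading, so
#'   that rows of the returned matrix are always nodes.
#' @param requireVariance reject constant rows (default TRUE; set FALSE for
#'   matrices that are not similarity inputs, e.g. 0/1 association tables).
#' @return numeric matrix with unique dimnames, all values finite.
#' @export
readFeatureMatrix <- function(path, format = "tsv", rowsAreNodes = TRUE,
                              requireVariance = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = .sep(format),
                          row.names = NULL, check.names = FALSE,
                          colClasses = "character", quote = "")
  ids <- df[[1L]]
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate row id(s): ", paste(unique(dup), collapse = ", "))
  colIds <- colnames(df)[-1L]
  dupc <- colIds[duplicated(colIds)]
  if (length(dupc))
    stop("duplicate column id(s): ", paste(unique(dupc), collapse = ", "))
  vals <- as.matrix(df[, -1L, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(vals), nrow(vals), ncol(vals)))
  bad <- which(is.na(num) & !(toupper(vals) %in% c("NA", "")), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-numeric value '%s' at row '%s', column '%s'",
                 vals[bad[1, 1], bad[1, 2]], ids[bad[1, 1]], colIds[bad[1, 2]]))
  dimnames(num) <- list(ids, colIds)
  m <- if (rowsAreNodes) num else t(num)
  validateFeatureMatrix(m, requireVariance = requireVariance)
  m
}

#' Validate a feature matrix
#'
#' Checks the invariants every node x feature matrix must satisfy before
#' similarity construction: unique ids, finite values, and no constant row
#' (a zero-variance feature vector has an undefined Pearson correlation).
#'
#' @param m numeric matrix with dimnames.
#' @param requireVariance reject constant rows (default TRUE).
#' @return invisibly TRUE; stops with an informative error otherwise.
#' @export
validateFeatureMatrix <- function(m, requireVariance = TRUE) {
  if (!is.matrix(m) || !is.numeric(m)) stop("not a numeric matrix")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("feature matrix must carry row and column ids")
  if (anyDuplicated(rownames(m)))
    stop("duplicate row id(s): ",
         paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "))
  if (anyDuplicated(colnames(m)))
    stop("duplicate column id(s): ",
         paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "))
  if (any(!is.finite(m))) stop("feature matrix contains non-finite values")
  if (requireVariance && ncol(m) > 1) {
    v <- apply(m, 1L, stats::var)
    if (any(v == 0))
      stop("constant (zero-variance) row(s): ",
           paste(rownames(m)[v == 0], collapse = ", "))
  }
  invisible(TRUE)
}

#' Write a numeric matrix as a delimited table
#'
#' Inverse of \code{\link{readFeatureMatrix}}: header row of column ids, a
#' leading index column named \code{id}, full-precision values (17 significant
#' digits, so a write/read round trip is exact).
#'
#' @param m numeric matrix with dimnames.
#' @param path output path.
#' @param format \code{"tsv"} or \code{"csv"}.
#' @export
writeFeatureMatrix <- function(m, path, format = "tsv") {
  sep <- .sep(format)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("id", colnames(m)), collapse = sep), con)
  body <- apply(m, 1L, function(r) paste(sprintf("%.17g", r), collapse = sep))
  writeLines(paste(rownames(m), body, sep = sep), con)
  invisible(path)
}

#' Read an edge list (PPI or drug-target pairs)
#'
#' Two-column files are unweighted pairs; three-column files carry a
#' confidence weight in [0, 1]. For weighted (PPI-style) input the adjacency
#' is symmetric: an edge listed once counts in both directions, and duplicate
#' listings collapse to the maximum weight (conservative for confidence
#' scores). Self-loops are rejected for weighted input.
#'
#' @param path file path; no header.
#' @param weighted expect a third, numeric weight column.
#' @param format \code{"tsv"} or \code{"csv"}.
#' @return data.frame with columns \code{from}, \code{to} and, if weighted,
#'   \code{weight}; an empty file yields a zero-row data.frame.
#' @seealso \code{\link{edgeListToAdjacency}}
#' @export
readEdgeList <- function(path, weighted = TRUE, format = "tsv") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    out <- data.frame(from = character(), to = character())
    if (weighted) out$weight <- numeric()
    return(out)
  }
  parts <- strsplit(lines, .sep(format), fixed = TRUE)
  need <- if (weighted) 3L else 2L
  nf <- lengths(parts)
  if (any(nf < need))
    stop(sprintf("line %d has %d field(s); %d required",
                 which(nf < need)[1L], nf[nf < need][1L], need))
  from <- vapply(parts, `[[`, "", 1L)
  to <- vapply(parts, `[[`, "", 2L)
  out <- data.frame(from = from, to = to)
  if (weighted) {
    w <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3L)))
    if (any(is.na(w)))
      stop("non-numeric weight at line ", which(is.na(w))[1L])
    if (any(w < 0 | w > 1))
      stop("weight outside [0, 1] at line ", which(w < 0 | w > 1)[1L])
    if (any(from == to))
      stop("self-loop at line ", which(from == to)[1L])
    out$weight <- w
  }
  out
}

#' Symmetric weighted adjacency from an edge list
#'
#' Builds the square adjacency over a given (or inferred) node universe.
#' Edges are symmetrized and duplicates keep the maximum weight. Nodes
#' absent from the edge list get all-zero rows.
#'
#' @param edges data.frame from \code{\link{readEdgeList}} (weighted).
#' @param nodeIds node universe; defaults to the ids present in the edges.
#' @return symmetric numeric matrix with \code{nodeIds} dimnames, zero
#'   diagonal.
#' @export
edgeListToAdjacency <- function(edges, nodeIds = NULL) {
  if (is.null(nodeIds))
    nodeIds <- sort(unique(c(edges$from, edges$to)))
  nodeIds <- as.character(nodeIds)
  w <- matrix(0, length(nodeIds), length(nodeIds),
              dimnames = list(nodeIds, nodeIds))
  if (nrow(edges)) {
    keep <- edges$from %in% nodeIds & edges$to %in% nodeIds
    e <- edges[keep, , drop = FALSE]
    wt <- if ("weight" %in% names(e)) e$weight else rep(1, nrow(e))
    for (k in seq_len(nrow(e))) {
      i <- e$from[k]; j <- e$to[k]
      v <- max(w[i, j], wt[k])
      w[i, j] <- v
      w[j, i] <- v
    }
  }
  diag(w) <- 0
  w
}

#' Read an IC50 response table and per-drug thresholds
#'
#' The response table is cells x drugs with empty fields (or \code{NA}) for
#' untested pairs; thresholds are a two-column table (drug id, threshold).
#'
#' @param responsePath path to the IC50 matrix.
#' @param thresholdPath path to the per-drug threshold table.
#' @param format \code{"tsv"} or \code{"csv"}.
#' @return a \linkS4class{ResponseTable}.
#' @export
readResponseTable <- function(responsePath, thresholdPath, format = "tsv") {
  sep <- .sep(format)
  df <- utils::read.table(responsePath, header = TRUE, sep = sep,
                          check.names = FALSE, quote = "",
                          colClasses = "character")
  ids <- df[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate cell id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- as.matrix(df[, -1L, drop = FALSE])
  vals[vals == ""] <- NA
  suppressWarnings(num <- matrix(as.numeric(vals), nrow(vals), ncol(vals)))
  bad <- which(is.na(num) & !is.na(vals) & toupper(vals) != "NA", arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-numeric IC50 '%s' at row '%s', column '%s'",
                 vals[bad[1, 1], bad[1, 2]], ids[bad[1, 1]],
                 colnames(df)[-1L][bad[1, 2]]))
  dimnames(num) <- list(ids, colnames(df)[-1L])
  thr <- utils::read.table(thresholdPath, header = TRUE, sep = sep,
                           check.names = FALSE, quote = "")
  thresholds <- stats::setNames(as.numeric(thr[[2L]]), as.character(thr[[1L]]))
  ResponseTable(num, thresholds)
}

#' Write a bipartite matrix (and its mask) as TSVs
#'
#' @param x a \linkS4class{BipartiteMatrix}.
#' @param path output path for the 0/1 values.
#' @param maskPath optional output path for the unknown mask.
#' @param format \code{"tsv"} or \code{"csv"}.
#' @export
writeBipartite <- function(x, path, maskPath = NULL, format = "tsv") {
  writeFeatureMatrix(simValues(x), path, format)
  if (!is.null(maskPath)) writeFeatureMatrix(unknownMask(x), maskPath, format)
  invisible(path)
}
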