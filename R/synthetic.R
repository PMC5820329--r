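#' @include AllClasses.R
NULL

#' Configuration for the planted-block synthetic generator
#'
#' Validates and fills the parameter bag consumed by
#' \code{\link{generateSynthetic}}. Cells, drugs and genes are each
#' partitioned into \code{nBlocks} blocks; a cell tends to be sensitive to
#' the drugs of its own block, drugs target the genes of their block, and
#' features are correlated within blocks. Within-block feature correlation
#' is controlled analytically: rows are a shared block basis of scale
#' \eqn{s} plus Gaussian noise of sd \eqn{\sigma}, giving pairwise
#' correlation \eqn{s^2/(s^2+\sigma^2)}; the constructor solves for
#' \eqn{s} from the requested correlation.
#'
#' The default configuration is the clean, block-determined regime used to
#' calibrate the whole pipeline: labels are fully determined by block
#' membership (no off-block sensitivities, strictly in-block drug targets,
#' no label flips), with measurement-level realism retained (feature noise,
#' IC50 sampling noise, untested pairs). The degradation parameters
#' (\code{sensOffBlock}, \code{labelFlipRate}, \code{targetInBlockProb})
#' exist to move away from that regime in controlled experiments.
#'
#' @param nCells,nDrugs,nGenes node counts.
#' @param nBlocks number of planted blocks (must not exceed any node count).
#' @param exprDim,descDim feature counts for cell expression and drug
#'   descriptors (defaults 200 / 100, a scaled-down stand-in for
#'   genome-wide expression and 1-D/2-D descriptor panels).
#' @param withinBlockCorr target within-block correlation for cell
#'   expression and gene co-expression (default 0.7).
#' @param drugWithinBlockCorr target within-block correlation for drug
#'   descriptors (default 0.5; chemical similarity is a noisier proxy for a
#'   shared mechanism than the target layer, so the drug-feature signal is
#'   deliberately weaker).
#' @param noiseSd feature noise standard deviation (default 1; 0 gives
#'   exactly identical within-block rows).
#' @param sensInBlock,sensOffBlock probability that a within-block /
#'   off-block cell-drug pair is planted sensitive (defaults 0.95 / 0: in
#'   the clean regime off-block sensitivity, which no network feature can
#'   predict, is label noise and is absent).
#' @param unknownRate fraction of cell-drug pairs blanked to unknown
#'   (default 0.1).
#' @param labelFlipRate probability a planted label is flipped before its
#'   IC50 is drawn (default 0; 0.5 destroys all signal).
#' @param targetsPerDrug drug-target links drawn per drug (default 3), each
#'   from the drug's own gene block with probability
#'   \code{targetInBlockProb} (default 1: strictly in-block).
#' @param targetInBlockProb see above.
#' @param ppiWithinProb,ppiOffProb PPI edge probabilities within / across
#'   gene blocks (defaults 0.3 / 0.05); within-block confidences are drawn
#'   in [0.6, 0.95], cross-block in [0.1, 0.39] (mostly below the 0.4 cut).
#' @param ic50Shift half-distance between the sensitive and resistant IC50
#'   means (default 2; per-drug thresholds sit at 0, IC50 sd is 1).
#' @param seed integer; fully determines the generated bundle.
#' @return validated list of class \code{"SyntheticConfig"}.
#' @export
syntheticConfig <- function(nCells = 60L, nDrugs = 12L, nGenes = 40L,
                            nBlocks = 3L, exprDim = 200L, descDim = 100L,
                            withinBlockCorr = 0.7, drugWithinBlockCorr = 0.5,
                            noiseSd = 1, sensInBlock = 0.95, sensOffBlock = 0,
                            unknownRate = 0.1, labelFlipRate = 0,
                            targetsPerDrug = 3L, targetInBlockProb = 1,
                            ppiWithinProb = 0.3, ppiOffProb = 0.05,
                            ic50Shift = 2, seed = 1L) {
  cfg <- list(nCells = as.integer(nCells), nDrugs = as.integer(nDrugs),
              nGenes = as.integer(nGenes), nBlocks = as.integer(nBlocks),
              exprDim = as.integer(exprDim), descDim = as.integer(descDim),
              withinBlockCorr = withinBlockCorr,
              drugWithinBlockCorr = drugWithinBlockCorr, noiseSd = noiseSd,
              sensInBlock = sensInBlock, sensOffBlock = sensOffBlock,
              unknownRate = unknownRate, labelFlipRate = labelFlipRate,
              targetsPerDrug = as.integer(targetsPerDrug),
              targetInBlockProb = targetInBlockProb,
              ppiWithinProb = ppiWithinProb, ppiOffProb = ppiOffProb,
              ic50Shift = ic50Shift, seed = as.integer(seed))
  rates <- c(cfg$sensInBlock, cfg$sensOffBlock, cfg$unknownRate,
             cfg$labelFlipRate, cfg$targetInBlockProb, cfg$ppiWithinProb,
             cfg$ppiOffProb)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (cfg$withinBlockCorr < 0 || cfg$withinBlockCorr >= 1 ||
      cfg$drugWithinBlockCorr < 0 || cfg$drugWithinBlockCorr >= 1)
    stop("within-block correlations must lie in [0, 1)")
  if (cfg$nBlocks < 1L || cfg$nBlocks > min(cfg$nCells, cfg$nDrugs, cfg$nGenes))
    stop("nBlocks must be between 1 and min(nCells, nDrugs, nGenes)")
  if (cfg$exprDim < 3L || cfg$descDim < 3L)
    stop("need at least 3 features per node")
  if (cfg$noiseSd < 0) stop("noiseSd must be nonnegative")
  class(cfg) <- "SyntheticConfig"
  cfg
}

# basis scale giving within-block correlation rho at noise sd sigma
.basisScale <- function(rho, sigma) {
  if (sigma == 0) return(1)
  sigma * sqrt(rho / (1 - rho))
}

.blockFeatures <- function(blocks, dim, rho, sigma, ids, featPrefix) {
  nBlocks <- max(blocks)
  s <- .basisScale(rho, sigma)
  basis <- matrix(stats::rnorm(nBlocks * dim), nBlocks, dim)
  m <- s * basis[blocks, , drop = FALSE] +
    matrix(stats::rnorm(length(blocks) * dim, sd = sigma), length(blocks), dim)
  dimnames(m) <- list(ids, paste0(featPrefix, seq_len(dim)))
  m
}

#' Generate a complete synthetic input bundle with planted ground truth
#'
#' Emulates every input of the pipeline: block-correlated cell expression
#' and drug descriptor matrices, a confidence-weighted PPI concentrated
#' within gene blocks, gene expression over the cell-line samples (for the
#' co-expression layer), drug-target links drawn mostly within block, an
#' IC50 table whose two shifted Gaussians reproduce the planted
#' sensitive/resistant labels up to the flip rate, per-drug thresholds, and
#' tissue labels equal to the cell blocks. The same seed always yields the
#' identical bundle.
#'
#' @param cfg a \code{\link{syntheticConfig}}.
#' @param assemble also run the standard network-construction pipeline on
#'   the generated inputs and return the resulting
#'   \linkS4class{HeterogeneousNetwork} (default TRUE).
#' @return list with the raw inputs (\code{cellExpr}, \code{drugDesc},
#'   \code{geneExpr}, \code{ppiEdges}, \code{dtPairs}, \code{responses},
#'   \code{tissue}), the ground-truth block assignments (\code{cellBlock},
#'   \code{drugBlock}, \code{geneBlock}), and (if \code{assemble}) the
#'   assembled \code{network}.
#' @export
generateSynthetic <- function(cfg = syntheticConfig(), assemble = TRUE) {
  stopifnot(inherits(cfg, "SyntheticConfig"))
  oldSeed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(oldSeed))
    assign(".Random.seed", oldSeed, envir = globalenv()))
  set.seed(cfg$seed)

  cellIds <- sprintf("cell%03d", seq_len(cfg$nCells))
  drugIds <- sprintf("drug%02d", seq_len(cfg$nDrugs))
  geneIds <- sprintf("gene%03d", seq_len(cfg$nGenes))
  cellBlock <- rep_len(seq_len(cfg$nBlocks), cfg$nCells)
  drugBlock <- rep_len(seq_len(cfg$nBlocks), cfg$nDrugs)
  geneBlock <- rep_len(seq_len(cfg$nBlocks), cfg$nGenes)

  cellExpr <- .blockFeatures(cellBlock, cfg$exprDim, cfg$withinBlockCorr,
                             cfg$noiseSd, cellIds, "g")
  drugDesc <- .blockFeatures(drugBlock, cfg$descDim, cfg$drugWithinBlockCorr,
                             cfg$noiseSd, drugIds, "f")
  # gene expression over cell-line samples, block-correlated like the cells
  geneExpr <- .blockFeatures(geneBlock, cfg$nCells, cfg$withinBlockCorr,
                             cfg$noiseSd, geneIds, "s")
  colnames(geneExpr) <- cellIds

  # PPI: dense high-confidence within blocks, sparse low-confidence across
  pairs <- which(upper.tri(matrix(0, cfg$nGenes, cfg$nGenes)), arr.ind = TRUE)
  within <- geneBlock[pairs[, 1L]] == geneBlock[pairs[, 2L]]
  prob <- ifelse(within, cfg$ppiWithinProb, cfg$ppiOffProb)
  has <- stats::runif(nrow(pairs)) < prob
  conf <- ifelse(within, stats::runif(nrow(pairs), 0.6, 0.95),
                 stats::runif(nrow(pairs), 0.1, 0.39))
  ppiEdges <- data.frame(from = geneIds[pairs[has, 1L]],
                         to = geneIds[pairs[has, 2L]],
                         weight = round(conf[has], 6))

  # drug-target links, concentrated in the drug's gene block
  dtFrom <- character(0); dtTo <- character(0)
  for (j in seq_len(cfg$nDrugs)) {
    for (t in seq_len(cfg$targetsPerDrug)) {
      pool <- if (stats::runif(1) < cfg$targetInBlockProb)
        which(geneBlock == drugBlock[j]) else seq_len(cfg$nGenes)
      dtFrom <- c(dtFrom, drugIds[j])
      dtTo <- c(dtTo, geneIds[sample(pool, 1L)])
    }
  }
  dtPairs <- unique(data.frame(from = dtFrom, to = dtTo))

  # planted sensitivity, optional label flips, IC50 from shifted Gaussians
  planted <- matrix(stats::runif(cfg$nCells * cfg$nDrugs) <
                      ifelse(outer(cellBlock, drugBlock, "=="),
                             cfg$sensInBlock, cfg$sensOffBlock),
                    cfg$nCells, cfg$nDrugs)
  flip <- matrix(stats::runif(cfg$nCells * cfg$nDrugs) < cfg$labelFlipRate,
                 cfg$nCells, cfg$nDrugs)
  label <- xor(planted, flip)
  ic50 <- matrix(stats::rnorm(cfg$nCells * cfg$nDrugs,
                              mean = ifelse(label, -cfg$ic50Shift, cfg$ic50Shift)),
                 cfg$nCells, cfg$nDrugs, dimnames = list(cellIds, drugIds))
  unknown <- matrix(stats::runif(cfg$nCells * cfg$nDrugs) < cfg$unknownRate,
                    cfg$nCells, cfg$nDrugs)
  ic50[unknown] <- NA
  thresholds <- stats::setNames(rep(0, cfg$nDrugs), drugIds)
  responses <- ResponseTable(ic50, thresholds)
  tissue <- stats::setNames(paste0("tissue", cellBlock), cellIds)

  out <- list(cellExpr = cellExpr, drugDesc = drugDesc, geneExpr = geneExpr,
              ppiEdges = ppiEdges, dtPairs = dtPairs, responses = responses,
              tissue = tissue, cellBlock = stats::setNames(cellBlock, cellIds),
              drugBlock = stats::setNames(drugBlock, drugIds),
              geneBlock = stats::setNames(geneBlock, geneIds), config = cfg)
  if (assemble) out$network <- assembleFromBundle(out)
  out
}

#' Run the standard network-construction pipeline on a synthetic bundle
#'
#' Convenience wrapper chaining \code{\link{buildSimilarity}},
#' \code{\link{buildTargetSimilarity}}, \code{\link{binarizeResponses}},
#' \code{\link{buildDrugTarget}} and \code{\link{buildNetwork}} with default
#' parameters (top 50 percent rank, p < 0.01, PPI confidence cut 0.4).
#'
#' @param bundle list as returned by \code{\link{generateSynthetic}}.
#' @param topFraction,pCut,confidenceCut pipeline parameters.
#' @param clampNegative clamp retained negative correlations to 0 in the
#'   cell and drug similarity networks (default TRUE here: nonnegative
#'   weights keep the degree-normalized propagation bounded, which is the
#'   point of the normalization; pass FALSE to keep signed similarities).
#' @return a \linkS4class{HeterogeneousNetwork}.
#' @export
assembleFromBundle <- function(bundle, topFraction = 0.5, pCut = 0.01,
                               confidenceCut = 0.4, clampNegative = TRUE) {
  simCC <- buildSimilarity(bundle$cellExpr, topFraction, pCut, kind = "cell",
                           clampNegative = clampNegative)
  simDD <- buildSimilarity(bundle$drugDesc, topFraction, pCut, kind = "drug",
                           clampNegative = clampNegative)
  geneIds <- rownames(bundle$geneExpr)
  tt <- buildTargetSimilarity(bundle$ppiEdges, bundle$geneExpr,
                              geneIds = geneIds,
                              confidenceCut = confidenceCut,
                              topFraction = topFraction, pCut = pCut)
  acd0 <- binarizeResponses(bundle$responses)
  adt0 <- buildDrugTarget(bundle$dtPairs, drugIds = colnames(acd0@values),
                          geneIds = geneIds)
  buildNetwork(simCC, simDD, tt$simTT, acd0, adt0)
}

#' Write a synthetic bundle to disk in the package's table formats
#'
#' Emits the TSV bundle consumed by the command-line interface plus a
#' ground-truth JSON (block assignments and the generating configuration).
#'
#' @param bundle list from \code{\link{generateSynthetic}}.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
writeSyntheticBundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(dir, f)
  writeFeatureMatrix(bundle$cellExpr, fp("cell_expression.tsv"))
  writeFeatureMatrix(bundle$drugDesc, fp("drug_descriptors.tsv"))
  writeFeatureMatrix(bundle$geneExpr, fp("gene_expression.tsv"))
  utils::write.table(bundle$ppiEdges, fp("ppi_edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(bundle$dtPairs, fp("drug_target_pairs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  ic <- bundle$responses@ic50
  df <- data.frame(id = rownames(ic), ic, check.names = FALSE)
  utils::write.table(df, fp("ic50.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  utils::write.table(data.frame(drug = names(bundle$responses@thresholds),
                                threshold = bundle$responses@thresholds),
                     fp("thresholds.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(cell = names(bundle$tissue),
                                tissue = bundle$tissue),
                     fp("tissue.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    truth <- list(cellBlock = as.list(bundle$cellBlock),
                  drugBlock = as.list(bundle$drugBlock),
                  geneBlock = as.list(bundle$geneBlock),
                  config = unclass(bundle$config))
    jsonlite::write_json(truth, fp("ground_truth.json"), auto_unbox = TRUE)
  }
  invisible(dir)
}
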