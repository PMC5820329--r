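test_that("rocAUC agrees with both the pairwise and trapezoidal oracles", {
  set.seed(12)
  for (rep in 1:100) {
    n <- sample(5:30, 1)
    labels <- rbinom(n, 1, 0.5)
    if (sum(labels) == 0) labels[1] <- 1
    if (sum(labels) == n) labels[1] <- 0
    # coarse scores force ties
    scores <- round(runif(n), sample(c(1, 2), 1))
    a <- rocAUC(labels, scores)
    expect_equal(a, oracleAUCPairs(labels, scores), tolerance = 1e-12)
    expect_equal(a, oracleAUCTrapezoid(labels, scores), tolerance = 1e-12)
  }
})

test_that("rocAUC boundary values and invariances", {
  expect_equal(rocAUC(c(1, 1, 0, 0), c(4, 3, 2, 1)), 1)
  expect_equal(rocAUC(c(0, 0, 1, 1), c(4, 3, 2, 1)), 0)
  expect_error(rocAUC(c(1, 1), c(1, 2)), "undefined")
  set.seed(13)
  labels <- rbinom(20, 1, 0.4); labels[1] <- 1; labels[2] <- 0
  scores <- rnorm(20)
  a <- rocAUC(labels, scores)
  expect_equal(rocAUC(labels, exp(scores)), a)          # monotone transform
  expect_equal(rocAUC(labels, rank(scores)), a)
  # independent library cross-check
  expect_equal(a, as.numeric(pROC::auc(pROC::roc(labels, scores,
                                                 quiet = TRUE,
                                                 direction = "<"))))
})

test_that("retrievalAtPercentiles counts by explicit sort-and-count", {
  set.seed(14)
  scores <- rnorm(10)
  labels <- rbinom(10, 1, 0.5)
  got <- retrievalAtPercentiles(labels, scores, c(0.3, 1))
  ord <- order(scores, decreasing = TRUE)
  expect_equal(unname(got[1]), sum(labels[ord][1:3]))
  expect_equal(unname(got[2]), sum(labels))
  # perfect ranking puts all P positives in the top-P
  lab2 <- c(1, 1, 1, 0, 0, 0)
  expect_equal(unname(retrievalAtPercentiles(lab2, 6:1, 0.5)[1]), 3)
  # non-decreasing in p
  many <- retrievalAtPercentiles(labels, scores, seq(0.1, 1, by = 0.1))
  expect_true(all(diff(many) >= 0))
  expect_error(retrievalAtPercentiles(labels, scores, 0), "percentiles")
})

test_that("LOOCV scores each sensitive pair without using its own label", {
  b <- generateSynthetic(syntheticConfig(nCells = 12, nDrugs = 6, nGenes = 12,
                                         seed = 15))
  net <- b$network
  cv <- runLOOCV(net, alpha = 0.4)
  sens <- which(net@acd0@values == 1)
  expect_equal(sum(!is.na(cv$heldOut)), length(sens))
  expect_equal(cv$folds, length(sens))

  # flipping the held-out entry's stored label cannot change its score:
  # recompute one fold from a network where that entry was never sensitive
  ij <- which(net@acd0@values == 1, arr.ind = TRUE)[1, ]
  masked <- net@acd0@values
  masked[ij[1], ij[2]] <- 0
  res <- propagate(setAssociations(net, masked), alpha = 0.4)
  expect_equal(cv$heldOut[ij[1], ij[2]],
               unname(predictionScores(res)[ij[1], ij[2]]), tolerance = 1e-12)

  # alpha = 0: every held-out score restarts to a zeroed entry
  cv0 <- runLOOCV(net, alpha = 0)
  expect_true(all(cv0$heldOut[!is.na(cv0$heldOut)] == 0))
})

test_that("ranked predictions exclude unknown pairs and order stably", {
  b <- generateSynthetic(syntheticConfig(nCells = 12, nDrugs = 6, nGenes = 12,
                                         seed = 16, unknownRate = 0.3))
  net <- b$network
  cv <- runLOOCV(net)
  rk <- rankedPredictions(cv, net)
  mask <- unknownMask(net@acd0)
  for (j in seq_along(rk)) {
    expect_equal(nrow(rk[[j]]), sum(mask[, j] == 0))
    expect_false(any(rk[[j]]$cell %in% rownames(mask)[mask[, j] == 1]))
    expect_true(all(diff(rk[[j]]$score) <= 1e-15))
  }
})

test_that("planted-block LOOCV ranks held-out sensitives above resistants", {
  wins <- 0L
  for (seed in 1:5) {
    b <- generateSynthetic(syntheticConfig(nCells = 24, nDrugs = 6,
                                           nGenes = 18, seed = seed))
    cv <- runLOOCV(b$network)
    rk <- rankedPredictions(cv, b$network)
    for (d in rk) {
      if (sum(d$label == 1) && sum(d$label == 0)) {
        held <- d$score[d$label == 1]
        if (mean(held) > stats::median(d$score[d$label == 0])) wins <- wins + 1L
      }
    }
  }
  expect_gt(wins / (5 * 6), 0.8)   # large majority across seeds and drugs
})

test_that("stratified AUC reduces to per-subset brute force", {
  b <- generateSynthetic(syntheticConfig(nCells = 24, nDrugs = 6, nGenes = 18,
                                         seed = 17))
  net <- b$network
  cv <- runLOOCV(net)
  rk <- rankedPredictions(cv, net)

  # single tissue: equals the unstratified mean AUC
  oneTissue <- setNames(rep("all", 24), net@acd0@rowIds)
  expect_equal(unname(stratifiedAUC(rk, oneTissue)),
               mean(suppressWarnings(perDrugAUC(rk)), na.rm = TRUE))

  # three planted tissues: match explicit per-subset computation
  # (tissues whose drugs are all single-class are dropped with a warning)
  got <- suppressWarnings(stratifiedAUC(rk, b$tissue))
  for (tt in names(got)) {
    aucs <- c()
    for (d in rk) {
      sub <- d[b$tissue[d$cell] == tt, ]
      if (sum(sub$label == 1) && sum(sub$label == 0))
        aucs <- c(aucs, oracleAUCPairs(sub$label, sub$score))
    }
    expect_equal(unname(got[tt]), mean(aucs), tolerance = 1e-12)
  }

  # a tissue whose drugs are all single-class is omitted with a warning
  weird <- setNames(ifelse(net@acd0@values[, 1] == 1 &
                             rowSums(net@acd0@values) == ncol(net@acd0@values),
                           "odd", "rest"), net@acd0@rowIds)
  expect_true(all(names(suppressWarnings(stratifiedAUC(rk, weird))) %in%
                    c("odd", "rest")))
})
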