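test_that("degreeNormalize matches its defining formula", {
  expect_equal(degreeNormalize(matrix(1, 2, 2)), matrix(0.5, 2, 2))
  expect_equal(degreeNormalize(diag(3)), diag(3))
  expect_equal(degreeNormalize(matrix(0, 3, 2)), matrix(0, 3, 2))
  for (seed in 1:5) {
    set.seed(seed)
    w <- matrix(runif(5 * 4), 5, 4) * (matrix(runif(20), 5, 4) < 0.6)
    expect_equal(degreeNormalize(w), oracleDegreeNormalize(w), tolerance = 1e-12)
  }
})

test_that("propagationStep matches the straight-line oracle and its fixed points", {
  # alpha = 0: one step restores the initial associations exactly
  net <- randomNet(4, 3, 3, seed = 2)
  st <- propagationStep(net, net@acd0@values, net@adt0@values, alpha = 0)
  expect_identical(st$acd, net@acd0@values)
  expect_identical(st$adt, net@adt0@values)

  # hand case: n=2, m=1, l=1 with unit similarities is a fixed point
  one <- matrix(1, 1, 1, dimnames = list("d1", "d1"))
  tt <- matrix(1, 1, 1, dimnames = list("g1", "g1"))
  acd <- matrix(c(1, 0), 2, 1, dimnames = list(c("c1", "c2"), "d1"))
  adt <- matrix(1, 1, 1, dimnames = list("d1", "g1"))
  handNet <- buildNetwork(SimilarityMatrix(diag(2), c("c1", "c2"), "cell"),
                          SimilarityMatrix(one, kind = "drug"), tt,
                          BipartiteMatrix(acd), BipartiteMatrix(adt))
  st <- propagationStep(handNet, acd, adt, alpha = 0.5)
  expect_equal(st$acd, acd)

  # oracle equivalence on random instances, including mid-iteration states
  for (seed in 1:5) {
    net <- randomNet(3, 2, 2, seed = seed + 10)
    m <- drugFlow:::.netMatrices(net)
    set.seed(seed)
    acdK <- matrix(runif(6), 3, 2)
    adtK <- matrix(runif(4), 2, 2)
    got <- propagationStep(net, acdK, adtK, alpha = 0.4)
    want <- oracleStep(m$simCC, m$simDD, m$simTT, m$acd0, m$adt0,
                       acdK, adtK, alpha = 0.4)
    expect_equal(unname(got$acd), want$acd, tolerance = 1e-12)
    expect_equal(unname(got$adt), want$adt, tolerance = 1e-12)
  }
})

test_that("propagate matches an oracle-driven iteration trace", {
  for (seed in 1:3) {
    net <- randomNet(5, 4, 4, seed = seed)
    m <- drugFlow:::.netMatrices(net)
    res <- propagate(net, alpha = 0.4, tol = 1e-6)
    acd <- m$acd0; adt <- m$adt0
    for (k in seq_len(res@iterations)) {
      nxt <- oracleStep(m$simCC, m$simDD, m$simTT, m$acd0, m$adt0, acd, adt, 0.4)
      acd <- nxt$acd; adt <- nxt$adt
    }
    expect_equal(unname(res@scores), acd, tolerance = 1e-10)
    expect_equal(unname(res@adtFinal), adt, tolerance = 1e-10)
  }
})

test_that("stopping rule, residual behaviour and degenerate alphas", {
  net <- randomNet(5, 4, 4, seed = 3)
  # huge tolerance stops after one step
  res <- propagate(net, alpha = 0.4, tol = 1e9)
  expect_equal(res@iterations, 1L)

  # alpha = 0 returns the initial associations exactly
  res0 <- propagate(net, alpha = 0)
  expect_identical(unname(res0@scores), unname(net@acd0@values))

  # small alpha stays O(alpha) from the initial associations
  resS <- propagate(net, alpha = 0.01)
  expect_lt(max(abs(resS@scores - net@acd0@values)), 0.05)

  expect_error(propagate(net, alpha = 1.2), "alpha")
  expect_error(propagate(net, alpha = -0.1), "alpha")
})

test_that("convergence contract holds on random nonnegative instances", {
  for (seed in 1:5) {
    net <- randomNet(6, 5, 5, seed = seed + 30)
    res <- propagate(net, alpha = 0.4, tol = 1e-4)
    expect_true(res@converged)
    expect_lt(res@residual, 1e-4)
    tr <- res@residualTrace
    if (length(tr) > 3)
      expect_true(all(diff(tr[3:length(tr)]) <= 1e-12))
  }
})

test_that("training sensitive pairs keep their restart floor", {
  net <- randomNet(5, 4, 4, seed = 8)
  res <- propagate(net, alpha = 0.4)
  sens <- net@acd0@values == 1
  expect_true(all(res@scores[sens] >= (1 - 0.4) - 1e-9))
})

test_that("permuting node order permutes scores identically", {
  b <- generateSynthetic(syntheticConfig(nCells = 12, nDrugs = 6, nGenes = 12,
                                         seed = 9))
  net <- b$network
  res <- propagate(net, alpha = 0.4)
  set.seed(1)
  pc <- sample(12); pd <- sample(6); pg <- sample(12)
  net2 <- buildNetwork(
    SimilarityMatrix(net@simCC@values[pc, pc], net@simCC@nodeIds[pc], "cell"),
    SimilarityMatrix(net@simDD@values[pd, pd], net@simDD@nodeIds[pd], "drug"),
    net@simTT[pg, pg],
    BipartiteMatrix(net@acd0@values[pc, pd], net@acd0@rowIds[pc],
                    net@acd0@colIds[pd], net@acd0@unknownMask[pc, pd]),
    BipartiteMatrix(net@adt0@values[pd, pg], net@adt0@rowIds[pd],
                    net@adt0@colIds[pg]))
  res2 <- propagate(net2, alpha = 0.4)
  expect_equal(res2@scores, res@scores[pc, pd], tolerance = 1e-10)
})
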