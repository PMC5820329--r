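test_that("pearsonCor matches hand-evaluated and boundary cases", {
  x <- c(1, 2, 3, 5)
  expect_equal(pearsonCor(x, x), 1)
  expect_equal(pearsonCor(c(1, 2, 3), c(3, 2, 1)), -1)
  # deviations (-1.5,-.5,.5,1.5)*(-1.5,.5,-.5,1.5) sum 4; denominator 5
  expect_equal(pearsonCor(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_error(pearsonCor(c(1, 1, 1), c(1, 2, 3)), "constant vector: x")
  expect_error(pearsonCor(1:2, 2:1), "at least 3")
})

test_that("pearsonPValue agrees with cor.test and handles boundaries", {
  expect_equal(pearsonPValue(0, 10), 1)
  expect_equal(pearsonPValue(1, 10), 0)
  expect_equal(pearsonPValue(-1, 5), 0)
  # r = 0.8, n = 4: t = 1.8856 on 2 df, p ~ 0.2
  expect_equal(pearsonPValue(0.8, 4), 0.2, tolerance = 1e-4)
  expect_error(pearsonPValue(0.5, 2), "n >= 3")
  # independent check via cor.test on random draws
  set.seed(21)
  for (rep in 1:5) {
    x <- rnorm(12); y <- rnorm(12)
    ct <- stats::cor.test(x, y)
    expect_equal(pearsonPValue(unname(ct$estimate), 12), ct$p.value,
                 tolerance = 1e-12)
  }
})

test_that("buildSimilarity equals the brute-force oracle on random instances", {
  for (seed in 1:5) {
    set.seed(seed)
    feats <- matrix(rnorm(8 * 10), 8, 10,
                    dimnames = list(paste0("n", 1:8), paste0("f", 1:10)))
    got <- simValues(buildSimilarity(feats, topFraction = 0.5, pCut = 0.2))
    want <- oracleSimilarity(feats, topFraction = 0.5, pCut = 0.2)
    expect_equal(unname(got), want, tolerance = 1e-12)
  }
})

test_that("buildSimilarity boundary and structure cases", {
  ids <- list(paste0("n", 1:3), paste0("f", 1:4))
  same <- matrix(rep(c(1, 3, 2, 5), each = 3), 3, 4, dimnames = ids)
  same <- same + 0   # identical non-constant rows
  sm <- buildSimilarity(same, topFraction = 0.5, pCut = 0.05)
  expect_true(all(simValues(sm) == 1))

  set.seed(3)
  feats <- matrix(rnorm(4 * 12), 4, 12,
                  dimnames = list(paste0("n", 1:4), paste0("f", 1:12)))
  expect_equal(unname(simValues(buildSimilarity(feats, topFraction = 0))),
               diag(4))

  # two orthogonal block patterns: only (1,2) and (3,4) survive
  base1 <- rnorm(12); base2 <- rnorm(12)
  blk <- rbind(base1, base1 + rnorm(12, sd = 0.01),
               base2, base2 + rnorm(12, sd = 0.01))
  dimnames(blk) <- list(paste0("n", 1:4), paste0("f", 1:12))
  v <- simValues(buildSimilarity(blk, topFraction = 1 / 3, pCut = 0.01))
  expect_equal(sum(v[upper.tri(v)] != 0), 2)
  expect_gt(v["n1", "n2"], 0.99)
  expect_gt(v["n3", "n4"], 0.99)
})

test_that("similarity output is symmetric, unit-diagonal, permutation-equivariant", {
  set.seed(7)
  feats <- matrix(rnorm(6 * 15), 6, 15,
                  dimnames = list(paste0("n", 1:6), paste0("f", 1:15)))
  v <- simValues(buildSimilarity(feats))
  expect_equal(v, t(v))
  expect_equal(unname(diag(v)), rep(1, 6))
  expect_true(all(abs(v) <= 1 + 1e-12))
  # at most half the distinct pairs retained (ties aside)
  expect_lte(sum(v[upper.tri(v)] != 0), floor(0.5 * choose(6, 2)))

  perm <- sample(6)
  vp <- simValues(buildSimilarity(feats[perm, ]))
  expect_equal(vp, v[perm, perm])
})

test_that("clampNegative zeroes retained negative correlations only", {
  set.seed(9)
  base <- rnorm(12)
  feats <- rbind(a = base, b = -base + rnorm(12, sd = 0.01),
                 c = rnorm(12), d = base + rnorm(12, sd = 0.01))
  colnames(feats) <- paste0("f", 1:12)
  signed <- simValues(buildSimilarity(feats, pCut = 0.05))
  clamped <- simValues(buildSimilarity(feats, pCut = 0.05, clampNegative = TRUE))
  expect_lt(signed["a", "b"], -0.9)
  expect_equal(unname(clamped["a", "b"]), 0)
  expect_equal(clamped[signed > 0], signed[signed > 0])
})
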