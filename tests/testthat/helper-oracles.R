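# Independent brute-force reference implementations used as oracles.
# Deliberately written as explicit loops / explicit sorts, sharing no code
# with the package internals.

oraclePearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  num <- 0; dx2 <- 0; dy2 <- 0
  for (i in seq_len(n)) {
    num <- num + (x[i] - mx) * (y[i] - my)
    dx2 <- dx2 + (x[i] - mx)^2
    dy2 <- dy2 + (y[i] - my)^2
  }
  num / sqrt(dx2 * dy2)
}

# all-pairs similarity with explicit rank cutoff by sorting
oracleSimilarity <- function(features, topFraction = 0.5, pCut = 0.01) {
  n <- nrow(features)
  r <- matrix(0, n, n)
  p <- matrix(1, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) {
      r[i, j] <- oraclePearson(features[i, ], features[j, ])
      tt <- abs(r[i, j]) * sqrt(ncol(features) - 2) /
        sqrt(max(1 - r[i, j]^2, 1e-300))
      p[i, j] <- if (abs(r[i, j]) >= 1) 0 else 2 * stats::pt(tt, ncol(features) - 2,
                                                            lower.tail = FALSE)
    }
  }
  absVals <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) absVals <- c(absVals, abs(r[i, j]))
  k <- floor(topFraction * length(absVals))
  out <- matrix(0, n, n)
  if (k >= 1) {
    cutoff <- sort(absVals, decreasing = TRUE)[k]
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i != j && abs(r[i, j]) >= cutoff && p[i, j] < pCut) out[i, j] <- r[i, j]
    }
  }
  diag(out) <- 1
  out
}

oracleNormalizePPI <- function(w) {
  n <- nrow(w)
  d <- numeric(n)
  for (i in seq_len(n)) for (j in seq_len(n)) d[i] <- d[i] + w[i, j]
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (d[i] > 0 && d[j] > 0) out[i, j] <- w[i, j] / sqrt(d[i] * d[j])
  }
  out
}

oracleDegreeNormalize <- function(w) {
  nr <- nrow(w); nc <- ncol(w)
  rs <- numeric(nr); cs <- numeric(nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    rs[i] <- rs[i] + w[i, j]
    cs[j] <- cs[j] + w[i, j]
  }
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (rs[i] * cs[j] > 0) out[i, j] <- w[i, j] / sqrt(rs[i] * cs[j])
  }
  out
}

# one coupled update, straight-line index arithmetic
oracleStep <- function(scc, sdd, stt, acd0, adt0, acd, adt, alpha) {
  n <- nrow(acd); m <- ncol(acd); l <- ncol(adt)
  bcd <- matrix(0, m, m)
  for (a in seq_len(m)) for (b in seq_len(m)) {
    s <- 0
    for (u in seq_len(m)) for (g1 in seq_len(l)) for (g2 in seq_len(l))
      s <- s + sdd[a, u] * adt[u, g1] * stt[g1, g2] * adt[b, g2]
    bcd[a, b] <- s
  }
  nb <- oracleDegreeNormalize(bcd)
  acdNext <- matrix(0, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- 0
    for (k in seq_len(m)) s <- s + acd[i, k] * nb[k, j]
    acdNext[i, j] <- alpha * s + (1 - alpha) * acd0[i, j]
  }
  bdt <- matrix(0, m, m)
  for (a in seq_len(m)) for (b in seq_len(m)) {
    s <- 0
    for (i1 in seq_len(n)) for (i2 in seq_len(n)) for (k in seq_len(m))
      s <- s + acd[i1, a] * scc[i1, i2] * acd[i2, k] * sdd[k, b]
    bdt[a, b] <- s
  }
  nd <- oracleDegreeNormalize(bdt)
  adtNext <- matrix(0, m, l)
  for (a in seq_len(m)) for (g in seq_len(l)) {
    s <- 0
    for (k in seq_len(m)) s <- s + nd[a, k] * adt[k, g]
    adtNext[a, g] <- alpha * s + (1 - alpha) * adt0[a, g]
  }
  list(acd = acdNext, adt = adtNext)
}

# AUC oracle 1: explicit pairwise comparison (Mann-Whitney U / (P*N))
oracleAUCPairs <- function(labels, scores) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  s <- 0
  for (p in pos) for (q in neg)
    s <- s + if (p > q) 1 else if (p == q) 0.5 else 0
  s / (length(pos) * length(neg))
}

# AUC oracle 2: trapezoidal integration of the empirical ROC curve
oracleAUCTrapezoid <- function(labels, scores) {
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  P <- sum(labels == 1); N <- sum(labels == 0)
  tpr <- fpr <- numeric(length(thr))
  for (t in seq_along(thr)) {
    called <- scores >= thr[t]
    tpr[t] <- sum(called & labels == 1) / P
    fpr[t] <- sum(called & labels == 0) / N
  }
  auc <- 0
  for (t in seq_len(length(thr) - 1))
    auc <- auc + (fpr[t + 1] - fpr[t]) * (tpr[t + 1] + tpr[t]) / 2
  auc
}

# small random heterogeneous network with nonnegative similarities
randomNet <- function(n = 4, m = 3, l = 3, seed = 1, density = 0.5) {
  set.seed(seed)
  symSim <- function(k) {
    s <- matrix(stats::runif(k * k), k, k) * (matrix(stats::runif(k * k), k, k) < density)
    s <- (s + t(s)) / 2
    diag(s) <- 1
    s
  }
  ids <- function(p, k) paste0(p, seq_len(k))
  scc <- symSim(n); dimnames(scc) <- list(ids("c", n), ids("c", n))
  sdd <- symSim(m); dimnames(sdd) <- list(ids("d", m), ids("d", m))
  stt <- symSim(l); dimnames(stt) <- list(ids("g", l), ids("g", l))
  acd <- matrix(as.numeric(stats::rbinom(n * m, 1, 0.5)), n, m,
                dimnames = list(ids("c", n), ids("d", m)))
  if (sum(acd) == 0) acd[1, 1] <- 1
  adt <- matrix(as.numeric(stats::rbinom(m * l, 1, 0.5)), m, l,
                dimnames = list(ids("d", m), ids("g", l)))
  if (sum(adt) == 0) adt[1, 1] <- 1
  buildNetwork(SimilarityMatrix(scc, kind = "cell"),
               SimilarityMatrix(sdd, kind = "drug"),
               stt, BipartiteMatrix(acd), BipartiteMatrix(adt))
}

# target-layer ablation: identity gene similarity, diagonal drug-target stub
ablateTargetLayer <- function(net) {
  l <- nrow(net@simTT); m <- length(net@simDD@nodeIds)
  stopifnot(l >= m)
  stub <- matrix(0, m, l, dimnames = list(net@adt0@rowIds, net@adt0@colIds))
  stub[cbind(seq_len(m), seq_len(m))] <- 1
  ttI <- diag(l)
  dimnames(ttI) <- dimnames(net@simTT)
  buildNetwork(net@simCC, net@simDD, ttI, net@acd0,
               BipartiteMatrix(stub, net@adt0@rowIds, net@adt0@colIds))
}

meanLoocvAUC <- function(net, alpha = 0.4) {
  cv <- runLOOCV(net, alpha = alpha)
  suppressWarnings(mean(perDrugAUC(rankedPredictions(cv, net)), na.rm = TRUE))
}
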