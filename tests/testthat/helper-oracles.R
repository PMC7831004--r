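# Independent oracles used to cross-check package implementations.
# These deliberately avoid the code paths they validate.

# Build an EffectSet directly from numbers (bypasses curve estimation).
makeEffectSet <- function(a, b, c, abc) {
  e <- c(A = a, B = b, C = c, ABC = abc)
  new("EffectSet", effects = e, se = rep(0, 4), endpointH = 120,
      nReplicates = 3L, growthPromotion = e < 0, comboArm = "ABC")
}

# Exact two-sided Wilcoxon rank-sum p by full enumeration of all
# choose(n1+n2, n1) group assignments (tie-free data only).
enumWilcoxP <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  ranks <- rank(pooled)
  wObs <- sum(ranks[seq_len(n1)]) - n1 * (n1 + 1) / 2  # Mann-Whitney U
  idx <- utils::combn(n1 + n2, n1)
  wAll <- apply(idx, 2, function(i) sum(ranks[i]) - n1 * (n1 + 1) / 2)
  pLo <- mean(wAll <= wObs)
  pHi <- mean(wAll >= wObs)
  min(1, 2 * min(pLo, pHi))
}

# Hand-computed two-group log-rank chi-squared statistic (standard
# hypergeometric-moment formula), independent of survival::survdiff.
logrankChisq <- function(time, event, group) {
  g <- as.integer(factor(group)) == 1L
  eventTimes <- sort(unique(time[event == 1]))
  o <- e <- v <- 0
  for (t in eventTimes) {
    atRisk <- time >= t
    n <- sum(atRisk); n1 <- sum(atRisk & g)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g)
    o <- o + d1
    e <- e + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  if (v == 0) return(0)
  (o - e)^2 / v
}

# Hypergeometric upper/lower tail by direct combinatorial summation.
sumHyperP <- function(k, n, K, N) {
  j <- max(0, n - (N - K)):min(n, K)
  pmf <- exp(lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n))
  list(p_over = sum(pmf[j >= k]), p_under = sum(pmf[j <= k]))
}

# Literal subset enumeration of the hypergeometric tail: count size-n
# subsets of 1..N with at least / at most k members among the first K.
combnHyperP <- function(k, n, K, N) {
  hits <- utils::combn(N, n, function(s) sum(s <= K))
  list(p_over = mean(hits >= k), p_under = mean(hits <= k))
}

# One-way permutation test on the difference of two group means.
permMeanDiffP <- function(x, y, iters = 20000, seed = 1) {
  pooled <- c(x, y)
  obs <- abs(mean(x) - mean(y))
  withr::with_seed(seed, {
    stat <- replicate(iters, {
      i <- sample.int(length(pooled), length(x))
      abs(mean(pooled[i]) - mean(pooled[-i]))
    })
  })
  (1 + sum(stat >= obs)) / (iters + 1)
}

# Adjusted Rand index between two partitions (via mclust when available).
ari <- function(a, b) {
  mclust::adjustedRandIndex(a, b)
}

# Tiny hand-built DE study table.
deTable <- function(gene_id, log2fc, padj, biotype = "protein_coding",
                    study = "s") {
  data.frame(study = study, gene_id = gene_id, biotype = biotype,
             log2fc = log2fc, padj = padj, stringsAsFactors = FALSE)
}
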