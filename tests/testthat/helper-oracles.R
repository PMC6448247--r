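# Independent oracles used across the suite. Deliberately brute-force and
# kept free of any package internals beyond trivially simple primitives.

# Upper-tail hypergeometric probability by exhaustive enumeration of all
# subsets of size n from a universe of size N whose first K elements are
# the "successes": P(overlap >= k).
enumHyperTail <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  overlaps <- colSums(draws <= K)
  mean(overlaps >= k)
}

# Benjamini-Hochberg step-up, written directly from the formula.
bruteBH <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in m:1) {
    prev <- min(prev, p[o[i]] * m / i)
    adj[o[i]] <- prev
  }
  pmin(adj, 1)
}

# Holm step-down, written directly from the formula.
bruteHolm <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    running <- max(running, (m - i + 1) * p[o[i]])
    adj[o[i]] <- min(running, 1)
  }
  adj
}

# Classical equal-variance two-sample t statistic from first principles.
bruteTwoSampleT <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
}

# Otsu oracle: exhaustive sweep over candidate thresholds maximizing
# between-class variance.
sweepOtsu <- function(v) {
  cand <- sort(unique(v))
  best <- -Inf; thr <- cand[1]
  for (t in cand[-1]) {
    lo <- v[v < t]; hi <- v[v >= t]
    w <- length(lo) / length(v)
    bc <- w * (1 - w) * (mean(lo) - mean(hi))^2
    if (bc > best) { best <- bc; thr <- t }
  }
  thr
}

# A digital disk mask of radius r (pixel centers within r of the center).
digitalDisk <- function(r) {
  n <- 2L * ceiling(r) + 5L
  c0 <- (n + 1) / 2
  g <- expand.grid(row = seq_len(n), col = seq_len(n))
  matrix(as.numeric((g$row - c0)^2 + (g$col - c0)^2 <= r^2), n, n)
}

# Per-gene scores (signed normal quantiles of two-sided p) from a DE table.
zScores <- function(de) {
  data.frame(gene = de$gene,
             score = qnorm(pmax(de$pValue, 1e-300) / 2, lower.tail = FALSE) *
               sign(de$log2fc))
}
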