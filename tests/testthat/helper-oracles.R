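# Independent oracles used across tests. These recompute expected values by
# brute force, never through the code paths they check.

# Unweighted KS enrichment oracle from the empirical CDF difference:
# running[i] = (#hits at ranks <= i)/k - (#misses <= i)/(N-k), extremum with
# the larger magnitude (tie resolved positive).
ks_oracle <- function(N, hit_positions) {
  k <- length(hit_positions)
  hits <- cumsum(seq_len(N) %in% hit_positions)
  running <- hits / k - (seq_len(N) - hits) / (N - k)
  hi <- max(running)
  lo <- min(running, 0)
  if (hi >= -lo - 1e-12) hi else lo  # magnitude ties resolve positive
}

# Weighted running-sum oracle evaluated step by step with an explicit loop.
weighted_es_oracle <- function(stats_sorted, hit_positions, p_w = 1) {
  N <- length(stats_sorted)
  k <- length(hit_positions)
  wsum <- sum(abs(stats_sorted[hit_positions])^p_w)
  running <- numeric(N)
  cur <- 0
  for (i in seq_len(N)) {
    cur <- cur + if (i %in% hit_positions) abs(stats_sorted[i])^p_w / wsum
                 else -1 / (N - k)
    running[i] <- cur
  }
  hi <- max(running)
  lo <- min(running, 0)
  list(es = if (hi >= -lo - 1e-12) hi else lo, running = running)
}

# Step-up BH by its definition: sort, multiply by m/rank, enforce
# monotonicity from the largest p down, cap at 1.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) adj[i] <- min(adj[i], adj[i + 1])
  pmin(adj, 1)[order(o)]
}

# Exact two-group log-rank permutation p: enumerate all assignments of the
# observed group sizes and compare chi-square statistics.
logrank_perm_p <- function(time, event, group) {
  obs <- logrank_test(time, event, group)$chisq
  idx_a <- utils::combn(length(time), sum(group == unique(group)[1]))
  stats <- apply(idx_a, 2, function(ia) {
    g <- rep("b", length(time))
    g[ia] <- "a"
    logrank_test(time, event, g)$chisq
  })
  mean(stats >= obs - 1e-12)
}

# Empirical survival function (no censoring): S(t) = mean(time > t).
empirical_surv <- function(times, at) vapply(at, function(t) mean(times > t),
                                             numeric(1))

# Two-sided 99% binomial bounds on an empirical fraction.
binom_bounds99 <- function(p, n) qbinom(c(0.005, 0.995), n, p) / n

expect_within <- function(x, lo, hi) {
  expect_gte(x, lo)
  expect_lte(x, hi)
}
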