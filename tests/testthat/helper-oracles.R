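# Independent brute-force oracles used across tests.

# KS D statistic computed directly from the two ECDFs.
brute_ks_stat <- function(x, y) {
  z <- sort(unique(c(x, y)))
  max(abs(stats::ecdf(x)(z) - stats::ecdf(y)(z)))
}

# Exhaustive-permutation two-sided KS p value (all C(n+m, n) splits).
brute_ks_p <- function(x, y) {
  z <- c(x, y)
  n <- length(x)
  d_obs <- brute_ks_stat(x, y)
  idx <- utils::combn(length(z), n)
  ds <- apply(idx, 2, function(i) brute_ks_stat(z[i], z[-i]))
  mean(ds >= d_obs - 1e-12)
}

# Hypergeometric upper tail P(X >= k) by direct combinatorial summation.
brute_hyper_tail <- function(k, n, K, N) {
  i <- k:min(n, K)
  if (length(i) == 0 || k > min(n, K)) return(0)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Two-sided Fisher exact p for a 2x2 table: sum of hypergeometric point
# probabilities no larger than the observed one.
brute_fisher_2x2 <- function(tab) {
  a <- tab[1, 1]
  m1 <- sum(tab[1, ]); m2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  support <- max(0, c1 - m2):min(m1, c1)
  probs <- choose(m1, support) * choose(m2, c1 - support) /
    choose(m1 + m2, c1)
  p_obs <- probs[support == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Benjamini-Hochberg step-up written out directly.
brute_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# Median-of-ratios size factors computed the slow, explicit way.
brute_size_factors <- function(counts) {
  ref <- apply(counts, 1, function(r) all(r > 0))
  geo <- apply(counts[ref, , drop = FALSE], 1, function(r)
    prod(r)^(1 / length(r)))
  apply(counts[ref, , drop = FALSE], 2, function(col)
    median(col / geo))
}

# small convenience: wild-type-only config for fast pipeline tests
wt_config <- function(...) {
  sim_config(genotypes = c(GP = 1), ...)
}
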