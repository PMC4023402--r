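# Independent brute-force oracles used to cross-check the statistical
# routines. These deliberately avoid the distribution functions the
# implementation relies on.

# Hypergeometric upper tail by direct summation of binomial-coefficient
# point masses.
oracle_hypergeom_tail <- function(k, n, K, N) {
  js <- seq(k, min(n, K))
  if (length(js) == 0 || k > min(n, K)) return(0)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Exact two-sided rank-sum p-value by full enumeration of all assignments
# of group labels to the pooled observations (tie-free inputs only).
oracle_ranksum_exact <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  idx <- utils::combn(length(pooled), na)
  u_all <- apply(idx, 2, function(i) sum(r[i])) - na * (na + 1) / 2
  p_low <- mean(u_all <= u_obs)
  p_high <- mean(u_all >= u_obs)
  min(1, 2 * min(p_low, p_high))
}

# Exact two-sided permutation p-value for the pooled-variance t statistic.
oracle_permutation_t <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  tstat <- function(idx) {
    x <- pooled[idx]; y <- pooled[-idx]
    sp <- sqrt(((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
                 (length(x) + length(y) - 2))
    (mean(x) - mean(y)) / (sp * sqrt(1 / length(x) + 1 / length(y)))
  }
  t_obs <- abs(tstat(seq_len(na)))
  idx <- utils::combn(length(pooled), na)
  t_all <- abs(apply(idx, 2, tstat))
  mean(t_all >= t_obs - 1e-12)
}
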