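# Independent brute-force oracles used to check the package's statistics.

# Two-sided Wilcoxon rank-sum p by exhaustive enumeration, computed through
# the Mann-Whitney U statistic (pairwise comparisons), independent of the
# package's rank-sum path.
oracle_ranksum_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  N <- length(pooled)
  u_of <- function(a, b) {
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  u_obs <- u_of(x, y)
  sets <- utils::combn(N, n1)
  us <- apply(sets, 2, function(idx) u_of(pooled[idx], pooled[-idx]))
  eps <- 1e-9
  min(1, 2 * min(mean(us <= u_obs + eps), mean(us >= u_obs - eps)))
}

# Two-sided Fisher p for a 2x2 table by direct summation of the
# conditional hypergeometric point masses not exceeding the observed one.
oracle_fisher_p <- function(n11, n10, n01, n00) {
  r1 <- n11 + n10
  c1 <- n11 + n01
  N <- n11 + n10 + n01 + n00
  lo <- max(0, r1 + c1 - N)
  hi <- min(r1, c1)
  k <- lo:hi
  probs <- stats::dhyper(k, c1, N - c1, r1)
  p_obs <- stats::dhyper(n11, c1, N - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Textbook Benjamini-Hochberg step-up, computed directly from the sorted
# p-values.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- rev(cummin(rev(p[o] * m / seq_len(m))))
  pmin(1, adj)[order(o)]
}

# Upper-tail hypergeometric by direct summation of choose() terms.
oracle_hyper_tail <- function(k, K, N, n) {
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}
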