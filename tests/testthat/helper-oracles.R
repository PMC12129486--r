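# Independent oracles used across test files. Each recomputes a quantity by
# brute force (enumeration, transition matrices, closed forms), never through
# the package code paths it is checking.

# Exact two-sided Fisher p by full hypergeometric enumeration over all tables
# with the observed margins: sum point probabilities <= observed * (1 + 1e-7).
fisher_enum_two_sided <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  support <- lo:hi
  logp <- lchoose(m, support) + lchoose(n, k - support) - lchoose(m + n, k)
  p_obs <- logp[support == a]
  sum(exp(logp[logp <= p_obs + log(1 + 1e-7)]))
}

# Exact two-sided signed-rank p by enumeration of all 2^n sign assignments
# (tie-free x), doubling the smaller tail and capping at 1.
signrank_enum_p <- function(x) {
  n <- length(x)
  r <- rank(abs(x))
  W_obs <- sum(r[x > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  W_all <- as.vector(signs %*% r)
  p_low <- mean(W_all <= W_obs)
  p_high <- mean(W_all >= W_obs)
  min(1, 2 * min(p_low, p_high))
}

# Exact retention probability of a Wright-Fisher chain with 2N chromosomes
# after t generations, by powering the (2N+1)-state binomial transition
# matrix from the deterministic start round(2N * p0).
wf_markov_retention <- function(two_n, p0, t) {
  P <- outer(0:two_n, 0:two_n,
             function(i, j) dbinom(j, two_n, i / two_n))
  v <- rep(0, two_n + 1)
  v[round(two_n * p0) + 1] <- 1
  for (g in seq_len(t)) v <- as.vector(v %*% P)
  sum(v[2:two_n])
}

# Small deterministic haplotype window: 4 haplotypes, 100 covered sites,
# variant derived counts {2, 1} (the worked diversity example).
worked_window <- function() {
  haplotype_window(rbind(c(1, 1), c(1, 0), c(0, 0), c(0, 0)),
                   positions = c(10, 20), window_length = 100,
                   n_monomorphic_covered = 98)
}
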