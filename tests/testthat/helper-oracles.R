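# Brute-force enumeration oracles shared by the stats and acceptance tests.

# Exact two-sided Wilcoxon p by enumerating all C(m+n, m) rank splits.
enumWilcoxP <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled)
  m <- length(x)
  ranks <- rank(pooled)
  wObs <- sum(ranks[seq_len(m)]) - m * (m + 1) / 2
  combs <- utils::combn(n, m)
  ws <- apply(combs, 2, function(ix) sum(ranks[ix])) - m * (m + 1) / 2
  mu <- m * length(y) / 2
  mean(abs(ws - mu) >= abs(wObs - mu) - 1e-9)
}

# Exact two-sided Fisher p for a 2x2 table: sum of hypergeometric
# probabilities of all tables with the observed margins that are at most
# as probable as the observed one.
enumFisherP <- function(tab) {
  r1 <- sum(tab[1, ])
  c1 <- sum(tab[, 1])
  n <- sum(tab)
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- dhyper(support, c1, n - c1, r1)
  pObs <- dhyper(tab[1, 1], c1, n - c1, r1)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}
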