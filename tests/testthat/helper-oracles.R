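# Independent brute-force oracles used to validate the implementation paths.
# These deliberately avoid the functions (and library calls) they check.

oracle_shannon <- function(p) {
  h <- 0
  for (pi in p) if (pi > 0) h <- h - pi * log(pi)
  h
}

oracle_simpson <- function(p) {
  d <- 0
  for (pi in p) d <- d + pi * pi
  d
}

# Two-sided Fisher p for a 2x2 table by full hypergeometric enumeration
# (sum of table probabilities no larger than the observed one).
oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  supp <- max(0, c1 - r2):min(r1, c1)
  probs <- vapply(supp, function(x) {
    exp(lchoose(r1, x) + lchoose(r2, c1 - x) - lchoose(r1 + r2, c1))
  }, numeric(1))
  p_obs <- probs[supp == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Hand log-rank tableau for two groups (observed-minus-expected with
# hypergeometric variance at each distinct event time).
oracle_logrank_2g <- function(times, events, groups) {
  g <- as.integer(factor(groups))
  stopifnot(max(g) == 2)
  ts <- sort(unique(times[events == 1]))
  O1 <- 0; E1 <- 0; V <- 0
  for (t in ts) {
    at <- times >= t
    n <- sum(at); n1 <- sum(at & g == 1)
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & g == 1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- (O1 - E1)^2 / V
  list(statistic = chisq, p = pchisq(chisq, 1, lower.tail = FALSE))
}

# Delta-method approximation to the SD of the plug-in Shannon estimate when
# keeping a fraction f of N cells without replacement.
oracle_subsample_sd <- function(p, N, f) {
  h <- oracle_shannon(p)
  v <- sum(((log(p) + h)^2 * p)[p > 0])
  sqrt(v * (1 - f) / (f * N))
}
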