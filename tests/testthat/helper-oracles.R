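# Independent brute-force oracles used to pin down the statistical
# primitives.  These never call the implementation they check.

# Two-sided Fisher exact p by full hypergeometric enumeration over the
# fixed margins of a 2x2 table [[a, b], [c, d]]: sum the probabilities of
# every table at most as probable as the observed one (same relative
# slack as R's fisher.test).
fisher_oracle <- function(a, b, c, d) {
  m <- a + c; n <- b + d; k <- a + b
  if (m + n == 0 || k == 0 || k == m + n) return(1)
  lo <- max(0L, k - n); hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Mann-Whitney U from its definition: count pairs (x_i, y_j) with
# x_i > y_j, ties counted 1/2.
brute_U <- function(x, y) {
  u <- 0
  for (xi in x) for (yj in y) u <- u + (xi > yj) + 0.5 * (xi == yj)
  u
}

# Definitional BH oracle: q_i is the smallest alpha at which the step-up
# procedure (reject H_(1..k), k = max{ j : p_(j) <= alpha j / m }) rejects
# hypothesis i.  Candidate alphas are m p_(j) / j.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  alphas <- sort(unique(pmin(m * p[o] / seq_len(m), 1)))
  q <- rep(NA_real_, m)
  for (alpha in alphas) {
    ps <- p[o]
    # tiny slack so alpha = m p_(j) / j rejects rank j despite rounding
    ok <- which(ps <= alpha * seq_len(m) / m + 1e-12)
    if (!length(ok)) next
    rejected <- o[seq_len(max(ok))]
    newly <- rejected[is.na(q[rejected])]
    q[newly] <- alpha
  }
  q[is.na(q)] <- 1
  q
}

# Closed-form MLE of the two-group binomial model (the genotype logistic
# regression is saturated at group level): fitted group rates are the
# pooled per-group frequencies.
two_group_mle <- function(edited, coverage, genotype, levels) {
  f <- vapply(levels, function(l) {
    sum(edited[genotype == l]) / sum(coverage[genotype == l])
  }, numeric(1))
  c(beta0 = stats::qlogis(f[[1]]), beta1 = stats::qlogis(f[[2]]) - stats::qlogis(f[[1]]))
}
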