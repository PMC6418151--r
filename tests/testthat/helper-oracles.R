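# Independent brute-force oracles, written as naive index-by-index
# summations straight from the defining formulas. Deliberately slow and
# loop-based so they share no code path with the package implementation.

# Burt constraint (x100) for node i = 1 (the ego) of weight matrix z.
oracle_constraint <- function(z) {
  nn <- nrow(z)
  p <- function(i, j) {
    num <- z[i, j] + z[j, i]
    den <- 0
    for (k in seq_len(nn)) if (k != i) den <- den + z[i, k] + z[k, i]
    num / den
  }
  total <- 0
  for (j in 2:nn) {
    indirect <- 0
    for (q in 2:nn) {
      if (q != j) indirect <- indirect + p(1, q) * p(q, j)
    }
    total <- total + (p(1, j) + indirect)^2
  }
  100 * total
}

# Effective size for the ego of weight matrix z; the max in m_jq runs over
# j's alter neighbours only (the ego excluded).
oracle_effective_size <- function(z) {
  nn <- nrow(z)
  p <- function(i, j) {
    num <- z[i, j] + z[j, i]
    den <- 0
    for (k in seq_len(nn)) if (k != i) den <- den + z[i, k] + z[k, i]
    num / den
  }
  total <- 0
  for (j in 2:nn) {
    mx <- 0
    for (k in 2:nn) if (k != j) mx <- max(mx, z[j, k])
    red <- 0
    if (mx > 0) {
      for (q in 2:nn) {
        if (q != j) red <- red + p(1, q) * z[j, q] / mx
      }
    }
    total <- total + 1 - red
  }
  total
}

# Two-sided Fisher exact p for a 2x2 table by hypergeometric enumeration:
# sum of probabilities of all tables (with the same margins) whose
# probability does not exceed the observed one.
oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  lo <- max(0L, c1 - (n - r1)); hi <- min(r1, c1)
  probs <- stats::dhyper(lo:hi, r1, n - r1, c1)
  # tolerance for floating-point ties, as in stats::fisher.test
  sum(probs[probs <= probs[a - lo + 1] * (1 + 1e-7)])
}

# All equal-weight ego networks with n alters: one per subset of the
# C(n, 2) possible alter-alter ties.
enumerate_networks <- function(n, prefix = "g") {
  ids <- sprintf("a%d", seq_len(n))
  alters <- data.frame(alter_id = ids, tie_to_ego = "strong")
  pairs <- if (n >= 2) t(utils::combn(ids, 2)) else
    matrix(character(), ncol = 2)
  npairs <- nrow(pairs)
  lapply(seq_len(2^npairs) - 1L, function(mask) {
    present <- as.logical(bitwAnd(mask, 2^(seq_len(npairs) - 1L)))
    ties <- if (any(present)) {
      data.frame(alter_a = pairs[present, 1], alter_b = pairs[present, 2],
                 strength = "strong")
    } else NULL
    ego_network(sprintf("%s%d_%d", prefix, n, mask), alters, ties)
  })
}
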