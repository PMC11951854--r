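# Independent oracles for partition agreement, kept deliberately separate from
# the package's pair-count formula implementation.

# All set partitions of n objects as 1-based label vectors (restricted growth
# strings). Bell numbers: 1, 2, 5, 15, 52, 203, 877 for n = 1..7.
enumerate_set_partitions <- function(n) {
  out <- list()
  recurse <- function(labels, next_max) {
    i <- length(labels) + 1L
    if (i > n) {
      out[[length(out) + 1L]] <<- labels
      return(invisible())
    }
    for (l in seq_len(next_max)) {
      recurse(c(labels, l), max(next_max, l + 1L))
    }
  }
  recurse(integer(0), 1L)
  out
}

# Pair counts by brute-force enumeration of all object pairs.
pair_counts_oracle <- function(p, q) {
  n <- length(p)
  n0 <- n1 <- n2 <- n3 <- 0
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      same_p <- p[a] == p[b]
      same_q <- q[a] == q[b]
      if (same_p && same_q) n0 <- n0 + 1
      else if (!same_p && !same_q) n1 <- n1 + 1
      else if (same_p) n2 <- n2 + 1
      else n3 <- n3 + 1
    }
  }
  c(n0 = n0, n1 = n1, n2 = n2, n3 = n3)
}

# Hubert-Arabie adjusted Rand index, (Index - Expected) / (Max - Expected),
# from the contingency table. Algebraically distinct route from the package's
# 2(n0 n1 - n2 n3) / (...) pair-count formula.
hubert_arabie_ari <- function(p, q) {
  kp <- max(p)
  kq <- max(q)
  n <- length(p)
  nij <- tabulate((p - 1L) * kq + q, kp * kq)
  ai <- tabulate(p, kp)
  bj <- tabulate(q, kq)
  sij <- sum(nij * (nij - 1) / 2)
  sa <- sum(ai * (ai - 1) / 2)
  sb <- sum(bj * (bj - 1) / 2)
  tot <- n * (n - 1) / 2
  e <- sa * sb / tot
  mx <- (sa + sb) / 2
  if (mx == e) return(1) # both trivial in the same way => identical partitions
  (sij - e) / (mx - e)
}

# Random partition of n objects into at most kmax clusters (labels compacted).
random_partition <- function(n, kmax) {
  as.integer(factor(sample.int(kmax, n, replace = TRUE)))
}

anscombe_xy <- function(which) {
  a <- anscombe_quartet()[[which]]
  list(x = a$x, y = a$y)
}
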