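# Independent brute-force oracles for the exact-mode tests. These are
# written against the definitions (pairwise win counts, explicit sign
# vectors, explicit label rearrangements), not against the package's own
# enumeration machinery, so they can serve as a second route.

# Midrank of each element computed by counting, not by rank().
counting_midrank <- function(x) {
  vapply(x, function(xi) sum(x < xi) + (sum(x == xi) + 1) / 2, numeric(1))
}

two_sided <- function(p_lo, p_hi) min(1, 2 * min(p_lo, p_hi))

# Rank-sum oracle: enumerate every subset of the pooled sample taking the
# role of `a`, score it by the Mann-Whitney pairwise count U (ties 1/2),
# and compare to the observed U. W and U order arrangements identically
# (W = U + na(na+1)/2), so tail probabilities agree with the W-based test.
oracle_rank_sum_p <- function(a, b, alternative = "two.sided") {
  pooled <- c(a, b)
  na <- length(a)
  u_of <- function(idx) {
    x <- pooled[idx]
    y <- pooled[-idx]
    tot <- 0
    for (xi in x) tot <- tot + sum(xi > y) + 0.5 * sum(xi == y)
    tot
  }
  obs <- u_of(seq_len(na))
  dist <- apply(utils::combn(length(pooled), na), 2, u_of)
  p_hi <- mean(dist >= obs - 1e-9)
  p_lo <- mean(dist <= obs + 1e-9)
  switch(alternative,
         two.sided = two_sided(p_lo, p_hi),
         greater = p_hi,
         less = p_lo)
}

# Signed-rank oracle: explicit enumeration of every sign vector on the
# nonzero differences.
oracle_signed_rank_p <- function(d, alternative = "two.sided") {
  d <- d[d != 0]
  n <- length(d)
  r <- counting_midrank(abs(d))
  obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  dist <- as.vector(signs %*% r)
  p_hi <- mean(dist >= obs - 1e-9)
  p_lo <- mean(dist <= obs + 1e-9)
  switch(alternative,
         two.sided = two_sided(p_lo, p_hi),
         greater = p_hi,
         less = p_lo)
}

# All distinct permutations of a label multiset, generated recursively.
all_label_arrangements <- function(labels) {
  uniq <- unique(labels)
  if (length(labels) == 1) return(list(labels))
  out <- list()
  for (u in uniq) {
    rest <- labels[-match(u, labels)]
    for (tail in all_label_arrangements(rest)) {
      out[[length(out) + 1]] <- c(u, tail)
    }
  }
  out
}

oracle_jt_stat <- function(values, labels) {
  ks <- sort(unique(labels))
  tot <- 0
  for (ii in seq_along(ks)) {
    for (jj in seq_along(ks)) {
      if (jj <= ii) next
      x <- values[labels == ks[ii]]
      y <- values[labels == ks[jj]]
      for (xi in x) tot <- tot + sum(xi < y) + 0.5 * sum(xi == y)
    }
  }
  tot
}

# Jonckheere-Terpstra oracle: enumerate every distinct arrangement of the
# group labels over the pooled values.
oracle_jt_p <- function(groups, alternative = "two.sided") {
  values <- unlist(groups, use.names = FALSE)
  labels <- rep(seq_along(groups), lengths(groups))
  obs <- oracle_jt_stat(values, labels)
  arrangements <- all_label_arrangements(labels)
  dist <- vapply(arrangements, function(lab) oracle_jt_stat(values, lab),
                 numeric(1))
  p_hi <- mean(dist >= obs - 1e-9)
  p_lo <- mean(dist <= obs + 1e-9)
  switch(alternative,
         two.sided = two_sided(p_lo, p_hi),
         greater = p_hi,
         less = p_lo)
}
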