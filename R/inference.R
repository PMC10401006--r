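# Nonparametric inference with small-sample exact modes and permutation
# nulls. Exact-mode p-values are computed by full enumeration (rank
# assignments, sign flips, or group-label arrangements), so they are
# rational multiples of 1 / (number of arrangements). Two-sided p-values
# double the smaller tail and cap at 1.

new_ci_test <- function(method, statistic, p_value, alternative, n, mode,
                        estimate = NULL, conf_low = NULL, conf_high = NULL,
                        conf_level = NULL) {
  structure(
    list(
      method = method, statistic = unname(statistic), p_value = unname(p_value),
      alternative = alternative, n = n, mode = mode, estimate = estimate,
      conf_low = conf_low, conf_high = conf_high, conf_level = conf_level
    ),
    class = "ci_test"
  )
}

#' @export
print.ci_test <- function(x, ...) {
  cat(sprintf("<ci_test> %s (%s)\n", x$method, x$mode))
  cat(sprintf("  statistic = %g, p = %.4g, alternative = %s, n = %s\n",
              x$statistic, x$p_value, x$alternative,
              paste(x$n, collapse = "/")))
  if (!is.null(x$estimate)) {
    cat(sprintf("  estimate = %g", x$estimate))
    if (!is.null(x$conf_low)) {
      cat(sprintf(" [%g, %g] (%.0f%%)", x$conf_low, x$conf_high,
                  100 * x$conf_level))
    }
    cat("\n")
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
#' @method tidy ci_test
tidy.ci_test <- function(x, ...) {
  tibble(
    method = x$method,
    statistic = x$statistic,
    p.value = x$p_value,
    alternative = x$alternative,
    mode = x$mode,
    n = paste(x$n, collapse = "/"),
    estimate = x$estimate %||% NA_real_,
    conf.low = x$conf_low %||% NA_real_,
    conf.high = x$conf_high %||% NA_real_
  )
}

#' @export
#' @method glance ci_test
glance.ci_test <- function(x, ...) tidy(x, ...)

`%||%` <- function(a, b) if (is.null(a)) b else a

two_sided_p <- function(p_lo, p_hi) min(1, 2 * min(p_lo, p_hi))

tail_p <- function(alternative, p_lo, p_hi) {
  switch(alternative,
    two.sided = two_sided_p(p_lo, p_hi),
    greater = p_hi,
    less = p_lo
  )
}

# Wilcoxon rank sum ------------------------------------------------------

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Compares two independent samples by the sum of midranks of `a` in the
#' pooled sample. In exact mode the null distribution is built by full
#' enumeration of all `choose(n, n_a)` assignments of the pooled values
#' (ties are handled naturally, making this a permutation test on the
#' tie-adjusted statistic); otherwise a normal approximation with tie
#' correction and continuity correction is used. `alternative = "greater"`
#' means `a` tends to exceed `b`.
#'
#' @param a,b Numeric samples.
#' @param alternative `"two.sided"` (default), `"greater"`, or `"less"`.
#' @param mode `"auto"` (exact when `length(a) + length(b) <= 12`),
#'   `"exact"`, or `"normal"`.
#' @param continuity Apply the 0.5 continuity correction in normal mode.
#' @return A `ci_test` object.
#' @export
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))$p_value # 0.1
wilcoxon_rank_sum <- function(a, b,
                              alternative = c("two.sided", "greater", "less"),
                              mode = c("auto", "exact", "normal"),
                              continuity = TRUE) {
  alternative <- match.arg(alternative)
  mode <- match.arg(mode)
  if (length(a) == 0 || length(b) == 0) {
    abort("both samples must be non-empty.", class = "netwisdom_invalid_input")
  }
  na <- length(a)
  nb <- length(b)
  N <- na + nb
  pooled <- c(a, b)
  r <- rank(pooled)
  W <- sum(r[seq_len(na)])
  if (mode == "auto") mode <- if (N <= 12) "exact" else "normal"

  if (mode == "exact") {
    sets <- utils::combn(N, na)
    dist <- colSums(matrix(r[sets], nrow = na))
    eps <- 1e-9
    p_hi <- mean(dist >= W - eps)
    p_lo <- mean(dist <= W + eps)
  } else {
    E <- na * (N + 1) / 2
    ties <- table(pooled)
    V <- na * nb / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    cc <- if (continuity) 0.5 else 0
    if (V <= 0) {
      p_lo <- p_hi <- 1
    } else {
      p_hi <- stats::pnorm((W - E - cc) / sqrt(V), lower.tail = FALSE)
      p_lo <- stats::pnorm((W - E + cc) / sqrt(V))
    }
  }
  new_ci_test("Wilcoxon rank sum", W, tail_p(alternative, p_lo, p_hi),
              alternative, c(na, nb), mode)
}

# Wilcoxon signed rank ---------------------------------------------------

# Exact sign-flip distribution of V = sum of ranks of positive differences,
# by polynomial convolution over (1 + x^r) factors. Ranks are doubled so
# midranks (.5) live on an integer support.
signed_rank_distribution <- function(r2) {
  # r2: doubled ranks (integers). Returns counts over V2 = 0..sum(r2).
  counts <- c(1, rep(0, sum(r2)))
  for (ri in r2) {
    shifted <- c(rep(0, ri), counts[seq_len(length(counts) - ri)])
    counts <- counts + shifted
  }
  counts
}

#' Wilcoxon signed-rank test
#'
#' One-sample / paired-difference test on the sum of midranks of the
#' positive differences. Zero differences are dropped by default
#' (Wilcoxon's convention); `zeros = "pratt"` ranks them first and then
#' discards their ranks. Exact mode enumerates all `2^n` sign patterns via
#' convolution; otherwise a tie-corrected normal approximation with
#' continuity correction is used. `alternative = "greater"` means the
#' differences tend to be positive.
#'
#' @param d Numeric vector of (paired) differences.
#' @param alternative `"two.sided"`, `"greater"`, or `"less"`.
#' @param mode `"auto"` (exact when the nonzero count is at most 15),
#'   `"exact"`, or `"normal"`.
#' @param zeros `"wilcoxon"` (drop zeros) or `"pratt"`.
#' @param continuity Apply continuity correction in normal mode.
#' @return A `ci_test` object.
#' @export
#' @examples
#' wilcoxon_signed_rank(c(1, 2, 3, 4, 5), alternative = "greater")$p_value # 1/32
wilcoxon_signed_rank <- function(d,
                                 alternative = c("two.sided", "greater", "less"),
                                 mode = c("auto", "exact", "normal"),
                                 zeros = c("wilcoxon", "pratt"),
                                 continuity = TRUE) {
  alternative <- match.arg(alternative)
  mode <- match.arg(mode)
  zeros <- match.arg(zeros)
  if (all(d == 0)) {
    abort("all differences are zero.", class = "netwisdom_degenerate_input")
  }
  if (zeros == "wilcoxon") {
    d <- d[d != 0]
    r <- rank(abs(d))
  } else {
    r_all <- rank(abs(d))
    keep <- d != 0
    d <- d[keep]
    r <- r_all[keep]
  }
  n <- length(d)
  V <- sum(r[d > 0])
  if (mode == "auto") mode <- if (n <= 15) "exact" else "normal"

  if (mode == "exact") {
    counts <- signed_rank_distribution(as.integer(round(2 * r)))
    total <- sum(counts)
    v2 <- round(2 * V)
    idx <- seq_along(counts) - 1
    p_hi <- sum(counts[idx >= v2 - 1e-9]) / total
    p_lo <- sum(counts[idx <= v2 + 1e-9]) / total
  } else {
    E <- sum(r) / 2
    V_var <- sum(r^2) / 4
    cc <- if (continuity) 0.5 else 0
    p_hi <- stats::pnorm((V - E - cc) / sqrt(V_var), lower.tail = FALSE)
    p_lo <- stats::pnorm((V - E + cc) / sqrt(V_var))
  }
  new_ci_test("Wilcoxon signed rank", V, tail_p(alternative, p_lo, p_hi),
              alternative, n, mode)
}

# Jonckheere-Terpstra ----------------------------------------------------

jt_statistic <- function(groups) {
  k <- length(groups)
  s <- 0
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      cmp <- outer(groups[[i]], groups[[j]], "<")
      tie <- outer(groups[[i]], groups[[j]], "==")
      s <- s + sum(cmp) + 0.5 * sum(tie)
    }
  }
  s
}

# All distinct assignments of `values` into ordered groups of the given
# sizes; calls fun(groups) for each and collects the results.
enumerate_group_assignments <- function(values, sizes, fun) {
  out <- numeric(0)
  recurse <- function(remaining, gi, acc) {
    if (gi > length(sizes)) {
      out[[length(out) + 1]] <<- fun(acc)
      return(invisible(NULL))
    }
    picks <- utils::combn(length(remaining), sizes[gi], simplify = FALSE)
    for (p in picks) {
      recurse(remaining[-p], gi + 1, c(acc, list(remaining[p])))
    }
  }
  recurse(values, 1, list())
  out
}

#' Jonckheere-Terpstra test for an ordered trend across groups
#'
#' Tests for a monotone location trend across `k >= 3` ordered groups using
#' the sum of pairwise Mann-Whitney counts over all ordered group pairs
#' (ties count 1/2). `alternative = "greater"` is an increasing trend
#' (later groups tend larger). The p-value comes from full enumeration of
#' group-label arrangements for tiny inputs, a seeded Monte-Carlo
#' permutation null by default, or a tie-corrected normal approximation.
#'
#' @param groups List of numeric vectors in their hypothesised order.
#' @param alternative `"two.sided"`, `"greater"`, or `"less"`.
#' @param mode `"auto"` (exact when the pooled size is at most 10,
#'   permutation up to 2000 observations, else normal), `"exact"`,
#'   `"permutation"`, or `"normal"`.
#' @param n_perm Number of permutations in permutation mode (default 10000).
#' @param seed Optional seed for the permutation null.
#' @return A `ci_test` object.
#' @export
#' @examples
#' jonckheere_terpstra(list(c(1, 2), c(3, 4), c(5, 6)),
#'                     alternative = "greater")$statistic # 12
jonckheere_terpstra <- function(groups,
                                alternative = c("two.sided", "greater", "less"),
                                mode = c("auto", "exact", "permutation", "normal"),
                                n_perm = 10000L, seed = NULL) {
  alternative <- match.arg(alternative)
  mode <- match.arg(mode)
  if (!is.list(groups) || length(groups) < 3 || any(lengths(groups) == 0)) {
    abort("need at least 3 non-empty ordered groups.",
          class = "netwisdom_invalid_input")
  }
  sizes <- lengths(groups)
  N <- sum(sizes)
  JT <- jt_statistic(groups)
  if (mode == "auto") {
    mode <- if (N <= 10) "exact" else if (N <= 2000) "permutation" else "normal"
  }
  eps <- 1e-9

  if (mode == "exact") {
    pooled <- unlist(groups, use.names = FALSE)
    dist <- enumerate_group_assignments(pooled, sizes, jt_statistic)
    p_hi <- mean(dist >= JT - eps)
    p_lo <- mean(dist <= JT + eps)
  } else if (mode == "permutation") {
    if (!is.null(seed)) set.seed(as.integer(seed))
    # sort so the sampled null depends only on the pooled multiset: the
    # Monte-Carlo p is then invariant to relabeling within groups
    pooled <- sort(unlist(groups, use.names = FALSE))
    idx_end <- cumsum(sizes)
    idx_start <- c(1, utils::head(idx_end, -1) + 1)
    dist <- vapply(seq_len(n_perm), function(i) {
      perm <- sample(pooled)
      jt_statistic(lapply(seq_along(sizes), function(g) {
        perm[idx_start[g]:idx_end[g]]
      }))
    }, numeric(1))
    # add-one rule: the observed arrangement counts as one realization
    p_hi <- (1 + sum(dist >= JT - eps)) / (1 + n_perm)
    p_lo <- (1 + sum(dist <= JT + eps)) / (1 + n_perm)
  } else {
    pooled <- unlist(groups, use.names = FALSE)
    E <- (N^2 - sum(sizes^2)) / 4
    t <- as.numeric(table(pooled))
    v1 <- (N * (N - 1) * (2 * N + 5) -
             sum(sizes * (sizes - 1) * (2 * sizes + 5)) -
             sum(t * (t - 1) * (2 * t + 5))) / 72
    v2 <- sum(sizes * (sizes - 1) * (sizes - 2)) * sum(t * (t - 1) * (t - 2)) /
      (36 * N * (N - 1) * (N - 2))
    v3 <- sum(sizes * (sizes - 1)) * sum(t * (t - 1)) / (8 * N * (N - 1))
    V <- v1 + v2 + v3
    if (V <= 0) {
      p_lo <- p_hi <- 1
    } else {
      z <- (JT - E) / sqrt(V)
      p_hi <- stats::pnorm(z, lower.tail = FALSE)
      p_lo <- stats::pnorm(z)
    }
  }
  new_ci_test("Jonckheere-Terpstra", JT, tail_p(alternative, p_lo, p_hi),
              alternative, sizes, mode)
}

# Spearman ---------------------------------------------------------------

#' Spearman rank correlation
#'
#' Pearson correlation of midranks, with a p-value from the t
#' approximation (default) or a seeded permutation null.
#'
#' @param x,y Equal-length numeric vectors, `n >= 3`.
#' @param alternative `"two.sided"`, `"greater"`, or `"less"`.
#' @param mode `"t-approx"` or `"permutation"`.
#' @param n_perm,seed Permutation settings.
#' @return A `ci_test` object with `estimate` set to `r_s`.
#' @export
spearman_cor <- function(x, y,
                         alternative = c("two.sided", "greater", "less"),
                         mode = c("t-approx", "permutation"),
                         n_perm = 10000L, seed = NULL) {
  alternative <- match.arg(alternative)
  mode <- match.arg(mode)
  if (length(x) != length(y) || length(x) < 3) {
    abort("`x` and `y` must have equal length >= 3.",
          class = "netwisdom_invalid_input")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort("constant input: rank correlation undefined.",
          class = "netwisdom_degenerate_input")
  }
  rx <- rank(x)
  ry <- rank(y)
  rs <- stats::cor(rx, ry)
  n <- length(x)

  if (mode == "t-approx") {
    if (abs(rs) >= 1) {
      p_hi <- if (rs >= 1) 0 else 1
      p_lo <- if (rs <= -1) 0 else 1
    } else {
      tstat <- rs * sqrt((n - 2) / (1 - rs^2))
      p_hi <- stats::pt(tstat, df = n - 2, lower.tail = FALSE)
      p_lo <- stats::pt(tstat, df = n - 2)
    }
  } else {
    if (!is.null(seed)) set.seed(as.integer(seed))
    dist <- vapply(seq_len(n_perm), function(i) stats::cor(rx, sample(ry)),
                   numeric(1))
    eps <- 1e-12
    p_hi <- (1 + sum(dist >= rs - eps)) / (1 + n_perm)
    p_lo <- (1 + sum(dist <= rs + eps)) / (1 + n_perm)
  }
  new_ci_test("Spearman rank correlation", rs, tail_p(alternative, p_lo, p_hi),
              alternative, n, mode, estimate = rs)
}

# Hodges-Lehmann shift ---------------------------------------------------

#' Hodges-Lehmann shift estimate with rank-sum confidence interval
#'
#' Estimates the location shift of sample `b` relative to sample `a` as the
#' median of all pairwise differences `b_j - a_i`, with the confidence
#' interval obtained by inverting the rank-sum test: the interval runs from
#' the `(k+1)`-th smallest to the `(k+1)`-th largest pairwise difference,
#' where `k` is the lower-tail critical value of the Mann-Whitney U
#' statistic at `(1 - conf_level) / 2` (exact null distribution for
#' moderate samples, normal approximation otherwise).
#'
#' @param a,b Numeric samples; the estimate is the shift of `b` relative
#'   to `a`.
#' @param conf_level Confidence level (default 0.95).
#' @return A `ci_test` object with `estimate`, `conf_low`, `conf_high`.
#' @export
#' @examples
#' rank_sum_ci(c(1, 2, 3, 4), c(6, 7, 8, 9))$estimate # 5
rank_sum_ci <- function(a, b, conf_level = 0.95) {
  if (length(a) == 0 || length(b) == 0) {
    abort("both samples must be non-empty.", class = "netwisdom_invalid_input")
  }
  m <- length(a)
  n <- length(b)
  diffs <- sort(as.vector(outer(b, a, "-")))
  est <- stats::median(diffs)
  alpha <- 1 - conf_level

  # c = largest u with P(U <= u) <= alpha/2 under the null; the interval
  # keeps the shifts not rejected by the two-sided level-alpha test:
  # [d_(c+1), d_(mn-c)].
  if (m * n <= 5000) {
    cdf <- cumsum(mann_whitney_pmf(m, n))
    k <- sum(cdf <= alpha / 2 + 1e-12) # = c + 1, counting u = 0..c
  } else {
    mu <- m * n / 2
    sigma <- sqrt(m * n * (m + n + 1) / 12)
    k <- floor(mu + stats::qnorm(alpha / 2) * sigma + 0.5) + 1
  }
  k <- min(max(1, k), ceiling(m * n / 2))
  lo <- diffs[k]
  hi <- diffs[m * n - k + 1]
  new_ci_test("Hodges-Lehmann shift (rank-sum inversion)", est, NA_real_,
              "two.sided", c(m, n), if (m * n <= 5000) "exact" else "normal-approx",
              estimate = est, conf_low = lo, conf_high = hi,
              conf_level = conf_level)
}

# Exact pmf of Mann-Whitney U for samples of size m and n (no ties assumed;
# used only to pick the CI order statistic). Lattice recursion:
# N(u; m, n) = N(u - n; m - 1, n) + N(u; m, n - 1).
mann_whitney_pmf <- function(m, n) {
  prev <- matrix(0, nrow = m + 1, ncol = m * n + 1)
  prev[1, 1] <- 1 # n' = 0: only u = 0 reachable, any m
  for (mm in seq_len(m)) prev[mm + 1, 1] <- 1
  for (nn in seq_len(n)) {
    cur <- matrix(0, nrow = m + 1, ncol = m * n + 1)
    cur[1, 1] <- 1
    for (mm in seq_len(m)) {
      for (u in 0:(mm * nn)) {
        left <- if (u - nn >= 0) cur[mm, u - nn + 1] else 0
        cur[mm + 1, u + 1] <- left + prev[mm + 1, u + 1]
      }
    }
    prev <- cur
  }
  counts <- prev[m + 1, ]
  counts / sum(counts)
}

# Student/Welch t --------------------------------------------------------

#' Two-sample t test
#'
#' Welch's unequal-variance t test by default (`var_equal = TRUE` gives the
#' pooled Student form). If both samples are constant: equal constants give
#' `t = 0, p = 1`; unequal constants are a degenerate input (zero variance,
#' infinite statistic) and raise an error.
#'
#' @param a,b Numeric samples with at least 2 observations each.
#' @param alternative `"two.sided"`, `"greater"`, or `"less"`
#'   (`"greater"`: `a` exceeds `b`).
#' @param var_equal Pooled-variance Student form.
#' @return A `ci_test` object with `estimate = mean(a) - mean(b)`.
#' @export
two_sample_t <- function(a, b,
                         alternative = c("two.sided", "greater", "less"),
                         var_equal = FALSE) {
  alternative <- match.arg(alternative)
  if (length(a) < 2 || length(b) < 2) {
    abort("each sample needs at least 2 observations.",
          class = "netwisdom_invalid_input")
  }
  na <- length(a)
  nb <- length(b)
  va <- stats::var(a)
  vb <- stats::var(b)
  delta <- mean(a) - mean(b)
  if (va == 0 && vb == 0) {
    if (delta == 0) {
      return(new_ci_test("Two-sample t", 0, 1, alternative, c(na, nb),
                         if (var_equal) "pooled" else "welch",
                         estimate = 0))
    }
    abort("both samples constant but unequal: t statistic undefined.",
          class = "netwisdom_degenerate_input")
  }
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  tstat <- delta / se
  p_hi <- stats::pt(tstat, df, lower.tail = FALSE)
  p_lo <- stats::pt(tstat, df)
  new_ci_test("Two-sample t", tstat, tail_p(alternative, p_lo, p_hi),
              alternative, c(na, nb), if (var_equal) "pooled" else "welch",
              estimate = delta)
}

# Power ------------------------------------------------------------------

#' Simulated power of the two-sided rank-sum comparison
#'
#' Monte-Carlo power of the Wilcoxon rank-sum test under a normal location
#' shift of Cohen's `d` standard deviations, at the trial-level sample
#' sizes of the study design (56 network vs 28 control trials by default).
#'
#' @param d Cohen's d (standardised shift).
#' @param n1,n2 Group sizes (defaults 56 and 28).
#' @param alpha Two-sided significance level.
#' @param n_sim Number of simulated datasets.
#' @param seed Integer seed.
#' @return One-row tibble: `power`, `d`, `n1`, `n2`, `alpha`, `n_sim`.
#' @export
power_rank_sum <- function(d, n1 = 56L, n2 = 28L, alpha = 0.05,
                           n_sim = 2000L, seed = 1L) {
  check_scalar_number(n1, "n1", lo = 2)
  check_scalar_number(n2, "n2", lo = 2)
  set.seed(as.integer(seed))
  rejections <- vapply(seq_len(n_sim), function(i) {
    x <- stats::rnorm(n1, mean = d)
    y <- stats::rnorm(n2)
    wilcoxon_rank_sum(x, y, mode = "normal")$p_value < alpha
  }, logical(1))
  tibble(power = mean(rejections), d = d, n1 = n1, n2 = n2,
         alpha = alpha, n_sim = n_sim)
}
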