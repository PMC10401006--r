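test_that("rank-sum exact p-values match the pairwise-count enumeration oracle", {
  res <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_identical(res$mode, "exact")
  expect_equal(res$p_value, 0.1) # 2 of the 20 arrangements are as extreme
  expect_equal(res$p_value, oracle_rank_sum_p(c(1, 2, 3), c(4, 5, 6)))

  a <- c(2, 2, 5)
  expect_equal(wilcoxon_rank_sum(a, a)$p_value, 1) # identical samples

  set.seed(10)
  for (i in 1:30) {
    na <- sample(2:5, 1)
    nb <- sample(2:5, 1)
    x <- sample(1:6, na, replace = TRUE) + stats::runif(na) * sample(0:1, 1)
    y <- sample(1:6, nb, replace = TRUE)
    for (alt in c("two.sided", "greater", "less")) {
      expect_equal(wilcoxon_rank_sum(x, y, alternative = alt)$p_value,
                   oracle_rank_sum_p(x, y, alt), tolerance = 1e-12)
    }
  }
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3),
               class = "netwisdom_invalid_input")
})

test_that("rank-sum normal approximation agrees with the reference implementation", {
  set.seed(11)
  for (i in 1:10) {
    x <- rnorm(20 + i)
    y <- rnorm(25) + 0.3
    expect_equal(wilcoxon_rank_sum(x, y, mode = "normal")$p_value,
                 stats::wilcox.test(x, y, exact = FALSE)$p.value,
                 tolerance = 1e-10)
  }
  # tied data engage the tie correction
  x <- rep(1:5, 3)
  y <- rep(2:6, 3)
  expect_equal(wilcoxon_rank_sum(x, y, mode = "normal")$p_value,
               suppressWarnings(stats::wilcox.test(x, y, exact = FALSE)$p.value),
               tolerance = 1e-10)
})

test_that("signed-rank exact p-values match the sign-flip enumeration oracle", {
  expect_equal(wilcoxon_signed_rank(c(-3, -1, 1, 3))$p_value, 1)
  res <- wilcoxon_signed_rank(c(1, 2, 3, 4, 5), alternative = "greater")
  expect_identical(res$mode, "exact")
  expect_equal(res$p_value, 1 / 32)

  set.seed(12)
  for (i in 1:30) {
    n <- sample(3:9, 1)
    d <- sample(-5:5, n, replace = TRUE)
    if (all(d == 0)) d[1] <- 1
    for (alt in c("two.sided", "greater", "less")) {
      expect_equal(wilcoxon_signed_rank(d, alternative = alt)$p_value,
                   oracle_signed_rank_p(d, alt), tolerance = 1e-12)
    }
  }
  expect_error(wilcoxon_signed_rank(c(0, 0, 0)),
               class = "netwisdom_degenerate_input")
})

test_that("signed-rank matches the reference implementation when tie-free", {
  set.seed(13)
  d <- rnorm(12)
  expect_equal(wilcoxon_signed_rank(d)$p_value,
               stats::wilcox.test(d)$p.value, tolerance = 1e-12)
  d30 <- rnorm(30)
  expect_equal(wilcoxon_signed_rank(d30, mode = "normal")$p_value,
               stats::wilcox.test(d30, exact = FALSE)$p.value,
               tolerance = 1e-10)
})

test_that("zeros are dropped by default and kept-ranked under Pratt", {
  d <- c(0, 0, 1, 2, -3)
  res_w <- wilcoxon_signed_rank(d)
  expect_identical(res_w$n, 3L)
  res_p <- wilcoxon_signed_rank(d, zeros = "pratt")
  # Pratt: |d| ranks computed over all five values, zeros then discarded
  expect_identical(res_p$n, 3L)
  expect_equal(res_p$statistic, sum(rank(abs(d))[d > 0]))
})

test_that("Jonckheere-Terpstra statistic and exact p match the arrangement oracle", {
  g <- list(c(1, 2), c(3, 4), c(5, 6))
  res <- jonckheere_terpstra(g, alternative = "greater")
  expect_identical(res$mode, "exact")
  expect_equal(res$statistic, 12) # maximal: all cross-group pairs ordered
  expect_equal(res$p_value, oracle_jt_p(g, "greater"))
  expect_equal(res$p_value, 1 / 90) # 1 of C(6,2)*C(4,2) = 90 arrangements

  set.seed(14)
  for (i in 1:12) {
    sizes <- sample(2:3, 3, replace = TRUE)
    while (sum(sizes) > 9) sizes <- sample(2:3, 3, replace = TRUE)
    g2 <- lapply(sizes, function(s) sample(1:5, s, replace = TRUE))
    for (alt in c("two.sided", "greater")) {
      expect_equal(jonckheere_terpstra(g2, alternative = alt, mode = "exact")$p_value,
                   oracle_jt_p(g2, alt), tolerance = 1e-12)
    }
  }
  expect_error(jonckheere_terpstra(list(1:3, 4:6)),
               class = "netwisdom_invalid_input")
})

test_that("reversing the group order mirrors the JT statistic", {
  set.seed(15)
  g <- lapply(c(4, 3, 5), function(s) rnorm(s))
  sizes <- lengths(g)
  max_jt <- sum(outer(sizes, sizes)[upper.tri(outer(sizes, sizes))])
  fwd <- jonckheere_terpstra(g, mode = "normal")$statistic
  rev_ <- jonckheere_terpstra(rev(g), mode = "normal")$statistic
  expect_equal(rev_, max_jt - fwd)
})

test_that("JT permutation p-values are seeded, reproducible, and label-invariant", {
  set.seed(16)
  g <- lapply(1:4, function(i) rnorm(6) + 0.3 * i)
  a <- jonckheere_terpstra(g, mode = "permutation", n_perm = 500, seed = 42)
  b <- jonckheere_terpstra(g, mode = "permutation", n_perm = 500, seed = 42)
  expect_identical(a$p_value, b$p_value)
  # relabeling within groups (shuffling values inside each group) changes nothing
  g_shuf <- lapply(g, sample)
  c_ <- jonckheere_terpstra(g_shuf, mode = "permutation", n_perm = 500, seed = 42)
  expect_identical(a$p_value, c_$p_value)
})

test_that("JT permutation null p-values are calibrated under exchangeability", {
  set.seed(17)
  pvals <- vapply(1:120, function(i) {
    g <- lapply(1:3, function(j) rnorm(4))
    jonckheere_terpstra(g, mode = "permutation", n_perm = 400,
                        seed = i)$p_value
  }, numeric(1))
  # the add-one Monte-Carlo p is valid (super-uniform) and close to uniform
  for (alpha in c(0.1, 0.3, 0.5)) {
    hit <- mean(pvals <= alpha)
    se <- sqrt(alpha * (1 - alpha) / length(pvals))
    expect_lte(hit, alpha + 4 * se)
    expect_gte(hit, alpha - 4 * se - 1 / 400)
  }
})

test_that("Spearman correlation equals the midrank Pearson correlation", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(spearman_cor(x, x * 2)$estimate, 1)
  expect_equal(spearman_cor(x, rev(x))$estimate, -1)

  # hand-computed midrank example with ties
  x6 <- c(1, 2, 2, 4, 5, 6)
  y6 <- c(3, 3, 1, 5, 6, 5)
  rx <- c(1, 2.5, 2.5, 4, 5, 6)
  ry <- c(2.5, 2.5, 1, 4.5, 6, 4.5)
  expect_equal(spearman_cor(x6, y6)$estimate, stats::cor(rx, ry))
  expect_equal(spearman_cor(x6, y6)$estimate,
               stats::cor(x6, y6, method = "spearman"))
  expect_error(spearman_cor(rep(1, 5), 1:5),
               class = "netwisdom_degenerate_input")
  expect_error(spearman_cor(1:2, 1:2), class = "netwisdom_invalid_input")
})

test_that("Hodges-Lehmann shift recovers pure shifts and brackets the estimate", {
  a <- c(1, 2, 3, 4)
  res <- rank_sum_ci(a, a + 5)
  expect_equal(res$estimate, 5)
  expect_lte(res$conf_low, res$estimate)
  expect_gte(res$conf_high, res$estimate)

  # small samples: endpoints match the order-statistic inversion computed
  # by the reference implementation
  set.seed(18)
  for (i in 1:8) {
    x <- rnorm(sample(4:9, 1))
    y <- rnorm(sample(4:9, 1)) + 1
    mine <- rank_sum_ci(x, y)
    ref <- suppressWarnings(stats::wilcox.test(y, x, conf.int = TRUE))
    expect_equal(mine$estimate, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(c(mine$conf_low, mine$conf_high),
                 as.numeric(ref$conf.int), tolerance = 1e-12)
  }
})

test_that("two-sample t reproduces the Welch and pooled formulas", {
  a <- c(1, 5, 3, 7, 2)
  expect_equal(two_sample_t(a, a)$statistic, 0)
  expect_equal(two_sample_t(a, a)$p_value, 1)

  set.seed(19)
  x <- rnorm(8)
  y <- rnorm(12) + 0.5
  mine <- two_sample_t(x, y)
  ref <- stats::t.test(x, y)
  expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
  mine_p <- two_sample_t(x, y, var_equal = TRUE)
  ref_p <- stats::t.test(x, y, var.equal = TRUE)
  expect_equal(mine_p$p_value, ref_p$p.value, tolerance = 1e-12)

  # degenerate variance handling
  expect_equal(two_sample_t(c(2, 2), c(2, 2))$p_value, 1)
  expect_error(two_sample_t(c(0, 0), c(1, 1)),
               class = "netwisdom_degenerate_input")
  expect_error(two_sample_t(1, 1:3), class = "netwisdom_invalid_input")
})

test_that("simulated rank-sum power behaves like a power function", {
  p0 <- power_rank_sum(0, n1 = 30, n2 = 30, n_sim = 600, seed = 3)$power
  expect_lt(abs(p0 - 0.05), 0.03) # null calibration at alpha
  grid <- vapply(c(0.3, 0.8, 1.5), function(d) {
    power_rank_sum(d, n1 = 30, n2 = 30, n_sim = 300, seed = 4)$power
  }, numeric(1))
  expect_true(all(diff(grid) >= 0))
  expect_gt(power_rank_sum(3, n1 = 20, n2 = 20, n_sim = 200, seed = 5)$power,
            0.99)
})

test_that("test results tidy into one-row tibbles", {
  res <- wilcoxon_rank_sum(1:4, 3:8)
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_identical(nrow(td), 1L)
  expect_named(td, c("method", "statistic", "p.value", "alternative", "mode",
                     "n", "estimate", "conf.low", "conf.high"))
  expect_identical(glance(res), td)
})
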