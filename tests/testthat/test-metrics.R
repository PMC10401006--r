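test_that("absolute error is the symmetric distance, bounded by the scale", {
  expect_equal(absolute_error(30, 30), 0)
  expect_equal(absolute_error(0, 100), 100)
  expect_equal(absolute_error(55, 30), 25)
  expect_equal(absolute_error(5, 30), 25)
  expect_error(absolute_error(105, 30), class = "netwisdom_invalid_input")
  expect_error(absolute_error(50, -2), class = "netwisdom_invalid_input")
})

test_that("fixed-bounds normalization satisfies accuracy + error/100 = 1 exactly", {
  err <- c(0, 23.2, 23.7, 50, 100, runif(50, 0, 100))
  acc <- accuracy_from_error(err)
  expect_equal(acc + err / 100, rep(1, length(err)))
  expect_equal(accuracy_from_error(0), 1)
  expect_equal(accuracy_from_error(100), 0)
  expect_true(all(diff(accuracy_from_error(sort(err))) <= 0))
  expect_error(accuracy_from_error(10, bounds = c(0, 0)),
               class = "netwisdom_invalid_bounds")
})

test_that("observed-bounds normalization maps the sample range onto [0, 1]", {
  err <- c(5, 10, 20, 40)
  acc <- accuracy_from_error(err, bounds = range(-err))
  expect_equal(acc, (max(err) - err) / (max(err) - min(err)))
  expect_equal(max(acc), 1)
  expect_equal(min(acc), 0)
})

test_that("trial mean accuracy equals the elementwise mean of clinician accuracies", {
  est <- matrix(c(30, 30, 30, 30, 0, 100, 20, 40), nrow = 4)
  resp <- hand_panel_responses(estimates_by_round = est)
  expect_equal(trial_mean_accuracy(resp, truth = 30, round = 1), 1)

  set.seed(7)
  est2 <- matrix(runif(12, 0, 100), nrow = 6, ncol = 2)
  resp2 <- hand_panel_responses(estimates_by_round = est2)
  expect_equal(
    trial_mean_accuracy(resp2, truth = 45, round = 2),
    mean(1 - abs(est2[, 2] - 45) / 100)
  )
  # invariant under clinician reordering
  shuffled <- resp2[sample(nrow(resp2)), ]
  expect_equal(trial_mean_accuracy(shuffled, truth = 45, round = 2),
               trial_mean_accuracy(resp2, truth = 45, round = 2))
  # two clinicians at errors 0 and 100
  est3 <- matrix(rep(0, 4), nrow = 2)
  resp3 <- hand_panel_responses(estimates_by_round = est3)
  resp3$estimate[resp3$clinician_id == "c02"] <- 100 # truth 0 below
  expect_equal(trial_mean_accuracy(resp3, truth = 0, round = 1), 0.5)
  # incomplete panel
  expect_error(trial_mean_accuracy(resp2[-1, ], truth = 45, round = 1),
               class = "netwisdom_missing_data")
})

test_that("accuracy panel computes error, accuracy, correctness and exclusions", {
  vig <- tiny_vignettes()
  est <- matrix(c(30, 10, 70, 30, 20, 60), nrow = 3)
  resp <- hand_panel_responses(estimates_by_round = est)
  panel <- accuracy_panel(resp, vig)
  expect_equal(panel$error, abs(panel$estimate - 30))
  expect_equal(panel$accuracy, 1 - panel$error / 100)
  expect_identical(panel$correct, panel$recommendation == "mid")
  expect_identical(nrow(attr(panel, "exclusions")), 0L)

  # a clinician missing one round is excluded entirely and logged
  broken <- resp[!(resp$clinician_id == "c03" & resp$round == 2), ]
  panel2 <- accuracy_panel(broken, vig)
  expect_false("c03" %in% panel2$clinician_id)
  expect_identical(attr(panel2, "exclusions")$clinician_id, "c03")
})

test_that("equal-frequency binning partitions clinicians with balanced sizes", {
  vig <- tiny_vignettes()
  # 8 clinicians, distinct accuracies: exactly 2 per quartile, worst 2 in Q1
  est <- matrix(rep(c(30, 35, 25, 45, 60, 5, 90, 28), 2), nrow = 8)
  resp <- hand_panel_responses(estimates_by_round = est)
  clin <- clinician_summary(accuracy_panel(resp, vig))
  binned <- bin_by_initial_accuracy(clin, k = 4)
  expect_identical(unname(c(table(binned$bin))), rep(2L, 4))
  worst2 <- clin$clinician_id[order(clin$initial_accuracy)][1:2]
  expect_setequal(binned$clinician_id[binned$bin == 1], worst2)

  # all accuracies identical: deterministic tie-broken 2/2/2/2 split
  est_t <- matrix(rep(40, 16), nrow = 8)
  resp_t <- hand_panel_responses(estimates_by_round = est_t)
  clin_t <- clinician_summary(accuracy_panel(resp_t, vig))
  b1 <- bin_by_initial_accuracy(clin_t, k = 4)
  b2 <- bin_by_initial_accuracy(clin_t[sample(nrow(clin_t)), ], k = 4)
  expect_identical(unname(c(table(b1$bin))), rep(2L, 4))
  # stable tie order: assignment independent of row order
  m1 <- b1[order(b1$clinician_id), c("clinician_id", "bin")]
  m2 <- b2[order(b2$clinician_id), c("clinician_id", "bin")]
  expect_identical(as.data.frame(m1), as.data.frame(m2))

  # 40 clinicians into deciles: sizes all 4
  est_40 <- matrix(rep(seq(1, 79, 2), 2), nrow = 40)
  resp_40 <- hand_panel_responses(estimates_by_round = est_40)
  clin_40 <- clinician_summary(accuracy_panel(resp_40, vig))
  b40 <- bin_by_initial_accuracy(clin_40, k = 10)
  expect_identical(unname(c(table(b40$bin))), rep(4L, 10))

  # sizes differ by at most one when not divisible
  est_10 <- matrix(rep(seq(5, 95, 10), 2), nrow = 10)
  resp_10 <- hand_panel_responses(estimates_by_round = est_10)
  clin_10 <- clinician_summary(accuracy_panel(resp_10, vig))
  b10 <- bin_by_initial_accuracy(clin_10, k = 4)
  sizes <- c(table(b10$bin))
  expect_lte(diff(range(sizes)), 1)
  expect_identical(sum(sizes), 10L)

  expect_error(bin_by_initial_accuracy(clin_10, k = 11),
               class = "netwisdom_invalid_parameters")
})

test_that("change in accuracy is the difference of round means in points", {
  vig <- tiny_vignettes()
  est <- matrix(c(20, 40, 25, 35, 30, 30), nrow = 2) # rounds at errs 10,5,0
  resp <- hand_panel_responses(estimates_by_round = est)
  panel <- accuracy_panel(resp, vig)
  expect_equal(change_in_accuracy(panel, 1, 3), 10)
  expect_equal(change_in_accuracy(panel, 1, 2), 5)
  expect_equal(change_in_accuracy(panel, 2, 2), 0)
  expect_error(change_in_accuracy(panel, 1, 9),
               class = "netwisdom_invalid_parameters")
})

test_that("revision magnitude is the sign-free estimate change", {
  vig <- tiny_vignettes()
  est <- matrix(c(40, 40, 55, 48, 42, 40, 40, 55, 40), nrow = 3)
  resp <- hand_panel_responses(estimates_by_round = est)
  panel <- accuracy_panel(resp, vig)
  rm <- revision_magnitude(panel)
  expect_equal(rm$revision_magnitude[match(c("c01", "c02", "c03"), rm$clinician_id)],
               c(0, 15, 15))
})

test_that("correct and switch rates match manual enumeration", {
  vig <- tiny_vignettes()
  # truth 30, correct option "mid" (thresholds 25/50)
  # c1: 10 -> 30 (low -> mid): incorrect to correct
  # c2: 30 -> 30 (mid -> mid): stays correct
  # c3: 60 -> 70 (high -> high): stays incorrect
  # c4: 40 -> 80 (mid -> high): correct to incorrect
  est <- matrix(c(10, 30, 60, 40, 20, 30, 65, 60, 30, 30, 70, 80), nrow = 4)
  resp <- hand_panel_responses(estimates_by_round = est)
  panel <- accuracy_panel(resp, vig)
  expect_equal(correct_rate(resp, 1, "mid"), 0.5)
  expect_equal(correct_rate(resp, 3, "mid"), 0.5)
  sw <- switch_rate(panel)
  expect_equal(sw$incorrect_to_correct, 0.5)
  expect_equal(sw$correct_to_incorrect, 0.5)
  expect_identical(sw$n_initially_incorrect, 2L)
  # literal switcher count is an integer
  expect_equal(sw$incorrect_to_correct * sw$n_initially_incorrect, 1)

  # everyone initially wrong, everyone finally right -> (1, NA)
  est2 <- matrix(c(10, 5, 30, 30), nrow = 2)
  resp2 <- hand_panel_responses(estimates_by_round = est2)
  panel2 <- accuracy_panel(resp2, tiny_vignettes())
  sw2 <- switch_rate(panel2, to_round = 2)
  expect_equal(sw2$incorrect_to_correct, 1)
  expect_true(is.na(sw2$correct_to_incorrect))

  # no changes at all -> (0, 0)
  est3 <- matrix(c(10, 30, 10, 30), nrow = 2)
  resp3 <- hand_panel_responses(estimates_by_round = est3)
  panel3 <- accuracy_panel(resp3, tiny_vignettes())
  sw3 <- switch_rate(panel3, to_round = 2)
  expect_equal(sw3$incorrect_to_correct, 0)
  expect_equal(sw3$correct_to_incorrect, 0)
})

test_that("quartile summary table matches hand-computed row values", {
  vig <- tiny_vignettes()
  # 8 clinicians, truth 30: initial errors 25,20,15,12,8,6,3,0
  init <- c(5, 10, 15, 18, 22, 24, 27, 30)
  final <- c(15, 15, 18, 20, 24, 25, 27, 28)
  est <- cbind(init, (init + final) / 2, final)
  resp <- hand_panel_responses(estimates_by_round = est)
  panel <- accuracy_panel(resp, vig)
  tab <- tabulate_quartile_summary(panel)
  expect_identical(nrow(tab), 4L)
  # Q1 = two least accurate (init 5, 10 -> errors 25, 20)
  expect_equal(tab$initial_accuracy[tab$quartile == 1], 100 - mean(c(25, 20)))
  expect_equal(tab$final_accuracy[tab$quartile == 1], 100 - mean(c(15, 15)))
  expect_equal(tab$change_accuracy[tab$quartile == 1], mean(c(10, 5)))
  # recommendation columns: initial low/low -> both incorrect; final low/low
  expect_equal(tab$initial_correct_rate[tab$quartile == 1], 0)

  # frozen dynamics: initial = final in every row, change columns zero
  study <- small_study(seed = 2, gen = frozen_generator())
  panel_f <- accuracy_panel(study$responses, study$vignettes)
  tab_f <- tabulate_quartile_summary(panel_f)
  expect_identical(nrow(tab_f), 8L) # conditions x quartiles
  expect_equal(tab_f$change_accuracy, rep(0, 8))
  expect_equal(tab_f$initial_accuracy, tab_f$final_accuracy)
  expect_equal(tab_f$change_correct_rate, rep(0, 8))
})

test_that("revision magnitude declines across initial-accuracy deciles", {
  study <- simulate_study(seed = 21)
  panel <- accuracy_panel(study$responses, study$vignettes)
  clin <- clinician_summary(panel)
  net <- bin_by_initial_accuracy(clin[clin$condition == "network", ], k = 10)
  means <- tapply(net$revision_magnitude, net$bin, mean)
  # monotone non-increasing trend over deciles (small wobble tolerated)
  expect_lt(means[10], means[1])
  expect_true(all(diff(means) <= 1))
  expect_equal(stats::cor(1:10, means, method = "spearman") < -0.9, TRUE)
})
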