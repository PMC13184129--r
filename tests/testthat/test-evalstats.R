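test_that("confusion counts are exact on constructed masks", {
  base <- matrix(0L, 10L, 10L)
  gt <- base; gt[1:10] <- 1L
  expect_identical(confusion(gt, gt), list(tp = 10L, fp = 0L, fn = 0L, tn = 90L))
  expect_identical(confusion(base, gt)[c("tp", "fn")], list(tp = 0L, fn = 10L))
  pred <- base; pred[11:15] <- 1L
  cc <- confusion(pred, gt)
  expect_identical(cc[c("tp", "fp", "fn")], list(tp = 0L, fp = 5L, fn = 10L))
  expect_identical(cc$tp + cc$fp + cc$fn + cc$tn, 100L)
  expect_error(confusion(base, matrix(0L, 5, 5)), "geometry")
})

test_that("metric formulas match hand arithmetic and flag undefined cases", {
  m <- seg_metrics(list(tp = 3, fp = 1, fn = 2, tn = 94))
  expect_equal(m$dsc, 6 / 9)
  expect_equal(m$iou, 0.5)
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.6)
  perfect <- seg_metrics(list(tp = 7, fp = 0, fn = 0, tn = 93))
  expect_equal(unlist(perfect), c(dsc = 1, iou = 1, precision = 1, recall = 1))
  void <- seg_metrics(list(tp = 0, fp = 0, fn = 0, tn = 100))
  expect_true(all(is.na(unlist(void))))
  noprec <- seg_metrics(list(tp = 0, fp = 0, fn = 5, tn = 95))
  expect_true(is.na(noprec$precision))
  expect_equal(noprec$recall, 0)
})

test_that("metrics agree with the pixel-set oracle on random mask pairs", {
  set.seed(30)
  for (i in 1:200) {
    pred <- random_mask(12, 12, runif(1, 0, 0.3))
    gt <- random_mask(12, 12, runif(1, 0.02, 0.3))
    got <- seg_metrics(confusion(pred, gt))
    want <- set_metrics_oracle(pred, gt)
    expect_equal(got, want)
    # DSC-IoU identity whenever defined
    if (!is.na(got$dsc)) {
      expect_equal(got$dsc, 2 * got$iou / (1 + got$iou), tolerance = 1e-12)
    }
  }
})

test_that("failure taxonomy matches hand counts and is cumulative", {
  fr <- classify_failure(c(0, 0.1, 0.25, 0.5))
  expect_equal(fr$complete, 25)
  expect_equal(fr$tracking, 50)
  expect_equal(fr$boundary, 75)
  ok <- classify_failure(c(0.3, 0.5, 1))
  expect_equal(unlist(ok[1:3]), c(complete = 0, tracking = 0, boundary = 0))
  allz <- classify_failure(rep(0, 5))
  expect_equal(unlist(allz[1:3]), c(complete = 100, tracking = 100, boundary = 100))
  expect_error(classify_failure(numeric(0)), "no DSC")
  expect_error(classify_failure(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("aggregation uses sample SD and midpoint medians", {
  df <- data.frame(dsc = c(0.5, 0.7, 0.9))
  ag <- aggregate_metrics(df)
  expect_equal(ag$mean, 0.7)
  expect_equal(ag$median, 0.7)
  expect_equal(ag$sd, 0.2)
  one <- aggregate_metrics(data.frame(dsc = 0.4))
  expect_true(is.na(one$sd))
  flat <- aggregate_metrics(data.frame(iou = rep(1, 4)))
  expect_equal(flat$mean, 1); expect_equal(flat$sd, 0)
  expect_warning(und <- aggregate_metrics(data.frame(dsc = c(NA_real_, NA_real_))),
                 "undefined")
  expect_identical(und$n, 0L)
  expect_identical(und$n_undefined, 2L)
})

test_that("exact Wilcoxon p-values match full sign enumeration for n <= 10", {
  set.seed(31)
  for (i in 1:30) {
    n <- sample(4:10, 1)
    d <- round(stats::rnorm(n), if (i %% 2 == 0) 0 else 3)  # force ties half the time
    if (all(d == 0)) d[1] <- 1
    got <- wilcoxon_signed_rank(d)
    expect_equal(got$p_value, wilcoxon_bruteforce(d), tolerance = 1e-12,
                 info = paste(d, collapse = ","))
  }
  # all-positive n = 6, no ties: two-sided p = 2/64
  r <- wilcoxon_signed_rank(c(1, 2, 3, 4, 5, 6))
  expect_equal(r$p_value, 2 / 64)
  expect_identical(r$statistic, 21)
})

test_that("Wilcoxon agrees with stats::wilcox.test in tie-free cases", {
  set.seed(32)
  # exact mode
  d <- stats::rnorm(12)
  expect_equal(wilcoxon_signed_rank(d)$p_value,
               stats::wilcox.test(d, exact = TRUE)$p.value, tolerance = 1e-12)
  # asymptotic mode with continuity correction
  d2 <- stats::rnorm(40) + 0.3
  expect_equal(wilcoxon_signed_rank(d2)$p_value,
               stats::wilcox.test(d2, exact = FALSE, correct = TRUE)$p.value,
               tolerance = 1e-10)
})

test_that("degenerate and Bonferroni behaviour", {
  same <- wilcoxon_signed_rank(rep(0, 8))
  expect_equal(same$p_value, 1)
  expect_true(same$all_zero)
  cmp <- compare_models(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5), family_size = 6L)
  expect_equal(cmp$p_adjusted, 1)
  # Bonferroni arithmetic: adjusted = min(1, m * p)
  a <- c(0.9, 0.8, 0.85, 0.95, 0.88, 0.92)
  b <- a - 0.1
  r <- compare_models(a, b, family_size = 6L)
  expect_equal(r$p_adjusted, min(1, 6 * r$p_raw))
  expect_gte(r$p_adjusted, r$p_raw)
  expect_identical(r$direction, 1)
})

test_that("failure rates are monotone on random DSC lists", {
  set.seed(33)
  for (i in 1:200) {
    v <- stats::runif(sample(1:50, 1))
    v[stats::runif(length(v)) < 0.2] <- 0
    fr <- classify_failure(v)
    expect_lte(fr$complete, fr$tracking)
    expect_lte(fr$tracking, fr$boundary)
    expect_gte(fr$complete, 0); expect_lte(fr$boundary, 100)
  }
})

test_that("evaluate_predictions excludes empty ground truth and reports it", {
  gt1 <- random_mask(8, 8, 0.3)
  if (sum(gt1) == 0) gt1[1] <- 1L
  empty <- matrix(0L, 8, 8)
  ev <- evaluate_predictions(list(gt1, empty), list(gt1, empty))
  expect_identical(nrow(ev$per_slice), 1L)
  expect_identical(ev$n_empty_gt, 1L)
  expect_equal(ev$per_slice$dsc, 1)
  expect_false(ev$per_slice$empty_prediction)
  # complete-failure flag vs empty-prediction flag are distinct notions
  ev2 <- evaluate_predictions(list(empty), list(gt1))
  expect_true(ev2$per_slice$empty_prediction)
  expect_equal(ev2$failures$complete, 100)
})
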