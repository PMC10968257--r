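test_that("sliding windows enumerate the expected segments", {
  eye <- linear_md_eye("E1", slope = -0.2, n_visits = 9, interval = 1)
  segs <- segment_series(eye, windows = 4:8, stride = 1)
  expect_length(segs, 15)  # 5+4+3+2+1 start/length combinations over 8 years
  tab <- table(vapply(segs, function(s) s$window_length, numeric(1)))
  expect_equal(unname(tab[as.character(4:8)]), c(5L, 4L, 3L, 2L, 1L),
               ignore_attr = TRUE)
  # short series yield nothing
  short <- linear_md_eye("E2", slope = 0, n_visits = 4, interval = 1)
  short <- short[short$test_date - min(short$test_date) <= 3.5, ]
  expect_length(segment_series(short, windows = 4:8, stride = 1), 0)
  # stride equal to the span: one segment per feasible length
  segs2 <- segment_series(eye, windows = 4:8, stride = 8)
  expect_length(segs2, 5)
  expect_equal(sort(vapply(segs2, function(s) s$window_length, numeric(1))),
               4:8)
})

test_that("ground-truth labels use the full-window slope with a strict cut", {
  t <- 0:7
  expect_true(label_segment(t, -1 - 0.6 * t))
  expect_false(label_segment(t, rep(-1, 8)))
  expect_false(label_segment(t, -1 - 0.5 * t))  # boundary: stable
  expect_error(label_segment(1, -1))
})

test_that("truncated classification reproduces forced cases", {
  t <- seq(0, 4, by = 0.5)
  md <- -2 - 1.0 * t
  expect_true(classify_at_time(t, md, 2, "vf"))
  expect_false(classify_at_time(t, rep(-2, length(t)), 2, "vf"))
  expect_false(classify_at_time(t, rep(-2, length(t)), 2, "blr",
                                mrnflt = rep(85, length(t)), kappa = 0.1))
  # fewer than two visits inside the truncation: unclassifiable
  expect_true(is.na(classify_at_time(c(0, 3, 4), c(0, -3, -4), 1, "vf")))
})

test_that("confusion metrics match forced arithmetic and a counting oracle", {
  m <- aedfuse:::counts_to_metrics(tp = 2, tn = 6, fp = 1, fn = 1)
  expect_equal(m$sensitivity, 2 / 3, tolerance = 1e-12)
  expect_equal(m$specificity, 6 / 7, tolerance = 1e-12)
  expect_equal(m$f1, 4 / 6, tolerance = 1e-12)
  perfect <- confusion_metrics(c(TRUE, FALSE, TRUE), c(TRUE, FALSE, TRUE))
  expect_equal(c(perfect$sensitivity, perfect$specificity, perfect$f1),
               c(1, 1, 1))
  # undefined ratios surface as NaN with a flag, never silently 0
  nolab <- confusion_metrics(c(TRUE, FALSE), c(FALSE, FALSE))
  expect_true(is.nan(nolab$sensitivity))
  expect_true("sensitivity" %in% nolab$undefined)
  set.seed(73)
  pred <- runif(200) > 0.5
  lab <- runif(200) > 0.5
  m2 <- confusion_metrics(pred, lab)
  tp <- 0; tn <- 0; fp <- 0; fn <- 0
  for (i in 1:200) {
    if (pred[i] && lab[i]) tp <- tp + 1
    if (!pred[i] && !lab[i]) tn <- tn + 1
    if (pred[i] && !lab[i]) fp <- fp + 1
    if (!pred[i] && lab[i]) fn <- fn + 1
  }
  expect_identical(c(m2$tp, m2$tn, m2$fp, m2$fn), c(tp, tn, fp, fn))
  expect_equal(m2$sensitivity, tp / (tp + fn))
  expect_equal(m2$f1, 2 * tp / (2 * tp + fp + fn))
})

test_that("aggregation returns mean and 1.96-SEM intervals", {
  same <- aggregate_ci(rep(0.7, 5))
  expect_equal(same$sem, 0)
  expect_equal(same$lower, same$upper)
  two <- aggregate_ci(c(0.4, 0.6))
  expect_equal(two$mean, 0.5)
  expect_equal(two$sem, 0.1, tolerance = 1e-12)
  expect_equal(two$lower, 0.304, tolerance = 1e-12)
  expect_equal(two$upper, 0.696, tolerance = 1e-12)
  set.seed(7)
  v <- runif(20)
  a <- aggregate_ci(v)
  expect_equal(a$mean, mean(v), tolerance = 1e-12)
  expect_equal(a$sem, sd(v) / sqrt(20), tolerance = 1e-12)
  expect_equal(a$upper, mean(v) + 1.96 * sd(v) / sqrt(20), tolerance = 1e-12)
  expect_error(aggregate_ci(0.5))
})

test_that("signed-rank test is exact under ties and symmetric", {
  a <- runif(10)
  res <- wilcoxon_signed_rank(a + 0.1, a)
  # all ten differences positive and tied: exact enumeration gives 2 * 2^-10
  expect_true(res$exact)
  expect_equal(res$p_value, 2 / 1024, tolerance = 1e-12)
  # exhaustive enumeration oracle on untied data
  set.seed(91)
  x <- rnorm(10); y <- rnorm(10)
  d <- x - y; r <- rank(abs(d)); w_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), 10))
  w_all <- as.matrix(signs) %*% r
  p_exact <- min(1, 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs)))
  res2 <- wilcoxon_signed_rank(x, y)
  expect_equal(res2$p_value, p_exact, tolerance = 1e-12)
  # agreement with the standard exact test when there are no ties
  expect_equal(res2$p_value,
               wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value,
               tolerance = 1e-9)
  # symmetry under swapping the samples
  res3 <- wilcoxon_signed_rank(y, x)
  expect_equal(res3$p_value, res2$p_value, tolerance = 1e-12)
  # degenerate identical series
  res4 <- compare_methods(a, a)
  expect_true(res4$degenerate)
  expect_true(is.na(res4$p_value))
  # large-sample branch with tie correction stays close to wilcox.test
  set.seed(13)
  xb <- rnorm(40); yb <- xb - 0.3 + rnorm(40, 0, 0.5)
  rb <- wilcoxon_signed_rank(xb, yb)
  expect_false(rb$exact)
  expect_equal(rb$p_value,
               wilcox.test(xb, yb, paired = TRUE, exact = FALSE,
                           correct = FALSE)$p.value,
               tolerance = 1e-9)
})

test_that("too few nonzero differences yields no p-value", {
  a <- c(1, 2, 3, 4)
  res <- compare_methods(a + 0.1, a)
  expect_true(is.na(res$p_value))
})

test_that("zero-noise series classify perfectly from measured fields", {
  rows <- list()
  set.seed(55)
  slopes <- c(-1.2, -0.8, -0.6, -0.3, -0.1, 0, 0.1, -0.55, -0.45, -0.05)
  for (i in seq_along(slopes)) {
    rows[[i]] <- linear_md_eye(sprintf("E%02d", i), slopes[i], n_visits = 10,
                               interval = 0.9, md0 = -2 - i %% 3)
  }
  coh <- bind_rows_list(rows)
  rpt <- evaluate_progression(coh, threshold = -0.5)
  expect_true(all(rpt$fp == 0))
  expect_true(all(rpt$fn == 0))
  # pooled over everything: perfect sensitivity and specificity
  expect_equal(sum(rpt$tp) + sum(rpt$tn), sum(rpt$n))
  expect_gt(sum(rpt$tp), 0)
  expect_gt(sum(rpt$tn), 0)
})

test_that("counts are conserved and fused labels inherit from measured", {
  sim <- simulate_cohort(sim_config(n_patients = 8, seed = 301,
                                    unreliable_rate = 0))
  coh <- apply_reliability_filters(sim$cohort)$cohort
  rpt <- evaluate_progression(coh, fused = coh, blr = TRUE)
  expect_true(all(rpt$tp + rpt$tn + rpt$fp + rpt$fn == rpt$n))
  # a fused cohort identical to the measured one must reproduce vf exactly
  for (m in c("sensitivity", "specificity", "f1")) {
    vf <- rpt[rpt$method == "vf", m]
    fu <- rpt[rpt$method == "fused", m]
    expect_identical(vf, fu)
  }
  expect_true(any(rpt$method == "blr"))
})
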