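test_that("paired t-test matches the textbook closed form", {
  set.seed(101)
  for (i in 1:100) {
    n <- sample(3:15, 1)
    x <- rnorm(n); y <- rnorm(n)
    got <- paired_t_test(x, y)
    ref <- manual_paired_t(x, y)
    expect_equal(got$statistic, ref$t, tolerance = 1e-10)
    expect_equal(got$df, ref$df)
    expect_equal(got$p, ref$p, tolerance = 1e-10)
  }
  z9 <- rnorm(9)
  expect_equal(paired_t_test(z9, z9)$p, 1)
  expect_equal(paired_t_test(rnorm(9), rnorm(9))$df, 8)  # 9 pairs -> df 8
})

test_that("degenerate paired differences are flagged, not crashed", {
  res <- paired_t_test(c(5, 6, 7), c(3, 4, 5))
  expect_equal(res$estimate, 2)
  expect_match(res$note, "machine floor")
  expect_lt(res$p, 1e-300)
})

test_that("Welch t-test matches the Welch-Satterthwaite closed form", {
  set.seed(102)
  for (i in 1:100) {
    x <- rnorm(sample(3:12, 1), sd = runif(1, 0.5, 3))
    y <- rnorm(sample(3:12, 1), sd = runif(1, 0.5, 3))
    got <- welch_t_test(x, y)
    ref <- manual_welch_t(x, y)
    expect_equal(got$statistic, ref$t, tolerance = 1e-10)
    expect_equal(got$df, ref$df, tolerance = 1e-10)
    expect_equal(got$p, ref$p, tolerance = 1e-10)
  }
  x <- rnorm(8)
  expect_equal(welch_t_test(x, x)$statistic, 0)
  expect_error(welch_t_test(rep(1, 5), rep(2, 5)), "zero variance")
})

test_that("Welch df never exceeds the pooled df", {
  set.seed(103)
  for (i in 1:30) {
    x <- rnorm(7); y <- rnorm(7)
    expect_lte(welch_t_test(x, y)$df, 12 + 1e-9)
  }
})

test_that("exact signed-rank p equals full enumeration, ties included", {
  expect_equal(wilcoxon_paired(2:7, rep(1, 6))$p, 2 / 64)  # all positive
  set.seed(104)
  for (i in 1:40) {
    n <- sample(4:10, 1)
    x <- sample(1:7, n, replace = TRUE)
    y <- sample(1:7, n, replace = TRUE)
    if (all(x == y)) next
    got <- wilcoxon_paired(x, y)
    expect_match(got$method, "exact")
    expect_equal(got$p, enum_signed_p(x, y), tolerance = 1e-12)
  }
  expect_equal(wilcoxon_paired(1:5, 1:5)$p, 1)
})

test_that("exact rank-sum p equals full enumeration, ties included", {
  set.seed(105)
  for (i in 1:40) {
    n1 <- sample(3:7, 1); n2 <- sample(3:7, 1)
    x <- sample(1:9, n1, replace = TRUE)
    y <- sample(1:9, n2, replace = TRUE)
    got <- wilcoxon_ranksum(x, y)
    expect_match(got$method, "exact")
    expect_equal(got$p, enum_ranksum_p(x, y), tolerance = 1e-12)
  }
})

test_that("exact Wilcoxon agrees with wilcox.test when there are no ties", {
  set.seed(106)
  for (i in 1:25) {
    x <- rnorm(8); y <- rnorm(8)
    expect_equal(wilcoxon_paired(x, y)$p,
                 wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value,
                 tolerance = 1e-12)
    expect_equal(wilcoxon_ranksum(x, y)$p,
                 wilcox.test(x, y, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("large samples fall back to the normal approximation", {
  set.seed(107)
  x <- rnorm(30); y <- rnorm(30)
  expect_match(wilcoxon_paired(x, y)$method, "normal approximation")
  x2 <- rnorm(25); y2 <- rnorm(25)
  expect_match(wilcoxon_ranksum(x2, y2)$method, "normal approximation")
})

test_that("point-biserial equals Pearson on dummy coding", {
  set.seed(108)
  for (i in 1:30) {
    v <- rnorm(20)
    lab <- factor(rep(c("a", "b"), 10))
    got <- as.numeric(point_biserial(v, lab))
    expect_equal(got, cor(v, as.numeric(lab == "a")), tolerance = 1e-12)
  }
  # equal group means -> r = 0
  v0 <- c(1, 2, 3, 1, 2, 3)
  expect_equal(as.numeric(point_biserial(v0, rep(c("a", "b"), each = 3))), 0)
})

test_that("effect-size bands follow the .20/.35 thresholds", {
  expect_equal(effect_band(0.15), "small")
  expect_equal(effect_band(0.20), "small")
  expect_equal(effect_band(0.30), "medium")
  expect_equal(effect_band(0.36), "large")
  expect_equal(attr(point_biserial(c(1, 1, 1, 9, 9, 9),
                                   rep(c("hi", "lo"), each = 3)), "band"),
               "large")
})

test_that("point-biserial is invariant under affine maps; label swap flips sign", {
  set.seed(109)
  v <- rnorm(16)
  lab <- factor(rep(c("x", "y"), 8))
  r0 <- as.numeric(point_biserial(v, lab))
  expect_equal(as.numeric(point_biserial(3 * v + 10, lab)), r0,
               tolerance = 1e-12)
  swapped <- factor(lab, levels = c("y", "x"))
  expect_equal(as.numeric(point_biserial(v, swapped)), -r0, tolerance = 1e-12)
  expect_warning(point_biserial(rep(1, 6), rep(c("a", "b"), 3)), "zero variance")
})

test_that("balanced 2x2 interaction F matches the closed-form decomposition", {
  set.seed(110)
  n_cell <- 5
  g <- rep(c("P", "C"), each = 2 * n_cell)
  ty <- rep(rep(c("OT", "NOT"), each = n_cell), 2)
  y <- rnorm(4 * n_cell, mean = c(rep(10, n_cell), rep(4, n_cell),
                                  rep(5, n_cell), rep(6, n_cell)))
  got <- two_way_anova_interaction(y, g, ty)
  # closed form for the balanced design
  cell <- tapply(y, list(g, ty), mean)
  grand <- mean(y)
  rowm <- tapply(y, g, mean); colm <- tapply(y, ty, mean)
  ss_int <- n_cell * sum((cell - outer(rowm, colm, "+") + grand)^2)
  sse <- sum((y - cell[cbind(g, ty)])^2)
  f_ref <- (ss_int / 1) / (sse / (4 * n_cell - 4))
  expect_equal(got$statistic, f_ref, tolerance = 1e-10)
  expect_equal(got$df, c(1, 4 * n_cell - 4))
})

test_that("additive cell means give zero interaction sum of squares", {
  g <- rep(c("P", "C"), each = 4)
  ty <- rep(rep(c("OT", "NOT"), each = 2), 2)
  # cell means perfectly additive (effect of g +3, of ty +1); symmetric
  # within-cell spread keeps the residual positive
  y <- c(3.5, 4.5, 2.5, 3.5, 0.5, 1.5, -0.5, 0.5)
  got <- two_way_anova_interaction(y, g, ty)
  expect_equal(got$estimate, 0, tolerance = 1e-12)
  expect_equal(got$statistic, 0, tolerance = 1e-10)
})

test_that("all-equal cell means give interaction p near 1", {
  set.seed(111)
  g <- rep(c("P", "C"), each = 20)
  ty <- rep(rep(c("OT", "NOT"), each = 10), 2)
  y <- rnorm(40, mean = 5, sd = 0.001)
  got <- two_way_anova_interaction(y, g, ty)
  expect_lt(got$statistic, 5)
  expect_gt(got$p, 0.01)
})

test_that("empty design cells are named in the error", {
  expect_error(
    two_way_anova_interaction(1:6, c("P", "P", "P", "C", "C", "C"),
                              c("OT", "OT", "OT", "NOT", "NOT", "NOT")),
    "cell is empty")
})

test_that("BCa interval behaves sensibly and is seed-reproducible", {
  # constant sample collapses to a point
  ci0 <- bca_ci(rep(3, 10), mean, B = 1000)
  expect_true(ci0$degenerate)
  expect_equal(c(ci0$lower, ci0$upper), c(3, 3))
  set.seed(112)
  x <- rnorm(40, mean = 2)
  a <- bca_ci(x, mean, B = 1500, seed = 9)
  b <- bca_ci(x, mean, B = 1500, seed = 9)
  expect_equal(c(a$lower, a$upper), c(b$lower, b$upper))
  expect_lt(a$lower, mean(x))
  expect_gt(a$upper, mean(x))
  # for a well-behaved mean, BCa should be near the t interval
  tt <- t.test(x)
  expect_equal(a$lower, tt$conf.int[1], tolerance = 0.05)
  expect_equal(a$upper, tt$conf.int[2], tolerance = 0.05)
  expect_error(bca_ci(x, mean, B = 500), "B >= 1000")
})

test_that("contrast report recovers injected effects and handles fixtures", {
  ct <- constant_change_table()
  rep_tbl <- contrast_report(ct)
  all_rows <- rep_tbl[rep_tbl$scope == "Mean of all", ]
  expect_equal(
    all_rows$mean_diff[all_rows$measure == "voxels"],
    c(7479 - 1904, 7479 - 697, 1904 - 697))
  expect_equal(
    all_rows$mean_diff[all_rows$measure == "weighted"],
    c(26.48 - 8.34, 26.48 - 2.45, 8.34 - 2.45), tolerance = 1e-12)
  # identical diffs everywhere: all contrasts 0, p = 1
  ct0 <- constant_change_table(ot = 5, not = 5, isi = 5,
                               ot_w = 1, not_w = 1, isi_w = 1)
  rep0 <- contrast_report(ct0)
  expect_true(all(rep0$mean_diff == 0))
  expect_true(all(is.na(rep0$p_t) | rep0$p_t == 1))
})

test_that("patients lacking a label drop from paired but stay in unpaired", {
  ct <- constant_change_table(n_patients = 4, n_controls = 4)
  # remove p01's NOT rows: no paired contribution, still one OT mean
  ct <- ct[!(ct$subject == "p01" & ct$label == "NOT"), ]
  rep_tbl <- contrast_report(ct)
  row_p <- rep_tbl[rep_tbl$scope == "Mean of all" &
                     rep_tbl$measure == "voxels" &
                     rep_tbl$contrast == "OT-NOT", ]
  expect_equal(row_p$n_1, 3)  # paired subjects only
  row_u <- rep_tbl[rep_tbl$scope == "Mean of all" &
                     rep_tbl$measure == "voxels" &
                     rep_tbl$contrast == "OT-ISI", ]
  expect_equal(row_u$n_1, 4)  # all patients with an OT mean
})

test_that("paired t type-I error is near nominal on null data", {
  set.seed(113)
  n_sims <- 2000
  rejections <- 0
  for (i in seq_len(n_sims)) {
    d <- rnorm(9)
    if (paired_t_test(d, rep(0, 9))$p < 0.05) rejections <- rejections + 1
  }
  expect_gt(rejections / n_sims, 0.03)
  expect_lt(rejections / n_sims, 0.07)
})
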