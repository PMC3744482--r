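sc06 <- rating_scale(0, 6)

test_that("fluctuation intensity matches its closed-form limits", {
  expect_identical(fluctuation_intensity(rep(3, 7), sc06), 0)
  expect_equal(fluctuation_intensity(c(0, 6, 0, 6, 0, 6, 0), sc06), 1)
  # single monotone run: a = 6, d = 6, normaliser 36
  expect_equal(fluctuation_intensity(0:6, sc06), 1 / 36)
})

test_that("distribution degree matches its closed-form limits", {
  expect_equal(distribution_degree(0:6, sc06), 1)
  expect_identical(distribution_degree(rep(4, 7), sc06), 0)
  # sorted [0,0,0,6,6,6,6]: sum dev = 14, sum ideal = 56
  expect_equal(distribution_degree(c(0, 6, 0, 6, 0, 6, 0), sc06), 0.75)
})

test_that("dynamic complexity is the product F * D", {
  w <- c(0, 6, 0, 6, 0, 6, 0)
  expect_equal(dynamic_complexity(w, sc06), 0.75)
  expect_identical(dynamic_complexity(rep(2, 7), sc06), 0)
  set.seed(3)
  for (i in 1:50) {
    w <- random_window(7, 0, 6)
    f <- fluctuation_intensity(w, sc06)
    d <- distribution_degree(w, sc06)
    expect_lte(dynamic_complexity(w, sc06), min(f, d) + 1e-15)
  }
})

test_that("F, D, C agree with independent brute-force oracles", {
  set.seed(42)
  for (i in 1:400) {
    m <- sample(5:9, 1)
    w <- if (i %% 2) random_window(m, 0, 6) else random_window(m, 1, 7, FALSE)
    lo <- if (i %% 2) 0 else 1
    hi <- if (i %% 2) 6 else 7
    sc <- rating_scale(lo, hi)
    expect_equal(fluctuation_intensity(w, sc), oracle_F(w, lo, hi),
                 tolerance = 1e-12)
    expect_equal(distribution_degree(w, sc), oracle_D(w, lo, hi),
                 tolerance = 1e-12)
  }
})

test_that("F, D, C stay in [0, 1] on random windows", {
  set.seed(7)
  for (i in 1:300) {
    m <- sample(3:12, 1)
    w <- random_window(m, 1, 7, integer_grid = i %% 2 == 0)
    sc <- rating_scale(1, 7)
    f <- fluctuation_intensity(w, sc)
    d <- distribution_degree(w, sc)
    expect_gte(f, 0); expect_lte(f, 1)
    expect_gte(d, 0); expect_lte(d, 1)
    expect_gte(f * d, 0); expect_lte(f * d, 1)
  }
})

test_that("measures are invariant under joint affine rescaling", {
  set.seed(9)
  for (i in 1:50) {
    w <- random_window(7, 1, 7)
    # 1-7 Likert mapped to 0-100 visual analogue
    w2 <- (w - 1) / 6 * 100
    expect_equal(fluctuation_intensity(w, rating_scale(1, 7)),
                 fluctuation_intensity(w2, rating_scale(0, 100)),
                 tolerance = 1e-12)
    expect_equal(distribution_degree(w, rating_scale(1, 7)),
                 distribution_degree(w2, rating_scale(0, 100)),
                 tolerance = 1e-12)
  }
})

test_that("D is permutation-invariant but F is not", {
  set.seed(13)
  w <- c(1, 5, 2, 7, 3, 6, 1)
  shuffled <- c(1, 1, 2, 3, 5, 6, 7)  # sorted: one monotone run
  sc <- rating_scale(1, 7)
  expect_equal(distribution_degree(w, sc), distribution_degree(shuffled, sc))
  expect_false(isTRUE(all.equal(fluctuation_intensity(w, sc),
                                fluctuation_intensity(shuffled, sc))))
})

test_that("F and C are invariant under time reversal (plateau-free windows)", {
  # plateaus anchor turning points on their *last* value (the convention
  # that keeps F continuous in the data), which is direction-dependent;
  # exact reversal symmetry therefore holds for windows without ties
  # between consecutive values
  set.seed(17)
  for (i in 1:50) {
    w <- random_window(7, 0, 6, integer_grid = FALSE)
    expect_equal(fluctuation_intensity(w, sc06),
                 fluctuation_intensity(rev(w), sc06), tolerance = 1e-12)
    expect_equal(dynamic_complexity(w, sc06),
                 dynamic_complexity(rev(w), sc06), tolerance = 1e-12)
  }
})

test_that("C is zero exactly for constant windows", {
  set.seed(19)
  for (i in 1:100) {
    w <- random_window(7, 0, 6)
    c_val <- dynamic_complexity(w, sc06)
    if (length(unique(w)) == 1) expect_identical(c_val, 0)
    else expect_gt(c_val, 0)
  }
})

test_that("missing values propagate and bad windows error", {
  expect_true(is.na(fluctuation_intensity(c(1, NA, 3, 4, 5, 6, 7),
                                          rating_scale(1, 7))))
  expect_error(fluctuation_intensity(3, sc06), "at least 2")
  expect_error(fluctuation_intensity(c(0, 9, 0, 0, 0, 0, 0), sc06),
               "outside the declared scale")
})

test_that("moving-window series stamps right-aligned windows on the last day", {
  sc <- rating_scale(1, 7)
  x <- c(2, 5, 1, 6, 3, 7, 2, 4)
  s <- rating_series("s", matrix(x, ncol = 1, dimnames = list(NULL, "a")), sc)
  cm <- complexity_series(s, window_width = 7)
  expect_equal(cm$window_width, 7)
  expect_true(all(is.na(cm$values[1:6, 1])))
  expect_equal(unname(cm$values[7, 1]), dynamic_complexity(x[1:7], sc))
  expect_equal(unname(cm$values[8, 1]), dynamic_complexity(x[2:8], sc))

  const <- rating_series("c", matrix(rep(4, 10), ncol = 1), sc)
  ccm <- complexity_series(const)
  expect_equal(unname(ccm$mean_curve[7:10]), rep(0, 4))

  expect_error(complexity_series(
    rating_series("x", matrix(1:5, ncol = 1), rating_scale(1, 7))),
    "days but the window")
})

test_that("windows containing missing data yield missing complexity", {
  sc <- rating_scale(1, 7)
  x <- c(2, 5, 1, NA, 3, 7, 2, 4, 5, 1, 2, 3, 4, 5)
  s <- rating_series("s", matrix(x, ncol = 1, dimnames = list(NULL, "a")), sc)
  cm <- complexity_series(s)
  expect_true(all(is.na(cm$values[1:10, 1])))  # windows touching day 4
  expect_false(anyNA(cm$values[11:14, 1]))
})

test_that("mean complexity averages non-missing items per day", {
  fake <- structure(
    list(subject_id = "s", window_width = 7, items = c("a", "b"),
         day_index = 1:3,
         values = matrix(c(0.2, NA, NA, 0.4, 0.6, NA), ncol = 2,
                         dimnames = list(NULL, c("a", "b")))),
    class = "complexity_matrix")
  mc <- mean_complexity(fake)
  expect_equal(unname(mc), c(0.3, 0.6, NA_real_))
})

test_that("5-item matrix mean matches hand-computed column means", {
  set.seed(23)
  vals <- matrix(runif(5 * 4), nrow = 4,
                 dimnames = list(NULL, paste0("i", 1:5)))
  fake <- structure(
    list(subject_id = "s", window_width = 7, items = colnames(vals),
         day_index = 1:4, values = vals),
    class = "complexity_matrix")
  expect_equal(unname(mean_complexity(fake)), unname(rowMeans(vals)))
  # single item: identity
  one <- structure(
    list(subject_id = "s", window_width = 7, items = "i1",
         day_index = 1:4, values = vals[, 1, drop = FALSE]),
    class = "complexity_matrix")
  expect_equal(unname(mean_complexity(one)), unname(vals[, 1]))
})
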