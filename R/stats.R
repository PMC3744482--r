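#' @title Statistical test results
#' @description Light container for the test statistics reported by the
#'   interval contrasts: estimate, statistic, degrees of freedom (possibly
#'   fractional, possibly length 2 for an F test), two-sided p-value and an
#'   optional point-biserial effect size. All tests in this package are
#'   two-sided.
#' @name stat_result
NULL

stat_result <- function(method, estimate, statistic, df, p,
                        effect_size = NULL, note = NULL) {
  structure(
    list(method = method, estimate = estimate, statistic = statistic,
         df = df, p = p, effect_size = effect_size, note = note),
    class = "stat_result"
  )
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("<stat_result> %s\n", x$method))
  cat(sprintf("  estimate = %.6g, statistic = %.4g, df = %s, p = %.4g\n",
              x$estimate, x$statistic,
              paste(signif(x$df, 4), collapse = ", "), x$p))
  if (!is.null(x$effect_size)) cat(sprintf("  effect size r = %.3f\n", x$effect_size))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Paired t-test
#'
#' Two-sided t-test on the mean of matched differences; `df = n - 1`, so 9
#' matched patients give `df = 8`. Used for within-patient comparisons such
#' as OT vs NOT interval changes.
#'
#' @param x,y Matched numeric vectors of equal length `n >= 2`.
#' @return A [stat_result]. When the differences have zero variance the
#'   p-value is 1 (all differences zero) or flagged at the machine floor
#'   (constant nonzero difference).
#' @export
paired_t_test <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  d <- x - y
  n <- length(d)
  if (sd(d) == 0) {
    if (all(d == 0)) {
      return(stat_result("paired t-test", 0, 0, n - 1, 1,
                         note = "all differences zero"))
    }
    return(stat_result("paired t-test", mean(d), sign(mean(d)) * Inf, n - 1,
                       .Machine$double.xmin,
                       note = "zero variance of differences; p at machine floor"))
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  stat_result("paired t-test", unname(tt$estimate), unname(tt$statistic),
              unname(tt$parameter), tt$p.value)
}

#' Welch two-sample t-test
#'
#' Unequal-variance t-test with Welch--Satterthwaite (fractional) degrees
#' of freedom. Used for patient vs control contrasts (e.g. OT vs ISI).
#'
#' @param x,y Numeric vectors with at least 2 values each.
#' @return A [stat_result] with `estimate = mean(x) - mean(y)`.
#' @export
welch_t_test <- function(x, y) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  if (sd(x) == 0 && sd(y) == 0) {
    stop("both groups have zero variance; Welch test undefined", call. = FALSE)
  }
  tt <- stats::t.test(x, y, var.equal = FALSE)
  stat_result("Welch t-test", mean(x) - mean(y), unname(tt$statistic),
              unname(tt$parameter), tt$p.value)
}

# Exact null distribution of the signed-rank statistic for (possibly tied)
# absolute ranks, on the doubled-rank integer lattice. Returns the
# probability vector over 2*V = 0..sum(w).
signed_rank_null <- function(w) {
  S <- sum(w)
  g <- numeric(S + 1)
  g[1] <- 1
  for (wi in w) {
    shifted <- c(numeric(wi), g[seq_len(S + 1 - wi)])
    g <- g + shifted
  }
  g / sum(g)
}

#' Wilcoxon signed-rank test (paired)
#'
#' Two-sided signed-rank test on matched differences, used to validate the
#' paired t-tests without normality assumptions. Zero differences are
#' dropped (Wilcoxon's original rule). The exact null distribution is used
#' for `n <= 25` retained pairs -- including tied ranks, via a
#' dynamic-programming enumeration on the doubled-rank lattice -- and a
#' tie-corrected normal approximation with continuity correction otherwise.
#'
#' @param x,y Matched numeric vectors.
#' @return A [stat_result]; `statistic` is the positive-rank sum `V`, and
#'   `method` records whether the p-value is exact.
#' @export
wilcoxon_paired <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  d <- x - y
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(stat_result("Wilcoxon signed rank (exact)", 0, 0, NA_real_, 1,
                       note = "all differences zero"))
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  note <- if (n_zero > 0) sprintf("%d zero difference(s) dropped", n_zero) else NULL
  if (n <= 25) {
    w <- as.integer(round(2 * r))
    dist <- signed_rank_null(w)
    v2 <- as.integer(round(2 * v))
    p_le <- sum(dist[seq_len(v2 + 1)])
    p_ge <- sum(dist[(v2 + 1):length(dist)])
    p <- min(1, 2 * min(p_le, p_ge))
    return(stat_result("Wilcoxon signed rank (exact)", median(d), v,
                       NA_real_, p, note = note))
  }
  mu <- n * (n + 1) / 4
  tie_tab <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
    sum(tie_tab^3 - tie_tab) / 48
  z <- (v - mu - sign(v - mu) * 0.5) / sqrt(sigma2)
  p <- min(1, 2 * pnorm(-abs(z)))
  stat_result("Wilcoxon signed rank (normal approximation)", median(d), v,
              NA_real_, p, note = note)
}

# Exact null distribution of the rank-sum of the first sample: number of
# ways to pick n1 of the doubled pooled ranks w with a given sum.
rank_sum_null <- function(w, n1) {
  S <- sum(w)
  f <- matrix(0, nrow = n1 + 1, ncol = S + 1)
  f[1, 1] <- 1
  for (wi in w) {
    for (k in n1:1) {
      cols <- (wi + 1):(S + 1)
      f[k + 1, cols] <- f[k + 1, cols] + f[k, cols - wi]
    }
  }
  f[n1 + 1, ] / sum(f[n1 + 1, ])
}

#' Wilcoxon rank-sum test (unpaired)
#'
#' Two-sided rank-sum (Mann-Whitney) test for two independent samples. The
#' exact null distribution is enumerated (ties handled on the doubled-rank
#' lattice) when `min(n1, n2) <= 15` and the pooled size is at most 40;
#' otherwise a tie-corrected normal approximation with continuity
#' correction is used.
#'
#' @param x,y Independent numeric samples with at least 2 values each.
#' @return A [stat_result]; `statistic` is the rank sum `W` of `x`.
#' @export
wilcoxon_ranksum <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  stopifnot(n1 >= 2, n2 >= 2)
  r <- rank(c(x, y))
  w_stat <- sum(r[seq_len(n1)])
  N <- n1 + n2
  if (min(n1, n2) <= 15 && N <= 40) {
    w <- as.integer(round(2 * r))
    dist <- rank_sum_null(w, n1)
    w2 <- as.integer(round(2 * w_stat))
    p_le <- sum(dist[seq_len(w2 + 1)])
    p_ge <- sum(dist[(w2 + 1):length(dist)])
    p <- min(1, 2 * min(p_le, p_ge))
    return(stat_result("Wilcoxon rank sum (exact)",
                       median(x) - median(y), w_stat, NA_real_, p))
  }
  mu <- n1 * (N + 1) / 2
  tie_tab <- table(r)
  sigma2 <- n1 * n2 / 12 *
    ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
  z <- (w_stat - mu - sign(w_stat - mu) * 0.5) / sqrt(sigma2)
  p <- min(1, 2 * pnorm(-abs(z)))
  stat_result("Wilcoxon rank sum (normal approximation)",
              median(x) - median(y), w_stat, NA_real_, p)
}

#' Point-biserial effect size
#'
#' Pearson correlation between pooled observations and a 0/1 coding of a
#' dichotomy (the *first* factor level is coded 1, so `r > 0` means higher
#' values in the first level). Interpreted with the conventional bands:
#' small up to .20, medium .21--.35, large above .35.
#'
#' @param values Pooled numeric observations.
#' @param labels Dichotomous grouping (factor or coercible); both levels
#'   must be present.
#' @return Numeric `r` of class `point_biserial` with attributes `band`
#'   and `n`. `NA` (with a warning) when the values have zero variance.
#' @export
point_biserial <- function(values, labels) {
  labels <- factor(labels)
  if (nlevels(labels) != 2) {
    stop("`labels` must contain exactly two levels", call. = FALSE)
  }
  stopifnot(length(values) == length(labels))
  if (sd(values) == 0) {
    warning("values have zero variance; point-biserial r undefined",
            call. = FALSE)
    r <- NA_real_
  } else {
    r <- cor(values, as.numeric(labels == levels(labels)[1]))
  }
  structure(r, band = effect_band(r), n = length(values),
            levels = levels(labels), class = "point_biserial")
}

#' Effect-size interpretation band
#' @param r Correlation-scale effect size.
#' @return `"small"` (|r| <= .20), `"medium"` (<= .35) or `"large"`.
#' @export
effect_band <- function(r) {
  if (is.na(r)) return(NA_character_)
  a <- abs(r)
  if (a <= 0.20) "small" else if (a <= 0.35) "medium" else "large"
}

#' @export
print.point_biserial <- function(x, ...) {
  cat(sprintf("point-biserial r = %.3f (%s effect, n = %d)\n",
              as.numeric(x), attr(x, "band"), attr(x, "n")))
  invisible(x)
}

#' Group x transition-type interaction ANOVA
#'
#' Two-factorial ANOVA with factors group (patients vs controls) and type
#' of transition, reporting the interaction term with Type-III sums of
#' squares under sum-to-zero coding (robust to the unbalanced designs that
#' arise from unequal interval counts).
#'
#' @param values Numeric response (e.g. per-interval activation changes).
#' @param group Factor-like, two levels (patients/controls).
#' @param type Factor-like transition type (e.g. OT vs NOT/ISI).
#' @return A [stat_result] for the interaction: `statistic` is F, `df` is
#'   `c(df_interaction, df_residual)`.
#' @export
two_way_anova_interaction <- function(values, group, type) {
  d <- data.frame(y = as.numeric(values), g = factor(group), ty = factor(type))
  tab <- table(d$g, d$ty)
  if (any(tab == 0)) {
    empty <- which(tab == 0, arr.ind = TRUE)[1, ]
    stop(sprintf("design cell is empty: group '%s' x type '%s'",
                 rownames(tab)[empty[1]], colnames(tab)[empty[2]]),
         call. = FALSE)
  }
  fit <- stats::lm(y ~ g * ty, data = d,
                   contrasts = list(g = "contr.sum", ty = "contr.sum"))
  a3 <- car::Anova(fit, type = 3)
  row <- a3["g:ty", ]
  df_res <- a3["Residuals", "Df"]
  stat_result("two-way ANOVA interaction (Type III)",
              estimate = row[["Sum Sq"]],
              statistic = row[["F value"]],
              df = c(row[["Df"]], df_res),
              p = row[["Pr(>F)"]])
}

#' BCa bootstrap confidence interval
#'
#' Bias-corrected and accelerated nonparametric bootstrap interval for a
#' scalar statistic (jackknife acceleration), the standard choice for small
#' samples with skewed statistics. Defaults follow common practice: 10,000
#' resamples and a 95% level.
#'
#' @param x Numeric sample, `n >= 2`.
#' @param statistic Function of a numeric vector returning a scalar
#'   (default `mean`).
#' @param B Number of bootstrap resamples (default 10000, minimum 1000).
#' @param level Confidence level (default 0.95).
#' @param seed Optional integer seed for reproducibility.
#' @return List of class `bca_ci` with `lower`, `upper`, `estimate`,
#'   `level`, `B` and a `degenerate` flag; a constant sample collapses to
#'   a point interval.
#' @export
bca_ci <- function(x, statistic = mean, B = 10000, level = 0.95, seed = NULL) {
  stopifnot(length(x) >= 2, B >= 1000, level > 0, level < 1)
  if (!is.null(seed)) set.seed(seed)
  est <- statistic(x)
  degenerate_out <- function() {
    structure(list(lower = est, upper = est, estimate = est, level = level,
                   B = B, degenerate = TRUE), class = "bca_ci")
  }
  if (length(unique(x)) == 1) return(degenerate_out())
  bt <- boot::boot(x, function(d, i) statistic(d[i]), R = B)
  if (var(bt$t[, 1]) == 0) return(degenerate_out())
  ci <- boot::boot.ci(bt, conf = level, type = "bca")
  structure(list(lower = ci$bca[4], upper = ci$bca[5], estimate = est,
                 level = level, B = B, degenerate = FALSE),
            class = "bca_ci")
}

#' @export
print.bca_ci <- function(x, ...) {
  cat(sprintf("BCa %.0f%% CI: [%.6g, %.6g] (estimate %.6g, B = %d)%s\n",
              100 * x$level, x$lower, x$upper, x$estimate, x$B,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}
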