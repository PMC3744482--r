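# Independent brute-force oracles, deliberately implemented along different
# paths than the package functions.

# Fluctuation intensity via plateau compression: collapse runs of equal
# values (keeping the last original index), locate direction reversals on
# the compressed sequence, and sum amplitude/duration between consecutive
# turning points.
oracle_F <- function(x, lo, hi) {
  m <- length(x)
  r <- rle(x)
  if (length(r$values) < 2) return(0)
  last_idx <- cumsum(r$lengths)
  v <- r$values
  s <- sign(diff(v))
  turns <- 1L
  if (length(s) > 1) {
    for (i in seq_len(length(s) - 1)) {
      if (s[i] != s[i + 1]) turns <- c(turns, i + 1L)
    }
  }
  turns <- c(turns, length(v))
  pts <- last_idx[turns]
  pts[1] <- 1L
  total <- 0
  for (k in seq_len(length(pts) - 1)) {
    total <- total + abs(x[pts[k + 1]] - x[pts[k]]) / (pts[k + 1] - pts[k])
  }
  total / ((hi - lo) * (m - 1))
}

# Distribution degree via the literal double loop over every span of the
# sorted values.
oracle_D <- function(x, lo, hi) {
  m <- length(x)
  y <- sort(x)
  R <- hi - lo
  dev <- 0
  tot <- 0
  for (c in 1:(m - 1)) {
    for (a in 1:(m - c)) {
      ideal <- c * R / (m - 1)
      dev <- dev + max(0, ideal - (y[a + c] - y[a]))
      tot <- tot + ideal
    }
  }
  1 - dev / tot
}

# Full enumeration of the signed-rank null (2^n sign patterns).
enum_signed_p <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- as.vector(signs %*% r)
  p_le <- mean(vs <= v_obs + 1e-9)
  p_ge <- mean(vs >= v_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# Full enumeration of the rank-sum null (all subsets of size n1).
enum_ranksum_p <- function(x, y) {
  n1 <- length(x)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)])
  cmb <- utils::combn(length(r), n1)
  ws <- colSums(matrix(r[cmb], nrow = n1))
  p_le <- mean(ws <= w_obs + 1e-9)
  p_ge <- mean(ws >= w_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# Textbook closed forms for the t tests.
manual_paired_t <- function(x, y) {
  d <- x - y
  n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  list(t = t, df = n - 1, p = 2 * stats::pt(-abs(t), n - 1))
}

manual_welch_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  vx <- var(x); vy <- var(y)
  se2 <- vx / n1 + vy / n2
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / n1)^2 / (n1 - 1) + (vy / n2)^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# Random bounded window on an integer grid or continuous scale.
random_window <- function(m, lo, hi, integer_grid = TRUE) {
  if (integer_grid) sample(lo:hi, m, replace = TRUE)
  else runif(m, lo, hi)
}

# Small deterministic cohort fixture: a change table with exact per-label
# means, one row per subject x interval x ROI.
constant_change_table <- function(ot = 7479, not = 1904, isi = 697,
                                  ot_w = 26.48, not_w = 8.34, isi_w = 2.45,
                                  n_patients = 9, n_controls = 9,
                                  rois = ocd_rois) {
  rows <- list()
  for (i in seq_len(n_patients)) {
    for (roi in rois) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        subject = sprintf("p%02d", i), group = "patient",
        interval = 1:2, label = c("OT", "NOT"), roi = roi,
        diff_voxels = c(ot, not), diff_weighted = c(ot_w, not_w))
    }
  }
  for (i in seq_len(n_controls)) {
    for (roi in rois) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        subject = sprintf("c%02d", i), group = "control",
        interval = 1:2, label = "ISI", roi = roi,
        diff_voxels = isi, diff_weighted = isi_w)
    }
  }
  dplyr::bind_rows(rows)
}
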