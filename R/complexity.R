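#' Fluctuation intensity of a window
#'
#' Measures the amplitude and frequency of direction changes in a short
#' signal, normalised by the theoretical scale range. The window is split
#' into maximal monotone runs delimited by strict direction reversals;
#' plateaus (equal consecutive values) extend the current run, and a run's
#' turning point sits on the last extremal value before the reversal. With
#' run amplitudes `a_k` and durations `d_k` (in steps),
#' `F = sum(a_k / d_k) / (R * (m - 1))` for window length `m` and scale
#' range `R`. `F` is 0 for a constant window and 1 for a full-range
#' alternation every step.
#'
#' @param window Numeric vector of length `m >= 2` (one moving window of the
#'   daily series). Any `NA` propagates to an `NA` result.
#' @param scale The item's [rating_scale()].
#' @return Fluctuation intensity in `[0, 1]` (or `NA`).
#' @examples
#' fluctuation_intensity(c(0, 6, 0, 6, 0, 6, 0), rating_scale(0, 6)) # 1
#' @export
fluctuation_intensity <- function(window, scale) {
  stopifnot(is_rating_scale(scale))
  m <- length(window)
  if (m < 2) stop("window must contain at least 2 values", call. = FALSE)
  if (anyNA(window)) return(NA_real_)
  check_window_in_scale(window, scale)
  s <- sign(diff(window))
  total <- 0
  run_dir <- 0L
  run_start <- 1L
  for (t in seq_along(s)) {
    if (s[t] == 0) next
    if (run_dir == 0L) {
      run_dir <- s[t]
    } else if (s[t] != run_dir) {
      # reversal: the run ends on the last extremal value, index t
      total <- total + abs(window[t] - window[run_start]) / (t - run_start)
      run_start <- t
      run_dir <- s[t]
    }
  }
  if (run_dir != 0L) {
    total <- total + abs(window[m] - window[run_start]) / (m - run_start)
  }
  total / (scale$range * (m - 1))
}

#' Distribution degree of a window
#'
#' Measures how evenly the window's values cover the theoretical scale
#' range. The values are sorted ascending; for every span of `c` order
#' statistics the ideal width under perfectly even full-range coverage is
#' `I_c = c * R / (m - 1)`, and under-dispersion is penalised by
#' `max(0, I_c - actual width)`. `D = 1 - sum(dev) / sum(I)`, so `D = 1`
#' for a perfectly even full-range spread and `D = 0` when all values
#' coincide.
#'
#' @inheritParams fluctuation_intensity
#' @param spans `"all"` (default) accumulates deviations over every pair of
#'   order statistics; `"adjacent"` uses only neighbouring order statistics.
#' @return Distribution degree in `[0, 1]` (or `NA`).
#' @examples
#' distribution_degree(0:6, rating_scale(0, 6)) # 1
#' @export
distribution_degree <- function(window, scale, spans = c("all", "adjacent")) {
  stopifnot(is_rating_scale(scale))
  spans <- match.arg(spans)
  m <- length(window)
  if (m < 2) stop("window must contain at least 2 values", call. = FALSE)
  if (anyNA(window)) return(NA_real_)
  check_window_in_scale(window, scale)
  y <- sort(window)
  r_ideal <- scale$range / (m - 1)
  cs <- if (spans == "all") seq_len(m - 1) else 1L
  dev_sum <- 0
  ideal_sum <- 0
  for (c in cs) {
    i_c <- c * r_ideal
    widths <- y[(1 + c):m] - y[seq_len(m - c)]
    dev_sum <- dev_sum + sum(pmax(0, i_c - widths))
    ideal_sum <- ideal_sum + (m - c) * i_c
  }
  1 - dev_sum / ideal_sum
}

#' Dynamic complexity of a window
#'
#' The composite instability measure: the product of fluctuation intensity
#' and distribution degree, `C = F * D`. High values flag phases where the
#' signal both changes direction strongly and roams widely over its
#' theoretical range -- the signature of critical fluctuations preceding an
#' order transition. `C = 0` exactly when the window is constant.
#'
#' @inheritParams distribution_degree
#' @return Dynamic complexity in `[0, 1]` (or `NA`).
#' @export
dynamic_complexity <- function(window, scale, spans = c("all", "adjacent")) {
  fluctuation_intensity(window, scale) *
    distribution_degree(window, scale, spans = spans)
}

check_window_in_scale <- function(window, scale) {
  if (any(window < scale$min_value | window > scale$max_value)) {
    stop("window contains values outside the declared scale", call. = FALSE)
  }
  invisible(TRUE)
}

#' Moving-window complexity of a rating series
#'
#' Slides a window of `window_width` days (default 7) over each item's
#' series and stamps the dynamic complexity of each window on the window's
#' *last* day (right alignment), so a complexity peak is attributable to
#' fluctuations that have already happened. The first `window_width - 1`
#' days, and any window containing a missing value, yield missing
#' complexity.
#'
#' @param series A [rating_series()] with at least `window_width` days.
#' @param window_width Moving window length in days (default 7).
#' @param spans Distribution-degree variant, see [distribution_degree()].
#' @return An object of class `complexity_matrix`: fields `subject_id`,
#'   `window_width`, `items`, `day_index`, `values` (day x item matrix of
#'   `C`) and `mean_curve` (item-averaged complexity per day).
#' @export
complexity_series <- function(series, window_width = 7,
                              spans = c("all", "adjacent")) {
  stopifnot(inherits(series, "rating_series"))
  spans <- match.arg(spans)
  m <- as.integer(window_width)
  if (m < 2) stop("`window_width` must be at least 2", call. = FALSE)
  n <- nrow(series$values)
  if (n < m) {
    stop(sprintf("series has %d days but the window needs %d", n, m),
         call. = FALSE)
  }
  out <- matrix(NA_real_, nrow = n, ncol = length(series$items),
                dimnames = list(NULL, series$items))
  for (j in seq_along(series$items)) {
    x <- series$values[, j]
    sc <- series$scales[[j]]
    for (t in m:n) {
      w <- x[(t - m + 1):t]
      if (!anyNA(w)) {
        out[t, j] <- fluctuation_intensity(w, sc) *
          distribution_degree(w, sc, spans = spans)
      }
    }
  }
  res <- structure(
    list(subject_id = series$subject_id, window_width = m,
         items = series$items, day_index = series$day_index,
         values = out, mean_curve = NULL),
    class = "complexity_matrix"
  )
  res$mean_curve <- mean_complexity(res)
  res
}

#' @export
print.complexity_matrix <- function(x, ...) {
  cat(sprintf(
    "<complexity_matrix> subject %s: %d days x %d items (window %d)\n",
    x$subject_id, nrow(x$values), length(x$items), x$window_width))
  invisible(x)
}

#' Item-averaged complexity curve
#'
#' Unweighted arithmetic mean of the per-item complexity values on each
#' day, skipping missing items; a day where every item is missing stays
#' missing. Unweighted averaging is appropriate because complexity is
#' already range-normalised per item, making Likert and visual-analogue
#' items commensurable.
#'
#' @param matrix A `complexity_matrix` from [complexity_series()].
#' @return Numeric vector of per-day mean complexity, named by day index.
#' @export
mean_complexity <- function(matrix) {
  stopifnot(inherits(matrix, "complexity_matrix"))
  v <- matrix$values
  curve <- rowMeans(v, na.rm = TRUE)
  curve[!is.finite(curve)] <- NA_real_
  names(curve) <- matrix$day_index
  curve
}

#' Long-format view of a complexity matrix
#'
#' @param matrix A `complexity_matrix`.
#' @return Tibble with columns `subject`, `day`, `item`, `C`.
#' @export
complexity_long <- function(matrix) {
  stopifnot(inherits(matrix, "complexity_matrix"))
  tibble::tibble(
    subject = matrix$subject_id,
    day = rep(matrix$day_index, times = length(matrix$items)),
    item = rep(matrix$items, each = length(matrix$day_index)),
    C = as.vector(matrix$values)
  )
}
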