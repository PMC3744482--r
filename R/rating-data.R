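#' Theoretical rating scale
#'
#' Declares the theoretical range of a rating instrument item (e.g. a
#' seven-point Likert item has `min_value = 1`, `max_value = 7`; a visual
#' analogue item might span 0--100). The range `max_value - min_value` is the
#' normaliser used by the fluctuation and distribution measures, so it must
#' be the *theoretical* range of the instrument, not the observed range of
#' the data.
#'
#' @param min_value Theoretical minimum of the scale.
#' @param max_value Theoretical maximum of the scale; must exceed `min_value`.
#' @return An object of class `rating_scale` with fields `min_value`,
#'   `max_value` and `range`.
#' @examples
#' likert7 <- rating_scale(1, 7)
#' likert7$range
#' @export
rating_scale <- function(min_value, max_value) {
  stopifnot(is.numeric(min_value), length(min_value) == 1,
            is.numeric(max_value), length(max_value) == 1)
  if (!is.finite(min_value) || !is.finite(max_value) || max_value <= min_value) {
    stop("`max_value` must be finite and strictly greater than `min_value`",
         call. = FALSE)
  }
  structure(
    list(min_value = min_value, max_value = max_value,
         range = max_value - min_value),
    class = "rating_scale"
  )
}

#' @export
print.rating_scale <- function(x, ...) {
  cat(sprintf("<rating_scale> [%g, %g] (range %g)\n",
              x$min_value, x$max_value, x$range))
  invisible(x)
}

is_rating_scale <- function(x) inherits(x, "rating_scale")

# Normalise a scales argument into a named list of rating_scale objects
# covering every item in `items`. Accepts a single scale (recycled), a named
# list, or a path to a YAML/JSON sidecar with entries item: {min, max}.
resolve_scales <- function(scales, items) {
  if (is.character(scales) && length(scales) == 1 && file.exists(scales)) {
    raw <- if (grepl("\\.json$", scales, ignore.case = TRUE)) {
      jsonlite::read_json(scales, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(scales)
    }
    scales <- lapply(raw, function(s) rating_scale(s$min, s$max))
  }
  if (is_rating_scale(scales)) {
    scales <- stats::setNames(rep(list(scales), length(items)), items)
  }
  if (!is.list(scales) || is.null(names(scales))) {
    stop("`scales` must be a rating_scale, a named list of them, ",
         "or a path to a YAML/JSON sidecar", call. = FALSE)
  }
  missing_items <- setdiff(items, names(scales))
  if (length(missing_items)) {
    stop("no scale declared for item(s): ",
         paste(missing_items, collapse = ", "), call. = FALSE)
  }
  stopifnot(all(vapply(scales, is_rating_scale, logical(1))))
  scales[items]
}

#' One subject's daily rating series
#'
#' Container for a day-by-item grid of bounded ratings. Days are stored on a
#' consecutive 1-step grid (gaps become missing rows), because the moving
#' window analysis assumes equally spaced daily observations.
#'
#' @param subject_id Subject identifier (scalar).
#' @param values Numeric matrix or data frame, days in rows, items in
#'   columns (column names are the item ids). `NA` marks a missing rating.
#' @param scales A single [rating_scale()] applied to all items, or a named
#'   list with one scale per item.
#' @param day_index Optional integer vector of day numbers for the rows of
#'   `values` (strictly increasing). Defaults to `1:nrow(values)`. Non
#'   consecutive indices are expanded to a consecutive grid with missing
#'   rows in between.
#' @return An object of class `rating_series` with fields `subject_id`,
#'   `items`, `scales`, `values` (matrix) and `day_index`.
#' @export
rating_series <- function(subject_id, values, scales, day_index = NULL) {
  stopifnot(length(subject_id) == 1)
  values <- as.matrix(values)
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("item", seq_len(ncol(values)))
  }
  storage.mode(values) <- "double"
  if (nrow(values) < 1) stop("a rating series needs at least one day", call. = FALSE)
  items <- colnames(values)
  scales <- resolve_scales(scales, items)

  if (is.null(day_index)) day_index <- seq_len(nrow(values))
  day_index <- as.integer(day_index)
  if (length(day_index) != nrow(values) || anyDuplicated(day_index) ||
      is.unsorted(day_index, strictly = TRUE)) {
    stop("`day_index` must be strictly increasing with one entry per row",
         call. = FALSE)
  }
  # expand to a consecutive daily grid
  full <- seq(day_index[1], day_index[length(day_index)])
  if (length(full) != length(day_index)) {
    grid <- matrix(NA_real_, nrow = length(full), ncol = ncol(values),
                   dimnames = list(NULL, items))
    grid[match(day_index, full), ] <- values
    values <- grid
    day_index <- full
  }

  for (it in items) {
    sc <- scales[[it]]
    v <- values[, it]
    bad <- which(!is.na(v) & (v < sc$min_value | v > sc$max_value))
    if (length(bad)) {
      stop(sprintf(
        "value out of declared scale [%g, %g]: subject %s, day %d, item %s (value %g)",
        sc$min_value, sc$max_value, subject_id, day_index[bad[1]], it, v[bad[1]]),
        call. = FALSE)
    }
  }

  structure(
    list(subject_id = as.character(subject_id), items = items,
         scales = scales, values = values, day_index = day_index),
    class = "rating_series"
  )
}

#' @export
print.rating_series <- function(x, ...) {
  cat(sprintf("<rating_series> subject %s: %d days x %d items\n",
              x$subject_id, nrow(x$values), length(x$items)))
  invisible(x)
}

#' Number of observation days of a rating series
#' @param series A [rating_series()].
#' @return Integer number of days on the grid.
#' @export
n_days <- function(series) {
  stopifnot(inherits(series, "rating_series"))
  nrow(series$values)
}

#' Scan schedule for one subject
#'
#' Ordered fMRI scan days for a patient or untreated control. Patients are
#' scanned 2--4 times over the observation period; the analysis works on the
#' intervals between consecutive scans.
#'
#' @param subject_id Subject identifier.
#' @param scan_days Strictly increasing integer vector of 2--4 day indices.
#' @param group `"patient"` or `"control"`.
#' @param n_days Optional length of the subject's observation window; when
#'   given, patient scan days must fall inside `[1, n_days]`.
#' @return Object of class `scan_schedule`.
#' @export
scan_schedule <- function(subject_id, scan_days, group = c("patient", "control"),
                          n_days = NULL) {
  group <- match.arg(group)
  scan_days <- as.integer(scan_days)
  if (length(scan_days) < 2 || length(scan_days) > 4) {
    stop("a schedule needs between 2 and 4 scans", call. = FALSE)
  }
  if (is.unsorted(scan_days, strictly = TRUE)) {
    stop("`scan_days` must be strictly increasing", call. = FALSE)
  }
  if (!is.null(n_days) && group == "patient" &&
      (scan_days[1] < 1 || scan_days[length(scan_days)] > n_days)) {
    stop("patient scan days must lie within the observation window", call. = FALSE)
  }
  structure(
    list(subject_id = as.character(subject_id), scan_days = scan_days,
         group = group),
    class = "scan_schedule"
  )
}

#' @export
print.scan_schedule <- function(x, ...) {
  cat(sprintf("<scan_schedule> subject %s (%s): scans on days %s\n",
              x$subject_id, x$group, paste(x$scan_days, collapse = ", ")))
  invisible(x)
}

#' Read daily process ratings from a long-format delimited file
#'
#' Expects one row per subject x day x item observation. Rows may appear in
#' any order; they are grouped by subject and day-sorted. Values outside an
#' item's declared theoretical scale are rejected.
#'
#' @param path Path to a delimited text file.
#' @param scales Scale declaration passed on to [rating_series()]: a single
#'   [rating_scale()], a named per-item list, or a YAML/JSON sidecar path.
#' @param delim Field delimiter (default `","`).
#' @param columns Named character vector mapping the roles `subject`, `day`,
#'   `item`, `value` to column names in the file.
#' @return Named list of [rating_series()], one per subject.
#' @export
load_ratings <- function(path, scales, delim = ",",
                         columns = c(subject = "subject", day = "day",
                                     item = "item", value = "value")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  needed <- c("subject", "day", "item", "value")
  stopifnot(all(needed %in% names(columns)))
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  if (nrow(raw) == 0) stop("empty ratings file: ", path, call. = FALSE)
  missing_cols <- setdiff(unname(columns[needed]), names(raw))
  if (length(missing_cols)) {
    stop("ratings file lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  dat <- tibble::tibble(
    subject = as.character(raw[[columns[["subject"]]]]),
    day = as.integer(raw[[columns[["day"]]]]),
    item = as.character(raw[[columns[["item"]]]]),
    value = as.numeric(raw[[columns[["value"]]]])
  )
  if (anyDuplicated(dat[c("subject", "day", "item")])) {
    stop("duplicated subject/day/item rows in ", path, call. = FALSE)
  }
  out <- lapply(split(dat, dat$subject), function(d) {
    wide <- tidyr::pivot_wider(d, id_cols = "day", names_from = "item",
                               values_from = "value")
    wide <- wide[order(wide$day), ]
    vals <- as.matrix(wide[setdiff(names(wide), "day")])
    rating_series(d$subject[1], vals, scales, day_index = wide$day)
  })
  out[order(names(out))]
}

#' Write rating series back to long format
#'
#' Inverse of [load_ratings()]: emits one row per observed (non-missing)
#' subject x day x item value, ordered by subject, day, item.
#'
#' @param series_list A [rating_series()] or list of them.
#' @param path Output CSV path.
#' @return The written tibble, invisibly.
#' @export
write_ratings <- function(series_list, path) {
  if (inherits(series_list, "rating_series")) series_list <- list(series_list)
  rows <- lapply(series_list, function(s) {
    long <- tibble::tibble(
      subject = s$subject_id,
      day = rep(s$day_index, times = length(s$items)),
      item = rep(s$items, each = length(s$day_index)),
      value = as.vector(s$values)
    )
    long[!is.na(long$value), ]
  })
  out <- dplyr::arrange(dplyr::bind_rows(rows), .data$subject, .data$day, .data$item)
  readr::write_csv(out, path)
  invisible(out)
}

#' Fill short gaps in a rating series
#'
#' Internal missing runs of length `<= max_gap` are filled by linear
#' interpolation between the flanking observed values; leading and trailing
#' missing days and longer runs are left missing and reported. Observed
#' values are never altered, and interpolated values cannot leave the item
#' scale (they are convex combinations of in-range values).
#'
#' @param series A [rating_series()].
#' @param max_gap Longest internal missing run to interpolate (days,
#'   default 1; 0 disables filling).
#' @return A `rating_series` with a `gap_report` attribute: a tibble of
#'   untreated gaps (`item`, `start_day`, `end_day`, `length`, `position`).
#' @export
prepare_series <- function(series, max_gap = 1) {
  stopifnot(inherits(series, "rating_series"), max_gap >= 0)
  vals <- series$values
  if (max_gap > 0) {
    for (j in seq_len(ncol(vals))) {
      if (sum(!is.na(vals[, j])) >= 2) {
        vals[, j] <- zoo::na.approx(vals[, j], maxgap = max_gap, na.rm = FALSE)
      }
    }
  }
  gaps <- list()
  for (j in seq_len(ncol(vals))) {
    r <- rle(is.na(vals[, j]))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in which(r$values)) {
      pos <- if (starts[k] == 1) "leading"
             else if (ends[k] == nrow(vals)) "trailing"
             else "internal"
      gaps[[length(gaps) + 1]] <- tibble::tibble(
        item = colnames(vals)[j],
        start_day = series$day_index[starts[k]],
        end_day = series$day_index[ends[k]],
        length = r$lengths[k],
        position = pos
      )
    }
  }
  report <- if (length(gaps)) dplyr::bind_rows(gaps) else
    tibble::tibble(item = character(), start_day = integer(),
                   end_day = integer(), length = integer(),
                   position = character())
  out <- series
  out$values <- vals
  attr(out, "gap_report") <- report
  out
}

#' Read scan schedules from CSV
#'
#' Expects columns `subject`, `group`, `scan_day` (one row per scan).
#'
#' @param path CSV path.
#' @return Named list of [scan_schedule()].
#' @export
load_scan_schedules <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(c("subject", "group", "scan_day"), names(raw))
  if (length(missing_cols)) {
    stop("scan file lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  out <- lapply(split(raw, as.character(raw$subject)), function(d) {
    scan_schedule(d$subject[1], sort(d$scan_day), group = d$group[1])
  })
  out[order(names(out))]
}

#' Flatten scan schedules to a tibble
#' @param schedules List of [scan_schedule()].
#' @return Tibble with columns `subject`, `group`, `scan`, `scan_day`.
#' @export
schedules_to_tibble <- function(schedules) {
  if (inherits(schedules, "scan_schedule")) schedules <- list(schedules)
  dplyr::bind_rows(lapply(schedules, function(s) {
    tibble::tibble(subject = s$subject_id, group = s$group,
                   scan = seq_along(s$scan_days), scan_day = s$scan_days)
  }))
}
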