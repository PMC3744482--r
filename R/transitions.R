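#' Detect order transitions on a mean complexity curve
#'
#' An order transition -- a discontinuous qualitative change of the
#' psychological pattern -- is operationalised as a maximum of the
#' item-averaged dynamic-complexity curve. The global maximum is always a
#' transition (ties break to the earliest day, since the earlier
#' instability is the meaningful event). Further local maxima qualify as
#' secondary transitions when they reach at least `secondary_fraction` of
#' the global peak and lie at least `min_separation` days from every
#' already-accepted transition; candidates are considered in decreasing
#' peak order.
#'
#' @param curve A `complexity_matrix` (its `mean_curve` is used) or a
#'   numeric per-day curve, optionally named by day index.
#' @param secondary_fraction Minimum height of a secondary peak relative to
#'   the global maximum (default 0.9).
#' @param min_separation Minimum distance in days between accepted
#'   transitions (default 14).
#' @param subject_id Subject identifier attached to the result (taken from
#'   the `complexity_matrix` when available).
#' @return A tibble of class `transition_set` with columns `day` and
#'   `peak`, ordered by day, and a `subject_id` attribute.
#' @export
detect_transitions <- function(curve, secondary_fraction = 0.9,
                               min_separation = 14, subject_id = NULL) {
  if (inherits(curve, "complexity_matrix")) {
    if (is.null(subject_id)) subject_id <- curve$subject_id
    days <- curve$day_index
    v <- unname(curve$mean_curve)
  } else {
    v <- as.numeric(curve)
    days <- if (!is.null(names(curve))) as.integer(names(curve)) else seq_along(v)
  }
  stopifnot(secondary_fraction > 0, secondary_fraction <= 1,
            min_separation >= 0)
  keep <- !is.na(v)
  if (!any(keep)) stop("complexity curve is entirely missing", call. = FALSE)
  v <- v[keep]
  days <- days[keep]
  n <- length(v)

  # local maxima among consecutive non-missing days; a plateau counts once,
  # at its earliest day
  is_cand <- rep(TRUE, n)
  if (n > 1) {
    is_cand <- (c(TRUE, v[-1] >= v[-n]) & c(v[-n] >= v[-1], TRUE))
    plateau <- c(FALSE, v[-1] == v[-n])
    is_cand <- is_cand & !plateau
  }
  cand_days <- days[is_cand]
  cand_peaks <- v[is_cand]

  global_peak <- max(v)
  g_idx <- which(cand_peaks == global_peak)[1]
  accepted_days <- cand_days[g_idx]
  accepted_peaks <- cand_peaks[g_idx]

  ord <- order(-cand_peaks, cand_days)
  for (i in ord) {
    d <- cand_days[i]
    if (d %in% accepted_days) next
    if (cand_peaks[i] < secondary_fraction * global_peak) next
    if (all(abs(d - accepted_days) >= min_separation)) {
      accepted_days <- c(accepted_days, d)
      accepted_peaks <- c(accepted_peaks, cand_peaks[i])
    }
  }

  o <- order(accepted_days)
  out <- tibble::tibble(day = as.integer(accepted_days[o]),
                        peak = accepted_peaks[o])
  class(out) <- c("transition_set", class(out))
  attr(out, "subject_id") <- subject_id
  out
}

#' Label inter-scan intervals by transition status
#'
#' Patients' intervals between consecutive scans are labelled `OT` when
#' they contain a detected order transition and `NOT` otherwise; every
#' interval of an untreated control is `ISI`. A transition on day `t` is
#' assigned to interval `k` when `scan_k < t <= scan_{k+1}` (half-open
#' convention); transitions before the first or after the last scan snap to
#' the nearest interval, mirroring scans performed shortly before or after
#' the transition point. Two transitions mapping to the same interval are
#' collapsed to one `OT` (earliest day kept) with a warning.
#'
#' @param schedule A [scan_schedule()].
#' @param transitions A `transition_set` from [detect_transitions()], a
#'   numeric vector of transition days, or `NULL`/empty for none. Ignored
#'   (with a warning if non-empty) for controls.
#' @return Tibble with columns `subject`, `group`, `interval`, `label`,
#'   `transition_day`.
#' @export
label_intervals <- function(schedule, transitions = NULL) {
  stopifnot(inherits(schedule, "scan_schedule"))
  s <- schedule$scan_days
  n_int <- length(s) - 1L
  out <- tibble::tibble(
    subject = schedule$subject_id,
    group = schedule$group,
    interval = seq_len(n_int),
    label = if (schedule$group == "control") "ISI" else "NOT",
    transition_day = NA_integer_
  )
  t_days <- if (inherits(transitions, "transition_set")) transitions$day
            else as.integer(transitions)
  if (schedule$group == "control") {
    if (length(t_days)) {
      warning("transitions supplied for a control subject are ignored",
              call. = FALSE)
    }
    return(out)
  }
  for (t in sort(t_days)) {
    k <- findInterval(t, s, left.open = TRUE)
    k <- min(max(k, 1L), n_int)  # snap out-of-range transitions
    if (out$label[k] == "OT") {
      warning(sprintf(
        "subject %s: several transitions fall in interval %d; collapsed to one",
        schedule$subject_id, k), call. = FALSE)
      next
    }
    out$label[k] <- "OT"
    out$transition_day[k] <- t
  }
  out
}

#' Label a whole cohort
#'
#' Applies [label_intervals()] to each schedule, pairing patients with
#' their transition sets by subject id.
#'
#' @param schedules Named list of [scan_schedule()].
#' @param transition_sets Named list of `transition_set`s (or numeric day
#'   vectors) for the patients; controls need no entry.
#' @return Tibble of interval labels for the whole cohort.
#' @export
label_cohort <- function(schedules, transition_sets = list()) {
  dplyr::bind_rows(lapply(schedules, function(sch) {
    label_intervals(sch, transition_sets[[sch$subject_id]])
  }))
}
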