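#' Validate an ROI activation panel
#'
#' A panel is a long tibble with one row per subject x scan x ROI, columns
#' `subject`, `group`, `scan`, `roi`, `voxels` (non-negative significant
#' voxel counts for the symptom-provocation > neutral contrast).
#'
#' @param panel Tibble to validate.
#' @return The panel, invisibly, or an error.
#' @export
validate_roi_panel <- function(panel) {
  needed <- c("subject", "group", "scan", "roi", "voxels")
  missing_cols <- setdiff(needed, names(panel))
  if (length(missing_cols)) {
    stop("ROI panel lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (any(panel$voxels < 0, na.rm = TRUE)) {
    stop("voxel counts must be non-negative", call. = FALSE)
  }
  if (anyDuplicated(panel[c("subject", "scan", "roi")])) {
    stop("duplicated subject/scan/roi rows in ROI panel", call. = FALSE)
  }
  invisible(panel)
}

#' Read an ROI panel from CSV
#' @param path CSV with columns `subject`, `group`, `scan`, `roi`, `voxels`.
#' @return Validated panel tibble.
#' @export
load_roi_panel <- function(path) {
  panel <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_roi_panel(panel)
  panel
}

#' Per-patient weighted voxel percentages
#'
#' Normalises each subject's voxel counts by that subject's single largest
#' ROI x scan count (independent of where it occurred) and scales to
#' percent, so the largest cell becomes 100 and brain areas with more
#' voxels carry more statistical weight. This also offsets sensitivity
#' differences between scanners, since the normaliser is within-subject.
#'
#' @param panel ROI panel tibble (see [validate_roi_panel()]).
#' @return The panel with an added `weighted` column in `[0, 100]`. An
#'   all-zero subject gets 0 throughout, with a warning.
#' @export
weighted_percent <- function(panel) {
  validate_roi_panel(panel)
  out <- dplyr::group_by(panel, .data$subject)
  out <- dplyr::mutate(out, .max_count = max(.data$voxels))
  out <- dplyr::ungroup(out)
  zero_subj <- unique(out$subject[out$.max_count == 0])
  if (length(zero_subj)) {
    warning("subject(s) with all-zero counts; weighted % set to 0: ",
            paste(zero_subj, collapse = ", "), call. = FALSE)
  }
  out$weighted <- ifelse(out$.max_count > 0,
                         100 * out$voxels / out$.max_count, 0)
  out$.max_count <- NULL
  out
}

#' Inter-scan activation changes
#'
#' For every subject, interval and ROI, the absolute difference of voxel
#' counts (and of weighted percentages) between the two bounding scans,
#' joined with the interval's OT/NOT/ISI label. Absolute magnitudes are
#' used because the interval contrasts concern the *size* of activation
#' change, while activation globally decreases over therapy.
#'
#' @param panel ROI panel tibble; a `weighted` column is added via
#'   [weighted_percent()] when absent.
#' @param labels Interval label tibble (`subject`, `interval`, `label`,
#'   optionally `transition_day`), e.g. from [label_cohort()]. Every
#'   interval present in the panel must be labelled.
#' @return Change-table tibble with one row per subject x interval x ROI:
#'   `subject`, `group`, `interval`, `label`, `roi`, `diff_voxels`,
#'   `diff_weighted`. Intervals with a missing bounding scan are skipped
#'   with a warning.
#' @export
interscan_changes <- function(panel, labels) {
  validate_roi_panel(panel)
  if (!"weighted" %in% names(panel)) panel <- weighted_percent(panel)
  rows <- list()
  for (subj in unique(panel$subject)) {
    p <- panel[panel$subject == subj, ]
    scans <- sort(unique(p$scan))
    for (k in seq_len(max(scans) - 1)) {
      if (!(k %in% scans) || !((k + 1) %in% scans)) {
        warning(sprintf("subject %s: scan %d or %d missing; interval %d skipped",
                        subj, k, k + 1, k), call. = FALSE)
        next
      }
      a <- p[p$scan == k, ]
      b <- p[p$scan == k + 1, ]
      b <- b[match(a$roi, b$roi), ]
      rows[[length(rows) + 1]] <- tibble::tibble(
        subject = subj, group = a$group[1], interval = k, roi = a$roi,
        diff_voxels = abs(b$voxels - a$voxels),
        diff_weighted = abs(b$weighted - a$weighted)
      )
    }
  }
  changes <- dplyr::bind_rows(rows)
  lab <- labels[c("subject", "interval", "label")]
  out <- dplyr::left_join(changes, lab, by = c("subject", "interval"))
  if (anyNA(out$label)) {
    bad <- out[is.na(out$label), c("subject", "interval")]
    stop("unlabelled interval(s): ",
         paste(unique(paste(bad$subject, bad$interval)), collapse = "; "),
         call. = FALSE)
  }
  dplyr::select(out, "subject", "group", "interval", "label", "roi",
                "diff_voxels", "diff_weighted")
}

# Build the subject x ROI activation matrix at a chosen scan.
# `scan` may be an integer, "first", "last", or a named vector mapping
# subject -> scan index (for e.g. the scan just before each subject's
# transition).
roi_matrix <- function(panel, scan, measure = c("voxels", "weighted")) {
  measure <- match.arg(measure)
  if (measure == "weighted" && !"weighted" %in% names(panel)) {
    panel <- weighted_percent(panel)
  }
  subjects <- sort(unique(panel$subject))
  pick <- function(p) {
    if (is.character(scan) && length(scan) == 1 && scan %in% c("first", "last")) {
      if (scan == "first") min(p$scan) else max(p$scan)
    } else if (!is.null(names(scan))) {
      s <- scan[[p$subject[1]]]
      if (is.null(s) || is.na(s)) NA_integer_ else as.integer(s)
    } else {
      as.integer(scan)
    }
  }
  rois <- unique(panel$roi)
  mat <- matrix(NA_real_, nrow = length(subjects), ncol = length(rois),
                dimnames = list(subjects, rois))
  for (subj in subjects) {
    p <- panel[panel$subject == subj, ]
    s <- pick(p)
    if (is.na(s) || !(s %in% p$scan)) next
    q <- p[p$scan == s, ]
    mat[subj, as.character(q$roi)] <- q[[measure]]
  }
  mat[stats::complete.cases(mat), , drop = FALSE]
}

#' Mean inter-ROI correlation at a scan
#'
#' Pearson correlation, computed across subjects, for every pair of the
#' ROIs at the chosen scan (8 ROIs give `8*7/2 = 28` pairs). The mean and
#' SD of the pairwise correlations summarise how tightly the regional
#' activations co-vary; a drop over therapy reflects differentiation of
#' the activation pattern.
#'
#' @param panel ROI panel tibble.
#' @param scan Scan selector: integer scan index, `"first"`, `"last"`, or a
#'   named subject -> scan vector.
#' @param measure `"voxels"` (default; raw counts) or `"weighted"`.
#' @return List with `mean_r`, `sd_r`, `pairs` (tibble `roi_a`, `roi_b`,
#'   `r` in fixed pair order) and `n_subjects`. Pairs involving a
#'   zero-variance ROI are `NA` and excluded from mean/SD, with a warning.
#' @export
mean_intercorrelation <- function(panel, scan = 1,
                                  measure = c("voxels", "weighted")) {
  measure <- match.arg(measure)
  validate_roi_panel(panel)
  mat <- roi_matrix(panel, scan, measure)
  if (nrow(mat) < 3) {
    stop("need at least 3 subjects with complete data at that scan",
         call. = FALSE)
  }
  sds <- apply(mat, 2, sd)
  if (any(sds == 0)) {
    warning("zero-variance ROI(s) excluded from mean/SD: ",
            paste(colnames(mat)[sds == 0], collapse = ", "), call. = FALSE)
  }
  cm <- suppressWarnings(cor(mat))
  idx <- combn(ncol(mat), 2)
  pairs <- tibble::tibble(
    roi_a = colnames(mat)[idx[1, ]],
    roi_b = colnames(mat)[idx[2, ]],
    r = cm[cbind(idx[1, ], idx[2, ])]
  )
  pairs$r[sds[idx[1, ]] == 0 | sds[idx[2, ]] == 0] <- NA_real_
  list(mean_r = mean(pairs$r, na.rm = TRUE),
       sd_r = sd(pairs$r, na.rm = TRUE),
       pairs = pairs,
       n_subjects = nrow(mat))
}

#' Compare two inter-ROI correlation structures
#'
#' Paired t-test over the matched pairwise correlations of two conditions
#' (e.g. first vs last scan, or pre- vs post-transition); with 8 ROIs the
#' 28 pairs give `df = 27`.
#'
#' @param pairs_a,pairs_b Results of [mean_intercorrelation()] or numeric
#'   vectors of pairwise correlations in identical pair order.
#' @return A [stat_result] from [paired_t_test()].
#' @export
compare_intercorrelation <- function(pairs_a, pairs_b) {
  extract <- function(p) {
    if (is.list(p) && !is.null(p$pairs)) p$pairs else
      tibble::tibble(roi_a = NA_character_, roi_b = NA_character_,
                     r = as.numeric(p))
  }
  a <- extract(pairs_a)
  b <- extract(pairs_b)
  if (nrow(a) != nrow(b)) {
    stop("pair lists have different lengths", call. = FALSE)
  }
  if (!all(is.na(a$roi_a)) && !all(is.na(b$roi_a)) &&
      !identical(a[c("roi_a", "roi_b")], b[c("roi_a", "roi_b")])) {
    stop("pair orderings differ between the two correlation sets",
         call. = FALSE)
  }
  keep <- !is.na(a$r) & !is.na(b$r)
  paired_t_test(a$r[keep], b$r[keep])
}
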