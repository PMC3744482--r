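#' OT/NOT/ISI contrast report
#'
#' The headline analysis: compares the size of inter-scan activation
#' changes across interval types. Each subject first contributes one mean
#' change per label they carry (a patient one OT and one NOT mean, a
#' control one ISI mean), per ROI and for the mean over all ROIs, for both
#' raw voxel differences and weighted percentages. Then:
#'
#' * `OT-NOT` -- within patients: paired t-test and paired Wilcoxon over
#'   patients carrying both labels;
#' * `OT-ISI` and `NOT-ISI` -- patients vs controls: Welch t-test and
#'   rank-sum Wilcoxon;
#' * a point-biserial effect size per contrast, computed on the pooled
#'   per-subject means with 0/1 label coding.
#'
#' Patients lacking one label are excluded from the paired contrast but
#' retained in the unpaired ones. Degenerate inputs (e.g. zero variance)
#' yield `NA` test columns rather than an error, so the mean differences
#' are always reported. No multiple-testing correction is applied across
#' ROIs by default; `p_adjust = "holm"` switches Holm correction on within
#' each contrast x measure family.
#'
#' @param change_table Change table from [interscan_changes()].
#' @param p_adjust `"none"` (default) or `"holm"`.
#' @return Tibble with one row per scope (`"Mean of all"` + each ROI) x
#'   measure (`voxels`, `weighted`) x contrast, columns `mean_diff`, `t`,
#'   `df`, `p_t`, `p_wilcoxon`, `r`, `n_1`, `n_2`.
#' @export
contrast_report <- function(change_table, p_adjust = c("none", "holm")) {
  p_adjust <- match.arg(p_adjust)
  needed <- c("subject", "label", "roi", "diff_voxels", "diff_weighted")
  stopifnot(all(needed %in% names(change_table)))

  per_roi <- dplyr::summarise(
    dplyr::group_by(change_table, .data$subject, .data$label, .data$roi),
    voxels = mean(.data$diff_voxels),
    weighted = mean(.data$diff_weighted),
    .groups = "drop"
  )
  overall <- dplyr::summarise(
    dplyr::group_by(per_roi, .data$subject, .data$label),
    voxels = mean(.data$voxels),
    weighted = mean(.data$weighted),
    .groups = "drop"
  )
  overall$roi <- "Mean of all"
  subj_means <- dplyr::bind_rows(overall, per_roi)

  scopes <- c("Mean of all", as.character(unique(per_roi$roi)))
  contrasts <- list(
    c("OT", "NOT", "paired"),
    c("OT", "ISI", "unpaired"),
    c("NOT", "ISI", "unpaired")
  )
  safely_na <- function(expr) tryCatch(expr, error = function(e) NULL)

  rows <- list()
  for (scope in scopes) {
    sm <- subj_means[subj_means$roi == scope, ]
    for (measure in c("voxels", "weighted")) {
      for (con in contrasts) {
        la <- con[1]; lb <- con[2]; kind <- con[3]
        a <- sm[sm$label == la, ]
        b <- sm[sm$label == lb, ]
        va <- a[[measure]]; vb <- b[[measure]]
        t_val <- df_val <- p_t <- p_w <- NA_real_
        if (kind == "paired") {
          both <- intersect(a$subject, b$subject)
          pa <- va[match(both, a$subject)]
          pb <- vb[match(both, b$subject)]
          mean_diff <- mean(pa) - mean(pb)
          n1 <- n2 <- length(both)
          if (length(both) >= 2) {
            tt <- safely_na(paired_t_test(pa, pb))
            wt <- safely_na(wilcoxon_paired(pa, pb))
            if (!is.null(tt)) { t_val <- tt$statistic; df_val <- tt$df; p_t <- tt$p }
            if (!is.null(wt)) p_w <- wt$p
          }
        } else {
          mean_diff <- mean(va) - mean(vb)
          n1 <- length(va); n2 <- length(vb)
          if (n1 >= 2 && n2 >= 2) {
            tt <- safely_na(welch_t_test(va, vb))
            wt <- safely_na(wilcoxon_ranksum(va, vb))
            if (!is.null(tt)) { t_val <- tt$statistic; df_val <- tt$df; p_t <- tt$p }
            if (!is.null(wt)) p_w <- wt$p
          }
        }
        pooled <- c(va, vb)
        lab <- factor(rep(c(la, lb), c(length(va), length(vb))),
                      levels = c(la, lb))
        r <- if (length(va) && length(vb) && sd(pooled) > 0) {
          as.numeric(point_biserial(pooled, lab))
        } else NA_real_
        rows[[length(rows) + 1]] <- tibble::tibble(
          scope = scope, measure = measure,
          contrast = paste0(la, "-", lb),
          mean_diff = mean_diff, t = t_val, df = df_val,
          p_t = p_t, p_wilcoxon = p_w, r = r, n_1 = n1, n_2 = n2
        )
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  if (p_adjust == "holm") {
    out <- dplyr::group_by(out, .data$measure, .data$contrast)
    out <- dplyr::mutate(
      out,
      p_t = stats::p.adjust(.data$p_t, method = "holm"),
      p_wilcoxon = stats::p.adjust(.data$p_wilcoxon, method = "holm")
    )
    out <- dplyr::ungroup(out)
  }
  out
}
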