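# Run code under a temporary RNG state so generators are seeded without
# clobbering the caller's random stream.
local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Stable per-subject seed derivation from a root seed (kept below 2^31).
derive_seed <- function(seed, index) {
  ((as.numeric(seed) %% 100000) * 20011 + index * 7919) %% 2147483647 + 1
}

#' Simulation design for a synthetic therapy cohort
#'
#' Encodes the study conditions the generators emulate: 9 patients (7
#' scanned three times with one order transition, 2 scanned four times
#' with two transitions) and 9 untreated controls; 37--65 daily
#' observations per subject; bounded ordinal items; a level shift at each
#' transition day preceded by a window of inflated fluctuations (critical
#' fluctuations precede the transition). Ratings follow a latent AR(1)
#' process per item, clipped and rounded to the item scale.
#'
#' @param n_patients,n_controls Cohort sizes (default 9 each).
#' @param scans_per_patient Scan counts per patient (default seven 3s and
#'   two 4s); patients with 4 scans receive two transitions.
#' @param scans_per_control Scan counts per control (default five 3s,
#'   three 2s, one 4).
#' @param days_range Range the per-subject observation length is drawn
#'   from, in days (default 37--65).
#' @param n_items Number of rating items (default 20).
#' @param scale Item [rating_scale()] (default 1--7 Likert).
#' @param level_shift Post-transition mean shift as a fraction of the
#'   scale range (default 0.25).
#' @param fluct_inflation Multiplier on the innovation SD during the
#'   pre-transition window (default 3; 1 disables the critical
#'   fluctuations).
#' @param fluct_window Length of the pre-transition inflation window in
#'   days (default 10).
#' @param ar_coef AR(1) coefficient of the latent item process
#'   (default 0.6; must be in `[0, 1)`).
#' @param innovation_sd Innovation SD as a fraction of the scale range
#'   (default 0.08).
#' @param discretize Round observed values to the integer Likert grid
#'   (default TRUE).
#' @param seed Root seed; all per-subject randomness is derived from it.
#' @return List of class `simulation_design`.
#' @export
simulation_design <- function(n_patients = 9, n_controls = 9,
                              scans_per_patient = c(rep(3, 7), rep(4, 2)),
                              scans_per_control = c(rep(3, 5), rep(2, 3), 4),
                              days_range = c(37, 65), n_items = 20,
                              scale = rating_scale(1, 7),
                              level_shift = 0.25, fluct_inflation = 3,
                              fluct_window = 10, ar_coef = 0.6,
                              innovation_sd = 0.08, discretize = TRUE,
                              seed = 42) {
  stopifnot(n_patients >= 1, length(scans_per_patient) == n_patients,
            all(scans_per_patient >= 2), all(scans_per_patient <= 4),
            n_controls >= 0, length(scans_per_control) == n_controls,
            days_range[1] >= 20, days_range[2] >= days_range[1],
            n_items >= 1, is_rating_scale(scale),
            level_shift >= 0, fluct_inflation >= 1, fluct_window >= 1,
            ar_coef >= 0, ar_coef < 1, innovation_sd >= 0)
  structure(
    list(n_patients = n_patients, n_controls = n_controls,
         scans_per_patient = as.integer(scans_per_patient),
         scans_per_control = as.integer(scans_per_control),
         days_range = as.integer(days_range), n_items = as.integer(n_items),
         scale = scale, level_shift = level_shift,
         fluct_inflation = fluct_inflation,
         fluct_window = as.integer(fluct_window),
         ar_coef = ar_coef, innovation_sd = innovation_sd,
         discretize = isTRUE(discretize), seed = seed),
    class = "simulation_design"
  )
}

place_scans <- function(n_days, n_scans) {
  round(seq(9, n_days - 1, length.out = n_scans))
}

#' Simulate one patient's rating series and scan schedule
#'
#' Per item, a latent AR(1) process around a baseline mean; during the
#' `fluct_window` days before each transition day the innovation SD is
#' multiplied by `fluct_inflation` (critical fluctuations), and from the
#' transition day onward the item mean shifts by `level_shift * R` with an
#' item-specific sign (the new regime). Values are clipped to the scale
#' and rounded to the Likert grid. Scan days are placed so that each true
#' transition falls inside its designated inter-scan interval.
#'
#' @param design A [simulation_design()].
#' @param subject_id Identifier for the simulated patient.
#' @param seed Integer seed for this subject.
#' @param n_scans Number of scans (2--4); patients with 4 scans get two
#'   transitions by default.
#' @param n_transitions Number of injected transitions (default 2 for 4
#'   scans, else 1).
#' @return List with `series` ([rating_series()]), `schedule`
#'   ([scan_schedule()]) and `truth` (list with `tau`, `intervals`,
#'   `n_days`).
#' @export
simulate_patient <- function(design, subject_id, seed,
                             n_scans = 3,
                             n_transitions = if (n_scans >= 4) 2 else 1) {
  stopifnot(inherits(design, "simulation_design"),
            n_scans >= 2, n_scans <= 4, n_transitions <= n_scans - 1)
  local_seed(seed, {
    n_days <- sample(design$days_range[1]:design$days_range[2], 1)
    scans <- place_scans(n_days, n_scans)
    n_int <- n_scans - 1
    ks <- if (n_transitions == 1) {
      if (n_int == 1 || runif(1) < 0.75) 1L else sample(2:n_int, 1)
    } else {
      sort(sample.int(n_int, n_transitions))
    }
    taus <- integer(0)
    for (k in ks) {
      lo <- scans[k] + 3
      hi <- scans[k + 1]
      if (length(taus)) lo <- max(lo, taus[length(taus)] + 16)
      tau <- if (lo >= hi) hi else sample(lo:hi, 1)
      taus <- c(taus, tau)
    }

    sc <- design$scale
    delta <- design$level_shift * sc$range
    sigma <- design$innovation_sd * sc$range
    phi <- design$ar_coef
    inflate <- rep(1, n_days)
    for (tau in taus) {
      win <- max(1, tau - design$fluct_window):(tau - 1)
      inflate[win] <- design$fluct_inflation
    }

    vals <- matrix(NA_real_, nrow = n_days, ncol = design$n_items)
    colnames(vals) <- sprintf("item%02d", seq_len(design$n_items))
    for (j in seq_len(design$n_items)) {
      mu0 <- runif(1, sc$min_value + 0.25 * sc$range,
                   sc$max_value - 0.25 * sc$range)
      shift_sign <- sample(c(-1, 1), length(taus), replace = TRUE)
      mu <- rep(mu0, n_days)
      for (i in seq_along(taus)) {
        from <- taus[i]
        mu[from:n_days] <- mu[from:n_days] + shift_sign[i] * delta
      }
      x <- numeric(n_days)
      x[1] <- mu[1] + if (sigma > 0) rnorm(1, 0, sigma / sqrt(1 - phi^2)) else 0
      for (t in 2:n_days) {
        x[t] <- mu[t] + phi * (x[t - 1] - mu[t - 1]) +
          rnorm(1, 0, sigma * inflate[t])
      }
      x <- pmin(pmax(x, sc$min_value), sc$max_value)
      if (design$discretize) x <- round(x)
      vals[, j] <- x
    }

    list(
      series = rating_series(subject_id, vals, sc),
      schedule = scan_schedule(subject_id, scans, "patient", n_days = n_days),
      truth = list(subject = as.character(subject_id), tau = taus,
                   intervals = ks, n_days = n_days)
    )
  })
}

#' Simulate a full cohort
#'
#' Generates all patients (ratings, schedules, ground truth) and controls
#' (schedules only -- untreated controls give no daily self-ratings and
#' have no transitions). The default design yields 20 patient inter-scan
#' intervals (7 patients x 2 + 2 patients x 3). All randomness derives
#' from the root seed through a stable per-subject fan-out, so identical
#' seeds give identical cohorts.
#'
#' @param design A [simulation_design()].
#' @param seed Root seed (defaults to `design$seed`).
#' @return List of class `synthetic_cohort` with `ratings` (named list of
#'   [rating_series()], patients only), `schedules` (named list of
#'   [scan_schedule()]), `truth` (named list per patient), `design`,
#'   `seed`.
#' @export
simulate_cohort <- function(design, seed = design$seed) {
  stopifnot(inherits(design, "simulation_design"))
  ratings <- list(); schedules <- list(); truth <- list()
  for (i in seq_len(design$n_patients)) {
    id <- sprintf("p%02d", i)
    sim <- simulate_patient(design, id, derive_seed(seed, i),
                            n_scans = design$scans_per_patient[i])
    ratings[[id]] <- sim$series
    schedules[[id]] <- sim$schedule
    truth[[id]] <- sim$truth
  }
  for (i in seq_len(design$n_controls)) {
    id <- sprintf("c%02d", i)
    schedules[[id]] <- local_seed(derive_seed(seed, design$n_patients + i), {
      n_days <- sample(design$days_range[1]:design$days_range[2], 1)
      scan_schedule(id, place_scans(n_days, design$scans_per_control[i]),
                    "control", n_days = n_days)
    })
  }
  structure(
    list(ratings = ratings, schedules = schedules, truth = truth,
         design = design, seed = seed),
    class = "synthetic_cohort"
  )
}

#' Interval labels from simulation ground truth
#'
#' Labels each patient interval by the *injected* transitions rather than
#' detected ones -- the reference labelling against which detection is
#' scored, and the labelling that drives the synthetic ROI effects.
#'
#' @param cohort A `synthetic_cohort` from [simulate_cohort()].
#' @return Interval label tibble as from [label_cohort()].
#' @export
truth_labels <- function(cohort) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  label_cohort(cohort$schedules,
               lapply(cohort$truth, function(tr) tr$tau))
}

#' Effect parameters for the synthetic ROI panel
#'
#' Defaults target the magnitudes the interval contrasts work at: mean
#' absolute inter-scan changes of 7479 (OT), 1904 (NOT) and 697 (ISI)
#' voxels; per-ROI baseline counts spanning roughly 1300--22600 voxels
#' (heterogeneous magnitudes as arise from scanner-specific voxelwise
#' thresholds); inter-ROI correlation 0.71 before and 0.29 after the
#' transition. These are convenience targets for end-to-end testing, not a
#' claim of distributional fidelity.
#'
#' @param ot_change_mean,not_change_mean,isi_change_mean Mean absolute
#'   voxel-count change per interval type.
#' @param baseline_mean Named vector of per-ROI baseline counts at scan 1
#'   (defaults cover [ocd_rois]).
#' @param noise_sd SD of the change magnitudes (voxels, default 1000).
#' @param cv Between-subject coefficient of variation of baselines
#'   (default 0.3).
#' @param rho_pre,rho_post Inter-ROI correlation of baselines and of
#'   change noise before/after a subject's first transition.
#' @return List of class `roi_effect`.
#' @export
roi_effect <- function(ot_change_mean = 7479, not_change_mean = 1904,
                       isi_change_mean = 697,
                       baseline_mean = c(
                         "CC/SMA" = 9949.5, "DLPFC r" = 1315.9,
                         "DLPFC l" = 11475.4, "Insula r" = 3077.8,
                         "Insula l" = 4619.6, "Parietal r" = 9991.1,
                         "Parietal l" = 15938.7, "Cuneus" = 22628.3),
                       noise_sd = 1000, cv = 0.3,
                       rho_pre = 0.71, rho_post = 0.29) {
  vals <- c(ot_change_mean, not_change_mean, isi_change_mean,
            baseline_mean, noise_sd, cv)
  if (any(vals < 0)) stop("effect parameters must be non-negative", call. = FALSE)
  stopifnot(rho_pre >= 0, rho_pre <= 1, rho_post >= 0, rho_post <= 1,
            !is.null(names(baseline_mean)))
  structure(
    list(ot_change_mean = ot_change_mean, not_change_mean = not_change_mean,
         isi_change_mean = isi_change_mean, baseline_mean = baseline_mean,
         noise_sd = noise_sd, cv = cv, rho_pre = rho_pre,
         rho_post = rho_post),
    class = "roi_effect"
  )
}

#' Simulate an ROI activation panel matched to a labelled cohort
#'
#' Scan-1 counts are drawn around per-ROI baselines with a common
#' within-subject latent factor giving inter-ROI correlation `rho_pre`
#' across subjects. Each subsequent scan moves by a label-dependent change
#' magnitude (`OT`/`NOT`/`ISI` mean plus correlated noise); the change
#' decrements the count when feasible and increments it otherwise, so the
#' absolute inter-scan difference equals the drawn magnitude and counts
#' stay non-negative. From a subject's first transition interval onward
#' the change noise uses `rho_post`, which erodes the initially tight
#' inter-ROI correlation.
#'
#' @param schedules Named list of [scan_schedule()].
#' @param labels Interval label tibble covering every interval (e.g.
#'   [truth_labels()] or [label_cohort()]).
#' @param effect A [roi_effect()].
#' @param seed Integer seed.
#' @return ROI panel tibble (`subject`, `group`, `scan`, `roi`, `voxels`).
#' @export
simulate_roi_panel <- function(schedules, labels, effect = roi_effect(),
                               seed = 42) {
  stopifnot(inherits(effect, "roi_effect"))
  rois <- names(effect$baseline_mean)
  b <- effect$baseline_mean
  label_means <- c(OT = effect$ot_change_mean, NOT = effect$not_change_mean,
                   ISI = effect$isi_change_mean)
  local_seed(seed, {
    rows <- list()
    for (sch in schedules) {
      subj <- sch$subject_id
      n_scans <- length(sch$scan_days)
      lab <- labels[labels$subject == subj, ]
      lab <- lab[order(lab$interval), ]
      if (nrow(lab) != n_scans - 1) {
        stop("labels do not cover every interval of subject ", subj,
             call. = FALSE)
      }
      u <- rnorm(1)
      z <- sqrt(effect$rho_pre) * u +
        sqrt(1 - effect$rho_pre) * rnorm(length(rois))
      counts <- pmax(0, round(b * (1 + effect$cv * z)))
      first_ot <- if (any(lab$label == "OT")) min(lab$interval[lab$label == "OT"]) else Inf
      rows[[length(rows) + 1]] <- tibble::tibble(
        subject = subj, group = sch$group, scan = 1L, roi = rois,
        voxels = as.numeric(counts))
      for (k in seq_len(n_scans - 1)) {
        rho_c <- if (k >= first_ot) effect$rho_post else effect$rho_pre
        g <- rnorm(1)
        eta <- sqrt(rho_c) * g + sqrt(1 - rho_c) * rnorm(length(rois))
        mag <- pmax(0, label_means[[lab$label[k]]] + effect$noise_sd * eta)
        dir <- ifelse(counts >= mag, -1, 1)
        counts <- round(counts + dir * mag)
        rows[[length(rows) + 1]] <- tibble::tibble(
          subject = subj, group = sch$group, scan = k + 1L, roi = rois,
          voxels = as.numeric(counts))
      }
    }
    out <- dplyr::bind_rows(rows)
    validate_roi_panel(out)
    out
  })
}
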