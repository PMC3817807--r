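#' Cross-validation plan for multi-profile testing
#'
#' The normal profile is cross-validated 3-fold: each fold trains on
#' `fold_size` randomly assigned healthy donors and tests every case not
#' in that training set. The patient profiles are cross-validated
#' leave-one-out: each round trains on one patient case and tests all
#' remaining cases. The diagnosis grid is every triple (normal fold, CLL
#' round, FL round) evaluated on every case held out from its own
#' cohort's training set in that triple.
#'
#' With the default cohort sizes (36 healthy, 21 CLL, 15 FL, folds of 12)
#' the plan yields 180 normal-profile, 1491 CLL-profile, and 1065
#' FL-profile capture-rate evaluations, and 54,810 grid diagnoses split
#' 22,680 / 18,900 / 13,230 by true cohort.
#'
#' @param n_normal,n_cll,n_fl Cohort sizes.
#' @param fold_size Healthy donors per normal training fold.
#' @param seed Seed for the random fold assignment.
#' @return A `cv_plan`: normal training folds (index sets), LOO round
#'   indices, and the closed-form evaluation counts in `$counts`.
#' @export
make_cv_plan <- function(n_normal = 36L, n_cll = 21L, n_fl = 15L,
                         fold_size = 12L, seed = 1L) {
  n_normal <- as.integer(n_normal)
  n_cll <- as.integer(n_cll)
  n_fl <- as.integer(n_fl)
  fold_size <- as.integer(fold_size)
  stopifnot(n_normal >= 1L, n_cll >= 2L, n_fl >= 2L, fold_size >= 1L)
  if (3L * fold_size > n_normal) {
    stop("three disjoint folds of ", fold_size,
         " need at least ", 3L * fold_size, " healthy donors")
  }
  perm <- with_seed(seed, sample.int(n_normal))
  folds <- lapply(0:2, function(f) {
    sort(perm[(f * fold_size + 1L):((f + 1L) * fold_size)])
  })
  n_triples <- 3L * n_cll * n_fl
  per_cohort <- c(Normal = n_triples * (n_normal - fold_size),
                  CLL = n_triples * (n_cll - 1L),
                  FL = n_triples * (n_fl - 1L))
  counts <- list(
    normal_ccr = 3L * ((n_normal - fold_size) + n_cll + n_fl),
    cll_ccr = n_cll * (n_normal + (n_cll - 1L) + n_fl),
    fl_ccr = n_fl * (n_normal + n_cll + (n_fl - 1L)),
    cll_ccr_per_round = n_normal + (n_cll - 1L) + n_fl,
    fl_ccr_per_round = n_normal + n_cll + (n_fl - 1L),
    n_triples = n_triples,
    diagnoses = per_cohort,
    total_diagnoses = sum(per_cohort))
  structure(list(n_normal = n_normal, n_cll = n_cll, n_fl = n_fl,
                 fold_size = fold_size, folds = folds,
                 cll_rounds = seq_len(n_cll), fl_rounds = seq_len(n_fl),
                 counts = counts),
            class = "cv_plan")
}

#' @export
print.cv_plan <- function(x, ...) {
  cat(sprintf("cv_plan: %d/%d/%d cases, 3 normal folds of %d\n",
              x$n_normal, x$n_cll, x$n_fl, x$fold_size))
  cat(sprintf("  CCR evaluations: %d normal, %d CLL, %d FL\n",
              x$counts$normal_ccr, x$counts$cll_ccr, x$counts$fl_ccr))
  cat(sprintf("  grid diagnoses: %d (%s)\n", x$counts$total_diagnoses,
              paste(x$counts$diagnoses, collapse = "/")))
  invisible(x)
}

# Number of training cases selected from a cohort of n at a given
# fraction; never zero.
n_selected <- function(n, fraction) max(1L, round(fraction * n))

#' Select representative patient training cases
#'
#' For each patient case the Euclidean distance between its T-cell cluster
#' center and its B-cell cluster center is computed (after the divisive
#' T/B clustering). Cases whose distance is closest to the cohort mean
#' distance are the most representative of the cohort geometry; the
#' `fraction` of cases nearest the mean (at least one, ties by case order)
#' is selected for profile building.
#'
#' @param cases List of patient [point3_table()] cases (k = 2 structure).
#' @param fraction Fraction of the cohort to select (default 0.15).
#' @return List with `indices` (selected case positions, ascending),
#'   `distances` (all T-to-B center distances), `mean_distance`.
#' @export
select_training_cases <- function(cases, fraction = 0.15) {
  if (length(cases) < 2L) stop("selection needs at least 2 cases")
  stopifnot(fraction > 0, fraction < 1)
  distances <- vapply(cases, function(p) {
    sp <- split_t_cells(p)
    cb <- cluster_b_cells(p$points[!sp$is_t, , drop = FALSE], 1L)
    sqrt(sum((sp$t_center - cb$centers[1L, ])^2))
  }, numeric(1))
  target <- mean(distances)
  ord <- order(abs(distances - target))  # stable: ties by case order
  idx <- sort(ord[seq_len(min(n_selected(length(cases), fraction),
                              length(cases)))])
  list(indices = idx, distances = distances, mean_distance = target)
}

# Box-plot summary (median, quartiles, 1.5*IQR whiskers, outliers).
box_stats <- function(v) {
  q <- unname(stats::quantile(v, c(0.25, 0.5, 0.75)))
  iqr <- q[3L] - q[1L]
  lo <- q[1L] - 1.5 * iqr
  hi <- q[3L] + 1.5 * iqr
  inside <- v >= lo & v <= hi
  list(q1 = q[1L], median = q[2L], q3 = q[3L],
       whisker_low = min(v[inside]), whisker_high = max(v[inside]),
       outliers = v[!inside])
}

#' Fit every case against the normal profile only
#'
#' Single-profile screening: each case's capture rate against the healthy
#' profile, with per-cohort box-plot summaries (median, quartiles,
#' 1.5 x IQR whiskers, outliers beyond them).
#'
#' @param cases List of [point3_table()] cases with cohort labels.
#' @param normal_profile A Normal `ccr_profile`.
#' @return List with `records` (case_id, cohort, ccr data.frame) and
#'   `summary` (per-cohort box statistics).
#' @export
run_single_profile <- function(cases, normal_profile) {
  stopifnot(inherits(normal_profile, "ccr_profile"),
            normal_profile$cohort == "Normal")
  records <- data.frame(
    case_id = vapply(cases, function(p) p$case_id, ""),
    cohort = vapply(cases, function(p) p$cohort, ""),
    ccr = vapply(cases, function(p) fit_case(normal_profile, p),
                 numeric(1)),
    stringsAsFactors = FALSE)
  summary <- lapply(split(records$ccr, records$cohort), box_stats)
  list(records = records, summary = summary)
}

ccr_vector <- function(profiles, points) {
  vapply(profiles, fit_case, numeric(1), points = points)
}

#' Run the full cross-validated multi-profile experiment
#'
#' Builds every profile instance the plan calls for (one normal profile
#' per fold by pooling its training donors; one patient profile per
#' leave-one-out round), computes one capture rate per (profile instance,
#' eligible case) pair, and then evaluates every (fold, CLL round, FL
#' round) triple on its eligible cases by reusing those rates — the only
#' composition in which the per-profile evaluation counts and the grid
#' totals are consistent. No case is ever evaluated against a profile
#' trained on it.
#'
#' @param plan A [make_cv_plan()].
#' @param cases List of [point3_table()] cases whose cohort labels
#'   partition into the plan's cohort sizes.
#' @param m Ellipsoid standard-deviation multiplier.
#' @param seed Base seed for profile building.
#' @return List with `mean_ccr` (true cohort x profile), `confusion`
#'   (counts, rows = true cohort), `confusion_rates`, `n_ccr` (evaluations
#'   per profile type), `n_diagnoses` (per true cohort), and the `plan`.
#' @export
run_multi_profile <- function(plan, cases, m = 2, seed = 1L) {
  stopifnot(inherits(plan, "cv_plan"))
  cohorts <- vapply(cases, function(p) p$cohort, "")
  by_cohort <- lapply(COHORTS, function(cc) cases[cohorts == cc])
  names(by_cohort) <- COHORTS
  if (length(by_cohort$Normal) != plan$n_normal ||
      length(by_cohort$CLL) != plan$n_cll ||
      length(by_cohort$FL) != plan$n_fl) {
    stop("case cohort sizes do not match the plan")
  }
  normals <- by_cohort$Normal
  clls <- by_cohort$CLL
  fls <- by_cohort$FL

  normal_profiles <- lapply(seq_along(plan$folds), function(f) {
    build_profile(merge_training_cases(normals[plan$folds[[f]]]),
                  "Normal", m = m, seed = seed + f)
  })
  cll_profiles <- lapply(plan$cll_rounds, function(i) {
    build_profile(clls[[i]], "CLL", m = m, seed = seed)
  })
  fl_profiles <- lapply(plan$fl_rounds, function(j) {
    build_profile(fls[[j]], "FL", m = m, seed = seed)
  })

  all_cases <- c(normals, clls, fls)
  case_cohort <- c(rep("Normal", plan$n_normal), rep("CLL", plan$n_cll),
                   rep("FL", plan$n_fl))
  n_cases <- length(all_cases)
  # training masks: trained[i, r] = TRUE when case i is in round r's
  # training set (such pairs are never evaluated)
  in_fold <- matrix(FALSE, n_cases, length(plan$folds))
  for (f in seq_along(plan$folds)) in_fold[plan$folds[[f]], f] <- TRUE
  in_cll <- matrix(FALSE, n_cases, plan$n_cll)
  for (i in plan$cll_rounds) in_cll[plan$n_normal + i, i] <- TRUE
  in_fl <- matrix(FALSE, n_cases, plan$n_fl)
  for (j in plan$fl_rounds) in_fl[plan$n_normal + plan$n_cll + j, j] <- TRUE

  fill_ccr <- function(profiles, trained) {
    ccr <- matrix(NA_real_, n_cases, length(profiles))
    for (r in seq_along(profiles)) {
      for (i in seq_len(n_cases)) {
        if (trained[i, r]) next
        ccr[i, r] <- fit_case(profiles[[r]], all_cases[[i]])
      }
    }
    ccr
  }
  ccr_n <- fill_ccr(normal_profiles, in_fold)
  ccr_c <- fill_ccr(cll_profiles, in_cll)
  ccr_f <- fill_ccr(fl_profiles, in_fl)

  labels <- c(COHORTS, "Inconclusive")
  confusion <- matrix(0L, 3L, 4L, dimnames = list(COHORTS, labels))
  for (f in seq_along(plan$folds)) {
    for (i in plan$cll_rounds) {
      for (j in plan$fl_rounds) {
        eligible <- which(!in_fold[, f] & !in_cll[, i] & !in_fl[, j])
        vn <- ccr_n[eligible, f]
        vc <- ccr_c[eligible, i]
        vf <- ccr_f[eligible, j]
        dn <- sqrt(vc^2 + vf^2)
        dc <- sqrt(vn^2 + vf^2)
        df <- sqrt(vn^2 + vc^2)
        lab <- ifelse(dn < dc & dn < df, "Normal",
                      ifelse(dc < dn & dc < df, "CLL",
                             ifelse(df < dn & df < dc, "FL",
                                    "Inconclusive")))
        tab <- table(factor(case_cohort[eligible], COHORTS),
                     factor(lab, labels))
        confusion <- confusion + tab
      }
    }
  }
  mean_ccr <- rbind(
    Normal = c(mean(ccr_n[case_cohort == "Normal", ], na.rm = TRUE),
               mean(ccr_c[case_cohort == "Normal", ], na.rm = TRUE),
               mean(ccr_f[case_cohort == "Normal", ], na.rm = TRUE)),
    CLL = c(mean(ccr_n[case_cohort == "CLL", ], na.rm = TRUE),
            mean(ccr_c[case_cohort == "CLL", ], na.rm = TRUE),
            mean(ccr_f[case_cohort == "CLL", ], na.rm = TRUE)),
    FL = c(mean(ccr_n[case_cohort == "FL", ], na.rm = TRUE),
           mean(ccr_c[case_cohort == "FL", ], na.rm = TRUE),
           mean(ccr_f[case_cohort == "FL", ], na.rm = TRUE)))
  colnames(mean_ccr) <- COHORTS
  n_ccr <- c(normal = sum(!is.na(ccr_n)), cll = sum(!is.na(ccr_c)),
             fl = sum(!is.na(ccr_f)))
  list(mean_ccr = mean_ccr, confusion = confusion,
       confusion_rates = confusion / rowSums(confusion),
       n_ccr = n_ccr, n_diagnoses = rowSums(confusion), plan = plan)
}

#' Run the selection-strategy multi-profile protocol
#'
#' The deployment-style experiment: about 15% of each cohort is used for
#' profile building — healthy training donors drawn at random (healthy
#' samples are homogeneous), patient training cases chosen by
#' [select_training_cases()] — and every remaining case is fitted to the
#' three profiles and diagnosed by [diagnose()].
#'
#' @param cases List of [point3_table()] cases covering all three cohorts.
#' @param fraction Training fraction per cohort (default 0.15).
#' @param m Ellipsoid standard-deviation multiplier.
#' @param seed Seed for the normal training draw and profile building.
#' @return List with `records` (one row per tested case: CCR triple,
#'   distances implicit in the label), `confusion` (counts), `accuracy`
#'   (per-cohort diagonal rate), `mean_ccr` (true cohort x profile), and
#'   `training` (case ids used per profile).
#' @export
run_selection_protocol <- function(cases, fraction = 0.15, m = 2,
                                   seed = 1L) {
  cohorts <- vapply(cases, function(p) p$cohort, "")
  normals <- cases[cohorts == "Normal"]
  clls <- cases[cohorts == "CLL"]
  fls <- cases[cohorts == "FL"]
  if (length(normals) < 2L || length(clls) < 2L || length(fls) < 2L) {
    stop("each cohort needs at least 2 cases")
  }
  n_train <- n_selected(length(normals), fraction)
  norm_idx <- with_seed(seed, sort(sample.int(length(normals), n_train)))
  cll_idx <- select_training_cases(clls, fraction)$indices
  fl_idx <- select_training_cases(fls, fraction)$indices

  profiles <- list(
    Normal = build_profile(merge_training_cases(normals[norm_idx]),
                           "Normal", m = m, seed = seed),
    CLL = build_profile(merge_training_cases(
      canonicalize_dominance(clls[cll_idx])), "CLL", m = m, seed = seed),
    FL = build_profile(merge_training_cases(
      canonicalize_dominance(fls[fl_idx])), "FL", m = m, seed = seed))

  test_cases <- c(normals[-norm_idx], clls[-cll_idx], fls[-fl_idx])
  records <- do.call(rbind, lapply(test_cases, function(p) {
    v <- ccr_vector(profiles, p)
    dg <- diagnose(v)
    data.frame(case_id = p$case_id, cohort = p$cohort,
               ccr_normal = v[[1L]], ccr_cll = v[[2L]], ccr_fl = v[[3L]],
               label = dg$label, stringsAsFactors = FALSE)
  }))
  labels <- c(COHORTS, "Inconclusive")
  confusion <- table(factor(records$cohort, COHORTS),
                     factor(records$label, labels))
  confusion <- unclass(as.matrix(confusion))
  accuracy <- diag(confusion[, COHORTS]) / rowSums(confusion)
  mean_ccr <- do.call(rbind, lapply(COHORTS, function(cc) {
    r <- records[records$cohort == cc, ]
    c(Normal = mean(r$ccr_normal), CLL = mean(r$ccr_cll),
      FL = mean(r$ccr_fl))
  }))
  rownames(mean_ccr) <- COHORTS
  list(records = records, confusion = confusion, accuracy = accuracy,
       mean_ccr = mean_ccr,
       training = list(
         Normal = vapply(normals[norm_idx], function(p) p$case_id, ""),
         CLL = vapply(clls[cll_idx], function(p) p$case_id, ""),
         FL = vapply(fls[fl_idx], function(p) p$case_id, "")))
}
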