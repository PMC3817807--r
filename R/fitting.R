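#' Separate T cells from B cells on the CD19 axis
#'
#' First stage of the hierarchical divisive clustering of a test case:
#' T lymphocytes lack CD19, so a 1-D 2-means split on the y (CD19) axis
#' isolates them. The split minimizing the within-group sum of squares is
#' found exactly by scanning the sorted values, so the result does not
#' depend on event order or initialization. The low-CD19 group is the
#' T-cell group.
#'
#' @param points A [point3_table()] or `n x 3` matrix.
#' @param min_events Minimum events required (default 20).
#' @return List with `is_t` (logical per event), `t_center` (mean of the
#'   T-cell events, length 3), and `threshold` (the CD19 cut).
#' @export
split_t_cells <- function(points, min_events = 20L) {
  pts <- if (inherits(points, "point3_table")) points$points else
    as.matrix(points)
  n <- nrow(pts)
  if (n < min_events) {
    stop("T/B separation needs at least ", min_events, " events")
  }
  y <- pts[, 2L]
  if (diff(range(y)) == 0) {
    stop("no T/B separation: CD19 values are all identical")
  }
  ys <- sort(y)
  cs <- cumsum(ys)
  css <- cumsum(ys^2)
  i <- seq_len(n - 1L)
  ss_left <- css[i] - cs[i]^2 / i
  ss_right <- (css[n] - css[i]) - (cs[n] - cs[i])^2 / (n - i)
  best <- which.min(ss_left + ss_right)
  threshold <- (ys[best] + ys[best + 1L]) / 2
  is_t <- y <= threshold
  if (!any(is_t) || all(is_t)) {
    stop("no T/B separation: CD19 split is degenerate")
  }
  list(is_t = is_t, t_center = colMeans(pts[is_t, , drop = FALSE]),
       threshold = threshold)
}

#' Cluster the non-T events into the profile's B-cell clusters
#'
#' K-means on the B-cell events. For two B clusters (normal profile) the
#' initialization splits on the median of the x (kappa - lambda) axis —
#' the axis separating kappa- from lambda-expressing B cells — making the
#' result deterministic and independent of event order. Clusters are
#' numbered by decreasing x center (kappa-side first).
#'
#' @param points `n x 3` matrix of non-T events (or a [point3_table()]).
#' @param k_minus_1 Number of B clusters, 1 or 2.
#' @return List with `labels` (in `1..k_minus_1`) and `centers`
#'   (`k_minus_1 x 3` cluster means).
#' @export
cluster_b_cells <- function(points, k_minus_1) {
  pts <- if (inherits(points, "point3_table")) points$points else
    as.matrix(points)
  if (!k_minus_1 %in% c(1L, 2L)) stop("k - 1 must be 1 or 2")
  n <- nrow(pts)
  if (n < k_minus_1) stop("fewer B-cell events than clusters")
  if (k_minus_1 == 1L) {
    return(list(labels = rep(1L, n),
                centers = matrix(colMeans(pts), 1L, 3L)))
  }
  split_axis <- if (diff(range(pts[, 1L])) > 0) 1L else
    which.max(apply(pts, 2L, function(v) diff(range(v))))
  if (diff(range(pts[, split_axis])) == 0) {
    stop("cannot separate two B-cell clusters: events are identical")
  }
  med <- stats::median(pts[, split_axis])
  lo <- pts[, split_axis] <= med
  if (all(lo) || !any(lo)) lo <- pts[, split_axis] < med
  if (all(lo) || !any(lo)) lo <- pts[, split_axis] <= min(pts[, split_axis])
  init <- rbind(colMeans(pts[lo, , drop = FALSE]),
                colMeans(pts[!lo, , drop = FALSE]))
  km <- suppressWarnings(stats::kmeans(pts, centers = init,
                                       iter.max = 100L,
                                       algorithm = "Lloyd"))
  ord <- order(km$centers[, 1L], decreasing = TRUE)
  labels <- match(km$cluster, ord)
  list(labels = labels,
       centers = unname(km$centers[ord, , drop = FALSE]))
}

#' Hierarchical divisive clustering of a test case
#'
#' Composition of [split_t_cells()] and [cluster_b_cells()]: B clusters
#' are labelled `1..k-1` and T cells `k`, matching the profile convention.
#'
#' @param points A [point3_table()] or `n x 3` matrix.
#' @param k Cluster count of the profile being fitted (2 or 3).
#' @return A `cluster_assignment`: list with `labels` (per event, in
#'   `1..k`), `centers` (`k x 3`, row `k` the T-cell center), `k`.
#' @export
assign_clusters <- function(points, k) {
  pts <- if (inherits(points, "point3_table")) points$points else
    as.matrix(points)
  stopifnot(k %in% c(2L, 3L))
  sp <- split_t_cells(pts)
  b_pts <- pts[!sp$is_t, , drop = FALSE]
  cb <- cluster_b_cells(b_pts, k - 1L)
  labels <- integer(nrow(pts))
  labels[sp$is_t] <- k
  labels[!sp$is_t] <- cb$labels
  structure(list(labels = labels,
                 centers = rbind(cb$centers, sp$t_center), k = k),
            class = "cluster_assignment")
}

#' Align a profile to a test case by its T-cell anchor
#'
#' Technical variation (operator, instrument calibration, day effects)
#' shifts a whole case rigidly in marker space. The T-cell cluster, present
#' in every case and unaffected by B-cell disease, anchors the correction:
#' all ellipsoid means are translated by
#' `delta = test T-center - profile T-center`. Covariances are unchanged.
#'
#' @param profile A `ccr_profile`.
#' @param assignment A [assign_clusters()] result for the test case.
#' @return A shifted copy of `profile`; `delta` is attached as
#'   `attr(, "delta")`.
#' @export
align_profile <- function(profile, assignment) {
  stopifnot(inherits(profile, "ccr_profile"),
            inherits(assignment, "cluster_assignment"))
  delta <- unname(assignment$centers[assignment$k, ] -
                    profile$ellipsoids[[profile$t_index]]$mean)
  profile$ellipsoids <- lapply(profile$ellipsoids, function(e) {
    e$mean <- e$mean + delta
    e
  })
  attr(profile, "delta") <- delta
  profile
}

#' B-cell capture rate of an aligned profile on a test case
#'
#' The fraction of the test case's B-labelled events falling inside at
#' least one of the profile's B-cell ellipsoids (the T-cell ellipsoid is
#' excluded: the method detects B-cell neoplasms). An event inside two
#' overlapping ellipsoids counts once, so the rate is always in \[0, 1\].
#'
#' @param profile An aligned `ccr_profile` (see [align_profile()]).
#' @param points The test case ([point3_table()] or `n x 3` matrix).
#' @param assignment The case's [assign_clusters()] result.
#' @return The capture rate, a fraction in \[0, 1\].
#' @export
compute_ccr <- function(profile, points, assignment) {
  pts <- if (inherits(points, "point3_table")) points$points else
    as.matrix(points)
  b_idx <- assignment$labels != assignment$k
  if (!any(b_idx)) stop("no B cells: capture rate undefined")
  b_pts <- pts[b_idx, , drop = FALSE]
  inside <- rep(FALSE, nrow(b_pts))
  for (c in setdiff(seq_len(profile$k), profile$t_index)) {
    inside <- inside | contains(profile$ellipsoids[[c]], b_pts)
  }
  sum(inside) / nrow(b_pts)
}

#' Mirror a profile across the kappa/lambda axis
#'
#' Reflects x to -x: ellipsoid x means are negated and the covariance
#' x row/column signs flipped. A kappa-dominant patient profile becomes
#' its lambda-dominant counterpart.
#'
#' @param profile A `ccr_profile`.
#' @return The mirrored profile.
#' @export
mirror_profile <- function(profile) {
  stopifnot(inherits(profile, "ccr_profile"))
  refl <- diag(c(-1, 1, 1))
  profile$ellipsoids <- lapply(profile$ellipsoids, function(e) {
    e$mean[1L] <- -e$mean[1L]
    e$cov <- refl %*% e$cov %*% refl
    e
  })
  if (!is.na(profile$dominance)) {
    profile$dominance <- c(kappa = "lambda", lambda = "kappa")[
      profile$dominance]
  }
  profile
}

#' Fit a test case to a cohort profile
#'
#' Full fitting pipeline: divisive T/B clustering ([assign_clusters()]),
#' T-cell-anchored alignment ([align_profile()]), and B-cell capture rate
#' ([compute_ccr()]). For a patient profile (CLL or FL) the case's clone
#' may be restricted to the opposite light chain from the training cases,
#' so the profile and its x-mirrored copy are both evaluated and the
#' larger capture rate returned.
#'
#' @param profile A `ccr_profile`.
#' @param points The test case as a [point3_table()].
#' @param details Return the full report instead of the bare rate.
#' @return The capture rate (fraction), or when `details = TRUE` a list
#'   with `case_id`, `ccr`, `delta`, `n_b`, `n_t`, `mirrored`.
#' @export
fit_case <- function(profile, points, details = FALSE) {
  stopifnot(inherits(profile, "ccr_profile"))
  asg <- assign_clusters(points, profile$k)
  aligned <- align_profile(profile, asg)
  ccr <- compute_ccr(aligned, points, asg)
  mirrored <- FALSE
  if (profile$cohort != "Normal") {
    alt <- align_profile(mirror_profile(profile), asg)
    ccr_alt <- compute_ccr(alt, points, asg)
    if (ccr_alt > ccr) {
      ccr <- ccr_alt
      aligned <- alt
      mirrored <- TRUE
    }
  }
  if (!details) return(ccr)
  list(case_id = if (inherits(points, "point3_table")) points$case_id else
         NA_character_,
       ccr = ccr, delta = unname(attr(aligned, "delta")),
       n_b = sum(asg$labels != asg$k), n_t = sum(asg$labels == asg$k),
       mirrored = mirrored)
}
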