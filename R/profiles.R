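#' Gating ellipsoid at m standard deviations
#'
#' An ellipsoid is the Mahalanobis ball of radius `m` around a component
#' mean: the set of points p with
#' `sqrt((p - mean)' solve(cov) (p - mean)) <= m`. The covariance supplies
#' the orientation and shape, `m` the size.
#'
#' @param mean Length-3 center.
#' @param cov 3x3 symmetric positive-definite covariance.
#' @param m Standard-deviation multiplier (> 0).
#' @return An `ellipsoid` object.
#' @export
ellipsoid <- function(mean, cov, m = 2) {
  mean <- as.numeric(mean)
  cov <- unname(as.matrix(cov))
  stopifnot(length(mean) == 3L, all(dim(cov) == 3L), m > 0)
  if (max(abs(cov - t(cov))) > 1e-8 * max(1, max(abs(cov)))) {
    stop("covariance must be symmetric")
  }
  cov <- (cov + t(cov)) / 2
  if (any(eigen(cov, symmetric = TRUE, only.values = TRUE)$values <= 0)) {
    stop("covariance must be positive definite")
  }
  structure(list(mean = mean, cov = cov, m = m), class = "ellipsoid")
}

#' Test whether points fall inside an ellipsoid
#'
#' Boundary inclusive: a point at Mahalanobis distance exactly `m` is
#' inside.
#'
#' @param e An [ellipsoid()].
#' @param p Length-3 point or `n x 3` matrix of points.
#' @return Logical vector, one entry per point.
#' @export
contains <- function(e, p) {
  stopifnot(inherits(e, "ellipsoid"))
  p <- if (is.matrix(p)) p else matrix(p, ncol = 3L)
  stats::mahalanobis(p, e$mean, e$cov) <= e$m^2
}

new_profile <- function(cohort, weights, ellipsoids, m, t_index,
                        dominance = NA_character_) {
  cohort <- match.arg(cohort, COHORTS)
  k <- length(ellipsoids)
  stopifnot(length(weights) == k,
            abs(sum(weights) - 1) < 1e-8, all(weights >= 0),
            t_index >= 1L, t_index <= k)
  if (cohort == "Normal" && k != 3L) stop("the Normal profile has k = 3")
  if (cohort != "Normal" && k != 2L) stop("patient profiles have k = 2")
  structure(list(cohort = cohort, k = k, m = m,
                 weights = as.numeric(weights), ellipsoids = ellipsoids,
                 t_index = as.integer(t_index),
                 dominance = dominance),
            class = "ccr_profile")
}

#' @export
print.ccr_profile <- function(x, ...) {
  cat(sprintf("%s profile: %d ellipsoids (m = %g), T-cell component %d",
              x$cohort, x$k, x$m, x$t_index))
  if (!is.na(x$dominance)) cat(", ", x$dominance, "-dominant", sep = "")
  cat("\n")
  for (c in seq_len(x$k)) {
    cat(sprintf("  [%d] w = %.3f, center = (%.2f, %.2f, %.2f)%s\n",
                c, x$weights[c], x$ellipsoids[[c]]$mean[1],
                x$ellipsoids[[c]]$mean[2], x$ellipsoids[[c]]$mean[3],
                if (c == x$t_index) "  <- T cells" else ""))
  }
  invisible(x)
}

#' Build a cohort profile from pooled training events
#'
#' Fits a `k`-component full-covariance Gaussian mixture (K-means
#' initialization, EM refinement; see [gmm_fit()]) to the pooled 3-D
#' points of a training cohort and wraps each converged component in an
#' ellipsoid of `m` standard deviations. The healthy cohort has `k = 3`
#' components (kappa-expressing B cells, lambda-expressing B cells,
#' T cells); a patient cohort has `k = 2` (the light-chain-restricted
#' clonal B population plus T cells).
#'
#' The T-cell component is the one with the lowest CD19 (y) mean, since
#' T lymphocytes lack CD19 expression. For patient profiles the B
#' component's light-chain dominance is read off the sign of its x mean:
#' kappa if positive, lambda if negative.
#'
#' @param points A [point3_table()] (typically the result of
#'   [merge_training_cases()]).
#' @param cohort Cohort label, `"Normal"`, `"CLL"`, or `"FL"`.
#' @param k Number of mixture components; defaults to 3 for Normal and 2
#'   otherwise.
#' @param m Standard-deviation multiplier for the ellipsoids (default 2).
#' @param seed Seed for the mixture fit.
#' @return A `ccr_profile` with `k` weighted ellipsoids, the T-cell
#'   component index, and (for patient profiles) the dominance label. The
#'   EM log-likelihood trace is attached as `attr(, "loglik")`.
#' @export
build_profile <- function(points, cohort, k = if (cohort == "Normal") 3L
                          else 2L, m = 2, seed = 1L) {
  stopifnot(inherits(points, "point3_table"))
  cohort <- match.arg(cohort, COHORTS)
  if (!k %in% c(2L, 3L)) stop("k must be 2 (patient) or 3 (normal)")
  n <- nrow(points$points)
  if (n < 10L * k) {
    stop("profile building needs at least 10*k = ", 10L * k,
         " events (got ", n, ")")
  }
  fit <- gmm_fit(points$points, k = k, seed = seed)
  ell <- lapply(seq_len(k), function(c) {
    ellipsoid(fit$means[c, ], fit$covs[[c]], m = m)
  })
  t_index <- which.min(fit$means[, 2L])
  dominance <- NA_character_
  if (k == 2L) {
    b_index <- setdiff(1:2, t_index)
    dominance <- if (fit$means[b_index, 1L] > 0) "kappa" else "lambda"
  }
  out <- new_profile(cohort = cohort, weights = fit$weights,
                     ellipsoids = ell, m = m, t_index = t_index,
                     dominance = dominance)
  attr(out, "loglik") <- fit$loglik
  out
}

#' Mirror patient training cases into a common light-chain orientation
#'
#' A patient cohort mixes kappa- and lambda-restricted clones, which sit on
#' opposite sides of the x (kappa - lambda) axis. Pooling them as-is would
#' hand the k = 2 mixture three clusters. Each case is therefore reflected
#' (x to -x) when its B-cluster center lies on the lambda side of its own
#' T-cluster center, so every training case presents a kappa-oriented
#' clone; the opposite orientation is recovered at test time by the
#' mirror-and-take-max rule of [fit_case()]. The T-relative comparison
#' makes the decision insensitive to global intensity shifts.
#'
#' @param cases List of patient [point3_table()] cases.
#' @return The list with lambda-oriented cases mirrored.
#' @export
canonicalize_dominance <- function(cases) {
  lapply(cases, function(p) {
    sp <- split_t_cells(p)
    cb <- cluster_b_cells(p$points[!sp$is_t, , drop = FALSE], 1L)
    if (cb$centers[1L, 1L] < sp$t_center[1L]) {
      p$points[, 1L] <- -p$points[, 1L]
    }
    p
  })
}

#' Pool the events of several training cases
#'
#' Row-concatenates the 3-D points of all cases; per-event case provenance
#' is kept in the `source` attribute.
#'
#' @param cases List of [point3_table()] objects.
#' @return A single [point3_table()] with the pooled events.
#' @export
merge_training_cases <- function(cases) {
  if (!length(cases)) stop("no training cases to merge")
  stopifnot(all(vapply(cases, inherits, TRUE, "point3_table")))
  pts <- do.call(rbind, lapply(cases, function(p) p$points))
  ids <- vapply(cases, function(p) p$case_id, "")
  cohort <- unique(vapply(cases, function(p) p$cohort, ""))
  cohort <- if (length(cohort) == 1L) cohort else "Unknown"
  out <- point3_table(pts, case_id = paste(ids, collapse = "+"),
                      cohort = cohort)
  attr(out, "source") <- rep(ids, vapply(cases,
                                         function(p) nrow(p$points), 1L))
  out
}
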