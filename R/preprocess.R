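#' Remove doublets by the FSC-A/FSC-H ratio
#'
#' A doublet (two cells measured as one event) has a disproportionately
#' large forward-scatter area relative to its height. Events are kept when
#' their FSC-A/FSC-H ratio lies in the band
#' `[med * (1 - tol), med * (1 + tol)]` around the case median ratio `med` —
#' a robust singlet gate, since singlets dominate and share a common ratio.
#'
#' @param table An [event_table()] with FSC-A and FSC-H channels.
#' @param ratio_tolerance Half-width of the relative ratio band
#'   (default 0.3).
#' @return The filtered `event_table`; the number of events removed is
#'   available as `attr(, "n_removed")`.
#' @export
remove_doublets <- function(table, ratio_tolerance = 0.3) {
  stopifnot(inherits(table, "event_table"), ratio_tolerance > 0)
  fsc_a <- channel_values(table, "FSC-A")
  fsc_h <- channel_values(table, "FSC-H")
  ok_h <- fsc_h > 0
  ratio <- ifelse(ok_h, fsc_a / fsc_h, Inf)
  med <- stats::median(ratio[ok_h])
  keep <- ok_h & ratio >= med * (1 - ratio_tolerance) &
    ratio <= med * (1 + ratio_tolerance)
  if (!any(keep)) {
    stop("doublet filter removed every event in case '", table$case_id, "'")
  }
  out <- table[keep]
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Gate lymphocytes on CD45 and side scatter
#'
#' Replaces the manual CD45/SSC-A gate with a two-component Gaussian
#' mixture on (CD45, SSC-A). Lymphocytes are the component with the higher
#' CD45 mean (ties broken by the lower SSC-A mean); events assigned to that
#' component and lying within Mahalanobis distance 3 of its center are
#' retained. `bypass = TRUE` returns the input unchanged, for data already
#' gated upstream.
#'
#' @param table An [event_table()] with CD45 and SSC-A channels.
#' @param bypass Skip gating (input already pure lymphocytes).
#' @param min_events Minimum events required to fit the mixture.
#' @param seed Seed for the mixture fit.
#' @return The gated `event_table`.
#' @export
gate_lymphocytes <- function(table, bypass = FALSE, min_events = 50L,
                             seed = 1L) {
  stopifnot(inherits(table, "event_table"))
  if (bypass) return(table)
  if (n_events(table) < min_events) {
    stop("lymphocyte gating needs at least ", min_events,
         " events (got ", n_events(table), "); ",
         "use bypass = TRUE for pre-gated input")
  }
  x <- cbind(channel_values(table, "CD45"), channel_values(table, "SSC-A"))
  fit <- tryCatch(gmm_fit(x, k = 2L, seed = seed), error = function(e) {
    stop("lymphocyte gate mixture failed (", conditionMessage(e),
         "); if the input is already gated, use bypass = TRUE")
  })
  lymph <- which.max(fit$means[, 1L] - 1e-9 * fit$means[, 2L])
  d2 <- stats::mahalanobis(x, fit$means[lymph, ], fit$covs[[lymph]])
  keep <- fit$labels == lymph & d2 <= 9
  if (!any(keep)) stop("lymphocyte gate retained no events")
  table[keep]
}

#' 3-D point table in the five-marker projection
#'
#' Container for a case's events after projection to the 3-D axes
#' x = kappa - lambda, y = CD19, z = CD5 - CD10.
#'
#' @param points Numeric `n x 3` matrix.
#' @param case_id Case identifier.
#' @param cohort Cohort label.
#' @param truth Optional per-event ground-truth data.frame.
#' @return A `point3_table` object.
#' @export
point3_table <- function(points, case_id = "case", cohort = "Unknown",
                         truth = NULL) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  stopifnot(ncol(points) == 3L, nrow(points) >= 1L)
  if (!all(is.finite(points))) stop("points must be finite")
  colnames(points) <- c("x", "y", "z")
  structure(list(case_id = as.character(case_id),
                 cohort = match.arg(cohort, c(COHORTS, "Unknown")),
                 points = points, truth = truth),
            class = "point3_table")
}

#' @export
print.point3_table <- function(x, ...) {
  cat(sprintf("point3_table '%s' (%s): %d events\n",
              x$case_id, x$cohort, nrow(x$points)))
  invisible(x)
}

#' Project events into the 3-D five-marker space
#'
#' Because a B cell expresses either kappa or lambda light chain (never
#' both), and a lymphoma is CD5+ or CD10+ (not both), subtracting the
#' paired markers cancels background signal: x = kappa - lambda,
#' y = CD19, z = CD5 - CD10. A kappa-restricted cell maps to x > 0, a
#' lambda-restricted cell to x < 0; CD5+ maps to z > 0, CD10+ to z < 0.
#'
#' @param table An [event_table()] with CD5, CD10, CD19, kappa, lambda.
#' @param asinh_cofactor Optional cofactor `b`; when given, each of the five
#'   fluorescence channels is transformed to `asinh(value / b)` before
#'   differencing (the usual variance-stabilizing scale for cytometry).
#'   `NULL` (default) models on the instrument scale.
#' @return A [point3_table()]; event order preserved.
#' @export
to_point3 <- function(table, asinh_cofactor = NULL) {
  stopifnot(inherits(table, "event_table"))
  ch <- lapply(c("kappa", "lambda", "CD19", "CD5", "CD10"),
               function(nm) channel_values(table, nm))
  names(ch) <- c("kappa", "lambda", "CD19", "CD5", "CD10")
  if (!is.null(asinh_cofactor)) {
    stopifnot(asinh_cofactor > 0)
    ch <- lapply(ch, function(v) asinh(v / asinh_cofactor))
  }
  pts <- cbind(x = ch$kappa - ch$lambda,
               y = ch$CD19,
               z = ch$CD5 - ch$CD10)
  point3_table(pts, case_id = table$case_id, cohort = table$cohort,
               truth = table$truth)
}

#' Standard preprocessing pipeline for one case
#'
#' Doublet removal, lymphocyte gating, and projection to the 3-D space, in
#' that order.
#'
#' @param table An [event_table()].
#' @param ratio_tolerance Doublet ratio band half-width.
#' @param bypass_gate Skip the lymphocyte gate.
#' @param asinh_cofactor See [to_point3()].
#' @param seed Seed for the gate mixture fit.
#' @return A [point3_table()].
#' @export
preprocess_case <- function(table, ratio_tolerance = 0.3,
                            bypass_gate = FALSE, asinh_cofactor = NULL,
                            seed = 1L) {
  table <- remove_doublets(table, ratio_tolerance)
  table <- gate_lymphocytes(table, bypass = bypass_gate, seed = seed)
  to_point3(table, asinh_cofactor = asinh_cofactor)
}
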