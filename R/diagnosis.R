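#' Diagnose a case from its three capture rates
#'
#' A test case yields a vector of capture rates (CCR_Normal, CCR_CLL,
#' CCR_FL). A case matching one cohort has a high rate on that profile and
#' low rates on the others, so it lies near that cohort's axis in CCR
#' space. The distance from the vector to axis i is
#' `d_i = sqrt(sum_{j != i} CCR_j^2)`, and the diagnosis is the axis with
#' the smallest distance. An exact tie among the minimizers is reported as
#' `Inconclusive` rather than silently preferring one label.
#'
#' @param ccr Named or unnamed numeric vector of the three capture rates,
#'   in the order Normal, CLL, FL; each in \[0, 1\].
#' @return A `ccr_diagnosis`: list with `label` (one of `"Normal"`,
#'   `"CLL"`, `"FL"`, `"Inconclusive"`), `distances` (named, per axis),
#'   and the input `ccr`.
#' @examples
#' diagnose(c(Normal = 0.8, CLL = 0.1, FL = 0.1))
#' @export
diagnose <- function(ccr) {
  ccr <- as.numeric(ccr)
  stopifnot(length(ccr) == 3L, all(is.finite(ccr)),
            all(ccr >= 0), all(ccr <= 1))
  names(ccr) <- COHORTS
  d <- vapply(seq_len(3L),
              function(i) sqrt(sum(ccr[-i]^2)), numeric(1))
  names(d) <- COHORTS
  minimizers <- which(d == min(d))
  label <- if (length(minimizers) == 1L) COHORTS[minimizers] else
    "Inconclusive"
  structure(list(label = label, distances = d, ccr = ccr),
            class = "ccr_diagnosis")
}

#' @export
print.ccr_diagnosis <- function(x, ...) {
  cat(sprintf("diagnosis: %s\n", x$label))
  cat(sprintf("  CCR = (%.3f, %.3f, %.3f), d = (%.3f, %.3f, %.3f)\n",
              x$ccr[1], x$ccr[2], x$ccr[3],
              x$distances[1], x$distances[2], x$distances[3]))
  invisible(x)
}
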