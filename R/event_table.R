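#' Channel map: semantic marker names to instrument channel names
#'
#' A case file names its columns after instrument detectors (for example
#' `"FITC-A"`); the model works with nine semantic channels: `FSC-A`,
#' `FSC-H`, `SSC-A`, `CD45`, `CD5`, `CD10`, `CD19`, `kappa`, `lambda`.
#' A channel map resolves each semantic name to the instrument name carrying
#' it.
#'
#' @param ... Named entries `semantic = "instrument"`. Semantic names not
#'   supplied default to the identity mapping.
#' @return A named character vector of length 9 (class `channel_map`):
#'   names are semantic channels, values instrument channel names.
#' @examples
#' channel_map(kappa = "PE-A", lambda = "FITC-A", CD19 = "APC-Cy7-A")
#' @export
channel_map <- function(...) {
  entries <- c(...)
  map <- stats::setNames(SEMANTIC_CHANNELS, SEMANTIC_CHANNELS)
  if (length(entries)) {
    if (is.null(names(entries)) || any(!nzchar(names(entries)))) {
      stop("channel_map() entries must be named semantic = \"instrument\"")
    }
    unknown <- setdiff(names(entries), SEMANTIC_CHANNELS)
    if (length(unknown)) {
      stop("unknown semantic channel(s): ", paste(unknown, collapse = ", "))
    }
    map[names(entries)] <- entries
  }
  if (anyDuplicated(map)) {
    stop("instrument channel names must be unique")
  }
  structure(map, class = "channel_map")
}

#' Flow cytometry event table
#'
#' One case's events in rows, channels in columns. After channel mapping the
#' columns carry the nine semantic names. Synthetic cases additionally carry
#' per-event ground-truth labels in the `truth` attribute.
#'
#' @param exprs Numeric matrix, events x channels, with column names.
#' @param case_id Case identifier.
#' @param cohort One of `"Normal"`, `"CLL"`, `"FL"`, `"Unknown"`.
#' @param truth Optional data.frame of per-event ground-truth annotations
#'   (same number of rows as `exprs`).
#' @return An `event_table` object.
#' @export
event_table <- function(exprs, case_id = "case", cohort = "Unknown",
                        truth = NULL) {
  exprs <- as.matrix(exprs)
  storage.mode(exprs) <- "double"
  if (nrow(exprs) < 1L) stop("an event table needs at least one event")
  if (is.null(colnames(exprs)) || any(!nzchar(colnames(exprs)))) {
    stop("all channels must be named")
  }
  if (anyNA(exprs)) stop("event data must not contain missing values")
  cohort <- match.arg(cohort, c(COHORTS, "Unknown"))
  if (!is.null(truth)) {
    stopifnot(is.data.frame(truth), nrow(truth) == nrow(exprs))
  }
  structure(
    list(case_id = as.character(case_id), cohort = cohort,
         exprs = exprs, truth = truth),
    class = "event_table"
  )
}

#' @export
print.event_table <- function(x, ...) {
  cat(sprintf("event_table '%s' (%s): %d events x %d channels\n",
              x$case_id, x$cohort, nrow(x$exprs), ncol(x$exprs)))
  cat("channels:", paste(colnames(x$exprs), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.event_table <- function(x) dim(x$exprs)

#' Subset events of an event table
#'
#' Row subsetting keeps the ground-truth annotations aligned.
#'
#' @param x An `event_table`.
#' @param i Row (event) index.
#' @param ... Ignored.
#' @return An `event_table` with the selected events.
#' @export
`[.event_table` <- function(x, i, ...) {
  x$exprs <- x$exprs[i, , drop = FALSE]
  if (!is.null(x$truth)) x$truth <- x$truth[i, , drop = FALSE]
  if (nrow(x$exprs) < 1L) stop("subset removed all events")
  x
}

#' Number of events in an event table
#' @param x An `event_table`.
#' @return Integer event count.
#' @export
n_events <- function(x) {
  stopifnot(inherits(x, "event_table"))
  nrow(x$exprs)
}

# Pull one semantic channel as a numeric vector; errors name the channel.
channel_values <- function(table, channel) {
  idx <- match(channel, colnames(table$exprs))
  if (is.na(idx)) {
    stop(sprintf("channel '%s' not present in case '%s'",
                 channel, table$case_id))
  }
  table$exprs[, idx]
}
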