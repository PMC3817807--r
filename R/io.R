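#' Read one case of flow cytometry events
#'
#' Accepts either an FCS 3.0/3.1 file (list-mode, 32-bit float data, the
#' standard export of modern cytometers) or a delimited text table with a
#' header row. Instrument channel names are resolved to the nine semantic
#' channels through `map`; every semantic channel must resolve or the
#' unresolved names are reported.
#'
#' @param path Path to an FCS file or a comma/tab-delimited table.
#' @param map A [channel_map()]. Defaults to the identity mapping.
#' @param case_id Case identifier; defaults to the file name.
#' @param cohort Cohort label, `"Unknown"` unless stated.
#' @return An [event_table()] whose columns are the nine semantic channels,
#'   event order preserved.
#' @export
read_case <- function(path, map = channel_map(), case_id = NULL,
                      cohort = "Unknown") {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  case_id <- case_id %||% basename(path)
  raw6 <- readBin(path, "raw", n = 6L)
  is_fcs <- length(raw6) == 6L &&
    rawToChar(raw6) %in% c("FCS3.0", "FCS3.1")
  exprs <- if (is_fcs) read_fcs_matrix(path) else read_delim_matrix(path)
  instrument <- colnames(exprs)
  idx <- match(unclass(map), instrument)
  missing <- names(map)[is.na(idx)]
  if (length(missing)) {
    stop("unresolved semantic channel(s): ", paste(missing, collapse = ", "))
  }
  out <- exprs[, idx, drop = FALSE]
  colnames(out) <- names(map)
  event_table(out, case_id = case_id, cohort = cohort)
}

#' Write one case of flow cytometry events
#'
#' Writes FCS 3.0 (32-bit float, list mode) when `path` ends in `.fcs`,
#' otherwise a comma-delimited table with a header row. Either form is
#' read back losslessly by [read_case()] (delimited: exact; FCS: to 32-bit
#' float precision).
#'
#' @param table An [event_table()].
#' @param path Destination path.
#' @param map Optional [channel_map()]; when given, columns are written under
#'   their instrument names.
#' @return `path`, invisibly.
#' @export
write_case <- function(table, path, map = NULL) {
  stopifnot(inherits(table, "event_table"))
  exprs <- table$exprs
  if (!is.null(map)) {
    idx <- match(colnames(exprs), names(map))
    colnames(exprs)[!is.na(idx)] <- unclass(map)[idx[!is.na(idx)]]
  }
  if (any(!nzchar(colnames(exprs)))) stop("empty channel name")
  if (grepl("\\.fcs$", path, ignore.case = TRUE)) {
    write_fcs_matrix(exprs, path)
  } else {
    utils::write.csv(as.data.frame(exprs), path, row.names = FALSE)
  }
  invisible(path)
}

read_delim_matrix <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE)
  if (!nrow(df)) stop("'", path, "' contains no events")
  as.matrix(df)
}

# --- minimal FCS 3.0 support ------------------------------------------------
# List-mode, $DATATYPE F (32-bit float) only: enough for channel/event
# fidelity; keyword-level fidelity is out of scope.

fcs_header_offsets <- function(con) {
  hdr <- readBin(con, "raw", n = 58L)
  if (length(hdr) < 58L) stop("truncated FCS header")
  txt <- rawToChar(hdr)
  version <- substr(txt, 1L, 6L)
  if (!version %in% c("FCS3.0", "FCS3.1")) {
    stop("unsupported FCS version '", version, "'")
  }
  field <- function(i) {
    as.numeric(trimws(substr(txt, 11L + (i - 1L) * 8L, 10L + i * 8L)))
  }
  list(text_start = field(1), text_end = field(2),
       data_start = field(3), data_end = field(4))
}

read_fcs_matrix <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  off <- fcs_header_offsets(con)
  seek(con, off$text_start)
  text <- rawToChar(readBin(con, "raw", n = off$text_end - off$text_start + 1))
  delim <- substr(text, 1L, 1L)
  parts <- strsplit(substring(text, 2L), delim, fixed = TRUE)[[1]]
  if (length(parts) < 2L) stop("malformed FCS TEXT segment")
  keys <- toupper(parts[seq(1L, length(parts) - 1L, by = 2L)])
  vals <- parts[seq(2L, length(parts), by = 2L)]
  kw <- stats::setNames(vals, keys)
  if ((kw["$DATATYPE"] %||% "") != "F") {
    stop("only $DATATYPE F (float) FCS data is supported")
  }
  if (!is.na(kw["$MODE"]) && kw["$MODE"] != "L") {
    stop("only list-mode ($MODE L) FCS data is supported")
  }
  endian <- switch(kw[["$BYTEORD"]],
                   "1,2,3,4" = "little", "4,3,2,1" = "big",
                   stop("unsupported $BYTEORD '", kw[["$BYTEORD"]], "'"))
  p <- as.integer(kw[["$PAR"]])
  n <- as.integer(kw[["$TOT"]])
  data_start <- off$data_start
  if (is.na(data_start) || data_start == 0) {
    data_start <- as.numeric(kw[["$BEGINDATA"]])
  }
  seek(con, data_start)
  vals <- readBin(con, "numeric", n = n * p, size = 4L, endian = endian)
  if (length(vals) < n * p) stop("truncated FCS data segment")
  ch <- vapply(seq_len(p), function(i) kw[[paste0("$P", i, "N")]], "")
  matrix(vals, nrow = n, ncol = p, byrow = TRUE,
         dimnames = list(NULL, ch))
}

write_fcs_matrix <- function(exprs, path) {
  n <- nrow(exprs)
  p <- ncol(exprs)
  kw <- c("$DATATYPE", "F", "$MODE", "L", "$BYTEORD", "1,2,3,4",
          "$NEXTDATA", "0", "$TOT", as.character(n), "$PAR", as.character(p))
  for (i in seq_len(p)) {
    kw <- c(kw, paste0("$P", i, "N"), colnames(exprs)[i],
            paste0("$P", i, "B"), "32", paste0("$P", i, "E"), "0,0",
            paste0("$P", i, "R"), "262144")
  }
  # fixed-width (10-digit) data offsets so the TEXT length is known
  # before the offsets themselves are
  kw <- c(kw, "$BEGINDATA", "0000000000", "$ENDDATA", "0000000000")
  text <- paste0("/", paste(kw, collapse = "/"), "/")
  text_start <- 58L
  text_end <- text_start + nchar(text) - 1L
  data_start <- text_start + nchar(text)
  data_end <- data_start + 4L * n * p - 1L
  text <- sub("0000000000", sprintf("%010d", data_start), text,
              fixed = TRUE)
  text <- sub("0000000000", sprintf("%010d", data_end), text,
              fixed = TRUE)
  header <- sprintf("FCS3.0    %8d%8d%8d%8d%8d%8d",
                    text_start, text_end, data_start, data_end, 0L, 0L)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(header), con)
  writeBin(charToRaw(text), con)
  writeBin(as.vector(t(exprs)), con, size = 4L, endian = "little")
  invisible(path)
}

# --- profile serialization --------------------------------------------------

PROFILE_SCHEMA <- "flowccr-profile/1"

#' Save a cohort profile to a versioned JSON document
#'
#' Serialization is plain text and lossless: weights, means, covariances,
#' the standard-deviation multiplier `m`, the T-cell component index, and
#' the light-chain dominance label all round-trip exactly.
#'
#' @param profile A [build_profile()] result.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
save_profile <- function(profile, path) {
  stopifnot(inherits(profile, "ccr_profile"))
  # numbers are written with 17 significant digits so every double
  # round-trips bit-exactly through the decimal representation
  num <- function(v) sprintf("%.17g", v)
  arr <- function(v) paste0("[", paste(num(v), collapse = ","), "]")
  mat <- function(s) {
    paste0("[", paste(apply(s, 1L, arr), collapse = ","), "]")
  }
  ell <- vapply(profile$ellipsoids, function(e) {
    paste0("{\"mean\":", arr(e$mean), ",\"cov\":", mat(e$cov), "}")
  }, "")
  dominance <- if (is.na(profile$dominance)) "null" else
    paste0("\"", profile$dominance, "\"")
  doc <- paste0(
    "{\"schema\":\"", PROFILE_SCHEMA, "\",",
    "\"cohort\":\"", profile$cohort, "\",",
    "\"k\":", profile$k, ",",
    "\"m\":", num(profile$m), ",",
    "\"weights\":", arr(profile$weights), ",",
    "\"t_index\":", profile$t_index, ",",
    "\"dominance\":", dominance, ",",
    "\"ellipsoids\":[", paste(ell, collapse = ","), "]}")
  writeLines(doc, path)
  invisible(path)
}

#' Load a cohort profile saved by [save_profile()]
#'
#' @param path Path to a profile JSON document.
#' @return A `ccr_profile` object.
#' @export
load_profile <- function(path) {
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyDataFrame = FALSE),
                  error = function(e) {
                    stop("cannot parse profile document '", path, "': ",
                         conditionMessage(e))
                  })
  if (!identical(doc$schema, PROFILE_SCHEMA)) {
    stop("profile schema mismatch: expected '", PROFILE_SCHEMA,
         "', found '", doc$schema %||% "<none>", "'")
  }
  ell <- lapply(doc$ellipsoids, function(e) {
    cv <- e$cov
    if (is.list(cv)) cv <- do.call(rbind, lapply(cv, unlist))
    ellipsoid(mean = unlist(e$mean), cov = cv, m = doc$m)
  })
  dominance <- doc$dominance
  if (is.null(dominance) || is.na(dominance)) dominance <- NA_character_
  new_profile(cohort = doc$cohort, weights = unlist(doc$weights),
              ellipsoids = ell, m = doc$m, t_index = doc$t_index,
              dominance = dominance)
}
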