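#' Recording file dialect
#'
#' Recordings are stored as delimited text with one skeleton frame per row and
#' 31 numeric fields: time, then three coordinates per joint. Because
#' different capture programs order columns and choose units differently, the
#' reader is parameterized by a small dialect description.
#'
#' @param columns Character vector naming the 31 fields in on-disk order.
#'   Defaults to `t`, then each joint of [fma_joints()] as `.x`, `.y`, `.z`.
#' @param delimiter Field delimiter: `"auto"` (detect comma vs whitespace per
#'   file), `","`, or `"whitespace"`.
#' @param units Length unit of coordinates on disk, `"m"` or `"mm"`;
#'   positions are always meters in memory.
#' @param time_units `"s"` or `"ms"`.
#' @return A list of class `recording_dialect`.
#' @export
recording_dialect <- function(columns = recording_columns(),
                              delimiter = c("auto", ",", "whitespace"),
                              units = c("m", "mm"),
                              time_units = c("s", "ms")) {
  delimiter <- match.arg(delimiter)
  units <- match.arg(units)
  time_units <- match.arg(time_units)
  if (length(columns) != 31L || anyDuplicated(columns) ||
      !setequal(columns, recording_columns())) {
    stop("dialect columns must be a permutation of the 31 standard fields")
  }
  structure(list(columns = columns, delimiter = delimiter, units = units,
                 time_units = time_units),
            class = "recording_dialect")
}

#' Read a skeletal motion recording from delimited text
#'
#' Parses a 31-column text recording (see [recording_dialect()]). Metadata may
#' be given in `#`-prefixed header lines (`# subject=S01`, `# side=left`,
#' `# item=elbow_flexion`) or supplied via arguments, which take precedence.
#'
#' @param path Path to the text file.
#' @param dialect A [recording_dialect()].
#' @param subject_id,side,item Optional metadata overriding file headers.
#' @param frame_rate Nominal rate in Hz; defaults to a `# frame_rate=` header
#'   or, failing that, the median frame interval.
#' @return A [motion_recording()].
#' @export
read_recording <- function(path, dialect = recording_dialect(),
                           subject_id = NULL, side = NULL, item = NULL,
                           frame_rate = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  is_header <- startsWith(trimws(lines), "#")
  meta <- parse_header_meta(lines[is_header])
  data_lines <- lines[!is_header]
  if (length(data_lines) == 0L) {
    stop("parse error in ", path, ": empty file, 0 frames found")
  }
  delim <- dialect$delimiter
  if (delim == "auto") {
    delim <- if (grepl(",", data_lines[1L], fixed = TRUE)) "," else "whitespace"
  }
  split_re <- if (delim == ",") "\\s*,\\s*" else "\\s+"
  fields <- strsplit(trimws(data_lines), split_re)
  nf <- lengths(fields)
  if (any(nf != 31L)) {
    bad <- which(nf != 31L)[1L]
    stop("parse error in ", path, " line ", which(!is_header)[bad],
         ": expected 31 fields, found ", nf[bad])
  }
  vals <- suppressWarnings(vapply(fields, as.numeric, numeric(31)))
  if (anyNA(vals)) {
    bad <- which(apply(vals, 2L, anyNA))[1L]
    stop("parse error in ", path, " line ", which(!is_header)[bad],
         ": non-numeric field")
  }
  frames <- as.data.frame(t(vals))
  names(frames) <- dialect$columns
  frames <- frames[, recording_columns()]
  if (dialect$units == "mm") frames[, -1L] <- frames[, -1L] / 1000
  if (dialect$time_units == "ms") frames$t <- frames$t / 1000
  fr <- frame_rate %||% meta$frame_rate %||%
    (1 / stats::median(diff(frames$t)))
  motion_recording(frames,
                   subject_id = subject_id %||% meta$subject %||% "unknown",
                   side = side %||% meta$side %||% "left",
                   item = item %||% meta$item %||% fma_items()[1L],
                   frame_rate = fr)
}

parse_header_meta <- function(header_lines) {
  meta <- list()
  for (ln in header_lines) {
    ln <- sub("^\\s*#\\s*", "", ln)
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(kv) == 2L) meta[[trimws(kv[1L])]] <- trimws(kv[2L])
  }
  if (!is.null(meta$frame_rate)) meta$frame_rate <- as.numeric(meta$frame_rate)
  meta
}

#' Write a motion recording to delimited text
#'
#' Inverse of [read_recording()]: emits `#` metadata headers followed by one
#' 31-field row per frame. Round-trips losslessly at the written precision.
#'
#' @param rec A valid [motion_recording()].
#' @param path Output file path.
#' @param dialect A [recording_dialect()]; the column order and delimiter to
#'   emit (`"auto"` means whitespace).
#' @param digits Significant digits written (default 17: exact for doubles).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, dialect = recording_dialect(),
                            digits = 17L) {
  stopifnot(inherits(rec, "motion_recording"))
  if (!all(is.finite(as.matrix(rec$frames)))) {
    stop("recording contains non-finite values; refusing to write")
  }
  frames <- rec$frames[, dialect$columns]
  if (dialect$units == "mm") frames[, dialect$columns != "t"] <-
      frames[, dialect$columns != "t"] * 1000
  if (dialect$time_units == "ms") frames$t <- frames$t * 1000
  sep <- if (dialect$delimiter == ",") "," else " "
  header <- c(paste0("# subject=", rec$subject_id),
              paste0("# side=", rec$side),
              paste0("# item=", rec$item),
              paste0("# frame_rate=", format(rec$frame_rate, digits = digits)))
  body <- apply(frames, 1L, function(r)
    paste(formatC(r, digits = digits, format = "g"), collapse = sep))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
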