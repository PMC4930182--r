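#' Assemble and validate a cohort score table
#'
#' One row per assessed arm: the therapist's 13 item scores (0/1/2), the
#' 13-item sum (0--26), the full 33-item upper-extremity total (0--66), the
#' Brunnstrom arm stage (1--6) and whether the arm is the hemiplegic side.
#' Rows violating the scale invariants are reported in `$issues`, never
#' silently dropped.
#'
#' @param df data.frame with columns `subject_id`, `hemiplegic_side`
#'   (`"left"`/`"right"`), `brunnstrom_stage`, `total_33`, and one
#'   `score_<item>` column per [fma_items()] member; an optional `sum_13`
#'   column is cross-checked against the recomputed item sum.
#' @return Object of class `cohort_table`: list with `$data` (the table, with
#'   `sum_13` recomputed) and `$issues` (data.frame of row/field/message).
#' @export
cohort_table <- function(df) {
  df <- as.data.frame(df)
  score_cols <- paste0("score_", fma_items())
  required <- c("subject_id", "hemiplegic_side", "brunnstrom_stage",
                "total_33", score_cols)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("cohort table schema error; missing columns: ",
         paste(missing, collapse = ", "))
  }
  issues <- list()
  flag <- function(row, field, msg) {
    issues[[length(issues) + 1L]] <<- data.frame(
      row = row, field = field, message = msg)
  }
  for (i in seq_len(nrow(df))) {
    sc <- as.numeric(df[i, score_cols])
    bad <- which(!(sc %in% 0:2))
    for (b in bad) flag(i, score_cols[b],
                        paste0("item score ", sc[b], " outside {0,1,2}"))
    s13 <- sum(sc[sc %in% 0:2])
    if ("sum_13" %in% names(df) && !is.na(df$sum_13[i]) &&
        df$sum_13[i] != s13) {
      flag(i, "sum_13", paste0("stored sum ", df$sum_13[i],
                               " != recomputed ", s13))
    }
    if (!(df$brunnstrom_stage[i] %in% 1:6)) {
      flag(i, "brunnstrom_stage", "stage outside 1..6")
    }
    if (!is.na(df$total_33[i]) &&
        (df$total_33[i] < 0 || df$total_33[i] > FMA_UE_TOTAL_MAX)) {
      flag(i, "total_33", paste0("total outside [0, ", FMA_UE_TOTAL_MAX, "]"))
    }
    if (!(df$hemiplegic_side[i] %in% c("left", "right"))) {
      flag(i, "hemiplegic_side", "must be 'left' or 'right'")
    }
  }
  m <- as.matrix(df[score_cols])
  storage.mode(m) <- "double"
  df$sum_13 <- rowSums(m)
  structure(list(data = df,
                 issues = if (length(issues)) do.call(rbind, issues)
                          else data.frame(row = integer(), field = character(),
                                          message = character())),
            class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("<cohort_table> %d arms, %d validation issue(s)\n",
              nrow(x$data), nrow(x$issues)))
  invisible(x)
}

#' Read a cohort score table from CSV or XLSX
#'
#' @param path Path to a `.csv` (or any delimited text readable by
#'   [utils::read.csv()]) or `.xlsx` file.
#' @param column_map Named character vector mapping canonical column names
#'   (see [cohort_table()]) to the names used in the file, for tables whose
#'   headers differ from the canonical ones.
#' @return A [cohort_table()].
#' @export
read_cohort <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop("reading .xlsx cohort tables requires the 'readxl' package")
    }
    as.data.frame(readxl::read_excel(path))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      if (!column_map[[canon]] %in% names(df)) {
        stop("column_map refers to absent column: ", column_map[[canon]])
      }
      names(df)[names(df) == column_map[[canon]]] <- canon
    }
  }
  cohort_table(df)
}

#' Write a cohort table to CSV
#' @param cohort A [cohort_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort_table"))
  utils::write.csv(cohort$data, path, row.names = FALSE)
  invisible(path)
}
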