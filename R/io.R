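# File input: wide (matrix) and long (paired ratings) CSV/TSV dialects.

#' Read a rating table from CSV/TSV
#'
#' Two dialects are supported and auto-detected by shape:
#' \describe{
#'   \item{wide}{first row = rater-B category labels, first column =
#'     rater-A category labels, cells = non-negative integer counts;}
#'   \item{long}{columns `subject_id`, `rater_a`, `rater_b`, one row per
#'     subject (routed through [build_table()]).}
#' }
#' Tab-separated files are recognised by a `.tsv`/`.tab` extension or by
#' tabs in the header line.
#'
#' @param path Path to the file.
#' @param dialect `"auto"` (default), `"wide"` or `"long"`.
#' @param scale Optional [rating_scale()]; inferred from the file when
#'   absent (wide: header order; long: sorted observed labels), assumed
#'   ordinal.
#' @param rater_names Length-2 character vector of rater identifiers.
#' @return A [contingency_table()].
#' @export
read_rating_table <- function(path, dialect = c("auto", "wide", "long"),
                              scale = NULL,
                              rater_names = c("rater A", "rater B")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L)
    stop(sprintf("empty file: %s", path), call. = FALSE)
  sep <- if (grepl("\t", first) ||
             grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character", row.names = NULL)
  if (nrow(df) == 0L)
    stop(sprintf("no data rows in %s", path), call. = FALSE)

  if (dialect == "auto") {
    long_names <- c("rater_a", "rater_b")
    dialect <- if (all(long_names %in% names(df))) "long"
               else if (ncol(df) == nrow(df) + 1L) "wide"
               else if (ncol(df) == 3L) "long"
               else "wide"
  }

  if (dialect == "long") {
    need <- c("rater_a", "rater_b")
    if (!all(need %in% names(df))) {
      if (ncol(df) == 3L) {
        names(df) <- c("subject_id", "rater_a", "rater_b")
      } else {
        stop(sprintf(
          "long dialect needs columns subject_id, rater_a, rater_b; %s has: %s",
          path, paste(names(df), collapse = ", ")), call. = FALSE)
      }
    }
    if (is.null(scale))
      scale <- rating_scale(sort(unique(c(df$rater_a, df$rater_b))))
    r <- paired_ratings(df$rater_a, df$rater_b,
                        subject = if ("subject_id" %in% names(df))
                          df$subject_id else NULL)
    return(build_table(r, scale, rater_names = rater_names))
  }

  # wide: first column = row labels, remaining columns = counts
  row_labels <- df[[1L]]
  body <- df[, -1L, drop = FALSE]
  if (ncol(body) != nrow(body))
    stop(sprintf("wide table in %s must be square, got %d rows x %d count columns",
                 path, nrow(body), ncol(body)), call. = FALSE)
  col_labels <- names(body)
  if (!setequal(row_labels, col_labels))
    stop(sprintf("inconsistent labels in %s: rows (%s) vs columns (%s)",
                 path, paste(row_labels, collapse = ","),
                 paste(col_labels, collapse = ",")), call. = FALSE)
  counts <- suppressWarnings(
    matrix(as.numeric(as.matrix(body)), nrow(body), ncol(body)))
  if (any(is.na(counts)))
    stop(sprintf("non-numeric count cell in %s", path), call. = FALSE)
  if (any(counts < 0) || any(abs(counts - round(counts)) > 1e-8))
    stop(sprintf("counts in %s must be non-negative integers", path),
         call. = FALSE)
  dimnames(counts) <- list(row_labels, col_labels)
  counts <- counts[, row_labels, drop = FALSE]  # align columns to row order
  if (is.null(scale)) scale <- rating_scale(row_labels)
  contingency_table(counts, scale = scale, rater_names = rater_names)
}

#' Write paired ratings to a long-format CSV
#'
#' @param ratings A [paired_ratings()] data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ratings_csv <- function(ratings, path) {
  utils::write.csv(as.data.frame(ratings)[, c("subject_id", "rater_a",
                                              "rater_b")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
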