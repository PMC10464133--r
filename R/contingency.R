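#' Paired two-rater ratings
#'
#' Bundles subject-level ratings by two raters into a validated long-format
#' container, the unit of resampling for the subject bootstrap.
#'
#' @param rater_a,rater_b Vectors of category labels (one element per
#'   subject) assigned by rater A and rater B.
#' @param subject Optional subject identifiers; defaults to `1:n`.
#' @return An object of class `"paired_ratings"`: a data frame with columns
#'   `subject_id`, `rater_a`, `rater_b`.
#' @examples
#' paired_ratings(c("PR", "SD", "SD"), c("PR", "SD", "PD"))
#' @export
paired_ratings <- function(rater_a, rater_b, subject = NULL) {
  if (length(rater_a) != length(rater_b))
    stop("rater_a and rater_b must have the same length", call. = FALSE)
  if (length(rater_a) == 0L)
    stop("no subjects: paired ratings cannot be empty", call. = FALSE)
  if (is.null(subject)) subject <- seq_along(rater_a)
  if (length(subject) != length(rater_a))
    stop("subject ids must match the number of ratings", call. = FALSE)
  out <- data.frame(subject_id = subject,
                    rater_a = as.character(rater_a),
                    rater_b = as.character(rater_b),
                    stringsAsFactors = FALSE)
  class(out) <- c("paired_ratings", "data.frame")
  out
}

#' Tally paired ratings into a contingency table
#'
#' Cross-tabulates subject-level ratings over the full declared scale:
#' categories never used by either rater keep their zero row and column,
#' because weight distances depend on the declared scale, not the observed
#' one.
#'
#' @param ratings A [paired_ratings()] object (or data frame with columns
#'   `rater_a`, `rater_b` and optionally `subject_id`).
#' @param scale A [rating_scale()]. Rows index rater A's category, columns
#'   rater B's.
#' @param rater_names Length-2 character vector of rater identifiers.
#' @return A `"contingency_table"` object; see [contingency_table()].
#' @examples
#' r <- paired_ratings(c("PR", "SD", "PD"), c("PR", "SD", "SD"))
#' build_table(r, rating_scale(c("PR", "SD", "PD")))
#' @export
build_table <- function(ratings, scale,
                        rater_names = c("rater A", "rater B")) {
  assert_scale(scale)
  if (!is.data.frame(ratings) ||
      !all(c("rater_a", "rater_b") %in% names(ratings)))
    stop("`ratings` must have columns rater_a and rater_b", call. = FALSE)
  if (nrow(ratings) == 0L)
    stop("no subjects: paired ratings cannot be empty", call. = FALSE)
  ids <- if ("subject_id" %in% names(ratings)) ratings$subject_id
         else seq_len(nrow(ratings))
  for (col in c("rater_a", "rater_b")) {
    bad <- !(ratings[[col]] %in% scale$labels)
    if (any(bad)) {
      i <- which(bad)[1L]
      stop(sprintf("unknown label '%s' for subject '%s' (%s)",
                   ratings[[col]][i], ids[i], col), call. = FALSE)
    }
  }
  fa <- factor(ratings$rater_a, levels = scale$labels)
  fb <- factor(ratings$rater_b, levels = scale$labels)
  counts <- unclass(table(fa, fb))
  dimnames(counts) <- list(scale$labels, scale$labels)
  contingency_table(counts, scale = scale, rater_names = rater_names)
}

#' Construct a two-rater contingency table
#'
#' @param counts Square matrix of non-negative integer counts; rows = rater
#'   A's category, columns = rater B's category. Dimnames, if absent, are
#'   taken from `scale`.
#' @param scale A [rating_scale()]; defaults to an ordinal scale built from
#'   the matrix dimnames.
#' @param rater_names Length-2 character vector identifying the raters.
#' @param id Optional provenance tag carried into estimates and reports.
#' @return Object of class `"contingency_table"` with fields `counts`,
#'   `scale`, `rater_names`, `n_subjects`, `id`.
#' @examples
#' m <- matrix(c(1, 0, 2, 4, 3, 3, 1, 1, 16), 3, byrow = TRUE,
#'             dimnames = list(c("PR", "SD", "PD"), c("PR", "SD", "PD")))
#' contingency_table(m)
#' @export
contingency_table <- function(counts, scale = NULL,
                              rater_names = c("rater A", "rater B"),
                              id = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts))
    stop(sprintf("contingency table must be square, got %d x %d",
                 nrow(counts), ncol(counts)), call. = FALSE)
  storage <- suppressWarnings(as.numeric(counts))
  if (any(is.na(storage)))
    stop("counts must be numeric", call. = FALSE)
  if (any(storage < 0) || any(abs(storage - round(storage)) > 1e-8))
    stop("counts must be non-negative integers", call. = FALSE)
  counts[] <- round(storage)
  if (is.null(scale)) {
    labs <- rownames(counts)
    if (is.null(labs)) labs <- as.character(seq_len(nrow(counts)))
    scale <- rating_scale(labs, ordinal = TRUE)
  }
  assert_scale(scale)
  if (nrow(counts) != scale$n_categories)
    stop(sprintf("counts side (%d) does not match scale (%d categories)",
                 nrow(counts), scale$n_categories), call. = FALSE)
  if (!is.null(rownames(counts)) &&
      !identical(rownames(counts), scale$labels) &&
      all(rownames(counts) %in% scale$labels)) {
    counts <- counts[scale$labels, scale$labels, drop = FALSE]
  }
  dimnames(counts) <- list(scale$labels, scale$labels)
  n <- sum(counts)
  if (n <= 0) stop("contingency table has zero total count", call. = FALSE)
  if (length(rater_names) != 2L)
    stop("rater_names must have length 2", call. = FALSE)
  structure(
    list(counts = counts, scale = scale,
         rater_names = as.character(rater_names),
         n_subjects = as.integer(n), id = id),
    class = "contingency_table"
  )
}

is_contingency_table <- function(x) inherits(x, "contingency_table")

assert_table <- function(table) {
  if (!is_contingency_table(table))
    stop("`table` must be a contingency_table object", call. = FALSE)
  invisible(table)
}

#' Joint proportions and marginals of a contingency table
#'
#' @param table A [contingency_table()].
#' @return List with `p` (joint proportion matrix), `p_row` (rater A
#'   marginals), `p_col` (rater B marginals), `n`.
#' @export
table_proportions <- function(table) {
  assert_table(table)
  p <- table$counts / table$n_subjects
  list(p = p, p_row = rowSums(p), p_col = colSums(p), n = table$n_subjects)
}

#' Transpose a contingency table (swap the raters)
#'
#' @param table A [contingency_table()].
#' @return The table with rows and columns (and rater names) exchanged.
#' @export
transpose_table <- function(table) {
  assert_table(table)
  contingency_table(t(table$counts), scale = table$scale,
                    rater_names = rev(table$rater_names), id = table$id)
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("Two-rater contingency table (%d subjects)\n", x$n_subjects))
  cat(sprintf("  rows: %s, columns: %s\n", x$rater_names[1], x$rater_names[2]))
  m <- cbind(x$counts, Total = rowSums(x$counts))
  m <- rbind(m, Total = colSums(m))
  print(m)
  invisible(x)
}

#' @export
as.matrix.contingency_table <- function(x, ...) x$counts
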