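#' Define a rating scale
#'
#' A rating scale is the ordered set of category labels both raters draw
#' from. Whether the scale is ordinal governs which kappa statistics are
#' meaningful: power-weighted kappa presumes an ordering of the categories,
#' Cohen's kappa does not.
#'
#' @param labels Character vector of unique category names, in scale order
#'   (for ordinal scales the order carries meaning, e.g. `c("PR","SD","PD")`
#'   for RECIST response worsening).
#' @param ordinal Logical; `TRUE` when the categories have a natural order.
#' @return An object of class `"rating_scale"` with fields `labels`,
#'   `is_ordinal` and `n_categories`.
#' @examples
#' rating_scale(c("PR", "SD", "PD"))
#' rating_scale(c("blue", "green", "brown", "hazel"), ordinal = FALSE)
#' @export
rating_scale <- function(labels, ordinal = TRUE) {
  labels <- as.character(labels)
  if (length(labels) < 2L)
    stop("a rating scale needs at least 2 categories", call. = FALSE)
  if (anyDuplicated(labels))
    stop("rating scale labels must be unique: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  if (any(is.na(labels)) || any(!nzchar(labels)))
    stop("rating scale labels must be non-missing, non-empty strings",
         call. = FALSE)
  structure(
    list(labels = labels,
         is_ordinal = isTRUE(ordinal),
         n_categories = length(labels)),
    class = "rating_scale"
  )
}

#' @export
print.rating_scale <- function(x, ...) {
  sep <- if (x$is_ordinal) " < " else ", "
  cat(sprintf("Rating scale (%s, %d categories): %s\n",
              if (x$is_ordinal) "ordinal" else "nominal",
              x$n_categories, paste(x$labels, collapse = sep)))
  invisible(x)
}

is_rating_scale <- function(x) inherits(x, "rating_scale")

assert_scale <- function(scale) {
  if (!is_rating_scale(scale))
    stop("`scale` must be a rating_scale object", call. = FALSE)
  invisible(scale)
}
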