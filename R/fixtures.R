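# Bundled RECIST response-assessment confusion matrices.

recist_comparisons <- data.frame(
  id = c("testing_r1", "testing_r2", "testing_auto",
         "validation_r1", "validation_r2", "validation_auto"),
  cohort = rep(c("testing dataset", "validation cohort"), each = 3),
  rater = rep(c("R1", "R2", "automated segmentation"), 2),
  # agreement values reported by the original study (computation method
  # unknown there; carried as metadata only, never recomputed)
  reference_kappa = c(0.48, 0.30, 0.51, 0.63, 0.45, 0.60),
  stringsAsFactors = FALSE
)

#' Bundled RECIST response-assessment tables
#'
#' Six 3x3 confusion matrices of RECIST 1.1 treatment-response categories
#' (PR = partial response < SD = stable disease < PD = progressive
#' disease) from a published liver-metastases study: two radiologists (R1,
#' 8 years' experience; R2, 4 years') and an automated deep-learning
#' segmentation method, each against the reference standard, in a testing
#' dataset and a validation cohort of 31 subjects apiece. Rows are the
#' rater's categories, columns the reference standard's.
#'
#' Each table carries an `id` and, as an attribute `reference_kappa`, the
#' agreement value the original study reported for that comparison. Those
#' reference values were computed by an unstated method and are metadata
#' only.
#'
#' @return Named list of six [contingency_table()] objects.
#' @examples
#' tabs <- recist_fixtures()
#' cohen_kappa(tabs$testing_r1)
#' @export
recist_fixtures <- function() {
  scale <- rating_scale(c("PR", "SD", "PD"), ordinal = TRUE)
  out <- lapply(seq_len(nrow(recist_comparisons)), function(i) {
    row <- recist_comparisons[i, ]
    path <- system.file("extdata", paste0(row$id, ".csv"),
                        package = "raterkappa", mustWork = TRUE)
    tab <- read_rating_table(path, dialect = "wide", scale = scale,
                             rater_names = c(row$rater,
                                             "reference standard"))
    tab$id <- row$id
    attr(tab, "cohort") <- row$cohort
    attr(tab, "reference_kappa") <- row$reference_kappa
    tab
  })
  names(out) <- recist_comparisons$id
  out
}
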