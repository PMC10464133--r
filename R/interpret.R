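# Qualitative interpretation of kappa magnitudes and advice on which
# statistic suits a measurement scale.

#' Landis-Koch interpretation bands
#'
#' Default band edges for labelling kappa magnitude. Intervals are closed
#' on the right, so 0.40 is still "fair" and 0.60 still "moderate".
#'
#' @return Named numeric vector of right edges: the label applies to
#'   `(previous edge, edge]`; anything `<= 0` is "no agreement".
#' @export
landis_koch_edges <- function() {
  c("no agreement" = 0, "slight" = 0.20, "fair" = 0.40,
    "moderate" = 0.60, "substantial" = 0.80, "almost perfect" = 1)
}

band_label <- function(point, edges) {
  labs <- names(edges)
  if (point <= edges[1]) return(labs[1])
  for (i in 2:length(edges)) if (point <= edges[i]) return(labs[i])
  labs[length(labs)]  # point == 1 handled above; defensive
}

#' Interpret a kappa estimate qualitatively
#'
#' Maps a kappa point estimate to an agreement label. With the
#' significance gate on (the default, mirroring the common reporting rule
#' that a non-significant kappa is reported as no agreement), any estimate
#' with `p >= alpha` is labelled "no agreement" regardless of magnitude.
#'
#' @param inference A `"kappa_inference"` (or a `"kappa_estimate"`, in
#'   which case no gating is possible and `gate` must be `FALSE`).
#' @param gate Logical; apply the significance gate. Default `TRUE`.
#' @param edges Interpretation bands, as from [landis_koch_edges()]; must
#'   cover (0, 1] with strictly increasing right edges ending at 1.
#' @return Object of class `"agreement_verdict"`: fields `label`,
#'   `gated_by_significance`, `band_edges`, `point`, `p_value`.
#' @examples
#' tab <- contingency_table(matrix(c(1, 0, 2, 4, 3, 3, 1, 1, 16), 3,
#'                                 byrow = TRUE))
#' inf <- wald_interval(weighted_kappa(tab, 1), asymptotic_se(tab, 1))
#' interpret_agreement(inf)   # "fair"
#' @export
interpret_agreement <- function(inference, gate = TRUE,
                                edges = landis_koch_edges()) {
  if (inherits(inference, "kappa_estimate")) {
    if (isTRUE(gate))
      stop("significance gating needs a kappa_inference (p-value); ",
           "pass gate = FALSE to label a bare estimate", call. = FALSE)
    point <- inference$point
    p_value <- NA_real_
    alpha <- NA_real_
  } else if (inherits(inference, "kappa_inference")) {
    point <- inference$estimate$point
    p_value <- inference$p_value
    alpha <- inference$alpha
  } else {
    stop("`inference` must be a kappa_inference or kappa_estimate",
         call. = FALSE)
  }
  if (is.null(names(edges)) || is.unsorted(edges, strictly = TRUE) ||
      edges[length(edges)] != 1)
    stop("`edges` must be a named, strictly increasing vector ending at 1",
         call. = FALSE)
  gated <- isTRUE(gate) && !is.na(p_value) && p_value >= alpha
  label <- if (gated) names(edges)[1] else band_label(point, edges)
  structure(
    list(label = label, gated_by_significance = gated,
         band_edges = edges, point = point, p_value = p_value),
    class = "agreement_verdict"
  )
}

#' @export
print.agreement_verdict <- function(x, ...) {
  cat(sprintf("Agreement: %s (kappa = %.2f%s)\n", x$label, x$point,
              if (x$gated_by_significance)
                sprintf("; not significant, p = %.3f", x$p_value)
              else ""))
  invisible(x)
}

#' Advise which kappa statistic fits a measurement scale
#'
#' Cohen's kappa suits two raters with two categories, or nominal
#' (unordered) categories however many there are. For ordinal scales with
#' three or more categories the weighted kappa is recommended, and
#' reporting both the linear and the quadratic weighting gives a fuller
#' picture of how disagreements distribute across the scale.
#'
#' @param scale A [rating_scale()].
#' @return Object of class `"statistic_advice"`: fields `recommended`
#'   (`"cohen"` or `"weighted"`), `reason`, `suggest_both_weightings`.
#' @examples
#' select_statistic(rating_scale(c("PR", "SD", "PD")))
#' select_statistic(rating_scale(c("yes", "no")))
#' @export
select_statistic <- function(scale) {
  assert_scale(scale)
  if (scale$n_categories == 2L) {
    rec <- "cohen"
    why <- "two categories: all disagreements are equivalent"
    both <- FALSE
  } else if (!scale$is_ordinal) {
    rec <- "cohen"
    why <- paste("nominal categories carry no distance,",
                 "so partial-credit weights are meaningless")
    both <- FALSE
  } else {
    rec <- "weighted"
    why <- paste("ordered categories with 3+ levels: near-miss",
                 "disagreements deserve partial credit; report both the",
                 "linear and quadratic weightings")
    both <- TRUE
  }
  structure(list(recommended = rec, reason = why,
                 suggest_both_weightings = both),
            class = "statistic_advice")
}

#' @export
print.statistic_advice <- function(x, ...) {
  cat(sprintf("Recommended statistic: %s kappa\n",
              if (x$recommended == "cohen") "Cohen's" else "weighted"))
  cat("  ", x$reason, "\n", sep = "")
  invisible(x)
}
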