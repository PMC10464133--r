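# Core chance-corrected agreement statistics.
#
# Both statistics are the same functional
#   kappa = (P_o - P_e) / (1 - P_e)
# with P_o = sum_ij w_ij p_ij the weighted observed agreement and
# P_e = sum_ij w_ij p_i q_j the weighted agreement expected under
# independence of the raters' marginals; Cohen's kappa is the identity-
# weight case. A table where P_e = 1 (both raters use one identical
# category throughout) leaves kappa undefined and raises a classed error.

undefined_kappa <- function(msg) {
  stop(structure(class = c("undefined_kappa", "error", "condition"),
                 list(message = msg, call = NULL)))
}

kappa_core <- function(p, w) {
  p_row <- rowSums(p)
  p_col <- colSums(p)
  po <- sum(w * p)
  pe <- sum(w * outer(p_row, p_col))
  if (pe >= 1 - 1e-12) {
    if (po >= 1 - 1e-12)
      undefined_kappa(
        "kappa undefined: expected agreement is 1 (degenerate table)")
    pe <- 1 - 1e-12  # unreachable for valid weights, defensive
  }
  list(point = (po - pe) / (1 - pe), po = po, pe = pe)
}

new_kappa_estimate <- function(statistic, m, core, table) {
  structure(
    list(statistic = statistic, m = m,
         point = min(core$point, 1),
         observed_agreement = core$po,
         expected_agreement = core$pe,
         n_subjects = table$n_subjects,
         table_id = table$id,
         table = table),
    class = "kappa_estimate"
  )
}

#' Cohen's kappa
#'
#' Chance-corrected agreement for two raters on a fully-crossed design:
#' \deqn{\kappa_C = \frac{P_o - P_e}{1 - P_e}}
#' where \eqn{P_o} is the proportion of subjects placed in the same
#' category by both raters and \eqn{P_e = \sum_j p_{Aj}\, p_{Bj}} is the
#' agreement expected by chance from the raters' marginal category usage.
#'
#' @param table A [contingency_table()].
#' @return Object of class `"kappa_estimate"` with fields `statistic`
#'   (`"cohen"`), `point`, `observed_agreement`, `expected_agreement`,
#'   `n_subjects`.
#' @seealso [weighted_kappa()], [kappa_fit()]
#' @examples
#' m <- matrix(c(1, 0, 2, 4, 3, 3, 1, 1, 16), 3, byrow = TRUE)
#' cohen_kappa(contingency_table(m))
#' @export
cohen_kappa <- function(table) {
  assert_table(table)
  p <- table_proportions(table)$p
  core <- kappa_core(p, diag(nrow(p)))
  new_kappa_estimate("cohen", NA_real_, core, table)
}

#' Weighted kappa
#'
#' Kappa with partial credit for near-miss disagreements:
#' \deqn{\kappa_m = 1 - \frac{1 - \sum_{ij} w_{ij} p_{ij}}
#'                          {1 - \sum_{ij} w_{ij} p_i q_j}}
#' with \eqn{p_i} the row (rater A) and \eqn{q_j} the column (rater B)
#' marginal proportions. With [power_weights()] at `m = 1` this is the
#' linear weighted kappa (LWK), at `m = 2` the quadratic weighted kappa
#' (QWK); identity weights recover Cohen's kappa exactly.
#'
#' @param table A [contingency_table()].
#' @param weights A `"kappa_weights"` object matching the table's side, or
#'   a number, interpreted as the power exponent `m`.
#' @return A `"kappa_estimate"` (statistic `"weighted"`, exponent in `m`
#'   when the power scheme is used).
#' @examples
#' m <- matrix(c(1, 0, 2, 4, 3, 3, 1, 1, 16), 3, byrow = TRUE)
#' tab <- contingency_table(m)
#' weighted_kappa(tab, 1)  # linear
#' weighted_kappa(tab, 2)  # quadratic
#' @export
weighted_kappa <- function(table, weights) {
  assert_table(table)
  if (is.numeric(weights) && length(weights) == 1L)
    weights <- power_weights(table$scale, m = weights)
  if (!is_kappa_weights(weights))
    stop("`weights` must be a kappa_weights object or an exponent m",
         call. = FALSE)
  if (weights$n_categories != table$scale$n_categories)
    stop(sprintf("weight matrix side (%d) does not match table side (%d)",
                 weights$n_categories, table$scale$n_categories),
         call. = FALSE)
  p <- table_proportions(table)$p
  core <- kappa_core(p, weights$weights)
  new_kappa_estimate("weighted", weights$m, core, table)
}

statistic_label <- function(statistic, m) {
  if (statistic == "cohen") return("Cohen's kappa")
  if (is.na(m)) return("weighted kappa")
  if (m == 1) return("linear weighted kappa")
  if (m == 2) return("quadratic weighted kappa")
  sprintf("weighted kappa (m = %g)", m)
}

#' @export
print.kappa_estimate <- function(x, digits = 4, ...) {
  cat(sprintf("%s: %.*f  (P_o = %.*f, P_e = %.*f, n = %d)\n",
              statistic_label(x$statistic, x$m),
              digits, x$point, digits, x$observed_agreement,
              digits, x$expected_agreement, x$n_subjects))
  invisible(x)
}

# half-away-from-zero rounding for report presentation (2 dp like the
# source tables); base round() is half-to-even
round_half_away <- function(x, digits = 2) {
  s <- sign(x)
  s * floor(abs(x) * 10^digits + 0.5) / 10^digits
}
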