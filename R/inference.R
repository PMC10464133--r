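# Standard errors, confidence intervals and tests of kappa = 0.
#
# The large-sample non-null variance of weighted kappa (Fleiss, Cohen &
# Everitt 1969) is used for both the Wald CI and the Wald test, so that
# "p < alpha" and "the (1-alpha) CI excludes 0" are the same statement.
# Cohen's kappa is the identity-weight special case of the same formula.

#' Asymptotic standard error of (weighted) kappa
#'
#' Large-sample non-null standard error of weighted kappa after Fleiss,
#' Cohen and Everitt: with joint proportions \eqn{p_{ij}}, marginals
#' \eqn{p_i, q_j}, weights \eqn{w_{ij}}, row/column expected weights
#' \eqn{\bar w_{i\cdot} = \sum_j w_{ij} q_j},
#' \eqn{\bar w_{\cdot j} = \sum_i w_{ij} p_i},
#' \deqn{\mathrm{var}(\hat\kappa) = \frac{\sum_{ij} p_{ij}
#'   [w_{ij} - (\bar w_{i\cdot} + \bar w_{\cdot j})(1-\hat\kappa)]^2
#'   - [\hat\kappa - P_e(1-\hat\kappa)]^2}{n\,(1-P_e)^2}.}
#' The SE scales as \eqn{1/\sqrt{n}}.
#'
#' @param table A [contingency_table()] with at least 2 subjects.
#' @param weights A `"kappa_weights"` object, a power exponent `m`, or
#'   `NULL` for identity weights (Cohen's kappa).
#' @return A single non-negative number.
#' @references Fleiss JL, Cohen J, Everitt BS (1969). Large sample standard
#'   errors of kappa and weighted kappa. Psychological Bulletin 72:323-327.
#' @export
asymptotic_se <- function(table, weights = NULL) {
  assert_table(table)
  if (table$n_subjects < 2L)
    stop("asymptotic SE needs at least 2 subjects", call. = FALSE)
  if (is.null(weights)) weights <- identity_weights(table$scale)
  if (is.numeric(weights) && length(weights) == 1L)
    weights <- power_weights(table$scale, m = weights)
  if (weights$n_categories != table$scale$n_categories)
    stop("weight matrix side does not match table side", call. = FALSE)
  pr <- table_proportions(table)
  w <- weights$weights
  core <- kappa_core(pr$p, w)     # propagates undefined-kappa
  k <- core$point
  pe <- core$pe
  w_row <- as.vector(w %*% pr$p_col)   # \bar w_{i.}
  w_col <- as.vector(pr$p_row %*% w)   # \bar w_{.j}
  dev <- w - outer(w_row, w_col, "+") * (1 - k)
  v <- (sum(pr$p * dev^2) - (k - pe * (1 - k))^2) / (pr$n * (1 - pe)^2)
  sqrt(max(v, 0))
}

new_kappa_inference <- function(estimate, se, ci, alpha, p_value, method,
                                n_boot = NULL, seed = NULL,
                                n_undefined = 0L, degenerate = FALSE) {
  structure(
    list(estimate = estimate, se = se,
         ci_low = max(ci[1], -1), ci_high = min(ci[2], 1),
         alpha = alpha, p_value = p_value, method = method,
         n_boot = n_boot, seed = seed, n_undefined = n_undefined,
         degenerate = degenerate),
    class = "kappa_inference"
  )
}

#' Wald interval and test for a kappa estimate
#'
#' Builds `point +/- z_(1-alpha/2) * se`, clipped to kappa's parameter
#' space \[-1, 1\], and the two-sided normal p-value for the null of zero
#' agreement beyond chance. CI and test use the same standard error, so
#' the CI excludes 0 exactly when `p_value < alpha`.
#'
#' @param estimate A `"kappa_estimate"` (from [cohen_kappa()] or
#'   [weighted_kappa()]).
#' @param se Standard error, `>= 0`; usually [asymptotic_se()].
#' @param alpha Significance level in (0, 1); default 0.05.
#' @return Object of class `"kappa_inference"`: fields `estimate`, `se`,
#'   `ci_low`, `ci_high`, `alpha`, `p_value`, `method = "asymptotic"`. A
#'   zero SE with a non-zero point yields a degenerate CI flagged via the
#'   `degenerate` field.
#' @examples
#' tab <- contingency_table(matrix(c(1, 0, 2, 4, 3, 3, 1, 1, 16), 3,
#'                                 byrow = TRUE))
#' est <- cohen_kappa(tab)
#' wald_interval(est, asymptotic_se(tab))
#' @export
wald_interval <- function(estimate, se, alpha = 0.05) {
  if (!inherits(estimate, "kappa_estimate"))
    stop("`estimate` must be a kappa_estimate", call. = FALSE)
  if (!is.numeric(se) || length(se) != 1L || is.na(se) || se < 0)
    stop("`se` must be a single non-negative number", call. = FALSE)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("`alpha` must lie in (0, 1)", call. = FALSE)
  point <- estimate$point
  degenerate <- FALSE
  if (se == 0) {
    p <- if (point == 0) 1 else 0
    degenerate <- point != 0
    ci <- c(point, point)
  } else {
    z <- stats::qnorm(1 - alpha / 2)
    ci <- point + c(-1, 1) * z * se
    p <- 2 * stats::pnorm(-abs(point / se))
  }
  new_kappa_inference(estimate, se, ci, alpha, p, "asymptotic",
                      degenerate = degenerate)
}

#' Bootstrap confidence interval for (weighted) kappa
#'
#' Percentile bootstrap. Given paired ratings, subjects are resampled with
#' replacement; given a contingency table, cell counts are redrawn
#' multinomially (the two schemes are equivalent in distribution).
#' Replicates with undefined kappa are dropped and counted; more than 50%
#' undefined aborts with a diagnostic. Fully reproducible under `seed`.
#'
#' @param ratings A [paired_ratings()] data frame or a
#'   [contingency_table()].
#' @param weights A `"kappa_weights"`, a power exponent `m`, or `NULL` for
#'   identity weights.
#' @param n_boot Number of replicates, `>= 100`; default 2000.
#' @param alpha Significance level; default 0.05.
#' @param seed Integer seed (required: bootstrap results must be
#'   replayable).
#' @param scale Rating scale; required when `ratings` is a data frame
#'   without one.
#' @return A `"kappa_inference"` with `method = "bootstrap"`; the p-value
#'   is the (two-sided) bootstrap tail probability of the replicates
#'   falling on the other side of 0.
#' @export
bootstrap_ci <- function(ratings, weights = NULL, n_boot = 2000,
                         alpha = 0.05, seed, scale = NULL) {
  if (missing(seed) || !is.numeric(seed))
    stop("an integer `seed` is required for the bootstrap", call. = FALSE)
  if (n_boot < 100) stop("n_boot must be at least 100", call. = FALSE)
  if (is_contingency_table(ratings)) {
    tab <- ratings
  } else {
    if (is.null(scale))
      scale <- rating_scale(sort(unique(c(ratings$rater_a,
                                          ratings$rater_b))))
    tab <- build_table(ratings, scale)
  }
  if (is.null(weights)) weights <- identity_weights(tab$scale)
  if (is.numeric(weights) && length(weights) == 1L)
    weights <- power_weights(tab$scale, m = weights)
  full <- weighted_kappa(tab, weights)
  n <- tab$n_subjects
  nc <- tab$scale$n_categories
  by_subject <- !is_contingency_table(ratings)
  if (by_subject) {
    # subject resampling: each subject is a (row, col) cell index
    ia <- match(ratings$rater_a, tab$scale$labels)
    ib <- match(ratings$rater_b, tab$scale$labels)
    cell <- (ib - 1L) * nc + ia
  } else {
    probs <- as.vector(tab$counts) / n
  }

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))

  reps <- numeric(n_boot)
  undef <- 0L
  for (b in seq_len(n_boot)) {
    if (by_subject) {
      draw <- cell[sample.int(n, n, replace = TRUE)]
      cnt <- matrix(tabulate(draw, nbins = nc * nc), nc, nc)
    } else {
      cnt <- matrix(stats::rmultinom(1, n, probs), nc, nc)
    }
    k <- tryCatch(
      kappa_core(cnt / n, weights$weights)$point,
      undefined_kappa = function(e) NA_real_)
    if (is.na(k)) undef <- undef + 1L else reps[b - undef] <- k
  }
  if (undef > n_boot / 2)
    stop(sprintf(paste0("bootstrap failed: %d of %d replicates had ",
                        "undefined kappa (degenerate resamples)"),
                 undef, n_boot), call. = FALSE)
  reps <- reps[seq_len(n_boot - undef)]
  ci <- unname(stats::quantile(reps, c(alpha / 2, 1 - alpha / 2),
                               type = 7))
  p <- 2 * min(mean(reps <= 0), mean(reps >= 0))
  new_kappa_inference(full, stats::sd(reps), ci, alpha, min(p, 1),
                      "bootstrap", n_boot = n_boot,
                      seed = as.integer(seed), n_undefined = undef)
}

#' @export
print.kappa_inference <- function(x, digits = 4, ...) {
  est <- x$estimate
  cat(sprintf("%s = %.*f, SE = %.*f, %d%% CI [%.*f, %.*f], p = %s (%s)\n",
              statistic_label(est$statistic, est$m), digits, est$point,
              digits, x$se, round(100 * (1 - x$alpha)),
              digits, x$ci_low, digits, x$ci_high,
              format.pval(x$p_value, digits = 3), x$method))
  if (x$degenerate) cat("  note: degenerate interval (zero SE)\n")
  if (x$n_undefined > 0)
    cat(sprintf("  note: %d undefined bootstrap replicates dropped\n",
                x$n_undefined))
  invisible(x)
}
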