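#' Fit two-rater agreement statistics
#'
#' The headline interface: computes the requested kappa statistics from a
#' contingency table or paired ratings, attaches standard errors,
#' confidence intervals, tests of zero agreement and qualitative verdicts,
#' and records which statistic the scale calls for. Returns a classed
#' object with `print`, `summary`, `coef`, `confint`, `simulate` and
#' `plot` methods.
#'
#' @param x A [contingency_table()], a square count matrix/table, a
#'   [paired_ratings()] data frame (columns `rater_a`, `rater_b`), or a
#'   vector of rater-A labels (then `y` gives rater B's).
#' @param y Optional vector of rater-B labels when `x` is a vector.
#' @param statistics Character vector from `c("cohen", "linear",
#'   "quadratic")`, or numeric power exponents `m >= 1`; default all three
#'   named statistics for ordinal scales with 3+ categories, Cohen only
#'   otherwise.
#' @param scale Optional [rating_scale()]; inferred from the data when
#'   absent (observed labels, in sorted order, assumed ordinal).
#' @param ci `"asymptotic"` (Fleiss-Cohen-Everitt Wald, the default) or
#'   `"bootstrap"` (subject-resampling percentile).
#' @param alpha Significance level; default 0.05.
#' @param n_boot Bootstrap replicates (bootstrap CI only); default 2000.
#' @param seed Integer seed (required for the bootstrap CI).
#' @param gate Logical: label non-significant estimates "no agreement"
#'   (default `TRUE`).
#' @param edges Interpretation band edges; default [landis_koch_edges()].
#' @return Object of class `"kappa_fit"`: fields `table`, `inferences`
#'   (named list of `"kappa_inference"`), `verdicts`, `advice`, `alpha`,
#'   `ci_method`, `call`.
#' @examples
#' m <- matrix(c(1, 0, 2, 4, 3, 3, 1, 1, 16), 3, byrow = TRUE,
#'             dimnames = list(c("PR", "SD", "PD"), c("PR", "SD", "PD")))
#' fit <- kappa_fit(m)
#' summary(fit)
#' coef(fit)
#' confint(fit)
#' @export
kappa_fit <- function(x, y = NULL, statistics = NULL, scale = NULL,
                      ci = c("asymptotic", "bootstrap"), alpha = 0.05,
                      n_boot = 2000, seed = NULL, gate = TRUE,
                      edges = landis_koch_edges()) {
  ci <- match.arg(ci)
  cl <- match.call()

  ratings <- NULL
  if (is_contingency_table(x)) {
    tab <- x
  } else if (is.matrix(x) || inherits(x, "table")) {
    tab <- contingency_table(x, scale = scale)
  } else if (is.data.frame(x)) {
    if (is.null(scale))
      scale <- rating_scale(sort(unique(c(as.character(x$rater_a),
                                          as.character(x$rater_b)))))
    ratings <- if (inherits(x, "paired_ratings")) x
               else paired_ratings(x$rater_a, x$rater_b,
                                   subject = x$subject_id)
    tab <- build_table(ratings, scale)
  } else if (is.atomic(x) && !is.null(y)) {
    if (is.null(scale))
      scale <- rating_scale(sort(unique(c(as.character(x),
                                          as.character(y)))))
    ratings <- paired_ratings(x, y)
    tab <- build_table(ratings, scale)
  } else {
    stop("`x` must be a contingency table, count matrix, data frame of ",
         "paired ratings, or a label vector with `y`", call. = FALSE)
  }

  if (is.null(statistics)) {
    statistics <- if (tab$scale$is_ordinal && tab$scale$n_categories >= 3)
      c("cohen", "linear", "quadratic") else "cohen"
  }

  infs <- list()
  for (s in statistics) {
    if (identical(s, "cohen")) {
      w <- identity_weights(tab$scale)
      est <- cohen_kappa(tab)
      nm <- "cohen"
    } else {
      m <- switch(as.character(s), linear = 1, quadratic = 2,
                  suppressWarnings(as.numeric(s)))
      if (is.na(m))
        stop(sprintf("unknown statistic '%s'", s), call. = FALSE)
      w <- power_weights(tab$scale, m = m)
      est <- weighted_kappa(tab, w)
      nm <- if (m == 1) "linear" else if (m == 2) "quadratic"
            else sprintf("m=%g", m)
    }
    infs[[nm]] <- if (ci == "asymptotic") {
      wald_interval(est, asymptotic_se(tab, w), alpha = alpha)
    } else {
      if (is.null(seed))
        stop("the bootstrap CI requires a `seed`", call. = FALSE)
      bootstrap_ci(if (is.null(ratings)) tab else ratings, w,
                   n_boot = n_boot, alpha = alpha, seed = seed,
                   scale = tab$scale)
    }
  }

  verdicts <- lapply(infs, interpret_agreement, gate = gate, edges = edges)
  structure(
    list(table = tab, inferences = infs, verdicts = verdicts,
         advice = select_statistic(tab$scale), alpha = alpha,
         ci_method = ci, gate = isTRUE(gate), call = cl),
    class = "kappa_fit"
  )
}

#' @export
print.kappa_fit <- function(x, digits = 2, ...) {
  cat(sprintf("Two-rater agreement, n = %d subjects, %d categories (%s)\n",
              x$table$n_subjects, x$table$scale$n_categories,
              if (x$table$scale$is_ordinal) "ordinal" else "nominal"))
  for (nm in names(x$inferences)) {
    inf <- x$inferences[[nm]]
    est <- inf$estimate
    cat(sprintf("  %-26s %5.*f  %d%% CI [%.*f, %.*f]  p %s  -> %s\n",
                statistic_label(est$statistic, est$m), digits, est$point,
                round(100 * (1 - inf$alpha)), digits, inf$ci_low,
                digits, inf$ci_high, format.pval(inf$p_value, digits = 2),
                x$verdicts[[nm]]$label))
  }
  invisible(x)
}

#' @export
summary.kappa_fit <- function(object, ...) {
  rows <- lapply(names(object$inferences), function(nm) {
    inf <- object$inferences[[nm]]
    est <- inf$estimate
    data.frame(statistic = nm,
               kappa = est$point,
               observed = est$observed_agreement,
               expected = est$expected_agreement,
               se = inf$se,
               ci_low = inf$ci_low, ci_high = inf$ci_high,
               p_value = inf$p_value,
               verdict = object$verdicts[[nm]]$label,
               stringsAsFactors = FALSE)
  })
  out <- list(fit = object, coefficients = do.call(rbind, rows))
  class(out) <- "summary.kappa_fit"
  out
}

#' @export
print.summary.kappa_fit <- function(x, ...) {
  fit <- x$fit
  print(fit$table)
  cat("\n")
  df <- x$coefficients
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) signif(v, 4))
  print(df, row.names = FALSE)
  cat("\n")
  print(fit$advice)
  invisible(x)
}

#' @export
coef.kappa_fit <- function(object, ...) {
  vapply(object$inferences, function(i) i$estimate$point, numeric(1))
}

#' @export
confint.kappa_fit <- function(object, parm, level, ...) {
  nms <- names(object$inferences)
  if (!missing(parm)) nms <- intersect(nms, parm)
  out <- t(vapply(object$inferences[nms],
                  function(i) c(i$ci_low, i$ci_high), numeric(2)))
  pct <- 100 * c(object$alpha / 2, 1 - object$alpha / 2)
  colnames(out) <- sprintf("%g %%", pct)
  out
}

#' @describeIn kappa_fit Draw new paired-rating datasets from the fitted
#'   joint proportions (parametric simulation at the fitted table).
#' @param object,nsim,... Standard [stats::simulate()] arguments.
#' @export
simulate.kappa_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (is.null(seed))
    stop("`seed` is required for reproducible simulation", call. = FALSE)
  model <- joint_model(object$table$counts / object$table$n_subjects,
                       object$table$scale)
  lapply(seq_len(nsim), function(k)
    sample_ratings(model, object$table$n_subjects,
                   seed = as.integer(seed) + k - 1L))
}

#' @export
plot.kappa_fit <- function(x, ...) {
  graphics::mosaicplot(x$table$counts,
                       main = "Two-rater agreement",
                       xlab = x$table$rater_names[1],
                       ylab = x$table$rater_names[2],
                       color = grDevices::gray.colors(
                         x$table$scale$n_categories), ...)
  invisible(x)
}
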