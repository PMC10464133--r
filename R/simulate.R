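# Paired-rating simulator: joint models with closed-form population
# kappas, multinomial sampling, and the prevalence-paradox demonstration.

#' Joint rating model
#'
#' A population model for a fully-crossed two-rater design: cell (i, j)
#' is the probability that a subject is rated category i by rater A and
#' category j by rater B. Population kappas follow in closed form from
#' the joint matrix and its marginals.
#'
#' @param joint Square matrix of probabilities summing to 1 (tolerance
#'   1e-12 after normalisation is *not* applied — the caller supplies a
#'   proper distribution).
#' @param scale A [rating_scale()]; defaults to an ordinal scale from the
#'   matrix dimnames (or 1..n).
#' @return Object of class `"joint_model"` with fields `joint`, `scale`.
#' @examples
#' joint_model(diag(3) / 3)
#' @export
joint_model <- function(joint, scale = NULL) {
  joint <- as.matrix(joint)
  if (nrow(joint) != ncol(joint))
    stop("joint matrix must be square", call. = FALSE)
  if (any(is.na(joint)) || any(joint < 0))
    stop("joint probabilities must be non-negative", call. = FALSE)
  if (abs(sum(joint) - 1) > 1e-12)
    stop(sprintf("joint probabilities must sum to 1 (got %.15g)",
                 sum(joint)), call. = FALSE)
  if (is.null(scale)) {
    labs <- rownames(joint)
    if (is.null(labs)) labs <- as.character(seq_len(nrow(joint)))
    scale <- rating_scale(labs, ordinal = TRUE)
  }
  assert_scale(scale)
  if (nrow(joint) != scale$n_categories)
    stop("joint matrix side does not match scale", call. = FALSE)
  dimnames(joint) <- list(scale$labels, scale$labels)
  structure(list(joint = joint, scale = scale), class = "joint_model")
}

#' Population kappa of a joint rating model
#'
#' The kappa functional applied to the model probabilities themselves
#' (no sampling): observed agreement \eqn{\sum w_{ij} \pi_{ij}}, chance
#' agreement \eqn{\sum w_{ij} \pi_{i\cdot} \pi_{\cdot j}}.
#'
#' @param model A [joint_model()].
#' @param weights A `"kappa_weights"`, a power exponent `m`, or `NULL` for
#'   identity weights (population Cohen's kappa).
#' @return A single number in \[-1, 1\].
#' @examples
#' population_kappa(joint_model(diag(3) / 3))        # 1
#' m <- outer(c(.5, .3, .2), c(.5, .3, .2))
#' population_kappa(joint_model(m))                  # 0
#' @export
population_kappa <- function(model, weights = NULL) {
  if (!inherits(model, "joint_model"))
    stop("`model` must be a joint_model", call. = FALSE)
  if (is.null(weights)) weights <- identity_weights(model$scale)
  if (is.numeric(weights) && length(weights) == 1L)
    weights <- power_weights(model$scale, m = weights)
  if (weights$n_categories != model$scale$n_categories)
    stop("weight matrix side does not match model", call. = FALSE)
  kappa_core(model$joint, weights$weights)$point
}

#' Sample paired ratings from a joint model
#'
#' Draws `n` independent subjects from the joint distribution (one
#' multinomial draw over the n_categories^2 cells; subjects are laid out
#' in index order, so a fixed seed fully determines the sample).
#'
#' @param model A [joint_model()].
#' @param n Number of subjects, `>= 1`.
#' @param seed Integer seed.
#' @return A [paired_ratings()] data frame with `n` rows.
#' @export
sample_ratings <- function(model, n, seed) {
  if (!inherits(model, "joint_model"))
    stop("`model` must be a joint_model", call. = FALSE)
  if (!is.numeric(n) || n < 1) stop("n must be >= 1", call. = FALSE)
  if (missing(seed) || !is.numeric(seed))
    stop("an integer `seed` is required", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  nc <- model$scale$n_categories
  cell <- sample.int(nc * nc, size = n, replace = TRUE,
                     prob = as.vector(model$joint))
  i <- ((cell - 1L) %% nc) + 1L        # rater A (row index)
  j <- ((cell - 1L) %/% nc) + 1L       # rater B (column index)
  paired_ratings(model$scale$labels[i], model$scale$labels[j])
}

#' Demonstrate the kappa prevalence paradox
#'
#' Builds a grid of 2x2 joint models that all share the same observed
#' agreement but have increasingly skewed (and symmetric, equal for both
#' raters) marginals, and evaluates Cohen's kappa on each. At fixed
#' observed agreement \eqn{P_o}, marginals \eqn{(s, 1-s)} force
#' off-diagonal mass \eqn{(1-P_o)/2} in each cell and diagonal
#' \eqn{\pi_{11} = s - (1-P_o)/2}; chance agreement
#' \eqn{P_e = s^2 + (1-s)^2} grows with the skew, so kappa falls even
#' though raw agreement never changes -- the prevalence paradox.
#'
#' @param base_agreement Observed agreement held fixed, in (0, 1);
#'   default 0.8.
#' @param skews Vector of first-category marginal probabilities; default
#'   `seq(0.5, 0.95, by = 0.05)`.
#' @return Data frame with columns `skew`, `feasible`,
#'   `observed_agreement`, `cohen_kappa`; infeasible (agreement, skew)
#'   combinations are kept as flagged rows with `NA` kappa.
#' @examples
#' prevalence_paradox_demo(0.8, c(0.5, 0.7, 0.9))
#' @export
prevalence_paradox_demo <- function(base_agreement = 0.8,
                                    skews = seq(0.5, 0.95, by = 0.05)) {
  if (!is.numeric(base_agreement) || base_agreement <= 0 ||
      base_agreement >= 1)
    stop("base_agreement must lie in (0, 1)", call. = FALSE)
  if (any(skews <= 0 | skews >= 1))
    stop("skews must be probabilities in (0, 1)", call. = FALSE)
  d <- (1 - base_agreement) / 2
  out <- data.frame(skew = skews, feasible = NA, observed_agreement = NA_real_,
                    cohen_kappa = NA_real_)
  for (r in seq_along(skews)) {
    s <- skews[r]
    p11 <- s - d
    p22 <- base_agreement - p11
    ok <- p11 >= -1e-12 && p22 >= -1e-12
    out$feasible[r] <- ok
    if (!ok) next
    joint <- matrix(c(max(p11, 0), d, d, max(p22, 0)), 2, 2)
    model <- joint_model(joint / sum(joint),
                         rating_scale(c("a", "b"), ordinal = FALSE))
    out$observed_agreement[r] <- base_agreement
    out$cohen_kappa[r] <- kappa_core(model$joint, diag(2))$point
  }
  out
}
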