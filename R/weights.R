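#' Power-family agreement weights
#'
#' Builds the agreement weight matrix
#' \deqn{w_{ij} = 1 - \left(\frac{|i-j|}{n-1}\right)^m}
#' over the 0-based consecutive integer indices of the ordered labels.
#' `m = 1` gives the linear weights (LWK), `m = 2` the quadratic weights
#' (QWK); any real `m >= 1` is accepted. For a two-category scale every
#' power collapses to the identity matrix, so weighted kappa equals Cohen's
#' kappa there.
#'
#' @param scale A [rating_scale()] or a single integer giving the number of
#'   categories (then assumed ordinal).
#' @param m Power exponent, `>= 1`.
#' @param allow_nominal Weighted kappa presumes ordered categories; pass
#'   `TRUE` to override the ordinality check deliberately.
#' @return Object of class `"kappa_weights"`: fields `weights` (symmetric
#'   matrix, unit diagonal, entries in \[0,1\]), `m`, `scheme`.
#' @examples
#' power_weights(rating_scale(c("PR", "SD", "PD")), m = 1)$weights
#' power_weights(3, m = 2)$weights
#' @export
power_weights <- function(scale, m = 1, allow_nominal = FALSE) {
  if (is.numeric(scale) && length(scale) == 1L)
    scale <- rating_scale(as.character(seq_len(scale)), ordinal = TRUE)
  assert_scale(scale)
  if (!is.numeric(m) || length(m) != 1L || is.na(m) || m < 1)
    stop("power exponent m must be a single number >= 1", call. = FALSE)
  if (!scale$is_ordinal && !isTRUE(allow_nominal))
    stop("power weights presume an ordinal scale; ",
         "set allow_nominal = TRUE to override", call. = FALSE)
  n <- scale$n_categories
  idx <- seq_len(n) - 1L
  d <- abs(outer(idx, idx, "-")) / (n - 1L)
  w <- 1 - d^m
  dimnames(w) <- list(scale$labels, scale$labels)
  new_kappa_weights(w, m = m, scheme = "power")
}

#' Identity agreement weights
#'
#' Full credit on the diagonal, none off it; weighted kappa with identity
#' weights is exactly Cohen's kappa.
#'
#' @param scale A [rating_scale()] or category count.
#' @return A `"kappa_weights"` object with `scheme = "identity"`.
#' @export
identity_weights <- function(scale) {
  if (is.numeric(scale) && length(scale) == 1L)
    scale <- rating_scale(as.character(seq_len(scale)), ordinal = TRUE)
  assert_scale(scale)
  w <- diag(scale$n_categories)
  dimnames(w) <- list(scale$labels, scale$labels)
  new_kappa_weights(w, m = NA_real_, scheme = "identity")
}

#' Custom agreement weights
#'
#' Accepts a user-supplied weight matrix (the choice of weights is a matter
#' of expert judgment); it must be symmetric with a unit diagonal and
#' entries in \[0, 1\].
#'
#' @param weights Square numeric matrix of weights.
#' @return A `"kappa_weights"` object with `scheme = "custom"`.
#' @export
kappa_weights <- function(weights) {
  new_kappa_weights(as.matrix(weights), m = NA_real_, scheme = "custom")
}

new_kappa_weights <- function(weights, m, scheme) {
  if (nrow(weights) != ncol(weights))
    stop("weight matrix must be square", call. = FALSE)
  if (nrow(weights) < 2L)
    stop("weight matrix needs at least 2 categories", call. = FALSE)
  if (any(is.na(weights)) || any(weights < -1e-12) || any(weights > 1 + 1e-12))
    stop("weights must lie in [0, 1]", call. = FALSE)
  if (max(abs(weights - t(weights))) > 1e-12)
    stop("weight matrix must be symmetric", call. = FALSE)
  if (max(abs(diag(weights) - 1)) > 1e-12)
    stop("weight matrix must have a unit diagonal", call. = FALSE)
  weights[] <- pmin(pmax(weights, 0), 1)
  structure(list(weights = weights, m = m, scheme = scheme,
                 n_categories = nrow(weights)),
            class = "kappa_weights")
}

is_kappa_weights <- function(x) inherits(x, "kappa_weights")

#' @export
print.kappa_weights <- function(x, ...) {
  tag <- switch(x$scheme,
                power = sprintf("power, m = %g", x$m),
                x$scheme)
  cat(sprintf("Agreement weights (%s), %d categories\n", tag, x$n_categories))
  print(round(x$weights, 4))
  invisible(x)
}
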