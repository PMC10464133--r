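fake_inference <- function(point, p_value, alpha = 0.05) {
  est <- structure(list(statistic = "cohen", m = NA_real_, point = point,
                        observed_agreement = NA_real_,
                        expected_agreement = NA_real_, n_subjects = 31L),
                   class = "kappa_estimate")
  structure(list(estimate = est, se = 0.1, ci_low = point - 0.2,
                 ci_high = point + 0.2, alpha = alpha, p_value = p_value,
                 method = "asymptotic", n_boot = NULL, seed = NULL,
                 n_undefined = 0L, degenerate = FALSE),
            class = "kappa_inference")
}

test_that("verdicts follow the interpretation bands", {
  expect_identical(interpret_agreement(fake_inference(0.38, 0.008))$label,
                   "fair")
  expect_identical(interpret_agreement(fake_inference(0.67, 1e-5))$label,
                   "substantial")
  expect_identical(interpret_agreement(fake_inference(0.95, 1e-9))$label,
                   "almost perfect")
  expect_identical(interpret_agreement(fake_inference(0.50, 0.001))$label,
                   "moderate")
  expect_identical(interpret_agreement(fake_inference(0.10, 0.001))$label,
                   "slight")
  expect_identical(interpret_agreement(fake_inference(-0.2, 0.001))$label,
                   "no agreement")
})

test_that("the significance gate forces 'no agreement' when p >= alpha", {
  v <- interpret_agreement(fake_inference(0.22, 0.09))
  expect_identical(v$label, "no agreement")
  expect_true(v$gated_by_significance)
  # gate off: the magnitude speaks for itself
  v2 <- interpret_agreement(fake_inference(0.22, 0.09), gate = FALSE)
  expect_identical(v2$label, "fair")
  # gate never changes significant labels
  for (pt in c(0.1, 0.35, 0.55, 0.75, 0.95)) {
    on <- interpret_agreement(fake_inference(pt, 0.01))$label
    off <- interpret_agreement(fake_inference(pt, 0.01), gate = FALSE)$label
    expect_identical(on, off)
  }
})

test_that("bands are exhaustive, mutually exclusive and right-closed", {
  edges <- landis_koch_edges()
  pts <- seq(-1, 1, by = 0.005)
  labels <- vapply(pts, function(p)
    interpret_agreement(fake_inference(p, 1e-6))$label, character(1))
  expect_true(all(labels %in% names(edges)))
  # every point gets exactly one label and the mapping is monotone
  expect_true(all(diff(match(labels, names(edges))) >= 0))
  # right-closed boundaries: 0.40 is still "fair", 0.60 still "moderate"
  expect_identical(interpret_agreement(fake_inference(0.40, 1e-6))$label,
                   "fair")
  expect_identical(interpret_agreement(fake_inference(0.60, 1e-6))$label,
                   "moderate")
  expect_identical(interpret_agreement(fake_inference(0, 1e-6))$label,
                   "no agreement")
})

test_that("custom band edges are honoured and validated", {
  coarse <- c("low" = 0, "high" = 1)
  expect_identical(
    interpret_agreement(fake_inference(0.9, 1e-6), edges = coarse)$label,
    "high")
  expect_error(
    interpret_agreement(fake_inference(0.9, 1e-6),
                        edges = c(a = 0, b = 0.5)), "ending at 1")
})

test_that("statistic advice follows scale type and size", {
  two <- select_statistic(rating_scale(c("yes", "no")))
  expect_identical(two$recommended, "cohen")
  expect_false(two$suggest_both_weightings)

  nominal4 <- select_statistic(
    rating_scale(c("blue", "green", "brown", "hazel"), ordinal = FALSE))
  expect_identical(nominal4$recommended, "cohen")

  likert <- select_statistic(rating_scale(as.character(1:5)))
  expect_identical(likert$recommended, "weighted")
  expect_true(likert$suggest_both_weightings)

  recist <- select_statistic(recist_scale())
  expect_identical(recist$recommended, "weighted")
})
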