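test_that("Cohen's kappa matches the frozen cross-implementation values", {
  for (id in rownames(frozen_reference)) {
    est <- cohen_kappa(fixture_table(id))
    expect_equal(est$point, frozen_reference[id, "kc"], tolerance = 1e-9)
  }
})

test_that("weighted kappa matches the frozen cross-implementation values", {
  for (id in rownames(frozen_reference)) {
    tab <- fixture_table(id)
    expect_equal(weighted_kappa(tab, 1)$point,
                 frozen_reference[id, "klw"], tolerance = 1e-9)
    expect_equal(weighted_kappa(tab, 2)$point,
                 frozen_reference[id, "kqw"], tolerance = 1e-9)
  }
})

test_that("kappa handles the canonical edge tables", {
  perfect <- contingency_table(matrix(c(5, 0, 0, 7), 2))
  expect_equal(cohen_kappa(perfect)$point, 1)
  indep <- contingency_table(matrix(5, 2, 2))
  expect_equal(cohen_kappa(indep)$point, 0)
  expect_equal(cohen_kappa(indep)$expected_agreement, 0.5)
  # both raters glued to one category: kappa undefined, classed signal
  degenerate <- contingency_table(matrix(c(9, 0, 0, 0), 2))
  expect_error(cohen_kappa(degenerate), class = "undefined_kappa")
  expect_error(weighted_kappa(degenerate, 1), class = "undefined_kappa")
})

test_that("estimate components satisfy the defining identity", {
  for (id in c("testing_r1", "validation_auto")) {
    tab <- fixture_table(id)
    for (est in list(cohen_kappa(tab), weighted_kappa(tab, 1),
                     weighted_kappa(tab, 2))) {
      expect_equal(est$point,
                   (est$observed_agreement - est$expected_agreement) /
                     (1 - est$expected_agreement))
      expect_lte(est$point, 1)
      expect_gte(est$observed_agreement, 0)
      expect_lte(est$observed_agreement, 1)
    }
  }
})

test_that("weighted kappa rejects mismatched weight matrices", {
  tab <- fixture_table("testing_r1")
  expect_error(weighted_kappa(tab, identity_weights(4)), "side")
})

test_that("transpose symmetry holds for Cohen's and weighted kappa", {
  set.seed(11)
  for (rep in 1:20) {
    k <- sample(2:4, 1)
    cnt <- matrix(rpois(k * k, 3) + diag(rpois(k, 4), k), k)
    cnt[1, 1] <- cnt[1, 1] + 1  # ensure non-zero total
    tab <- contingency_table(cnt)
    tt <- transpose_table(tab)
    expect_equal(cohen_kappa(tab)$point, cohen_kappa(tt)$point)
    m <- runif(1, 1, 3)
    expect_equal(weighted_kappa(tab, m)$point,
                 weighted_kappa(tt, m)$point)
  }
})

test_that("identity weights reproduce Cohen's kappa on every table", {
  set.seed(12)
  for (rep in 1:20) {
    k <- sample(2:5, 1)
    cnt <- matrix(rpois(k * k, 3), k) + diag(k)
    tab <- contingency_table(cnt)
    expect_equal(weighted_kappa(tab, identity_weights(k))$point,
                 cohen_kappa(tab)$point, tolerance = 1e-12)
  }
})

test_that("2x2 power-weighted kappa collapses to Cohen's for any m", {
  set.seed(13)
  for (rep in 1:10) {
    cnt <- matrix(rpois(4, 5), 2) + diag(2)
    tab <- contingency_table(cnt)
    for (m in c(1, 2, 7, 2.5))
      expect_equal(weighted_kappa(tab, m)$point, cohen_kappa(tab)$point)
  }
})

test_that("label permutations leave Cohen's kappa unchanged; order reversal leaves power-weighted kappa unchanged", {
  set.seed(14)
  for (rep in 1:10) {
    k <- sample(3:4, 1)
    cnt <- matrix(rpois(k * k, 3), k) + diag(k)
    tab <- contingency_table(cnt)
    perm <- sample(k)
    tab_p <- contingency_table(cnt[perm, perm])
    expect_equal(cohen_kappa(tab_p)$point, cohen_kappa(tab)$point)
    rev_idx <- k:1
    tab_r <- contingency_table(cnt[rev_idx, rev_idx])
    for (m in c(1, 2))
      expect_equal(weighted_kappa(tab_r, m)$point,
                   weighted_kappa(tab, m)$point)
  }
})

test_that("kappa is 1 exactly when no below-unit-weight cell is occupied", {
  diag3 <- contingency_table(diag(c(3, 4, 5)))
  expect_equal(cohen_kappa(diag3)$point, 1)
  expect_equal(weighted_kappa(diag3, 2)$point, 1)
  off <- contingency_table(diag(c(3, 4, 5)) +
                             matrix(c(0, 1, 0, 0, 0, 0, 0, 0, 0), 3))
  expect_lt(cohen_kappa(off)$point, 1)
  expect_lt(weighted_kappa(off, 1)$point, 1)
})

test_that("matrix computation agrees exactly with the per-subject brute-force tally", {
  set.seed(42)
  for (rep in 1:60) {
    k <- sample(2:4, 1)
    n <- sample(5:50, 1)
    r <- random_ratings(n, k)
    labels <- LETTERS[seq_len(k)]
    scale <- rating_scale(labels)
    tab <- build_table(r, scale)
    for (m in c(NA, 1, 2)) {
      w <- if (is.na(m)) identity_weights(scale) else power_weights(scale, m)
      est <- weighted_kappa(tab, w)
      oracle <- brute_force_kappa(r$rater_a, r$rater_b, labels, w$weights)
      expect_equal(est$point, oracle, tolerance = 1e-10)
    }
  }
})
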