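test_that("asymptotic SEs match the frozen cross-implementation values", {
  for (id in rownames(frozen_reference)) {
    tab <- fixture_table(id)
    expect_equal(asymptotic_se(tab), frozen_reference[id, "se_c"],
                 tolerance = 1e-8)
    expect_equal(asymptotic_se(tab, 1), frozen_reference[id, "se_lw"],
                 tolerance = 1e-8)
    expect_equal(asymptotic_se(tab, 2), frozen_reference[id, "se_qw"],
                 tolerance = 1e-8)
  }
  # independent tables of another size, same frozen source
  t1 <- contingency_table(matrix(c(11, 9, 7, 5, 5, 16, 1, 8,
                                   2, 1, 19, 11, 8, 9, 8, 18),
                                 4, byrow = TRUE))
  expect_equal(cohen_kappa(t1)$point, 0.2808957116, tolerance = 1e-9)
  expect_equal(asymptotic_se(t1), 0.0570932450, tolerance = 1e-8)
  expect_equal(weighted_kappa(t1, 1)$point, 0.2714932127, tolerance = 1e-9)
  expect_equal(asymptotic_se(t1, 1), 0.0653194050, tolerance = 1e-8)
  expect_equal(weighted_kappa(t1, 2)$point, 0.2659269418, tolerance = 1e-9)
  expect_equal(asymptotic_se(t1, 2), 0.0853877929, tolerance = 1e-8)
})

test_that("the SE scales as 1/sqrt(n)", {
  tab <- fixture_table("testing_r1")
  doubled <- contingency_table(2 * tab$counts, scale = tab$scale)
  for (w in list(NULL, 1, 2))
    expect_equal(asymptotic_se(doubled, w),
                 asymptotic_se(tab, w) / sqrt(2), tolerance = 1e-9)
})

test_that("the asymptotic SE tracks the Monte-Carlo sampling SD", {
  tab <- fixture_table("testing_r1")
  model <- joint_model(tab$counts / tab$n_subjects, tab$scale)
  n <- 31L * 64L  # population proportions stay exactly representable
  kappas <- numeric(500)
  for (r in seq_len(500)) {
    s <- sample_ratings(model, n, seed = 50000 + r)
    kappas[r] <- cohen_kappa(build_table(s, tab$scale))$point
  }
  se_pred <- asymptotic_se(contingency_table(tab$counts * 64L,
                                             scale = tab$scale))
  expect_lt(abs(se_pred - sd(kappas)) / sd(kappas), 0.15)
})

test_that("Wald intervals and tests are mutually consistent", {
  tab <- fixture_table("testing_r2")
  inf <- wald_interval(cohen_kappa(tab), asymptotic_se(tab))
  expect_gt(inf$p_value, 0.05)
  expect_lt(inf$ci_low, 0)
  expect_gt(inf$ci_high, 0)

  sig <- wald_interval(cohen_kappa(fixture_table("testing_r1")),
                       asymptotic_se(fixture_table("testing_r1")))
  expect_lt(sig$p_value, 0.05)
  expect_gt(sig$ci_low, 0)

  # CI excludes 0 <=> p < alpha, across a grid of alphas
  for (alpha in c(0.01, 0.05, 0.2, 0.5)) {
    i <- wald_interval(cohen_kappa(tab), asymptotic_se(tab), alpha)
    excludes <- i$ci_low > 0 || i$ci_high < 0
    expect_identical(excludes, i$p_value < alpha)
  }

  # wider confidence -> wider interval
  i95 <- wald_interval(sig$estimate, sig$se, 0.05)
  i99 <- wald_interval(sig$estimate, sig$se, 0.01)
  expect_lt(i99$ci_low, i95$ci_low)
  expect_gt(i99$ci_high, i95$ci_high)
})

test_that("Wald edge cases behave: null point, zero SE, clipping", {
  indep <- cohen_kappa(contingency_table(matrix(5, 2, 2)))
  inf <- wald_interval(indep, 0.2)
  expect_equal(inf$p_value, 1)
  expect_equal(inf$ci_low, -inf$ci_high)

  perfect <- cohen_kappa(contingency_table(matrix(c(5, 0, 0, 7), 2)))
  degen <- wald_interval(perfect, 0)
  expect_equal(degen$p_value, 0)
  expect_true(degen$degenerate)
  expect_equal(c(degen$ci_low, degen$ci_high), c(1, 1))

  wide <- wald_interval(perfect, 5)
  expect_gte(wide$ci_low, -1)
  expect_lte(wide$ci_high, 1)
})

test_that("p-values fall as the point estimate grows at fixed SE", {
  tab <- fixture_table("testing_r1")
  se <- asymptotic_se(tab)
  ps <- vapply(list(fixture_table("testing_r2"), tab,
                    fixture_table("validation_r1")), function(t) {
    est <- cohen_kappa(t)
    wald_interval(est, se)$p_value
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("bootstrap CIs are reproducible and bracket the asymptotic CI", {
  ratings <- expand_to_ratings(fixture_table("testing_r1"))
  b1 <- bootstrap_ci(ratings, NULL, n_boot = 2000, seed = 1)
  b2 <- bootstrap_ci(ratings, NULL, n_boot = 2000, seed = 1)
  expect_identical(c(b1$ci_low, b1$ci_high), c(b2$ci_low, b2$ci_high))
  expect_identical(b1$method, "bootstrap")

  a <- wald_interval(cohen_kappa(fixture_table("testing_r1")),
                     asymptotic_se(fixture_table("testing_r1")))
  expect_lt(abs(b1$ci_low - a$ci_low), 0.08)
  expect_lt(abs(b1$ci_high - a$ci_high), 0.08)
})

test_that("bootstrap accepts a table (multinomial cells) and handles degeneracy", {
  tab <- fixture_table("testing_r1")
  bt <- bootstrap_ci(tab, 1, n_boot = 200, seed = 3)
  expect_s3_class(bt, "kappa_inference")
  expect_lte(bt$ci_low, bt$ci_high)

  # perfect agreement over two categories: every defined replicate is 1
  perfect <- paired_ratings(rep(c("a", "b"), 5), rep(c("a", "b"), 5))
  bp <- bootstrap_ci(perfect, NULL, n_boot = 300, seed = 4)
  expect_equal(c(bp$ci_low, bp$ci_high), c(1, 1))

  expect_error(bootstrap_ci(tab, NULL, n_boot = 50, seed = 1),
               "at least 100")
  expect_error(bootstrap_ci(tab, NULL, n_boot = 200), "seed")
})
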