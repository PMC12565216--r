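test_that("CUS totals sum components and positivity is total >= 1", {
  expect_equal(cus_total(2, 1, 0), 3L)
  expect_equal(cus_total(0, 0, 0), 0L)
  expect_error(cus_total(4, 0, 0), "0..3")
  expect_error(cus_total(1, 3, 0), "0..2")
  expect_false(cus_positive(0L))
  expect_true(cus_positive(1L))
  expect_equal(cus_positive(c(0L, 1L, 6L)), c(FALSE, TRUE, TRUE))
})

test_that("SSS class mapping follows the published bands", {
  expect_equal(sss_total(3, 2, 1), 6L)
  expect_error(sss_total(-1, 0, 0), "0..3")
  cls <- sss_class(c(0L, 1L, 2L, 3L, 4L, 5L, 7L))
  expect_equal(as.character(cls),
               c("none", "mild", "mild", "moderate", "moderate",
                 "severe", "severe"))
  over <- sss_class(8L)
  expect_equal(as.character(over), "severe")
  expect_true(attr(over, "out_of_table"))
  expect_equal(steatosis_grade(c(0L, 2L, 4L, 7L)), c(0L, 1L, 2L, 3L))
})

test_that("screening metrics match a hand-tallied confusion matrix", {
  truth <- c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, TRUE, FALSE, FALSE)
  pred <- c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, TRUE, FALSE)
  s <- screening_metrics(truth, pred)
  expect_equal(c(s$tp, s$fp, s$tn, s$fn), c(3, 2, 3, 2))
  expect_equal(s$sensitivity, 3 / 5)
  expect_equal(s$specificity, 3 / 5)
  expect_equal(s$accuracy, 6 / 10)
  expect_equal(s$ppv, 3 / 5)
  expect_equal(s$tp + s$fp + s$tn + s$fn, s$n)

  perfect <- screening_metrics(truth, truth)
  expect_equal(
    c(perfect$sensitivity, perfect$specificity, perfect$accuracy, perfect$ppv),
    rep(1, 4)
  )
})

test_that("swapping the truth labels swaps sensitivity and specificity", {
  set.seed(77)
  truth <- runif(40) > 0.5
  pred <- runif(40) > 0.5
  a <- screening_metrics(truth, pred)
  b <- screening_metrics(!truth, !pred)
  expect_equal(a$sensitivity, b$specificity)
  expect_equal(a$specificity, b$sensitivity)
})

test_that("zero-denominator rates are reported as NA", {
  s <- screening_metrics(c(TRUE, TRUE), c(FALSE, FALSE))
  expect_true(is.na(s$specificity))
  expect_true(is.na(s$ppv))
  expect_equal(s$sensitivity, 0)
})

test_that("tidy and glance expose the screening result as tibbles", {
  s <- screening_metrics(c(TRUE, FALSE), c(TRUE, FALSE))
  td <- tidy(s)
  expect_equal(td$metric,
               c("sensitivity", "specificity", "accuracy", "ppv"))
  expect_equal(td$estimate, rep(1, 4))
  expect_equal(glance(s)$n, 2L)
})

test_that("cutoffs are the reference maximum with a strict rule", {
  vals <- c(0.5, 0.69, 0.803, 1.2, 0.9)
  ref <- c(TRUE, TRUE, TRUE, FALSE, FALSE)
  cut <- derive_cutoff(vals, ref)
  expect_equal(as.numeric(cut), 0.803)
  expect_match(attr(cut, "rule"), "value > cutoff")
  expect_equal(as.numeric(derive_cutoff(5, TRUE)), 5)
  expect_error(derive_cutoff(vals, rep(FALSE, 5)), "empty")
  # strict rule: the reference set itself is all-negative -> specificity 1
  s <- screening_metrics(!ref, vals > cut)
  expect_equal(s$specificity, 1)
})

test_that("indeterminate zone is the class overlap interval", {
  z <- indeterminate_zone(c(0.5, 0.8, 0.6, 1.2), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(c(z$low, z$high), c(0.6, 0.8))
  expect_false(z$empty)
  z2 <- indeterminate_zone(c(0.5, 0.9), c(FALSE, TRUE))
  expect_true(z2$empty)
  expect_error(indeterminate_zone(c(1, 2), c(TRUE, TRUE)), "classes")
})

test_that("spearman matches the explicit ranking oracle on 1000 tied vectors", {
  set.seed(99)
  for (i in 1:1000) {
    n <- sample(4:12, 1)
    x <- sample(0:4, n, replace = TRUE)
    y <- sample(0:6, n, replace = TRUE)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    expect_equal(spearman_cor(x, y)$estimate, oracle_spearman(x, y),
                 tolerance = 1e-10)
  }
})

test_that("spearman handles monotone pairs and the worked tie example", {
  r <- spearman_cor(1:10, (1:10)^3)
  expect_equal(r$estimate, 1)
  expect_lt(r$p, 1e-12)
  tied <- spearman_cor(c(1, 2, 2, 3), c(10, 20, 20, 40))
  expect_equal(tied$estimate, oracle_spearman(c(1, 2, 2, 3), c(10, 20, 20, 40)))
  expect_error(spearman_cor(c(1, 1, 1, 1), 1:4), "rank variance")
  ci <- spearman_cor(1:20, 1:20 + rnorm(20, sd = 3))
  expect_true(ci$ci_low <= ci$estimate && ci$estimate <= ci$ci_high)
})

test_that("Bonferroni thresholds divide the family alpha", {
  expect_equal(bonferroni_alpha(0.05, 1), 0.05)
  expect_equal(bonferroni_alpha(0.05, 5), 0.01)
  expect_equal(bonferroni_alpha(0.05, 6), 0.05 / 6)
  expect_error(bonferroni_alpha(0.05, 0), ">= 1")
})

test_that("min-max normalization maps range to [0,1] preserving order", {
  expect_equal(as.numeric(minmax_normalize(c(0, 5, 10))), c(0, 0.5, 1))
  set.seed(4)
  v <- rnorm(30)
  nv <- minmax_normalize(v)
  expect_equal(min(nv), 0)
  expect_equal(max(nv), 1)
  expect_equal(rank(nv), rank(v))
  flat <- minmax_normalize(c(2, 2, 2))
  expect_equal(as.numeric(flat), rep(0.5, 3))
  expect_true(attr(flat, "degenerate"))
})

test_that("percent change reproduces the worked phenotype examples", {
  expect_equal(round(percent_change(239.4, 262.8), 1), 9.8)
  expect_equal(round(percent_change(90.5, 144.95)), 60)
  expect_equal(percent_change(7, 7), 0)
  expect_error(percent_change(0, 5), "Zero")
})
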