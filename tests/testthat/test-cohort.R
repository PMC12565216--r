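fixture <- load_cohort_fixture()

test_that("fixture tables pass their integrity checks", {
  expect_s3_class(fixture, "cohort_fixture")
  expect_equal(sum(fixture$table3$n), 45)
  sizes <- vapply(split(fixture$table3$n, fixture$table3$group), sum, integer(1))
  expect_equal(sizes[c("WT_SD", "KO_SD", "WT_WD", "KO_WD")],
               c(WT_SD = 7L, KO_SD = 7L, WT_WD = 16L, KO_WD = 15L))
  # corrupting a count is caught
  broken <- unclass(fixture)
  broken$table3$n[1] <- broken$table3$n[1] + 1L
  expect_error(steatoscan:::validate_fixture(broken), "integrity")
})

test_that("fixture prevalences match the published per-group fractions", {
  t3 <- fixture$table3
  steatotic <- function(g) {
    sum(t3$n[t3$group == g & t3$sss_total >= 1]) / sum(t3$n[t3$group == g])
  }
  expect_equal(steatotic("KO_SD"), 3 / 7)
  expect_equal(steatotic("WT_WD"), 12 / 16)
  expect_equal(steatotic("KO_WD"), 15 / 15)
  expect_equal(steatotic("WT_SD"), 0)
})

test_that("exact mode reproduces the published confusion matrix", {
  co <- simulate_cohort(fixture, "exact", seed = 1)
  expect_equal(nrow(co), 45)
  s <- screening_metrics(co$sss_total >= 1, cus_positive(co$cus_total))
  expect_equal(c(s$tp, s$fp, s$tn, s$fn), c(30, 6, 9, 0))
  # score components recompose their totals
  expect_equal(cus_total(co$cus_parenchyma, co$cus_relative, co$cus_ascites),
               co$cus_total)
  expect_equal(sss_total(co$sss_macro, co$sss_micro, co$sss_hypertrophy),
               co$sss_total)
})

test_that("exact mode is deterministic given a seed", {
  a <- simulate_cohort(fixture, "exact", seed = 9)
  b <- simulate_cohort(fixture, "exact", seed = 9)
  expect_identical(a, b)
})

test_that("drawn HRI respects the published cell ranges where consistent", {
  co <- simulate_cohort(fixture, "exact", seed = 3)
  t4 <- fixture$table4
  for (i in seq_len(nrow(t4))) {
    if (t4$range_inconsistent[i] || is.na(t4$hri_min[i])) next
    cell <- co$hri[co$group == t4$group[i] & co$sss_total == t4$sss_total[i]]
    expect_true(all(cell >= t4$hri_min[i] & cell <= t4$hri_max[i]),
                label = paste(t4$group[i], t4$sss_total[i]))
  }
  expect_true(all(co$hri > 0))
})

test_that("resampled cohorts track the fixture cell frequencies within 3 SE", {
  n <- 450
  co <- simulate_cohort(fixture, "resample", n = n, seed = 12)
  expect_equal(nrow(co), n)
  t3 <- fixture$table3
  for (g in unique(t3$group)) {
    rows <- t3[t3$group == g, ]
    ng <- sum(co$group == g)
    for (j in seq_len(nrow(rows))) {
      p <- rows$n[j] / sum(rows$n)
      obs <- sum(co$group == g & co$cus_total == rows$cus_total[j] &
                   co$sss_total == rows$sss_total[j])
      se <- sqrt(ng * p * (1 - p))
      expect_lt(abs(obs - ng * p), max(3 * se, 1e-9) + 1e-9)
    }
  }
  expect_error(simulate_cohort(fixture, "resample", n = 3), ">= 4")
})

test_that("resampled cohorts keep a strong CUS-grade correlation", {
  for (s in 1:5) {
    co <- simulate_cohort(fixture, "resample", n = 45, seed = 100 + s)
    expect_gt(spearman_cor(co$cus_total, co$grade)$estimate, 0.7)
  }
})

test_that("phenotype summary reproduces the published percent changes", {
  ph <- phenotype_summary(fixture)
  pick <- function(geno, var) {
    ph$percent_change[ph$genotype == geno & ph$variable == var]
  }
  expect_equal(round(pick("WT", "energy_intake"), 1), 9.8)
  expect_equal(round(pick("KO", "fer")), 60)
  expect_equal(round(pick("WT", "bw_gain"), 1), 25.6)
  expect_equal(round(pick("KO", "energy_intake"), 1), 17.5)
})

test_that("the full pipeline runs end to end with ordered HRI class means", {
  rep1 <- run_pipeline(seed = 5, fixture = fixture, n_lobes = 2, size = 256)
  expect_s3_class(rep1, "steatosis_report")
  expect_equal(rep1$cus_screening$sensitivity, 1)
  expect_equal(rep1$alpha, 0.05 / 6)
  expect_equal(nrow(rep1$cohort), 45)
  expect_equal(sum(rep1$table3_style$n), 45)
  expect_true(all(c("hri_img", "contrast", "sum_entropy") %in%
                    names(rep1$cohort)))
  # HRI screening at the derived cutoff is fully specific by construction
  expect_equal(rep1$hri_screening$specificity, 1)
  expect_equal(rep1$hri_cutoff,
               max(rep1$cohort$hri[rep1$cohort$sss_total == 0]))
  # image-derived HRI class means are ordered none < mild < moderate < severe
  cls_means <- tapply(rep1$cohort$hri_img, rep1$cohort$steatosis_class, mean)
  expect_true(all(diff(cls_means) > 0))
})

test_that("the pipeline is seed-reproducible", {
  rep1 <- run_pipeline(seed = 7, fixture = fixture, n_lobes = 1, size = 64)
  rep2 <- run_pipeline(seed = 7, fixture = fixture, n_lobes = 1, size = 64)
  expect_identical(rep1$cohort, rep2$cohort)
  expect_identical(tidy(rep1$cus_screening), tidy(rep2$cus_screening))
})

test_that("report plots build without error", {
  co <- simulate_cohort(fixture, "exact", seed = 2)
  co$contrast <- rnorm(45)
  co$correlation <- rnorm(45)
  co$energy <- runif(45)
  co$sum_entropy <- runif(45, 6, 8)
  expect_s3_class(plot_feature_distributions(co), "ggplot")
  expect_s3_class(plot_hri_by_class(co, cutoff = 0.803), "ggplot")
  s <- screening_metrics(co$sss_total >= 1, cus_positive(co$cus_total))
  expect_s3_class(autoplot(s), "ggplot")
})
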