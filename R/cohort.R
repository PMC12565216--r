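# Inverse-CDF draw from a normal truncated to [lo, hi].
rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  a <- pnorm(lo, mean, sd)
  b <- pnorm(hi, mean, sd)
  qnorm(runif(n, a, b), mean, sd)
}

draw_hri <- function(n, mean, sd, lo, hi, inconsistent) {
  if (is.na(sd)) return(rep(mean, n))
  if (isTRUE(inconsistent) || is.na(lo) || is.na(hi)) return(rnorm(n, mean, sd))
  rtruncnorm1(n, mean, sd, lo, hi)
}

#' Simulate a cohort from the packaged score distributions
#'
#' Two modes:
#' \describe{
#'   \item{exact}{One animal per table3 count cell: a deterministic 45-animal
#'     cohort whose joint (group, CUS, SSS) distribution reproduces the
#'     published counts exactly.}
#'   \item{resample}{`n` animals, allocated to the four groups
#'     proportionally to the study sizes (7/7/16/15, largest-remainder
#'     rounding) and drawn group-conditionally from the table3 cell
#'     multinomial.}
#' }
#' In both modes each animal's hepatorenal index is drawn from a normal
#' truncated to the published range with the (group, SSS) cell mean/SD from
#' table4; single-animal cells use the printed value; the one
#' range-inconsistent cell falls back to an untruncated normal. Score totals
#' are split into components by a fixed fill rule (parenchyma, then relative
#' echogenicity, then ascites; macro, then micro, then hypertrophy; each
#' component at its ceiling).
#'
#' @param fixture A [load_cohort_fixture()] result.
#' @param mode `"exact"` or `"resample"`.
#' @param n Cohort size for resample mode (>= 4).
#' @param seed Optional RNG seed.
#' @return Tibble with one row per animal: `subject`, `group`, `genotype`,
#'   `diet`, `age_weeks`, CUS components and total, SSS components and
#'   total, `steatosis_class`, `grade`, `hri`.
#' @export
simulate_cohort <- function(fixture, mode = c("exact", "resample"),
                            n = NULL, seed = NULL) {
  stopifnot(inherits(fixture, "cohort_fixture"))
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  t3 <- fixture$table3

  if (mode == "exact") {
    cells <- t3[rep(seq_len(nrow(t3)), t3$n), ]
  } else {
    if (is.null(n) || n < 4L) {
      abort("Resample mode needs `n` >= 4 (one animal per group at minimum).")
    }
    share <- n * GROUP_SIZES / sum(GROUP_SIZES)
    sizes <- floor(share)
    rem <- n - sum(sizes)
    if (rem > 0) {
      top <- order(share - sizes, decreasing = TRUE)[seq_len(rem)]
      sizes[top] <- sizes[top] + 1L
    }
    cells <- purrr::map_dfr(names(GROUP_SIZES), function(g) {
      rows <- t3[t3$group == g, ]
      draw <- sample(nrow(rows), sizes[[g]], replace = TRUE, prob = rows$n)
      rows[draw, ]
    })
  }

  cohort <- dplyr::bind_cols(
    tibble::tibble(
      subject = sprintf("M%03d", seq_len(nrow(cells))),
      group = cells$group, genotype = cells$genotype, diet = cells$diet,
      age_weeks = 24
    ),
    split_cus_total(cells$cus_total),
    tibble::tibble(cus_total = as.integer(cells$cus_total)),
    split_sss_total(cells$sss_total),
    tibble::tibble(sss_total = as.integer(cells$sss_total))
  )
  cohort$steatosis_class <- sss_class(cohort$sss_total)
  cohort$grade <- steatosis_grade(cohort$sss_total)

  t4 <- fixture$table4
  key <- match(
    paste(cohort$group, cohort$sss_total),
    paste(t4$group, t4$sss_total)
  )
  if (anyNA(key)) abort("Drawn (group, SSS) combination has no table4 cell.")
  cohort$hri <- vapply(key, function(k) {
    draw_hri(1L, t4$hri_mean[k], t4$hri_sd[k], t4$hri_min[k], t4$hri_max[k],
             t4$range_inconsistent[k])
  }, numeric(1))
  cohort
}

#' Phenotype percent changes, Western diet vs standard diet
#'
#' Applies [percent_change()] to the table1 group means of body-weight gain,
#' cumulative energy intake, and feed efficiency ratio, per genotype.
#'
#' @param fixture A [load_cohort_fixture()] result.
#' @return Tibble with `genotype`, `variable`, `sd_mean`, `wd_mean`,
#'   `percent_change`.
#' @export
phenotype_summary <- function(fixture) {
  stopifnot(inherits(fixture, "cohort_fixture"))
  t1 <- dplyr::filter(
    fixture$table1,
    .data$variable %in% c("bw_gain", "energy_intake", "fer")
  )
  wide <- tidyr::pivot_wider(
    dplyr::select(t1, "genotype", "diet", "variable", "mean"),
    names_from = "diet", values_from = "mean"
  )
  dplyr::mutate(
    dplyr::select(wide, "genotype", "variable", sd_mean = "SD", wd_mean = "WD"),
    percent_change = percent_change(.data$sd_mean, .data$wd_mean)
  )
}

#' Run the full assessment pipeline on a simulated cohort
#'
#' End-to-end orchestration: builds the exact 45-animal cohort, simulates
#' `n_lobes` B-mode scans per animal at its steatosis grade, extracts the
#' hepatorenal index and the four texture features from each scan, averages
#' features per animal, and computes the study's statistical layer — CUS
#' screening against histology, HRI screening at the data-derived cutoff
#' (max over SSS = 0), the second-stage cutoff (max over SSS 1-2),
#' Bonferroni-controlled Spearman correlations of the six ultrasound
#' parameters against the steatosis grade, and the report cross-tabs.
#'
#' @param seed RNG seed driving every stochastic stage.
#' @param fixture A [load_cohort_fixture()] result.
#' @param n_lobes Simulated scans per animal (the study averaged features
#'   over all imaged liver lobes).
#' @param size Simulated image side length in pixels.
#' @return A `steatosis_report` list: `cohort` (with image-derived `hri_img`
#'   and features), `cus_screening`, `hri_screening`, `hri_cutoff`,
#'   `severity_cutoff`, `correlations`, `alpha`, `table3_style`,
#'   `table4_style`, `feature_distribution`.
#' @export
run_pipeline <- function(seed = 1, fixture = load_cohort_fixture(),
                         n_lobes = 3, size = 256) {
  cohort <- simulate_cohort(fixture, "exact", seed = seed)

  imaging <- purrr::map_dfr(seq_len(nrow(cohort)), function(i) {
    per_lobe <- purrr::map_dfr(seq_len(n_lobes), function(lobe) {
      sim <- simulate_grade_image(
        grade = cohort$grade[i],
        seed = seed + 1000L + i * n_lobes + lobe,
        size = size
      )
      feats <- extract_features(sim$image, sim$liver_roi)
      feats$hri_img <- hri_from_image(sim$image, sim$liver_roi, sim$renal_roi)$hri
      feats
    })
    out <- features_for_subject(per_lobe)
    out$hri_img <- mean(per_lobe$hri_img)
    out
  })
  cohort <- dplyr::bind_cols(cohort, imaging)

  truth <- cohort$sss_total >= 1L
  cus_screening <- screening_metrics(truth, cus_positive(cohort$cus_total))

  hri_cutoff <- derive_cutoff(cohort$hri, reference = !truth)
  hri_screening <- screening_metrics(truth, cohort$hri > hri_cutoff,
                                     cutoff = as.numeric(hri_cutoff))

  mild_ref <- cohort$sss_total >= 1L & cohort$sss_total <= 2L
  severity_cutoff <- derive_cutoff(cohort$hri[truth], mild_ref[truth])

  alpha <- bonferroni_alpha(0.05, 6)
  predictors <- c("cus_total", "hri", "contrast", "correlation",
                  "energy", "sum_entropy")
  correlations <- purrr::map_dfr(predictors, function(v) {
    tidy(spearman_cor(cohort[[v]], cohort$grade, n_tests = 6))[
      , c("estimate", "ci_low", "ci_high", "p.value", "significant")
    ] |>
      dplyr::mutate(parameter = v, .before = 1)
  })

  table3_style <- dplyr::count(cohort, .data$group, .data$cus_total,
                               .data$sss_total, name = "n")
  table4_style <- dplyr::summarise(
    dplyr::group_by(cohort, .data$group, .data$sss_total),
    n = dplyr::n(),
    hri_mean = mean(.data$hri), hri_sd = sd(.data$hri),
    hri_min = min(.data$hri), hri_max = max(.data$hri),
    .groups = "drop"
  )
  feature_distribution <- cohort |>
    dplyr::mutate(dplyr::across(
      dplyr::all_of(c("contrast", "correlation", "energy", "sum_entropy")),
      ~ as.numeric(minmax_normalize(.x))
    )) |>
    tidyr::pivot_longer(
      dplyr::all_of(c("contrast", "correlation", "energy", "sum_entropy")),
      names_to = "feature", values_to = "normalized"
    ) |>
    dplyr::group_by(.data$steatosis_class, .data$feature) |>
    dplyr::summarise(
      n = dplyr::n(), median = stats::median(.data$normalized),
      mean = mean(.data$normalized),
      .groups = "drop"
    )

  structure(
    list(
      cohort = cohort,
      cus_screening = cus_screening,
      hri_screening = hri_screening,
      hri_cutoff = as.numeric(hri_cutoff),
      severity_cutoff = as.numeric(severity_cutoff),
      correlations = correlations,
      alpha = alpha,
      table3_style = table3_style,
      table4_style = table4_style,
      feature_distribution = feature_distribution,
      seed = seed
    ),
    class = "steatosis_report"
  )
}

#' @export
print.steatosis_report <- function(x, ...) {
  cat("Steatosis assessment report (simulated cohort, n =",
      nrow(x$cohort), ")\n")
  cat(sprintf("Significance threshold (Bonferroni, m = 6): %.5f\n", x$alpha))
  cat("\nCUS screening vs histology:\n")
  print(x$cus_screening)
  cat(sprintf("\nHRI screening at cutoff > %.3f:\n", x$hri_cutoff))
  print(x$hri_screening)
  cat("\nSpearman correlations with steatosis grade:\n")
  print(as.data.frame(x$correlations), digits = 3)
  invisible(x)
}
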