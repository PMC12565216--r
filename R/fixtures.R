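#' Load the packaged 45-animal cohort fixture
#'
#' Reads the published study tables shipped with the package as plain CSV:
#' \describe{
#'   \item{table1}{Per-group phenotype means/SDs (body-weight gain,
#'     cumulative energy intake, feed efficiency ratio, BUN, creatinine) for
#'     the four genotype-by-diet groups.}
#'   \item{table3}{Joint counts over (group, CUS total, SSS total) for the
#'     45 animals at 24 weeks (7 WT-SD, 7 KO-SD, 16 WT-WD, 15 KO-WD).}
#'   \item{table4}{Per-(group, SSS total) hepatorenal-index mean, SD and
#'     range. One cell prints a mean outside its own range in the source and
#'     is stored verbatim with `range_inconsistent = TRUE`.}
#'   \item{table4_classes}{HRI mean/SD/range per severity class (none, mild,
#'     moderate, severe) over all animals.}
#' }
#' Counts are validated on load: the table3 cells must sum to 45 with the
#' stated group sizes, and per-group SSS marginals must agree between
#' table3 and table4.
#'
#' @return A `cohort_fixture`: list of tibbles `table1`, `table3`, `table4`,
#'   `table4_classes`.
#' @export
load_cohort_fixture <- function() {
  path <- function(f) system.file("extdata", f, package = "steatoscan", mustWork = TRUE)
  fixture <- list(
    table1 = tibble::as_tibble(read.csv(path("table1_phenotype.csv"))),
    table3 = tibble::as_tibble(read.csv(path("table3_counts.csv"))),
    table4 = tibble::as_tibble(read.csv(path("table4_hri.csv"))),
    table4_classes = tibble::as_tibble(read.csv(path("table4_classes.csv")))
  )
  validate_fixture(fixture)
}

GROUP_SIZES <- c(WT_SD = 7L, KO_SD = 7L, WT_WD = 16L, KO_WD = 15L)

validate_fixture <- function(fixture) {
  t3 <- fixture$table3
  if (sum(t3$n) != 45L) {
    abort(sprintf("Fixture integrity error: table3 counts sum to %d, not 45.", sum(t3$n)))
  }
  sizes <- vapply(split(t3$n, t3$group), sum, integer(1))
  if (!identical(sizes[names(GROUP_SIZES)], GROUP_SIZES)) {
    abort("Fixture integrity error: table3 group sizes are not 7/7/16/15.")
  }
  t3_marg <- dplyr::count(t3, .data$group, .data$sss_total, wt = .data$n, name = "n3")
  t4 <- dplyr::select(fixture$table4, "group", "sss_total", n4 = "n")
  joined <- dplyr::full_join(t3_marg, t4, by = c("group", "sss_total"))
  if (anyNA(joined$n3) || anyNA(joined$n4) || any(joined$n3 != joined$n4)) {
    abort("Fixture integrity error: table3/table4 SSS marginals disagree.")
  }
  structure(fixture, class = c("cohort_fixture", class(fixture)))
}

# Deterministic split of score totals into components, filling each
# component to its ceiling in a fixed order. Component values are not
# printed per animal in the source tables, so the split is a documented
# package convention.
split_cus_total <- function(total) {
  parenchyma <- pmin(total, 3L)
  relative <- pmin(total - parenchyma, 2L)
  tibble::tibble(
    cus_parenchyma = as.integer(parenchyma),
    cus_relative = as.integer(relative),
    cus_ascites = as.integer(total - parenchyma - relative)
  )
}

split_sss_total <- function(total) {
  macro <- pmin(total, 3L)
  micro <- pmin(total - macro, 3L)
  tibble::tibble(
    sss_macro = as.integer(macro),
    sss_micro = as.integer(micro),
    sss_hypertrophy = as.integer(total - macro - micro)
  )
}
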