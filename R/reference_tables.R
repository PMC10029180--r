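# Published calibration values from the source field survey (a
# cross-sectional 24-h recall survey of 201 women of reproductive age on
# a Bangladeshi island, sampled from a frame of 1169 households across
# nine villages). The raw data are not public; these printed summary
# statistics calibrate the synthetic generator and supply the worked
# examples in the documentation.

#' Reference EAR/TUL values for women of reproductive age
#'
#' ICMR-based estimated average requirements and tolerable upper intake
#' levels for women aged 15-49, one row per micronutrient, in the
#' vocabulary's units. Thiamin, riboflavin and vitamin B12 have no TUL.
#'
#' @return An [ear_table()].
#' @export
ref_ear_wra <- function() {
  ear_table(tibble::tibble(
    nutrient = c("vitamin_a", "vitamin_c", "thiamin", "riboflavin",
                 "niacin", "vitamin_b6", "folate", "vitamin_b12",
                 "calcium", "iron", "zinc"),
    sex = "female", age_lo = 15L, age_hi = 49L,
    ear = c(390, 55, 1.4, 2, 12, 1.6, 180, 2, 800, 15, 11),
    tul = c(3000, 2000, NA, NA, 35, 100, 1000, NA, 2000, 45, 40)))
}

#' Survey intake distribution summaries
#'
#' Median and interquartile daily intakes of the eleven micronutrients
#' observed in the source survey, together with the median NAR it
#' reported. Used to calibrate the generator's intake distributions and
#' in worked adequacy examples.
#'
#' @return Tibble: nutrient, median, p25, p75, median_nar.
#' @export
survey_intake_quantiles <- function() {
  tibble::tibble(
    nutrient = c("vitamin_a", "vitamin_c", "thiamin", "riboflavin",
                 "niacin", "vitamin_b6", "folate", "vitamin_b12",
                 "calcium", "iron", "zinc"),
    median = c(80.4, 45.2, 1.4, 0.7, 34.4, 1.8, 116.9, 2.9, 283.5, 9.5, 9.6),
    p25 = c(29.5, 27.8, 1.2, 0.6, 27.5, 1.5, 87.4, 1.16, 155.8, 6.9, 8.3),
    p75 = c(214.8, 63.9, 1.6, 0.9, 39.8, 2.3, 145.1, 5.5, 645.0, 12.9, 11.4),
    median_nar = c(0.21, 0.82, 0.99, 0.37, 2.67, 1.15, 0.65, 1.49,
                   0.35, 0.64, 0.87))
}

#' Survey food-group consumption prevalence
#'
#' Percentage of surveyed women whose previous-day recall counted each
#' MDD-W food group (15-g rule applied). These proportions drive the
#' generator's default Bernoulli consumption probabilities; by linearity
#' of expectation their sum is the expected dietary diversity score.
#'
#' @return Tibble: group, pct_total.
#' @export
survey_group_prevalence <- function() {
  tibble::tibble(
    group = mddw_groups(),
    pct_total = c(100, 35.3, 10.9, 2.0, 86.6, 21.9, 35.8, 10.9, 78.6, 43.3))
}

#' Survey socio-economic marginal distributions
#'
#' Category proportions of the source survey's woman- and
#' household-level covariates (n = 201), used as the generator's default
#' covariate marginals.
#'
#' @return Named list of named proportion vectors (each sums to 1).
#' @export
survey_covariate_marginals <- function() {
  list(
    age_band = c(`15-24` = 23, `25-34` = 72, `35-49` = 106) / 201,
    village = c(purba_para = 26, deil_para = 24, uttar_para = 19,
                paschim_para = 17, zinzira = 7, konar_para = 29,
                nazrul_para = 19, dakshin_para = 35, majher_para = 25) / 201,
    marital = c(married = 170, unmarried = 31) / 201,
    education = c(none = 74, primary = 112, secondary = 15) / 201,
    occupation = c(housewife = 189, other = 12) / 201,
    household_size_band = c(`<=5` = 112, `>5` = 89) / 201,
    decision_role = c(yes = 127, no = 74) / 201,
    bmi_category = c(underweight = 14, normal = 110, overweight = 77) / 201,
    food_secure = c(secure = 112, insecure = 89) / 201)
}

#' Fit lognormal intake distributions to the survey quantiles
#'
#' For each micronutrient, solves for the lognormal (meanlog, sdlog)
#' matching the printed median and interquartile range:
#' `meanlog = log(median)`, `sdlog = log(p75/p25) / (2 * qnorm(0.75))`.
#' Under the EAR cut-point approach the implied inadequacy prevalence is
#' then `pnorm((log(ear) - meanlog) / sdlog)` in closed form.
#'
#' @param quantiles Tibble as returned by [survey_intake_quantiles()].
#' @return Tibble: nutrient, meanlog, sdlog.
#' @export
fit_intake_lognormal <- function(quantiles = survey_intake_quantiles()) {
  tibble::tibble(
    nutrient = quantiles$nutrient,
    meanlog = log(quantiles$median),
    sdlog = log(quantiles$p75 / quantiles$p25) / (2 * stats::qnorm(0.75)))
}

#' Path to a packaged example/fixture file
#'
#' @param file File name under the package's `extdata/` directory; empty
#'   to list the available files.
#' @return Full path (or the file listing).
#' @export
wradiet_example <- function(file = "") {
  if (!nzchar(file)) {
    return(dir(system.file("extdata", package = "wradiet")))
  }
  path <- system.file("extdata", file, package = "wradiet")
  if (!nzchar(path)) stop("no packaged file called ", file, call. = FALSE)
  path
}

#' Small demonstration food composition table
#'
#' A ~20-food synthetic FCT covering all ten MDD-W groups plus an
#' unclassified oil, with plausible per-100-g densities; used by the
#' generator's defaults, the examples and the tests. Not a copy of any
#' published table.
#'
#' @return An [fct_table()].
#' @export
demo_fct <- function() {
  load_fct(wradiet_example("fct_synthetic.csv"))
}
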