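raw_woman <- function(...) {
  dplyr::mutate(tibble::tibble(
    woman_id = "w1", age_years = 30, village = "konar_para",
    marital = "married", education = "primary", occupation = "housewife",
    income = 12000, household_size = 4, decision_q1 = 1, decision_q2 = 1,
    decision_q3 = 1, height_m = 1.5, weight_kg = 48, food_secure = TRUE,
    energy_kcal = 2000), ...)
}

test_that("covariate derivation applies the banding rules", {
  pop <- dplyr::bind_rows(lapply(1:8, function(i) {
    raw_woman(woman_id = paste0("w", i), income = i * 1000)
  }))
  cov <- derive_covariates(pop)
  # rank quartiles of income: two women per quartile
  expect_equal(as.vector(table(cov$income_quartile)), c(2, 2, 2, 2))
  expect_equal(levels(cov$income_quartile),
               c("lowest", "second", "third", "highest"))

  one <- derive_covariates(raw_woman())
  expect_equal(one$decision_score, 3L)
  expect_equal(as.character(one$decision_role), "yes")
  partial <- derive_covariates(raw_woman(decision_q3 = 0))
  expect_equal(partial$decision_score, 2L)
  expect_equal(as.character(partial$decision_role), "no")

  # WHO BMI bands, boundaries inclusive on the left
  h <- 1.6
  at185 <- derive_covariates(raw_woman(height_m = h,
                                       weight_kg = 18.5 * h^2))
  expect_equal(as.character(at185$bmi_category), "normal")
  at25 <- derive_covariates(raw_woman(height_m = h, weight_kg = 25 * h^2))
  expect_equal(as.character(at25$bmi_category), "overweight")
  under <- derive_covariates(raw_woman(height_m = h, weight_kg = 17 * h^2))
  expect_equal(as.character(under$bmi_category), "underweight")

  expect_error(derive_covariates(raw_woman(age_years = 52)), "15-49")
  expect_error(derive_covariates(raw_woman(height_m = 0)), "positive")
  expect_error(derive_covariates(raw_woman(decision_q1 = 2)), "0/1")
  expect_error(derive_covariates(dplyr::select(raw_woman(), -income)),
               "income")
})

test_that("logistic fit reports odds ratios, references, GOF and null CIs", {
  set.seed(53)
  cov <- derive_covariates(simulate_covariates(3000, seed = 53))
  out <- simulate_mddw_outcomes(cov, effects = list(), seed = 53)
  fit <- fit_mddw_logistic(cov, out,
                           terms = c("education", "decision_role",
                                     "household_size_band"))
  # null generator: every CI should cover OR = 1 in this single draw
  expect_true(all(fit$terms$ci_lo <= 1 & fit$terms$ci_hi >= 1))
  expect_equal(fit$reference_levels$education, "none")
  expect_equal(fit$reference_levels$decision_role, "no")
  gof <- fit$diagnostics$gof
  expect_gt(gof$statistic, 0)
  expect_equal(gof$df, 3000 - length(coef(fit$fit)))
  expect_error(fit_mddw_logistic(cov, rep(TRUE, nrow(cov))),
               "single class")
})

test_that("an injected education odds ratio is recovered", {
  set.seed(59)
  cov <- derive_covariates(simulate_covariates(4000, seed = 59))
  out <- simulate_mddw_outcomes(
    cov, effects = list(list(covariate = "education", level = "secondary",
                             or = 3)), seed = 59)
  fit <- fit_mddw_logistic(cov, out)
  row <- fit$terms[fit$terms$term == "educationsecondary", ]
  expect_true(row$ci_lo <= 3 && 3 <= row$ci_hi)
  expect_gt(row$estimate, 1.5)
})

test_that("collinear terms are flagged by the VIF screen", {
  set.seed(61)
  cov <- derive_covariates(simulate_covariates(500, seed = 61))
  cov$x1 <- rnorm(500)
  cov$x2 <- cov$x1 + rnorm(500, sd = 0.05)   # near-duplicate column
  out <- simulate_mddw_outcomes(cov, seed = 61)
  fit <- fit_mddw_logistic(cov, out, terms = c("education", "x1", "x2"))
  flagged <- fit$diagnostics$vif$term[fit$diagnostics$vif$flagged]
  expect_true(all(c("x1", "x2") %in% flagged))
})

test_that("linear MAR fit recovers structure and screens influence", {
  set.seed(67)
  cov <- derive_covariates(simulate_covariates(800, seed = 67))
  cov$mddw_met <- as.logical(simulate_mddw_outcomes(cov, seed = 670))

  # constant outcome: intercept carries it, slopes vanish ("perfect
  # fit" warnings from the summary machinery are expected here)
  flat <- suppressWarnings(fit_mar_linear(cov, rep(0.5, 800)))
  expect_true(all(abs(flat$terms$estimate) < 1e-10))
  expect_equal(unname(coef(flat$fit)["(Intercept)"]), 0.5)

  mar_v <- simulate_mar_outcomes(
    cov, intercept = 0.3,
    effects = list(list(covariate = "mddw_met", level = "adequate",
                        beta = 0.05)), sd = 0.1, seed = 67)
  fit <- fit_mar_linear(cov, mar_v)
  row <- fit$terms[fit$terms$term == "mddw_metadequate", ]
  expect_true(row$ci_lo <= 0.05 && 0.05 <= row$ci_hi)

  # a gross outlier (in both x and y) lands in the influence listings
  cov_o <- cov
  cov_o$energy_kcal[13] <- 60000
  mar_out <- mar_v
  mar_out[13] <- 40
  fit_o <- fit_mar_linear(cov_o, mar_out)
  expect_true(13 %in% c(fit_o$diagnostics$cooks_over_1,
                        fit_o$diagnostics$high_leverage))

  # fixed leverage cutoff option is honoured
  fit_f <- fit_mar_linear(cov, mar_v, leverage_cutoff = "fixed",
                          leverage_fixed = 0.05)
  expect_equal(fit_f$diagnostics$leverage_cutoff, 0.05)
})

test_that("Cochran's sample-size formula", {
  expect_equal(cochran_sample_size(0.5), 385L)
  expect_equal(cochran_sample_size(0.132), 177L)
  # halving the precision quadruples the requirement (before ceiling)
  expect_equal(1.96^2 * 0.3 * 0.7 / 0.025^2,
               4 * (1.96^2 * 0.3 * 0.7 / 0.05^2))
  expect_error(cochran_sample_size(0), "p must be")
  expect_error(cochran_sample_size(0.5, d = 0), "d must be")
})
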