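test_that("config validation catches malformed inputs", {
  expect_s3_class(survey_config(), "survey_config")
  bad <- survey_config()
  bad$group_prob[["dairy"]] <- 1.2
  expect_error(validate_config(bad), "group_prob")
  bad2 <- survey_config()
  bad2$villages <- bad2$villages * 2
  expect_error(validate_config(bad2), "sum to 1")
  expect_error(survey_config(effects = list(list(covariate = "education",
                                                 level = "secondary"))),
               "malformed effect")
})

test_that("default configuration carries the published calibration", {
  cfg <- survey_config()
  expect_equal(cfg$n_households, 201)
  expect_equal(cfg$sampling_frame_households, 1169)
  expect_equal(cfg$group_prob[["starchy_staples"]], 1.00)
  expect_equal(cfg$group_prob[["dairy"]], 0.02)
  expect_equal(cfg$covariate_marginals$age_band[["35-49"]], 106 / 201)
})

test_that("generation is deterministic for a fixed seed", {
  a <- generate_survey(survey_config(n_households = 40, seed = 9))
  b <- generate_survey(survey_config(n_households = 40, seed = 9))
  expect_identical(a$roster, b$roster)
  expect_identical(a$recall, b$recall)
  expect_identical(a$covariates, b$covariates)
  expect_identical(a$truth$women, b$truth$women)
  c <- generate_survey(survey_config(n_households = 40, seed = 10))
  expect_false(identical(a$recall, c$recall))
})

test_that("structural invariants of generated surveys hold", {
  s <- generate_survey(survey_config(n_households = 60, seed = 13))
  idx <- s$roster[s$roster$is_index_wra, ]
  expect_equal(nrow(idx), 60)                      # one index woman each
  expect_true(all(idx$sex == "female"))
  expect_true(all(idx$age_years >= 15 & idx$age_years <= 49))
  expect_true(all(s$recall$grams >= 0))

  cfg0 <- survey_config(n_households = 60, seed = 13)
  cfg0$group_prob[["dairy"]] <- 0
  s0 <- generate_survey(cfg0)
  fct <- demo_fct()
  dairy_codes <- fct$entries$food_code[fct$entries$mddw_group == "dairy"]
  expect_false(any(s0$recall$food_code %in% dairy_codes))
})

test_that("written survey files round-trip and exclude the truth", {
  dir <- withr::local_tempdir()
  s <- generate_survey(survey_config(n_households = 15, seed = 21))
  write_survey(s, dir)
  expect_setequal(dir(dir), c("roster.csv", "recall.csv", "covariates.csv",
                              "truth.json"))
  roster <- readr::read_csv(file.path(dir, "roster.csv"),
                            col_types = "ccicl")
  expect_equal(roster$member_id, s$roster$member_id)
  expect_false("dds" %in% names(readr::read_csv(
    file.path(dir, "covariates.csv"), show_col_types = FALSE)))
})

test_that("closed-form expectations match the independence structure", {
  cfg <- survey_config()
  cfg$group_prob[] <- 1
  e <- closed_form_expectations(cfg)
  expect_equal(e$expected_dds, 10)
  expect_equal(e$expected_mddw_prevalence, 1)

  expect_equal(closed_form_expectations()$expected_dds, 4.253,
               tolerance = 1e-12)

  with_fx <- survey_config(effects = list(list(
    covariate = "education", level = "secondary",
    outcome = "group_prob_shift", size = 2)))
  expect_error(closed_form_expectations(with_fx), "independence")
  with_latent <- survey_config(latent_sd = 0.5)
  expect_error(closed_form_expectations(with_latent), "independence")
})

test_that("generated covariate marginals converge to the configuration", {
  raw <- simulate_covariates(20000, seed = 31)
  marg <- survey_covariate_marginals()
  for (nm in c("village", "education", "marital")) {
    obs <- table(factor(raw[[nm]], levels = names(marg[[nm]])))
    p <- stats::chisq.test(obs, p = marg[[nm]])$p.value
    expect_gt(p, 0.01)
  }
  cov <- derive_covariates(raw)
  obs_bmi <- table(factor(cov$bmi_category,
                          levels = names(marg$bmi_category)))
  expect_gt(stats::chisq.test(obs_bmi, p = marg$bmi_category)$p.value, 0.01)
})

test_that("a latent diet-quality factor induces DDS overdispersion", {
  ind <- generate_survey(survey_config(n_households = 3000, seed = 37))
  dep <- generate_survey(survey_config(n_households = 3000, seed = 37,
                                       latent_sd = 1.5))
  expect_gt(stats::var(dep$truth$women$dds), stats::var(ind$truth$women$dds))
})
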