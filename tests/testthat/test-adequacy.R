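ears <- ref_ear_wra()

test_that("NAR is the intake:requirement ratio", {
  expect_equal(round(nar(45.2, 55), 2), 0.82)      # vitamin C
  expect_equal(round(nar(283.5, 800), 2), 0.35)    # calcium
  expect_equal(nar(55, 55), 1.0)
  expect_error(nar(10, 0), "EAR")
  expect_error(nar(-1, 55), "intake")
  # scale invariance
  set.seed(3)
  for (rep in 1:20) {
    i <- runif(1, 0, 100); e <- runif(1, 1, 100); k <- runif(1, 0.1, 10)
    expect_equal(nar(k * i, k * e), nar(i, e), tolerance = 1e-12)
  }
})

test_that("truncation follows the selected convention", {
  expect_equal(truncate_nar(1.49, "binary"), 1)
  expect_equal(truncate_nar(0.82, "binary"), 0)
  expect_equal(truncate_nar(0.82, "cap"), 0.82)
  expect_equal(truncate_nar(1.0, "binary"), 1)
  expect_equal(truncate_nar(1.0, "cap"), 1)
  expect_equal(truncate_nar(1.49, "cap"), 1)
  # cap dominates binary pointwise
  x <- runif(200, 0, 3)
  expect_true(all(truncate_nar(x, "cap") >= truncate_nar(x, "binary")))
})

test_that("MAR averages the truncated NARs over exactly 11 nutrients", {
  all_met <- stats::setNames(rep(1, 11), micronutrients())
  expect_equal(mar(all_met), 1)
  expect_equal(mar(all_met * 0), 0)
  one_met <- stats::setNames(truncate_nar(c(2, rep(0.5, 10)), "binary"),
                             micronutrients())
  expect_equal(mar(one_met), 1 / 11)
  expect_error(mar(all_met[-1]), "missing: vitamin_a")
})

test_that("adequacy profiles classify against the EAR reference", {
  at_ear <- adequacy_profile(ear_intake_vector(), ears, 30)
  expect_false(any(at_ear$per_nutrient$below_ear))
  expect_equal(at_ear$mar, 1)

  zero <- adequacy_profile(nutrient_vector(), ears, 30)
  expect_equal(zero$mar, 0)
  expect_true(all(zero$per_nutrient$nar == 0))

  # woman at the survey's median intakes: inadequate exactly for
  # vitamin A, vitamin C, riboflavin, folate, calcium, iron, zinc
  med <- survey_intake_quantiles()
  iv <- nutrient_vector(.values = c(
    energy = 2000, stats::setNames(med$median, med$nutrient)))
  prof <- adequacy_profile(iv, ears, 30)
  below <- prof$per_nutrient$nutrient[prof$per_nutrient$below_ear]
  expect_setequal(below, c("vitamin_a", "vitamin_c", "riboflavin",
                           "folate", "calcium", "iron", "zinc"))
  # above_tul undefined where no TUL exists (thiamin, riboflavin, B12)
  na_tul <- prof$per_nutrient$nutrient[is.na(prof$per_nutrient$above_tul)]
  expect_setequal(na_tul, c("thiamin", "riboflavin", "vitamin_b12"))

  expect_error(adequacy_profile(iv, ears[-1, ], 30), "vitamin_a")
})

test_that("MAR is monotone in any single intake and cap >= binary", {
  set.seed(17)
  for (rep in 1:50) {
    iv <- nutrient_vector(.values = stats::setNames(
      runif(12, 0, 1500), nutrient_names()))
    pb <- adequacy_profile(iv, ears, 30, mode = "binary")
    pc <- adequacy_profile(iv, ears, 30, mode = "cap")
    expect_gte(pc$mar, pb$mar)
    nu <- sample(micronutrients(), 1)
    iv2 <- iv; iv2[[nu]] <- iv2[[nu]] + runif(1, 0, 500)
    expect_gte(adequacy_profile(iv2, ears, 30, mode = "binary")$mar, pb$mar)
    expect_gte(adequacy_profile(iv2, ears, 30, mode = "cap")$mar, pc$mar)
  }
})

test_that("population summary counts, quantiles and ties behave", {
  med <- survey_intake_quantiles()
  iv <- nutrient_vector(.values = c(
    energy = 2000, stats::setNames(med$median, med$nutrient)))
  prof <- adequacy_profile(iv, ears, 30)
  same <- population_adequacy_table(rep(list(prof), 5))
  expect_equal(same$mar_sd, 0)
  expect_equal(same$nutrients$median_intake,
               med$median[match(same$nutrients$nutrient, med$nutrient)])

  # 10 women, 4 with iron below EAR -> 40%
  profs <- lapply(1:10, function(i) {
    iv_i <- ear_intake_vector()
    if (i <= 4) iv_i[["iron"]] <- 10   # EAR iron = 15
    adequacy_profile(iv_i, ears, 30)
  })
  tab <- population_adequacy_table(profs)
  expect_equal(tab$nutrients$pct_below_ear[
    tab$nutrients$nutrient == "iron"], 40)
  # intake exactly at the EAR counts as adequate
  expect_equal(tab$nutrients$pct_below_ear[
    tab$nutrients$nutrient == "calcium"], 0)
  # no-TUL rows stay undefined rather than zero
  expect_true(is.na(tab$nutrients$pct_above_tul[
    tab$nutrients$nutrient == "riboflavin"]))
})

test_that("median NAR equals median intake over EAR for a single stratum", {
  set.seed(29)
  intakes <- generate_intakes(501, seed = 29)
  profs <- lapply(seq_len(nrow(intakes)), function(i) {
    adequacy_profile(nutrient_vector(.values = unlist(
      intakes[i, nutrient_names()])), ears, 30)
  })
  tab <- population_adequacy_table(profs)
  expect_equal(tab$nutrients$median_nar,
               tab$nutrients$median_intake / tab$nutrients$ear,
               tolerance = 1e-12)
})
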