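ame <- load_ame_table()

test_that("AME weights come from the unique covering band", {
  expect_equal(ame_weight(35, "male", ame), 1.0)   # adult-male reference
  expect_equal(ame_weight(30, "female", ame), 0.80)
  expect_equal(ame_weight(12, "female", ame), 0.75)
  expect_error(ame_weight(130, "female", ame), "no AME band")
})

test_that("malformed AME tables are rejected", {
  rows <- tibble::tibble(sex = c("female", "male"), age_lo = 0L,
                         age_hi = 120L, weight = c(0.8, 1))
  expect_s3_class(ame_table(rows), "ame_table")
  expect_error(ame_table(dplyr::mutate(rows, age_hi = 100L)),
               "cover ages 0-120")
  expect_error(ame_table(dplyr::bind_rows(rows, rows[1, ])), "overlapping")
  expect_error(ame_table(dplyr::mutate(rows, weight = c(-1, 1))), "> 0")
})

test_that("household totals sum food contributions", {
  fct <- mini_fct()
  zero <- household_totals(tibble::tibble(food_code = character(),
                                          grams = numeric()), fct)
  expect_equal(zero, nutrient_vector())

  one <- household_totals(tibble::tibble(food_code = "milk", grams = 100),
                          fct)
  expect_equal(one[["calcium"]], 120)

  split2 <- household_totals(
    tibble::tibble(food_code = c("milk", "milk"), grams = c(150, 50)), fct)
  whole <- household_totals(tibble::tibble(food_code = "milk", grams = 200),
                            fct)
  expect_equal(split2, whole, tolerance = 1e-12)
})

test_that("per-capita allocation follows the AME share", {
  members1 <- tibble::tibble(member_id = "m", age_years = 40, sex = "male")
  tot <- nutrient_vector(calcium = 900, energy = 2000)
  solo <- per_capita_intake(tot, members1, "m", ame)
  expect_equal(solo$intake, tot)

  members2 <- tibble::tibble(member_id = c("m", "w"),
                             age_years = c(40, 30),
                             sex = c("male", "female"))
  woman <- per_capita_intake(tot, members2, "w", ame)
  expect_equal(woman$ame_weight, 0.8)
  expect_equal(woman$total_units, 1.8)
  expect_equal(woman$intake[["calcium"]], 900 * 0.8 / 1.8)  # = 400

  # equal weights split evenly regardless of the weight's value
  members3 <- tibble::tibble(member_id = c("a", "b", "c"),
                             age_years = c(30, 40, 25),
                             sex = "female")
  each <- per_capita_intake(tot, members3, "b", ame)
  expect_equal(each$intake, tot / 3)

  expect_error(per_capita_intake(tot, members2, "nobody", ame),
               "not on the household roster")
})

test_that("allocation conserves the household total over random rosters", {
  set.seed(101)
  for (rep in 1:1000) {
    k <- sample(1:7, 1)
    members <- tibble::tibble(
      member_id = paste0("m", seq_len(k)),
      age_years = sample(0:80, k, replace = TRUE),
      sex = sample(c("female", "male"), k, replace = TRUE))
    tot <- nutrient_vector(.values = stats::setNames(
      runif(12, 0, 3000), nutrient_names()))
    shares <- lapply(members$member_id, function(id) {
      per_capita_intake(tot, members, id, ame)$intake
    })
    expect_equal(Reduce(`+`, shares), tot, tolerance = 1e-9)
  }
})

test_that("allocation is scale-equivariant in grams and invariant to AME rescaling", {
  fct <- mini_fct()
  members <- tibble::tibble(member_id = c("m", "w", "k"),
                            age_years = c(40, 30, 7),
                            sex = c("male", "female", "female"))
  recall <- tibble::tibble(food_code = c("rice", "hilsa", "milk"),
                           grams = c(300, 120, 80))
  base <- per_capita_intake(household_totals(recall, fct), members, "w", ame)
  doubled <- per_capita_intake(
    household_totals(dplyr::mutate(recall, grams = grams * 2), fct),
    members, "w", ame)
  expect_equal(doubled$intake, base$intake * 2, tolerance = 1e-12)

  scaled_ame <- ame_table(dplyr::mutate(as.data.frame(ame),
                                        weight = weight * 3.7))
  rescaled <- per_capita_intake(household_totals(recall, fct), members, "w",
                                scaled_ame)
  expect_equal(rescaled$intake, base$intake, tolerance = 1e-12)
})

test_that("survey allocation requires exactly one index woman per household", {
  fct <- mini_fct()
  roster <- tibble::tibble(
    household_id = c("h1", "h1"), member_id = c("h1_w", "h1_m"),
    age_years = c(30, 40), sex = c("female", "male"),
    is_index_wra = c(TRUE, FALSE))
  recall <- tibble::tibble(household_id = "h1", food_code = "rice",
                           grams = 450)
  out <- allocate_survey(roster, recall, fct, ame)
  expect_equal(nrow(out$intakes), 1)
  expect_equal(out$woman_recall$grams, 450 * 0.8 / 1.8)

  expect_error(
    allocate_survey(dplyr::mutate(roster, is_index_wra = FALSE),
                    recall, fct, ame),
    "exactly one index woman")
})
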