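# Seeded synthetic-survey generator. Emulates a village-stratified
# household survey: rosters, household-level 24-h recalls, woman-level
# covariates, with configurable food-group consumption probabilities,
# injected covariate effects, and a ground-truth file for recovery
# tests. Truth is emitted alongside the data, never inside it.

#' Default generator configuration
#'
#' Calibrated to the source survey's printed marginals: 201 surveyed
#' households (one index woman of reproductive age each) drawn from a
#' nine-village frame of 1169 households with the published village,
#' age, education, occupation, decision-role, BMI and food-security
#' proportions, and food-group consumption probabilities equal to the
#' published food-group prevalences (so the expected dietary diversity
#' score is their sum, 4.253). Grams for a consumed group follow a
#' shifted lognormal `threshold + Lognormal(meanlog, sdlog)`: the
#' consumption probabilities already describe post-15-g-rule
#' consumption, so a consumed group always counts.
#'
#' @param n_households Number of surveyed households.
#' @param seed Integer seed; all generator randomness flows from it
#'   through a named stream per component.
#' @param effects List of injected effects; each element a list with
#'   `covariate`, `level`, `outcome` (`"group_prob_shift"`) and `size`
#'   (an odds ratio applied to every group's consumption log-odds for
#'   women at that covariate level).
#' @param latent_sd Standard deviation of a woman-level latent
#'   diet-quality factor added to all group log-odds; 0 (default) keeps
#'   groups independent and closed-form expectations exact.
#' @return A `survey_config` list.
#' @export
survey_config <- function(n_households = 201, seed = 20200301,
                          effects = list(), latent_sd = 0) {
  marg <- survey_covariate_marginals()
  prev <- survey_group_prevalence()
  cfg <- list(
    n_households = n_households,
    sampling_frame_households = 1169,
    villages = marg$village,
    group_prob = stats::setNames(prev$pct_total / 100, prev$group),
    # median grams (beyond the 15-g threshold) a consuming woman eats,
    # by group; field-plausible portions for a rice-and-fish diet
    grams_median = c(starchy_staples = 335, beans_peas = 35,
                     nuts_seeds = 15, dairy = 105, flesh_foods = 75,
                     eggs = 35, dark_green_leafy_veg = 45,
                     vitamin_a_rich_fv = 45, other_vegetables = 105,
                     other_fruits = 85),
    grams_sdlog = 0.5,
    threshold_g = 15,
    oil_grams_median = 10,
    covariate_marginals = marg,
    income_lognormal = c(meanlog = log(15000), sdlog = 0.5),
    effects = effects,
    latent_sd = latent_sd,
    seed = as.integer(seed))
  class(cfg) <- "survey_config"
  validate_config(cfg)
  cfg
}

#' @rdname survey_config
#' @param config A `survey_config` to validate.
#' @export
validate_config <- function(config) {
  stopifnot(inherits(config, "survey_config"))
  if (config$n_households < 1) stop("n_households must be >= 1", call. = FALSE)
  if (abs(sum(config$villages) - 1) > 1e-9) {
    stop("village proportions must sum to 1", call. = FALSE)
  }
  for (nm in c("age_band", "marital", "education", "occupation",
               "household_size_band", "decision_role", "bmi_category",
               "food_secure")) {
    if (abs(sum(config$covariate_marginals[[nm]]) - 1) > 1e-6) {
      stop("covariate marginal ", nm, " must sum to 1", call. = FALSE)
    }
  }
  if (!setequal(names(config$group_prob), mddw_groups()) ||
      any(config$group_prob < 0 | config$group_prob > 1)) {
    stop("group_prob must map the 10 MDD-W groups to [0,1]", call. = FALSE)
  }
  if (config$grams_sdlog <= 0) stop("grams_sdlog must be > 0", call. = FALSE)
  if (config$latent_sd < 0) stop("latent_sd must be >= 0", call. = FALSE)
  for (ef in config$effects) {
    if (!all(c("covariate", "level", "outcome", "size") %in% names(ef)) ||
        !ef$outcome %in% "group_prob_shift" || ef$size <= 0) {
      stop("malformed effect specification", call. = FALSE)
    }
  }
  invisible(config)
}

# deterministic per-component seed derived from the master seed
component_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  (as.double(seed) * 1009 + h * 101) %% 2147483629
}

sample_level <- function(n, marginal) {
  sample(names(marginal), n, replace = TRUE, prob = marginal)
}

#' Generate a synthetic survey
#'
#' Deterministic for a fixed seed. Each surveyed household has exactly
#' one index woman of reproductive age; household sizes are drawn to
#' match the configured small/large split; each woman's food-group
#' consumption is Bernoulli on the log-odds scale (with injected effects
#' and the optional latent diet-quality factor applied), grams are drawn
#' shifted-lognormal conditional on consumption, and one food is sampled
#' from the packaged FCT within each consumed group. Household-level
#' recall grams are the woman's grams scaled back up by the household's
#' consumption units over hers, so that the AME allocation is exercised
#' non-trivially and recovers her intake exactly.
#'
#' @param config A [survey_config()].
#' @return List of class `synthetic_survey`: `roster`, `recall`,
#'   `covariates` (analysis input tibbles, truth-free) and `truth` (per
#'   woman: true group indicators, DDS, MDD-W, nutrient intakes, MAR in
#'   both truncation modes, plus the injected effects).
#' @export
generate_survey <- function(config = survey_config()) {
  validate_config(config)
  fct <- demo_fct()
  ame <- load_ame_table()
  ears <- ref_ear_wra()
  n <- config$n_households
  marg <- config$covariate_marginals

  # --- roster stream ------------------------------------------------
  set.seed(component_seed(config$seed, "roster"))
  village <- sample_level(n, config$villages)
  band <- sample_level(n, marg$age_band)
  age_w <- ifelse(band == "15-24", sample(15:24, n, TRUE),
                  ifelse(band == "25-34", sample(25:34, n, TRUE),
                         sample(35:49, n, TRUE)))
  size_small <- stats::runif(n) < marg$household_size_band[["<=5"]]
  hh_size <- ifelse(size_small, sample(2:5, n, TRUE), sample(6:9, n, TRUE))

  hh_ids <- sprintf("hh%05d", seq_len(n))
  woman_id <- paste0(hh_ids, "_w")
  household_id <- rep(hh_ids, hh_size)
  pos <- sequence(hh_size)
  total <- length(pos)
  member_id <- ifelse(pos == 1, paste0(household_id, "_w"),
                      paste0(household_id, "_m", pos - 1))
  age_years <- integer(total)
  sex <- character(total)
  age_years[pos == 1] <- age_w
  sex[pos == 1] <- "female"
  head_row <- pos == 2           # an adult (male) head besides the woman
  age_years[head_row] <- sample(20:60, sum(head_row), TRUE)
  sex[head_row] <- "male"
  rest <- pos > 2
  age_years[rest] <- sample(0:70, sum(rest), TRUE)
  sex[rest] <- sample(c("female", "male"), sum(rest), TRUE)
  roster <- tibble::tibble(household_id = household_id,
                           member_id = member_id, age_years = age_years,
                           sex = sex, is_index_wra = pos == 1)

  # --- covariate stream ---------------------------------------------
  set.seed(component_seed(config$seed, "covariates"))
  marital <- sample_level(n, marg$marital)
  education <- sample_level(n, marg$education)
  occupation <- sample_level(n, marg$occupation)
  income <- stats::rlnorm(n, config$income_lognormal[["meanlog"]],
                          config$income_lognormal[["sdlog"]])
  role <- stats::runif(n) < marg$decision_role[["yes"]]
  partial <- sample(0:2, n, TRUE)          # score when no full role
  dec <- matrix(0L, n, 3)
  dec[role, ] <- 1L
  pick <- stats::runif(n)                  # which items a partial score hits
  for (j in 1:3) {
    dec[!role, j] <- as.integer(
      (floor(pick[!role] * 3) + j - 1) %% 3 < partial[!role])
  }
  bmi_cat <- sample_level(n, marg$bmi_category)
  bmi <- ifelse(bmi_cat == "underweight", stats::runif(n, 16.5, 18.4),
                ifelse(bmi_cat == "normal", stats::runif(n, 18.5, 24.9),
                       stats::runif(n, 25.0, 31.0)))
  height <- stats::rnorm(n, 1.515, 0.05)
  food_secure <- stats::runif(n) < marg$food_secure[["secure"]]

  covariates <- tibble::tibble(
    woman_id = woman_id, age_years = age_w, village = village,
    marital = marital, education = education, occupation = occupation,
    income = income, household_size = hh_size,
    decision_q1 = dec[, 1], decision_q2 = dec[, 2], decision_q3 = dec[, 3],
    height_m = round(height, 2), weight_kg = round(bmi * height^2, 1),
    food_secure = food_secure, energy_kcal = NA_real_)

  # --- recall stream ------------------------------------------------
  set.seed(component_seed(config$seed, "recall"))
  resolved_all <- fct_lookup_all(fct, unique(fct$entries$food_code))
  foods_by_group <- split(resolved_all$food_code, resolved_all$mddw_group)
  dens <- as.matrix(resolved_all[, names(fct_nutrient_columns())])
  rownames(dens) <- resolved_all$food_code
  colnames(dens) <- unname(fct_nutrient_columns())

  logit0 <- stats::qlogis(pmin(pmax(config$group_prob, 1e-12), 1 - 1e-12))
  logit <- matrix(logit0, n, 10, byrow = TRUE,
                  dimnames = list(NULL, mddw_groups()))
  for (ef in config$effects) {
    hit <- as.character(covariates[[ef$covariate]]) == as.character(ef$level)
    logit[hit, ] <- logit[hit, ] + log(ef$size)
  }
  if (config$latent_sd > 0) {
    logit <- logit + stats::rnorm(n, 0, config$latent_sd)
  }
  p_mat <- stats::plogis(logit)
  p_mat[, config$group_prob == 0] <- 0
  p_mat[, config$group_prob == 1] <- 1
  consumed <- matrix(stats::runif(n * 10), n, 10) < p_mat
  colnames(consumed) <- mddw_groups()

  cells <- which(consumed, arr.ind = TRUE)      # (woman, group) pairs
  cells <- cells[order(cells[, 1], cells[, 2]), , drop = FALSE]
  g_idx <- cells[, 2]
  codes <- character(nrow(cells))
  for (g in seq_len(10)) {
    sel <- g_idx == g
    if (any(sel)) {
      codes[sel] <- sample(foods_by_group[[mddw_groups()[g]]], sum(sel),
                           replace = TRUE)
    }
  }
  grams_w <- config$threshold_g +
    stats::rlnorm(nrow(cells), log(config$grams_median[g_idx]),
                  config$grams_sdlog)
  # every household also uses some cooking oil (unclassified group)
  oil_g <- stats::rlnorm(n, log(config$oil_grams_median), config$grams_sdlog)
  w_row <- c(cells[, 1], seq_len(n))
  codes <- c(codes, rep("soybean_oil", n))
  grams_w <- c(grams_w, oil_g)
  o <- order(w_row)
  w_row <- w_row[o]; codes <- codes[o]; grams_w <- grams_w[o]

  # household recall = woman's grams scaled by household units / hers
  w_all <- ame_weights(roster, ame)
  total_units <- as.numeric(tapply(w_all, factor(household_id, hh_ids), sum))
  w_woman <- w_all[pos == 1]
  scale_up <- total_units / w_woman
  recall <- tibble::tibble(household_id = hh_ids[w_row],
                           food_code = codes,
                           grams = grams_w * scale_up[w_row])

  # ground truth: the woman's own intake and scores
  intake_mat <- rowsum(dens[codes, , drop = FALSE] * (grams_w / 100),
                       group = w_row)
  nar_mat <- ear_matrix(ears, age_w)
  nar_mat <- intake_mat[, micronutrients(), drop = FALSE] / nar_mat
  mar_binary <- rowMeans(nar_mat >= 1)
  mar_cap <- rowMeans(pmin(nar_mat, 1))
  dds_true <- rowSums(consumed)

  truth <- tibble::tibble(woman_id = woman_id)
  for (g in mddw_groups()) truth[[paste0("group_", g)]] <-
    as.integer(consumed[, g])
  truth$dds <- unname(dds_true)
  truth$mddw_met <- unname(dds_true >= 5)
  for (nm in nutrient_names()) truth[[nm]] <- unname(intake_mat[, nm])
  truth$mar_binary <- unname(mar_binary)
  truth$mar_cap <- unname(mar_cap)
  covariates$energy_kcal <- truth$energy

  structure(list(roster = roster, recall = recall, covariates = covariates,
                 truth = list(women = truth, effects = config$effects,
                              seed = config$seed)),
            class = "synthetic_survey")
}

# EAR value per (woman, nutrient) as a matrix, honouring age strata
ear_matrix <- function(ears, ages, sex = "female") {
  out <- matrix(NA_real_, length(ages), length(micronutrients()),
                dimnames = list(NULL, micronutrients()))
  for (i in seq_len(nrow(ears))) {
    row <- ears[i, ]
    if (!row$sex %in% c(sex, "any")) next
    hit <- ages >= row$age_lo & ages <= row$age_hi
    fill <- is.na(out[, row$nutrient]) & hit
    out[fill, row$nutrient] <- row$ear
  }
  if (any(is.na(out))) {
    stop("EAR table does not cover every (nutrient, age) stratum",
         call. = FALSE)
  }
  out
}

#' Write a synthetic survey to disk
#'
#' Emits the analysis CSVs (`roster.csv`, `recall.csv`,
#' `covariates.csv`) and the ground truth as `truth.json` (kept separate
#' so it can never leak into the analysis inputs).
#'
#' @param survey A [generate_survey()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_survey <- function(survey, dir) {
  stopifnot(inherits(survey, "synthetic_survey"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(survey$roster, file.path(dir, "roster.csv"))
  readr::write_csv(survey$recall, file.path(dir, "recall.csv"))
  readr::write_csv(survey$covariates, file.path(dir, "covariates.csv"))
  jsonlite::write_json(survey$truth, file.path(dir, "truth.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Closed-form expectations under an independence configuration
#'
#' With no injected effects and no latent factor, food groups are
#' independent Bernoulli draws, so the expected dietary diversity score
#' is the sum of the group probabilities (linearity of expectation) and
#' the MDD-W prevalence is the Poisson-binomial tail `P(DDS >= 5)`.
#'
#' @param config A [survey_config()] without effects and with
#'   `latent_sd = 0`.
#' @return List with `expected_dds` and `expected_mddw_prevalence`.
#' @export
closed_form_expectations <- function(config = survey_config()) {
  validate_config(config)
  if (length(config$effects) || config$latent_sd > 0) {
    stop("closed-form expectations require the independence ",
         "configuration (no effects, latent_sd = 0)", call. = FALSE)
  }
  p <- config$group_prob
  list(expected_dds = sum(p),
       expected_mddw_prevalence = poisson_binomial_tail(p, 5))
}

# P(sum of independent Bernoulli(p) >= k) by exact convolution
poisson_binomial_tail <- function(p, k) {
  pmf <- 1
  for (pi in p) pmf <- c(pmf * (1 - pi), 0) + c(0, pmf * pi)
  sum(pmf[(k + 1):length(pmf)])
}

#' Draw per-nutrient lognormal intakes
#'
#' Draws each woman's daily micronutrient vector from independent
#' lognormal laws (energy included), bypassing the food layer. Used for
#' EAR cut-point calibration: the population fraction below an EAR then
#' has the closed form `pnorm((log(ear) - meanlog) / sdlog)`.
#'
#' @param n Number of women.
#' @param params Tibble `nutrient, meanlog, sdlog` (default: lognormals
#'   fitted to the survey's printed intake quantiles).
#' @param energy_meanlog,energy_sdlog Lognormal law for daily energy.
#' @param seed Integer seed.
#' @return Tibble with `woman_id` and one intake column per nutrient.
#' @export
generate_intakes <- function(n, params = fit_intake_lognormal(),
                             energy_meanlog = log(2000),
                             energy_sdlog = 0.25, seed = 1) {
  set.seed(component_seed(seed, "intakes"))
  out <- tibble::tibble(woman_id = sprintf("w%05d", seq_len(n)),
                        energy = stats::rlnorm(n, energy_meanlog,
                                               energy_sdlog))
  for (i in seq_len(nrow(params))) {
    out[[params$nutrient[i]]] <- stats::rlnorm(n, params$meanlog[i],
                                               params$sdlog[i])
  }
  out
}

#' Simulate MDD-W outcomes from a logistic law
#'
#' Draws a binary MDD-W outcome for each woman directly from a logistic
#' model on her covariates — the simulation oracle for odds-ratio
#' recovery by [fit_mddw_logistic()].
#'
#' @param covariates Tibble from [derive_covariates()].
#' @param intercept Baseline log-odds.
#' @param effects List of `list(covariate=, level=, or=)` effects.
#' @param seed Integer seed.
#' @return Logical outcome vector.
#' @export
simulate_mddw_outcomes <- function(covariates, intercept = stats::qlogis(0.4),
                                   effects = list(), seed = 1) {
  set.seed(component_seed(seed, "mddw_outcomes"))
  eta <- rep(intercept, nrow(covariates))
  for (ef in effects) {
    hit <- as.character(covariates[[ef$covariate]]) == ef$level
    eta <- eta + log(ef$or) * hit
  }
  stats::runif(nrow(covariates)) < stats::plogis(eta)
}

#' Simulate MAR outcomes from a linear law
#'
#' Draws a continuous mean-adequacy-ratio outcome from a linear model on
#' the covariates plus Gaussian noise — the simulation oracle for
#' coefficient recovery by [fit_mar_linear()].
#'
#' @param covariates Tibble (may include an `mddw_met` column).
#' @param intercept Baseline MAR.
#' @param effects List of `list(covariate=, level=, beta=)` effects; for
#'   numeric covariates `level` is ignored and `beta` multiplies the
#'   value.
#' @param sd Residual standard deviation.
#' @param seed Integer seed.
#' @return Numeric outcome vector (not clamped; keep effects small).
#' @export
simulate_mar_outcomes <- function(covariates, intercept = 0.4,
                                  effects = list(), sd = 0.1, seed = 1) {
  set.seed(component_seed(seed, "mar_outcomes"))
  if ("mddw_met" %in% names(covariates) &&
      is.logical(covariates$mddw_met)) {
    # same convention as fit_mar_linear()
    covariates$mddw_met <- factor(ifelse(covariates$mddw_met,
                                         "adequate", "inadequate"),
                                  levels = c("inadequate", "adequate"))
  }
  mu <- rep(intercept, nrow(covariates))
  for (ef in effects) {
    x <- covariates[[ef$covariate]]
    mu <- mu + if (is.numeric(x)) ef$beta * x else
      ef$beta * (as.character(x) == ef$level)
  }
  mu + stats::rnorm(nrow(covariates), 0, sd)
}

#' Simulate covariate records only
#'
#' Raw woman-level covariate records (the [derive_covariates()] input
#' schema) drawn from the configured marginals — for regression
#' simulations that do not need the food layer.
#'
#' @param n Number of women.
#' @param config A [survey_config()].
#' @param seed Integer seed (defaults to the config's).
#' @return Tibble in the raw covariate schema.
#' @export
simulate_covariates <- function(n, config = survey_config(), seed = config$seed) {
  cfg <- config
  cfg$n_households <- n
  cfg$seed <- as.integer(seed)
  marg <- cfg$covariate_marginals
  set.seed(component_seed(cfg$seed, "covariates-only"))
  band <- sample_level(n, marg$age_band)
  age <- ifelse(band == "15-24", sample(15:24, n, TRUE),
                ifelse(band == "25-34", sample(25:34, n, TRUE),
                       sample(35:49, n, TRUE)))
  role <- stats::runif(n) < marg$decision_role[["yes"]]
  dec <- t(vapply(role, function(r) {
    if (r) c(1L, 1L, 1L) else {
      s <- sample(0:2, 1)
      out <- integer(3); if (s > 0) out[sample(3, s)] <- 1L
      out
    }
  }, integer(3)))
  bmi_cat <- sample_level(n, marg$bmi_category)
  bmi <- ifelse(bmi_cat == "underweight", stats::runif(n, 16.5, 18.4),
                ifelse(bmi_cat == "normal", stats::runif(n, 18.5, 24.9),
                       stats::runif(n, 25.0, 31.0)))
  height <- stats::rnorm(n, 1.515, 0.05)
  small <- stats::runif(n) < marg$household_size_band[["<=5"]]
  tibble::tibble(
    woman_id = sprintf("w%05d", seq_len(n)),
    age_years = age,
    village = sample_level(n, cfg$villages),
    marital = sample_level(n, marg$marital),
    education = sample_level(n, marg$education),
    occupation = sample_level(n, marg$occupation),
    income = stats::rlnorm(n, cfg$income_lognormal[["meanlog"]],
                           cfg$income_lognormal[["sdlog"]]),
    household_size = ifelse(small, sample(2:5, n, TRUE),
                            sample(6:9, n, TRUE)),
    decision_q1 = dec[, 1], decision_q2 = dec[, 2], decision_q3 = dec[, 3],
    height_m = round(height, 2), weight_kg = round(bmi * height^2, 1),
    food_secure = stats::runif(n) < marg$food_secure[["secure"]],
    energy_kcal = stats::rlnorm(n, log(2000), 0.25))
}
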