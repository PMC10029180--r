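# End-to-end pipeline: survey CSVs in, diet-quality report out.

#' Run the diet-quality analysis on a survey
#'
#' The full computation: resolve the household recalls against the food
#' composition table, allocate household totals to each index woman with
#' AME consumption units, score her dietary diversity (15-g rule over
#' her allocated food grams) and her micronutrient adequacy against the
#' EAR reference, and summarise the population.
#'
#' @param roster,recall Data frames (or CSV paths) in the roster and
#'   recall schemas (see [allocate_survey()]).
#' @param fct An [fct_table()] or CSV path.
#' @param ears An [ear_table()] or CSV path.
#' @param ame An [ame_table()] or CSV path.
#' @param truncation_mode NAR truncation mode, see [truncate_nar()].
#' @param dds_rule 15-g rule reading, see [dds_score()].
#' @param threshold_g Gram threshold for a group to count.
#' @return List of class `diet_report`: `per_woman` (tibble: woman_id,
#'   household_id, dds, mddw_met, mar, energy and the 11 intake
#'   columns), `group_table` (population food-group summary),
#'   `adequacy_table` (population adequacy summary), and `settings`.
#' @export
run_diet_analysis <- function(roster, recall, fct = demo_fct(),
                              ears = ref_ear_wra(),
                              ame = load_ame_table(),
                              truncation_mode = c("binary", "cap"),
                              dds_rule = c("group_sum", "item_level"),
                              threshold_g = 15) {
  truncation_mode <- match.arg(truncation_mode)
  dds_rule <- match.arg(dds_rule)
  if (is.character(roster)) {
    roster <- readr::read_csv(roster, col_types = "ccicl", progress = FALSE)
  }
  if (is.character(recall)) {
    recall <- readr::read_csv(recall, col_types = "ccd", progress = FALSE)
  }
  if (is.character(fct)) fct <- load_fct(fct)
  if (is.character(ears)) ears <- load_ear_table(ears)
  if (is.character(ame)) ame <- load_ame_table(ame)

  alloc <- allocate_survey(roster, recall, fct, ame)
  intakes <- alloc$intakes

  dds_results <- vector("list", nrow(intakes))
  profiles <- vector("list", nrow(intakes))
  for (i in seq_len(nrow(intakes))) {
    wid <- intakes$woman_id[i]
    wr <- alloc$woman_recall[alloc$woman_recall$woman_id == wid,
                             c("food_code", "grams")]
    dds_results[[i]] <- dds_score(group_foods(wr, fct, woman_id = wid),
                                  threshold = threshold_g, rule = dds_rule)
    iv <- nutrient_vector(.values = unlist(intakes[i, nutrient_names()]))
    profiles[[i]] <- adequacy_profile(iv, ears, intakes$age_years[i],
                                      "female", truncation_mode,
                                      woman_id = wid)
  }

  per_woman <- intakes |>
    dplyr::mutate(
      dds = vapply(dds_results, function(d) d$dds, numeric(1)),
      mddw_met = vapply(dds_results, function(d) d$mddw_met, logical(1)),
      mar = vapply(profiles, function(p) p$mar, numeric(1)))

  structure(list(
    per_woman = per_woman,
    group_table = population_group_table(dds_results),
    adequacy_table = population_adequacy_table(profiles),
    settings = list(truncation_mode = truncation_mode, dds_rule = dds_rule,
                    threshold_g = threshold_g)), class = "diet_report")
}

#' @export
print.diet_report <- function(x, ...) {
  cat("<diet_report> n =", nrow(x$per_woman), "women\n")
  cat(sprintf("mean DDS %.2f (SD %.2f); %.1f%% met MDD-W; MAR %s mean %.2f (SD %.2f)\n",
              x$group_table$mean_dds, x$group_table$sd_dds,
              x$group_table$pct_mddw_met, x$settings$truncation_mode,
              x$adequacy_table$mar_mean, x$adequacy_table$mar_sd))
  invisible(x)
}

#' Fit both determinant models on a computed report
#'
#' Joins the raw covariate records with the report's per-woman outcomes
#' and fits the MDD-W logistic model and the MAR linear model. The
#' energy covariate for the MAR model is the pipeline's computed energy
#' intake.
#'
#' @param report A [run_diet_analysis()] result.
#' @param covariates_raw Data frame or CSV path in the raw covariate
#'   schema (see [derive_covariates()]).
#' @param leverage_cutoff,leverage_fixed Passed to [fit_mar_linear()].
#' @return List with `logistic_mddw` and `linear_mar` fits plus the
#'   derived `covariates`.
#' @export
run_regressions <- function(report, covariates_raw,
                            leverage_cutoff = "2p_over_n",
                            leverage_fixed = 0.05) {
  if (is.character(covariates_raw)) {
    covariates_raw <- readr::read_csv(covariates_raw, progress = FALSE,
                                      show_col_types = FALSE)
  }
  cov <- derive_covariates(covariates_raw)
  merged <- dplyr::inner_join(cov, report$per_woman[, c("woman_id", "dds",
                                                        "mddw_met", "mar",
                                                        "energy")],
                              by = "woman_id",
                              suffix = c("", ".computed"))
  if (!nrow(merged)) stop("no overlap between covariates and outcomes",
                          call. = FALSE)
  merged$energy_kcal <- merged$energy
  list(
    logistic_mddw = fit_mddw_logistic(merged, merged$mddw_met),
    linear_mar = fit_mar_linear(merged, merged$mar,
                                leverage_cutoff = leverage_cutoff,
                                leverage_fixed = leverage_fixed),
    covariates = merged)
}

#' Write a diet report (and optional regressions) as JSON
#'
#' Full-precision JSON mirroring the report structure; rounding is a
#' concern of rendered text tables only.
#'
#' @param report A `diet_report`.
#' @param path Output file.
#' @param regressions Optional [run_regressions()] result.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path, regressions = NULL) {
  out <- list(
    settings = report$settings,
    n_women = nrow(report$per_woman),
    group_table = report$group_table[c("groups", "mean_dds", "sd_dds",
                                       "pct_mddw_met", "n")],
    adequacy_table = report$adequacy_table[c("nutrients", "mar_mean",
                                             "mar_sd", "mode", "n")],
    per_woman = report$per_woman)
  if (!is.null(regressions)) {
    out$regressions <- lapply(regressions[c("logistic_mddw", "linear_mar")],
                              function(f) {
                                list(model = f$model, terms = f$terms,
                                     reference_levels = f$reference_levels,
                                     vif = f$diagnostics$vif)
                              })
  }
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(out, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}
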