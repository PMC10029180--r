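# MDD-W: ten food groups, the 15-g rule, the dietary diversity score.

#' The ten MDD-W food groups
#'
#' Fixed vocabulary of the FAO Minimum Dietary Diversity for Women food
#' groups used throughout the package (CSV and JSON outputs included).
#' @return Character vector of the ten group names.
#' @export
mddw_groups <- function() {
  c("starchy_staples", "beans_peas", "nuts_seeds", "dairy", "flesh_foods",
    "eggs", "dark_green_leafy_veg", "vitamin_a_rich_fv", "other_vegetables",
    "other_fruits")
}

#' Aggregate recall foods into MDD-W food groups
#'
#' Sums the grams of each recall food into its FCT entry's MDD-W group.
#' Foods whose entry carries group `"none"` (oils, condiments, sugar)
#' accumulate in `unclassified_grams`. Mixed dishes are classified by the
#' single group of their FCT entry; no ingredient disaggregation is done.
#'
#' @param recall Data frame with columns `food_code` and `grams` — one
#'   woman's (or household's) 24-h recall.
#' @param fct An [fct_table()].
#' @param woman_id Optional identifier carried into the result.
#' @return An object of class `food_group_intake`: list with
#'   `grams_by_group` (named numeric over [mddw_groups()]),
#'   `unclassified_grams`, and `items` (per-food grams with group, summed
#'   over duplicate codes).
#' @export
group_foods <- function(recall, fct, woman_id = NA_character_) {
  stopifnot(is.data.frame(recall), all(c("food_code", "grams") %in% names(recall)))
  if (nrow(recall) && any(recall$grams < 0)) {
    stop("recall grams must be non-negative", call. = FALSE)
  }
  grams_by_group <- stats::setNames(numeric(10), mddw_groups())
  unclassified <- 0
  items <- tibble::tibble(food_code = character(), mddw_group = character(),
                          grams = numeric())
  if (nrow(recall)) {
    resolved <- fct_lookup_all(fct, recall$food_code)
    items <- tibble::tibble(food_code = resolved$food_code,
                            mddw_group = resolved$mddw_group,
                            grams = recall$grams) |>
      dplyr::summarise(grams = sum(.data$grams),
                       .by = c("food_code", "mddw_group"))
    by_grp <- items |>
      dplyr::filter(.data$mddw_group != "none") |>
      dplyr::summarise(grams = sum(.data$grams), .by = "mddw_group")
    grams_by_group[by_grp$mddw_group] <- by_grp$grams
    unclassified <- sum(items$grams[items$mddw_group == "none"])
  }
  structure(list(woman_id = woman_id, grams_by_group = grams_by_group,
                 unclassified_grams = unclassified, items = items),
            class = "food_group_intake")
}

#' Dietary diversity score and the MDD-W indicator
#'
#' A food group counts towards the score only if at least `threshold`
#' grams (default 15 g) from it were consumed in the recall period. Two
#' readings of the rule are supported: `"group_sum"` (default; the summed
#' grams of the group must reach the threshold) and `"item_level"` (some
#' single food in the group must reach it on its own). An item-level flag
#' implies the group-sum flag, so `"item_level"` scores are never larger.
#' The MDD-W indicator is met when at least 5 of the 10 groups count.
#'
#' @param groups A `food_group_intake` from [group_foods()].
#' @param threshold Minimum grams for a group to count (> 0).
#' @param rule `"group_sum"` or `"item_level"`.
#' @return An object of class `dds_result`: list with `woman_id`,
#'   `group_flags` (named 0/1 over the ten groups), `dds` (0-10) and
#'   `mddw_met` (`dds >= 5`).
#' @export
#' @examples
#' fct <- demo_fct()
#' gi <- group_foods(tibble::tibble(
#'   food_code = c("rice_boiled", "hilsa_curry", "spinach_cooked"),
#'   grams = c(300, 80, 40)), fct)
#' dds_score(gi)
dds_score <- function(groups, threshold = 15,
                      rule = c("group_sum", "item_level")) {
  stopifnot(inherits(groups, "food_group_intake"))
  rule <- match.arg(rule)
  if (!is.numeric(threshold) || threshold <= 0) {
    stop("threshold must be > 0", call. = FALSE)
  }
  flags <- if (rule == "group_sum") {
    as.integer(groups$grams_by_group >= threshold)
  } else {
    hit <- groups$items |>
      dplyr::filter(.data$mddw_group != "none",
                    .data$grams >= threshold) |>
      dplyr::pull(.data$mddw_group)
    as.integer(mddw_groups() %in% hit)
  }
  names(flags) <- mddw_groups()
  dds <- sum(flags)
  structure(list(woman_id = groups$woman_id, group_flags = flags,
                 dds = dds, mddw_met = dds >= 5, rule = rule,
                 threshold = threshold),
            class = "dds_result")
}

#' Population food-group consumption summary
#'
#' Summarises a set of per-woman diversity results: the percentage of
#' women whose recall counted each food group, overall and within the
#' MDD-W adequate / inadequate strata, with a chi-square test per group
#' comparing the strata; plus mean (SD) DDS and the MDD-W prevalence.
#'
#' @param results List of `dds_result` objects.
#' @return List with `groups` (a tibble: group, pct_total, pct_inadequate,
#'   pct_adequate, p_value), `mean_dds`, `sd_dds`, `pct_mddw_met`, `n`.
#'   Stratum percentages are `NA` when a stratum is empty.
#' @export
population_group_table <- function(results) {
  stopifnot(length(results) >= 1)
  flags <- t(vapply(results, function(r) r$group_flags, numeric(10)))
  colnames(flags) <- mddw_groups()
  met <- vapply(results, function(r) r$mddw_met, logical(1))
  dds <- vapply(results, function(r) r$dds, numeric(1))

  pct <- function(m) {
    if (nrow(m) == 0) rep(NA_real_, 10) else unname(100 * colMeans(m))
  }
  pvals <- vapply(seq_len(10), function(j) {
    f <- flags[, j]
    if (!any(met) || all(met) || length(unique(f)) < 2) return(NA_real_)
    suppressWarnings(stats::chisq.test(table(factor(f, levels = 0:1),
                                             factor(met, levels = c(FALSE, TRUE))))$p.value)
  }, numeric(1))

  list(
    groups = tibble::tibble(
      group = mddw_groups(),
      pct_total = pct(flags),
      pct_inadequate = pct(flags[!met, , drop = FALSE]),
      pct_adequate = pct(flags[met, , drop = FALSE]),
      p_value = pvals),
    mean_dds = mean(dds),
    sd_dds = stats::sd(dds),
    pct_mddw_met = 100 * mean(met),
    n = length(results))
}
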