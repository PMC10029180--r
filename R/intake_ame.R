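# Adult-male-equivalent allocation of household 24-h recall totals.
#
# Dietary data are collected once per household; the sampled woman's
# intake is inferred by weighting each member with an age- and
# sex-specific consumption unit (adult male = 1) and giving her the
# share  household_total * weight / sum(weights).

#' Load an AME consumption-unit table
#'
#' CSV schema: `sex,age_lo,age_hi,weight` with inclusive integer age
#' bounds in years. Bands within a sex must not overlap and must jointly
#' cover ages 0-120; all weights must be positive. The adult-male
#' reference band carries weight 1.
#'
#' @param path CSV path. The default is a documented fixture table
#'   shipped with the package (adult male 1.00, adult female 0.80, ages
#'   10-17 0.75, 5-9 0.60, 1-4 0.40, under 1 0.25); studies should supply
#'   the reference table they actually use.
#' @return A tibble of class `ame_table`.
#' @export
load_ame_table <- function(path = wradiet_example("ame_fixture.csv")) {
  tab <- readr::read_csv(path, col_types = "ciid", progress = FALSE)
  missing <- setdiff(c("sex", "age_lo", "age_hi", "weight"), names(tab))
  if (length(missing)) {
    stop("AME table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  ame_table(tab)
}

#' @rdname load_ame_table
#' @param rows Data frame with the same columns as the CSV schema.
#' @export
ame_table <- function(rows) {
  rows <- tibble::as_tibble(rows)
  stopifnot(all(rows$sex %in% c("female", "male")))
  if (any(rows$weight <= 0)) stop("AME weights must be > 0", call. = FALSE)
  for (s in c("female", "male")) {
    b <- rows[rows$sex == s, ]
    covered <- rep(FALSE, 121)
    for (i in seq_len(nrow(b))) {
      idx <- seq(b$age_lo[i], b$age_hi[i]) + 1
      if (any(covered[idx])) {
        stop("overlapping AME bands for sex ", s, call. = FALSE)
      }
      covered[idx] <- TRUE
    }
    if (!all(covered)) {
      stop("AME bands for sex ", s, " do not cover ages 0-120", call. = FALSE)
    }
  }
  class(rows) <- c("ame_table", class(rows))
  rows
}

#' AME consumption-unit weight for one person
#'
#' @param age Age in completed years.
#' @param sex `"female"` or `"male"`.
#' @param table An [ame_table()].
#' @return The weight of the unique band containing (sex, age).
#' @export
ame_weight <- function(age, sex, table) {
  stopifnot(inherits(table, "ame_table"))
  sex <- match.arg(sex, c("female", "male"))
  hit <- table$sex == sex & table$age_lo <= age & age <= table$age_hi
  if (sum(hit) != 1) {
    stop("no AME band covers (", sex, ", age ", age, ")", call. = FALSE)
  }
  table$weight[hit]
}

# vectorised over a roster
ame_weights <- function(roster, table) {
  out <- rep(NA_real_, nrow(roster))
  for (i in seq_len(nrow(table))) {
    hit <- roster$sex == table$sex[i] &
      roster$age_years >= table$age_lo[i] &
      roster$age_years <= table$age_hi[i]
    out[hit] <- table$weight[i]
  }
  if (anyNA(out)) {
    j <- which(is.na(out))[1]
    stop("no AME band covers (", roster$sex[j], ", age ",
         roster$age_years[j], ")", call. = FALSE)
  }
  out
}

#' Household 24-h nutrient totals
#'
#' Sums `nutrient_content(lookup(code), grams)` over all recall records
#' of one household. Unresolvable food codes are aggregated and reported
#' together.
#'
#' @param recall Data frame with columns `food_code`, `grams`.
#' @param fct An [fct_table()].
#' @return Per-day nutrient vector of the household total.
#' @export
household_totals <- function(recall, fct) {
  total <- nutrient_vector()
  if (!nrow(recall)) return(total)
  resolved <- fct_lookup_all(fct, recall$food_code)
  dens <- as.matrix(resolved[, names(fct_nutrient_columns())])
  contrib <- dens * (recall$grams / 100)
  total_vals <- colSums(contrib)
  names(total_vals) <- unname(fct_nutrient_columns())
  nutrient_vector(.values = total_vals)
}

#' Allocate a household total to one member
#'
#' Implements the adult-male-equivalent allocation: the member's per-day
#' intake is the household total scaled by their consumption-unit weight
#' over the household's summed weights.
#'
#' @param household_total Per-day nutrient vector (see
#'   [household_totals()]).
#' @param members Roster data frame with columns `member_id`, `age_years`,
#'   `sex`.
#' @param person_id `member_id` of the member whose share is wanted.
#' @param table An [ame_table()].
#' @return List of class `individual_intake`: `intake` (nutrient vector),
#'   `ame_weight`, `total_units`, `household_total`.
#' @export
#' @examples
#' ame <- load_ame_table()
#' members <- tibble::tibble(member_id = c("m", "w"), age_years = c(35, 30),
#'                           sex = c("male", "female"))
#' tot <- nutrient_vector(calcium = 900)
#' per_capita_intake(tot, members, "w", ame)$intake[["calcium"]]  # 400
per_capita_intake <- function(household_total, members, person_id, table) {
  household_total <- as_nutrient_vector(household_total)
  if (!person_id %in% members$member_id) {
    stop("person ", person_id, " is not on the household roster",
         call. = FALSE)
  }
  w <- ame_weights(members, table)
  total_units <- sum(w)
  if (total_units <= 0) {
    stop("degenerate household: total consumption units must be > 0",
         call. = FALSE)
  }
  wi <- w[match(person_id, members$member_id)]
  structure(list(
    member_id = person_id,
    intake = household_total * (wi / total_units),
    ame_weight = wi,
    total_units = total_units,
    household_total = household_total), class = "individual_intake")
}

#' Per-woman intakes and food shares for a whole survey
#'
#' Runs the full allocation for every surveyed household: resolves the
#' household recall against the FCT, computes household nutrient totals,
#' and gives the index woman of reproductive age her AME share of both
#' the nutrients and the food grams (the gram shares feed the MDD-W
#' scoring, which is defined at the woman level).
#'
#' @param roster Data frame: `household_id`, `member_id`, `age_years`,
#'   `sex`, `is_index_wra` (exactly one `TRUE` per household).
#' @param recall Data frame: `household_id`, `food_code`, `grams`.
#' @param fct An [fct_table()].
#' @param ame An [ame_table()].
#' @return List with `intakes` — a tibble, one row per index woman
#'   (`woman_id`, `household_id`, `age_years`, `ame_weight`,
#'   `total_units`, `energy`, one column per micronutrient) — and
#'   `woman_recall`, the per-woman food-level gram shares
#'   (`woman_id`, `food_code`, `grams`).
#' @export
allocate_survey <- function(roster, recall, fct, ame) {
  stopifnot(all(c("household_id", "member_id", "age_years", "sex",
                  "is_index_wra") %in% names(roster)))
  idx <- roster[roster$is_index_wra, ]
  bad <- setdiff(unique(roster$household_id), idx$household_id)
  if (length(bad) || anyDuplicated(idx$household_id)) {
    stop("each household must have exactly one index woman", call. = FALSE)
  }
  # resolve all codes once up-front so offenders aggregate across households
  if (nrow(recall)) fct_lookup_all(fct, recall$food_code)

  rows <- vector("list", nrow(idx))
  shares <- vector("list", nrow(idx))
  for (i in seq_len(nrow(idx))) {
    hh <- idx$household_id[i]
    members <- roster[roster$household_id == hh, ]
    rec <- recall[recall$household_id == hh, c("food_code", "grams")]
    tot <- household_totals(rec, fct)
    alloc <- per_capita_intake(tot, members, idx$member_id[i], ame)
    frac <- alloc$ame_weight / alloc$total_units
    rows[[i]] <- tibble::tibble(
      woman_id = idx$member_id[i], household_id = hh,
      age_years = idx$age_years[i], ame_weight = alloc$ame_weight,
      total_units = alloc$total_units,
      !!!stats::setNames(as.list(alloc$intake), names(alloc$intake)))
    if (nrow(rec)) {
      shares[[i]] <- tibble::tibble(woman_id = idx$member_id[i],
                                    food_code = rec$food_code,
                                    grams = rec$grams * frac)
    }
  }
  list(intakes = dplyr::bind_rows(rows),
       woman_recall = dplyr::bind_rows(shares))
}
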