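# Micronutrient adequacy scoring: NAR, truncation, MAR, EAR cut-point
# inadequacy prevalence and tolerable-upper-level exceedance.

#' Load an EAR/TUL reference table
#'
#' CSV schema: `nutrient,sex,age_lo,age_hi,ear,tul` with `tul` left blank
#' for nutrients without a tolerable upper level. `sex` may be
#' `"female"`, `"male"` or `"any"`. Each EAR must be positive and each
#' TUL, when present, larger than its EAR.
#'
#' @param path CSV path; the default is the package's reference fixture
#'   of ICMR-based requirements for women of reproductive age.
#' @return Tibble of class `ear_table`.
#' @export
load_ear_table <- function(path = wradiet_example("ear_icmr_wra.csv")) {
  tab <- readr::read_csv(path, col_types = "cciidd", progress = FALSE)
  ear_table(tab)
}

#' @rdname load_ear_table
#' @param rows Data frame with the CSV schema's columns.
#' @export
ear_table <- function(rows) {
  rows <- tibble::as_tibble(rows)
  missing <- setdiff(c("nutrient", "sex", "age_lo", "age_hi", "ear", "tul"),
                     names(rows))
  if (length(missing)) {
    stop("EAR table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(rows$nutrient), micronutrients())
  if (length(bad)) {
    stop("unknown nutrient(s) in EAR table: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (any(rows$ear <= 0)) stop("EAR values must be > 0", call. = FALSE)
  if (any(!is.na(rows$tul) & rows$tul <= rows$ear)) {
    stop("TUL must exceed EAR where present", call. = FALSE)
  }
  class(rows) <- c("ear_table", class(rows))
  rows
}

# internal: EAR/TUL row for one (nutrient, sex, age) stratum
ear_for <- function(ears, nutrient, sex, age) {
  hit <- ears$nutrient == nutrient &
    (ears$sex == sex | ears$sex == "any") &
    ears$age_lo <= age & age <= ears$age_hi
  if (!any(hit)) return(NULL)
  ears[which(hit)[1], ]
}

#' Nutrient adequacy ratio
#'
#' The ratio of an individual's daily intake of a nutrient to the age-
#' and sex-specific estimated average requirement; not truncated.
#'
#' @param intake Daily intake (>= 0), in the nutrient's unit.
#' @param ear Estimated average requirement (> 0), same unit.
#' @return `intake / ear`.
#' @export
#' @examples
#' nar(45.2, 55)   # vitamin C, ~0.82
nar <- function(intake, ear) {
  if (any(ear <= 0)) stop("EAR must be > 0", call. = FALSE)
  if (any(intake < 0)) stop("intake must be >= 0", call. = FALSE)
  intake / ear
}

#' Truncate a NAR value
#'
#' Two truncation conventions are supported. `"binary"` scores a
#' nutrient 1 when the requirement is met (NAR >= 1) and 0 otherwise, so
#' the MAR becomes the fraction of nutrients whose EAR is reached.
#' `"cap"` is the common ceiling convention, `min(NAR, 1)`, which keeps
#' partial credit below the requirement while preventing a surplus in
#' one nutrient from masking a deficit in another. Both are first-class;
#' results should always be reported with the mode label.
#'
#' @param value NAR value(s), >= 0.
#' @param mode `"binary"` or `"cap"`.
#' @return Truncated value(s) in `[0, 1]`.
#' @export
truncate_nar <- function(value, mode = c("binary", "cap")) {
  mode <- match.arg(mode)
  if (any(value < 0)) stop("NAR must be >= 0", call. = FALSE)
  out <- value                      # keep names/dims of the input
  out[] <- if (mode == "binary") as.numeric(value >= 1) else pmin(value, 1)
  out
}

#' Mean adequacy ratio
#'
#' The arithmetic mean of the truncated NARs over exactly the eleven
#' configured micronutrients: 0 means no requirement was met, 1 means
#' all were.
#'
#' @param truncated Named numeric vector of truncated NARs; names must
#'   be exactly [micronutrients()].
#' @return Scalar in `[0, 1]`.
#' @export
mar <- function(truncated) {
  if (!setequal(names(truncated), micronutrients())) {
    stop("MAR needs a truncated NAR for each of the 11 micronutrients; ",
         "missing: ",
         paste(setdiff(micronutrients(), names(truncated)), collapse = ", "),
         call. = FALSE)
  }
  mean(truncated[micronutrients()])
}

#' Adequacy profile of one woman
#'
#' Compares a woman's allocated daily intake with the age- and
#' sex-specific EAR of each micronutrient, and summarises: per-nutrient
#' NAR, truncated NAR, whether intake falls below the EAR (strictly) or
#' above the TUL, and the MAR.
#'
#' @param intake Per-day nutrient vector ([nutrient_vector()]) or the
#'   `intake` element of a [per_capita_intake()] result.
#' @param ears An [ear_table()].
#' @param age Age in years.
#' @param sex `"female"` or `"male"`.
#' @param mode Truncation mode, see [truncate_nar()].
#' @param woman_id Optional identifier.
#' @return Object of class `adequacy_result`: `per_nutrient` (tibble with
#'   columns nutrient, intake, ear, tul, nar, truncated_nar, below_ear,
#'   above_tul — `above_tul` is `NA` where no TUL is defined), `mar`,
#'   `mode`, `woman_id`.
#' @export
adequacy_profile <- function(intake, ears, age, sex = "female",
                             mode = c("binary", "cap"),
                             woman_id = NA_character_) {
  mode <- match.arg(mode)
  if (inherits(intake, "individual_intake")) intake <- intake$intake
  intake <- as_nutrient_vector(intake)
  rows <- lapply(micronutrients(), function(nu) {
    ref <- ear_for(ears, nu, sex, age)
    if (is.null(ref)) {
      stop("no EAR covers (", nu, ", ", sex, ", age ", age, ")",
           call. = FALSE)
    }
    x <- intake[[nu]]
    tibble::tibble(
      nutrient = nu, intake = x, ear = ref$ear, tul = ref$tul,
      nar = nar(x, ref$ear),
      below_ear = x < ref$ear,
      above_tul = if (is.na(ref$tul)) NA else x > ref$tul)
  })
  per_nutrient <- dplyr::bind_rows(rows)
  per_nutrient$truncated_nar <- truncate_nar(per_nutrient$nar, mode)
  structure(list(
    woman_id = woman_id,
    per_nutrient = per_nutrient[, c("nutrient", "intake", "ear", "tul",
                                    "nar", "truncated_nar", "below_ear",
                                    "above_tul")],
    mar = mar(stats::setNames(per_nutrient$truncated_nar,
                              per_nutrient$nutrient)),
    mode = mode), class = "adequacy_result")
}

#' Population adequacy summary
#'
#' The EAR cut-point summary over a set of adequacy profiles: for each
#' micronutrient the median and interquartile intake, the percentage of
#' women with intake below the EAR (inadequacy prevalence), the
#' percentage above the TUL (`NA` where no TUL is defined), and the
#' median NAR; plus the mean (SD) of the MAR. Quantiles use linear
#' interpolation between closest ranks.
#'
#' @param profiles List of `adequacy_result` objects (same mode).
#' @return List with `nutrients` (tibble: nutrient, ear, tul,
#'   median_intake, p25, p75, pct_below_ear, pct_above_tul, median_nar),
#'   `mar_mean`, `mar_sd`, `mode`, `n`.
#' @export
population_adequacy_table <- function(profiles) {
  stopifnot(length(profiles) >= 1)
  long <- dplyr::bind_rows(lapply(profiles, function(p) {
    dplyr::mutate(p$per_nutrient, woman_id = p$woman_id)
  }))
  nutrients <- long |>
    dplyr::summarise(
      ear = .data$ear[1], tul = .data$tul[1],
      median_intake = stats::median(.data$intake),
      p25 = stats::quantile(.data$intake, 0.25, names = FALSE),
      p75 = stats::quantile(.data$intake, 0.75, names = FALSE),
      pct_below_ear = 100 * mean(.data$below_ear),
      pct_above_tul = if (all(is.na(.data$above_tul))) NA_real_ else
        100 * mean(.data$above_tul),
      median_nar = stats::median(.data$nar),
      .by = "nutrient") |>
    dplyr::arrange(match(.data$nutrient, micronutrients()))
  mars <- vapply(profiles, function(p) p$mar, numeric(1))
  list(nutrients = nutrients, mar_mean = mean(mars),
       mar_sd = stats::sd(mars), mode = profiles[[1]]$mode,
       n = length(profiles))
}
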