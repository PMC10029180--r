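# Food composition tables: loading, fallback-source resolution, scaling.

# canonical CSV column -> nutrient name mapping (per 100 g edible portion)
fct_nutrient_columns <- function() {
  c(energy_kcal = "energy", vitamin_a_ug = "vitamin_a",
    vitamin_c_mg = "vitamin_c", thiamin_mg = "thiamin",
    riboflavin_mg = "riboflavin", niacin_mg = "niacin",
    vitamin_b6_mg = "vitamin_b6", folate_ug = "folate",
    vitamin_b12_ug = "vitamin_b12", calcium_mg = "calcium",
    iron_mg = "iron", zinc_mg = "zinc")
}

#' Recognised food-composition sources, in default precedence order
#'
#' The primary table is the national (Bangladeshi) FCT; foods absent from
#' it fall back to the Indian FCT, then the USDA database, then any other
#' source.
#' @return Character vector of source codes.
#' @export
fct_sources <- function() c("BGD_FCT", "IFCT", "USDA", "OTHER")

#' Build a food composition table
#'
#' @param entries A data frame with columns `food_code`, `name`, the
#'   twelve per-100-g nutrient columns (`energy_kcal`, `vitamin_a_ug`,
#'   `vitamin_c_mg`, `thiamin_mg`, `riboflavin_mg`, `niacin_mg`,
#'   `vitamin_b6_mg`, `folate_ug`, `vitamin_b12_ug`, `calcium_mg`,
#'   `iron_mg`, `zinc_mg`), `mddw_group` and `source`. Densities are for
#'   the edible portion; any refuse factor is applied upstream.
#' @param precedence Ordered character vector of sources; the first table
#'   containing a food code wins lookups.
#' @return An object of class `fct_table`.
#' @export
fct_table <- function(entries, precedence = fct_sources()) {
  required <- c("food_code", "name", names(fct_nutrient_columns()),
                "mddw_group", "source")
  missing <- setdiff(required, names(entries))
  if (length(missing)) {
    stop("food composition table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  entries <- tibble::as_tibble(entries)[required]
  entries$food_code <- as.character(entries$food_code)

  bad_src <- setdiff(unique(entries$source), precedence)
  if (length(bad_src)) {
    stop("unknown source(s): ", paste(bad_src, collapse = ", "),
         " (precedence covers ", paste(precedence, collapse = " > "), ")",
         call. = FALSE)
  }
  bad_grp <- setdiff(unique(entries$mddw_group), c(mddw_groups(), "none"))
  if (length(bad_grp)) {
    stop("mddw_group outside the 10-group vocabulary: ",
         paste(bad_grp, collapse = ", "), call. = FALSE)
  }
  dup <- entries |>
    dplyr::count(.data$source, .data$food_code) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup)) {
    stop("duplicate food_code within one source: ",
         paste(unique(dup$food_code), collapse = ", "), call. = FALSE)
  }
  structure(list(entries = entries, precedence = precedence),
            class = "fct_table")
}

#' @export
print.fct_table <- function(x, ...) {
  cat("<fct_table> ", nrow(x$entries), " foods; precedence ",
      paste(x$precedence, collapse = " > "), "\n", sep = "")
  invisible(x)
}

#' Load a food composition table from CSV
#'
#' Rows with malformed or negative nutrient values are rejected with a
#' row-indexed warning; the remaining rows are loaded.
#'
#' @param path Path to a CSV file with the `fct_table()` schema.
#' @inheritParams fct_table
#' @return An `fct_table`.
#' @export
load_fct <- function(path, precedence = fct_sources()) {
  if (!file.exists(path)) stop("FCT file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  required <- c("food_code", "name", names(fct_nutrient_columns()),
                "mddw_group", "source")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    stop("FCT ", path, " is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  num_cols <- names(fct_nutrient_columns())
  parsed <- raw
  for (cl in num_cols) parsed[[cl]] <- suppressWarnings(as.numeric(raw[[cl]]))
  num <- as.matrix(parsed[num_cols])
  bad <- !stats::complete.cases(num) | apply(num < 0, 1, any)
  if (any(bad)) {
    warning("rejected ", sum(bad), " FCT row(s) with malformed or negative ",
            "nutrient values (row ", paste(which(bad), collapse = ", "), ")",
            call. = FALSE)
    parsed <- parsed[!bad, , drop = FALSE]
  }
  fct_table(parsed, precedence = precedence)
}

#' Resolve a food code against a composition table
#'
#' Lookup honours the table's source precedence: the first source in
#' precedence order that carries the code supplies the entry, so a food
#' present in both the national table and a fallback resolves to the
#' national entry.
#'
#' @param table An `fct_table`.
#' @param code Food code (single string).
#' @return A one-row tibble (the winning entry, including its `source`).
#' @export
fct_lookup <- function(table, code) {
  stopifnot(inherits(table, "fct_table"))
  hits <- table$entries[table$entries$food_code == as.character(code), ,
                        drop = FALSE]
  if (!nrow(hits)) {
    stop("unresolved food code: ", code, call. = FALSE)
  }
  hits[order(match(hits$source, table$precedence)), ][1, ]
}

# internal: resolve many codes at once; aggregates all offenders before
# failing so a survey with several unknown codes reports them together.
fct_lookup_all <- function(table, codes) {
  codes <- as.character(codes)
  uc <- unique(codes)
  missing <- setdiff(uc, table$entries$food_code)
  if (length(missing)) {
    stop("unresolved food code(s): ", paste(sort(missing), collapse = ", "),
         call. = FALSE)
  }
  rows <- lapply(uc, function(cd) fct_lookup(table, cd))
  resolved <- dplyr::bind_rows(rows)
  resolved[match(codes, resolved$food_code), ]
}

#' Nutrient content of a consumed amount
#'
#' Scales an entry's per-100-g densities linearly to the consumed grams.
#'
#' @param entry A one-row FCT entry (as returned by [fct_lookup()]).
#' @param grams Amount consumed, in grams (>= 0).
#' @return A per-day nutrient vector (see [nutrient_vector()]).
#' @export
#' @examples
#' fct <- fct_table(tibble::tibble(
#'   food_code = "rice", name = "rice, boiled", energy_kcal = 130,
#'   vitamin_a_ug = 0, vitamin_c_mg = 0, thiamin_mg = 0.02,
#'   riboflavin_mg = 0.01, niacin_mg = 0.4, vitamin_b6_mg = 0.09,
#'   folate_ug = 2, vitamin_b12_ug = 0, calcium_mg = 10, iron_mg = 0.2,
#'   zinc_mg = 0.5, mddw_group = "starchy_staples", source = "BGD_FCT"))
#' nutrient_content(fct_lookup(fct, "rice"), 300)
nutrient_content <- function(entry, grams) {
  if (!is.numeric(grams) || length(grams) != 1 || is.na(grams) || grams < 0) {
    stop("grams must be a single non-negative number", call. = FALSE)
  }
  dens <- unlist(entry[1, names(fct_nutrient_columns())])
  names(dens) <- unname(fct_nutrient_columns())
  nutrient_vector(.values = dens * (grams / 100))
}
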