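#' Nutrient vocabulary
#'
#' The pipeline tracks dietary energy plus eleven micronutrients. All
#' nutrient vectors in the package are named numeric vectors over this
#' fixed vocabulary, in the units listed below.
#'
#' @details Units: energy in kcal, vitamin A in µg RAE, vitamin C in mg,
#'   thiamin in mg, riboflavin in mg, niacin in mg, vitamin B6 in mg,
#'   folate in µg, vitamin B12 in µg, calcium in mg, iron in mg, zinc in
#'   mg. Depending on context a vector is per 100 g edible portion (food
#'   composition entries) or per day (intakes); functions document which.
#'
#' @return `micronutrients()` returns the eleven micronutrient names;
#'   `nutrient_names()` returns `"energy"` followed by the micronutrients.
#' @export
#' @examples
#' micronutrients()
micronutrients <- function() {
  c("vitamin_a", "vitamin_c", "thiamin", "riboflavin", "niacin",
    "vitamin_b6", "folate", "vitamin_b12", "calcium", "iron", "zinc")
}

#' @rdname micronutrients
#' @export
nutrient_names <- function() {
  c("energy", micronutrients())
}

#' Nutrient units, keyed by nutrient name
#' @return Named character vector of units.
#' @export
nutrient_units <- function() {
  c(energy = "kcal", vitamin_a = "ug", vitamin_c = "mg", thiamin = "mg",
    riboflavin = "mg", niacin = "mg", vitamin_b6 = "mg", folate = "ug",
    vitamin_b12 = "ug", calcium = "mg", iron = "mg", zinc = "mg")
}

#' Construct a nutrient vector
#'
#' Builds a named numeric vector over the full nutrient vocabulary.
#' Components not supplied default to zero.
#'
#' @param ... Named components, e.g. `calcium = 120`.
#' @param .values Optionally a named numeric vector or single-row data
#'   frame to take components from instead of `...`.
#' @return Named numeric vector of length 12 in vocabulary order.
#' @export
#' @examples
#' nutrient_vector(energy = 130, calcium = 10)
nutrient_vector <- function(..., .values = NULL) {
  vals <- if (is.null(.values)) c(...) else unlist(.values)
  out <- stats::setNames(numeric(length(nutrient_names())), nutrient_names())
  if (length(vals)) {
    bad <- setdiff(names(vals), nutrient_names())
    if (length(bad)) {
      stop("unknown nutrient component(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    out[names(vals)] <- as.numeric(vals)
  }
  if (any(!is.finite(out)) || any(out < 0)) {
    stop("nutrient components must be finite and non-negative", call. = FALSE)
  }
  out
}

# internal: validate an existing vector as a nutrient vector
as_nutrient_vector <- function(x) {
  if (!is.numeric(x) || !setequal(names(x), nutrient_names())) {
    stop("expected a named numeric vector over nutrient_names()", call. = FALSE)
  }
  x[nutrient_names()]
}
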