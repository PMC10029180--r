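# Shared test fixtures, built in code.

# minimal hand-written FCT rows (one food per call keeps tests terse)
fct_row <- function(code, group = "starchy_staples", source = "BGD_FCT",
                    energy = 100, calcium = 50, iron = 1, ...) {
  tibble::tibble(
    food_code = code, name = code, energy_kcal = energy, vitamin_a_ug = 5,
    vitamin_c_mg = 2, thiamin_mg = 0.1, riboflavin_mg = 0.1, niacin_mg = 1,
    vitamin_b6_mg = 0.1, folate_ug = 10, vitamin_b12_ug = 0.1,
    calcium_mg = calcium, iron_mg = iron, zinc_mg = 0.5,
    mddw_group = group, source = source) |>
    dplyr::mutate(...)
}

mini_fct <- function() {
  fct_table(dplyr::bind_rows(
    fct_row("rice", "starchy_staples", calcium = 10),
    fct_row("dal", "beans_peas"),
    fct_row("spinach", "dark_green_leafy_veg"),
    fct_row("amaranth", "dark_green_leafy_veg"),
    fct_row("hilsa", "flesh_foods"),
    fct_row("egg", "eggs"),
    fct_row("milk", "dairy", calcium = 120),
    fct_row("banana", "other_fruits"),
    fct_row("oil", "none", energy = 884, calcium = 0, iron = 0)))
}

# flat EAR table: one row per nutrient, female 15-49
flat_ears <- function(ear = NULL) {
  base <- ref_ear_wra()
  if (!is.null(ear)) {
    base$ear <- ear[base$nutrient]
  }
  base
}

# a nutrient vector equal to the reference EARs (handy boundary case)
ear_intake_vector <- function(ears = ref_ear_wra(), energy = 2000) {
  nutrient_vector(.values = c(
    energy = energy, stats::setNames(ears$ear, ears$nutrient)))
}

# independent brute-force DDS oracle: plain base-R enumeration over the
# ten groups, no shared code with dds_score()
naive_dds <- function(recall, fct, threshold = 15,
                      rule = c("group_sum", "item_level")) {
  rule <- match.arg(rule)
  ent <- as.data.frame(fct$entries)
  ent <- ent[order(match(ent$source, fct$precedence)), ]
  ent <- ent[!duplicated(ent$food_code), ]
  grp <- ent$mddw_group[match(recall$food_code, ent$food_code)]
  score <- 0L
  for (g in mddw_groups()) {
    gr <- recall$grams[!is.na(grp) & grp == g]
    counts <- if (rule == "group_sum") {
      sum(gr) >= threshold
    } else {
      per_food <- tapply(gr, recall$food_code[!is.na(grp) & grp == g], sum)
      length(per_food) > 0 && any(per_food >= threshold)
    }
    score <- score + as.integer(counts)
  }
  score
}

# random recall of up to max_foods foods drawn from a table
random_recall <- function(fct, max_foods = 8, max_grams = 60) {
  k <- sample(0:max_foods, 1)
  tibble::tibble(
    food_code = sample(unique(fct$entries$food_code), k, replace = TRUE),
    grams = stats::runif(k, 0, max_grams))
}
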