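# Aggregation of classified occasions into per-meal-type and total intakes.
# All dietary variables are 4-day (n_days-day) mean daily values, with zero
# assigned to non-consumers of a stratum, so every participant contributes
# a row to every stratum (per-capita convention).

intake_value_cols <- function() {
  c(nutrient_names(), hei_equivalent_names(),
    paste0("grams_", gsub("[^a-z_]", "", gsub(" ", "_", food_groups()))))
}

group_col <- function(groups) {
  paste0("grams_", gsub("[^a-z_]", "", gsub(" ", "_", groups)))
}

#' Aggregate classified occasions into meal-type and total intakes
#'
#' Sums line-level nutrients, HEI pattern equivalents and food-group grams
#' per participant and meal type across all record days, then divides by
#' the number of record days (zero days included), giving mean daily
#' intakes. A `total` stratum row is the component-wise sum of the four
#' meal strata. `consumed_any` is `FALSE` iff the stratum is empty on every
#' record day.
#'
#' @param classification A `meal_classification` (see [classify_records()]).
#' @param composition Composition table.
#' @param participants Optional participant tibble; participants with no
#'   retained diary lines still receive all-zero rows.
#' @param n_days Number of record days (default 4).
#' @return A tibble with one row per participant x stratum
#'   (`breakfast`, `lunch`, `dinner`, `snack`, `total`) holding mean daily
#'   nutrient columns, equivalent columns, `grams_<food group>` columns and
#'   `consumed_any`.
#' @export
aggregate_intakes <- function(classification, composition,
                              participants = NULL, n_days = 4) {
  lines <- line_nutrients(classification$lines, composition)
  ids <- if (!is.null(participants)) {
    participants$participant_id
  } else {
    unique(lines$participant_id)
  }
  vals <- c(nutrient_names(), hei_equivalent_names())
  per_group_grams <- lines %>%
    group_by(.data$participant_id, .data$label, .data$food_group) %>%
    summarise(g = sum(.data$amount), .groups = "drop") %>%
    mutate(col = group_col(.data$food_group)) %>%
    select(-all_of("food_group")) %>%
    tidyr::pivot_wider(names_from = "col", values_from = "g",
                       values_fill = 0)
  by_stratum <- lines %>%
    group_by(.data$participant_id, .data$label) %>%
    summarise(across(all_of(vals), sum), .groups = "drop") %>%
    left_join(per_group_grams, by = c("participant_id", "label"))
  # complete the participant x stratum grid with zeros for non-consumers
  grid <- tidyr::expand_grid(participant_id = ids, label = meal_types())
  all_cols <- intake_value_cols()
  filled <- grid %>%
    left_join(by_stratum, by = c("participant_id", "label"))
  for (cn in all_cols) {
    if (!cn %in% names(filled)) filled[[cn]] <- 0
    filled[[cn]][is.na(filled[[cn]])] <- 0
  }
  consumed <- classification$occasions %>%
    distinct(.data$participant_id, .data$label) %>%
    mutate(consumed_any = TRUE)
  meals <- filled %>%
    left_join(consumed, by = c("participant_id", "label")) %>%
    mutate(consumed_any = !is.na(.data$consumed_any),
           across(all_of(all_cols), ~ .x / n_days))
  total <- meals %>%
    group_by(.data$participant_id) %>%
    summarise(across(all_of(all_cols), sum),
              consumed_any = any(.data$consumed_any), .groups = "drop") %>%
    mutate(label = "total")
  bind_rows(meals, total) %>%
    rename(stratum = "label") %>%
    mutate(stratum = factor(.data$stratum,
                            levels = meal_types(with_total = TRUE))) %>%
    arrange(.data$participant_id, .data$stratum) %>%
    select(all_of(c("participant_id", "stratum", "consumed_any", all_cols)))
}

#' Percentage contribution of each meal type to total intake
#'
#' For each dietary variable, the contribution of meal type m is
#' `100 * mean_m / mean_total`, both means taken over the whole population
#' with zeros for non-consumers (per-capita, ratio-of-means). The four
#' contributions of a variable sum to 100 before rounding. Variables whose
#' population mean total intake is zero are reported as missing.
#'
#' @param intakes Intake tibble from [aggregate_intakes()].
#' @param variables Character vector of intake columns to decompose
#'   (default: all nutrient and food-group gram columns).
#' @return A tibble: `variable`, `mean_total`, and one percentage column
#'   per meal type.
#' @export
percent_contribution <- function(intakes, variables = NULL) {
  variables <- variables %||%
    intersect(c(nutrient_names(), group_col(food_groups())),
              names(intakes))
  means <- intakes %>%
    group_by(.data$stratum) %>%
    summarise(across(all_of(variables), mean), .groups = "drop") %>%
    tidyr::pivot_longer(all_of(variables), names_to = "variable",
                        values_to = "mean_intake") %>%
    tidyr::pivot_wider(names_from = "stratum", values_from = "mean_intake")
  means %>%
    mutate(mean_total = .data$total,
           across(all_of(meal_types()),
                  ~ ifelse(.data$total > 0, 100 * .x / .data$total,
                           NA_real_))) %>%
    select(all_of(c("variable", "mean_total", meal_types())))
}

#' Percentage of energy from macronutrients per stratum
#'
#' Computes each participant's percentage of stratum energy supplied by
#' protein, fat, saturated fat, carbohydrate, added sugars and alcohol
#' (Atwater 4/9/4/7 kcal/g; SFA and added sugars use the factors of their
#' parent macronutrient), then averages over participants who consumed the
#' stratum at least once (`consumed_any`); non-consumers are excluded from
#' the denominator rather than entering as zeros.
#'
#' @param intakes Intake tibble from [aggregate_intakes()].
#' @return A tibble: `stratum`, `n` (consumers with positive energy), and
#'   `mean_`/`sd_` columns of %E for each macronutrient.
#' @export
percent_energy_profile <- function(intakes) {
  cons <- intakes %>%
    filter(.data$consumed_any, .data$energy_kcal > 0) %>%
    mutate(pe_protein = 100 * 4 * .data$protein_g / .data$energy_kcal,
           pe_fat = 100 * 9 * .data$fat_g / .data$energy_kcal,
           pe_sfa = 100 * 9 * .data$sfa_g / .data$energy_kcal,
           pe_carb = 100 * 4 * .data$carb_g / .data$energy_kcal,
           pe_added_sugar = 100 * 4 * .data$added_sugar_g /
             .data$energy_kcal,
           pe_alcohol = 100 * 7 * .data$alcohol_g / .data$energy_kcal)
  cons %>%
    group_by(.data$stratum) %>%
    summarise(n = dplyr::n(),
              across(dplyr::starts_with("pe_"),
                     list(mean = mean, sd = sd),
                     .names = "{.fn}_{sub('pe_', '', .col)}"),
              .groups = "drop")
}

#' Food-group intake summary (per-capita and consumer-only)
#'
#' Per food group and stratum: the per-capita mean daily intake in grams
#' (zeros included), the number of consumers (participants with any intake
#' of the group in the stratum over the record period), and the mean among
#' consumers only.
#'
#' @param intakes Intake tibble from [aggregate_intakes()].
#' @return A tibble: `food_group`, `stratum`, `mean_per_capita`,
#'   `n_consumers`, `mean_consumers_only`.
#' @export
food_group_summary <- function(intakes) {
  cols <- intersect(group_col(food_groups()), names(intakes))
  intakes %>%
    tidyr::pivot_longer(all_of(cols), names_to = "food_group",
                        values_to = "grams") %>%
    mutate(food_group = food_groups()[match(.data$food_group,
                                            group_col(food_groups()))]) %>%
    group_by(.data$food_group, .data$stratum) %>%
    summarise(mean_per_capita = mean(.data$grams),
              n_consumers = sum(.data$grams > 0),
              mean_consumers_only = ifelse(any(.data$grams > 0),
                                           mean(.data$grams[.data$grams > 0]),
                                           NA_real_),
              .groups = "drop")
}
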