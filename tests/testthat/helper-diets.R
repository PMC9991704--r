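# Shared fixture builders: miniature composition tables and constructed
# intake rows for score-oracle tests. All fixtures are built in code.

# a composition tibble with every required column, zero-filled
make_composition <- function(...) {
  rows <- dplyr::bind_rows(...)
  defaults <- c(mealquality::nutrient_names(),
                mealquality::hei_equivalent_names())
  for (cn in defaults) {
    if (!cn %in% names(rows)) rows[[cn]] <- 0
    rows[[cn]][is.na(rows[[cn]])] <- 0
  }
  if (!"is_water_only" %in% names(rows)) rows$is_water_only <- FALSE
  rows$is_water_only[is.na(rows$is_water_only)] <- FALSE
  if (!"food_group" %in% names(rows)) rows$food_group <- "rice"
  rows
}

# an intake row (as produced by aggregate_intakes) with zero defaults
make_intake <- function(..., participant_id = "X1", stratum = "total") {
  row <- tibble::tibble(participant_id = participant_id,
                        stratum = stratum, consumed_any = TRUE, ...)
  for (cn in c(mealquality::nutrient_names(),
               mealquality::hei_equivalent_names())) {
    if (!cn %in% names(row)) row[[cn]] <- 0
  }
  row
}

# a diet saturating every HEI-2015 component standard (scores exactly 100)
ideal_hei_intake <- function(std = mealquality::hei_standards(),
                             energy = 2000) {
  row <- make_intake(energy_kcal = energy, sfa_g = 1, mufa_g = 5,
                     pufa_g = 5)
  for (j in seq_len(nrow(std))) {
    s <- std[j, ]
    if (s$basis == "density" && s$direction == "adequacy") {
      row[[s$source]] <- s$max_threshold * energy / 1000
    }
  }
  row
}

# a diet failing every HEI-2015 component (scores exactly 0)
failing_hei_intake <- function(energy = 2000) {
  make_intake(energy_kcal = energy,
              sfa_g = 40, mufa_g = 0, pufa_g = 0,     # 18 %E SFA, ratio 0
              added_sugar_g = 150,                    # 30 %E added sugars
              sodium_mg = 5000,                       # 2.5 g/1000 kcal
              heq_refined_grains_oz = 10)             # 5 oz-eq/1000 kcal
}

# random diets for property tests (non-negative, positive energy)
random_diets <- function(n, seed = 1) {
  set.seed(seed)
  rows <- lapply(seq_len(n), function(i) {
    energy <- runif(1, 300, 3500)
    make_intake(
      participant_id = sprintf("R%04d", i),
      energy_kcal = energy,
      protein_g = runif(1, 0, 150), fat_g = runif(1, 0, 150),
      carb_g = runif(1, 0, 400), alcohol_g = runif(1, 0, 60),
      sfa_g = runif(1, 0, 50), mufa_g = runif(1, 0, 60),
      pufa_g = runif(1, 0, 40), added_sugar_g = runif(1, 0, 120),
      fibre_g = runif(1, 0, 40), sodium_mg = runif(1, 0, 8000),
      potassium_mg = runif(1, 0, 5000), calcium_mg = runif(1, 0, 1500),
      magnesium_mg = runif(1, 0, 600), iron_mg = runif(1, 0, 25),
      vit_a_ug_rae = runif(1, 0, 2000), vit_d_ug = runif(1, 0, 30),
      vit_c_mg = runif(1, 0, 300),
      heq_total_fruit_cup = runif(1, 0, 4),
      heq_whole_fruit_cup = runif(1, 0, 3),
      heq_total_veg_cup = runif(1, 0, 5),
      heq_greens_beans_cup = runif(1, 0, 2),
      heq_whole_grains_oz = runif(1, 0, 6),
      heq_refined_grains_oz = runif(1, 0, 12),
      heq_dairy_cup = runif(1, 0, 4),
      heq_total_protein_oz = runif(1, 0, 12),
      heq_seafood_plant_oz = runif(1, 0, 6))
  })
  dplyr::bind_rows(rows)
}

# random participants matched to a set of intake rows
random_participants <- function(ids, seed = 2) {
  set.seed(seed)
  tibble::tibble(
    participant_id = ids,
    sex = sample(c("male", "female"), length(ids), replace = TRUE),
    age = sample(20:81, length(ids), replace = TRUE),
    height_cm = runif(length(ids), 150, 185),
    weight_kg = runif(length(ids), 45, 95),
    survey_year = sample(c("2003", "2013"), length(ids), replace = TRUE))
}

# one diary line in minutes-since-midnight form
diary_line <- function(pid, day, section, start, end, code, amount) {
  tibble::tibble(participant_id = pid, day_index = as.integer(day),
                 section = section,
                 start_time = mealquality::parse_clock(start),
                 end_time = mealquality::parse_clock(end),
                 next_day = FALSE, food_code = code, amount = amount)
}
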