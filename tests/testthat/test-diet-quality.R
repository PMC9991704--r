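std <- hei_standards()
refs <- nrf_reference_values()

test_that("component scoring is linear between thresholds and clamped", {
  tf <- std[std$name == "total_fruits", ]
  expect_equal(hei_component_score(0.8, tf), 5)    # at the maximum standard
  expect_equal(hei_component_score(1.6, tf), 5)    # clamped above
  expect_equal(hei_component_score(0, tf), 0)
  expect_equal(hei_component_score(0.4, tf), 2.5)  # linear in between
  sf <- std[std$name == "saturated_fats", ]
  expect_equal(hei_component_score(8, sf), 10)
  expect_equal(hei_component_score(16, sf), 0)
  expect_equal(hei_component_score(12, sf), 5)     # halfway -> half points
  expect_error(hei_component_score(-1, tf), "non-negative")
})

test_that("an ideal diet scores 100 and an all-failing diet scores 0", {
  ideal <- hei_score(ideal_hei_intake(std), std)
  expect_equal(ideal$hei_total, 100)
  expect_true(all(ideal[paste0("hei_", std$name)] ==
                    rep(std$max_points, each = 1)))
  worst <- hei_score(failing_hei_intake(), std)
  expect_equal(worst$hei_total, 0)
})

test_that("the fatty-acid ratio handles zero saturated fat continuously", {
  fa <- std[std$name == "fatty_acids", ]
  base <- make_intake(energy_kcal = 2000, sfa_g = 0, mufa_g = 5,
                      pufa_g = 5)
  sc <- hei_score(base, std)
  expect_equal(sc$hei_fatty_acids, fa$max_points)
  none <- make_intake(energy_kcal = 2000, sfa_g = 0, mufa_g = 0,
                      pufa_g = 0)
  expect_equal(hei_score(none, std)$hei_fatty_acids, 0)
})

test_that("zero-energy strata yield missing scores, not errors", {
  empty <- make_intake(energy_kcal = 0, stratum = "snack")
  expect_message(sc <- hei_score(empty, std), "zero-energy")
  expect_true(is.na(sc$hei_total))
  parts <- random_participants("X1")
  expect_message(ns <- nrf_score(empty, parts, refs), "zero-energy")
  expect_true(is.na(ns$nrf_total))
})

test_that("a diet at full reference values scores exactly 900", {
  band <- refs$bands[refs$bands$sex == "male" &
                       refs$bands$age_min == 30, ]
  intake <- make_intake(
    energy_kcal = band$eer_kcal,
    protein_g = band$protein_g, fibre_g = band$fibre_g,
    vit_a_ug_rae = band$vit_a_ug_rae, vit_c_mg = band$vit_c_mg,
    vit_d_ug = band$vit_d_ug, calcium_mg = band$calcium_mg,
    iron_mg = band$iron_mg, potassium_mg = band$potassium_mg,
    magnesium_mg = band$magnesium_mg)
  parts <- tibble::tibble(participant_id = "X1", sex = "male", age = 35L,
                          height_cm = 170, weight_kg = 65,
                          survey_year = "2013")
  sc <- nrf_score(intake, parts, refs)
  expect_equal(sc$nrf_total, 900)
  # doubling the qualifying intakes changes nothing (capped at 100 %DV)
  doubled <- intake
  for (nu in c("protein_g", "fibre_g", "vit_a_ug_rae", "vit_c_mg",
               "vit_d_ug", "calcium_mg", "iron_mg", "potassium_mg",
               "magnesium_mg")) {
    doubled[[nu]] <- doubled[[nu]] * 2
  }
  expect_equal(nrf_score(doubled, parts, refs)$nrf_total, 900)
})

test_that("disqualifying nutrients subtract uncapped percentages", {
  band <- refs$bands[refs$bands$sex == "male" &
                       refs$bands$age_min == 30, ]
  # protein at 50 %DV and Na at 150 %DV, everything else zero -> -100
  intake <- make_intake(energy_kcal = band$eer_kcal,
                        protein_g = band$protein_g / 2,
                        sodium_mg = band$sodium_mg * 1.5)
  parts <- tibble::tibble(participant_id = "X1", sex = "male", age = 35L,
                          height_cm = 170, weight_kg = 65,
                          survey_year = "2013")
  sc <- nrf_score(intake, parts, refs)
  expect_equal(sc$nrf_protein, 50)
  expect_equal(sc$nrf_sodium, 150)
  expect_equal(sc$nrf_total, -100)
  # all-zero nutrients score 0
  zero <- make_intake(energy_kcal = 1000)
  expect_equal(nrf_score(zero, parts, refs)$nrf_total, 0)
})

test_that("both scores are invariant to scaling every amount", {
  diets <- random_diets(200, seed = 41)
  parts <- random_participants(diets$participant_id, seed = 42)
  k <- 2.7
  scaled <- diets
  for (cn in c(nutrient_names(), hei_equivalent_names())) {
    scaled[[cn]] <- scaled[[cn]] * k
  }
  h1 <- hei_score(diets, std)
  h2 <- hei_score(scaled, std)
  expect_equal(h1$hei_total, h2$hei_total, tolerance = 1e-10)
  n1 <- nrf_score(diets, parts, refs)
  n2 <- nrf_score(scaled, parts, refs)
  expect_equal(n1$nrf_total, n2$nrf_total, tolerance = 1e-10)
})

test_that("scores respect monotonicity and component caps", {
  diets <- random_diets(150, seed = 51)
  parts <- random_participants(diets$participant_id, seed = 52)
  h <- hei_score(diets, std)
  comp_cols <- paste0("hei_", std$name)
  for (j in seq_len(nrow(std))) {
    expect_true(all(h[[comp_cols[j]]] <= std$max_points[j] + 1e-12))
    expect_true(all(h[[comp_cols[j]]] >= 0))
  }
  n <- nrf_score(diets, parts, refs)
  for (cn in paste0("nrf_", c("protein", "fibre", "vit_a", "vit_c",
                              "vit_d", "calcium", "iron", "potassium",
                              "magnesium"))) {
    expect_true(all(n[[cn]] <= 100 + 1e-12))
    expect_true(all(n[[cn]] >= 0))
  }
  expect_true(all(n$nrf_total <= 900 + 1e-9))
  # increasing a qualifying nutrient never decreases the NRF total
  bumped <- diets
  bumped$potassium_mg <- bumped$potassium_mg * 1.5
  n_b <- nrf_score(bumped, parts, refs)
  expect_true(all(n_b$nrf_total >= n$nrf_total - 1e-9))
  # increasing a moderation intake never increases the HEI total
  salted <- diets
  salted$sodium_mg <- salted$sodium_mg + 1000
  h_s <- hei_score(salted, std)
  expect_true(all(h_s$hei_total <= h$hei_total + 1e-9))
})

test_that("meal strata of a generated day rank plausibly on both indices", {
  comp <- default_composition_table()
  pop <- generate_population(generator_config(n_participants = 80),
                             comp, seed = 61)
  cls <- classify_records(pop$records, comp)
  intakes <- aggregate_intakes(cls, comp, pop$participants, 4)
  sc <- suppressMessages(score_population(intakes, pop$participants,
                                          std, refs))
  means <- tapply(sc$hei_total, sc$stratum, mean, na.rm = TRUE)
  expect_gt(means[["dinner"]], means[["snack"]])
  nrf_means <- tapply(sc$nrf_total, sc$stratum, mean, na.rm = TRUE)
  expect_gt(nrf_means[["dinner"]], nrf_means[["snack"]])
})
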