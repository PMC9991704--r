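comp <- default_composition_table()

test_that("generation is deterministic given the seed", {
  cfg <- generator_config(n_participants = 10)
  a <- generate_population(cfg, comp, seed = 7)
  b <- generate_population(cfg, comp, seed = 7)
  expect_identical(a$records, b$records)
  expect_identical(a$participants, b$participants)
  c_ <- generate_population(cfg, comp, seed = 8)
  expect_false(identical(a$records$amount, c_$records$amount))
})

test_that("config invariants are enforced before sampling", {
  expect_error(generator_config(meal_energy_share_means =
                                  c(breakfast = 0.3, lunch = 0.3,
                                    dinner = 0.3, snack = 0.3)),
               "sum to 1")
  bad_alloc <- generator_config()$food_allocation_matrix
  bad_alloc[1, ] <- c(0.5, 0.5, 0.5, 0.5)
  expect_error(generator_config(food_allocation_matrix = bad_alloc),
               "rows must sum to 1")
  expect_error(generator_config(n_participants = 0), "n_participants")
})

test_that("no skipping and no snacks yields exactly three occasions a day", {
  cfg <- generator_config(
    n_participants = 8,
    skip_probabilities = c(breakfast = 0, lunch = 0, dinner = 0),
    snack_count = list(size = 8, mean = 0, sd = 0.5),
    double_entry_rate = 0, overlap_rate = 0)
  pop <- generate_population(cfg, comp, seed = 3)
  cls <- classify_records(pop$records, comp)
  per_day <- dplyr::count(cls$occasions, participant_id, day_index)
  expect_true(all(per_day$n == 3))
  expect_setequal(unique(cls$occasions$label),
                  c("breakfast", "lunch", "dinner"))
})

test_that("line energies conserve the drawn daily energy", {
  pop <- generate_population(generator_config(n_participants = 30),
                             comp, seed = 11)
  en <- line_nutrients(pop$records, comp) |>
    dplyr::group_by(participant_id, day_index) |>
    dplyr::summarise(e = sum(energy_kcal), .groups = "drop") |>
    dplyr::left_join(pop$day_targets, by = c("participant_id", "day_index"))
  expect_true(all(abs(en$e - en$target_energy_kcal) /
                    en$target_energy_kcal < 1e-6))
})

test_that("default calibration reproduces its configured targets", {
  cfg <- generator_config(n_participants = 500)
  pop <- generate_population(cfg, comp, seed = 21)
  cls <- classify_records(pop$records, comp)
  intakes <- aggregate_intakes(cls, comp, pop$participants, cfg$n_days)
  contrib <- percent_contribution(intakes, variables = "energy_kcal")
  tgt <- cfg$meal_energy_share_means * 100
  for (m in meal_types()) {
    expect_lt(abs(contrib[[m]] - tgt[[m]]), 1.5)
  }
  d <- meal_descriptives(cls$occasions, cfg$n_days)
  expect_lt(abs(d$snack_mean - cfg$snack_count$mean), 0.15)
  expect_lt(abs(d$snack_sd - cfg$snack_count$sd), 0.2)
  mt <- d$meal_times
  for (m in main_meals()) {
    se <- cfg$meal_start_sds[[m]] / sqrt(mt$n[mt$label == m])
    expect_lt(abs(mt$mean_start[mt$label == m] -
                    cfg$meal_start_means[[m]]), 3 * se + 1)
  }
  # main meals are consumed on all days by the large majority
  cons <- d$meal_consumption |>
    dplyr::group_by(label) |>
    dplyr::summarise(all_days = mean(days_consumed == cfg$n_days))
  expect_gt(cons$all_days[cons$label == "breakfast"], 0.8)
  expect_gt(cons$all_days[cons$label == "dinner"],
            cons$all_days[cons$label == "breakfast"] - 0.02)
})

test_that("the empirical allocation matrix converges to the configured one", {
  cfg <- generator_config(n_participants = 2000)
  pop <- generate_population(cfg, comp, seed = 31)
  cls <- classify_records(pop$records, comp)
  intakes <- aggregate_intakes(cls, comp, pop$participants, cfg$n_days)
  contrib <- percent_contribution(intakes)
  alloc <- cfg$food_allocation_matrix
  for (g in food_groups()) {
    row <- contrib[contrib$variable == paste0("grams_", gsub("[^a-z_]", "",
                                              gsub(" ", "_", g))), ]
    for (m in meal_types()) {
      expect_lt(abs(row[[m]] - 100 * alloc[g, m]), 3,
                label = paste(g, m, round(row[[m]], 1)))
    }
  }
})

test_that("anomaly days exercise the classifier at the configured rate", {
  cfg <- generator_config(n_participants = 400)
  pop <- generate_population(cfg, comp, seed = 13)
  cls <- classify_records(pop$records, comp)
  merged <- cls$occasions[grepl("\\+", cls$occasions$merged_from), ]
  n_days <- 400 * cfg$n_days
  # overlap rate 0.095 -> expect merged occasions on roughly that share
  expect_gt(nrow(merged) / n_days, 0.05)
  expect_lt(nrow(merged) / n_days, 0.15)
  # snacks recorded in main-meal sections exist (double entries)
  relabelled <- cls$occasions[cls$occasions$label == "snack" &
                                cls$occasions$merged_from %in%
                                  main_meals(), ]
  expect_gt(nrow(relabelled), 0)
})

test_that("worked fixtures align occasions with expectations one-to-one", {
  fx <- generate_worked_fixtures()
  expect_gt(nrow(fx$records), 0)
  cls <- classify_records(fx$records, comp)
  n_excluded <- sum(fx$expected$label == "excluded")
  expect_equal(nrow(cls$occasions) + n_excluded, nrow(fx$expected))
  expect_true(any(fx$expected$label == "excluded"))
  # the double-entry breakfast case is expected as (breakfast, snack)
  fx2 <- fx$expected[fx$expected$participant_id == "FX2", ]
  expect_equal(fx2$label[order(fx2$start_time)][1:2],
               c("breakfast", "snack"))
  expect_silent(validate_records(fx$records, comp))
  expect_silent(validate_participants(fx$participants))
})
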