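comp <- default_composition_table()

test_that("water-only occasions are excluded, mixed occasions retained", {
  lines <- dplyr::bind_rows(
    diary_line("P1", 1, "snack", "10:00", "10:05", "W004", 200),
    diary_line("P1", 1, "breakfast", "07:00", "07:10", "W004", 200),
    diary_line("P1", 1, "breakfast", "07:00", "07:10", "R001", 150))
  kept <- drop_water_only(lines, comp)
  expect_equal(nrow(kept), 2)
  expect_true(all(kept$section == "breakfast"))
  expect_equal(nrow(drop_water_only(lines[0, ], comp)), 0)
})

test_that("later entries in a main-meal section become snacks", {
  lines <- dplyr::bind_rows(
    diary_line("P1", 1, "dinner", "18:00", "18:20", "R001", 150),
    diary_line("P1", 1, "dinner", "21:00", "21:10", "A001", 350),
    diary_line("P1", 1, "dinner", "23:00", "23:10", "C003", 20))
  cls <- classify_day(lines, comp)
  expect_equal(cls$occasions$label, c("dinner", "snack", "snack"))
  # single entries are left unchanged
  single <- classify_day(diary_line("P2", 1, "lunch", "12:00", "12:20",
                                    "N001", 200), comp)
  expect_equal(single$occasions$label, "lunch")
})

test_that("overlapping occasions merge with meal-over-snack precedence", {
  # lunch + snack overlap, no earlier lunch -> merged occasion is lunch
  l1 <- dplyr::bind_rows(
    diary_line("P1", 1, "lunch", "12:00", "12:30", "R001", 200),
    diary_line("P1", 1, "snack", "12:10", "12:20", "C001", 30))
  c1 <- classify_day(l1, comp)
  expect_equal(c1$occasions$label, "lunch")
  expect_equal(c1$occasions$start_time, parse_clock("12:00"))
  expect_equal(c1$occasions$end_time, parse_clock("12:30"))
  expect_equal(c1$occasions$n_lines, 2L)

  # same-named meal already recorded earlier -> merged occasion is a snack
  l2 <- dplyr::bind_rows(
    diary_line("P1", 1, "lunch", "12:00", "12:20", "N001", 200),
    diary_line("P1", 1, "lunch", "15:00", "15:20", "R001", 100),
    diary_line("P1", 1, "snack", "15:05", "15:15", "C004", 20))
  c2 <- classify_day(l2, comp)
  expect_equal(c2$occasions$label, c("lunch", "snack"))
  expect_equal(c2$occasions$n_lines, c(1L, 2L))

  # snack-on-snack overlap -> one merged snack spanning both
  l3 <- dplyr::bind_rows(
    diary_line("P1", 1, "snack", "10:00", "10:10", "Q001", 350),
    diary_line("P1", 1, "snack", "10:05", "10:15", "C001", 30))
  c3 <- classify_day(l3, comp)
  expect_equal(c3$occasions$label, "snack")
  expect_equal(c3$occasions$end_time, parse_clock("10:15"))

  # touching intervals do not merge
  l4 <- dplyr::bind_rows(
    diary_line("P1", 1, "lunch", "12:00", "12:30", "R001", 200),
    diary_line("P1", 1, "snack", "12:30", "12:40", "C001", 30))
  c4 <- classify_day(l4, comp)
  expect_equal(nrow(c4$occasions), 2)
})

test_that("the hand-worked fixture classifies exactly as expected", {
  fx <- generate_worked_fixtures()
  cls <- classify_records(fx$records, comp)
  got <- cls$occasions[order(cls$occasions$participant_id,
                             cls$occasions$start_time),
                       c("participant_id", "day_index", "label",
                         "start_time", "n_lines")]
  want <- fx$expected[fx$expected$label != "excluded", ]
  want <- want[order(want$participant_id, want$start_time), ]
  expect_equal(as.data.frame(got), as.data.frame(want),
               ignore_attr = TRUE)
  # excluded water-only occasions are absent from the classified lines
  excl <- fx$expected[fx$expected$label == "excluded", ]
  for (i in seq_len(nrow(excl))) {
    expect_false(any(cls$lines$participant_id == excl$participant_id[i] &
                       cls$lines$start_time == excl$start_time[i]))
  }
})

test_that("classification is idempotent", {
  fx <- generate_worked_fixtures()
  cls <- classify_records(fx$records, comp)
  relabelled <- cls$lines
  relabelled$section <- relabelled$label
  again <- classify_records(relabelled[names(fx$records)], comp)
  key <- function(o) {
    as.data.frame(o[order(o$participant_id, o$start_time),
                    c("participant_id", "day_index", "label",
                      "start_time", "end_time", "n_lines")])
  }
  expect_equal(key(again$occasions), key(cls$occasions),
               ignore_attr = TRUE)
})

test_that("every non-excluded line lands in exactly one occasion", {
  fx <- generate_worked_fixtures()
  water <- comp$food_code[comp$is_water_only]
  cls <- classify_records(fx$records, comp)
  # conservation on the fixture: lines partition into occasions
  expect_equal(sum(cls$occasions$n_lines), nrow(cls$lines))
  expect_false(any(is.na(cls$lines$occasion_id)))
  # a generated population conserves lines too (no water foods generated)
  pop <- generate_population(generator_config(n_participants = 15),
                             comp, seed = 5)
  pcls <- classify_records(pop$records, comp)
  expect_equal(nrow(pcls$lines), nrow(pop$records))
  expect_equal(sum(pcls$occasions$n_lines), nrow(pop$records))
})

test_that("input line order only matters through documented tie-breaks", {
  fx <- generate_worked_fixtures()
  cls <- classify_records(fx$records, comp)
  set.seed(9)
  perm <- fx$records[sample.int(nrow(fx$records)), ]
  cls2 <- classify_records(perm, comp)
  key <- function(o) {
    as.data.frame(o[order(o$participant_id, o$start_time),
                    c("participant_id", "day_index", "label",
                      "start_time", "end_time", "n_lines")])
  }
  expect_equal(key(cls2$occasions), key(cls$occasions), ignore_attr = TRUE)
})

test_that("meal descriptives summarise start times and snack frequency", {
  lines <- dplyr::bind_rows(lapply(1:4, function(d) {
    diary_line("P1", d, "breakfast", "07:00", "07:15", "R001", 150)
  }))
  cls <- classify_records(lines, comp)
  d <- meal_descriptives(cls$occasions, n_days = 4)
  expect_equal(d$meal_times$mean_start, 420)
  expect_equal(d$meal_times$sd_start, 0)
  expect_equal(d$meal_times$mean_clock, "07:00")
  expect_equal(d$snack_mean, 0)
  cons <- d$meal_consumption
  expect_equal(cons$days_consumed[cons$label == "breakfast"], 4L)
})
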