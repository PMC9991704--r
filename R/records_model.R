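# Data model and I/O for participants, diary records and the composition
# table. All three travel as tibbles with fixed column contracts; readers
# validate every row and fail with line-numbered messages so that a broken
# input file never propagates silently into the analysis.

#' Read a dietary-record file
#'
#' Reads a comma-delimited diary file with one row per food item within an
#' eating occasion. Required columns: `participant_id`, `day_index`,
#' `section` (one of breakfast/lunch/dinner/snack), `start_time` and
#' `end_time` as `"HH:MM"` clock strings, `food_code`, `amount` (grams).
#' An optional logical `next_day` column marks occasions whose finish time
#' falls after midnight; such occasions stay attributed to the day on which
#' they started.
#'
#' @param path Path to the CSV file.
#' @param composition Optional composition table (see [read_composition()]);
#'   when supplied, unknown food codes are a hard error listing the missing
#'   codes.
#' @return A tibble of diary lines with `start_time`/`end_time` converted to
#'   integer minutes since midnight.
#' @export
read_records <- function(path, composition = NULL) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (nrow(raw) == 0) {
    warn(paste0("no diary lines in ", path))
    return(empty_records())
  }
  stop_if_missing_cols(raw, c("participant_id", "day_index", "section",
                              "start_time", "end_time", "food_code",
                              "amount"), "records file")
  lines <- tibble(
    participant_id = raw$participant_id,
    day_index = as.integer(raw$day_index),
    section = raw$section,
    start_time = parse_clock(raw$start_time),
    end_time = parse_clock(raw$end_time),
    next_day = if ("next_day" %in% names(raw)) {
      tolower(raw$next_day) %in% c("true", "t", "1", "yes")
    } else FALSE,
    food_code = raw$food_code,
    amount = as.numeric(raw$amount)
  )
  validate_records(lines, composition)
}

#' Validate a tibble of diary lines
#'
#' @param lines Tibble as returned by [read_records()].
#' @param composition Optional composition table for food-code lookup.
#' @return The validated tibble, invisibly unchanged.
#' @export
validate_records <- function(lines, composition = NULL) {
  bad_line <- function(idx, msg) {
    abort(paste0("invalid diary line(s) ", paste(idx, collapse = ", "),
                 ": ", msg))
  }
  if (anyNA(lines$day_index) || any(lines$day_index < 1)) {
    bad_line(which(is.na(lines$day_index) | lines$day_index < 1),
             "day_index must be a positive integer")
  }
  bad_sec <- !lines$section %in% meal_types()
  if (any(bad_sec)) {
    bad_line(which(bad_sec), paste0("section must be one of ",
                                    paste(meal_types(), collapse = "/")))
  }
  if (anyNA(lines$amount) || any(lines$amount < 0)) {
    bad_line(which(is.na(lines$amount) | lines$amount < 0),
             "negative amount")
  }
  bad_end <- !lines$next_day & lines$end_time < lines$start_time
  if (any(bad_end)) {
    bad_line(which(bad_end),
             "end_time before start_time without next_day flag")
  }
  if (!is.null(composition)) {
    missing_codes <- setdiff(lines$food_code, composition$food_code)
    if (length(missing_codes)) {
      abort(paste0("unknown food code(s): ",
                   paste(sort(missing_codes), collapse = ", ")))
    }
  }
  lines
}

empty_records <- function() {
  tibble(participant_id = character(), day_index = integer(),
         section = character(), start_time = integer(),
         end_time = integer(), next_day = logical(),
         food_code = character(), amount = numeric())
}

#' Write a dietary-record file
#'
#' Inverse of [read_records()] under canonical formatting: clock times are
#' written back as `"HH:MM"` and a read/write round trip reproduces every
#' field value exactly.
#'
#' @param lines Tibble of diary lines (minutes-since-midnight times).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_records <- function(lines, path) {
  out <- lines %>%
    mutate(start_time = format_clock(.data$start_time),
           end_time = format_clock(.data$end_time))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a participant file
#'
#' Required columns: `participant_id`, `sex` (male/female), `age` (years),
#' `height_cm`, `weight_kg`, `survey_year` (categorical label). Adults only:
#' age must be >= 18, height in (100, 220) cm, weight in (25, 200) kg.
#'
#' @param path Path to the CSV file.
#' @return A validated participant tibble.
#' @export
read_participants <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  stop_if_missing_cols(raw, c("participant_id", "sex", "age", "height_cm",
                              "weight_kg", "survey_year"),
                       "participant file")
  validate_participants(tibble(
    participant_id = raw$participant_id,
    sex = tolower(raw$sex),
    age = as.integer(raw$age),
    height_cm = as.numeric(raw$height_cm),
    weight_kg = as.numeric(raw$weight_kg),
    survey_year = as.character(raw$survey_year)
  ))
}

#' Validate a participant tibble
#'
#' @param participants Tibble with the columns of [read_participants()].
#' @return The validated tibble.
#' @export
validate_participants <- function(participants) {
  stop_if_missing_cols(participants,
                       c("participant_id", "sex", "age", "height_cm",
                         "weight_kg", "survey_year"), "participant table")
  if (anyDuplicated(participants$participant_id)) {
    abort("duplicated participant_id")
  }
  if (!all(participants$sex %in% c("male", "female"))) {
    abort("sex must be 'male' or 'female'")
  }
  with(participants, {
    if (any(age < 18, na.rm = TRUE)) abort("age must be >= 18")
    if (any(height_cm <= 100 | height_cm >= 220, na.rm = TRUE)) {
      abort("height_cm must lie in (100, 220)")
    }
    if (any(weight_kg <= 25 | weight_kg >= 200, na.rm = TRUE)) {
      abort("weight_kg must lie in (25, 200)")
    }
  })
  participants
}

#' Read a food-composition table
#'
#' One row per food code with per-100 g nutrient values (see
#' [nutrient_names()]), HEI-2015 pattern equivalents (see
#' [hei_equivalent_names()]), a single food-group assignment and an
#' `is_water_only` flag (true only for plain tap/mineral water).
#'
#' @param path Path to the CSV file.
#' @return A validated composition tibble.
#' @export
read_composition <- function(path) {
  tab <- readr::read_csv(path, col_types = readr::cols(
    food_code = "c", food_name = "c", food_group = "c", is_water_only = "l",
    .default = "d"), progress = FALSE)
  validate_composition(tab)
}

#' The bundled synthetic composition table
#'
#' A miniature food-composition table of 61 food codes (>= 3 per food
#' group) with values loosely modeled on Japanese staple foods. It is a
#' fixture for simulation and testing, not a nutritional reference, and can
#' be swapped for any table that passes [validate_composition()].
#'
#' @return The composition tibble.
#' @export
#' @examples
#' tab <- default_composition_table()
#' table(tab$food_group)
default_composition_table <- function() {
  read_composition(system.file("extdata", "food_composition_synthetic.csv",
                               package = "mealquality", mustWork = TRUE))
}

#' Validate a composition table
#'
#' Checks the column contract, non-negativity, uniqueness of food codes,
#' one food group per code, and energy consistency with the Atwater
#' general factors (4/9/4/7 kcal/g for protein/fat/carbohydrate/alcohol)
#' within 25 % — slack that absorbs fibre fermentation and rounding.
#'
#' @param tab Composition tibble.
#' @param atwater_tol Relative tolerance of the energy check (default 0.25).
#' @return The validated tibble.
#' @export
validate_composition <- function(tab, atwater_tol = 0.25) {
  stop_if_missing_cols(tab, c("food_code", "food_group", "is_water_only",
                              nutrient_names(), hei_equivalent_names()),
                       "composition table")
  if (anyDuplicated(tab$food_code)) {
    abort("composition table has duplicated food codes")
  }
  if (!all(tab$food_group %in% food_groups())) {
    abort(paste0("unknown food group(s): ",
                 paste(setdiff(tab$food_group, food_groups()),
                       collapse = ", ")))
  }
  num_cols <- c(nutrient_names(), hei_equivalent_names())
  neg <- vapply(tab[num_cols], function(x) any(x < 0, na.rm = TRUE),
                logical(1))
  if (any(neg)) {
    abort(paste0("negative per-100 g value(s) in: ",
                 paste(num_cols[neg], collapse = ", ")))
  }
  fac <- atwater_factors()
  pred <- as.matrix(tab[names(fac)]) %*% fac
  bad <- abs(tab$energy_kcal - pred) > atwater_tol * pmax(pred, 10)
  if (any(bad)) {
    abort(paste0("energy inconsistent with Atwater 4/9/4/7 for: ",
                 paste(tab$food_code[bad], collapse = ", ")))
  }
  tab
}

#' Nutrients supplied by diary lines
#'
#' Scales each line's per-100 g composition by `amount / 100`, appending
#' one column per nutrient, per HEI equivalent, and the food group. Exact
#' proportionality: 150 g of a food with 100 kcal/100 g contributes
#' 150 kcal.
#'
#' @param lines Tibble of diary lines (at least `food_code` and `amount`).
#' @param composition Composition table.
#' @return `lines` with nutrient, equivalent and `food_group` columns added.
#' @export
line_nutrients <- function(lines, composition) {
  missing_codes <- setdiff(lines$food_code, composition$food_code)
  if (length(missing_codes)) {
    abort(paste0("unknown food code(s): ",
                 paste(sort(missing_codes), collapse = ", ")))
  }
  per100 <- c(nutrient_names(), hei_equivalent_names())
  lines %>%
    left_join(composition %>%
                select(all_of(c("food_code", "food_group", per100))),
              by = "food_code") %>%
    mutate(across(all_of(per100), ~ .x * .data$amount / 100))
}
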