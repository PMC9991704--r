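# BMI classification and Goldberg EI:BMR screening of energy-intake
# misreporting. The Goldberg cut-offs used (1.02 and 2.35) were derived for
# a 4-day record under an assumed sedentary physical activity level of
# 1.55; they are treated as fixed constants, with the PAL recorded as
# metadata only.

goldberg_cutoffs <- function() c(lower = 1.02, upper = 2.35, pal = 1.55)

#' Classify weight status from BMI
#'
#' Underweight below 18.5 kg/m2, normal weight from 18.5 up to (but not
#' including) 25.0, overweight at 25.0 and above.
#'
#' @param bmi Numeric BMI values (kg/m2), positive.
#' @return Character vector: `"underweight"`, `"normal"`, `"overweight"`.
#' @export
#' @examples
#' classify_weight(c(18.49, 18.5, 25))
classify_weight <- function(bmi) {
  stopifnot(all(bmi > 0, na.rm = TRUE))
  dplyr::case_when(bmi < 18.5 ~ "underweight",
                   bmi < 25.0 ~ "normal",
                   TRUE ~ "overweight")
}

#' Estimate basal metabolic rate
#'
#' Default equation: the Japanese-adult equation of Ganpule and colleagues,
#' `BMR (MJ/d) = 0.0481 x weight(kg) + 0.0234 x height(cm) - 0.0138 x
#' age(y) - k`, with `k = 0.4235` for men and `0.9708` for women, converted
#' to kcal/d at 239.006 kcal/MJ. Alternative equations (e.g.
#' Schofield-type weight-only equations) can be plugged in via `equation`;
#' the screening contract downstream does not change.
#'
#' @param participants Participant tibble (`sex`, `age`, `height_cm`,
#'   `weight_kg`).
#' @param equation `"ganpule"` (default) or a function
#'   `f(sex, age, height_cm, weight_kg) -> kcal/d`.
#' @return Numeric vector of BMR in kcal/d (error if any non-positive).
#' @export
estimate_bmr <- function(participants, equation = "ganpule") {
  fn <- if (is.function(equation)) {
    equation
  } else if (identical(equation, "ganpule")) {
    bmr_ganpule
  } else {
    abort(paste0("unknown BMR equation: ", equation))
  }
  bmr <- fn(participants$sex, participants$age, participants$height_cm,
            participants$weight_kg)
  if (any(bmr <= 0, na.rm = TRUE)) {
    abort("BMR equation returned non-positive value(s)")
  }
  bmr
}

bmr_ganpule <- function(sex, age, height_cm, weight_kg) {
  k <- ifelse(sex == "male", 0.4235, 0.9708)
  mj <- 0.0481 * weight_kg + 0.0234 * height_cm - 0.0138 * age - k
  mj * 239.006
}

#' Classify dietary reporting status from the EI:BMR ratio
#'
#' Underreporting below 1.02, plausible reporting from 1.02 up to (but not
#' including) 2.35, overreporting at 2.35 and above.
#'
#' @param ei Reported mean daily energy intake (kcal/d).
#' @param bmr Estimated BMR (kcal/d), positive.
#' @return Character vector: `"under"`, `"plausible"`, `"over"`.
#' @export
#' @examples
#' classify_reporting(c(1.019, 1.02, 2.349, 2.35) * 1500, 1500)
classify_reporting <- function(ei, bmr) {
  stopifnot(all(bmr > 0, na.rm = TRUE))
  cut <- goldberg_cutoffs()
  ratio <- ei / bmr
  dplyr::case_when(ratio < cut[["lower"]] ~ "under",
                   ratio < cut[["upper"]] ~ "plausible",
                   TRUE ~ "over")
}

#' Screen a population for misreporting
#'
#' Computes BMI and weight status, estimates BMR, and classifies reporting
#' status from the ratio of the 4-day mean daily energy intake (total-diet
#' stratum) to BMR.
#'
#' @param participants Participant tibble.
#' @param intakes Intake tibble from [aggregate_intakes()] (the `total`
#'   stratum supplies EI).
#' @param equation BMR equation, see [estimate_bmr()].
#' @return A tibble: `participant_id`, `bmi`, `weight_status`, `bmr`,
#'   `ei`, `ei_bmr_ratio`, `reporting_status`.
#' @export
screen_misreporting <- function(participants, intakes,
                                equation = "ganpule") {
  ei_tab <- intakes %>%
    filter(.data$stratum == "total") %>%
    select(all_of(c("participant_id", "energy_kcal")))
  out <- participants %>%
    left_join(ei_tab, by = "participant_id") %>%
    mutate(bmi = .data$weight_kg / (.data$height_cm / 100)^2,
           weight_status = classify_weight(.data$bmi),
           bmr = estimate_bmr(dplyr::pick(everything()), equation),
           ei = .data$energy_kcal,
           ei_bmr_ratio = .data$ei / .data$bmr,
           reporting_status = classify_reporting(.data$ei, .data$bmr))
  out %>%
    select(all_of(c("participant_id", "bmi", "weight_status", "bmr", "ei",
                    "ei_bmr_ratio", "reporting_status")))
}
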