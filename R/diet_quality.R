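# Diet-quality scoring: Healthy Eating Index-2015 (13 components, 100
# points) and Nutrient-Rich Food Index 9.3 (9 qualifying minus 3
# disqualifying components, maximum 900). Both are computed on
# energy-adjusted intakes (density method), so they apply unchanged to the
# total diet or to any single meal type; NRF densities are re-scaled to
# absolute daily amounts with the participant's sex- and age-specific
# Estimated Energy Requirement before comparison with reference daily
# values.

#' HEI-2015 scoring standards
#'
#' Loads the component scoring-standard table: for each of the 13
#' components, its direction (adequacy or moderation), unit basis (amount
#' per 1000 kcal, percentage of energy, or the unadjusted
#' (MUFA+PUFA)/SFA ratio), maximum points (5 or 10) and the thresholds at
#' which the maximum and zero scores are awarded. The default table ships
#' with the package; any YAML file with the same layout can be substituted.
#'
#' @param path Path to a standards YAML file (default: bundled table).
#' @return A tibble with columns `name`, `direction`, `basis`, `source`,
#'   `max_points`, `max_threshold`, `zero_threshold`.
#' @export
#' @examples
#' hei_standards()
hei_standards <- function(path = NULL) {
  path <- path %||% system.file("extdata", "hei2015_standards.yaml",
                                package = "mealquality", mustWork = TRUE)
  raw <- yaml::read_yaml(path)
  std <- purrr::map_dfr(raw$components, as_tibble)
  stopifnot(sum(std$max_points) == 100,
            all(std$direction %in% c("adequacy", "moderation")))
  with(std, {
    adeq <- direction == "adequacy"
    stopifnot(all(zero_threshold[adeq] < max_threshold[adeq]),
              all(max_threshold[!adeq] < zero_threshold[!adeq]))
  })
  std
}

#' Score one HEI-2015 component
#'
#' Linear scoring between the zero and maximum thresholds, clamped at both
#' ends. Adequacy components gain points with intake; moderation components
#' lose them.
#'
#' @param value Energy-adjusted intake value(s) on the component's unit
#'   basis; must be non-negative (`Inf` allowed for the fatty-acid ratio).
#' @param standard One row of [hei_standards()] (or an equivalent list with
#'   `direction`, `max_points`, `max_threshold`, `zero_threshold`).
#' @return Numeric score(s) in `[0, max_points]`.
#' @export
#' @examples
#' std <- hei_standards()
#' hei_component_score(0.8, std[std$name == "total_fruits", ])  # 5
hei_component_score <- function(value, standard) {
  if (any(value < 0, na.rm = TRUE)) {
    abort("component intake value must be non-negative")
  }
  mx <- standard$max_threshold
  z <- standard$zero_threshold
  frac <- if (standard$direction == "adequacy") {
    ifelse(is.infinite(value), 1, (value - z) / (mx - z))
  } else {
    (z - value) / (z - mx)
  }
  standard$max_points * pmin(pmax(frac, 0), 1)
}

# energy-adjusted value of each component for one or more intake rows
hei_component_values <- function(intakes, std) {
  energy <- intakes$energy_kcal
  vals <- matrix(NA_real_, nrow = nrow(intakes), ncol = nrow(std),
                 dimnames = list(NULL, std$name))
  for (j in seq_len(nrow(std))) {
    s <- std[j, ]
    vals[, j] <- switch(
      s$basis,
      density = {
        amt <- if (s$source == "sodium_g") {
          intakes$sodium_mg / 1000
        } else {
          intakes[[s$source]]
        }
        amt * 1000 / energy
      },
      percent_energy = {
        kcal_per_g <- if (s$source == "sfa_g") 9 else 4
        100 * kcal_per_g * intakes[[s$source]] / energy
      },
      ratio = {
        num <- intakes$mufa_g + intakes$pufa_g
        ifelse(intakes$sfa_g > 0, num / intakes$sfa_g,
               ifelse(num > 0, Inf, 0))
      },
      abort(paste0("unknown basis: ", s$basis))
    )
  }
  vals
}

#' Compute HEI-2015 scores
#'
#' Scores each intake row (any diet stratum) against the 13 component
#' standards. Densities are `amount x 1000 / energy`; added sugars and
#' saturated fats use percentage of energy; the fatty-acid component uses
#' the unadjusted (MUFA+PUFA)/SFA ratio, with a zero-SFA diet scoring full
#' points when unsaturated fat is present and zero points otherwise.
#' Zero-energy strata yield missing scores.
#'
#' @param intakes Intake tibble ([aggregate_intakes()] rows, or any tibble
#'   with energy, fatty-acid, sodium, added-sugar and HEI-equivalent
#'   columns).
#' @param standards Standards table from [hei_standards()].
#' @return `intakes`' identifier columns (`participant_id`, `stratum` when
#'   present) plus one `hei_<component>` column per component and
#'   `hei_total` in `[0, 100]`.
#' @export
hei_score <- function(intakes, standards = hei_standards()) {
  ids <- intersect(c("participant_id", "stratum"), names(intakes))
  out <- intakes[ids]
  ok <- intakes$energy_kcal > 0
  if (any(!ok)) {
    rlang::inform(paste0(sum(!ok), " zero-energy stratum row(s); ",
                         "HEI-2015 reported as missing"))
  }
  vals <- hei_component_values(intakes[ok, , drop = FALSE], standards)
  scores <- matrix(NA_real_, nrow = nrow(intakes), ncol = nrow(standards),
                   dimnames = list(NULL, paste0("hei_", standards$name)))
  for (j in seq_len(nrow(standards))) {
    scores[ok, j] <- hei_component_score(vals[, j], standards[j, ])
  }
  out <- bind_cols(out, as_tibble(scores))
  out$hei_total <- rowSums(scores)
  out
}

#' NRF9.3 reference daily values and energy requirements
#'
#' Loads the sex- and age-band table of reference daily values for the
#' nine qualifying nutrients (protein, dietary fibre, vitamins A, C and D,
#' Ca, Fe, K, Mg), the sodium limit, and the Estimated Energy Requirement
#' (EER, moderate physical activity), together with the percentage-of-
#' energy limits used to derive gram limits for added sugars (5 %E, WHO
#' conditional recommendation) and saturated fats (7 %E). The default
#' table transcribes the 2015 Dietary Reference Intakes for Japanese.
#'
#' @param path Path to a reference YAML file (default: bundled table).
#' @return A list with `bands` (tibble) and scalars
#'   `added_sugar_pct_energy`, `sfa_pct_energy`.
#' @export
nrf_reference_values <- function(path = NULL) {
  path <- path %||% system.file("extdata", "nrf93_reference_jp2015.yaml",
                                package = "mealquality", mustWork = TRUE)
  raw <- yaml::read_yaml(path)
  bands <- purrr::map_dfr(raw$bands, as_tibble)
  stopifnot(all(bands$eer_kcal > 0),
            all(as.matrix(bands[!names(bands) %in%
                                  c("sex", "age_min", "age_max")]) > 0))
  list(bands = bands,
       added_sugar_pct_energy = raw$added_sugar_pct_energy,
       sfa_pct_energy = raw$sfa_pct_energy)
}

nrf_qualifying <- function() {
  c("protein_g", "fibre_g", "vit_a_ug_rae", "vit_c_mg", "vit_d_ug",
    "calcium_mg", "iron_mg", "potassium_mg", "magnesium_mg")
}

# band lookup: one reference row per participant
nrf_band_for <- function(participants, refs) {
  bands <- refs$bands
  idx <- vapply(seq_len(nrow(participants)), function(i) {
    hit <- which(bands$sex == participants$sex[i] &
                   bands$age_min <= participants$age[i] &
                   participants$age[i] <= bands$age_max)
    if (length(hit) != 1) {
      abort(paste0("no reference band for sex=", participants$sex[i],
                   ", age=", participants$age[i]))
    }
    hit
  }, integer(1))
  bands[idx, ]
}

#' Compute NRF9.3 scores
#'
#' Each nutrient intake is adjusted for energy by the density method and
#' re-scaled by the participant's EER (`amount/energy x EER`), then
#' expressed as a percentage of its reference daily value. Qualifying
#' percentages are capped at 100; disqualifying percentages (added sugars,
#' saturated fats, Na) are not capped. The total is the sum of the nine
#' qualifying minus the three disqualifying percentages, so the maximum is
#' 900 and the minimum is unbounded below. Zero-energy strata yield
#' missing scores.
#'
#' @param intakes Intake tibble from [aggregate_intakes()] (must carry
#'   `participant_id`).
#' @param participants Participant tibble (sex and age drive the band
#'   lookup).
#' @param refs Reference list from [nrf_reference_values()].
#' @return Identifier columns plus `nrf_<nutrient>` percentage columns
#'   (signed: qualifying positive contribution, disqualifying columns
#'   reported as the uncapped %DV) and `nrf_total`.
#' @export
nrf_score <- function(intakes, participants,
                      refs = nrf_reference_values()) {
  pt <- participants[match(intakes$participant_id,
                           participants$participant_id), ]
  if (anyNA(pt$participant_id)) {
    abort("intake rows reference unknown participant_id")
  }
  band <- nrf_band_for(pt, refs)
  eer <- band$eer_kcal
  energy <- intakes$energy_kcal
  ok <- energy > 0
  if (any(!ok)) {
    rlang::inform(paste0(sum(!ok), " zero-energy stratum row(s); ",
                         "NRF9.3 reported as missing"))
  }
  norm <- function(col) ifelse(ok, intakes[[col]] / energy * eer, NA_real_)
  qual <- vapply(nrf_qualifying(), function(nu) {
    pmin(100 * norm(nu) / band[[nu]], 100)
  }, numeric(nrow(intakes)))
  if (is.null(dim(qual))) {
    qual <- matrix(qual, nrow = nrow(intakes),
                   dimnames = list(NULL, nrf_qualifying()))
  }
  dv_sugar <- refs$added_sugar_pct_energy / 100 * eer / 4
  dv_sfa <- refs$sfa_pct_energy / 100 * eer / 9
  disq <- cbind(
    added_sugar_g = 100 * norm("added_sugar_g") / dv_sugar,
    sfa_g = 100 * norm("sfa_g") / dv_sfa,
    sodium_mg = 100 * norm("sodium_mg") / band$sodium_mg
  )
  ids <- intersect(c("participant_id", "stratum"), names(intakes))
  out <- intakes[ids]
  colnames(qual) <- paste0("nrf_", sub("_g$|_mg$|_ug.*$", "",
                                       colnames(qual)))
  colnames(disq) <- paste0("nrf_", c("added_sugar", "sfa", "sodium"))
  out <- bind_cols(out, as_tibble(qual), as_tibble(disq))
  out$nrf_total <- rowSums(qual) - rowSums(disq)
  out
}

#' Score a population on both diet-quality indices
#'
#' Convenience wrapper: runs [hei_score()] and [nrf_score()] over an
#' intake table and returns the totals side by side.
#'
#' @inheritParams nrf_score
#' @param standards HEI standards table.
#' @return Tibble: `participant_id`, `stratum`, `hei_total`, `nrf_total`.
#' @export
score_population <- function(intakes, participants,
                             standards = hei_standards(),
                             refs = nrf_reference_values()) {
  hei <- hei_score(intakes, standards)
  nrf <- nrf_score(intakes, participants, refs)
  hei %>%
    select(all_of(c("participant_id", "stratum", "hei_total"))) %>%
    left_join(nrf %>%
                select(all_of(c("participant_id", "stratum", "nrf_total"))),
              by = c("participant_id", "stratum"))
}
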