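# End-to-end orchestration: generate (or read) records, classify,
# aggregate, score, screen, and render the report tables as CSVs plus a
# machine-readable JSON summary. Deterministic given the seed.

#' Pipeline configuration
#'
#' Either a generator configuration (synthetic mode) or paths to records
#' and participants CSVs. The composition table, HEI standards and NRF
#' reference files default to the bundled ones.
#'
#' @param out_dir Output directory for tables, summary and log.
#' @param seed Integer seed (recorded in the summary).
#' @param generator A [generator_config()], or NULL when reading files.
#' @param records_path,participants_path Input CSVs (ignored in synthetic
#'   mode).
#' @param composition_path,standards_path,reference_path Optional
#'   overrides of the bundled configuration tables.
#' @param n_days Record days per participant (for file inputs).
#' @param stages Which stages to run after classification/aggregation:
#'   any of `"descriptives"`, `"comparisons"`, `"contributions"`,
#'   `"tertiles"`.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1,
                            generator = generator_config(),
                            records_path = NULL,
                            participants_path = NULL,
                            composition_path = NULL,
                            standards_path = NULL,
                            reference_path = NULL,
                            n_days = 4,
                            stages = c("descriptives", "comparisons",
                                       "contributions", "tertiles")) {
  if (is.null(generator) &&
      (is.null(records_path) || is.null(participants_path))) {
    abort("either a generator config or records/participants paths required")
  }
  for (pth in c(records_path, participants_path, composition_path,
                standards_path, reference_path)) {
    if (!is.null(pth) && !file.exists(pth)) {
      abort(paste0("input file does not exist: ", pth))
    }
  }
  structure(list(out_dir = out_dir, seed = seed, generator = generator,
                 records_path = records_path,
                 participants_path = participants_path,
                 composition_path = composition_path,
                 standards_path = standards_path,
                 reference_path = reference_path,
                 n_days = n_days, stages = stages),
            class = "pipeline_config")
}

#' Run the full meal-level analysis pipeline
#'
#' Executes generate (or read) -> classify -> aggregate -> score ->
#' screen -> describe/associate, writing the report tables
#' (`table1_...csv` ... `table6_...csv`, `supplemental_table1_...csv`),
#' a run log and a machine-readable `summary.json` to the configured
#' output directory. Any stage failure aborts with a stage-named error
#' and removes partially written outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory results (`participants`,
#'   `classification`, `intakes`, `scores`, `screening`, `tables`,
#'   `summary`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  log_lines <- character()
  note <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    log_lines <<- c(log_lines, msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(written)
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
  }

  composition <- stage("inputs", {
    if (is.null(config$composition_path)) default_composition_table()
    else read_composition(config$composition_path)
  })
  standards <- stage("inputs", hei_standards(config$standards_path))
  refs <- stage("inputs", nrf_reference_values(config$reference_path))

  dat <- stage("generate", {
    if (!is.null(config$generator)) {
      note("generating synthetic population, seed ", config$seed)
      pop <- generate_population(config$generator, composition,
                                 seed = config$seed)
      list(participants = pop$participants, records = pop$records,
           n_days = config$generator$n_days)
    } else {
      note("reading records from ", config$records_path)
      list(participants = read_participants(config$participants_path),
           records = read_records(config$records_path, composition),
           n_days = config$n_days)
    }
  })

  cls <- stage("classify", classify_records(dat$records, composition))
  note("classified ", nrow(cls$occasions), " occasions from ",
       nrow(cls$lines), " lines")
  intakes <- stage("aggregate",
                   aggregate_intakes(cls, composition,
                                     participants = dat$participants,
                                     n_days = dat$n_days))
  scores <- stage("score", suppressMessages(
    score_population(intakes, dat$participants, standards, refs)))
  screening <- stage("screen",
                     screen_misreporting(dat$participants, intakes))
  note("reporting status: ",
       paste(names(table(screening$reporting_status)),
             table(screening$reporting_status), collapse = ", "))

  tables <- list()
  descr <- meal_descriptives(cls$occasions, n_days = dat$n_days)
  tables$supplemental_table1 <- supplemental_frequency_table(
    descr, dat$participants, dat$n_days)

  if ("descriptives" %in% config$stages) {
    tables$table1 <- stage("describe", describe_scores(scores))
  }
  if ("comparisons" %in% config$stages) {
    tables$table2 <- stage("compare",
                           group_comparison_table(scores, screening,
                                                  dat$participants))
  }
  if ("contributions" %in% config$stages) {
    tables$table3 <- stage("contributions", nutrient_table(intakes))
    tables$table4 <- stage("contributions", food_table(intakes))
  }
  if ("tertiles" %in% config$stages) {
    tert_tabs <- stage("tertiles",
                       tertile_tables(intakes, scores, screening,
                                      dat$participants))
    tables$table5 <- tert_tabs$nutrients
    tables$table6 <- tert_tabs$foods
  }

  file_names <- c(table1 = "table1_score_descriptives.csv",
                  table2 = "table2_group_comparisons.csv",
                  table3 = "table3_nutrient_contributions.csv",
                  table4 = "table4_food_contributions.csv",
                  table5 = "table5_tertile_nutrients.csv",
                  table6 = "table6_tertile_foods.csv",
                  supplemental_table1 =
                    "supplemental_table1_meal_frequencies.csv")
  stage("write", {
    for (nm in names(tables)) {
      pth <- file.path(config$out_dir, file_names[[nm]])
      readr::write_csv(tables[[nm]], pth, progress = FALSE)
      written <- c(written, pth)
    }
  })

  contrib <- percent_contribution(intakes, variables = "energy_kcal")
  summary <- list(
    seed = config$seed,
    n_participants = nrow(dat$participants),
    n_days = dat$n_days,
    n_occasions = nrow(cls$occasions),
    energy_contribution_pct = as.list(round(
      unlist(contrib[1, meal_types()]), 4)),
    snack_frequency_mean = round(descr$snack_mean, 4),
    mean_hei_total = round(mean(scores$hei_total[
      scores$stratum == "total"], na.rm = TRUE), 4),
    mean_nrf_total = round(mean(scores$nrf_total[
      scores$stratum == "total"], na.rm = TRUE), 4),
    reporting_status = as.list(table(screening$reporting_status)),
    package_version = as.character(utils::packageVersion("mealquality")),
    r_version = paste(R.version$major, R.version$minor, sep = ".")
  )
  stage("write", {
    jsonlite::write_json(summary,
                         file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))
  })
  invisible(list(participants = dat$participants, classification = cls,
                 intakes = intakes, scores = scores,
                 screening = screening, tables = tables,
                 summary = summary))
}

# ---- table builders --------------------------------------------------------

supplemental_frequency_table <- function(descr, participants, n_days) {
  cons <- descr$meal_consumption %>%
    tidyr::pivot_wider(names_from = "label",
                       values_from = "days_consumed", values_fill = 0L)
  for (m in main_meals()) if (!m %in% names(cons)) cons[[m]] <- 0L
  all_ids <- tibble(participant_id = participants$participant_id)
  cons <- all_ids %>%
    left_join(cons, by = "participant_id") %>%
    mutate(across(all_of(main_meals()), ~ tidyr::replace_na(.x, 0L)))
  freq <- purrr::map_dfr(main_meals(), function(m) {
    tibble(meal = m,
           days = 0:n_days,
           n = vapply(0:n_days, function(k) sum(cons[[m]] == k),
                      integer(1))) %>%
      mutate(pct = 100 * n / nrow(cons))
  })
  snack_days <- descr$snack_frequency %>%
    group_by(.data$participant_id) %>%
    summarise(days_with_snack = sum(.data$n_snacks > 0), .groups = "drop")
  snack_days <- all_ids %>%
    left_join(snack_days, by = "participant_id") %>%
    mutate(days_with_snack = tidyr::replace_na(.data$days_with_snack, 0L))
  snack_freq <- tibble(meal = "snack", days = 0:n_days,
                       n = vapply(0:n_days, function(k) {
                         sum(snack_days$days_with_snack == k)
                       }, integer(1))) %>%
    mutate(pct = 100 * n / nrow(snack_days))
  bind_rows(freq, snack_freq)
}

group_comparison_table <- function(scores, screening, participants) {
  covars <- participants %>%
    select(all_of(c("participant_id", "sex", "survey_year", "age"))) %>%
    mutate(age_band = age_band(.data$age)) %>%
    left_join(screening %>%
                select(all_of(c("participant_id", "weight_status",
                                "reporting_status"))),
              by = "participant_id")
  dat <- scores %>% left_join(covars, by = "participant_id")
  groupings <- c("sex", "survey_year", "age_band", "weight_status",
                 "reporting_status")
  out <- list()
  for (idx in c("hei_total", "nrf_total")) {
    for (st in meal_types(with_total = TRUE)) {
      sub <- dat %>% filter(.data$stratum == st, !is.na(.data[[idx]]))
      for (gv in groupings) {
        cmp <- suppressWarnings(compare_groups(sub, idx, gv))
        if (is.null(cmp)) next
        g <- cmp$groups
        if (!"letter" %in% names(g)) g$letter <- ""
        out[[length(out) + 1]] <- g %>%
          mutate(index = idx, stratum = st, grouping = gv,
                 method = cmp$method, overall_p = cmp$p_value,
                 .before = 1)
      }
    }
  }
  bind_rows(out)
}

nutrient_table <- function(intakes) {
  stats_tab <- intakes %>%
    group_by(.data$stratum) %>%
    summarise(across(all_of(nutrient_names()),
                     list(mean = mean, sd = sd)), .groups = "drop") %>%
    tidyr::pivot_longer(-all_of("stratum"),
                        names_to = c("variable", ".value"),
                        names_pattern = "(.*)_(mean|sd)$")
  contrib <- percent_contribution(intakes,
                                  variables = nutrient_names()) %>%
    tidyr::pivot_longer(all_of(meal_types()), names_to = "stratum",
                        values_to = "pct_contribution")
  stats_tab %>%
    mutate(stratum = as.character(.data$stratum)) %>%
    left_join(contrib %>%
                select(all_of(c("variable", "stratum",
                                "pct_contribution"))),
              by = c("variable", "stratum"))
}

food_table <- function(intakes) {
  summ <- food_group_summary(intakes)
  contrib <- percent_contribution(intakes,
                                  variables = group_col(food_groups())) %>%
    mutate(food_group = food_groups()[match(.data$variable,
                                            group_col(food_groups()))]) %>%
    tidyr::pivot_longer(all_of(meal_types()), names_to = "stratum",
                        values_to = "pct_contribution")
  summ %>%
    mutate(stratum = as.character(.data$stratum)) %>%
    left_join(contrib %>%
                select(all_of(c("food_group", "stratum",
                                "pct_contribution"))),
              by = c("food_group", "stratum"))
}

tertile_tables <- function(intakes, scores, screening, participants) {
  total_scores <- scores %>%
    filter(.data$stratum == "total", !is.na(.data$hei_total))
  tert <- assign_tertiles(total_scores, "hei_total")
  covars <- participants %>%
    select(all_of(c("participant_id", "sex", "survey_year", "age"))) %>%
    mutate(age_band = age_band(.data$age)) %>%
    left_join(screening %>%
                select(all_of(c("participant_id", "weight_status",
                                "reporting_status"))),
              by = "participant_id") %>%
    left_join(tert %>% select(all_of(c("participant_id", "tertile"))),
              by = "participant_id")
  covariate_set <- c("sex", "age_band", "weight_status",
                     "reporting_status", "survey_year")
  run_rows <- function(vars, var_labels) {
    out <- list()
    for (st in main_meals()) {
      sub <- intakes %>%
        filter(.data$stratum == st) %>%
        left_join(covars, by = "participant_id") %>%
        filter(!is.na(.data$tertile))
      for (i in seq_along(vars)) {
        fit <- suppressWarnings(tertile_glm(sub, vars[i], covariate_set))
        m <- setNames(fit$means$adjusted_mean, fit$means$tertile)
        out[[length(out) + 1]] <- tibble(
          stratum = st, variable = var_labels[i],
          T1 = m[["T1"]], T2 = m[["T2"]], T3 = m[["T3"]],
          trend_p = fit$trend_p)
      }
    }
    bind_rows(out)
  }
  list(nutrients = run_rows(nutrient_names(), nutrient_names()),
       foods = run_rows(group_col(food_groups()), food_groups()))
}
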