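# Eating-occasion classification. Diary lines are grouped into candidate
# occasions keyed by (participant, day, section, start time) — an eating
# occasion is a separate intake event with its own start clock time and
# diary name. The pipeline is:
#   1. drop occasions consisting solely of plain water;
#   2. within each main-meal diary section, keep the earliest entry as the
#      meal and relabel later entries as snacks;
#   3. merge occasions with overlapping time intervals (transitively), a
#      merged meal+snack keeping the meal label unless the same main meal
#      already occurred earlier that day, in which case it becomes a snack.
# The result satisfies: at most one breakfast, one lunch and one dinner per
# participant-day, and every retained line belongs to exactly one occasion.

#' Group diary lines into candidate eating occasions
#'
#' Assigns an `occasion_id` keyed by (participant, day, diary section,
#' start time); lines sharing all four are one occasion (duplicate keys are
#' deliberately collapsed — the occasion definition keys on start time and
#' name). Adds the line's row number as `line_id` if absent.
#'
#' @param lines Diary-line tibble (see [read_records()]).
#' @return `lines` with `line_id` and `occasion_id` columns.
#' @export
candidate_occasions <- function(lines) {
  if (!"line_id" %in% names(lines)) lines$line_id <- seq_len(nrow(lines))
  if (!"next_day" %in% names(lines)) lines$next_day <- FALSE
  lines %>%
    mutate(occasion_id = paste(.data$participant_id, .data$day_index,
                               .data$section, .data$start_time, sep = "|"))
}

#' Drop water-only eating occasions
#'
#' Removes candidate occasions in which every member food is plain tap or
#' mineral water (`is_water_only` in the composition table). Occasions
#' containing water plus any other item are retained whole.
#'
#' @param lines Diary-line tibble.
#' @param composition Composition table with an `is_water_only` column.
#' @return The retained diary lines (with `occasion_id` assigned).
#' @export
drop_water_only <- function(lines, composition) {
  lines <- candidate_occasions(lines)
  if (nrow(lines) == 0) return(lines)
  water <- composition$food_code[composition$is_water_only]
  keep <- lines %>%
    group_by(.data$occasion_id) %>%
    summarise(all_water = all(.data$food_code %in% water)) %>%
    filter(!.data$all_water)
  lines %>% filter(.data$occasion_id %in% keep$occasion_id)
}

# Build the occasion-level table from grouped lines. `label` starts as the
# diary section; `end_eff` is the end minute with +1440 for occasions that
# finish after midnight, so interval logic stays within one record day.
occasion_table <- function(lines) {
  lines %>%
    group_by(.data$participant_id, .data$day_index, .data$occasion_id) %>%
    summarise(section = first(.data$section),
              label = first(.data$section),
              start_time = first(.data$start_time),
              end_time = max(.data$end_time +
                               ifelse(.data$next_day, 1440L, 0L)),
              order = min(.data$line_id),
              n_lines = dplyr::n(),
              .groups = "drop") %>%
    mutate(merged_from = .data$section) %>%
    arrange(.data$participant_id, .data$day_index, .data$start_time,
            .data$order)
}

#' Resolve multiple entries within one main-meal diary section
#'
#' When a participant records more than one eating occasion (with different
#' times) in a breakfast, lunch or dinner section of the same day, the
#' first occasion keeps the main-meal label and every subsequent occasion
#' is relabelled a snack. Ties on start time are broken by input order
#' (first recorded wins).
#'
#' @param occasions Occasion table (see [candidate_occasions()] /
#'   [classify_day()]).
#' @return The occasion table with updated `label`s.
#' @export
resolve_multiple_entries <- function(occasions) {
  occasions %>%
    group_by(.data$participant_id, .data$day_index, .data$section) %>%
    arrange(.data$start_time, .data$order, .by_group = TRUE) %>%
    mutate(label = ifelse(.data$section %in% main_meals() &
                            row_number() > 1, "snack", .data$label)) %>%
    ungroup() %>%
    arrange(.data$participant_id, .data$day_index, .data$start_time,
            .data$order)
}

# overlap on half-open minute intervals [start, end): a touch at a single
# boundary minute does not merge
intervals_overlap <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1

# union-find style transitive grouping of overlapping intervals within one
# participant-day; intervals sorted by start, a group extends while the
# next start is strictly inside the running max end
overlap_groups <- function(start, end) {
  ord <- order(start, end)
  grp <- integer(length(start))
  g <- 0L
  run_end <- -Inf
  for (i in ord) {
    if (start[i] < run_end) {
      grp[i] <- g
    } else {
      g <- g + 1L
      grp[i] <- g
    }
    run_end <- max(run_end, end[i])
  }
  grp
}

#' Merge eating occasions recorded within overlapping time periods
#'
#' Occasions of one participant-day whose time intervals overlap (touching
#' endpoints do not count) are combined — transitively — into a single
#' occasion spanning the earliest start to the latest end. Label of the
#' merged occasion: a meal+snack set keeps the main-meal label unless that
#' same main meal already occurred earlier in the day (then it is a snack);
#' if two different main meals overlap — a case the diary design does not
#' anticipate — the earlier-starting label wins and the event is reported;
#' all-snack sets stay snacks.
#'
#' @param occasions Occasion table, labels already section-resolved.
#' @return The merged occasion table.
#' @export
merge_overlaps <- function(occasions) {
  occ <- occasions %>%
    arrange(.data$participant_id, .data$day_index, .data$start_time,
            .data$order)
  if (!"member_ids" %in% names(occ)) {
    occ$member_ids <- as.list(occ$occasion_id)
  }
  n <- nrow(occ)
  if (n == 0) return(occ)
  # vectorizable sweep: rows are start-sorted within participant-day, so a
  # row opens a new overlap group unless it starts inside the running
  # maximum end of the current group
  day_key <- paste(occ$participant_id, occ$day_index, sep = "\r")
  new_day <- !duplicated(day_key)
  grp <- integer(n)
  gid <- 0L
  run_end <- -Inf
  for (i in seq_len(n)) {
    if (new_day[i] || occ$start_time[i] >= run_end) {
      gid <- gid + 1L
      run_end <- occ$end_time[i]
    } else {
      run_end <- max(run_end, occ$end_time[i])
    }
    grp[i] <- gid
  }
  # only days that actually contain a multi-occasion group need the full
  # merge-and-relabel treatment; all other days pass through untouched
  slow_idx <- day_key %in% unique(day_key[tabulate(grp)[grp] > 1L])
  out <- occ[!slow_idx, ]
  if (any(slow_idx)) {
    slow_days <- split(occ[slow_idx, ],
                       factor(day_key[slow_idx],
                              levels = unique(day_key[slow_idx])))
    out <- bind_rows(out, bind_rows(lapply(slow_days, merge_overlaps_day)))
  }
  out %>% arrange(.data$participant_id, .data$day_index, .data$start_time,
                  .data$order)
}

merge_overlaps_day <- function(day_occ) {
  day_occ$.grp <- overlap_groups(day_occ$start_time, day_occ$end_time)
  groups <- split(day_occ, day_occ$.grp)
  groups <- groups[order(vapply(groups, function(g) min(g$start_time),
                                numeric(1)))]
  out <- vector("list", length(groups))
  finalized_mains <- character(0)   # main-meal labels already placed earlier
  for (k in seq_along(groups)) {
    g <- groups[[k]] %>% arrange(.data$start_time, .data$order)
    mains <- unique(g$label[g$label %in% main_meals()])
    if (length(mains) > 1) {
      lab <- g$label[g$label %in% main_meals()][1]
      rlang::inform(paste0("overlap of two different main meals (",
                           paste(mains, collapse = ", "), ") for ",
                           g$occasion_id[1], "; keeping '", lab, "'"))
    } else if (length(mains) == 1) {
      lab <- if (mains %in% finalized_mains) "snack" else mains
    } else {
      lab <- "snack"
    }
    out[[k]] <- tibble(
      participant_id = g$participant_id[1],
      day_index = g$day_index[1],
      occasion_id = g$occasion_id[1],
      section = g$section[1],
      label = lab,
      start_time = min(g$start_time),
      end_time = max(g$end_time),
      order = min(g$order),
      n_lines = sum(g$n_lines),
      merged_from = paste(g$merged_from, collapse = "+"),
      member_ids = list(unlist(g$member_ids))
    )
    if (lab %in% main_meals()) finalized_mains <- c(finalized_mains, lab)
  }
  bind_rows(out)
}

#' Classify the diary lines of one participant-day (or a whole population)
#'
#' Runs the full pipeline: water-only exclusion, candidate-occasion
#' grouping, multiple-entry resolution, overlap merging. The output
#' guarantees at most one breakfast, one lunch and one dinner per
#' participant-day.
#'
#' @param lines Diary-line tibble (any number of participants and days).
#' @param composition Composition table.
#' @return A list of class `meal_classification` with elements
#'   `occasions` (one row per final eating occasion: `participant_id`,
#'   `day_index`, `label`, `start_time`, `end_time`, `merged_from`,
#'   `n_lines`) and `lines` (every retained diary line annotated with the
#'   `occasion_id` and final `label` of the occasion it belongs to).
#' @export
classify_day <- function(lines, composition) {
  kept <- drop_water_only(lines, composition)
  if (nrow(kept) == 0) {
    occ <- tibble(participant_id = character(), day_index = integer(),
                  occasion_id = character(), label = character(),
                  start_time = integer(), end_time = integer(),
                  merged_from = character(), n_lines = integer())
    return(structure(list(occasions = occ,
                          lines = kept %>% mutate(label = character(0))),
                     class = "meal_classification"))
  }
  occ <- occasion_table(kept)
  occ <- resolve_multiple_entries(occ)
  occ <- merge_overlaps(occ)
  # map each retained line to its merged occasion
  membership <- occ %>%
    select(all_of(c("participant_id", "day_index", "occasion_id",
                    "member_ids", "label"))) %>%
    tidyr::unnest(cols = "member_ids") %>%
    rename(source_occasion = "member_ids", merged_occasion = "occasion_id")
  lines_out <- kept %>%
    left_join(membership %>%
                select(all_of(c("source_occasion", "merged_occasion",
                                "label"))),
              by = c(occasion_id = "source_occasion")) %>%
    mutate(occasion_id = .data$merged_occasion) %>%
    select(-all_of("merged_occasion"))
  occ_out <- occ %>%
    select(all_of(c("participant_id", "day_index", "occasion_id", "label",
                    "start_time", "end_time", "merged_from", "n_lines")))
  main_counts <- occ_out %>%
    filter(.data$label %in% main_meals()) %>%
    dplyr::count(.data$participant_id, .data$day_index, .data$label)
  stopifnot(nrow(main_counts) == 0 || all(main_counts$n <= 1))
  structure(list(occasions = occ_out, lines = lines_out),
            class = "meal_classification")
}

#' @rdname classify_day
#' @export
classify_records <- function(lines, composition) classify_day(lines, composition)

#' @export
print.meal_classification <- function(x, ...) {
  cat("<meal_classification>\n")
  cat("  occasions:", nrow(x$occasions), "  lines:", nrow(x$lines), "\n")
  if (nrow(x$occasions)) {
    print(table(x$occasions$label))
  }
  invisible(x)
}

#' Descriptive statistics of classified eating occasions
#'
#' Summarises a classified population: mean and SD of the start clock time
#' of each main meal (across participant-day occasions), per-participant
#' counts of days on which each main meal was consumed, the distribution of
#' daily snack frequency, and daily total eating frequency.
#'
#' @param occasions Occasion table from [classify_records()].
#' @param n_days Number of record days per participant (default 4).
#' @return A list with tibbles `meal_times`, `meal_consumption`,
#'   `snack_frequency` and scalar summaries `snack_mean`, `snack_sd`,
#'   `eating_frequency_mean`.
#' @export
meal_descriptives <- function(occasions, n_days = 4) {
  meal_times <- occasions %>%
    filter(.data$label %in% main_meals()) %>%
    group_by(.data$label) %>%
    summarise(n = dplyr::n(),
              mean_start = mean(.data$start_time),
              sd_start = sd(.data$start_time),
              mean_clock = format_clock(mean(.data$start_time)),
              .groups = "drop")
  meal_consumption <- occasions %>%
    filter(.data$label %in% main_meals()) %>%
    distinct(.data$participant_id, .data$day_index, .data$label) %>%
    group_by(.data$participant_id, .data$label) %>%
    summarise(days_consumed = dplyr::n(), .groups = "drop")
  snacks_per_day <- occasions %>%
    group_by(.data$participant_id, .data$day_index) %>%
    summarise(n_snacks = sum(.data$label == "snack"),
              n_occasions = dplyr::n(), .groups = "drop")
  list(
    meal_times = meal_times,
    meal_consumption = meal_consumption,
    snack_frequency = snacks_per_day,
    snack_mean = mean(snacks_per_day$n_snacks),
    snack_sd = sd(snacks_per_day$n_snacks),
    eating_frequency_mean = mean(snacks_per_day$n_occasions)
  )
}
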