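# Synthetic 4-day weighed-record generator. The generator emulates the
# population structure a meal-level analysis needs: meal energy shares
# around 21/32/40/11 % of daily energy, main-meal start clock times around
# 07:28/12:32/19:25 with realistic spread, a 0-8 daily snack frequency with
# mean 1.8 and SD 1.3, rare meal skipping, and strong food-to-meal
# dependence (e.g. confectioneries predominantly at snacks). Within-meal
# food-group sampling weights are solved from the target contribution
# matrix and meal energy shares so that the post-classification
# contribution decomposition converges to the configured targets.

default_allocation_matrix <- function() {
  m <- rbind(
    rice                        = c(0.19, 0.40, 0.40, 0.01),
    bread                       = c(0.71, 0.15, 0.06, 0.08),
    noodles                     = c(0.05, 0.58, 0.30, 0.07),
    potatoes                    = c(0.10, 0.25, 0.60, 0.05),
    `pulses (incl. nuts)`       = c(0.15, 0.20, 0.60, 0.05),
    total_vegetables            = c(0.14, 0.31, 0.53, 0.02),
    fruit                       = c(0.29, 0.29, 0.25, 0.17),
    `fish (incl. shellfish)`    = c(0.08, 0.25, 0.65, 0.02),
    meat                        = c(0.05, 0.28, 0.65, 0.02),
    eggs                        = c(0.33, 0.30, 0.35, 0.02),
    dairy                       = c(0.50, 0.15, 0.10, 0.25),
    confectioneries             = c(0.02, 0.10, 0.09, 0.79),
    sugar_sweetened_beverages   = c(0.10, 0.20, 0.18, 0.52),
    alcoholic_beverages         = c(0.04, 0.16, 0.70, 0.10),
    non_energetic_beverages     = c(0.25, 0.28, 0.22, 0.25)
  )
  colnames(m) <- meal_types()
  m
}

# plausible share of daily energy supplied by each energetic food group;
# starting point for the constrained solve in group_sampling_weights()
default_group_energy_shares <- function() {
  c(rice = 0.30, bread = 0.06, noodles = 0.07, potatoes = 0.02,
    `pulses (incl. nuts)` = 0.05, total_vegetables = 0.03, fruit = 0.04,
    `fish (incl. shellfish)` = 0.08, meat = 0.12, eggs = 0.04,
    dairy = 0.05, confectioneries = 0.08,
    sugar_sweetened_beverages = 0.02, alcoholic_beverages = 0.04)
}

#' Configuration of the synthetic-record generator
#'
#' Every default is a study-condition parameter: meal energy shares
#' proportional to 21/32/40/11 % of daily energy (normalized to sum to
#' one — a per-capita contribution decomposition sums to exactly 100 %
#' while independently rounded descriptive targets need not),
#' breakfast/lunch/dinner start times
#' 07:28/12:32/19:25 (SD 46/32/56 min), a beta-binomial snack count on
#' 0-8 with mean 1.8 and SD 1.3, skip probabilities calibrated so roughly
#' 88/92/97 % of participants consume breakfast/lunch/dinner on all four
#' days, and a 15-food-group x 4-meal-type allocation matrix (rows sum to
#' one) giving the target share of each group's intake eaten at each meal
#' type. Anomaly rates inject double-entry and overlapping occasions at
#' the relative frequency a 639-participant, 4-day diary produces (about
#' 10 and 243 cases respectively), to exercise the classifier rules.
#'
#' @param n_participants Number of participants (default 639).
#' @param n_days Record days per participant (default 4).
#' @param seed Default seed used by [generate_population()].
#' @param prop_female Proportion of women (default 0.5).
#' @param age_range Integer age bounds, inclusive (default 20-81).
#' @param survey_year_probs Named probabilities of survey-year labels.
#' @param meal_energy_share_means Length-4 shares (breakfast, lunch,
#'   dinner, snack) summing to 1.
#' @param share_concentration Dirichlet concentration of the per-day share
#'   draw; the default (36) gives a between-person SD of about 8
#'   percentage points on the dinner share.
#' @param meal_start_means,meal_start_sds Main-meal start-time normal
#'   parameters, minutes since midnight.
#' @param occasion_duration_range Uniform bounds (minutes) of occasion
#'   durations.
#' @param snack_count `list(size, mean, sd)` of the beta-binomial daily
#'   snack count.
#' @param skip_probabilities Per-day probability that each main meal is
#'   skipped.
#' @param food_allocation_matrix 15 x 4 matrix, rows = [food_groups()],
#'   columns = meal types, rows summing to 1.
#' @param daily_energy Per-sex `c(mean, sd)` of mean daily energy (kcal).
#' @param double_entry_rate,overlap_rate Per participant-day probability
#'   of a duplicated main-meal-section entry / an occasion overlapping a
#'   main meal.
#' @param group_energy_shares Starting values for the share of daily
#'   energy supplied by each energetic food group (solved to be consistent
#'   with the allocation matrix and meal shares).
#' @param drink_propensity Scaling of the probability that an occasion
#'   includes a non-energetic beverage line.
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(n_participants = 639,
                             n_days = 4,
                             seed = 1,
                             prop_female = 0.5,
                             age_range = c(20L, 81L),
                             survey_year_probs = c("2003" = 0.4,
                                                   "2013" = 0.6),
                             meal_energy_share_means =
                               c(breakfast = 0.21, lunch = 0.32,
                                 dinner = 0.40, snack = 0.11) / 1.04,
                             share_concentration = 36,
                             meal_start_means = c(breakfast = 448,
                                                  lunch = 752,
                                                  dinner = 1165),
                             meal_start_sds = c(breakfast = 46,
                                                lunch = 32,
                                                dinner = 56),
                             occasion_duration_range = c(10, 40),
                             snack_count = list(size = 8, mean = 1.8,
                                                sd = 1.3),
                             skip_probabilities = c(breakfast = 0.031,
                                                    lunch = 0.020,
                                                    dinner = 0.008),
                             food_allocation_matrix =
                               default_allocation_matrix(),
                             daily_energy = list(
                               male = c(mean = 2300, sd = 350),
                               female = c(mean = 1850, sd = 300)),
                             double_entry_rate = 0.004,
                             overlap_rate = 0.095,
                             group_energy_shares =
                               default_group_energy_shares(),
                             drink_propensity = 2.4) {
  cfg <- structure(
    list(n_participants = n_participants, n_days = n_days, seed = seed,
         prop_female = prop_female, age_range = age_range,
         survey_year_probs = survey_year_probs,
         meal_energy_share_means = meal_energy_share_means,
         share_concentration = share_concentration,
         meal_start_means = meal_start_means,
         meal_start_sds = meal_start_sds,
         occasion_duration_range = occasion_duration_range,
         snack_count = snack_count,
         skip_probabilities = skip_probabilities,
         food_allocation_matrix = food_allocation_matrix,
         daily_energy = daily_energy,
         double_entry_rate = double_entry_rate,
         overlap_rate = overlap_rate,
         group_energy_shares = group_energy_shares,
         drink_propensity = drink_propensity),
    class = "generator_config")
  validate_generator_config(cfg)
}

#' @export
print.generator_config <- function(x, ...) {
  cat("<generator_config>\n")
  cat("  n_participants:", x$n_participants, " n_days:", x$n_days,
      " seed:", x$seed, "\n")
  cat("  meal energy shares:",
      paste(sprintf("%s=%.2f", names(x$meal_energy_share_means),
                    x$meal_energy_share_means), collapse = " "), "\n")
  cat("  snack count: beta-binomial(", x$snack_count$size, "), mean ",
      x$snack_count$mean, ", sd ", x$snack_count$sd, "\n", sep = "")
  invisible(x)
}

validate_generator_config <- function(cfg) {
  if (abs(sum(cfg$meal_energy_share_means) - 1) > 1e-9) {
    abort("meal_energy_share_means must sum to 1")
  }
  m <- cfg$food_allocation_matrix
  if (!identical(rownames(m), food_groups()) ||
      !identical(colnames(m), meal_types())) {
    abort("food_allocation_matrix must have food_groups() rows and meal_types() columns")
  }
  if (any(abs(rowSums(m) - 1) > 1e-9)) {
    abort("food_allocation_matrix rows must sum to 1")
  }
  if (any(m < 0)) abort("food_allocation_matrix entries must be >= 0")
  if (any(cfg$meal_start_sds <= 0) || cfg$snack_count$sd < 0 ||
      cfg$snack_count$mean < 0) {
    abort("meal start SDs must be > 0 and snack-count moments >= 0")
  }
  if (any(cfg$skip_probabilities < 0 | cfg$skip_probabilities >= 1)) {
    abort("skip_probabilities must lie in [0, 1)")
  }
  if (cfg$n_participants < 1 || cfg$n_days < 1) {
    abort("n_participants and n_days must be >= 1")
  }
  cfg
}

# beta-binomial parameters matched to (mean, sd) on support 0..size;
# falls back to a plain binomial when the requested variance is not
# overdispersed relative to the binomial
bb_params <- function(size, mean, sd) {
  mu <- mean / size
  if (mu <= 0) return(list(size = size, mu = 0, s = Inf, p0 = 1))
  d <- sd^2 / (size * mu * (1 - mu))
  if (d <= 1) {
    p0 <- (1 - mu)^size
    return(list(size = size, mu = mu, s = Inf, p0 = p0))
  }
  s <- (size - d) / (d - 1)
  beta <- s * (1 - mu)
  k <- 0:(size - 1)
  p0 <- prod((beta + k) / (s + k))
  list(size = size, mu = mu, s = s, p0 = p0)
}

rsnack_count <- function(n, p) {
  if (is.infinite(p$s)) return(rbinom(n, p$size, p$mu))
  pr <- rbeta(n, p$s * p$mu, p$s * (1 - p$mu))
  rbinom(n, p$size, pr)
}

rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

# Solve for per-group daily energy shares r (energetic groups only) such
# that sum_g r_g * alloc[g, m] = meal share E_m for every meal type m;
# minimal-distance solution from the configured starting shares. With
# weights u[g, m] = r_g * alloc[g, m] the energy sampled into group g at
# meal m is proportional to alloc[g, m], so the realized contribution
# matrix converges to the configured one.
group_sampling_weights <- function(cfg, composition) {
  energetic <- setdiff(food_groups(), "non_energetic_beverages")
  C <- cfg$food_allocation_matrix[energetic, , drop = FALSE]
  E <- cfg$meal_energy_share_means
  r0 <- cfg$group_energy_shares[energetic]
  r0 <- r0 / sum(r0)
  # minimize ||r - r0|| subject to t(C) %*% r = E  (KKT, pseudo-inverse
  # because the four constraints carry one linear redundancy)
  rhs <- as.numeric(E - t(C) %*% r0)
  G <- t(C) %*% C
  sv <- svd(G)
  pos <- sv$d > max(sv$d) * 1e-10
  lambda <- sv$v[, pos, drop = FALSE] %*%
    ((t(sv$u[, pos, drop = FALSE]) %*% rhs) / sv$d[pos])
  r <- as.numeric(r0 + C %*% lambda)
  names(r) <- energetic
  if (any(r < 0)) {
    warn("group energy shares clipped at zero; contribution targets may drift")
    r <- pmax(r, 1e-4)
  }
  u <- sweep(C, 1, r, `*`)                      # u[g, m] = r_g * c_{g,m}
  sweep(u, 2, colSums(u), `/`)                  # per-column sampling probs
}

#' Generate a synthetic population of weighed dietary records
#'
#' Draws participants (sex, age, anthropometry via a BMI distribution,
#' survey year), then for each participant-day: which main meals are
#' consumed, the snack count, an energy partition over the consumed
#' occasions (Dirichlet centred on the configured meal shares), main-meal
#' start times, and food lines whose amounts are back-solved so line
#' energies sum exactly to each occasion's energy target. Anomaly days
#' inject a second entry into a main-meal diary section or an occasion
#' overlapping a main meal, to exercise the classifier. Deterministic
#' given the seed.
#'
#' @param config A [generator_config()].
#' @param composition Composition table (default: bundled table).
#' @param seed Integer seed (default `config$seed`).
#' @return A list of class `synthetic_population`: `participants`,
#'   `records` (diary-line tibble as read by [read_records()]),
#'   `day_targets` (the drawn daily energy per participant-day) and
#'   `config`.
#' @export
generate_population <- function(config = generator_config(),
                                composition = default_composition_table(),
                                seed = config$seed) {
  cfg <- validate_generator_config(config)
  set.seed(seed)
  participants <- generate_participants(cfg)
  weights <- group_sampling_weights(cfg, composition)
  snack_p <- bb_params(cfg$snack_count$size, cfg$snack_count$mean,
                       cfg$snack_count$sd)
  # per-occasion probability of adding a non-energetic beverage line,
  # shaped by the beverage row of the allocation matrix
  bev_row <- cfg$food_allocation_matrix["non_energetic_beverages", ]
  occ_rate <- c(1, 1, 1, max(cfg$snack_count$mean, 0.5))
  bev_p <- pmin(cfg$drink_propensity * bev_row / occ_rate, 0.9)
  foods_by_group <- split(
    composition[!composition$is_water_only,
                c("food_code", "food_group", "energy_kcal")],
    composition$food_group[!composition$is_water_only])

  n_total_days <- nrow(participants) * cfg$n_days
  day_chunks <- vector("list", n_total_days)
  target_energy <- numeric(n_total_days)
  chunk <- 0L
  for (i in seq_len(nrow(participants))) {
    p <- participants[i, ]
    en <- cfg$daily_energy[[p$sex]]
    base_energy <- max(rnorm(1, en[["mean"]], en[["sd"]]), 800)
    for (d in seq_len(cfg$n_days)) {
      chunk <- chunk + 1L
      day_energy <- base_energy * exp(rnorm(1, 0, 0.05))
      target_energy[chunk] <- day_energy
      day_chunks[[chunk]] <- generate_day(p$participant_id, d, day_energy,
                                          cfg, weights, snack_p, bev_p,
                                          foods_by_group)
    }
  }
  pull_col <- function(nm) unlist(lapply(day_chunks, `[[`, nm),
                                  use.names = FALSE)
  records <- tibble(
    participant_id = pull_col("participant_id"),
    day_index = pull_col("day_index"),
    section = pull_col("section"),
    start_time = as.integer(pull_col("start_time")),
    end_time = as.integer(pull_col("end_time")),
    next_day = FALSE,
    food_code = pull_col("food_code"),
    amount = pull_col("amount")
  )
  records$line_id <- seq_len(nrow(records))
  day_targets <- tibble(
    participant_id = rep(participants$participant_id,
                         each = cfg$n_days),
    day_index = rep(seq_len(cfg$n_days), nrow(participants)),
    target_energy_kcal = target_energy
  )
  structure(list(participants = participants,
                 records = records,
                 day_targets = day_targets,
                 config = cfg),
            class = "synthetic_population")
}

#' @export
print.synthetic_population <- function(x, ...) {
  cat("<synthetic_population>\n")
  cat("  participants:", nrow(x$participants),
      " diary lines:", nrow(x$records),
      " days/participant:", x$config$n_days, "\n")
  invisible(x)
}

generate_participants <- function(cfg) {
  n <- cfg$n_participants
  sex <- ifelse(runif(n) < cfg$prop_female, "female", "male")
  age <- sample(seq(cfg$age_range[1], cfg$age_range[2]), n, replace = TRUE)
  height <- ifelse(sex == "male",
                   rnorm(n, 170, 6), rnorm(n, 157, 5.5))
  height <- pmin(pmax(height, 140), 200)
  bmi <- pmin(pmax(rnorm(n, 23.1, 3.4), 15), 40)
  weight <- round(bmi * (height / 100)^2, 1)
  tibble(participant_id = sprintf("P%04d", seq_len(n)),
         sex = sex, age = as.integer(age),
         height_cm = round(height, 1), weight_kg = weight,
         survey_year = sample(names(cfg$survey_year_probs), n,
                              replace = TRUE,
                              prob = cfg$survey_year_probs))
}

# one participant-day of diary lines
generate_day <- function(pid, day, day_energy, cfg, weights, snack_p,
                         bev_p, foods_by_group) {
  mains <- main_meals()
  consumed <- mains[runif(3) >= cfg$skip_probabilities]
  n_snacks <- rsnack_count(1, snack_p)
  double_entry <- runif(1) < cfg$double_entry_rate && length(consumed) > 0
  overlap <- runif(1) < cfg$overlap_rate && length(consumed) > 0

  # energy partition: Dirichlet over consumed strata, snack mass split
  # across snack-type occasions (regular snacks + a double-entry extra);
  # the conditional snack share is inflated by 1/(1 - P(no snacks)) so
  # that the population mean share matches the configured target despite
  # zero-snack days
  n_snack_units <- n_snacks + as.integer(double_entry)
  strata <- c(consumed, if (n_snack_units > 0) "snack")
  eff_shares <- cfg$meal_energy_share_means
  eff_shares[["snack"]] <- min(eff_shares[["snack"]] / (1 - snack_p$p0),
                               0.5)
  alpha <- cfg$share_concentration * eff_shares[strata]
  shares <- rdirichlet1(as.numeric(alpha))
  names(shares) <- strata
  meal_energy <- day_energy * shares[consumed]
  snack_energies <- numeric(0)
  if (n_snack_units > 0) {
    snack_total <- day_energy * shares[["snack"]]
    snack_energies <- snack_total * rdirichlet1(rep(2, n_snack_units))
  }

  dur <- function(n = 1) {
    round(runif(n, cfg$occasion_duration_range[1],
                cfg$occasion_duration_range[2]))
  }
  occ <- list()
  intervals <- matrix(numeric(0), ncol = 2)
  add_interval <- function(s, e) rbind(intervals, c(s, e))
  for (m in consumed) {
    s <- round(rnorm(1, cfg$meal_start_means[[m]], cfg$meal_start_sds[[m]]))
    s <- min(max(s, 240), 1400)
    e <- min(s + dur(), 1439)
    occ[[length(occ) + 1]] <- list(section = m, start = s, end = e,
                                   column = m, energy = meal_energy[[m]])
    intervals <- add_interval(s, e)
  }
  place_free <- function(duration) {
    for (try in 1:60) {
      s <- round(runif(1, 330, 1380 - duration))
      e <- s + duration
      if (nrow(intervals) == 0 ||
          !any(intervals_overlap(s, e, intervals[, 1], intervals[, 2]))) {
        return(c(s, e))
      }
    }
    c(1380 - duration, 1380)   # deterministic fallback, may overlap
  }
  snack_section_energies <- snack_energies
  if (double_entry) {
    # second occasion recorded in an already-consumed main-meal section;
    # classified downstream as a snack, so it draws snack-column foods
    host <- consumed[sample.int(length(consumed), 1)]
    d2 <- dur()
    se <- place_free(d2)
    occ[[length(occ) + 1]] <- list(section = host, start = se[1],
                                   end = se[2], column = "snack",
                                   energy = snack_section_energies[1])
    intervals <- add_interval(se[1], se[2])
    snack_section_energies <- snack_section_energies[-1]
  }
  for (k in seq_len(n_snacks)) {
    d2 <- round(runif(1, 10, 20))
    se <- place_free(d2)
    occ[[length(occ) + 1]] <- list(section = "snack", start = se[1],
                                   end = se[2], column = "snack",
                                   energy = snack_section_energies[k])
    intervals <- add_interval(se[1], se[2])
  }
  if (overlap) {
    # an occasion recorded as a snack but overlapping a main meal; the
    # classifier merges it into the meal, so it draws that meal's column
    # and its energy is carved out of the meal's share
    host_i <- which(vapply(occ, function(o) o$section %in% mains &&
                             o$column %in% mains, logical(1)))
    host_i <- host_i[sample.int(length(host_i), 1)]
    host <- occ[[host_i]]
    frac <- runif(1, 0.15, 0.3)
    carve <- host$energy * frac
    occ[[host_i]]$energy <- host$energy - carve
    s <- host$start + round(runif(1, 2, max(host$end - host$start - 2, 3)))
    e <- min(s + round(runif(1, 8, 15)), 1439)
    occ[[length(occ) + 1]] <- list(section = "snack", start = s, end = e,
                                   column = host$column, energy = carve)
  }

  lines <- lapply(occ, function(o) {
    occasion_lines(o, cfg, weights, bev_p, foods_by_group)
  })
  n_per <- vapply(lines, function(l) length(l$food_code), integer(1))
  list(
    participant_id = rep(pid, sum(n_per)),
    day_index = rep(day, sum(n_per)),
    section = rep(vapply(occ, `[[`, "", "section"), n_per),
    start_time = rep(vapply(occ, function(o) o$start, numeric(1)), n_per),
    end_time = rep(vapply(occ, function(o) o$end, numeric(1)), n_per),
    food_code = unlist(lapply(lines, `[[`, "food_code"),
                       use.names = FALSE),
    amount = unlist(lapply(lines, `[[`, "amount"), use.names = FALSE)
  )
}

# food lines of one occasion: k energetic lines splitting the energy
# target exactly, plus an optional fixed-gram non-energetic beverage;
# returns plain vectors (performance: ~15k occasions per default run)
occasion_lines <- function(o, cfg, weights, bev_p, foods_by_group) {
  col <- weights[, o$column]
  k <- if (o$column %in% main_meals() && o$section == o$column) {
    sample(3:5, 1)
  } else {
    sample(1:2, 1)
  }
  groups <- sample(names(col), k, replace = TRUE, prob = col)
  split_w <- rdirichlet1(rep(2, k))
  codes <- character(k)
  amounts <- numeric(k)
  for (j in seq_len(k)) {
    pool <- foods_by_group[[groups[j]]]
    pick <- sample.int(nrow(pool), 1)
    codes[j] <- pool$food_code[pick]
    amounts[j] <- o$energy * split_w[j] * 100 / pool$energy_kcal[pick]
  }
  if (runif(1) < bev_p[[if (o$section %in% main_meals()) o$section
                        else "snack"]]) {
    pool <- foods_by_group[["non_energetic_beverages"]]
    pick <- sample.int(nrow(pool), 1)
    codes <- c(codes, pool$food_code[pick])
    amounts <- c(amounts, round(runif(1, 100, 250), 1))
  }
  list(food_code = codes, amount = amounts)
}

#' Hand-worked classifier fixture
#'
#' A small, fully hand-written record set (six participant-days) covering
#' every classifier branch: a water-only occasion, a water-plus-food
#' occasion, a double-entry breakfast section, an overlapping meal+snack
#' with and without an earlier occurrence of the same meal, a
#' snack-on-snack overlap, and a triple-entry dinner section. The expected
#' final classification of every occasion is stored alongside.
#'
#' @return A list: `records` (diary lines), `participants`, and
#'   `expected` — one row per expected final eating occasion
#'   (`participant_id`, `day_index`, `label`, `start_time`, `n_lines`),
#'   with water-only occasions listed under label `"excluded"`.
#' @export
generate_worked_fixtures <- function() {
  ln <- function(pid, sec, s, e, code, amt) {
    tibble(participant_id = pid, day_index = 1L, section = sec,
           start_time = parse_clock(s), end_time = parse_clock(e),
           next_day = FALSE, food_code = code, amount = amt)
  }
  records <- bind_rows(
    # FX1: standard day plus a water-only snack occasion (excluded)
    ln("FX1", "breakfast", "07:00", "07:20", "R001", 150),
    ln("FX1", "breakfast", "07:00", "07:20", "E001", 50),
    ln("FX1", "snack", "10:00", "10:05", "W004", 200),
    ln("FX1", "lunch", "12:00", "12:20", "N001", 250),
    ln("FX1", "dinner", "19:00", "19:30", "R001", 150),
    ln("FX1", "dinner", "19:00", "19:30", "S001", 80),
    # FX2: two entries in the breakfast section -> (breakfast, snack)
    ln("FX2", "breakfast", "07:00", "07:15", "B001", 60),
    ln("FX2", "breakfast", "10:00", "10:10", "B001", 40),
    ln("FX2", "dinner", "19:30", "19:50", "M001", 120),
    # FX3: lunch overlapping a snack, no earlier lunch -> merged lunch
    ln("FX3", "lunch", "12:00", "12:30", "R001", 200),
    ln("FX3", "snack", "12:10", "12:20", "C001", 30),
    # FX4: second lunch-section entry overlapping a snack after a real
    # lunch -> relabelled snack, then merged with the snack
    ln("FX4", "lunch", "12:00", "12:20", "N001", 200),
    ln("FX4", "lunch", "15:00", "15:20", "R001", 100),
    ln("FX4", "snack", "15:05", "15:15", "C004", 20),
    # FX5: two overlapping snacks -> one merged snack
    ln("FX5", "snack", "10:00", "10:10", "Q001", 350),
    ln("FX5", "snack", "10:05", "10:15", "C001", 30),
    # FX6: triple-entry dinner section; water-plus-food occasion retained
    ln("FX6", "breakfast", "07:30", "07:40", "W004", 200),
    ln("FX6", "breakfast", "07:30", "07:40", "R001", 100),
    ln("FX6", "dinner", "18:00", "18:20", "R001", 150),
    ln("FX6", "dinner", "21:00", "21:10", "A001", 350),
    ln("FX6", "dinner", "23:00", "23:10", "C003", 20)
  )
  exp_row <- function(pid, label, s, n) {
    tibble(participant_id = pid, day_index = 1L, label = label,
           start_time = parse_clock(s), n_lines = n)
  }
  expected <- bind_rows(
    exp_row("FX1", "breakfast", "07:00", 2),
    exp_row("FX1", "excluded", "10:00", 1),
    exp_row("FX1", "lunch", "12:00", 1),
    exp_row("FX1", "dinner", "19:00", 2),
    exp_row("FX2", "breakfast", "07:00", 1),
    exp_row("FX2", "snack", "10:00", 1),
    exp_row("FX2", "dinner", "19:30", 1),
    exp_row("FX3", "lunch", "12:00", 2),
    exp_row("FX4", "lunch", "12:00", 1),
    exp_row("FX4", "snack", "15:00", 2),
    exp_row("FX5", "snack", "10:00", 2),
    exp_row("FX6", "breakfast", "07:30", 2),
    exp_row("FX6", "dinner", "18:00", 1),
    exp_row("FX6", "snack", "21:00", 1),
    exp_row("FX6", "snack", "23:00", 1)
  )
  participants <- tibble(
    participant_id = paste0("FX", 1:6),
    sex = rep(c("male", "female"), 3),
    age = c(35L, 42L, 28L, 55L, 63L, 47L),
    height_cm = c(172, 158, 168, 155, 176, 161),
    weight_kg = c(68, 52, 63, 50, 74, 55),
    survey_year = rep(c("2003", "2013"), 3)
  )
  list(records = records, participants = participants, expected = expected)
}
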