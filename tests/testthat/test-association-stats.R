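test_that("tertile assignment is balanced, ordered and order-invariant", {
  set.seed(91)
  scores <- tibble::tibble(participant_id = sprintf("P%03d", 1:100),
                           hei_total = rnorm(100, 50, 10))
  t1 <- assign_tertiles(scores)
  expect_true(max(table(t1$tertile)) - min(table(t1$tertile)) <= 2)
  summ <- tertile_summary(t1)
  expect_true(summ$median[1] < summ$median[2])
  expect_true(summ$median[2] < summ$median[3])
  expect_true(summ$max[1] <= summ$min[2])
  # permuting rows never changes any participant's tertile
  perm <- scores[sample.int(100), ]
  t2 <- assign_tertiles(perm)
  merged <- merge(t1, t2, by = "participant_id")
  expect_true(all(merged$tertile.x == merged$tertile.y))
})

test_that("score descriptives degenerate correctly", {
  scores <- tibble::tibble(participant_id = c("A", "B", "C"),
                           stratum = "total",
                           hei_total = c(50, 50, 50),
                           nrf_total = c(300, 300, 300))
  d <- describe_scores(scores)
  expect_equal(d$sd, c(0, 0))
  expect_equal(d$q25, d$median)
  expect_equal(d$median, d$q75)
  one <- describe_scores(scores[1, ])
  expect_equal(one$q25, one$q75)
  expect_equal(one$mean, one$median)
})

test_that("stratum correlations behave at the identity and under a null", {
  set.seed(101)
  n <- 300
  base <- tibble::tibble(participant_id = sprintf("P%03d", 1:n))
  # independent strata: correlations near zero; total = sum: positive
  strata_scores <- lapply(meal_types(), function(m) {
    dplyr::mutate(base, stratum = m, hei_total = rnorm(n, 50, 8))
  })
  wide <- dplyr::bind_rows(strata_scores)
  tot <- wide |>
    dplyr::group_by(participant_id) |>
    dplyr::summarise(hei_total = mean(hei_total)) |>
    dplyr::mutate(stratum = "total")
  m <- correlate_scores(dplyr::bind_rows(wide, tot))
  expect_equal(unname(diag(m)), rep(1, 5))
  off <- m[meal_types(), meal_types()]
  expect_true(all(abs(off[upper.tri(off)]) < 0.15))
  expect_true(all(m["total", meal_types()] > 0.3))
  # zero variance -> missing, not an error
  flat <- dplyr::bind_rows(
    dplyr::mutate(base[1:10, ], stratum = "breakfast", hei_total = 42),
    dplyr::mutate(base[1:10, ], stratum = "total",
                  hei_total = rnorm(10)))
  mf <- correlate_scores(flat)
  expect_true(is.na(mf["breakfast", "total"]))
})

test_that("two-level comparisons use the t test and detect identity", {
  dat <- tibble::tibble(score = c(rnorm(30, 50, 5)),
                        g = rep(c("a", "b"), each = 15))
  dup <- tibble::tibble(score = rep(dat$score[1:15], 2),
                        g = rep(c("a", "b"), each = 15))
  res <- compare_groups(dup, "score", "g")
  expect_equal(res$method, "t-test")
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1, tolerance = 1e-12)
})

test_that("multi-level comparisons gate the post hoc on the overall P", {
  set.seed(111)
  separated <- tibble::tibble(
    score = c(rnorm(50, 0), rnorm(50, 0), rnorm(50, 5)),
    g = rep(c("g1", "g2", "g3"), each = 50))
  res <- compare_groups(separated, "score", "g")
  expect_equal(res$method, "anova")
  expect_lt(res$p_value, 0.05)
  expect_false(is.null(res$posthoc))
  lt <- res$groups$letter[match(c("g1", "g2", "g3"), res$groups$group)]
  expect_equal(lt[1], lt[2])          # g1 and g2 share a letter
  expect_false(lt[3] %in% lt[1:2])    # g3 is separated
  null_dat <- tibble::tibble(score = rnorm(150),
                             g = rep(c("g1", "g2", "g3"), each = 50))
  res0 <- compare_groups(null_dat, "score", "g")
  if (res0$p_value >= 0.05) {
    expect_null(res0$posthoc)
    expect_false("letter" %in% names(res0$groups))
  }
  tiny <- tibble::tibble(score = c(1, 2, 3, 1, 2),
                         g = c("a", "a", "b", "b", "c"))
  expect_warning(res_tiny <- compare_groups(tiny, "score", "g"), "n < 2")
  expect_equal(res_tiny$method, "t-test")
})

test_that("adjusted means equal raw means in orthogonal designs", {
  set.seed(121)
  n <- 120
  dat <- tibble::tibble(
    outcome = rnorm(n, 100, 10),
    tertile = factor(rep(c("T1", "T2", "T3"), each = n / 3)),
    sex = rep(rep(c("male", "female"), each = n / 6), 3))
  # no covariates: exact equality
  fit0 <- tertile_glm(dat, "outcome")
  expect_equal(fit0$means$adjusted_mean, fit0$means$raw_mean,
               tolerance = 1e-10)
  # balanced (orthogonal) covariate: still exact
  fit1 <- tertile_glm(dat, "outcome", covariates = "sex")
  expect_equal(fit1$means$adjusted_mean, fit1$means$raw_mean,
               tolerance = 1e-10)
})

test_that("a planted tertile effect is recovered with its spacing", {
  set.seed(131)
  n <- 300
  tert <- rep(c("T1", "T2", "T3"), each = n / 3)
  dat <- tibble::tibble(
    outcome = 2 * as.numeric(factor(tert)) + rnorm(n, 0, 1),
    tertile = factor(tert),
    sex = sample(c("male", "female"), n, TRUE))
  fit <- tertile_glm(dat, "outcome", covariates = "sex")
  spacing <- diff(fit$means$adjusted_mean)
  expect_equal(spacing, c(2, 2), tolerance = 0.25)
  expect_lt(fit$trend_p, 1e-3)
  expect_equal(fit$trend_estimate, 2, tolerance = 0.25)
})

test_that("single-level covariates are dropped with a warning", {
  dat <- tibble::tibble(outcome = rnorm(60),
                        tertile = factor(rep(c("T1", "T2", "T3"), 20)),
                        yr = "2013")
  expect_warning(fit <- tertile_glm(dat, "outcome", covariates = "yr"),
                 "single observed level")
  expect_equal(fit$covariates, character(0))
})

test_that("age bands split at 40 and 60", {
  expect_equal(as.character(age_band(c(39, 40, 59, 60))),
               c("<40", "40-59", "40-59", ">=60"))
})
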