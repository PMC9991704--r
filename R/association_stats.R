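# Descriptive and inferential statistics: score descriptives, Pearson
# correlations between strata, two-group t tests / multi-group ANOVA with
# Bonferroni post hoc letters, and the tertile general-linear-model
# analysis with covariate-adjusted (population-marginal) means and an
# ordinal trend test.

#' Assign diet-quality tertiles
#'
#' Splits participants into three near-equal groups (sizes differing by at
#' most one... at most two for pathological tie runs) by ascending score.
#' Ties are broken by stable input order, so the assignment is a
#' deterministic, permutation-invariant function of the (score,
#' participant order) pairs.
#'
#' @param scores Tibble with `participant_id` and the score column.
#' @param score_col Name of the score column (e.g. `"hei_total"`).
#' @return Tibble: `participant_id`, score, `tertile` (ordered factor
#'   T1 < T2 < T3).
#' @export
assign_tertiles <- function(scores, score_col = "hei_total") {
  stop_if_missing_cols(scores, c("participant_id", score_col), "scores")
  n <- nrow(scores)
  ord <- order(scores[[score_col]])          # stable for ties
  sizes <- diff(floor(n * (0:3) / 3))
  tert <- integer(n)
  tert[ord] <- rep(1:3, times = sizes)
  out <- scores[c("participant_id", score_col)]
  out$tertile <- factor(paste0("T", tert), levels = c("T1", "T2", "T3"),
                        ordered = TRUE)
  out
}

#' Median and range of scores per tertile
#'
#' @param assignment Output of [assign_tertiles()].
#' @param score_col Score column name.
#' @return Tibble: `tertile`, `n`, `median`, `min`, `max`.
#' @export
tertile_summary <- function(assignment, score_col = "hei_total") {
  assignment %>%
    group_by(.data$tertile) %>%
    summarise(n = dplyr::n(),
              median = median(.data[[score_col]]),
              min = min(.data[[score_col]]),
              max = max(.data[[score_col]]), .groups = "drop")
}

#' Descriptive statistics of diet-quality scores
#'
#' Mean, SD and quartiles of each index per diet stratum, over
#' participants with a defined (non-missing) score.
#'
#' @param scores Tibble from [score_population()].
#' @param index_cols Score columns to summarise.
#' @return Tibble: `index`, `stratum`, `n`, `mean`, `sd`, `q25`, `median`,
#'   `q75`.
#' @export
describe_scores <- function(scores,
                            index_cols = c("hei_total", "nrf_total")) {
  scores %>%
    tidyr::pivot_longer(all_of(index_cols), names_to = "index",
                        values_to = "score") %>%
    filter(!is.na(.data$score)) %>%
    group_by(.data$index, .data$stratum) %>%
    summarise(n = dplyr::n(), mean = mean(.data$score),
              sd = sd(.data$score),
              q25 = unname(quantile(.data$score, 0.25)),
              median = median(.data$score),
              q75 = unname(quantile(.data$score, 0.75)),
              .groups = "drop")
}

#' Pearson correlations of a score between diet strata
#'
#' Pairwise-complete Pearson correlations of one index across the five
#' strata (total, breakfast, lunch, dinner, snack). Pairs with zero
#' variance are reported as missing.
#'
#' @param scores Tibble from [score_population()].
#' @param index_col Score column name.
#' @return A 5 x 5 correlation matrix.
#' @export
correlate_scores <- function(scores, index_col = "hei_total") {
  wide <- scores %>%
    select(all_of(c("participant_id", "stratum", index_col))) %>%
    tidyr::pivot_wider(names_from = "stratum",
                       values_from = all_of(index_col))
  for (st in meal_types(with_total = TRUE)) {
    if (!st %in% names(wide)) wide[[st]] <- NA_real_
  }
  m <- as.matrix(wide[meal_types(with_total = TRUE)])
  suppressWarnings(cor(m, use = "pairwise.complete.obs",
                       method = "pearson"))
}

# compact letter display from a logical "significantly different" matrix;
# groups are processed in ascending mean order and share a letter with
# every group of a clique they are not significantly different from
cld_letters <- function(sig_diff, order_means) {
  g <- rownames(sig_diff)[order_means]
  cliques <- list()
  for (gi in g) {
    placed <- FALSE
    for (k in seq_along(cliques)) {
      if (!any(sig_diff[gi, cliques[[k]]])) {
        cliques[[k]] <- c(cliques[[k]], gi)
        placed <- TRUE
      }
    }
    if (!placed) cliques[[length(cliques) + 1]] <- gi
  }
  letters_out <- setNames(rep("", length(g)), g)
  for (k in seq_along(cliques)) {
    for (gi in cliques[[k]]) {
      letters_out[gi] <- paste0(letters_out[gi], letters[k])
    }
  }
  letters_out
}

#' Compare a score between participant groups
#'
#' Two-level groupings (sex, survey year) use the independent two-sample
#' t test (pooled variance); groupings with three or more levels (age
#' band, weight status, reporting status) use one-way ANOVA, followed by
#' Bonferroni-adjusted all-pairs post hoc tests — and compact letters —
#' only when the overall P is below 0.05. Groups with fewer than two
#' observations are dropped with a warning.
#'
#' @param data Tibble with the outcome and grouping columns.
#' @param outcome Name of the numeric outcome column.
#' @param group Name of the grouping column.
#' @param alpha Significance level gating the post hoc step (default 0.05).
#' @return A list: `method` ("t-test" or "anova"), `groups` (tibble of
#'   per-group n/mean/sd, with post hoc `letter`s when computed),
#'   `statistic`, `p_value`, and `posthoc` (Bonferroni-adjusted pairwise
#'   p-value matrix, or NULL).
#' @export
compare_groups <- function(data, outcome, group, alpha = 0.05) {
  stop_if_missing_cols(data, c(outcome, group), "comparison data")
  df <- data[!is.na(data[[outcome]]) & !is.na(data[[group]]), ]
  df[[group]] <- factor(df[[group]])
  sizes <- table(df[[group]])
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warn(paste0("group(s) with n < 2 skipped: ",
                paste(small, collapse = ", ")))
    df <- df[!df[[group]] %in% small, ]
    df[[group]] <- droplevels(df[[group]])
  }
  lv <- levels(df[[group]])
  if (length(lv) < 2) {
    warn("fewer than two usable groups; comparison skipped")
    return(NULL)
  }
  summ <- df %>%
    group_by(.data[[group]]) %>%
    summarise(n = dplyr::n(), mean = mean(.data[[outcome]]),
              sd = sd(.data[[outcome]]), .groups = "drop") %>%
    rename(group = 1)
  x <- df[[outcome]]
  g <- df[[group]]
  if (length(lv) == 2) {
    tt <- t.test(x ~ g, var.equal = TRUE)
    return(list(method = "t-test", groups = summ,
                statistic = unname(tt$statistic),
                p_value = tt$p.value, posthoc = NULL))
  }
  fit <- aov(x ~ g)
  an <- anova(fit)
  p <- an$`Pr(>F)`[1]
  posthoc <- NULL
  if (p < alpha) {
    ph <- stats::pairwise.t.test(x, g, p.adjust.method = "bonferroni",
                                 pool.sd = TRUE)
    pm <- matrix(1, length(lv), length(lv), dimnames = list(lv, lv))
    pv <- ph$p.value
    pm[rownames(pv), colnames(pv)] <- ifelse(is.na(pv), 1, pv)
    pm <- pmin(pm, t(pm))
    diag(pm) <- 1
    posthoc <- pm
    summ$letter <- unname(cld_letters(pm < alpha,
                                      order(summ$mean))[summ$group])
  }
  list(method = "anova", groups = summ,
       statistic = unname(an$`F value`[1]), p_value = p,
       posthoc = posthoc)
}

#' Tertile general linear model with covariate-adjusted means
#'
#' Fits `outcome ~ tertile + covariates` (all covariates categorical) and
#' reports per-tertile adjusted means computed as population-marginal
#' means: the model's predictions with every participant assigned to a
#' given tertile, averaged over the observed covariate distribution. With
#' no covariates — or covariates orthogonal to the tertile — the adjusted
#' means equal the raw tertile means. The trend statistic comes from a
#' parallel fit with the tertile entered as the ordinal score 1/2/3.
#'
#' @param data Tibble with the outcome, a `tertile` factor (T1/T2/T3) and
#'   any covariate columns.
#' @param outcome Name of the numeric outcome column.
#' @param covariates Character vector of covariate column names (may be
#'   empty). Covariate levels with no observations are dropped; a
#'   covariate left with a single level is removed with a warning.
#' @return A list of class `tertile_glm`: `outcome`, `means` (tibble:
#'   `tertile`, `n`, `raw_mean`, `adjusted_mean`), `trend_estimate`,
#'   `trend_p`, `covariates`, and the fitted `model`.
#' @export
tertile_glm <- function(data, outcome, covariates = character()) {
  stop_if_missing_cols(data, c(outcome, "tertile", covariates),
                       "tertile GLM data")
  df <- data[stats::complete.cases(data[c(outcome, "tertile",
                                          covariates)]), , drop = FALSE]
  df$tertile <- droplevels(factor(df$tertile, ordered = FALSE))
  keep <- character()
  for (cv in covariates) {
    df[[cv]] <- droplevels(factor(df[[cv]]))
    if (nlevels(df[[cv]]) >= 2) {
      keep <- c(keep, cv)
    } else {
      warn(paste0("covariate '", cv, "' has a single observed level; dropped"))
    }
  }
  rhs <- paste(c("tertile", keep), collapse = " + ")
  fml <- stats::as.formula(paste(outcome, "~", rhs))
  fit <- lm(fml, data = df)
  adj <- vapply(levels(df$tertile), function(tl) {
    nd <- df
    nd$tertile <- factor(tl, levels = levels(df$tertile))
    mean(suppressWarnings(predict(fit, newdata = nd)))
  }, numeric(1))
  raw <- tapply(df[[outcome]], df$tertile, mean)
  ns <- tapply(df[[outcome]], df$tertile, length)
  df$tertile_score <- as.numeric(df$tertile)
  fml_tr <- stats::as.formula(paste(outcome, "~",
                                    paste(c("tertile_score", keep),
                                          collapse = " + ")))
  fit_tr <- lm(fml_tr, data = df)
  ct <- summary(fit_tr)$coefficients
  structure(list(outcome = outcome,
                 means = tibble(tertile = levels(df$tertile),
                                n = as.integer(ns),
                                raw_mean = as.numeric(raw),
                                adjusted_mean = as.numeric(adj)),
                 trend_estimate = ct["tertile_score", "Estimate"],
                 trend_p = ct["tertile_score", "Pr(>|t|)"],
                 covariates = keep, model = fit),
            class = "tertile_glm")
}

#' @export
print.tertile_glm <- function(x, ...) {
  cat("<tertile_glm> outcome:", x$outcome, "\n")
  cat("  covariates:",
      if (length(x$covariates)) paste(x$covariates, collapse = ", ")
      else "(none)", "\n")
  print(as.data.frame(x$means), row.names = FALSE)
  cat(sprintf("  trend: %.4g per tertile, p = %.3g\n",
              x$trend_estimate, x$trend_p))
  invisible(x)
}

#' Age bands used as an adjustment covariate
#'
#' Three bands: under 40, 40-59, 60 and over.
#'
#' @param age Integer ages.
#' @return Factor with levels `"<40"`, `"40-59"`, `">=60"`.
#' @export
age_band <- function(age) {
  cut(age, breaks = c(-Inf, 39, 59, Inf),
      labels = c("<40", "40-59", ">=60"))
}
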