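#' Default screener cut-points
#'
#' Insomnia Severity Index >= 10; RMT20 depression >= 13, generalized
#' anxiety >= 11, social anxiety >= 12, panic >= 9, posttraumatic stress >= 8;
#' ASRS (ADHD) >= 4.
#'
#' @return Named integer vector of cut-points.
#' @export
default_cut_points <- function() {
  c(ISI = 10L, MDD = 13L, GAD = 11L, SAD = 12L, PD = 9L, PTSD = 8L, ASRS = 4L)
}

#' Classify probable disorders from screener scores
#'
#' Thresholds each severity scale at its cut-point (`score >= cut_point`) and
#' summarizes how many persons screen positive for none, one, or multiple
#' disorders.
#'
#' @param severity Tibble with `person_id` (optional) and one numeric column
#'   per scale.
#' @param cut_points Named vector of per-scale cut-points; every scale column
#'   must have one.
#' @return List with `classification` (tibble of logicals per scale plus
#'   `n_positive`) and `counts` (tibble: none / one / multiple).
#' @export
classify_probable_disorders <- function(severity, cut_points = default_cut_points()) {
  df <- as.data.frame(severity)
  pid <- if ("person_id" %in% names(df)) df$person_id else seq_len(nrow(df))
  df$person_id <- NULL
  unknown <- setdiff(names(df), names(cut_points))
  if (length(unknown)) stopf("no cut-point for scale(s): %s",
                             paste(unknown, collapse = ", "))
  cls <- as.data.frame(lapply(names(df), function(s) df[[s]] >= cut_points[s]))
  names(cls) <- names(df)
  n_pos <- rowSums(cls, na.rm = TRUE)
  counts <- tibble(category = c("none", "one", "multiple"),
                   n = c(sum(n_pos == 0), sum(n_pos == 1), sum(n_pos >= 2)))
  list(classification = dplyr::bind_cols(tibble(person_id = pid),
                                         as_tibble(cls),
                                         tibble(n_positive = n_pos)),
       counts = counts)
}

#' Standardized regression profile of a severity outcome on dimension scores
#'
#' Ordinary least squares of one severity scale on the dimension scores plus
#' covariates, on listwise-complete rows. Continuous variables (outcome,
#' dimension scores, and continuous covariates such as age) are scaled to unit
#' standard deviation on the analysis sample before fitting, so coefficients
#' are standardized betas; a binary `sex` covariate enters as 0/1
#' unstandardized. Confidence intervals are t-based.
#'
#' @param data Tibble containing the outcome, predictor, and covariate
#'   columns (e.g. dimension scores joined with severities and covariates).
#' @param outcome Name of the severity column.
#' @param predictors Character vector of dimension-score columns (a single
#'   name gives a single-dimension model).
#' @param covariates Character vector of covariate columns (default age and
#'   sex; extend for sensitivity analyses).
#' @param conf_level Confidence level for the t-based intervals.
#' @return Object of class `regression_profile`: tibble with `outcome`,
#'   `term`, `beta`, `se`, `t`, `p_value`, `ci_low`, `ci_high`, plus
#'   attributes `n`, `r_squared`, `covariate_set`.
#' @export
fit_profile <- function(data, outcome, predictors,
                        covariates = c("age", "sex"), conf_level = 0.95) {
  covariates <- intersect(covariates, names(data))
  vars <- c(outcome, predictors, covariates)
  df <- as.data.frame(data)[, vars, drop = FALSE]
  df <- df[complete.cases(df), , drop = FALSE]
  n <- nrow(df)
  n_par <- length(predictors) + length(covariates) + 1
  if (n < n_par + 10) stopf("need at least %d complete cases", n_par + 10)

  if ("sex" %in% names(df) && !is.numeric(df$sex)) {
    df$sex <- as.numeric(df$sex == "female")
  }
  for (v in vars) {
    if (is.numeric(df[[v]]) && !identical(v, "sex")) {
      s <- sd(df[[v]])
      if (s == 0) stopf("zero-variance variable: %s", v)
      df[[v]] <- (df[[v]] - mean(df[[v]])) / s
    }
  }

  fml <- as.formula(paste(outcome, "~",
                          paste(c(predictors, covariates), collapse = " + ")))
  fit <- lm(fml, data = df)
  if (any(is.na(coef(fit)))) stopf("rank-deficient model")
  sm <- summary(fit)
  ci <- confint(fit, level = conf_level)
  tab <- sm$coefficients
  keep <- rownames(tab) != "(Intercept)"
  out <- tibble(outcome = outcome,
                term = rownames(tab)[keep],
                beta = tab[keep, 1], se = tab[keep, 2],
                t = tab[keep, 3], p_value = tab[keep, 4],
                ci_low = ci[keep, 1], ci_high = ci[keep, 2])
  attr(out, "n") <- n
  attr(out, "r_squared") <- sm$r.squared
  attr(out, "covariate_set") <- paste(covariates, collapse = "+")
  class(out) <- c("regression_profile", class(out))
  out
}

#' Demographic sensitivity correlations of dimension scores
#'
#' Pearson correlations for continuous demographics (age, years of education)
#' and Spearman rank correlations for ordinal socioeconomic status, per
#' dimension, on pairwise-complete data.
#'
#' @param scores Tibble: `person_id` + one column per dimension.
#' @param demographics Tibble with `person_id` and demographic columns.
#' @param pearson_vars,spearman_vars Which demographic columns get which
#'   correlation.
#' @return Tibble: `dimension`, `variable`, `method`, `estimate`, `n`.
#' @export
demographic_sensitivity <- function(scores, demographics,
                                    pearson_vars = c("age", "education_years"),
                                    spearman_vars = "ses") {
  merged <- dplyr::inner_join(scores, demographics, by = "person_id")
  dims <- setdiff(names(scores), "person_id")
  specs <- rbind(
    expand.grid(variable = intersect(pearson_vars, names(demographics)),
                method = "pearson", stringsAsFactors = FALSE),
    expand.grid(variable = intersect(spearman_vars, names(demographics)),
                method = "spearman", stringsAsFactors = FALSE)
  )
  purrr::map_dfr(dims, function(d) {
    purrr::map_dfr(seq_len(nrow(specs)), function(i) {
      v <- specs$variable[i]
      ok <- !is.na(merged[[d]]) & !is.na(merged[[v]])
      if (sum(ok) < 3) stopf("fewer than 3 complete pairs for %s ~ %s", d, v)
      tibble(dimension = d, variable = v, method = specs$method[i],
             estimate = cor(merged[[d]][ok], merged[[v]][ok],
                            method = specs$method[i]),
             n = sum(ok))
    })
  })
}
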