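#' Specify a synthetic ordinal questionnaire battery
#'
#' A battery configuration fully determines a latent-factor data-generating
#' process for ordinal questionnaire items: correlated standard-normal factors,
#' continuous item variables `y = lambda' f + e` with unit total variance,
#' discretization at fixed thresholds, severity outcomes linear in the factors,
#' age/sex covariates, and (optionally) a block of "external" items driven by
#' the same factors, emulating items available in an outside cohort.
#'
#' Item thresholds live on the standard-normal scale: because every item's
#' implied total variance is constrained to 1, the marginal category
#' probabilities are exactly the normal-CDF increments between consecutive
#' thresholds.
#'
#' @param n_persons Number of persons to simulate.
#' @param loadings Items x factors matrix of true loadings.
#' @param factor_correlations Factors x factors correlation matrix (symmetric,
#'   positive definite, unit diagonal).
#' @param item_category_counts Integer vector (per item) of response categories,
#'   typically 2, 4 or 5.
#' @param item_thresholds Optional list of strictly increasing threshold vectors
#'   (length `categories - 1` each). Defaults to equal-probability cut-points.
#' @param severity_betas Optional outcomes x factors matrix of linear effects of
#'   the factors on severity outcomes.
#' @param severity_noise_sd Per-outcome residual standard deviation.
#' @param missing_rate Probability that any response cell is missing (MCAR).
#' @param covariate_spec List with `age_mean`, `age_sd`, `age_range`,
#'   `female_prob` controlling the covariate table.
#' @param external_loadings Optional external-items x factors loading matrix.
#' @param external_category_counts,external_thresholds Category structure of the
#'   external block (same conventions as the battery items).
#' @param seed Master seed; all random draws derive deterministic sub-streams
#'   from it, so identical configurations reproduce identical data.
#'
#' @return An object of class `battery_config`.
#' @seealso [generate_battery()], [preset_study_like()], [study_battery_config()]
#' @export
battery_config <- function(n_persons,
                           loadings,
                           factor_correlations = NULL,
                           item_category_counts,
                           item_thresholds = NULL,
                           severity_betas = NULL,
                           severity_noise_sd = NULL,
                           missing_rate = 0,
                           covariate_spec = list(age_mean = 58.3, age_sd = 13.8,
                                                 age_range = c(18, 90),
                                                 female_prob = 0.776),
                           external_loadings = NULL,
                           external_category_counts = NULL,
                           external_thresholds = NULL,
                           seed = 1L) {
  loadings <- as.matrix(loadings)
  n_items <- nrow(loadings)
  k <- ncol(loadings)
  if (is.null(factor_correlations)) factor_correlations <- diag(k)
  phi <- as.matrix(factor_correlations)
  check_symmetric_pd(phi, "factor_correlations")
  if (max(abs(diag(phi) - 1)) > 1e-10) {
    stopf("factor_correlations must have unit diagonal")
  }
  if (length(item_category_counts) != n_items) {
    stopf("item_category_counts must have one entry per item")
  }
  if (any(item_category_counts < 2)) stopf("items need at least 2 categories")

  comm <- rowSums((loadings %*% phi) * loadings)
  if (any(comm > 1 + 1e-10)) {
    stopf("loadings and factor correlations imply negative uniqueness for item(s) %s",
          paste(which(comm > 1 + 1e-10), collapse = ", "))
  }

  if (is.null(item_thresholds)) {
    item_thresholds <- lapply(item_category_counts, function(cc) {
      qnorm(seq_len(cc - 1) / cc)
    })
  }
  validate_thresholds(item_thresholds, item_category_counts, "item_thresholds")

  if (!is.null(severity_betas)) {
    severity_betas <- as.matrix(severity_betas)
    if (ncol(severity_betas) != k) {
      stopf("severity_betas must have one column per factor")
    }
    if (is.null(severity_noise_sd)) {
      severity_noise_sd <- rep(1, nrow(severity_betas))
    }
    if (any(severity_noise_sd <= 0)) stopf("severity_noise_sd must be positive")
    if (length(severity_noise_sd) != nrow(severity_betas)) {
      stopf("severity_noise_sd must have one entry per outcome")
    }
    if (is.null(rownames(severity_betas))) {
      rownames(severity_betas) <- default_severity_names(nrow(severity_betas))
    }
  }

  if (missing_rate < 0 || missing_rate >= 1) {
    stopf("missing_rate must lie in [0, 1)")
  }

  if (!is.null(external_loadings)) {
    external_loadings <- as.matrix(external_loadings)
    if (ncol(external_loadings) != k) {
      stopf("external_loadings must have one column per factor")
    }
    n_ext <- nrow(external_loadings)
    if (is.null(external_category_counts)) {
      external_category_counts <- rep(4L, n_ext)
    }
    ecomm <- rowSums((external_loadings %*% phi) * external_loadings)
    if (any(ecomm > 1 + 1e-10)) {
      stopf("external loadings imply negative uniqueness")
    }
    if (is.null(external_thresholds)) {
      external_thresholds <- lapply(external_category_counts, function(cc) {
        qnorm(seq_len(cc - 1) / cc)
      })
    }
    validate_thresholds(external_thresholds, external_category_counts,
                        "external_thresholds")
    if (is.null(rownames(external_loadings))) {
      rownames(external_loadings) <- item_labels(n_ext, "ext")
    }
  }

  if (is.null(rownames(loadings))) rownames(loadings) <- item_labels(n_items)
  if (is.null(colnames(loadings))) colnames(loadings) <- default_dimension_names(k)
  dimnames(phi) <- list(colnames(loadings), colnames(loadings))

  structure(
    list(n_persons = as.integer(n_persons),
         loadings = loadings,
         factor_correlations = phi,
         item_category_counts = as.integer(item_category_counts),
         item_thresholds = item_thresholds,
         uniquenesses = pmax(1 - comm, 0),
         severity_betas = severity_betas,
         severity_noise_sd = severity_noise_sd,
         missing_rate = missing_rate,
         covariate_spec = covariate_spec,
         external_loadings = external_loadings,
         external_category_counts =
           if (is.null(external_loadings)) NULL else as.integer(external_category_counts),
         external_thresholds = external_thresholds,
         seed = as.integer(seed)),
    class = "battery_config"
  )
}

validate_thresholds <- function(thresholds, counts, name) {
  if (length(thresholds) != length(counts)) {
    stopf("%s must have one vector per item", name)
  }
  for (i in seq_along(thresholds)) {
    tau <- thresholds[[i]]
    if (length(tau) != counts[i] - 1) {
      stopf("%s[[%d]] must have length categories - 1", name, i)
    }
    if (length(tau) > 1 && any(diff(tau) <= 0)) {
      stopf("%s[[%d]] must be strictly increasing", name, i)
    }
  }
  invisible(TRUE)
}

#' @export
print.battery_config <- function(x, ...) {
  cat(sprintf("<battery_config> %d persons, %d items, %d factors\n",
              x$n_persons, nrow(x$loadings), ncol(x$loadings)))
  cat(sprintf("  categories: %s\n",
              paste(sprintf("%dx%d", table(x$item_category_counts),
                            as.integer(names(table(x$item_category_counts)))),
                    collapse = ", ")))
  if (!is.null(x$severity_betas)) {
    cat(sprintf("  severities: %s\n",
                paste(rownames(x$severity_betas), collapse = ", ")))
  }
  if (!is.null(x$external_loadings)) {
    cat(sprintf("  external items: %d\n", nrow(x$external_loadings)))
  }
  cat(sprintf("  missing rate: %g, seed: %d\n", x$missing_rate, x$seed))
  invisible(x)
}

# Discretize a matrix of continuous item variables at per-item thresholds.
discretize_items <- function(Y, thresholds) {
  X <- matrix(0L, nrow(Y), ncol(Y), dimnames = dimnames(Y))
  for (j in seq_len(ncol(Y))) {
    X[, j] <- findInterval(Y[, j], thresholds[[j]]) + 1L
  }
  X
}

#' Generate a synthetic battery with ground truth
#'
#' Draws factor scores `f ~ MVN(0, Phi)`, continuous item variables
#' `y = Lambda f + e` with `e ~ N(0, diag(psi))` (unit total variance per
#' item), discretizes them at the configured thresholds, generates severity
#' outcomes `B f + noise`, covariates, MCAR missingness, and (if configured)
#' an external item block. The same configuration always yields identical
#' output.
#'
#' @param config A [battery_config()].
#' @return An object of class `battery_data`: a list with tibbles `responses`
#'   (person_id + one integer column per item), `items` (metadata), `factors`
#'   (true latent factor scores), `severities`, `covariates`, optionally
#'   `external`, and the generating `config`.
#' @export
generate_battery <- function(config = study_battery_config()) {
  if (!inherits(config, "battery_config")) {
    stopf("config must be a battery_config")
  }
  n <- config$n_persons
  L <- config$loadings
  phi <- config$factor_correlations
  k <- ncol(L)
  n_items <- nrow(L)
  psi <- config$uniquenesses

  f <- with_seed(substream(config$seed, 1), {
    Z <- matrix(rnorm(n * k), n, k)
    Z %*% chol(phi)
  })
  colnames(f) <- colnames(L)

  Y <- with_seed(substream(config$seed, 2), {
    E <- matrix(rnorm(n * n_items), n, n_items)
    f %*% t(L) + E * rep(sqrt(psi), each = n)
  })
  colnames(Y) <- rownames(L)
  X <- discretize_items(Y, config$item_thresholds)

  if (config$missing_rate > 0) {
    miss <- with_seed(substream(config$seed, 3), {
      matrix(runif(n * n_items) < config$missing_rate, n, n_items)
    })
    X[miss] <- NA_integer_
  }

  severities <- NULL
  if (!is.null(config$severity_betas)) {
    B <- config$severity_betas
    noise <- with_seed(substream(config$seed, 4), {
      matrix(rnorm(n * nrow(B)), n, nrow(B))
    })
    S <- f %*% t(B) + noise * rep(config$severity_noise_sd, each = n)
    colnames(S) <- rownames(B)
    severities <- as_tibble(as.data.frame(S))
    severities <- dplyr::bind_cols(tibble(person_id = seq_len(n)), severities)
  }

  cs <- config$covariate_spec
  covariates <- with_seed(substream(config$seed, 5), {
    age <- rnorm(n, cs$age_mean, cs$age_sd)
    lo <- cs$age_range[1]; hi <- cs$age_range[2]
    while (any(bad <- age < lo | age > hi)) {
      age[bad] <- rnorm(sum(bad), cs$age_mean, cs$age_sd)
    }
    tibble(person_id = seq_len(n),
           age = age,
           sex = ifelse(rbinom(n, 1, cs$female_prob) == 1, "female", "male"))
  })

  external <- NULL
  if (!is.null(config$external_loadings)) {
    Le <- config$external_loadings
    psie <- pmax(1 - rowSums((Le %*% phi) * Le), 0)
    Ye <- with_seed(substream(config$seed, 6), {
      Ee <- matrix(rnorm(n * nrow(Le)), n, nrow(Le))
      f %*% t(Le) + Ee * rep(sqrt(psie), each = n)
    })
    colnames(Ye) <- rownames(Le)
    Xe <- discretize_items(Ye, config$external_thresholds)
    external <- dplyr::bind_cols(tibble(person_id = seq_len(n)),
                                 as_tibble(as.data.frame(Xe)))
  }

  items <- tibble(item_id = rownames(L),
                  n_categories = config$item_category_counts,
                  scale = paste0("scale_", 1 + (seq_len(n_items) - 1) %% 18))

  structure(
    list(responses = dplyr::bind_cols(tibble(person_id = seq_len(n)),
                                      as_tibble(as.data.frame(X))),
         items = items,
         factors = dplyr::bind_cols(tibble(person_id = seq_len(n)),
                                    as_tibble(as.data.frame(f))),
         severities = severities,
         covariates = covariates,
         external = external,
         config = config),
    class = "battery_data"
  )
}

#' @export
print.battery_data <- function(x, ...) {
  cat(sprintf("<battery_data> %d persons x %d items",
              nrow(x$responses), nrow(x$items)))
  if (!is.null(x$external)) {
    cat(sprintf(" (+%d external items)", ncol(x$external) - 1))
  }
  cat("\n")
  invisible(x)
}

#' Write a generated battery (and its ground truth) to disk
#'
#' Writes responses, severities, covariates and external items as CSV plus a
#' JSON sidecar holding the generating parameters, so external harnesses can
#' re-load both data and truth.
#'
#' @param data A `battery_data` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_battery <- function(data, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(responses = file.path(dir, "responses.csv"),
             items = file.path(dir, "items.csv"),
             factors = file.path(dir, "factors.csv"),
             covariates = file.path(dir, "covariates.csv"))
  write.csv(data$responses, paths["responses"], row.names = FALSE)
  write.csv(data$items, paths["items"], row.names = FALSE)
  write.csv(data$factors, paths["factors"], row.names = FALSE)
  write.csv(data$covariates, paths["covariates"], row.names = FALSE)
  if (!is.null(data$severities)) {
    paths <- c(paths, severities = file.path(dir, "severities.csv"))
    write.csv(data$severities, paths["severities"], row.names = FALSE)
  }
  if (!is.null(data$external)) {
    paths <- c(paths, external = file.path(dir, "external.csv"))
    write.csv(data$external, paths["external"], row.names = FALSE)
  }
  cfg <- data$config
  truth <- list(
    n_persons = cfg$n_persons,
    loadings = cfg$loadings,
    factor_correlations = cfg$factor_correlations,
    item_category_counts = cfg$item_category_counts,
    item_thresholds = cfg$item_thresholds,
    severity_betas = cfg$severity_betas,
    severity_noise_sd = cfg$severity_noise_sd,
    missing_rate = cfg$missing_rate,
    seed = cfg$seed
  )
  paths <- c(paths, truth = file.path(dir, "ground_truth.json"))
  jsonlite::write_json(truth, paths["truth"], digits = NA, pretty = TRUE)
  invisible(paths)
}
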