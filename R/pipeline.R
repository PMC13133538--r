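#' Pipeline configuration
#'
#' Collects every stage parameter of the full analysis with defaults equal to
#' the reference settings: MSA screening at 0.7; redundancy reduction from
#' |0.9| to |0.5| in steps of 0.05; salience |0.32|; 0-4 rescaling; EBIC
#' gamma 0.5; 2000 bootstrap resamples thresholded at level 0.05; extension
#' thresholds 0.45 (primary) / 0.32 (cross).
#'
#' @param generator A [battery_config()] used when no data are supplied
#'   (default [preset_study_like()]).
#' @param n_factors Number of dimensions extracted (operator override of the
#'   parallel-analysis suggestion; the reference analysis retained 7).
#' @param msa_threshold,reduction_start,reduction_stop,reduction_step,salience
#'   Stage parameters (see the stage functions).
#' @param per_factor_counts Short-form marker counts per factor.
#' @param ebic_gamma,n_boot,boot_level Network stage parameters.
#' @param extension_primary,extension_cross,extension_min_items Extension
#'   stage parameters.
#' @param reduce,network,extension Stage toggles.
#' @param parallel_reps Parallel-analysis replicates.
#' @param seed Seed for the pipeline's stochastic stages (parallel analysis,
#'   bootstrap).
#' @param out_dir Output directory for artifacts and manifest.
#' @param run_id Label recorded in the manifest.
#' @return Object of class `pipeline_config` (a list).
#' @export
pipeline_config <- function(generator = preset_study_like(),
                            n_factors = 7,
                            msa_threshold = 0.7,
                            reduction_start = 0.9,
                            reduction_stop = 0.5,
                            reduction_step = 0.05,
                            salience = 0.32,
                            per_factor_counts = c(4, 5, 4, 4, 4, 2, 4),
                            ebic_gamma = 0.5,
                            n_boot = 2000,
                            boot_level = 0.05,
                            extension_primary = 0.45,
                            extension_cross = 0.32,
                            extension_min_items = 3,
                            reduce = TRUE,
                            network = TRUE,
                            extension = TRUE,
                            parallel_reps = 200,
                            seed = 1L,
                            out_dir = tempfile("hyperdim_run_"),
                            run_id = "run") {
  structure(as.list(environment()), class = "pipeline_config")
}

write_stage <- function(obj, name, out_dir, manifest) {
  path <- file.path(out_dir, name)
  if (is.matrix(obj)) {
    write_cor_csv(obj, path)
  } else if (is.data.frame(obj)) {
    write.csv(obj, path, row.names = FALSE, na = "")
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE)
  }
  manifest[[name]] <- unname(tools::md5sum(path))
  manifest
}

#' Run the full dimension-analysis pipeline
#'
#' Executes, in order: polychoric correlation, MSA screening, redundancy
#' reduction, parallel analysis, EFA (principal axis + promax),
#' loading-weighted scoring, short-form construction and scoring, CFA and
#' reliability on the short-form items, severity regression profiles plus the
#' partial-correlation network, and factor extension to external items (when
#' present). Every stage writes its artifact to `config$out_dir` and is
#' checksummed into a machine-readable manifest; identical data, config and
#' seed reproduce identical checksums.
#'
#' @param config A [pipeline_config()].
#' @param data Optional `battery_data`; when omitted, data are generated from
#'   `config$generator`.
#' @return Invisibly, a list with every stage result plus `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), data = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  stage <- "simulate"
  res <- list()

  run_stage <- function(name, expr) {
    stage <<- name
    tryCatch(expr, error = function(e) {
      stopf("pipeline stage '%s' failed: %s (last completed artifact: %s)",
            name, conditionMessage(e),
            if (length(manifest)) names(manifest)[length(manifest)] else "none")
    })
  }

  if (is.null(data)) data <- run_stage("simulate", generate_battery(config$generator))
  categories <- setNames(data$items$n_categories, data$items$item_id)

  # 1: polychoric
  poly <- run_stage("polychoric", polychoric_matrix(data$responses))
  manifest <- write_stage(poly$rho, "01_polychoric.csv", out_dir, manifest)

  # 2: MSA screening
  msa <- run_stage("screen", kmo_msa(poly, threshold = config$msa_threshold))
  manifest <- write_stage(msa$per_item, "02_msa_screen.csv", out_dir, manifest)
  kept <- msa$retained_items

  # 3: redundancy reduction
  if (config$reduce) {
    trace <- run_stage("reduce",
                       reduce_items(poly$rho[kept, kept],
                                    start_threshold = config$reduction_start,
                                    stop_threshold = config$reduction_stop,
                                    step = config$reduction_step))
    kept <- trace$surviving_items
    manifest <- write_stage(trace$removals, "03_reduction.csv", out_dir, manifest)
  } else {
    manifest <- write_stage(tibble(note = "reduction disabled"),
                            "03_reduction.csv", out_dir, manifest)
  }
  R <- poly$rho[kept, kept]

  # 4: parallel analysis
  pa <- run_stage("parallel",
                  parallel_analysis(R, n_obs = poly$n_obs,
                                    n_reps = config$parallel_reps,
                                    seed = substream(config$seed, 41)))
  manifest <- write_stage(pa$eigenvalues, "04_parallel.csv", out_dir, manifest)

  # 5: EFA
  k <- config$n_factors %||% pa$suggested_n_factors
  sol <- run_stage("efa", efa_promax(R, k = k, n_obs = poly$n_obs))
  manifest <- write_stage(sol$pattern, "05_efa_pattern.csv", out_dir, manifest)

  # 6: loading-weighted scores
  scores <- run_stage("scores",
                      weighted_factor_scores(data$responses[, c("person_id", kept)],
                                             sol, salience = config$salience))
  manifest <- write_stage(scores, "06_scores.csv", out_dir, manifest)

  # 7: short form
  sf_spec <- run_stage("shortform",
                       select_markers(sol,
                                      per_factor_counts = config$per_factor_counts,
                                      cross_loading_cap = config$salience,
                                      categories = categories))
  sf_scores <- run_stage("shortform", score_short_form(data$responses, sf_spec))
  consistency <- run_stage("shortform", consistency_with_full(sf_scores, scores))
  manifest <- write_stage(
    dplyr::left_join(sf_spec$markers, consistency, by = "factor"),
    "07_shortform.csv", out_dir, manifest)

  # 8: CFA + reliability on the short-form items (0-4 rescaled covariance)
  cfa <- run_stage("cfa", {
    mk <- sf_spec$markers
    X <- responses_to_matrix(data$responses)$values[, mk$item, drop = FALSE]
    lo <- 1; hi <- categories[mk$item]
    Z <- sweep(sweep(X, 2, lo, "-"), 2, hi - lo, "/") * 4
    Z <- Z[complete.cases(Z), , drop = FALSE]
    S <- cov(Z)
    assignment <- split(mk$item, mk$factor)[unique(mk$factor)]
    fit <- fit_cfa(S, nrow(Z), cfa_spec(assignment))
    rel <- reliability_report(S, assignment, nrow(Z))
    list(fit = fit, reliability = rel)
  })
  manifest <- write_stage(
    list(cfi = cfa$fit$cfi, tli = cfa$fit$tli, rmsea = cfa$fit$rmsea,
         srmr = cfa$fit$srmr, chi_square = cfa$fit$chi_square, df = cfa$fit$df,
         alpha_total = cfa$reliability$alpha_total,
         omega_total = cfa$reliability$omega_total),
    "08_cfa.json", out_dir, manifest)

  # 9: regression profiles + network
  profiles <- NULL; net <- NULL
  if (!is.null(data$severities)) {
    merged <- sf_scores |>
      dplyr::inner_join(data$severities, by = "person_id") |>
      dplyr::inner_join(data$covariates, by = "person_id")
    dims <- setdiff(names(sf_scores), "person_id")
    outcomes <- setdiff(names(data$severities), "person_id")
    profiles <- run_stage("profiles", purrr::map_dfr(outcomes, function(o) {
      fit_profile(merged, o, dims)
    }))
    manifest <- write_stage(profiles, "09_profiles.csv", out_dir, manifest)
    if (config$network) {
      net <- run_stage("network", {
        nd <- dplyr::inner_join(sf_scores, data$severities, by = "person_id")
        n0 <- ebic_glasso_network(nd, gamma = config$ebic_gamma)
        bootstrap_threshold(n0, n_boot = config$n_boot,
                            level = config$boot_level,
                            seed = substream(config$seed, 91))
      })
      manifest <- write_stage(network_edges(net, keep_zero = TRUE),
                              "09_network.csv", out_dir, manifest)
    }
  }

  # 10: factor extension
  ext <- NULL
  if (config$extension && !is.null(data$external)) {
    ext <- run_stage("extension", {
      mk_items <- sf_spec$markers$item
      ext_items <- setdiff(names(data$external), "person_id")
      combined <- dplyr::inner_join(data$responses[, c("person_id", mk_items)],
                                    data$external, by = "person_id")
      poly_all <- polychoric_matrix(combined)
      sol27 <- efa_promax(poly_all$rho[mk_items, mk_items], k = k,
                          n_obs = poly_all$n_obs)
      el <- extend_loadings(poly_all$rho[mk_items, mk_items], sol27,
                            poly_all$rho[ext_items, mk_items, drop = FALSE])
      ispec <- select_indicators(el, primary_min = config$extension_primary,
                                 cross_max = config$extension_cross,
                                 min_items = config$extension_min_items)
      ext_cat <- setNames(rep(max(responses_to_matrix(data$external)$values,
                                  na.rm = TRUE), length(ext_items)), ext_items)
      if (!is.null(data$config$external_category_counts)) {
        ext_cat <- setNames(data$config$external_category_counts, ext_items)
      }
      iscores <- score_indicators(data$external, ispec, ext_cat)
      # short-form factor columns carry the EFA factor names; align by the
      # marker-factor mapping of the 27-item solution
      validity <- tryCatch(validate_indicators(iscores, sf_scores),
                           error = function(e) NULL)
      list(loadings = el, spec = ispec, scores = iscores, validity = validity)
    })
    manifest <- write_stage(ext$loadings$pattern, "10_extension.csv",
                            out_dir, manifest)
  } else {
    manifest <- write_stage(tibble(note = "extension skipped"),
                            "10_extension.csv", out_dir, manifest)
  }

  manifest_obj <- list(
    run_id = config$run_id,
    seed = config$seed,
    n_factors = k,
    settings = list(msa_threshold = config$msa_threshold,
                    reduction = c(config$reduction_start,
                                  config$reduction_stop,
                                  config$reduction_step),
                    salience = config$salience,
                    ebic_gamma = config$ebic_gamma,
                    n_boot = config$n_boot,
                    boot_level = config$boot_level,
                    extension = c(config$extension_primary,
                                  config$extension_cross)),
    artifacts = manifest
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest_obj, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(data = data, polychoric = poly, msa = msa,
                 parallel = pa, solution = sol, scores = scores,
                 shortform = list(spec = sf_spec, scores = sf_scores,
                                  consistency = consistency),
                 cfa = cfa, profiles = profiles, network = net,
                 extension = ext, manifest = manifest_obj,
                 manifest_path = manifest_path))
}
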