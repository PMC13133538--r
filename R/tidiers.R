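# broom-style accessors for the package's result objects

#' @rdname tidiers
#' @param x A result object.
#' @param ... Unused.
#' @name tidiers
NULL

#' @rdname tidiers
#' @exportS3Method generics::tidy
tidy.polychoric <- function(x, ...) {
  ut <- which(upper.tri(x$rho))
  rc <- arrayInd(ut, dim(x$rho))
  tibble(item_i = rownames(x$rho)[rc[, 1]],
         item_j = colnames(x$rho)[rc[, 2]],
         rho = x$rho[ut])
}

#' @rdname tidiers
#' @exportS3Method generics::glance
glance.polychoric <- function(x, ...) {
  tibble(n_items = ncol(x$rho), n_obs = x$n_obs, smoothed = x$smoothed,
         n_pairs_zero_corrected = sum(x$pair_diagnostics$n_zero_corrected > 0))
}

#' @rdname tidiers
#' @exportS3Method generics::tidy
tidy.msa_report <- function(x, ...) x$per_item

#' @rdname tidiers
#' @exportS3Method generics::glance
glance.msa_report <- function(x, ...) {
  tibble(overall_kmo = x$overall_kmo, threshold = x$threshold,
         n_retained = length(x$retained_items), n_items = nrow(x$per_item))
}

#' @rdname tidiers
#' @exportS3Method generics::tidy
tidy.parallel_analysis <- function(x, ...) x$eigenvalues

#' @rdname tidiers
#' @exportS3Method generics::glance
glance.parallel_analysis <- function(x, ...) {
  tibble(suggested_n_factors = x$suggested_n_factors, n_reps = x$n_reps,
         quantile = x$quantile)
}

#' @rdname tidiers
#' @exportS3Method generics::tidy
tidy.factor_solution <- function(x, ...) {
  P <- x$pattern; S <- x$structure
  tibble(item = rep(rownames(P), ncol(P)),
         factor = rep(colnames(P), each = nrow(P)),
         pattern = as.vector(P), structure = as.vector(S))
}

#' @rdname tidiers
#' @exportS3Method generics::glance
glance.factor_solution <- function(x, ...) {
  tibble(n_items = nrow(x$pattern), n_factors = ncol(x$pattern),
         rotation = x$rotation,
         variance_explained = max(x$var_explained$cumulative),
         converged = x$converged, heywood = x$heywood, n_obs = x$n_obs)
}

#' @rdname tidiers
#' @exportS3Method generics::tidy
tidy.shortform_spec <- function(x, ...) x$markers

#' @rdname tidiers
#' @exportS3Method generics::tidy
tidy.cfa_fit <- function(x, ...) x$parameters

#' @rdname tidiers
#' @exportS3Method generics::glance
glance.cfa_fit <- function(x, ...) {
  tibble(chi_square = x$chi_square, df = x$df, p_value = x$p_value,
         cfi = x$cfi, tli = x$tli, rmsea = x$rmsea, srmr = x$srmr,
         loglik = x$loglik, n_obs = x$n_obs, converged = x$converged)
}

#' @rdname tidiers
#' @exportS3Method generics::tidy
tidy.reliability_report <- function(x, ...) x$alpha_by_dimension

#' @rdname tidiers
#' @exportS3Method generics::glance
glance.reliability_report <- function(x, ...) {
  tibble(alpha_total = x$alpha_total, omega_total = x$omega_total,
         omega_hierarchical = x$omega_hierarchical %||% NA_real_)
}

#' @rdname tidiers
#' @exportS3Method generics::tidy
tidy.pcor_network <- function(x, ...) network_edges(x, keep_zero = FALSE)

#' @rdname tidiers
#' @exportS3Method generics::glance
glance.pcor_network <- function(x, ...) {
  p <- length(x$nodes)
  E <- sum(abs(x$weights[upper.tri(x$weights)]) > 0)
  tibble(n_nodes = p, n_edges = E, density = E / (p * (p - 1) / 2),
         lambda_selected = x$lambda_selected, ebic_gamma = x$ebic_gamma,
         n_obs = x$n_obs,
         bootstrapped = !is.null(x$bootstrap))
}

#' @rdname tidiers
#' @exportS3Method generics::tidy
tidy.extension_loadings <- function(x, ...) {
  L <- x$pattern
  tibble(item = rep(rownames(L), ncol(L)),
         factor = rep(colnames(L), each = nrow(L)),
         loading = as.vector(L))
}

#' @rdname tidiers
#' @exportS3Method generics::tidy
tidy.indicator_spec <- function(x, ...) x$items

#' @rdname tidiers
#' @exportS3Method generics::glance
glance.indicator_spec <- function(x, ...) {
  tibble(n_items = nrow(x$items),
         n_representable = sum(x$representable$representable),
         primary_min = x$primary_min, cross_max = x$cross_max)
}
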