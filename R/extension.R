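#' Factor extension: loadings of external items on reference factors
#'
#' Dwyer-style extension: given the original items' correlation matrix
#' `R_oo`, a reference factor solution (pattern `Lambda`, factor correlations
#' `Phi`), and the cross-correlation block `R_eo` between external and
#' original items, the extension *structure* is
#' `S_e = R_eo R_oo^-1 (Lambda Phi)` and the extension *pattern* is
#' `Lambda_e = S_e Phi^-1`. An external item identical to an original item
#' reproduces that item's pattern row exactly — the defining contract of the
#' formula.
#'
#' @param R_oo Original-items correlation matrix (labeled, invertible).
#' @param solution A `factor_solution` on the original items.
#' @param R_eo External x original cross-correlation matrix (columns aligned
#'   with the solution's items).
#' @return Object of class `extension_loadings`: `pattern` (external x
#'   factors), `structure`, `R_eo`.
#' @export
extend_loadings <- function(R_oo, solution, R_eo) {
  P <- solution$pattern
  phi <- solution$phi
  items <- rownames(P)
  if (!all(items %in% colnames(R_oo))) stopf("solution items missing from R_oo")
  if (!all(items %in% colnames(R_eo))) stopf("R_eo columns must match solution items")
  R_oo <- R_oo[items, items]
  R_eo <- R_eo[, items, drop = FALSE]
  Rinv <- tryCatch(solve(R_oo), error = function(e) stopf("R_oo is singular"))
  S_e <- R_eo %*% Rinv %*% (P %*% phi)
  L_e <- S_e %*% solve(phi)
  colnames(S_e) <- colnames(L_e) <- colnames(P)
  structure(list(pattern = L_e, structure = S_e, R_eo = R_eo),
            class = "extension_loadings")
}

#' @export
print.extension_loadings <- function(x, ...) {
  cat(sprintf("<extension_loadings> %d external items x %d factors\n",
              nrow(x$pattern), ncol(x$pattern)))
  invisible(x)
}

#' Select external indicator items per dimension
#'
#' Applies the specificity rule: an external item indicates a dimension when
#' its absolute pattern loading on that dimension exceeds `primary_min` and
#' no other dimension's absolute loading exceeds `cross_max`. Dimensions with
#' at least `min_items` selected items are flagged representable.
#'
#' @param ext An `extension_loadings` object (or a loading matrix).
#' @param primary_min Primary loading threshold (default 0.45).
#' @param cross_max Cross-loading cap (default 0.32).
#' @param min_items Minimum items for a dimension to be representable
#'   (default 3).
#' @return Object of class `indicator_spec`: `items` (tibble: dimension,
#'   item, loading), `representable` (tibble: dimension, n_items,
#'   representable), thresholds.
#' @export
select_indicators <- function(ext, primary_min = 0.45, cross_max = 0.32,
                              min_items = 3) {
  if (primary_min <= cross_max) stopf("primary_min must exceed cross_max")
  if (primary_min <= 0 || primary_min >= 1) stopf("thresholds must lie in (0, 1)")
  L <- if (inherits(ext, "extension_loadings")) ext$pattern else as.matrix(ext)
  k <- ncol(L)
  dim_v <- itm_v <- character(0); load_v <- numeric(0)
  for (j in seq_len(nrow(L))) {
    a <- abs(L[j, ])
    f <- which.max(a)
    if (a[f] > primary_min && all(a[-f] <= cross_max)) {
      dim_v <- c(dim_v, colnames(L)[f])
      itm_v <- c(itm_v, rownames(L)[j])
      load_v <- c(load_v, L[j, f])
    }
  }
  items <- tibble(dimension = dim_v, item = itm_v, loading = load_v)
  rep_tbl <- tibble(dimension = colnames(L)) |>
    dplyr::left_join(dplyr::count(items, .data$dimension, name = "n_items"),
                     by = "dimension") |>
    dplyr::mutate(n_items = dplyr::coalesce(.data$n_items, 0L),
                  representable = .data$n_items >= min_items)
  structure(
    list(items = items, representable = rep_tbl,
         primary_min = primary_min, cross_max = cross_max,
         min_items = min_items),
    class = "indicator_spec"
  )
}

#' @export
print.indicator_spec <- function(x, ...) {
  rep_dims <- x$representable$dimension[x$representable$representable]
  cat(sprintf("<indicator_spec> %d items selected; representable: %s\n",
              nrow(x$items),
              if (length(rep_dims)) paste(rep_dims, collapse = ", ") else "none"))
  invisible(x)
}

#' Score indicator measures from external responses
#'
#' Rescales each selected external item to 0-4 and averages within dimension
#' over the items a person answered (item-wise exclusion of missing/refusal
#' responses, which must already be coded `NA`). Only representable
#' dimensions are scored.
#'
#' @param data External responses (tibble with `person_id` + item columns, or
#'   matrix).
#' @param spec An `indicator_spec`.
#' @param categories Named integer vector of per-item category counts
#'   (rescale bounds `1..n_categories`).
#' @return Tibble: `person_id` + one score column per representable dimension
#'   (`NA` when a person answered none of a dimension's items).
#' @export
score_indicators <- function(data, spec, categories) {
  if (inherits(data, "battery_data")) data <- data$external
  rm_ <- responses_to_matrix(data)
  X <- rm_$values
  rep_dims <- spec$representable$dimension[spec$representable$representable]
  if (!length(rep_dims)) stopf("no representable dimensions to score")
  sel <- spec$items[spec$items$dimension %in% rep_dims, ]
  if (!all(sel$item %in% colnames(X))) stopf("spec items missing from data")

  scores <- matrix(NA_real_, nrow(X), length(rep_dims),
                   dimnames = list(NULL, rep_dims))
  for (d in rep_dims) {
    its <- sel$item[sel$dimension == d]
    Z <- X[, its, drop = FALSE]
    hi <- categories[its]
    Z <- sweep(Z, 2, 1, "-")
    Z <- sweep(Z, 2, hi - 1, "/") * 4
    scores[, d] <- rowMeans(Z, na.rm = TRUE)
  }
  scores[is.nan(scores)] <- NA_real_
  dplyr::bind_cols(tibble(person_id = rm_$person_id),
                   as_tibble(as.data.frame(scores)))
}

#' Validate indicator scores against reference short-form scores
#'
#' @param indicator,reference Score tibbles (`person_id` + dimension columns).
#' @return Tibble: `dimension`, `r` (pairwise-complete Pearson), `n`.
#' @export
validate_indicators <- function(indicator, reference) {
  consistency_with_full(indicator, reference) |>
    dplyr::rename(dimension = "factor")
}
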