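#' Select short-form marker items per factor
#'
#' For each factor, picks the items with the highest absolute pattern loading
#' whose largest absolute loading on any *other* factor does not exceed
#' `cross_loading_cap`, until the requested count is reached. If a factor's
#' eligible pool is too small the cap is relaxed in recorded steps of 0.05.
#' Manual overrides replace the automatic pick for a factor and are recorded.
#'
#' @param solution A `factor_solution`.
#' @param per_factor_counts Integer vector (length = factors) of marker counts,
#'   each in 2..5. Default `c(4, 5, 4, 4, 4, 2, 4)` for seven factors.
#' @param cross_loading_cap Maximum tolerated cross-loading (default 0.32).
#' @param item_bounds Named list or function giving `(min_code, max_code)` per
#'   item; defaults to `c(1, n_categories)` when `categories` is supplied.
#' @param categories Optional named integer vector of per-item category counts
#'   used to derive rescale bounds.
#' @param overrides Optional named list `factor -> character vector of items`
#'   replacing the automatic selection for those factors.
#' @return Object of class `shortform_spec`: list with `markers` (tibble:
#'   factor, item, loading, overridden), `rescale_bounds`, `cap_relaxed`
#'   (tibble of any relaxation steps), `response_scale = c(0, 4)`.
#' @export
select_markers <- function(solution,
                           per_factor_counts = c(4, 5, 4, 4, 4, 2, 4),
                           cross_loading_cap = 0.32,
                           categories = NULL,
                           overrides = NULL) {
  P <- solution$pattern
  k <- ncol(P)
  if (length(per_factor_counts) == 1) {
    per_factor_counts <- rep(per_factor_counts, k)
  }
  if (length(per_factor_counts) != k) {
    stopf("per_factor_counts must have one entry per factor")
  }
  if (any(per_factor_counts < 2 | per_factor_counts > 5)) {
    stopf("per-factor marker counts must lie in 2..5")
  }

  taken <- character(0)
  fac_v <- itm_v <- character(0); load_v <- numeric(0); ovr_v <- logical(0)
  relax_f <- character(0); relax_cap <- numeric(0)

  for (f in seq_len(k)) {
    fname <- colnames(P)[f]
    want <- per_factor_counts[f]
    if (!is.null(overrides) && fname %in% names(overrides)) {
      sel <- overrides[[fname]]
      if (!all(sel %in% rownames(P))) stopf("override items missing from solution")
      fac_v <- c(fac_v, rep(fname, length(sel)))
      itm_v <- c(itm_v, sel)
      load_v <- c(load_v, P[sel, f])
      ovr_v <- c(ovr_v, rep(TRUE, length(sel)))
      taken <- c(taken, sel)
      next
    }
    cap <- cross_loading_cap
    repeat {
      other_max <- apply(abs(P[, -f, drop = FALSE]), 1, max)
      pool <- setdiff(rownames(P)[other_max <= cap], taken)
      if (length(pool) >= want || cap >= 1) break
      cap <- cap + 0.05
      relax_f <- c(relax_f, fname); relax_cap <- c(relax_cap, cap)
    }
    pool <- pool[order(abs(P[pool, f]), decreasing = TRUE)]
    sel <- head(pool, want)
    if (length(sel) < 2) {
      stopf("factor %s has fewer than 2 eligible marker items even after relaxation",
            fname)
    }
    fac_v <- c(fac_v, rep(fname, length(sel)))
    itm_v <- c(itm_v, sel)
    load_v <- c(load_v, P[sel, f])
    ovr_v <- c(ovr_v, rep(FALSE, length(sel)))
    taken <- c(taken, sel)
  }

  markers <- tibble(factor = fac_v, item = itm_v, loading = load_v,
                    overridden = ovr_v)
  bounds <- NULL
  if (!is.null(categories)) {
    bounds <- tibble(item = markers$item,
                     min_code = 1,
                     max_code = as.numeric(categories[markers$item]))
  }
  structure(
    list(markers = markers,
         rescale_bounds = bounds,
         cap_relaxed = tibble(factor = relax_f, cap = relax_cap),
         response_scale = c(0, 4)),
    class = "shortform_spec"
  )
}

#' @export
print.shortform_spec <- function(x, ...) {
  counts <- table(x$markers$factor)
  cat(sprintf("<shortform_spec> %d items over %d factors (%s)\n",
              nrow(x$markers), length(counts),
              paste(counts[unique(x$markers$factor)], collapse = ", ")))
  invisible(x)
}

#' Score the short-form instrument on the 0-4 scale
#'
#' Rescales each marker response to `(x - min_code) / (max_code - min_code) * 4`
#' and averages the rescaled responses within each factor. A person missing
#' any marker of a factor receives a missing score for that factor.
#'
#' @param data Persons x items responses (data frame, matrix or
#'   `battery_data`).
#' @param spec A `shortform_spec` (its `rescale_bounds` must cover all marker
#'   items; pass `categories` to [select_markers()] or set bounds manually).
#' @return Tibble: `person_id` plus one score column (in `[0, 4]` or `NA`) per
#'   factor.
#' @export
score_short_form <- function(data, spec) {
  if (inherits(data, "battery_data")) data <- data$responses
  rm_ <- responses_to_matrix(data)
  X <- rm_$values
  mk <- spec$markers
  if (!all(mk$item %in% colnames(X))) stopf("spec items missing from data")
  if (is.null(spec$rescale_bounds)) stopf("spec has no rescale bounds")
  b <- spec$rescale_bounds
  lo <- setNames(b$min_code, b$item); hi <- setNames(b$max_code, b$item)

  Xs <- X[, mk$item, drop = FALSE]
  out_of_range <- !is.na(Xs) &
    (Xs < rep(lo[mk$item], each = nrow(Xs)) |
       Xs > rep(hi[mk$item], each = nrow(Xs)))
  if (any(out_of_range)) {
    idx <- which(out_of_range, arr.ind = TRUE)[1, ]
    stopf("response outside declared bounds: person %s, item %s",
          rm_$person_id[idx[1]], mk$item[idx[2]])
  }

  factors <- unique(mk$factor)
  scores <- matrix(NA_real_, nrow(X), length(factors),
                   dimnames = list(NULL, factors))
  for (f in factors) {
    its <- mk$item[mk$factor == f]
    Z <- X[, its, drop = FALSE]
    Z <- sweep(Z, 2, lo[its], "-")
    Z <- sweep(Z, 2, (hi[its] - lo[its]), "/") * 4
    scores[, f] <- rowMeans(Z)  # NA if any marker missing
  }
  dplyr::bind_cols(tibble(person_id = rm_$person_id),
                   as_tibble(as.data.frame(scores)))
}

#' Consistency of short-form scores with full-battery scores
#'
#' @param short,full Tibbles of per-person scores (`person_id` + one column
#'   per factor) with matching factor columns.
#' @return Tibble with `factor`, `r` (pairwise-complete Pearson correlation),
#'   `n` complete pairs.
#' @export
consistency_with_full <- function(short, full) {
  common <- intersect(setdiff(names(short), "person_id"),
                      setdiff(names(full), "person_id"))
  if (!length(common)) stopf("no shared factor columns")
  merged <- dplyr::inner_join(short, full, by = "person_id",
                              suffix = c("_short", "_full"))
  purrr::map_dfr(common, function(f) {
    a <- merged[[paste0(f, "_short")]]
    b <- merged[[paste0(f, "_full")]]
    ok <- !is.na(a) & !is.na(b)
    if (sum(ok) < 3) stopf("fewer than 3 complete pairs for factor %s", f)
    tibble(factor = f, r = cor(a[ok], b[ok]), n = sum(ok))
  })
}
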