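#' Threshold estimates for one ordinal item
#'
#' First stage of the two-step polychoric estimator: thresholds are the
#' standard-normal quantiles of the cumulative observed category proportions.
#' Categories never observed are collapsed, so the returned vector is always
#' strictly increasing with one threshold per boundary between *observed*
#' categories.
#'
#' @param x Integer vector of ordinal responses (codes `1..n_categories`),
#'   `NA` allowed.
#' @param n_categories Optional declared category count (used to validate the
#'   codes; thresholds themselves depend only on the observed margin).
#' @return Numeric vector of strictly increasing thresholds.
#' @export
estimate_thresholds <- function(x, n_categories = NULL) {
  x <- x[!is.na(x)]
  if (!length(x)) stopf("no observed responses")
  if (!is.null(n_categories) && (any(x < 1) || any(x > n_categories))) {
    stopf("responses outside 1..%d", n_categories)
  }
  counts <- table(x)
  if (length(counts) < 2) {
    stopf("all responses identical: thresholds undefined")
  }
  p <- cumsum(as.numeric(counts)) / length(x)
  qnorm(p[-length(p)])
}

# Collapse all-empty rows/columns of a contingency table.
collapse_empty <- function(tab) {
  tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
}

thresholds_from_margin <- function(margin) {
  p <- cumsum(margin) / sum(margin)
  qnorm(p[-length(p)])
}

#' Polychoric correlation of one item pair
#'
#' Two-step maximum likelihood on a two-way contingency table: thresholds are
#' fixed (supplied, or computed from the table margins after continuity
#' correction), then the bivariate-normal multinomial log-likelihood is
#' maximized over the correlation alone by Brent search on (-0.999, 0.999).
#' Every zero cell of the (empty-category-collapsed) table is replaced by 0.1
#' as a continuity correction before the likelihood is evaluated.
#'
#' @param tab Two-way contingency table (matrix of nonnegative counts).
#' @param tau_row,tau_col Optional fixed threshold vectors. When omitted they
#'   are recomputed from the corrected table margins.
#' @return List with `rho`, `converged`, `n_zero_corrected`, `tau_row`,
#'   `tau_col`.
#' @export
estimate_polychoric_pair <- function(tab, tau_row = NULL, tau_col = NULL) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) stopf("table must be nonnegative")
  tab <- collapse_empty(tab)
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    stopf("each item needs at least 2 observed categories")
  }
  n_zero <- sum(tab == 0)
  tab[tab == 0] <- 0.1
  if (is.null(tau_row)) tau_row <- thresholds_from_margin(rowSums(tab))
  if (is.null(tau_col)) tau_col <- thresholds_from_margin(colSums(tab))

  opt <- optimize(function(r) cpp_pair_nll(tab, tau_row, tau_col, r),
                  interval = c(-0.999, 0.999), tol = 1e-7)
  rho <- max(min(opt$minimum, 0.999), -0.999)
  list(rho = rho,
       converged = is.finite(opt$objective),
       n_zero_corrected = n_zero,
       tau_row = tau_row, tau_col = tau_col)
}

#' Polychoric correlation matrix of an ordinal battery
#'
#' Pairwise-complete two-step estimation: for every item pair, rows complete on
#' both items are cross-tabulated, empty categories are collapsed, zero cells
#' receive the 0.1 continuity correction, and thresholds are re-estimated from
#' the pair's own margins (the "local thresholds" convention). If the
#' assembled matrix has negative eigenvalues it is smoothed by clipping them
#' at 1e-8, reconstructing, and rescaling to unit diagonal.
#'
#' @param data Persons x items data frame (an optional `person_id` column is
#'   ignored) or integer matrix; or a `battery_data` object.
#' @param smooth Apply eigenvalue-clipping smoothing when needed.
#' @param min_pairs Minimum number of pairwise-complete observations per pair.
#' @return Object of class `polychoric`: list with `rho` (items x items),
#'   `thresholds` (per item, from the full margin), `smoothed`,
#'   `pair_diagnostics` (tibble), `n_obs`.
#' @export
polychoric_matrix <- function(data, smooth = TRUE, min_pairs = 3) {
  if (inherits(data, "battery_data")) data <- data$responses
  rm_ <- responses_to_matrix(data)
  X <- rm_$values
  items <- rm_$item_ids
  p <- ncol(X)
  n <- nrow(X)

  for (j in seq_len(p)) {
    if (length(unique(X[!is.na(X[, j]), j])) < 2) {
      stopf("item %s has a single observed category", items[j])
    }
  }

  rho <- diag(1, p)
  dimnames(rho) <- list(items, items)
  di <- dj <- integer(0); dconv <- logical(0); dzero <- integer(0)

  maxcat <- max(X, na.rm = TRUE)
  for (i in seq_len(p - 1)) {
    xi <- X[, i]
    for (j in seq((i + 1), p)) {
      ok <- !is.na(xi) & !is.na(X[, j])
      if (sum(ok) < min_pairs) {
        stopf("items %s and %s have fewer than %d complete pairs",
              items[i], items[j], min_pairs)
      }
      a <- xi[ok]; b <- X[ok, j]
      tab <- matrix(tabulate((a - 1) * maxcat + b, nbins = maxcat * maxcat),
                    nrow = maxcat, byrow = TRUE)
      est <- estimate_polychoric_pair(tab)
      rho[i, j] <- rho[j, i] <- est$rho
      if (!est$converged || est$n_zero_corrected > 0) {
        di <- c(di, i); dj <- c(dj, j)
        dconv <- c(dconv, est$converged); dzero <- c(dzero, est$n_zero_corrected)
      }
    }
  }

  thresholds <- lapply(seq_len(p), function(j) estimate_thresholds(X[, j]))
  names(thresholds) <- items

  smoothed <- FALSE
  ev <- eigen(rho, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 0 && smooth) {
    rho <- smooth_psd(rho)
    smoothed <- TRUE
  }

  structure(
    list(rho = rho,
         thresholds = thresholds,
         smoothed = smoothed,
         pair_diagnostics = tibble(item_i = items[di], item_j = items[dj],
                                   converged = dconv, n_zero_corrected = dzero),
         n_obs = n),
    class = "polychoric"
  )
}

#' Eigenvalue-clipping smoothing to the nearest unit-diagonal PSD matrix
#'
#' Clips negative eigenvalues at `floor`, reconstructs, and rescales to unit
#' diagonal. Used when an assembled pairwise polychoric matrix is indefinite.
#'
#' @param R Symmetric matrix with unit diagonal.
#' @param floor Replacement for eigenvalues below it.
#' @return Smoothed correlation matrix.
#' @export
smooth_psd <- function(R, floor = 1e-8) {
  e <- eigen(R, symmetric = TRUE)
  vals <- pmax(e$values, floor)
  S <- e$vectors %*% (vals * t(e$vectors))
  S <- cov2cor(S)
  dimnames(S) <- dimnames(R)
  (S + t(S)) / 2
}

#' @export
print.polychoric <- function(x, ...) {
  cat(sprintf("<polychoric> %d items, n = %d%s; %d pair(s) with corrected zero cells\n",
              ncol(x$rho), x$n_obs,
              if (x$smoothed) " (smoothed)" else "",
              sum(x$pair_diagnostics$n_zero_corrected > 0)))
  invisible(x)
}

#' Kaiser-Meyer-Olkin sampling adequacy
#'
#' Contrasts raw correlations with anti-image partial correlations computed
#' from the inverse correlation matrix. Per-item MSA_j is
#' `sum(r_jk^2) / (sum(r_jk^2) + sum(q_jk^2))` over `k != j`; the overall KMO
#' statistic is the analogous ratio over all pairs.
#'
#' @param R Correlation matrix (or a `polychoric` object).
#' @param threshold Retention threshold for per-item MSA (default 0.7).
#' @return Object of class `msa_report`: list with `overall_kmo`, tibble
#'   `per_item` (`item`, `msa`, `retained`), `retained_items`, `threshold`.
#' @export
kmo_msa <- function(R, threshold = 0.7) {
  if (inherits(R, "polychoric")) R <- R$rho
  if (!is_cor_matrix(R)) stopf("R must be a correlation matrix")
  Rinv <- tryCatch(solve(R), error = function(e) stopf("R is singular"))
  Q <- -cov2cor(Rinv)
  diag(Q) <- 0
  R0 <- R; diag(R0) <- 0
  r2 <- R0^2; q2 <- Q^2
  msa <- rowSums(r2) / (rowSums(r2) + rowSums(q2))
  overall <- sum(r2) / (sum(r2) + sum(q2))
  items <- colnames(R) %||% item_labels(ncol(R))
  per_item <- tibble(item = items, msa = unname(msa),
                     retained = unname(msa) >= threshold)
  structure(
    list(overall_kmo = overall,
         per_item = per_item,
         retained_items = per_item$item[per_item$retained],
         threshold = threshold),
    class = "msa_report"
  )
}

#' @export
print.msa_report <- function(x, ...) {
  cat(sprintf("<msa_report> overall KMO = %.3f; %d/%d items retained at MSA >= %g\n",
              x$overall_kmo, length(x$retained_items), nrow(x$per_item),
              x$threshold))
  invisible(x)
}
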