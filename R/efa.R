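#' Parallel analysis for factor retention
#'
#' Compares the eigenvalues of an observed correlation matrix with the
#' distribution of eigenvalues of correlation matrices computed from
#' structureless standard-normal data of the same dimensions. The suggested
#' number of factors is the count of *leading* observed eigenvalues exceeding
#' their simulated quantile (stopping at the first failure).
#'
#' @param R Correlation matrix (or `polychoric` object).
#' @param n_obs Number of observations behind `R`.
#' @param n_reps Number of simulated data sets (>= 20).
#' @param quantile Simulated eigenvalue quantile to beat (default 0.95).
#' @param seed Seed for the simulation stream.
#' @return Object of class `parallel_analysis`: tibble `eigenvalues` (factor,
#'   observed, simulated), `suggested_n_factors`, `n_reps`, `quantile`.
#' @export
parallel_analysis <- function(R, n_obs, n_reps = 200, quantile = 0.95,
                              seed = 1L) {
  if (inherits(R, "polychoric")) { if (missing(n_obs)) n_obs <- R$n_obs; R <- R$rho }
  if (n_reps < 20) stopf("n_reps must be at least 20 for stable quantiles")
  p <- ncol(R)
  if (n_obs <= p) warnf("n_obs <= number of items; simulated quantiles are unstable")
  obs <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  sims <- with_seed(seed, {
    vapply(seq_len(n_reps), function(i) {
      Z <- matrix(rnorm(n_obs * p), n_obs, p)
      eigen(cor(Z), symmetric = TRUE, only.values = TRUE)$values
    }, numeric(p))
  })
  qs <- apply(sims, 1, stats::quantile, probs = quantile, names = FALSE)
  exceeds <- obs > qs
  suggested <- if (exceeds[1]) which.min(c(exceeds, FALSE)) - 1L else 0L
  structure(
    list(eigenvalues = tibble(factor = seq_len(p), observed = obs,
                              simulated = qs),
         suggested_n_factors = as.integer(suggested),
         n_reps = n_reps, quantile = quantile, n_obs = n_obs),
    class = "parallel_analysis"
  )
}

#' @export
print.parallel_analysis <- function(x, ...) {
  cat(sprintf("<parallel_analysis> %d factors suggested (%d reps, %g quantile)\n",
              x$suggested_n_factors, x$n_reps, x$quantile))
  invisible(x)
}

#' Principal-axis factoring
#'
#' Iterates the eigendecomposition of the reduced correlation matrix:
#' communalities start at squared multiple correlations (`1 - 1/diag(R^-1)`),
#' loadings are the leading eigenvectors scaled by the square roots of the
#' eigenvalues, and iteration stops when the largest communality change drops
#' below `tol`. Heywood cases (communality > 1) are clipped and flagged.
#'
#' @param R Correlation matrix (or `polychoric` object).
#' @param k Number of factors (1 <= k < items).
#' @param max_iter,tol Iteration controls.
#' @return List with `loadings` (unrotated, items x k), `uniquenesses`,
#'   `communalities`, `eigenvalues` (of the final reduced matrix),
#'   `converged`, `heywood`, `iterations`.
#' @export
principal_axis_factor <- function(R, k, max_iter = 100, tol = 1e-6) {
  if (inherits(R, "polychoric")) R <- R$rho
  p <- ncol(R)
  if (k < 1 || k >= p) stopf("k must satisfy 1 <= k < items")
  items <- colnames(R) %||% item_labels(p)

  Rinv <- tryCatch(solve(R), error = function(e) NULL)
  h2 <- if (is.null(Rinv)) rep(0.5, p) else pmin(pmax(1 - 1 / diag(Rinv), 0), 1)

  converged <- FALSE
  heywood <- FALSE
  Rr <- R
  it <- 0
  for (it in seq_len(max_iter)) {
    diag(Rr) <- h2
    e <- eigen(Rr, symmetric = TRUE)
    vals <- e$values[seq_len(k)]
    L <- e$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(pmax(vals, 0)), k)
    h2_new <- rowSums(L^2)
    if (any(h2_new > 1)) {
      heywood <- TRUE
      h2_new <- pmin(h2_new, 1)
    }
    delta <- max(abs(h2_new - h2))
    h2 <- h2_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) warnf("principal-axis iteration did not converge in %d steps", max_iter)

  diag(Rr) <- h2
  e <- eigen(Rr, symmetric = TRUE)
  L <- e$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(pmax(e$values[seq_len(k)], 0)), k)
  rownames(L) <- items
  colnames(L) <- paste0("F", seq_len(k))
  list(loadings = L,
       uniquenesses = setNames(1 - h2, items),
       communalities = setNames(h2, items),
       eigenvalues = e$values,
       converged = converged, heywood = heywood, iterations = it)
}

#' Promax rotation of an unrotated loading matrix
#'
#' Kaiser-normalized varimax first, then an oblique least-squares transform to
#' the powered target `sign(L) * |L|^m`, scaled so the implied factor
#' correlation matrix has unit diagonal. Columns are reflected so each
#' factor's largest-magnitude loading is positive and ordered by descending
#' sum of squared structure loadings.
#'
#' @param unrotated Items x k unrotated loading matrix, or the list returned
#'   by [principal_axis_factor()].
#' @param m Promax power (default 4).
#' @return Object of class `factor_solution` with `pattern`, `structure`,
#'   `phi`, `uniquenesses`, `communalities`, `eigenvalues`, `var_explained`,
#'   `rotation`, `n_obs` (NA unless set by the caller).
#' @export
promax_rotate <- function(unrotated, m = 4) {
  paf <- NULL
  if (is.list(unrotated) && !is.null(unrotated$loadings)) {
    paf <- unrotated
    unrotated <- paf$loadings
  }
  k <- ncol(unrotated)
  if (k < 2) stopf("promax needs at least 2 factors")

  vm <- stats::varimax(unrotated, normalize = TRUE)
  X <- unclass(vm$loadings)

  target <- sign(X) * abs(X)^m
  U <- tryCatch(solve(crossprod(X), crossprod(X, target)),
                error = function(e) NULL)
  fallback <- FALSE
  if (is.null(U) || any(!is.finite(U)) ||
      inherits(tryCatch(solve(crossprod(U)), error = function(e) e), "error")) {
    fallback <- TRUE
    P <- X
    phi <- diag(k)
  } else {
    d <- diag(solve(crossprod(U)))
    U <- U %*% diag(sqrt(d), k)
    P <- X %*% U
    phi <- solve(crossprod(U))
    phi <- (phi + t(phi)) / 2
  }

  # sign convention: largest |loading| per factor positive
  for (f in seq_len(k)) {
    s <- sign(P[which.max(abs(P[, f])), f])
    if (s < 0) {
      P[, f] <- -P[, f]
      phi[f, ] <- -phi[f, ]; phi[, f] <- -phi[, f]
    }
  }
  S <- P %*% phi
  ord <- order(colSums(S^2), decreasing = TRUE)
  P <- P[, ord, drop = FALSE]; phi <- phi[ord, ord, drop = FALSE]
  S <- S[, ord, drop = FALSE]
  colnames(P) <- colnames(S) <- paste0("F", seq_len(k))
  dimnames(phi) <- list(colnames(P), colnames(P))

  h2 <- if (!is.null(paf)) paf$communalities else rowSums(unrotated^2)
  sol <- structure(
    list(pattern = P, structure = S, phi = phi,
         uniquenesses = 1 - h2, communalities = h2,
         eigenvalues = if (!is.null(paf)) paf$eigenvalues else NULL,
         rotation = if (fallback) "varimax (promax fallback)" else
           sprintf("promax (m = %g)", m),
         converged = if (!is.null(paf)) paf$converged else NA,
         heywood = if (!is.null(paf)) paf$heywood else NA,
         n_obs = NA_integer_),
    class = "factor_solution"
  )
  sol$var_explained <- variance_explained(sol)
  sol
}

#' Exploratory factor analysis: principal axis + promax
#'
#' Convenience wrapper chaining [principal_axis_factor()] and
#' [promax_rotate()].
#'
#' @inheritParams principal_axis_factor
#' @inheritParams promax_rotate
#' @param n_obs Optional observation count stored on the solution.
#' @return A `factor_solution`.
#' @export
efa_promax <- function(R, k, m = 4, max_iter = 100, tol = 1e-6, n_obs = NA) {
  if (inherits(R, "polychoric")) { if (is.na(n_obs)) n_obs <- R$n_obs; R <- R$rho }
  sol <- promax_rotate(principal_axis_factor(R, k, max_iter, tol), m = m)
  sol$n_obs <- as.integer(n_obs)
  sol
}

#' Variance explained by each factor
#'
#' Under an oblique rotation the per-factor explained variance is the sum of
#' the products of pattern and structure loadings divided by the number of
#' items; the factor contributions then sum exactly to the mean communality
#' (so the cumulative proportion never exceeds 1), and for an orthogonal
#' solution this reduces to the usual sum of squared loadings. The convention
#' is recorded in the output.
#'
#' @param solution A `factor_solution`.
#' @return Tibble with `factor`, `proportion`, `cumulative`, and an attribute
#'   `convention`.
#' @export
variance_explained <- function(solution) {
  S <- solution$structure
  P <- solution$pattern
  prop <- colSums(P * S) / nrow(S)
  out <- tibble(factor = colnames(S), proportion = unname(prop),
                cumulative = cumsum(unname(prop)))
  attr(out, "convention") <-
    "sum of pattern x structure loading products / items"
  out
}

#' Salient items per factor
#'
#' @param solution A `factor_solution`.
#' @param threshold Salience threshold on `|pattern loading|` (default 0.32).
#' @return Tibble with `factor`, `item`, `loading` for every pattern loading
#'   with `|loading| >= threshold`.
#' @export
salience_map <- function(solution, threshold = 0.32) {
  P <- solution$pattern
  long <- tibble(
    item = rep(rownames(P), times = ncol(P)),
    factor = rep(colnames(P), each = nrow(P)),
    loading = as.vector(P)
  )
  out <- long[abs(long$loading) >= threshold, c("factor", "item", "loading")]
  attr(out, "threshold") <- threshold
  out
}

#' Loading-weighted factor scores
#'
#' Each person's score on a factor is the sum of their item responses
#' multiplied by the factor's pattern loadings over *all* items. A person
#' missing a response on any item whose `|loading|` reaches the salience
#' threshold on a factor receives a missing score for that factor;
#' non-salient missing items simply drop out of the sum.
#'
#' @param data Persons x items data frame / matrix (or `battery_data`).
#' @param solution A `factor_solution` whose items match the data columns.
#' @param salience Threshold controlling missingness propagation.
#' @return Tibble: `person_id` plus one numeric column per factor.
#' @export
weighted_factor_scores <- function(data, solution, salience = 0.32) {
  if (inherits(data, "battery_data")) data <- data$responses
  rm_ <- responses_to_matrix(data)
  X <- rm_$values
  P <- solution$pattern
  if (!setequal(colnames(X), rownames(P))) stopf("data items do not match solution items")
  X <- X[, rownames(P), drop = FALSE]

  X0 <- X; X0[is.na(X0)] <- 0
  scores <- X0 %*% P
  if (anyNA(X)) {
    for (f in seq_len(ncol(P))) {
      salient <- abs(P[, f]) >= salience
      if (any(salient)) {
        bad <- rowSums(is.na(X[, salient, drop = FALSE])) > 0
        scores[bad, f] <- NA_real_
      }
    }
  }
  dplyr::bind_cols(tibble(person_id = rm_$person_id),
                   as_tibble(as.data.frame(scores)))
}

#' Tucker congruence between two loading matrices
#'
#' Column-wise cosine similarity after optimal one-to-one factor matching
#' (greedy assignment on absolute congruence), with sign alignment. Used to
#' assess recovery of a generating loading pattern.
#'
#' @param A,B Items x k loading matrices on the same items.
#' @return Tibble with `factor_a`, `factor_b`, `congruence` (signed, after
#'   alignment).
#' @export
tucker_congruence <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  C <- crossprod(A, B) /
    outer(sqrt(colSums(A^2)), sqrt(colSums(B^2)))
  k <- ncol(A)
  fa <- integer(k); fb <- integer(k); cg <- numeric(k)
  Cw <- abs(C)
  for (i in seq_len(k)) {
    idx <- which(Cw == max(Cw), arr.ind = TRUE)[1, ]
    fa[i] <- idx[1]; fb[i] <- idx[2]
    cg[i] <- abs(C[idx[1], idx[2]])
    Cw[idx[1], ] <- -Inf; Cw[, idx[2]] <- -Inf
  }
  ord <- order(fa)
  tibble(factor_a = colnames(A)[fa][ord] %||% fa[ord],
         factor_b = colnames(B)[fb][ord] %||% fb[ord],
         congruence = cg[ord])
}

#' @export
print.factor_solution <- function(x, ...) {
  cat(sprintf("<factor_solution> %d items, %d factors, %s\n",
              nrow(x$pattern), ncol(x$pattern), x$rotation))
  cat(sprintf("  cumulative variance explained: %.1f%%\n",
              100 * max(x$var_explained$cumulative)))
  invisible(x)
}
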