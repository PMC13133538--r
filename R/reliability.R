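#' Cronbach's alpha
#'
#' `alpha = k/(k-1) * (1 - sum(item variances) / variance of the sum)` on the
#' item covariance matrix.
#'
#' @param S Item covariance (or correlation) matrix.
#' @param items Optional character/integer subset of items (default: all).
#' @return Numeric alpha.
#' @export
cronbach_alpha <- function(S, items = NULL) {
  if (!is.null(items)) S <- S[items, items, drop = FALSE]
  kk <- ncol(S)
  if (kk < 2) stopf("alpha needs at least 2 items")
  total <- sum(S)
  if (total <= 0) stopf("total score has zero variance")
  kk / (kk - 1) * (1 - sum(diag(S)) / total)
}

#' McDonald's omega (total)
#'
#' `omega_total = (sum lambda)^2 / ((sum lambda)^2 + sum psi)` from a
#' one-factor maximum-likelihood fit of the item subset; alternatively supply
#' `lambda` and `psi` directly.
#'
#' @param S Item covariance/correlation matrix (ignored when `lambda` given).
#' @param items Optional item subset.
#' @param n_obs Observations behind `S` (used by the one-factor fit).
#' @param lambda,psi Optional explicit one-factor loadings and uniquenesses.
#' @return Numeric omega.
#' @export
omega_total <- function(S = NULL, items = NULL, n_obs = 1000,
                        lambda = NULL, psi = NULL) {
  if (is.null(lambda)) {
    if (!is.null(items)) S <- S[items, items, drop = FALSE]
    fit <- fit_one_factor(S, n_obs)
    lambda <- fit$lambda
    psi <- fit$psi
  }
  s <- sum(lambda)
  s^2 / (s^2 + sum(psi))
}

# direct one-factor ML fit (no factor correlations to estimate)
fit_one_factor <- function(S, n_obs) {
  p <- ncol(S)
  pc1 <- eigen(S, symmetric = TRUE)$vectors[, 1]
  sgn <- ifelse(pc1 >= 0, 1, -1)
  if (sum(sgn) < 0) sgn <- -sgn
  start <- c(0.7 * sgn * sqrt(diag(S)), log(0.51 * diag(S)))
  fn <- function(th) {
    l <- th[seq_len(p)]; ps <- exp(th[p + seq_len(p)])
    Sg <- tcrossprod(l); diag(Sg) <- diag(Sg) + ps
    ch <- tryCatch(chol(Sg), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    2 * sum(log(diag(ch))) + sum(chol2inv(ch) * S)
  }
  gr <- function(th) {
    l <- th[seq_len(p)]; ps <- exp(th[p + seq_len(p)])
    Sg <- tcrossprod(l); diag(Sg) <- diag(Sg) + ps
    ch <- tryCatch(chol(Sg), error = function(e) NULL)
    if (is.null(ch)) return(rep(0, 2 * p))
    Sinv <- chol2inv(ch)
    G <- Sinv - Sinv %*% S %*% Sinv
    c(2 * (G %*% l)[, 1], diag(G) * ps)
  }
  res <- nlminb(start, fn, gr, control = list(iter.max = 500, rel.tol = 1e-12))
  if (res$objective >= 1e9) stopf("one-factor fit did not converge")
  l <- res$par[seq_len(p)]
  if (sum(l) < 0) l <- -l
  list(lambda = l, psi = exp(res$par[p + seq_len(p)]), objective = res$objective)
}

#' Reliability report for a dimensional instrument
#'
#' Overall and per-dimension Cronbach's alpha, McDonald's omega total from a
#' one-factor fit of all items, and (optionally) omega hierarchical from an
#' explicit higher-order model via the Schmid-Leiman projection
#' (item general-factor loading = lambda_j * gamma_f(j)). Omega hierarchical
#' is experimental: it depends on the higher-order fit being appropriate.
#'
#' @param S Item covariance/correlation matrix.
#' @param assignment Named list: dimension -> item ids.
#' @param n_obs Observations behind `S`.
#' @param hierarchical Also compute omega hierarchical.
#' @return Object of class `reliability_report`: list with `alpha_total`,
#'   `alpha_by_dimension` (tibble), `omega_total`, `omega_hierarchical`.
#' @export
reliability_report <- function(S, assignment, n_obs, hierarchical = FALSE) {
  items <- unlist(assignment, use.names = FALSE)
  S <- S[items, items]
  alpha_dim <- purrr::map_dfr(names(assignment), function(f) {
    tibble(dimension = f, alpha = cronbach_alpha(S, assignment[[f]]))
  })
  omega_h <- NULL
  if (hierarchical) {
    fit <- fit_cfa(S, n_obs, cfa_spec(assignment, type = "higher_order"))
    gam <- fit$parameters$estimate[fit$parameters$type == "higher_order_loading"]
    names(gam) <- fit$parameters$factor[fit$parameters$type == "higher_order_loading"]
    gen <- fit$lambda * gam[unlist(lapply(names(assignment), function(f) {
      rep(f, length(assignment[[f]]))
    }))]
    omega_h <- sum(gen)^2 / sum(fit$implied)
  }
  structure(
    list(alpha_total = cronbach_alpha(S),
         alpha_by_dimension = alpha_dim,
         omega_total = omega_total(S, n_obs = n_obs),
         omega_hierarchical = omega_h),
    class = "reliability_report"
  )
}

#' @export
print.reliability_report <- function(x, ...) {
  cat(sprintf("<reliability_report> alpha = %.3f, omega_total = %.3f%s\n",
              x$alpha_total, x$omega_total,
              if (!is.null(x$omega_hierarchical))
                sprintf(", omega_h = %.3f", x$omega_hierarchical) else ""))
  invisible(x)
}
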