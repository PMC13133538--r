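#' Specify a congeneric confirmatory factor model
#'
#' Each item loads on exactly one factor (simple structure). Factor
#' correlations are either free or generated by a higher-order general factor
#' (`Phi = gamma gamma' + diag(1 - gamma^2)`).
#'
#' @param assignment Named list: factor name -> character vector of item ids.
#' @param type `"free"` (correlated factors) or `"higher_order"`.
#' @return Object of class `cfa_spec`.
#' @export
cfa_spec <- function(assignment, type = c("free", "higher_order")) {
  type <- match.arg(type)
  if (any(duplicated(unlist(assignment)))) {
    stopf("every item must load on exactly one factor")
  }
  sizes <- lengths(assignment)
  if (any(sizes < 2)) stopf("each factor needs at least 2 items")
  if (type == "higher_order" && length(assignment) < 3) {
    stopf("a higher-order layer needs at least 3 first-order factors")
  }
  structure(list(assignment = assignment, type = type), class = "cfa_spec")
}

#' Merge factors of a CFA specification
#'
#' Produces the restricted model in which the named factors collapse into one
#' (their items load on a single common factor) — nested in the original.
#'
#' @param spec A `cfa_spec`.
#' @param factors Character vector (>= 2) of factor names to merge.
#' @param name Name of the merged factor.
#' @return A `cfa_spec`.
#' @export
merge_factors <- function(spec, factors, name = paste(factors, collapse = "_")) {
  if (!all(factors %in% names(spec$assignment))) stopf("unknown factor name")
  merged <- unlist(spec$assignment[factors], use.names = FALSE)
  rest <- spec$assignment[setdiff(names(spec$assignment), factors)]
  rest[[name]] <- merged
  cfa_spec(rest, type = spec$type)
}

# Build simple-structure index: for item j, which factor it loads on.
spec_index <- function(spec) {
  items <- unlist(spec$assignment, use.names = FALSE)
  fac <- rep(names(spec$assignment), lengths(spec$assignment))
  list(items = items, factor_of = setNames(fac, items),
       factors = names(spec$assignment))
}

# ML discrepancy and analytic gradient for the congeneric model.
cfa_objective <- function(S, fidx, k, p, type) {
  n_phi <- if (type == "free") k * (k - 1) / 2 else k
  lower_idx <- which(lower.tri(matrix(0, k, k)))

  unpack <- function(theta) {
    lambda <- theta[seq_len(p)]
    phi_par <- theta[p + seq_len(n_phi)]
    psi <- exp(theta[p + n_phi + seq_len(p)])
    if (type == "free") {
      phi <- diag(k)
      phi[lower_idx] <- phi_par
      phi <- phi + t(phi) - diag(diag(phi))
      gamma <- NULL
    } else {
      gamma <- tanh(phi_par)  # keep |gamma| < 1
      phi <- tcrossprod(gamma)
      diag(phi) <- 1
    }
    L <- matrix(0, p, k)
    L[cbind(seq_len(p), fidx)] <- lambda
    list(lambda = lambda, phi = phi, psi = psi, L = L, gamma = gamma)
  }

  sigma_of <- function(par) {
    Sg <- par$L %*% par$phi %*% t(par$L)
    diag(Sg) <- diag(Sg) + par$psi
    Sg
  }

  fn <- function(theta) {
    par <- unpack(theta)
    Sg <- sigma_of(par)
    ch <- tryCatch(chol(Sg), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    logdet <- 2 * sum(log(diag(ch)))
    Sinv <- chol2inv(ch)
    val <- logdet + sum(Sinv * S)
    if (!is.finite(val)) 1e10 else val
  }

  gr <- function(theta) {
    par <- unpack(theta)
    Sg <- sigma_of(par)
    ch <- tryCatch(chol(Sg), error = function(e) NULL)
    if (is.null(ch)) return(rep(0, length(theta)))
    Sinv <- chol2inv(ch)
    G <- Sinv - Sinv %*% S %*% Sinv
    GLP <- G %*% par$L %*% par$phi
    g_lambda <- 2 * GLP[cbind(seq_len(p), fidx)]
    M <- t(par$L) %*% G %*% par$L
    if (type == "free") {
      g_phi <- 2 * M[lower_idx]
    } else {
      gam <- par$gamma
      g_gamma <- 2 * (M %*% gam)[, 1] - 2 * diag(M) * gam
      g_phi <- g_gamma * (1 - gam^2)  # chain rule through tanh
    }
    g_psi <- diag(G) * par$psi
    c(g_lambda, g_phi, g_psi)
  }

  list(fn = fn, gr = gr, unpack = unpack, sigma_of = sigma_of, n_phi = n_phi)
}

#' Fit a confirmatory factor model by normal-theory maximum likelihood
#'
#' Minimizes the ML discrepancy
#' `F = log|Sigma| + tr(S Sigma^-1) - log|S| - p` from a deterministic start
#' (loadings 0.7 x sign of the first principal component, uniquenesses at 51%
#' of the item variances), with seeded jittered restarts on failure.
#' `chi^2 = (n - 1) F`; CFI/TLI are computed against the independence
#' baseline, RMSEA from the noncentrality estimate, and SRMR as the root mean
#' square residual of the standardized (correlation-scale) matrices.
#'
#' @param S Covariance or correlation matrix of the items (labeled).
#' @param n_obs Number of observations behind `S`.
#' @param spec A [cfa_spec()].
#' @param max_restarts Jittered restarts attempted on non-convergence.
#' @return Object of class `cfa_fit`.
#' @export
fit_cfa <- function(S, n_obs, spec, max_restarts = 5) {
  idx <- spec_index(spec)
  if (!all(idx$items %in% colnames(S))) stopf("spec items missing from S")
  S <- S[idx$items, idx$items]
  p <- length(idx$items)
  k <- length(idx$factors)
  fidx <- match(idx$factor_of[idx$items], idx$factors)
  obj <- cfa_objective(S, fidx, k, p, spec$type)

  pc1 <- eigen(S, symmetric = TRUE)$vectors[, 1]
  sgn <- ifelse(pc1 >= 0, 1, -1)
  if (sum(sgn) < 0) sgn <- -sgn
  start <- c(0.7 * sgn * sqrt(diag(S)),
             rep(if (spec$type == "free") 0.3 else atanh(0.5), obj$n_phi),
             log(0.51 * diag(S)))

  fit <- NULL
  for (attempt in 0:max_restarts) {
    th0 <- if (attempt == 0) start else {
      with_seed(1000 + attempt, start + rnorm(length(start), 0, 0.05))
    }
    res <- nlminb(th0, obj$fn, obj$gr,
                  control = list(iter.max = 1000, eval.max = 2000,
                                 rel.tol = 1e-12))
    if (res$objective < 1e9 && (is.null(fit) || res$objective < fit$objective)) {
      fit <- res
    }
    if (!is.null(fit) && res$convergence == 0 && res$objective < 1e9) break
  }
  if (is.null(fit)) stopf("CFA optimization failed to produce a valid solution")
  converged <- fit$convergence == 0

  par <- obj$unpack(fit$par)
  # sign convention: majority of loadings per factor positive
  for (f in seq_len(k)) {
    rows <- which(fidx == f)
    if (sum(par$L[rows, f]) < 0) {
      par$L[rows, f] <- -par$L[rows, f]
      par$lambda[rows] <- -par$lambda[rows]
      par$phi[f, -f] <- -par$phi[f, -f]; par$phi[-f, f] <- -par$phi[-f, f]
      if (!is.null(par$gamma)) par$gamma[f] <- -par$gamma[f]
    }
  }
  Sg <- obj$sigma_of(par)

  logdetS <- determinant(S, logarithm = TRUE)$modulus[1]
  Fmin <- fit$objective - logdetS - p
  Fmin <- max(Fmin, 0)
  n_free <- p + obj$n_phi + p
  df <- p * (p + 1) / 2 - n_free
  chisq <- (n_obs - 1) * Fmin

  # independence baseline
  Fb <- sum(log(diag(S))) - logdetS
  dfb <- p * (p + 1) / 2 - p
  chisq_b <- (n_obs - 1) * max(Fb, 0)

  num <- max(chisq - df, 0)
  den <- max(chisq_b - dfb, chisq - df, 0)
  cfi <- if (den == 0) 1 else 1 - num / den
  tli <- if (chisq_b / dfb - 1 <= 0 || df == 0) 1 else {
    (chisq_b / dfb - chisq / df) / (chisq_b / dfb - 1)
  }
  cfi <- min(max(cfi, 0), 1); tli <- min(max(tli, 0), 1)
  rmsea <- if (df > 0) sqrt(max(chisq - df, 0) / (df * (n_obs - 1))) else 0
  Rres <- cov2cor(S) - cov2cor(Sg)
  srmr <- sqrt(sum(Rres[lower.tri(Rres, diag = TRUE)]^2) / (p * (p + 1) / 2))
  loglik <- -0.5 * (n_obs - 1) *
    (fit$objective + p * log(2 * pi))

  params <- dplyr::bind_rows(
    tibble(type = "loading", item = idx$items,
           factor = idx$factor_of[idx$items], estimate = par$lambda),
    if (spec$type == "free") {
      lw <- which(lower.tri(par$phi), arr.ind = TRUE)
      tibble(type = "factor_correlation", item = NA_character_,
             factor = paste(idx$factors[lw[, 2]], idx$factors[lw[, 1]],
                            sep = "~"),
             estimate = par$phi[lw])
    } else {
      tibble(type = "higher_order_loading", item = NA_character_,
             factor = idx$factors, estimate = par$gamma)
    },
    tibble(type = "uniqueness", item = idx$items,
           factor = idx$factor_of[idx$items], estimate = par$psi)
  )

  structure(
    list(chi_square = chisq, df = df, p_value = pchisq(chisq, df, lower.tail = FALSE),
         cfi = cfi, tli = tli, rmsea = rmsea, srmr = srmr,
         discrepancy = Fmin, loglik = loglik, n_obs = n_obs,
         converged = converged,
         baseline = list(chi_square = chisq_b, df = dfb),
         parameters = params,
         lambda = setNames(par$lambda, idx$items),
         phi = structure(par$phi, dimnames = list(idx$factors, idx$factors)),
         psi = setNames(par$psi, idx$items),
         implied = structure(Sg, dimnames = list(idx$items, idx$items)),
         spec = spec),
    class = "cfa_fit"
  )
}

#' @export
print.cfa_fit <- function(x, ...) {
  cat(sprintf(
    "<cfa_fit> %d items, %d factors (%s): chi2(%d) = %.2f, CFI = %.3f, TLI = %.3f, RMSEA = %.3f, SRMR = %.3f\n",
    length(x$lambda), length(x$spec$assignment), x$spec$type,
    x$df, x$chi_square, x$cfi, x$tli, x$rmsea, x$srmr))
  invisible(x)
}

#' Likelihood-ratio comparison of nested CFA models
#'
#' @param fit_general,fit_restricted `cfa_fit` objects on the same matrix and
#'   sample size, restricted nested in general.
#' @return Tibble with `delta_chi_square`, `delta_df`, `p_value`,
#'   `boundary_flag` (TRUE when the statistic came out negative and was
#'   clipped, indicating a boundary or convergence issue).
#' @export
compare_nested <- function(fit_general, fit_restricted) {
  if (fit_general$n_obs != fit_restricted$n_obs) {
    stopf("fits use different sample sizes")
  }
  d_chi <- fit_restricted$chi_square - fit_general$chi_square
  d_df <- fit_restricted$df - fit_general$df
  if (d_df < 0) stopf("restricted model must have fewer free parameters")
  boundary <- d_chi < 0
  if (boundary) d_chi <- 0
  p <- if (d_df == 0) 1 else pchisq(d_chi, d_df, lower.tail = FALSE)
  tibble(delta_chi_square = d_chi, delta_df = d_df, p_value = p,
         boundary_flag = boundary)
}
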