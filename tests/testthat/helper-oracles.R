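# Independent oracles and small fixtures used across tests.

# Bivariate-normal cell probabilities via mvtnorm (independent of the
# package's own CDF), for the grid-search polychoric oracle.
oracle_cell_probs <- function(tau_r, tau_c, rho) {
  a <- c(-Inf, tau_r, Inf)
  b <- c(-Inf, tau_c, Inf)
  corr <- matrix(c(1, rho, rho, 1), 2)
  P <- matrix(0, length(a) - 1, length(b) - 1)
  for (i in seq_len(nrow(P))) {
    for (j in seq_len(ncol(P))) {
      P[i, j] <- mvtnorm::pmvnorm(lower = c(a[i], b[j]),
                                  upper = c(a[i + 1], b[j + 1]),
                                  corr = corr)[1]
    }
  }
  P
}

oracle_loglik <- function(tab, tau_r, tau_c, rho) {
  P <- oracle_cell_probs(tau_r, tau_c, rho)
  sum(tab * log(pmax(P, 1e-300)))
}

# Grid-search ML oracle: coarse pass over the full grid, then the exact
# 0.001-step grid in a window around the coarse argmax (the likelihood is
# unimodal in rho).
oracle_polychoric_grid <- function(tab, step = 0.001) {
  tab <- as.matrix(tab)
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  tab[tab == 0] <- 0.1
  pr <- cumsum(rowSums(tab)) / sum(tab)
  pc <- cumsum(colSums(tab)) / sum(tab)
  tau_r <- qnorm(pr[-length(pr)])
  tau_c <- qnorm(pc[-length(pc)])
  coarse <- seq(-0.99, 0.99, by = 0.02)
  ll <- vapply(coarse, function(r) oracle_loglik(tab, tau_r, tau_c, r), 0)
  r0 <- coarse[which.max(ll)]
  fine <- seq(max(-0.999, r0 - 0.04), min(0.999, r0 + 0.04), by = step)
  llf <- vapply(fine, function(r) oracle_loglik(tab, tau_r, tau_c, r), 0)
  fine[which.max(llf)]
}

# random two-way ordinal table from a latent bivariate normal
random_ordinal_table <- function(n, rho, cat_r, cat_c, seed) {
  withr::with_seed(seed, {
    z <- matrix(rnorm(2 * n), n, 2) %*% chol(matrix(c(1, rho, rho, 1), 2))
    tr <- sort(runif(cat_r - 1, -1.2, 1.2))
    tc <- sort(runif(cat_c - 1, -1.2, 1.2))
    x <- findInterval(z[, 1], tr) + 1
    y <- findInterval(z[, 2], tc) + 1
    table(factor(x, levels = 1:cat_r), factor(y, levels = 1:cat_c))
  })
}

# one-factor correlation matrix lambda lambda' + diag(1 - lambda^2)
one_factor_R <- function(lambda, p) {
  R <- tcrossprod(rep(lambda, p))
  diag(R) <- 1
  dimnames(R) <- list(item_labels_t(p), item_labels_t(p))
  R
}

item_labels_t <- function(n, prefix = "item") sprintf("%s_%03d", prefix, seq_len(n))

# the hand-traced 6-item reduction fixture (see test-reduction for the trace)
reduction_fixture <- function() {
  nm <- c("a", "b", "c", "d", "e", "f")
  R <- diag(1, 6)
  dimnames(R) <- list(nm, nm)
  set_r <- function(i, j, v) {
    R[i, j] <<- v
    R[j, i] <<- v
  }
  set_r("a", "b", 0.92); set_r("c", "d", 0.77); set_r("e", "f", 0.62)
  set_r("a", "c", 0.30); set_r("a", "d", 0.20); set_r("a", "e", 0.10)
  set_r("a", "f", 0.05); set_r("b", "c", 0.25); set_r("b", "d", 0.15)
  set_r("b", "e", 0.08); set_r("b", "f", 0.04); set_r("c", "e", 0.40)
  set_r("c", "f", 0.35); set_r("d", "e", 0.30); set_r("d", "f", 0.25)
  R
}

# random labeled correlation matrix (PD), for property tests
random_cor <- function(p, seed) {
  withr::with_seed(seed, {
    A <- matrix(rnorm(p * p), p)
    R <- cov2cor(crossprod(A) + p * diag(p))
    dimnames(R) <- list(item_labels_t(p), item_labels_t(p))
    R
  })
}

# small study-like config with a replicate seed
preset_with_seed <- function(seed) {
  cfg <- preset_study_like()
  cfg$seed <- as.integer(seed)
  cfg
}

# true marker -> dimension assignment of the preset (first 27 items)
preset_marker_assignment <- function(cfg = preset_study_like()) {
  L <- cfg$loadings
  markers <- which(apply(abs(L), 1, max) >= 0.32)
  fac <- colnames(L)[apply(abs(L[markers, ]), 1, which.max)]
  split(rownames(L)[markers], fac)[unique(fac)]
}

# 0-4 rescaled covariance matrix of a set of items
rescaled_cov <- function(data, items, categories) {
  X <- as.matrix(as.data.frame(data$responses)[, items])
  hi <- categories[items]
  Z <- sweep(sweep(X, 2, 1, "-"), 2, hi - 1, "/") * 4
  Z <- Z[stats::complete.cases(Z), , drop = FALSE]
  list(S = stats::cov(Z), n = nrow(Z))
}

# oblique reference solution with exact model-implied correlations
random_oblique_solution <- function(p, k, seed) {
  withr::with_seed(seed, {
    A <- matrix(rnorm(k * k), k)
    phi <- cov2cor(crossprod(A) + k * diag(k))
    L <- matrix(0, p, k)
    for (j in seq_len(p)) L[j, 1 + (j - 1) %% k] <- runif(1, 0.4, 0.8)
    rownames(L) <- item_labels_t(p)
    colnames(L) <- paste0("F", seq_len(k))
    R <- L %*% phi %*% t(L)
    diag(R) <- 1
    list(solution = structure(list(pattern = L, phi = phi),
                              class = "factor_solution"),
         R = R)
  })
}
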