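#' EBIC-selected regularized partial-correlation network
#'
#' Graphical-lasso precision estimation over a descending log-spaced penalty
#' path from `lambda_max` (the smallest penalty giving an empty graph) down to
#' `lambda_max * lambda_min_ratio`, with the Extended Bayesian Information
#' Criterion `EBIC = -2 loglik + E log(n) + 4 gamma E log(p)` (E = nonzero
#' upper-triangle precision entries) selecting the penalty. Edge weights are
#' the regularized partial correlations `-omega_ij / sqrt(omega_ii omega_jj)`.
#' Input correlations are Pearson correlations of the observed columns on
#' listwise-complete rows.
#'
#' @param data Tibble/data frame of the node variables (an optional
#'   `person_id` column is dropped).
#' @param gamma EBIC hyperparameter (default 0.5).
#' @param n_lambdas,lambda_min_ratio Penalty path controls.
#' @param penalize_diag Penalize the precision diagonal (default FALSE).
#' @return Object of class `pcor_network`: `weights` (nodes x nodes partial
#'   correlations), `lambda_selected`, `ebic_gamma`, `path` (tibble: lambda,
#'   ebic, n_edges, converged), `precision`, `nodes`, `n_obs`, and the
#'   complete-case `data` used (kept for bootstrapping).
#' @export
ebic_glasso_network <- function(data, gamma = 0.5, n_lambdas = 100,
                                lambda_min_ratio = 0.01,
                                penalize_diag = FALSE) {
  df <- as.data.frame(data)
  df$person_id <- NULL
  df <- df[complete.cases(df), , drop = FALSE]
  n <- nrow(df); p <- ncol(df)
  if (n < 3 * p) warnf("fewer than 3x nodes complete rows (%d for %d nodes)", n, p)
  X <- as.matrix(df)
  S <- cor(X)
  fit <- glasso_ebic_select(S, n, gamma, n_lambdas, lambda_min_ratio,
                            penalize_diag)
  structure(
    list(weights = fit$weights, precision = fit$omega,
         lambda_selected = fit$lambda, ebic_gamma = gamma,
         path = fit$path, nodes = colnames(S), n_obs = n,
         cor_input = S, data = as_tibble(df),
         n_lambdas = n_lambdas, lambda_min_ratio = lambda_min_ratio,
         penalize_diag = penalize_diag, bootstrap = NULL),
    class = "pcor_network"
  )
}

# path + EBIC selection on a correlation matrix
glasso_ebic_select <- function(S, n, gamma, n_lambdas, lambda_min_ratio,
                               penalize_diag = FALSE) {
  p <- ncol(S)
  lambda_max <- max(abs(S[upper.tri(S)]))
  lambdas <- exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
                     length.out = n_lambdas))
  res <- cpp_glasso_path(S, lambdas, penalize_diag)
  ebic <- rep(Inf, n_lambdas)
  n_edges <- integer(n_lambdas)
  for (l in seq_len(n_lambdas)) {
    if (!res$converged[l]) next
    Om <- res$omega[[l]]
    ch <- tryCatch(chol(Om), error = function(e) NULL)
    if (is.null(ch)) next
    E <- sum(abs(Om[upper.tri(Om)]) > 1e-10)
    ll <- (n / 2) * (2 * sum(log(diag(ch))) - sum(S * Om))
    ebic[l] <- -2 * ll + E * log(n) + 4 * gamma * E * log(p)
    n_edges[l] <- E
  }
  if (all(!is.finite(ebic))) stopf("graphical lasso failed at every penalty")
  best <- which.min(ebic)
  Om <- res$omega[[best]]
  W <- -Om / sqrt(tcrossprod(diag(Om)))
  diag(W) <- 0
  W[abs(W) < 1e-10] <- 0
  dimnames(W) <- dimnames(S)
  dimnames(Om) <- dimnames(S)
  list(weights = W, omega = Om, lambda = lambdas[best],
       path = tibble(lambda = lambdas, ebic = ebic, n_edges = n_edges,
                     converged = as.logical(res$converged)))
}

#' @export
print.pcor_network <- function(x, ...) {
  E <- sum(abs(x$weights[upper.tri(x$weights)]) > 0)
  cat(sprintf("<pcor_network> %d nodes, %d edges, lambda = %.4f (EBIC gamma = %g)%s\n",
              length(x$nodes), E, x$lambda_selected, x$ebic_gamma,
              if (!is.null(x$bootstrap)) " [bootstrap-thresholded]" else ""))
  invisible(x)
}

#' Bootstrap edge thresholding of a partial-correlation network
#'
#' Resamples persons with replacement, refits the full EBIC-selected
#' graphical lasso per resample (including penalty re-selection), computes
#' per-edge `(level/2, 1 - level/2)` quantile intervals of the bootstrap edge
#' weights, and sets to zero every edge whose interval covers 0.
#'
#' @param network A `pcor_network` from [ebic_glasso_network()].
#' @param n_boot Number of bootstrap resamples (>= 100; the reference
#'   procedure used 2000).
#' @param level Significance level of the interval rule (default 0.05).
#' @param seed Seed for the resampling stream.
#' @return The network with `weights` thresholded, original point estimates in
#'   `weights_unthresholded`, and a `bootstrap` tibble (`node_a`, `node_b`,
#'   `weight`, `q_low`, `q_high`, `retained`).
#' @export
bootstrap_threshold <- function(network, n_boot = 2000, level = 0.05,
                                seed = 1L) {
  if (!inherits(network, "pcor_network")) stopf("network must be a pcor_network")
  if (n_boot < 100) stopf("n_boot must be at least 100")
  X <- as.matrix(network$data)
  n <- nrow(X); p <- ncol(X)
  ut <- which(upper.tri(network$weights))

  boot_w <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      Sb <- tryCatch(cor(X[idx, , drop = FALSE]), error = function(e) NULL)
      if (is.null(Sb) || anyNA(Sb)) return(rep(NA_real_, length(ut)))
      fb <- tryCatch(
        glasso_ebic_select(Sb, n, network$ebic_gamma, network$n_lambdas,
                           network$lambda_min_ratio, network$penalize_diag),
        error = function(e) NULL)
      if (is.null(fb)) return(rep(NA_real_, length(ut)))
      fb$weights[ut]
    }, numeric(length(ut)))
  })

  q_low <- apply(boot_w, 1, quantile, probs = level / 2, na.rm = TRUE)
  q_high <- apply(boot_w, 1, quantile, probs = 1 - level / 2, na.rm = TRUE)
  w <- network$weights[ut]
  retained <- !(q_low <= 0 & q_high >= 0) & w != 0

  W <- network$weights
  W[ut][!retained] <- 0
  W[lower.tri(W)] <- t(W)[lower.tri(W)]

  rc <- arrayInd(ut, dim(network$weights))
  network$weights_unthresholded <- network$weights
  network$weights <- W
  network$bootstrap <- tibble(
    node_a = network$nodes[rc[, 1]], node_b = network$nodes[rc[, 2]],
    weight = w, q_low = q_low, q_high = q_high, retained = retained
  )
  network$n_boot <- n_boot
  network$level <- level
  network
}

#' Export a network as an edge list
#'
#' @param network A `pcor_network`.
#' @param keep_zero Include zero-weight pairs.
#' @return Tibble: `node_a`, `node_b`, `weight` (plus bootstrap columns when
#'   available).
#' @export
network_edges <- function(network, keep_zero = FALSE) {
  W <- network$weights
  ut <- which(upper.tri(W))
  rc <- arrayInd(ut, dim(W))
  out <- tibble(node_a = network$nodes[rc[, 1]],
                node_b = network$nodes[rc[, 2]],
                weight = W[ut])
  if (!is.null(network$bootstrap)) {
    out <- dplyr::left_join(out,
                            network$bootstrap[, c("node_a", "node_b", "q_low",
                                                  "q_high", "retained")],
                            by = c("node_a", "node_b"))
  }
  if (!keep_zero) out <- out[out$weight != 0, ]
  out
}

#' Write a network as GraphML
#'
#' Minimal GraphML serialization (node ids plus a `weight` edge attribute)
#' readable by igraph, Gephi or Cytoscape.
#'
#' @param network A `pcor_network`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_network_graphml <- function(network, path) {
  edges <- network_edges(network)
  esc <- function(x) gsub("&", "&amp;", gsub("<", "&lt;", x))
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    '  <key id="w" for="edge" attr.name="weight" attr.type="double"/>',
    '  <graph edgedefault="undirected">',
    sprintf('    <node id="%s"/>', esc(network$nodes)),
    sprintf('    <edge source="%s" target="%s"><data key="w">%.10g</data></edge>',
            esc(edges$node_a), esc(edges$node_b), edges$weight),
    '  </graph>',
    '</graphml>'
  )
  writeLines(lines, path)
  invisible(path)
}
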