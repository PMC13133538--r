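test_that("parallel analysis flags no factors in structureless data and all-ones spectra", {
  R <- diag(1, 15)
  dimnames(R) <- list(item_labels_t(15), item_labels_t(15))
  pa <- parallel_analysis(R, n_obs = 1000, n_reps = 50, seed = 1)
  expect_equal(pa$eigenvalues$observed, rep(1, 15))
  expect_equal(pa$suggested_n_factors, 0L)

  noise <- withr::with_seed(2, cor(matrix(rnorm(1000 * 20), 1000, 20)))
  pa2 <- parallel_analysis(noise, n_obs = 1000, n_reps = 100, seed = 3)
  expect_equal(pa2$suggested_n_factors, 0L)

  expect_error(parallel_analysis(R, 1000, n_reps = 10), "at least 20")
})

test_that("parallel analysis recovers the rank of clean three-factor data", {
  L <- matrix(0, 15, 3)
  for (f in 1:3) L[(f - 1) * 5 + 1:5, f] <- 0.7
  cfg <- battery_config(1000, L, item_category_counts = rep(5L, 15), seed = 11L)
  d <- generate_battery(cfg)
  R <- cor(as.matrix(d$responses[, -1]))
  pa <- parallel_analysis(R, n_obs = 1000, n_reps = 100, seed = 4)
  expect_equal(pa$suggested_n_factors, 3L)
})

test_that("principal-axis factoring reproduces exact low-rank structures", {
  R <- one_factor_R(0.8, 10)
  paf <- principal_axis_factor(R, 1)
  expect_lt(max(abs(abs(paf$loadings) - 0.8)), 1e-4)
  expect_true(paf$converged)

  # rank-2 structure
  L <- cbind(c(rep(0.7, 5), rep(0, 5)), c(rep(0, 5), rep(0.6, 5)))
  R2 <- tcrossprod(L); diag(R2) <- 1
  dimnames(R2) <- list(item_labels_t(10), item_labels_t(10))
  paf2 <- principal_axis_factor(R2, 2)
  Rhat <- tcrossprod(paf2$loadings)
  diag(Rhat) <- diag(Rhat) + paf2$uniquenesses
  expect_lt(max(abs(Rhat - R2)[upper.tri(R2)]), 1e-4)

  # robustness at k = items - 1
  R3 <- random_cor(6, seed = 9)
  paf3 <- suppressWarnings(principal_axis_factor(R3, 5))
  expect_true(all(paf3$communalities <= 1 + 1e-10))
})

test_that("promax leaves perfect simple structure fixed and recovers oblique factor correlations", {
  L <- cbind(c(rep(0.7, 5), rep(0, 5)), c(rep(0, 5), rep(0.6, 5)))
  rownames(L) <- item_labels_t(10)
  sol <- promax_rotate(L)
  ord <- apply(abs(sol$pattern), 2, which.max) > 5
  P <- sol$pattern[, order(ord)]
  expect_lt(max(abs(abs(P) - L)), 1e-6)
  expect_lt(max(abs(sol$phi[upper.tri(sol$phi)])), 1e-6)

  # oblique recovery from generated ordinal data
  phi <- matrix(c(1, 0.5, 0.5, 1), 2)
  cfg <- battery_config(5000, L, phi, rep(5L, 10), seed = 13L)
  d <- generate_battery(cfg)
  sol2 <- efa_promax(polychoric_matrix(d$responses), k = 2, n_obs = 5000)
  expect_lt(abs(abs(sol2$phi[1, 2]) - 0.5), 0.07)
})

test_that("promax with power 1 degenerates to the varimax solution", {
  R <- random_cor(9, seed = 5)
  paf <- principal_axis_factor(R, 2)
  sol <- promax_rotate(paf, m = 1)
  expect_lt(max(abs(sol$phi - diag(2))), 1e-8)
})

test_that("the model fit is invariant to rotation", {
  cfg <- preset_with_seed(8L)
  d <- generate_battery(cfg)
  poly <- polychoric_matrix(d$responses)
  paf <- principal_axis_factor(poly$rho, 7)
  sol <- promax_rotate(paf)
  fit_un <- tcrossprod(paf$loadings)
  fit_rot <- sol$pattern %*% sol$phi %*% t(sol$pattern)
  expect_lt(max(abs(fit_un - fit_rot)), 1e-8)
})

test_that("variance explained follows the stated closed forms", {
  sol1 <- promax_rotate(cbind(rep(0.8, 10), rep(0, 10)))
  ve <- variance_explained(sol1)
  expect_equal(sum(ve$proportion), 0.64, tolerance = 1e-10)

  # orthogonal case: equals SS pattern loadings / items
  L <- cbind(c(rep(0.7, 5), rep(0, 5)), c(rep(0, 5), rep(0.6, 5)))
  sol2 <- promax_rotate(L)
  expect_equal(sort(variance_explained(sol2)$proportion),
               sort(unname(colSums(sol2$pattern^2) / 10)), tolerance = 1e-5)

  # cumulative proportion is nondecreasing and bounded by 1
  cfg <- preset_with_seed(17L)
  sol3 <- efa_promax(polychoric_matrix(generate_battery(cfg)$responses),
                     k = 7, n_obs = 467)
  cum <- variance_explained(sol3)$cumulative
  expect_true(all(diff(cum) >= -1e-12))
  expect_lte(max(cum), 1 + 1e-8)
})

test_that("salient-item maps are exact filters of the pattern matrix", {
  cfg <- preset_with_seed(23L)
  sol <- efa_promax(polychoric_matrix(generate_battery(cfg)$responses),
                    k = 7, n_obs = 467)
  sm <- salience_map(sol, threshold = 0.32)
  expect_true(all(abs(sm$loading) >= 0.32))
  expect_equal(nrow(sm), sum(abs(sol$pattern) >= 0.32))
})

test_that("weighted factor scores are the loading-weighted response sums with per-factor missingness", {
  P <- cbind(F1 = c(1, 0, 0), F2 = c(0, 1, 0.5))
  rownames(P) <- c("i1", "i2", "i3")
  sol <- structure(list(pattern = P), class = "factor_solution")
  X <- tibble::tibble(person_id = 1:3, i1 = c(0, 2, 1), i2 = c(0, 1, 3),
                      i3 = c(0, 4, 2))
  sc <- weighted_factor_scores(X, sol)
  expect_equal(sc$F1, c(0, 2, 1))                     # one-hot selector
  expect_equal(sc$F2, c(0, 1 + 2, 3 + 1))            # hand product
  expect_equal(unlist(sc[1, -1]), c(F1 = 0, F2 = 0)) # all-zero responses

  # missing salient item kills the factor score; non-salient missing drops out
  X$i2[2] <- NA
  sc2 <- weighted_factor_scores(X, sol, salience = 0.32)
  expect_true(is.na(sc2$F2[2]))
  expect_equal(sc2$F1[2], 2)
  X2 <- X; X2$i3[3] <- NA
  sc3 <- weighted_factor_scores(X2, sol, salience = 0.6)
  expect_equal(sc3$F2[3], 3)   # i3 loading 0.5 below salience 0.6: dropped
})

test_that("factor recovery on the study-like preset reaches high congruence", {
  cfg <- preset_with_seed(29L)
  d <- generate_battery(cfg)
  sol <- suppressWarnings(efa_promax(polychoric_matrix(d$responses), k = 7,
                                     n_obs = 467))
  tc <- tucker_congruence(cfg$loadings, sol$pattern)
  expect_true(all(tc$congruence >= 0.95))
})
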