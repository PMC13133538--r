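toy_sigma <- function(lambda = 0.7, phi12 = 0.4, per_factor = 4) {
  p <- 2 * per_factor
  L <- matrix(0, p, 2)
  L[1:per_factor, 1] <- lambda
  L[per_factor + 1:per_factor, 2] <- lambda
  phi <- matrix(c(1, phi12, phi12, 1), 2)
  S <- L %*% phi %*% t(L)
  diag(S) <- 1
  dimnames(S) <- list(item_labels_t(p), item_labels_t(p))
  S
}

toy_spec <- function(per_factor = 4) {
  cfa_spec(list(F1 = item_labels_t(2 * per_factor)[1:per_factor],
                F2 = item_labels_t(2 * per_factor)[per_factor + 1:per_factor]))
}

test_that("a model-implied matrix is fit perfectly with exact parameter recovery", {
  S <- toy_sigma()
  fit <- fit_cfa(S, 500, toy_spec())
  expect_lt(fit$discrepancy, 1e-8)
  expect_equal(fit$cfi, 1)
  expect_equal(fit$rmsea, 0)
  expect_lt(fit$srmr, 1e-4)
  expect_lt(max(abs(fit$lambda - 0.7)), 1e-3)
  expect_lt(abs(fit$phi[1, 2] - 0.4), 1e-3)
  expect_lt(max(abs(fit$psi - 0.51)), 1e-3)
  # df accounting: p(p+1)/2 moments minus free parameters
  expect_equal(fit$df, 8 * 9 / 2 - (8 + 1 + 8))
})

test_that("fit indices degrade for a misspecified merged model and CFI stays in [0,1]", {
  cfg <- preset_with_seed(41L)
  d <- generate_battery(cfg)
  assignment <- preset_marker_assignment(cfg)
  cats <- setNames(d$items$n_categories, d$items$item_id)
  rc <- rescaled_cov(d, unlist(assignment, use.names = FALSE), cats)
  fit7 <- fit_cfa(rc$S, rc$n, cfa_spec(assignment))
  fit6 <- fit_cfa(rc$S, rc$n,
                  merge_factors(cfa_spec(assignment),
                                c("somatic", "sudomotor")))
  expect_gt(fit7$cfi, fit6$cfi)
  expect_true(fit6$cfi >= 0 && fit6$cfi <= 1)
  cmp <- compare_nested(fit7, fit6)
  expect_equal(cmp$delta_df, 6)
  expect_lt(cmp$p_value, 0.05)
})

test_that("identical models compare as no improvement", {
  S <- toy_sigma()
  fit <- fit_cfa(S, 300, toy_spec())
  cmp <- compare_nested(fit, fit)
  expect_equal(cmp$delta_chi_square, 0)
  expect_equal(cmp$p_value, 1)
})

test_that("a higher-order layer fits worse when factor correlations are not proportional", {
  # 4 factors with block-structured Phi, far from the rank-1-plus-diagonal
  # form a single general factor can induce
  L <- matrix(0, 12, 4)
  for (f in 1:4) L[(f - 1) * 3 + 1:3, f] <- 0.75
  phi <- diag(1, 4)
  phi[1, 2] <- phi[2, 1] <- 0.7
  phi[3, 4] <- phi[4, 3] <- 0.7
  phi[phi == 0] <- 0.05
  diag(phi) <- 1
  S <- L %*% phi %*% t(L); diag(S) <- 1
  dimnames(S) <- list(item_labels_t(12), item_labels_t(12))
  assignment <- split(item_labels_t(12), rep(paste0("F", 1:4), each = 3))
  free <- fit_cfa(S, 500, cfa_spec(assignment))
  ho <- fit_cfa(S, 500, cfa_spec(assignment, type = "higher_order"))
  expect_gt(ho$chi_square - free$chi_square, 0)
  cmp <- compare_nested(free, ho)
  expect_equal(cmp$delta_df, 2)
  expect_lt(cmp$p_value, 0.05)
})

test_that("fit statistics are invariant to item order", {
  cfg <- preset_with_seed(43L)
  d <- generate_battery(cfg)
  assignment <- preset_marker_assignment(cfg)
  items <- unlist(assignment, use.names = FALSE)
  cats <- setNames(d$items$n_categories, d$items$item_id)
  rc <- rescaled_cov(d, items, cats)
  fit1 <- fit_cfa(rc$S, rc$n, cfa_spec(assignment))
  perm <- withr::with_seed(1, sample(items))
  fit2 <- fit_cfa(rc$S[perm, perm], rc$n, cfa_spec(assignment))
  expect_equal(fit1$rmsea, fit2$rmsea, tolerance = 1e-6)
  expect_equal(fit1$srmr, fit2$srmr, tolerance = 1e-6)
  expect_equal(fit1$chi_square, fit2$chi_square, tolerance = 1e-4)
})

test_that("Cronbach's alpha matches its closed forms", {
  # k = 4 parallel items, r = 0.5: Spearman-Brown 4*0.5 / (1 + 3*0.5) = 0.8
  S <- matrix(0.5, 4, 4); diag(S) <- 1
  expect_equal(cronbach_alpha(S), 0.8, tolerance = 1e-12)

  expect_equal(cronbach_alpha(diag(1, 5)), 0, tolerance = 1e-12)

  S2 <- matrix(1, 2, 2)
  expect_equal(cronbach_alpha(S2), 1, tolerance = 1e-12)
})

test_that("omega total matches direct arithmetic and its limits", {
  expect_equal(omega_total(lambda = rep(0.8, 4), psi = rep(0.36, 4)),
               3.2^2 / (3.2^2 + 1.44), tolerance = 1e-12)
  expect_equal(omega_total(lambda = rep(0, 4), psi = rep(1, 4)), 0)
  expect_equal(omega_total(lambda = rep(0.7, 4), psi = rep(0, 4)), 1)

  # one-factor ML fit route on an exact one-factor matrix
  S <- one_factor_R(0.8, 6)
  expect_equal(omega_total(S, n_obs = 500),
               (6 * 0.8)^2 / ((6 * 0.8)^2 + 6 * 0.36), tolerance = 1e-4)
})

test_that("alpha approximates omega for tau-equivalent data", {
  S <- withr::with_seed(47, {
    L <- rep(0.7, 8)
    Sig <- tcrossprod(L); diag(Sig) <- 1
    X <- matrix(rnorm(5000 * 8), 5000, 8) %*% chol(Sig)
    cov(X)
  })
  dimnames(S) <- list(item_labels_t(8), item_labels_t(8))
  expect_lt(abs(cronbach_alpha(S) - omega_total(S, n_obs = 5000)), 0.01)
})

test_that("reliability reports cover per-dimension alpha and omega hierarchical", {
  cfg <- preset_with_seed(53L)
  d <- generate_battery(cfg)
  assignment <- preset_marker_assignment(cfg)
  cats <- setNames(d$items$n_categories, d$items$item_id)
  rc <- rescaled_cov(d, unlist(assignment, use.names = FALSE), cats)
  rel <- reliability_report(rc$S, assignment, rc$n, hierarchical = TRUE)
  expect_equal(nrow(rel$alpha_by_dimension), 7)
  expect_true(all(rel$alpha_by_dimension$alpha > 0.5))
  expect_true(rel$omega_total > 0.8 && rel$omega_total <= 1)
  expect_true(rel$omega_hierarchical > 0 && rel$omega_hierarchical < 1)
})
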