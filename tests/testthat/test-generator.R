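test_that("identical seed reproduces identical data; missingness obeys the rate", {
  cfg <- preset_study_like()
  d1 <- generate_battery(cfg)
  d2 <- generate_battery(cfg)
  expect_identical(d1$responses, d2$responses)
  expect_identical(d1$severities, d2$severities)
  expect_identical(d1$external, d2$external)

  cfg0 <- battery_config(
    n_persons = 200,
    loadings = matrix(0.6, 6, 1),
    item_category_counts = rep(4L, 6),
    missing_rate = 0
  )
  expect_false(anyNA(generate_battery(cfg0)$responses))
})

test_that("marginal category proportions follow the normal-CDF increments of the thresholds", {
  tau <- qnorm(c(0.30, 0.55, 0.75, 0.92))
  cfg <- battery_config(
    n_persons = 1e5,
    loadings = matrix(0.7, 1, 1),
    item_category_counts = 5L,
    item_thresholds = list(tau),
    seed = 42L
  )
  x <- generate_battery(cfg)$responses$item_001
  props <- tabulate(x, 5) / length(x)
  expected <- diff(c(0, pnorm(tau), 1))
  expect_lt(max(abs(props - expected)), 0.01)
})

test_that("severity outcomes reproduce the population R-squared implied by the betas", {
  cfg <- preset_study_like()
  cfg$n_persons <- 5000L
  cfg$seed <- 99L
  d <- generate_battery(cfg)
  B <- cfg$severity_betas
  phi <- cfg$factor_correlations
  expl <- diag(B %*% phi %*% t(B))
  r2_true <- expl / (expl + cfg$severity_noise_sd^2)
  f <- as.matrix(d$factors[, colnames(B)])
  for (o in rownames(B)) {
    r2_emp <- summary(lm(d$severities[[o]] ~ f))$r.squared
    expect_lt(abs(r2_emp - r2_true[o]), 0.03)
  }
})

test_that("zero loadings produce uncorrelated items", {
  cfg <- battery_config(
    n_persons = 1000,
    loadings = matrix(0, 12, 2),
    item_category_counts = rep(5L, 12),
    seed = 7L
  )
  poly <- polychoric_matrix(generate_battery(cfg)$responses)
  off <- poly$rho[upper.tri(poly$rho)]
  expect_lt(max(abs(off)), 0.1)
})

test_that("empirical polychoric matrix matches the model-implied correlation structure", {
  k <- 7
  L <- matrix(0, 21, k)
  for (f in seq_len(k)) L[(f - 1) * 3 + 1:3, f] <- 0.7
  for (seed in c(1L, 2L)) {  # second seed = independent re-simulation
    cfg <- battery_config(2000, L, preset_study_like()$factor_correlations,
                          rep(5L, 21), seed = seed)
    d <- generate_battery(cfg)
    implied <- L %*% cfg$factor_correlations %*% t(L)
    diag(implied) <- 1
    poly <- polychoric_matrix(d$responses)
    expect_lt(max(abs(poly$rho - implied)), 0.08)
  }
})

test_that("study battery preset mirrors the reported item composition", {
  cfg <- study_battery_config()
  expect_equal(nrow(cfg$loadings), 221)
  counts <- table(cfg$item_category_counts)
  expect_equal(unname(counts[c("2", "4", "5")]), c(12, 91, 118),
               ignore_attr = TRUE)
  expect_equal(cfg$n_persons, 467L)
})

test_that("study-like preset is frozen with the reported sample and factor structure", {
  cfg <- preset_study_like()
  expect_identical(cfg, preset_study_like())
  expect_equal(cfg$n_persons, 467L)
  off <- cfg$factor_correlations[upper.tri(cfg$factor_correlations)]
  expect_true(all(off >= 0.14 & off <= 0.57))
  # 27 salient markers (|loading| >= 0.32), everything else sub-salient
  expect_equal(sum(apply(abs(cfg$loadings), 1, max) >= 0.32), 27)
})

test_that("invalid configurations are rejected", {
  bad_phi <- matrix(c(1, 1.2, 1.2, 1), 2)
  expect_error(
    battery_config(100, matrix(0.5, 4, 2), bad_phi, rep(4L, 4)),
    "positive definite"
  )
  expect_error(
    battery_config(100, matrix(0.5, 4, 1), item_category_counts = rep(4L, 4),
                   item_thresholds = rep(list(c(1, 0, -1)), 4)),
    "increasing"
  )
  expect_error(
    battery_config(100, matrix(0.9, 4, 2),
                   matrix(c(1, 0.9, 0.9, 1), 2), rep(4L, 4)),
    "uniqueness"
  )
})

test_that("battery round-trips to disk with its ground truth", {
  dir <- withr::local_tempdir()
  cfg <- battery_config(50, matrix(0.6, 4, 1), item_category_counts = rep(4L, 4),
                        severity_betas = matrix(0.5, 1, 1), seed = 5L)
  d <- generate_battery(cfg)
  paths <- write_battery(d, dir)
  expect_true(all(file.exists(paths)))
  truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_equal(truth$n_persons, 50)
  expect_equal(unlist(truth$loadings), rep(0.6, 4), ignore_attr = TRUE)
})
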