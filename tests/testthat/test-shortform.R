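make_solution <- function(P) {
  structure(list(pattern = P, phi = diag(ncol(P))), class = "factor_solution")
}

test_that("marker selection honours the loading and cross-loading rules", {
  P <- rbind(
    i1 = c(0.70, 0.10), i2 = c(0.65, 0.05), i3 = c(0.50, 0.40),
    i4 = c(0.60, 0.20), i5 = c(0.05, 0.80), i6 = c(0.10, 0.75),
    i7 = c(0.00, 0.55), i8 = c(0.20, 0.45)
  )
  colnames(P) <- c("F1", "F2")
  spec <- select_markers(make_solution(P), per_factor_counts = c(3, 3),
                         categories = setNames(rep(5L, 8), rownames(P)))
  f1 <- spec$markers$item[spec$markers$factor == "F1"]
  # i3 (cross-loading 0.40 > 0.32) is ineligible; i1, i2, i4 selected
  expect_setequal(f1, c("i1", "i2", "i4"))
  expect_false("i3" %in% spec$markers$item)
  expect_equal(nrow(spec$cap_relaxed), 0)
})

test_that("planted markers are recovered from a synthetic solution", {
  k <- 3
  P <- matrix(0.05, 12, k)
  planted <- list(F1 = 1:2, F2 = 5:6, F3 = 9:10)
  for (f in seq_len(k)) P[planted[[f]], f] <- 0.8
  rownames(P) <- item_labels_t(12)
  colnames(P) <- names(planted)
  spec <- select_markers(make_solution(P), per_factor_counts = c(2, 2, 2),
                         categories = setNames(rep(4L, 12), rownames(P)))
  for (f in names(planted)) {
    expect_setequal(spec$markers$item[spec$markers$factor == f],
                    rownames(P)[planted[[f]]])
  }
})

test_that("insufficient pools relax the cap in recorded steps or fail loudly", {
  P <- rbind(i1 = c(0.8, 0.40), i2 = c(0.7, 0.35),
             i3 = c(0.35, 0.8), i4 = c(0.40, 0.7))
  colnames(P) <- c("F1", "F2")
  spec <- select_markers(make_solution(P), per_factor_counts = c(2, 2),
                         categories = setNames(rep(5L, 4), rownames(P)))
  expect_gt(nrow(spec$cap_relaxed), 0)
  expect_equal(nrow(spec$markers), 4)
})

test_that("short-form scores are 0-4 rescaled marker means with strict missingness", {
  spec <- structure(list(
    markers = tibble::tibble(factor = rep("F1", 4),
                             item = paste0("i", 1:4),
                             loading = rep(0.8, 4), overridden = FALSE),
    rescale_bounds = tibble::tibble(item = paste0("i", 1:4),
                                    min_code = 1, max_code = 5),
    response_scale = c(0, 4)
  ), class = "shortform_spec")
  X <- tibble::tibble(person_id = 1:4,
                      i1 = c(5, 1, 1, NA), i2 = c(5, 1, 3, 2),
                      i3 = c(5, 1, 5, 2), i4 = c(5, 1, 5, 2))
  sc <- score_short_form(X, spec)
  expect_equal(sc$F1[1], 4)            # all markers at maximum
  expect_equal(sc$F1[2], 0)            # all markers at minimum
  expect_equal(sc$F1[3], mean(c(0, 2, 4, 4)))  # (1,3,5,5) -> 2.5
  expect_true(is.na(sc$F1[4]))         # any missing marker -> missing score

  X_bad <- X; X_bad$i1[2] <- 6
  expect_error(score_short_form(X_bad, spec), "outside declared bounds")
})

test_that("rescaling is invariant to the original coding range and marker order", {
  base_spec <- function(bounds, items = paste0("i", 1:2)) {
    structure(list(
      markers = tibble::tibble(factor = "F1", item = items,
                               loading = 0.8, overridden = FALSE),
      rescale_bounds = tibble::tibble(item = items,
                                      min_code = bounds[1], max_code = bounds[2]),
      response_scale = c(0, 4)
    ), class = "shortform_spec")
  }
  X14 <- tibble::tibble(person_id = 1:3, i1 = c(1, 2, 4), i2 = c(4, 3, 1))
  X03 <- tibble::tibble(person_id = 1:3, i1 = c(0, 1, 3), i2 = c(3, 2, 0))
  s14 <- score_short_form(X14, base_spec(c(1, 4)))
  s03 <- score_short_form(X03, base_spec(c(0, 3)))
  expect_equal(s14$F1, s03$F1)

  rev_spec <- base_spec(c(1, 4), items = c("i2", "i1"))
  expect_equal(score_short_form(X14, rev_spec)$F1, s14$F1)
})

test_that("consistency with full-battery scores is affine-invariant and null-calibrated", {
  withr::with_seed(31, {
    full <- tibble::tibble(person_id = 1:300, F1 = rnorm(300), F2 = rnorm(300))
    short <- tibble::tibble(person_id = 1:300,
                            F1 = 0.5 * full$F1 + 2,
                            F2 = rnorm(300))
    cons <- consistency_with_full(short, full)
    expect_equal(cons$r[cons$factor == "F1"], 1, tolerance = 1e-12)
    expect_lt(abs(cons$r[cons$factor == "F2"]), 0.15)
  })
})

test_that("short-form scores track full-battery scores on the study-like preset", {
  cfg <- preset_with_seed(37L)
  d <- generate_battery(cfg)
  sol <- suppressWarnings(
    efa_promax(polychoric_matrix(d$responses), k = 7, n_obs = 467))
  cats <- setNames(d$items$n_categories, d$items$item_id)
  spec <- select_markers(sol, categories = cats)
  sf <- score_short_form(d$responses, spec)
  ws <- weighted_factor_scores(d$responses, sol)
  cons <- consistency_with_full(sf, ws)
  expect_true(all(cons$r >= 0.8))
  expect_true(all(sf[, -1] >= 0 & sf[, -1] <= 4, na.rm = TRUE))
})
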