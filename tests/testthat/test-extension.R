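test_that("an external duplicate of an original item reproduces its pattern row", {
  for (k in c(2, 7)) {
    for (s in 1:3) {
      obj <- random_oblique_solution(p = 3 * k, k = k, seed = 80 + 10 * k + s)
      R_eo <- obj$R[1:4, , drop = FALSE]
      rownames(R_eo) <- paste0("ext", 1:4)
      ext <- extend_loadings(obj$R, obj$solution, R_eo)
      expect_lt(max(abs(ext$pattern - obj$solution$pattern[1:4, ])), 1e-6)
    }
  }
})

test_that("uncorrelated external items get zero loadings and the map is linear", {
  obj <- random_oblique_solution(p = 9, k = 3, seed = 91)
  zero_row <- matrix(0, 1, 9, dimnames = list("ext1", rownames(obj$solution$pattern)))
  ext0 <- extend_loadings(obj$R, obj$solution, zero_row)
  expect_equal(max(abs(ext0$pattern)), 0)

  r1 <- obj$R[1, , drop = FALSE]; rownames(r1) <- "e1"
  r2 <- obj$R[5, , drop = FALSE]; rownames(r2) <- "e2"
  ravg <- (r1 + r2) / 2; rownames(ravg) <- "avg"
  e1 <- extend_loadings(obj$R, obj$solution, r1)$pattern
  e2 <- extend_loadings(obj$R, obj$solution, r2)$pattern
  eavg <- extend_loadings(obj$R, obj$solution, ravg)$pattern
  expect_equal(unname(eavg), unname((e1 + e2) / 2), tolerance = 1e-10)
})

test_that("a planted external item recovers its generating loading", {
  # extension loadings shrink by A/(1+A) with A = sum(lambda^2/psi) per
  # factor, so the reference battery must determine its factors well:
  # 12 items at 0.85 gives A ~ 31 (attenuation ~ 3%)
  k <- 3
  L <- matrix(0, 36, k)
  for (f in 1:k) L[(f - 1) * 12 + 1:12, f] <- 0.85
  Le <- matrix(0, 1, k); Le[1, 2] <- 0.7
  rownames(Le) <- "ext_001"
  cfg <- battery_config(5000, L, diag(k),
                        item_category_counts = rep(5L, 36),
                        external_loadings = Le,
                        external_category_counts = 5L,
                        seed = 97L)
  d <- generate_battery(cfg)
  comb <- dplyr::inner_join(d$responses, d$external, by = "person_id")
  poly <- polychoric_matrix(comb)
  orig <- rownames(cfg$loadings)
  sol <- efa_promax(poly$rho[orig, orig], k = k, n_obs = 5000)
  ext <- extend_loadings(poly$rho[orig, orig], sol,
                         poly$rho["ext_001", orig, drop = FALSE])
  prim <- which.max(abs(ext$pattern[1, ]))
  expect_lt(abs(abs(ext$pattern[1, prim]) - 0.7), 0.05)
  expect_lt(max(abs(ext$pattern[1, -prim])), 0.15)
})

test_that("the indicator selection rule is applied verbatim and monotone", {
  L <- rbind(e1 = c(0.50, 0.10, 0.00),
             e2 = c(0.50, 0.40, 0.00),
             e3 = c(0.44, 0.10, 0.00),
             e4 = c(0.00, 0.00, -0.60))
  colnames(L) <- paste0("F", 1:3)
  spec <- select_indicators(L, min_items = 1)
  expect_setequal(spec$items$item, c("e1", "e4"))  # e2 cross, e3 sub-primary
  expect_equal(spec$items$dimension[spec$items$item == "e4"], "F3")

  spec_hi <- select_indicators(L, primary_min = 0.55, min_items = 1)
  expect_true(all(spec_hi$items$item %in% spec$items$item))
  expect_error(select_indicators(L, primary_min = 0.3, cross_max = 0.32),
               "exceed")
})

test_that("indicator scores rescale to 0-4 with item-wise missing exclusion", {
  spec <- structure(list(
    items = tibble::tibble(dimension = rep("F1", 3),
                           item = paste0("e", 1:3), loading = 0.6),
    representable = tibble::tibble(dimension = "F1", n_items = 3L,
                                   representable = TRUE),
    primary_min = 0.45, cross_max = 0.32, min_items = 3
  ), class = "indicator_spec")
  X <- tibble::tibble(person_id = 1:3,
                      e1 = c(5, 1, NA), e2 = c(5, 3, NA), e3 = c(5, 5, NA))
  cats <- c(e1 = 5L, e2 = 5L, e3 = 5L)
  sc <- score_indicators(X, spec, cats)
  expect_equal(sc$F1[1], 4)                 # all items at maximum
  expect_equal(sc$F1[2], mean(c(0, 2, 4)))  # rescaled (0, 2, 4) -> 2
  expect_true(is.na(sc$F1[3]))              # nothing answered

  X$e1[2] <- NA   # refusal-coded response: excluded from the mean
  sc2 <- score_indicators(X, spec, cats)
  expect_equal(sc2$F1[2], mean(c(2, 4)))
})

test_that("indicator validity against reference scores behaves at both extremes", {
  withr::with_seed(101, {
    ref <- tibble::tibble(person_id = 1:300, F1 = rnorm(300))
    ind <- tibble::tibble(person_id = 1:300, F1 = ref$F1)
    expect_equal(validate_indicators(ind, ref)$r, 1, tolerance = 1e-12)
    ind_perm <- ind
    ind_perm$person_id <- sample(ind_perm$person_id)
    expect_lt(abs(validate_indicators(ind_perm, ref)$r), 0.15)
  })
})

test_that("the study-like external block yields three representable, valid dimensions", {
  cfg <- preset_with_seed(103L)
  d <- generate_battery(cfg)
  mk <- rownames(cfg$loadings)[1:27]
  comb <- dplyr::inner_join(d$responses[, c("person_id", mk)], d$external,
                            by = "person_id")
  poly <- polychoric_matrix(comb)
  sol <- suppressWarnings(efa_promax(poly$rho[mk, mk], k = 7, n_obs = 467))
  exti <- setdiff(names(d$external), "person_id")
  el <- extend_loadings(poly$rho[mk, mk], sol, poly$rho[exti, mk])
  isp <- select_indicators(el)
  expect_equal(sum(isp$representable$representable), 3)
  iscores <- score_indicators(d$external, isp,
                              setNames(cfg$external_category_counts, exti))
  cats <- setNames(d$items$n_categories, d$items$item_id)
  sf <- score_short_form(d$responses, select_markers(sol, categories = cats))
  val <- validate_indicators(iscores, sf)
  expect_true(all(val$r >= 0.7))
})
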