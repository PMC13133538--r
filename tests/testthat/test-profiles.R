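test_that("screener classification thresholds exactly at the cut-points", {
  sev <- tibble::tibble(person_id = 1:4,
                        ISI = c(10, 9, 0, 28),
                        ASRS = c(3, 4, 0, 6),
                        MDD = c(0, 0, 0, 20))
  cls <- classify_probable_disorders(sev)
  expect_true(cls$classification$ISI[1])    # ISI = 10 is positive
  expect_false(cls$classification$ASRS[1])  # ASRS = 3 is negative
  expect_true(cls$classification$ASRS[2])
  expect_equal(cls$classification$n_positive[3], 0)
  expect_equal(cls$counts$n[cls$counts$category == "none"], 1)
  expect_equal(cls$counts$n[cls$counts$category == "multiple"], 1)
  expect_equal(cls$counts$n[cls$counts$category == "one"], 2)
  expect_error(classify_probable_disorders(tibble::tibble(XYZ = 1)),
               "no cut-point")
})

test_that("noiseless outcomes are recovered exactly with standardized coefficients", {
  d <- withr::with_seed(59, tibble::tibble(
    person_id = 1:200,
    d1 = rnorm(200), d2 = rnorm(200), d3 = rnorm(200),
    age = rnorm(200, 50, 10),
    sex = sample(c("female", "male"), 200, replace = TRUE)
  ))
  d$y <- 2 * d$d1 - 1 * d$d3
  pr <- suppressWarnings(fit_profile(d, "y", c("d1", "d2", "d3")))
  beta_expected <- c(2 * sd(d$d1), 0, -1 * sd(d$d3)) / sd(d$y)
  expect_equal(unname(pr$beta[match(c("d1", "d2", "d3"), pr$term)]),
               beta_expected, tolerance = 1e-10)
  expect_equal(attr(pr, "r_squared"), 1, tolerance = 1e-12)
  expect_true(all(pr$ci_low <= pr$beta & pr$beta <= pr$ci_high))
})

test_that("standardized coefficients are invariant to affine recoding of inputs", {
  d <- withr::with_seed(61, tibble::tibble(
    person_id = 1:150,
    d1 = rnorm(150), d2 = rnorm(150), age = rnorm(150, 40, 5),
    sex = sample(c("female", "male"), 150, replace = TRUE)
  ))
  d$y <- 0.5 * d$d1 + 0.3 * d$d2 + rnorm(150, 0, 0.5)
  pr1 <- fit_profile(d, "y", c("d1", "d2"))
  d2 <- d
  d2$d1 <- 100 + 7 * d2$d1
  d2$y <- 3 * d2$y - 5
  pr2 <- fit_profile(d2, "y", c("d1", "d2"))
  expect_equal(pr1$beta, pr2$beta, tolerance = 1e-10)
  expect_equal(pr1$se, pr2$se, tolerance = 1e-10)
})

test_that("single-dimension models and extended covariates are supported", {
  cfg <- preset_with_seed(67L)
  d <- generate_battery(cfg)
  merged <- dplyr::inner_join(d$factors, d$severities, by = "person_id") |>
    dplyr::inner_join(d$covariates, by = "person_id")
  single <- fit_profile(merged, "ISI", "sleep_related")
  expect_equal(nrow(single), 3)  # dimension + age + sex
  expect_gt(single$beta[single$term == "sleep_related"], 0.4)

  merged$education_years <- withr::with_seed(1, rnorm(nrow(merged), 11, 3))
  ext <- fit_profile(merged, "ISI", "sleep_related",
                     covariates = c("age", "sex", "education_years"))
  expect_true("education_years" %in% ext$term)
})

test_that("null predictors rarely exceed |0.1| at the study sample size", {
  hits <- vapply(1:200, function(r) {
    d <- withr::with_seed(700 + r, tibble::tibble(
      person_id = 1:467, x = rnorm(467), y = rnorm(467),
      age = rnorm(467, 58, 14),
      sex = sample(c("female", "male"), 467, replace = TRUE, prob = c(0.78, 0.22))
    ))
    pr <- fit_profile(d, "y", "x")
    abs(pr$beta[pr$term == "x"]) < 0.1
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("demographic correlations use the right method per variable", {
  withr::with_seed(71, {
    scores <- tibble::tibble(person_id = 1:200, anxious = rnorm(200))
    demo <- tibble::tibble(person_id = 1:200,
                           age = scores$anxious,
                           education_years = rnorm(200),
                           ses = sample(1:7, 200, replace = TRUE))
    out <- demographic_sensitivity(scores, demo)
    expect_equal(out$estimate[out$variable == "age"], 1, tolerance = 1e-12)
    expect_equal(out$method[out$variable == "ses"], "spearman")

    # Spearman is invariant to monotone transforms of the ordinal variable
    demo2 <- demo
    demo2$ses <- exp(demo2$ses)
    out2 <- demographic_sensitivity(scores, demo2)
    expect_equal(out$estimate[out$variable == "ses"],
                 out2$estimate[out2$variable == "ses"], tolerance = 1e-12)
  })
})
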