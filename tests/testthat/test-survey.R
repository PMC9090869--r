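test_that("four-year weights halve two combined 2-year cycles", {
  d <- data.frame(subject_id = 1:4, weight_2yr = c(20000, 1e4, 3e4, 4e4),
                  cycle = c("A", "A", "B", "B"))
  out <- four_year_weights(d)
  expect_equal(out$weight_4yr[1], 10000)
  expect_equal(sum(out$weight_4yr), sum(d$weight_2yr) / 2)

  single <- d[d$cycle == "A", ]
  expect_error(four_year_weights(single), class = "actisleep_validation_error")
  expect_warning(out1 <- four_year_weights(single, "keep"), "unhalved")
  expect_equal(out1$weight_4yr, single$weight_2yr)
})

test_that("weighted mean matches hand computation and is scale invariant", {
  des <- svy_design(c(1, 1), c(1, 2), c(1, 3))
  expect_equal(unname(svy_mean(c(1, 3), des)["mean"]), 2.5)

  set.seed(1)
  x <- rnorm(200)
  w <- runif(200, 1, 5)
  d1 <- make_design(200, weights = w)
  d2 <- make_design(200, weights = 2 * w)
  expect_equal(svy_mean(x, d1), svy_mean(x, d2), tolerance = 1e-12)
})

test_that("with equal weights and many PSUs the SE approaches the SRS SE", {
  set.seed(2)
  n <- 2000
  x <- rnorm(n)
  des <- make_design(n, n_strata = 100L)
  se <- unname(svy_mean(x, des)["se"])
  expect_lt(abs(se - sd(x) / sqrt(n)) / (sd(x) / sqrt(n)), 0.1)
})

test_that("a lonely PSU triggers the centered-at-grand-mean rule with a warning", {
  des <- suppressWarnings(svy_design(c(1, 1, 2), c(1, 2, 1), c(1, 1, 1)))
  expect_warning(svy_mean(c(1, 2, 3), des), "lonely PSU")
})

test_that("estimated population size equals the summed weights exactly", {
  set.seed(3)
  w <- runif(150, 1e3, 1e5)
  des <- make_design(150, weights = w)
  expect_equal(unname(svy_total(rep(1, 150), des)["total"]), sum(w))
})

test_that("weighted quantiles follow the lower-CDF-inverse rule", {
  expect_equal(unname(svy_quantile(c(1, 2, 3), c(1, 1, 1), 0.5)), 2)
  expect_equal(unname(svy_quantile(c(1, 2, 3), c(1, 1, 100), 0.5)), 3)
  # agreement with a brute-force CDF inversion oracle
  oracle <- function(x, w, p) {
    ux <- sort(unique(x))
    W <- sum(w)
    for (v in ux) if (sum(w[x <= v]) >= p * W) return(v)
    max(ux)
  }
  set.seed(4)
  x <- sample(round(rnorm(1000, 10, 3), 1))
  w <- runif(1000, 0.5, 4)
  for (p in c(0.05, 0.1, 0.25, 0.5, 0.75, 0.9, 0.99)) {
    expect_equal(unname(svy_quantile(x, w, p)), oracle(x, w, p))
  }
})

test_that("svy_lm reduces to OLS under equal weights and ignores row order", {
  set.seed(5)
  n <- 120
  d <- data.frame(x1 = rnorm(n), x2 = runif(n))
  d$y <- 1 + 2 * d$x1 - d$x2 + rnorm(n)
  des <- make_design(n, n_strata = 1L)
  fit <- svy_lm(y ~ x1 + x2, d, des)
  expect_equal(coef(fit), coef(lm(y ~ x1 + x2, d)), tolerance = 1e-10)

  perm <- sample(n)
  des_p <- svy_design(des$strata[perm], des$psu[perm], des$weights[perm])
  fit_p <- svy_lm(y ~ x1 + x2, d[perm, ], des_p)
  expect_equal(coef(fit_p), coef(fit), tolerance = 1e-10)
  expect_equal(vcov(fit_p), vcov(fit), tolerance = 1e-10)
})

test_that("svy_lm names collinear columns on rank deficiency", {
  d <- data.frame(y = rnorm(20), x1 = rnorm(20))
  d$x2 <- 2 * d$x1
  expect_error(svy_lm(y ~ x1 + x2, d, make_design(20)), "x2",
               class = "actisleep_error")
})

test_that("design-based coverage of regression coefficients is near nominal", {
  set.seed(6)
  hit <- 0; reps <- 120
  for (r in seq_len(reps)) {
    n <- 240
    d <- data.frame(x = rnorm(n))
    d$y <- 0.5 + 1.5 * d$x + rnorm(n)
    fit <- svy_lm(y ~ x, d, make_design(n, n_strata = 30L,
                                        weights = runif(n, 1, 3)))
    hit <- hit + (abs(coef(fit)["x"] - 1.5) <= 2 * sqrt(vcov(fit)["x", "x"]))
  }
  expect_gt(hit / reps, 0.9)
})

test_that("proportional-odds fit matches MASS::polr point estimates", {
  skip_if_not_installed("MASS")
  set.seed(7)
  n <- 400
  x1 <- rnorm(n); x2 <- runif(n)
  eta <- 0.8 * x1 - 0.5 * x2
  zeta <- c(-1, 0.2, 1.2)
  u <- runif(n)
  p <- sapply(zeta, function(z) plogis(z - eta))
  y <- factor(1L + (u > p[, 1]) + (u > p[, 2]) + (u > p[, 3]),
              ordered = TRUE)
  d <- data.frame(y = y, x1 = x1, x2 = x2)
  fit <- svy_polr(y ~ x1 + x2, d, make_design(n))
  ref <- MASS::polr(y ~ x1 + x2, d)
  expect_equal(coef(fit), coef(ref), tolerance = 5e-3)
  expect_equal(unname(fit$zeta), unname(ref$zeta), tolerance = 5e-3)
})

test_that("reversing the category order flips proportional-odds signs", {
  set.seed(8)
  n <- 300
  x <- rnorm(n)
  u <- runif(n)
  p <- sapply(c(-0.5, 0.8), function(z) plogis(z - x))
  y <- 1L + (u > p[, 1]) + (u > p[, 2])
  d <- data.frame(x = x,
                  y = factor(y, levels = 1:3, ordered = TRUE),
                  yr = factor(4L - y, levels = 1:3, ordered = TRUE))
  des <- make_design(n)
  f1 <- svy_polr(y ~ x, d, des)
  f2 <- svy_polr(yr ~ x, d, des)
  expect_equal(unname(coef(f1)), -unname(coef(f2)), tolerance = 1e-4)
})

test_that("two-category collapse reproduces weighted binary logistic estimates", {
  set.seed(9)
  n <- 350
  x <- rnorm(n)
  y2 <- factor(1L + (runif(n) < plogis(x - 0.3)), levels = 1:2,
               ordered = TRUE)
  w <- runif(n, 0.5, 2)
  d <- data.frame(x = x, y2 = y2)
  fit <- svy_polr(y2 ~ x, d, make_design(n, weights = w))
  ref <- suppressWarnings(
    glm(I(y2 == 2) ~ x, data = d, family = quasibinomial(), weights = w))
  expect_equal(unname(coef(fit)["x"]), unname(coef(ref)["x"]),
               tolerance = 1e-4)
  expect_equal(unname(fit$zeta), -unname(coef(ref)["(Intercept)"]),
               tolerance = 1e-4)
})

test_that("trend models recover generator age curves and label Wald blocks", {
  cfg <- cohort_config(n_subjects = 400, seed = 15)
  co <- simulate_cohort(cfg, minutes = FALSE)
  d <- merge(truth_summary(co$truth), co$demographics, by = "subject_id")
  d <- four_year_weights(d, "keep")
  des <- svy_design(d$stratum, d$psu, d$weight_4yr)
  tr <- sleep_trend("true_onset", d, des, interactions = c("sex", "race"))
  expect_s3_class(tr$fit, "svy_lm")
  expect_named(tr$wald, c("sex", "race", "sex_age", "race_age"))
  expect_equal(tr$wald$race$df1, 3)
  expect_equal(tr$wald$sex_age$df1, 4)
  expect_equal(tr$wald$race_age$df1, 12)
  # fitted curve grid covers every age/sex/race cell
  expect_equal(nrow(tr$curves), 80 * 2 * 4)
  # main-effects fit recovers the quartic curve within 2 SEs (typical draw)
  tr0 <- sleep_trend("true_onset", d, des)
  b <- coef(tr0$fit); se <- sqrt(diag(vcov(tr0$fit)))
  nm <- paste0("age", 1:4)
  expect_true(all(abs(b[nm] - cfg$onset_curve_coeffs[2:5]) <= 3 * se[nm]))
})

test_that("quantile grid has the nine age groups in Table shape", {
  co <- simulate_cohort(cohort_config(n_subjects = 250, seed = 16),
                        minutes = FALSE)
  d <- merge(truth_summary(co$truth), co$demographics, by = "subject_id")
  d <- four_year_weights(d, "keep")
  des <- svy_design(d$stratum, d$psu, d$weight_4yr)
  qt <- quantile_table(d, des, outcomes = "true_onset")
  expect_equal(nrow(qt), 9)
  expect_setequal(qt$age_group,
                  c("6-13", "14-17", "18-25", "26-35", "36-45", "46-55",
                    "56-65", "66-75", ">=76"))
  expect_true(all(c("5%", "50%", "90%") %in% names(qt)))
  # quantiles are monotone across probabilities within each group
  qcols <- c("5%", "10%", "25%", "50%", "75%", "90%")
  for (r in seq_len(nrow(qt)))
    expect_true(all(diff(as.numeric(qt[r, qcols])) >= 0))
})
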