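test_that("generated covariates match the profile's published marginals", {
  co <- generate_covariates(5000, profile_atlantis_experimental(), seed = 11)
  expect_equal(nrow(co), 5000)
  # combination-arm profile: CTFI mean 157.9 d, brain-mets prevalence 15.6%
  expect_lt(abs(mean(co$ctfi_days) - 157.9) / 157.9, 0.05)
  expect_lt(abs(mean(co$brain_mets) - 0.156), 0.02)
  expect_true(all(co$ldh > 0 & co$nl_ratio > 0 & co$aag > 0 & co$albumin > 0))
  expect_true(all(co$bsa >= 1 & co$bsa <= 3))
  # CTFI group is a deterministic function of ctfi_days at the 90-day cut
  expect_identical(co$ctfi_group == "sensitive", co$ctfi_days >= 90)
  expect_identical(co$ctfi_ge180, co$ctfi_days >= 180)
})

test_that("sample moments converge to profile moments (3-SE check)", {
  prof <- profile_atlantis_experimental()
  co <- generate_covariates(1e5, prof, seed = 3)
  for (nm in c("nl_ratio", "ldh", "aag", "ctfi_days")) {
    col <- if (nm == "ctfi_days") co$ctfi_days else co[[nm]]
    spec <- prof$covariates[[nm]]
    se <- spec$sd / sqrt(1e5)
    expect_lt(abs(mean(col) - spec$mean), 3 * se)
  }
})

test_that("cohort generation handles edge cases and is seed-deterministic", {
  expect_equal(nrow(generate_covariates(0, profile_b005(), 1)), 0)
  a <- generate_covariates(50, profile_b005(), 42)
  b <- generate_covariates(50, profile_b005(), 42)
  expect_identical(a, b)
  expect_false(identical(a, generate_covariates(50, profile_b005(), 43)))
  # single-agent basket study excluded brain metastases
  expect_true(all(!generate_covariates(500, profile_b005(), 1)$brain_mets))
})

test_that("invalid profiles are rejected at construction", {
  expect_error(cohort_profile(list(x = list(family = "lognormal", mean = 1, sd = -1)), 0.1),
               "sd")
  expect_error(cohort_profile(list(x = list(family = "lognormal", mean = 1, sd = 1)), 1.5),
               "\\[0, 1\\]")
  expect_error(cohort_profile(list(x = list(family = "weird", mean = 1, sd = 1)), 0.1),
               "family")
})

test_that("profiles round-trip through YAML config files", {
  prof <- profile_atlantis_experimental()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_profile(prof, path)
  back <- read_profile(path)
  expect_equal(back$brain_mets_prev, prof$brain_mets_prev)
  expect_equal(back$covariates, prof$covariates)
  a <- generate_covariates(100, prof, 5)
  b <- generate_covariates(100, back, 5)
  expect_equal(a, b)
})

test_that("Gaussian-copula correlations induce the requested rank correlation", {
  corr <- matrix(c(1, 0.6, 0.6, 1), 2, 2,
                 dimnames = list(c("ldh", "nl_ratio"), c("ldh", "nl_ratio")))
  prof <- profile_atlantis_experimental()
  prof$correlations <- corr
  co <- generate_covariates(20000, prof, 9)
  rho <- cor(co$ldh, co$nl_ratio, method = "spearman")
  expect_lt(abs(rho - 6 / pi * asin(0.6 / 2)), 0.05)
  # independent pair stays uncorrelated
  expect_lt(abs(cor(co$age, co$ldh, method = "spearman")), 0.05)
})

test_that("exposure assignment hits the published median and is dose-linear", {
  co <- generate_covariates(5000, profile_atlantis_experimental(), 11)
  ex <- assign_exposures(co, regimen_spec(3.2, 0), pk_defaults(), 12)
  # approved single-agent regimen: median unbound AUC ~ 1063.7 ng.h/L
  expect_lt(abs(median(ex$auc_u) - 1063.7) / 1063.7, 0.10)
  expect_true(all(ex$auc_dox == 0))
  # zero dose -> exactly zero exposure
  ex0 <- assign_exposures(co, regimen_spec(0, 0), pk_defaults(), 12)
  expect_true(all(ex0$auc_u == 0 & ex0$auc_dox == 0))
  # with IIV disabled, doubling the dose doubles every AUC exactly
  pk <- pk_defaults()
  pk$lurbinectedin$iiv$cl <- 0
  e1 <- assign_exposures(co, regimen_spec(1.6, 0), pk, 13)
  e2 <- assign_exposures(co, regimen_spec(3.2, 0), pk, 13)
  expect_equal(e2$auc_u, 2 * e1$auc_u, tolerance = 1e-12)
})

test_that("simulated survival follows the analytic log-logistic distribution", {
  pars <- os_params_published()
  co <- reference_cohort(20000)
  ex <- reference_exposures(co)
  out <- simulate_os_outcomes(co, ex, pars, censoring = NULL, seed = 21)
  expect_true(all(out$event))
  # at the reference covariates the median is the scale parameter lambda
  expect_lt(abs(median(out$time) - pars$lambda) / pars$lambda, 0.03)
  # KS distance to the analytic survivor < 0.02 at n = 1e4
  tt <- out$time[1:10000]
  emp <- ecdf(tt)
  grid <- quantile(tt, seq(0.01, 0.99, 0.01))
  ks <- max(abs((1 - emp(grid)) - loglogistic_survival(grid, pars)))
  expect_lt(ks, 0.02)
})

test_that("administrative censoring behaves and degenerate horizons error", {
  expect_error(censoring_spec(365, 0), "positive")
  expect_error(censoring_spec(365, 100), "exceed")
  co <- reference_cohort(500)
  ex <- reference_exposures(co)
  a <- simulate_os_outcomes(co, ex, os_params_published(), censoring_spec(), 7)
  b <- simulate_os_outcomes(co, ex, os_params_published(), censoring_spec(), 7)
  expect_identical(a, b)
  expect_true(attr(a, "event_fraction") < 1)
  expect_true(all(a$time <= 1500))
})

test_that("simulated response outcomes converge to the model probability", {
  pars <- orr_params_published()
  co <- reference_cohort(5000, group = "sensitive")
  ex <- reference_exposures(co)
  ex$auc_u <- 0
  # zero exposure: response probability is the lower asymptote plogis(-10)
  out <- simulate_orr_outcomes(co, ex, pars, seed = 31)
  expect_lte(sum(out$responder), 2)
  co2 <- reference_cohort(50000, group = "sensitive")
  ex2 <- reference_exposures(co2)
  ex2$auc_u <- 1500
  out2 <- simulate_orr_outcomes(co2, ex2, pars, seed = 32)
  p_true <- orr_probability(1500, "sensitive", pars)
  expect_lt(abs(mean(out2$responder) - p_true), 0.01)
  expect_identical(out2, simulate_orr_outcomes(co2, ex2, pars, seed = 32))
})
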