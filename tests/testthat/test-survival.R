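test_that("Kaplan-Meier matches the hand product-limit computation", {
  km <- km_estimate(c(1, 2, 3), c(TRUE, TRUE, TRUE))
  expect_equal(km$curve$surv, c(2 / 3, 1 / 3, 0))
  # single censored record: curve stays at 1, median not reached
  km1 <- km_estimate(5, FALSE)
  expect_true(all(km1$curve$surv == 1))
  expect_true(is.na(km1$median))
  expect_error(km_estimate(numeric(0), logical(0)), "empty")
  expect_error(km_estimate(c(-1, 2), c(TRUE, TRUE)), "> 0")
  # oracle equivalence on 20 random small datasets
  set.seed(17)
  for (i in 1:20) {
    n <- sample(4:12, 1)
    tt <- sample(1:15, n, replace = TRUE)
    ev <- runif(n) < 0.7
    if (!any(ev)) ev[1] <- TRUE
    km <- km_estimate(tt, ev)
    orc <- product_limit_oracle(tt, ev)
    got <- km$curve$surv[km$curve$n_event > 0]
    expect_equal(got, orc$surv, tolerance = 1e-12)
  }
})

test_that("log-rank test: null identity, hand-checkable toy, empty groups", {
  g <- list(times = c(2, 4, 6, 8), events = c(TRUE, TRUE, FALSE, TRUE))
  res <- logrank_test(list(g, g))
  expect_lt(res$statistic, 1e-10)
  expect_gt(res$p_value, 0.999)
  expect_equal(res$df, 1)
  expect_error(logrank_test(list(g, list(times = numeric(0), events = logical(0)))),
               "non-empty")
  # 6-subject two-group toy: observed-minus-expected accumulated by hand;
  # at each event time exactly one death, expected group-1 share n1/n
  t1 <- c(1, 3, 5); t2 <- c(2, 4, 6)
  ev <- c(TRUE, TRUE, TRUE)
  all_t <- c(t1, t2); grp <- rep(0:1, each = 3)
  exp1 <- 0; obs1 <- 0; varsum <- 0
  for (d in sort(all_t)) {
    at_risk <- all_t >= d
    n <- sum(at_risk); n1 <- sum(at_risk & grp == 1)
    obs1 <- obs1 + as.numeric(any(all_t == d & grp == 1))
    exp1 <- exp1 + n1 / n
    varsum <- varsum + n1 / n * (1 - n1 / n)
  }
  hand_chisq <- (obs1 - exp1)^2 / varsum
  res2 <- logrank_test(list(list(times = t1, events = ev),
                            list(times = t2, events = ev)))
  expect_equal(res2$statistic, hand_chisq, tolerance = 1e-8)
})

test_that("log-rank type-I error is calibrated under the null", {
  set.seed(23)
  rej <- mean(replicate(5000, {
    tt <- rexp(40, 0.1)
    g <- rep(1:2, each = 20)
    r <- logrank_test(list(list(times = tt[g == 1], events = rep(TRUE, 20)),
                           list(times = tt[g == 2], events = rep(TRUE, 20))))
    r$p_value < 0.05
  }))
  expect_lt(abs(rej - 0.05), 0.01)
})

test_that("Cox coefficient equals the partial-likelihood grid maximizer", {
  d <- tibble::tibble(time = c(2, 5, 7, 11, 13), event = rep(TRUE, 5),
                      x = c(1, 0, 1, 0, 0))
  fit <- cox_fit(d, "x")
  grid <- seq(-3, 3, by = 1e-4)
  ll <- vapply(grid, cox_partial_loglik, 0, time = d$time, event = d$event, x = d$x)
  expect_equal(unname(fit$coefficients), grid[which.max(ll)], tolerance = 1e-4)
  # fit is deterministic
  expect_identical(fit$coefficients, cox_fit(d, "x")$coefficients)
})

test_that("Cox HR for an outcome-independent covariate is near 1", {
  set.seed(5)
  d <- tibble::tibble(time = rexp(2000, 0.01), event = rep(TRUE, 2000),
                      x = rnorm(2000))
  fit <- cox_fit(d, "x")
  expect_gt(fit$hr$hr[1], 0.9)
  expect_lt(fit$hr$hr[1], 1.1)
  expect_error(cox_fit(tibble::tibble(time = 1:3, event = rep(FALSE, 3), x = 1:3), "x"),
               "event")
  expect_error(cox_fit(tibble::tibble(time = 1:3, event = rep(TRUE, 3), x = rep(1, 3)), "x"),
               "constant")
})

test_that("log-logistic survivor: identities and hazard-integral oracle", {
  pars <- os_params_published()
  expect_equal(loglogistic_survival(pars$lambda, pars), 0.5)
  expect_equal(loglogistic_survival(0, pars), 1)
  x <- c(ctfi_ge90 = 1, log_ldh = 0.3, nl_ratio = -1, brain_mets = 0,
         auc_u = 0.2, auc_dox = 0.1, auc_u_auc_dox = 0.02)
  expect_equal(loglogistic_survival(0, pars, x), 1)
  # S(t) = exp(-integral of hazard)
  for (t in c(50, 294.2, 800)) {
    H <- integrate(function(u) loglogistic_hazard(u, pars, x), 1e-10, t,
                   rel.tol = 1e-10)$value
    expect_equal(loglogistic_survival(t, pars, x), exp(-H), tolerance = 1e-6)
  }
})

test_that("log-logistic hazard shape: unimodal for p > 1, monotone for p = 1", {
  a0 <- log(c(ctfi_ge90 = 1, log_ldh = 1, nl_ratio = 1, brain_mets = 1,
              auc_u = 1, auc_dox = 1, auc_u_auc_dox = 1))
  p24 <- loglogistic_os_params(p = 2.4, lambda = 294.2, alphas = a0)
  tt <- seq(1, 3000, by = 1)
  h <- loglogistic_hazard(tt, p24)
  peak <- which.max(h)
  expect_gt(peak, 1); expect_lt(peak, length(tt))
  expect_true(all(diff(h[1:peak]) > 0))
  expect_true(all(diff(h[peak:length(h)]) < 0))
  p1 <- loglogistic_os_params(p = 1, lambda = 200, alphas = a0)
  h1 <- loglogistic_hazard(tt, p1)
  expect_true(all(diff(h1) < 0))
  expect_equal(h1[1], 1 / 200 / (1 + 1 / 200), tolerance = 1e-6)
  expect_error(loglogistic_hazard(0, p1), "> 0")
  # hazard equals -d log S / dt (central difference)
  t0 <- 150; eps <- 1e-3
  num <- -(log(loglogistic_survival(t0 + eps, p24)) -
             log(loglogistic_survival(t0 - eps, p24))) / (2 * eps)
  expect_equal(loglogistic_hazard(t0, p24), num, tolerance = 1e-4)
})

test_that("density = hazard x survivor at random points", {
  pars <- os_params_published()
  set.seed(31)
  for (i in 1:100) {
    t0 <- runif(1, 10, 2000)
    x <- c(ctfi_ge90 = rbinom(1, 1, 0.5), log_ldh = rnorm(1, 0, 0.5),
           nl_ratio = rnorm(1), brain_mets = rbinom(1, 1, 0.2),
           auc_u = rnorm(1, 0, 0.3), auc_dox = rnorm(1, 0, 0.3),
           auc_u_auc_dox = rnorm(1, 0, 0.2))
    eps <- 1e-4 * t0
    f_num <- (loglogistic_survival(t0 - eps, pars, x) -
                loglogistic_survival(t0 + eps, pars, x)) / (2 * eps)
    hS <- loglogistic_hazard(t0, pars, x) * loglogistic_survival(t0, pars, x)
    expect_equal(f_num, hS, tolerance = 1e-6)
  }
})

test_that("exponential MLE matches the closed form n_events / sum(times)", {
  set.seed(41)
  d <- tibble::tibble(time = rexp(300, 0.02),
                      event = runif(300) < 0.8)
  fit <- fit_parametric_os(d, "exponential")
  rate_hat <- exp(-fit$estimates[["(Intercept)"]])
  expect_equal(rate_hat, sum(d$event) / sum(d$time), tolerance = 1e-6)
})

test_that("log-logistic MLE agrees with an independent AFT implementation", {
  d <- simulated_os_data(800, seed = 51)
  fit <- fit_parametric_os(d, "loglogistic", OS_COVARIATES)
  expect_true(fit$converged)
  sr <- survival::survreg(
    survival::Surv(time, event) ~ ctfi_ge90 + log_ldh + nl_ratio + brain_mets +
      auc_u + auc_dox + auc_u_auc_dox,
    data = d, dist = "loglogistic")
  expect_equal(unname(fit$coefficients),
               unname(coef(sr)[OS_COVARIATES]), tolerance = 1e-4)
  expect_equal(fit$estimates[["lambda"]], exp(coef(sr)[["(Intercept)"]]),
               tolerance = 1e-4)
  expect_equal(fit$estimates[["p"]], 1 / sr$scale, tolerance = 1e-4)
  expect_equal(fit$minus2LL, -2 * as.numeric(logLik(sr)), tolerance = 1e-6)
})

test_that("nested-model likelihood: full fit dominates pinned submodels", {
  d <- simulated_os_data(400, seed = 61)
  full <- fit_parametric_os(d, "loglogistic", OS_COVARIATES)
  for (drop in c("auc_u", "nl_ratio")) {
    red <- fit_parametric_os(d, "loglogistic", setdiff(OS_COVARIATES, drop))
    expect_lte(full$minus2LL, red$minus2LL + 1e-6)
  }
})

test_that("acceleration factors: identities, CI scaling, AFT-only guard", {
  set.seed(71)
  # covariate unrelated to outcome: AF ~ 1 with CI covering 1
  co <- reference_cohort(800)
  ex <- reference_exposures(co)
  out <- simulate_os_outcomes(co, ex, os_params_published(), NULL, 71)
  d <- os_model_frame(co, ex, out)
  d$noise <- rnorm(800)
  fit <- fit_parametric_os(d, "loglogistic", "noise")
  af <- acceleration_factors(fit)
  expect_lt(abs(af$af - 1), 0.1)
  expect_true(af$lo < 1 && af$hi > 1)
  # CI width shrinks like n^(-1/2)
  widths <- vapply(c(250, 1000, 4000), function(n) {
    dd <- simulated_os_data(n, seed = 72)
    f <- fit_parametric_os(dd, "loglogistic", OS_COVARIATES)
    a <- acceleration_factors(f)
    a$hi[a$covariate == "ctfi_ge90"] - a$lo[a$covariate == "ctfi_ge90"]
  }, 0)
  expect_equal(widths[1] / widths[2], 2, tolerance = 0.4)
  expect_equal(widths[2] / widths[3], 2, tolerance = 0.4)
  gfit <- fit_parametric_os(simulated_os_data(150, 73), "gaussian", "ctfi_ge90")
  expect_error(acceleration_factors(gfit), "AFT")
})

test_that("model comparison table is consistent and fingerprint-guarded", {
  d <- simulated_os_data(300, seed = 81)
  fits <- lapply(c("loglogistic", "weibull", "exponential", "lognormal"),
                 function(f) fit_parametric_os(d, f, c("ctfi_ge90", "log_ldh")))
  tab <- compare_models(fits)
  expect_equal(tab$delta_aic[1], 0)
  expect_equal(tab$aic - tab$minus2LL, 2 * tab$n_par)
  expect_equal(compare_models(fits[1])$delta_aic, 0)
  d2 <- simulated_os_data(301, seed = 82)
  f2 <- fit_parametric_os(d2, "weibull", c("ctfi_ge90", "log_ldh"))
  expect_error(compare_models(list(fits[[1]], f2)), "same dataset")
})

test_that("proportional-hazards diagnostic flags log-logistic crossing hazards", {
  set.seed(91)
  n <- 2000
  x <- rbinom(n, 1, 0.5)
  pars <- os_params_published()
  af <- exp(log(3) * x)
  u <- runif(n)
  tt <- pars$lambda * af * (1 / u - 1)^(1 / pars$p)
  d <- tibble::tibble(time = tt, event = rep(TRUE, n), x = x)
  fit <- cox_fit(d, "x")
  zph <- ph_diagnostic(fit)
  expect_lt(zph$p_value[zph$covariate == "x"], 0.05)
})
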