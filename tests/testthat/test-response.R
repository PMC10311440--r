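test_that("sigmoid-Emax probability: asymptote and half-maximum identities", {
  pars <- orr_params_published()
  expect_equal(orr_probability(0, "resistant", pars), plogis(-10))
  expect_equal(orr_probability(0, "sensitive", pars), plogis(-10))
  # at auc_u = ec50 the logit is exactly -10 + Emax/2
  expect_equal(orr_probability(877, "sensitive", pars), plogis(-10 + 10.8 / 2))
  expect_equal(orr_probability(877, "resistant", pars), plogis(-10 + 8.5 / 2))
  # 10x the ec50: the Hill term is 10^10/(1+10^10), essentially saturated
  frac <- 1e10 / (1 + 1e10)
  expect_equal(orr_probability(8770, "sensitive", pars),
               plogis(-10 + 10.8 * frac))
  expect_equal(round(plogis(-10 + 10.8 * frac), 3), 0.690)
  expect_error(orr_probability(-1, "sensitive", pars), ">= 0")
})

test_that("response probability is monotone and switch-like around ec50", {
  set.seed(3)
  for (i in 1:20) {
    pars <- emax_orr_params(runif(1, 1, 12), runif(1, 1, 12), runif(1, 200, 2000))
    auc <- seq(0, 5000, length.out = 400)
    p <- orr_probability(auc, "sensitive", pars)
    expect_true(all(diff(p) >= -1e-15))
  }
  # with Hill = 10 the exposure-effect term (the logit shift toward Emax)
  # covers 10%..90% of its range inside [0.8, 1.25] x ec50 — why maximal ORR
  # is reached below the median exposure of the 3.2 mg/m2 regimen
  pars <- orr_params_published()
  shift <- function(a) qlogis(orr_probability(a, "sensitive", pars)) + 10
  expect_lt(shift(0.8 * 877), 0.10 * 10.8)
  expect_gt(shift(1.25 * 877), 0.90 * 10.8)
})

test_that("Emax ORR fit matches a 3-D likelihood grid search at n = 200", {
  truth <- orr_params_published()
  set.seed(7)
  auc <- rlnorm(200, log(1000), 0.6)
  grp <- factor(rep(c("resistant", "sensitive"), 100),
                levels = c("resistant", "sensitive"))
  y <- runif(200) < orr_probability(auc, grp, truth)
  d <- tibble::tibble(auc_u = auc, ctfi_group = grp, responder = y)
  fit <- fit_emax_orr(d)
  expect_true(fit$converged)
  # the Bernoulli log-likelihood separates over CTFI groups for fixed ec50,
  # so the 3-D grid search reduces to two 1-D scans per ec50 value
  grp_ll <- function(emax, ec, sel) {
    p <- plogis(-10 + emax * plogis(10 * (log(auc[sel]) - log(ec))))
    sum(dbinom(as.numeric(y[sel]), 1, p, log = TRUE))
  }
  g_emax <- seq(5, 14, by = 0.1)
  g_ec <- exp(seq(log(500), log(2000), by = 0.01))
  res <- grp == "resistant"
  best <- c(NA, NA, NA); best_ll <- -Inf
  for (ec in g_ec) {
    ll_r <- vapply(g_emax, grp_ll, 0, ec = ec, sel = res)
    ll_s <- vapply(g_emax, grp_ll, 0, ec = ec, sel = !res)
    tot <- max(ll_r) + max(ll_s)
    if (tot > best_ll) {
      best_ll <- tot
      best <- c(g_emax[which.max(ll_r)], g_emax[which.max(ll_s)], ec)
    }
  }
  expect_gte(-fit$minus2LL / 2, best_ll - 1e-6)
  expect_equal(fit$estimates[["emax_resistant"]], best[1], tolerance = 0.11)
  expect_equal(fit$estimates[["emax_sensitive"]], best[2], tolerance = 0.11)
  expect_lt(abs(log(fit$estimates[["ec50"]]) - log(best[3])), 0.011)
})

test_that("fitted likelihood dominates the simulating truth", {
  truth <- orr_params_published()
  for (seed in 1:5) {
    set.seed(seed)
    auc <- rlnorm(500, log(1000), 0.6)
    grp <- factor(rep(c("resistant", "sensitive"), 250))
    y <- runif(500) < orr_probability(auc, grp, truth)
    d <- tibble::tibble(auc_u = auc, ctfi_group = grp, responder = y)
    fit <- fit_emax_orr(d)
    p_true <- orr_probability(auc, grp, truth)
    m2ll_truth <- -2 * sum(dbinom(as.numeric(y), 1, p_true, log = TRUE))
    expect_lte(fit$minus2LL, m2ll_truth + 1e-6)
  }
})

test_that("degenerate response data raise a separation error", {
  d <- tibble::tibble(auc_u = rlnorm(50, log(800), 0.5),
                      ctfi_group = rep(c("resistant", "sensitive"), 25),
                      responder = FALSE)
  expect_error(fit_emax_orr(d), "separation")
})

test_that("multivariate logistic comparator: null OR, 2x2 closed form", {
  set.seed(11)
  d <- tibble::tibble(responder = runif(2000) < 0.3, x = rnorm(2000))
  fit <- fit_logistic_multivariate(d, "x")
  expect_gt(fit$or$or[1], 0.85); expect_lt(fit$or$or[1], 1.18)
  # 2x2 table: OR equals the cross-product ratio
  d2 <- tibble::tibble(
    responder = rep(c(TRUE, FALSE, TRUE, FALSE), c(30, 70, 10, 90)),
    x = rep(c(1, 1, 0, 0), c(30, 70, 10, 90)))
  fit2 <- fit_logistic_multivariate(d2, "x")
  expect_equal(fit2$or$or[1], (30 * 90) / (70 * 10), tolerance = 1e-5)
  expect_identical(fit2$estimates, fit_logistic_multivariate(d2, "x")$estimates)
  expect_error(fit_logistic_multivariate(tibble::tibble(responder = c(TRUE, FALSE), x = c(1, 1)), "x"),
               "constant")
})

test_that("classification metrics reproduce confusion-matrix arithmetic", {
  m <- classification_metrics(c(0.9, 0.8, 0.7), c(TRUE, TRUE, TRUE))
  expect_equal(unlist(m[c("accuracy", "precision", "recall", "f1")]),
               c(accuracy = 1, precision = 1, recall = 1, f1 = 1))
  expect_warning(
    m2 <- classification_metrics(c(0.1, 0.2), c(TRUE, FALSE)),
    "precision")
  expect_equal(m2$recall, 0)
  # TP=3 FP=2 FN=1 TN=4
  probs <- c(rep(0.9, 3), rep(0.9, 2), rep(0.1, 1), rep(0.1, 4))
  obs <- c(rep(TRUE, 3), rep(FALSE, 2), rep(TRUE, 1), rep(FALSE, 4))
  m3 <- classification_metrics(probs, obs)
  expect_equal(m3$precision, 0.6)
  expect_equal(m3$recall, 0.75)
  expect_equal(m3$f1, 2 * 0.6 * 0.75 / 1.35)
  expect_equal(m3$accuracy, 0.7)
  expect_error(classification_metrics(numeric(0), logical(0)), "empty")
})
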