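# stable log(1 + e^u)
.log1pexp <- function(u) ifelse(u > 33, u, log1p(exp(u)))

# short content fingerprint so model comparisons can verify "same data"
.data_fingerprint <- function(data) {
  v <- c(nrow(data), round(sum(data$time), 6), sum(data$event))
  paste(format(v, trim = TRUE), collapse = ":")
}

# Right-censored log-logistic AFT log-likelihood and analytic gradient.
# theta = (log lambda, beta[covariates], log p); u = p * (log t - mu).
.llog_loglik <- function(theta, tt, ev, X) {
  k <- ncol(X)
  loglam <- theta[1]
  beta <- if (k) theta[2:(k + 1)] else numeric(0)
  p <- exp(theta[k + 2])
  mu <- loglam + if (k) drop(X %*% beta) else 0
  u <- p * (log(tt) - mu)
  sum(ev * (log(p) - log(tt) + u) - (1 + ev) * .log1pexp(u))
}

.llog_grad <- function(theta, tt, ev, X) {
  k <- ncol(X)
  loglam <- theta[1]
  beta <- if (k) theta[2:(k + 1)] else numeric(0)
  p <- exp(theta[k + 2])
  mu <- loglam + if (k) drop(X %*% beta) else 0
  u <- p * (log(tt) - mu)
  g <- ev - (1 + ev) * stats::plogis(u)   # d loglik / d u_i
  d_loglam <- -p * sum(g)
  d_beta <- if (k) -p * drop(crossprod(X, g)) else numeric(0)
  d_logp <- sum(ev) + sum(g * u)
  c(d_loglam, d_beta, d_logp)
}

#' Fit a parametric survival model to right-censored data
#'
#' Maximizes the right-censored log-likelihood
#' `sum(event * log f + (1 - event) * log S)`. The `"loglogistic"` family —
#' the final OS model — is fit directly by quasi-Newton (BFGS) optimization
#' with an analytic gradient on the unconstrained scale
#' `(log lambda, beta, log p)`, with up to three jittered restarts on
#' non-convergence; standard errors come from the observed information
#' (numerical Hessian at the optimum). Comparator families are delegated to
#' [survival::survreg()] (`"weibull"`, `"exponential"`, `"lognormal"`,
#' `"gaussian"`) and `flexsurv::flexsurvreg` (`"gompertz"`), reported in the
#' same result structure for AIC / -2LL comparison.
#'
#' @param data tibble with `time` (days, > 0), `event` (logical) and the
#'   covariate columns (e.g. from [os_model_frame()]).
#' @param family one of `"loglogistic"`, `"weibull"`, `"exponential"`,
#'   `"lognormal"`, `"gaussian"`, `"gompertz"`.
#' @param covariates character vector of covariate column names (may be
#'   empty for an intercept-only fit).
#' @return an object of class `survival_fit`: list with `family`,
#'   `estimates` (for `"loglogistic"`: `p`, `lambda` and named
#'   coefficients), `se`, `vcov` (unconstrained scale), `minus2LL`, `aic`,
#'   `n`, `n_events`, `converged`, `data_fingerprint`.
#' @export
fit_parametric_os <- function(data, family = "loglogistic",
                              covariates = character(0)) {
  family <- match.arg(family, c("loglogistic", "weibull", "exponential",
                                "lognormal", "gaussian", "gompertz"))
  stopifnot(all(c("time", "event") %in% names(data)))
  if (any(data$time <= 0)) stop("`time` must be > 0", call. = FALSE)
  if (sum(data$event) < 1) stop("at least one event is required", call. = FALSE)
  if (family == "loglogistic") {
    .fit_loglogistic(data, covariates)
  } else {
    .fit_comparator(data, family, covariates)
  }
}

.fit_loglogistic <- function(data, covariates) {
  tt <- data$time
  ev <- as.numeric(data$event)
  X <- as.matrix(data[, covariates, drop = FALSE])
  k <- ncol(X)
  start <- c(log(stats::median(tt)), rep(0, k), 0)
  fn <- function(th) -.llog_loglik(th, tt, ev, X)
  gr <- function(th) -.llog_grad(th, tt, ev, X)
  fit <- NULL
  for (attempt in 1:3) {
    st <- if (attempt == 1) start else start + stats::rnorm(length(start), 0, 0.3)
    res <- try(stats::optim(st, fn, gr, method = "BFGS",
                            control = list(maxit = 500, reltol = 1e-12)),
               silent = TRUE)
    if (!inherits(res, "try-error") && res$convergence == 0 &&
        (is.null(fit) || res$value < fit$value)) {
      fit <- res
      break
    }
    if (!inherits(res, "try-error") && (is.null(fit) || res$value < fit$value)) fit <- res
  }
  if (is.null(fit)) stop("log-logistic fit failed on all starts", call. = FALSE)
  converged <- fit$convergence == 0
  H <- try(stats::optimHess(fit$par, fn, gr), silent = TRUE)
  vcov <- NULL; se <- rep(NA_real_, length(fit$par))
  if (!inherits(H, "try-error")) {
    Vi <- try(solve(H), silent = TRUE)
    if (!inherits(Vi, "try-error") && all(diag(Vi) > 0)) {
      vcov <- Vi
      se <- sqrt(diag(Vi))
    }
  }
  par_names <- c("log_lambda", covariates, "log_p")
  names(fit$par) <- par_names
  names(se) <- par_names
  if (!is.null(vcov)) dimnames(vcov) <- list(par_names, par_names)
  beta <- if (k) fit$par[covariates] else numeric(0)
  est <- c(lambda = exp(fit$par[["log_lambda"]]), p = exp(fit$par[["log_p"]]), beta)
  m2ll <- 2 * fit$value
  npar <- length(fit$par)
  structure(list(
    family = "loglogistic", estimates = est, coefficients = beta,
    par = fit$par, se = se, vcov = vcov, minus2LL = m2ll,
    aic = m2ll + 2 * npar, n_par = npar, n = nrow(data),
    n_events = sum(ev), converged = converged, covariates = covariates,
    data_fingerprint = .data_fingerprint(data)
  ), class = "survival_fit")
}

.fit_comparator <- function(data, family, covariates) {
  fml <- stats::as.formula(paste(
    "survival::Surv(time, event) ~",
    if (length(covariates)) paste(covariates, collapse = " + ") else "1"
  ))
  if (family == "gompertz") {
    if (!requireNamespace("flexsurv", quietly = TRUE)) {
      stop("family 'gompertz' requires the flexsurv package", call. = FALSE)
    }
    fit <- flexsurv::flexsurvreg(fml, data = data, dist = "gompertz")
    ll <- fit$loglik
    npar <- fit$npars
    est <- fit$res[, "est"]
    se <- fit$res[, "se"]
    vcov <- stats::vcov(fit)
    coefs <- stats::coef(fit)[covariates]
  } else {
    fit <- survival::survreg(fml, data = data, dist = family)
    llo <- stats::logLik(fit)
    ll <- as.numeric(llo)
    npar <- attr(llo, "df")
    est <- c(stats::coef(fit), scale = fit$scale)
    se <- sqrt(diag(stats::vcov(fit)))
    vcov <- stats::vcov(fit)
    coefs <- stats::coef(fit)[covariates]
  }
  m2ll <- -2 * ll
  structure(list(
    family = family, estimates = est, coefficients = coefs,
    se = se, vcov = vcov, minus2LL = m2ll, aic = m2ll + 2 * npar,
    n_par = npar, n = nrow(data), n_events = sum(data$event),
    converged = TRUE, covariates = covariates,
    data_fingerprint = .data_fingerprint(data)
  ), class = "survival_fit")
}

#' @export
print.survival_fit <- function(x, ...) {
  cat(sprintf("<survival_fit> family=%s  n=%d (%d events)  -2LL=%.2f  AIC=%.2f%s\n",
              x$family, x$n, x$n_events, x$minus2LL, x$aic,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  print(round(x$estimates, 4))
  invisible(x)
}

#' Acceleration factors with Wald confidence intervals
#'
#' For an AFT-parameterized fit, `AF = exp(coef)` per covariate unit with
#' `CI = exp(coef +/- 1.96 * SE)`; AF > 1 means longer survival.
#'
#' @param fit a `survival_fit` from [fit_parametric_os()] with family
#'   `"loglogistic"`, `"weibull"`, `"exponential"` or `"lognormal"` (the
#'   AFT-parameterized families).
#' @return tibble with `covariate`, `af`, `lo`, `hi`.
#' @export
acceleration_factors <- function(fit) {
  stopifnot(inherits(fit, "survival_fit"))
  if (!fit$family %in% c("loglogistic", "weibull", "exponential", "lognormal")) {
    stop(sprintf("family '%s' is not AFT-parameterized", fit$family), call. = FALSE)
  }
  if (!fit$converged) stop("fit did not converge", call. = FALSE)
  cov_nms <- fit$covariates
  beta <- fit$coefficients[cov_nms]
  se <- fit$se[cov_nms]
  tibble::tibble(covariate = cov_nms,
                 af = exp(beta),
                 lo = exp(beta - 1.96 * se),
                 hi = exp(beta + 1.96 * se))
}

#' Rank fitted survival models by AIC
#'
#' @param fits list of `survival_fit` objects fitted to the identical
#'   dataset (verified by data fingerprint).
#' @return tibble sorted by AIC with `family`, `n_par`, `minus2LL`, `aic`,
#'   `delta_aic`, `delta_m2ll` relative to the best model.
#' @export
compare_models <- function(fits) {
  stopifnot(length(fits) >= 1, all(vapply(fits, inherits, TRUE, "survival_fit")))
  fps <- vapply(fits, `[[`, "", "data_fingerprint")
  if (length(unique(fps)) != 1) {
    stop("fits were not computed on the same dataset", call. = FALSE)
  }
  tab <- tibble::tibble(
    family = vapply(fits, `[[`, "", "family"),
    n_par = vapply(fits, `[[`, 0, "n_par"),
    minus2LL = vapply(fits, `[[`, 0, "minus2LL"),
    aic = vapply(fits, `[[`, 0, "aic")
  )
  tab <- tab[order(tab$aic), ]
  tab$delta_aic <- tab$aic - tab$aic[1]
  tab$delta_m2ll <- tab$minus2LL - tab$minus2LL[1]
  tab
}
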