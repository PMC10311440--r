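#' Kaplan-Meier estimate with Greenwood confidence bands
#'
#' Product-limit estimate of the survivor function (via
#' [survival::survfit()]) with Greenwood standard errors, plus the median
#' survival time and its 95% CI (reported as `NA` / "not reached" when the
#' curve never drops to 0.5).
#'
#' @param times event/censoring times (days), > 0.
#' @param events logical event indicators (TRUE = death observed).
#' @return list of class `km_estimate`: `curve` tibble (`time`, `n_risk`,
#'   `n_event`, `surv`, `lo`, `hi`), `median`, `median_lo`, `median_hi`
#'   (days), `n`, `n_events`.
#' @export
km_estimate <- function(times, events) {
  if (length(times) == 0) stop("empty input", call. = FALSE)
  if (any(times <= 0)) stop("times must be > 0", call. = FALSE)
  stopifnot(length(times) == length(events))
  sf <- survival::survfit(survival::Surv(times, events) ~ 1, conf.type = "log")
  med <- unname(stats::quantile(sf, probs = 0.5)$quantile)
  medci <- stats::quantile(sf, probs = 0.5)
  structure(list(
    curve = tibble::tibble(time = sf$time, n_risk = sf$n.risk,
                           n_event = sf$n.event, surv = sf$surv,
                           lo = sf$lower, hi = sf$upper),
    median = med,
    median_lo = unname(medci$lower),
    median_hi = unname(medci$upper),
    n = length(times), n_events = sum(events)
  ), class = "km_estimate")
}

#' @export
print.km_estimate <- function(x, ...) {
  med <- if (is.na(x$median)) "not reached" else
    sprintf("%.1f d (%.1f mo)", x$median, x$median / DAYS_PER_MONTH)
  cat(sprintf("<km_estimate> n=%d (%d events), median %s\n", x$n, x$n_events, med))
  invisible(x)
}

#' Log-rank test across groups
#'
#' @param groups list of length >= 2; each element a list/tibble with `times`
#'   and `events`.
#' @return list with `statistic` (chi-square), `df` (groups - 1), `p_value`.
#' @export
logrank_test <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  sizes <- vapply(groups, function(g) length(g$times), 0L)
  if (any(sizes == 0)) stop("every group must be non-empty", call. = FALSE)
  df <- data.frame(
    time = unlist(lapply(groups, `[[`, "times")),
    event = unlist(lapply(groups, `[[`, "events")),
    group = rep(seq_along(groups), sizes)
  )
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  k <- length(groups) - 1
  list(statistic = unname(sd_$chisq), df = k,
       p_value = stats::pchisq(sd_$chisq, k, lower.tail = FALSE))
}

#' Multivariate Cox proportional-hazards regression
#'
#' Wrapper around [survival::coxph()] (Efron tie handling) returning hazard
#' ratios with Wald 95% CIs in the package's common fit-result structure.
#'
#' @param data tibble with `time`, `event` and covariate columns.
#' @param covariates character vector of covariate names.
#' @return list of class `cox_fit`: `coefficients`, `se`, `hr` tibble
#'   (`covariate`, `hr`, `lo`, `hi`, `p_value`), `vcov`, `minus2LL`, `aic`,
#'   `n`, `n_events`, `converged`.
#' @export
cox_fit <- function(data, covariates) {
  stopifnot(length(covariates) >= 1)
  if (sum(data$event) < 1) stop("at least one event is required", call. = FALSE)
  for (cv in covariates) {
    if (length(unique(data[[cv]])) < 2) {
      stop(sprintf("covariate '%s' is constant: not identifiable", cv), call. = FALSE)
    }
  }
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(covariates, collapse = " + ")))
  fit <- survival::coxph(fml, data = data, ties = "efron")
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  z <- beta / se
  ll <- fit$loglik[2]
  structure(list(
    coefficients = beta, se = se,
    hr = tibble::tibble(covariate = names(beta), hr = unname(exp(beta)),
                        lo = unname(exp(beta - 1.96 * se)),
                        hi = unname(exp(beta + 1.96 * se)),
                        p_value = unname(2 * stats::pnorm(-abs(z)))),
    vcov = stats::vcov(fit), minus2LL = -2 * ll,
    aic = -2 * ll + 2 * length(beta),
    n = fit$n, n_events = fit$nevent,
    converged = is.null(fit$info) || !isTRUE(fit$info$flag),
    model = fit
  ), class = "cox_fit")
}

#' Proportional-hazards diagnostic
#'
#' Scaled-Schoenfeld-residual trend test ([survival::cox.zph()]) on a Cox
#' fit. Data generated by a log-logistic model with shape > 1 have crossing
#' hazards, and this test is expected to flag the violated proportionality
#' assumption — the reason the final OS model is parametric rather than Cox.
#'
#' @param fit a [cox_fit()] result.
#' @return tibble with `covariate`, `chisq`, `df`, `p_value` (last row is
#'   the global test).
#' @export
ph_diagnostic <- function(fit) {
  stopifnot(inherits(fit, "cox_fit"))
  zp <- survival::cox.zph(fit$model)
  tab <- as.data.frame(zp$table)
  tibble::tibble(covariate = rownames(tab), chisq = tab$chisq,
                 df = tab$df, p_value = tab$p)
}
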