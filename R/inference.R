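#' Univariate screening of OS predictors
#'
#' One univariate Cox regression per candidate covariate, reporting the
#' hazard ratio, Wald 95% CI and p-value, sorted by p-value — the screening
#' step that precedes multivariate model building. P-values are reported raw
#' (as in the source procedure); set `adjust = "holm"` for a safer
#' multiplicity-adjusted column.
#'
#' @param data tibble with `time`, `event` and covariate columns.
#' @param covariates candidate covariate names.
#' @param adjust `"none"` (default) or any method of [stats::p.adjust()].
#' @return tibble with `covariate`, `estimate` (HR), `lo`, `hi`, `p_value`
#'   (and `p_adjusted` unless `adjust = "none"`), `n`.
#' @export
univariate_screen_os <- function(data, covariates, adjust = "none") {
  rows <- lapply(covariates, function(cv) {
    if (length(unique(data[[cv]])) < 2) {
      warning(sprintf("covariate '%s' is constant: skipped", cv))
      return(NULL)
    }
    f <- cox_fit(data, cv)
    cbind(f$hr[1, ], n = f$n)
  })
  tab <- do.call(rbind, rows)
  names(tab)[names(tab) == "hr"] <- "estimate"
  tab <- tab[order(tab$p_value), ]
  if (adjust != "none") tab$p_adjusted <- stats::p.adjust(tab$p_value, adjust)
  tibble::as_tibble(tab)
}

#' Univariate screening of ORR predictors
#'
#' One univariate logistic regression per candidate covariate with odds
#' ratios, analogous to [univariate_screen_os()].
#'
#' @inheritParams univariate_screen_os
#' @return tibble with `covariate`, `estimate` (OR), `lo`, `hi`, `p_value`
#'   (and `p_adjusted` unless `adjust = "none"`), `n`.
#' @export
univariate_screen_orr <- function(data, covariates, adjust = "none") {
  rows <- lapply(covariates, function(cv) {
    if (length(unique(data[[cv]])) < 2) {
      warning(sprintf("covariate '%s' is constant: skipped", cv))
      return(NULL)
    }
    f <- fit_logistic_multivariate(data, cv)
    cbind(f$or[1, ], n = f$n)
  })
  tab <- do.call(rbind, rows)
  names(tab)[names(tab) == "or"] <- "estimate"
  tab <- tab[order(tab$p_value), ]
  if (adjust != "none") tab$p_adjusted <- stats::p.adjust(tab$p_value, adjust)
  tibble::as_tibble(tab)
}

#' Split a dataset into training and test partitions
#'
#' Disjoint, exhaustive random partition, optionally stratified (e.g. by
#' event status and CTFI group) so that the strata proportions in the test
#' set match the full data within one subject per stratum.
#'
#' @param data tibble.
#' @param test_fraction fraction assigned to the test set, in (0, 1).
#' @param seed integer seed.
#' @param stratify_by optional character vector of stratification columns.
#' @return list with tibbles `train` and `test`.
#' @export
train_test_split <- function(data, test_fraction, seed = 1L, stratify_by = NULL) {
  if (!(test_fraction > 0 && test_fraction < 1)) {
    stop("`test_fraction` must be in (0, 1)", call. = FALSE)
  }
  n <- nrow(data)
  strata <- if (is.null(stratify_by)) rep(1L, n) else
    interaction(data[, stratify_by, drop = FALSE], drop = TRUE)
  idx_test <- with_seed(seed, {
    unlist(lapply(split(seq_len(n), strata), function(ix) {
      k <- round(length(ix) * test_fraction)
      if (k == 0 || k == length(ix)) k <- max(1, min(length(ix) - 1, k))
      sample(ix, k)
    }), use.names = FALSE)
  })
  list(train = data[-idx_test, , drop = FALSE],
       test = data[idx_test, , drop = FALSE])
}

# simulate one replicate of survival outcomes from a fitted log-logistic
# model at the observed covariates, reusing the observed administrative
# censoring pattern (censored subjects keep their censoring time; subjects
# with observed events are censored at the maximum observed follow-up)
.simulate_from_os_fit <- function(fit, data) {
  stopifnot(fit$family == "loglogistic")
  X <- as.matrix(data[, fit$covariates, drop = FALSE])
  lam <- fit$estimates[["lambda"]]
  p <- fit$estimates[["p"]]
  af <- exp(drop(X %*% fit$coefficients))
  u <- stats::runif(nrow(data))
  tt <- lam * af * (1 / u - 1)^(1 / p)
  cens <- ifelse(data$event, max(data$time), data$time)
  tibble::tibble(time = pmin(tt, cens), event = tt <= cens)
}

# KM survivor evaluated at a fixed grid (right-continuous step function)
.km_at <- function(times, events, grid) {
  sf <- survival::survfit(survival::Surv(times, events) ~ 1)
  idx <- findInterval(grid, sf$time)
  c(1, sf$surv)[idx + 1]
}

#' Visual predictive check
#'
#' Simulates `n_replicates` outcome sets from a fitted model at the observed
#' covariates and overlays percentile bands on the observed data. For a
#' survival fit the bands are Kaplan-Meier percentiles on a monthly grid
#' (censoring pattern reused from the data); for a sigmoid-Emax response
#' fit they are response-rate percentiles in exposure quartile bins.
#'
#' @param fit a `survival_fit` (log-logistic) or `logistic_fit` (Emax ORR).
#' @param data the observed dataset the fit was computed on.
#' @param n_replicates number of simulation replicates (default 50, the
#'   procedure constant of the validation workflow).
#' @param seed integer seed.
#' @param probs lower/upper percentile of the prediction band.
#' @return object of class `vpc_result`: `bands` tibble (`month` or
#'   `bin_median_auc_u`, `lo`, `mid`, `hi`, `observed`), `n_replicates`,
#'   `probs`.
#' @export
vpc <- function(fit, data, n_replicates = 50, seed = 1L,
                probs = c(0.025, 0.975)) {
  if (n_replicates < 2) stop("`n_replicates` must be >= 2", call. = FALSE)
  UseMethod("vpc")
}

#' @export
vpc.survival_fit <- function(fit, data, n_replicates = 50, seed = 1L,
                             probs = c(0.025, 0.975)) {
  if (!fit$converged) stop("fit did not converge", call. = FALSE)
  months <- seq(0, floor(max(data$time) / DAYS_PER_MONTH))
  grid <- months * DAYS_PER_MONTH
  sims <- with_seed(seed, {
    vapply(seq_len(n_replicates), function(i) {
      r <- .simulate_from_os_fit(fit, data)
      .km_at(r$time, r$event, grid)
    }, numeric(length(grid)))
  })
  qs <- apply(sims, 1, stats::quantile, probs = c(probs[1], 0.5, probs[2]))
  structure(list(
    bands = tibble::tibble(month = months, lo = qs[1, ], mid = qs[2, ],
                           hi = qs[3, ],
                           observed = .km_at(data$time, data$event, grid)),
    n_replicates = n_replicates, probs = probs, type = "os"
  ), class = "vpc_result")
}

#' @export
vpc.logistic_fit <- function(fit, data, n_replicates = 50, seed = 1L,
                             probs = c(0.025, 0.975)) {
  stopifnot(all(c("auc_u", "ctfi_group", "responder") %in% names(data)))
  p_hat <- orr_probability(data$auc_u, data$ctfi_group,
                           emax_orr_params(fit$estimates[["emax_resistant"]],
                                           fit$estimates[["emax_sensitive"]],
                                           fit$estimates[["ec50"]]))
  qbrk <- stats::quantile(data$auc_u, c(0, 0.25, 0.5, 0.75, 1))
  bin <- cut(data$auc_u, unique(qbrk), include.lowest = TRUE)
  sims <- with_seed(seed, {
    vapply(seq_len(n_replicates), function(i) {
      y <- stats::runif(nrow(data)) < p_hat
      tapply(y, bin, mean)
    }, numeric(nlevels(bin)))
  })
  qs <- apply(sims, 1, stats::quantile, probs = c(probs[1], 0.5, probs[2]))
  structure(list(
    bands = tibble::tibble(
      bin_median_auc_u = as.numeric(tapply(data$auc_u, bin, stats::median)),
      lo = qs[1, ], mid = qs[2, ], hi = qs[3, ],
      observed = as.numeric(tapply(as.numeric(data$responder), bin, mean))),
    n_replicates = n_replicates, probs = probs, type = "orr"
  ), class = "vpc_result")
}

#' @export
print.vpc_result <- function(x, ...) {
  cat(sprintf("<vpc_result> %s, %d replicates, %g/%g%% bands\n", x$type,
              x$n_replicates, 100 * x$probs[1], 100 * x$probs[2]))
  print(x$bands, n = 6)
  invisible(x)
}

#' Calibration and prediction error of a survival fit
#'
#' Compares the model-predicted survivor probability (averaged over the
#' subjects' covariates) with the observed Kaplan-Meier estimate at the
#' requested timepoints. `error = predicted - observed`.
#'
#' @param fit a log-logistic `survival_fit`.
#' @param data the dataset (with `time`, `event` and the fit covariates).
#' @param timepoints times in days; points beyond the maximum follow-up are
#'   dropped with a warning.
#' @return tibble with `time`, `predicted`, `observed`, `error`.
#' @export
calibration_and_prediction_error <- function(fit, data, timepoints) {
  stopifnot(inherits(fit, "survival_fit"), fit$family == "loglogistic")
  beyond <- timepoints > max(data$time)
  if (any(beyond)) {
    warning(sprintf("%d timepoint(s) beyond max follow-up dropped", sum(beyond)))
    timepoints <- timepoints[!beyond]
  }
  X <- as.matrix(data[, fit$covariates, drop = FALSE])
  af <- exp(drop(X %*% fit$coefficients))
  lam <- fit$estimates[["lambda"]]; p <- fit$estimates[["p"]]
  pred <- vapply(timepoints,
                 function(t) mean(1 / (1 + (t / (lam * af))^p)), 0)
  obs <- .km_at(data$time, data$event, timepoints)
  tibble::tibble(time = timepoints, predicted = pred, observed = obs,
                 error = pred - obs)
}

#' Bootstrap resampling of a model fit
#'
#' Resamples patients with replacement `n_boot` times (default 250, the
#' procedure constant of the uncertainty assessment), refits on every
#' replicate, and summarizes each parameter by its percentile 95% CI.
#' Replicate fit failures are excluded and counted; more than 20% failures
#' is an error.
#'
#' @param data patient-level tibble.
#' @param fit_fun function taking a resampled tibble and returning a named
#'   numeric vector of parameter estimates.
#' @param n_boot number of bootstrap subsamples, >= 2.
#' @param seed integer seed.
#' @return list of class `bootstrap_result`: `estimates` (replicate x
#'   parameter matrix), `ci` tibble (`parameter`, `lo`, `median`, `hi`),
#'   `n_boot`, `n_failed`.
#' @export
bootstrap_fits <- function(data, fit_fun, n_boot = 250, seed = 1L) {
  if (n_boot < 2) stop("`n_boot` must be >= 2", call. = FALSE)
  n <- nrow(data)
  seeds <- spawn_seeds(seed, n_boot)
  reps <- lapply(seq_len(n_boot), function(b) {
    idx <- with_seed(seeds[b], sample.int(n, n, replace = TRUE))
    try(fit_fun(data[idx, , drop = FALSE]), silent = TRUE)
  })
  ok <- !vapply(reps, inherits, TRUE, "try-error")
  n_failed <- sum(!ok)
  if (n_failed > 0.2 * n_boot) {
    stop(sprintf("%d/%d bootstrap replicates failed", n_failed, n_boot),
         call. = FALSE)
  }
  est <- do.call(rbind, reps[ok])
  qs <- apply(est, 2, stats::quantile, probs = c(0.025, 0.5, 0.975))
  structure(list(
    estimates = est,
    ci = tibble::tibble(parameter = colnames(est), lo = qs[1, ],
                        median = qs[2, ], hi = qs[3, ]),
    n_boot = n_boot, n_failed = n_failed
  ), class = "bootstrap_result")
}
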