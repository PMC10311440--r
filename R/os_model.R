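#' Covariates of the final overall-survival model
#'
#' Fixed covariate set of the final log-logistic OS model, in design-matrix
#' order: CTFI chemosensitivity group (indicator, >= 90 days), log LDH,
#' NL ratio, brain metastases (indicator), unbound lurbinectedin exposure
#' `auc_u` (model scale: µg·h/L), total doxorubicin exposure `auc_dox`
#' (model scale: mg·h/L), and their product `auc_u_auc_dox`.
#'
#' @format character vector of length 7.
#' @export
OS_COVARIATES <- c("ctfi_ge90", "log_ldh", "nl_ratio", "brain_mets",
                   "auc_u", "auc_dox", "auc_u_auc_dox")

# Reference values subtracted from the continuous covariates so the scale
# parameter lambda is the median survival time of a reference patient
# (resistant, no brain metastases, LDH 250 IU/L, NL ratio 4.5, exposures at
# typical combination-regimen medians). Acceleration factors are invariant
# to these constants.
.os_default_centers <- c(ctfi_ge90 = 0, log_ldh = log(250), nl_ratio = 4.5,
                         brain_mets = 0, auc_u = 1.0, auc_dox = 1.5,
                         auc_u_auc_dox = 1.5)

#' Parameters of the log-logistic accelerated failure time OS model
#'
#' The survivor function is `S(t | x) = 1 / (1 + (t / (lambda * AF(x)))^p)`
#' with acceleration factor `AF(x) = exp(alpha0 + sum(alphas * x))`: `lambda`
#' is the median survival (days) of a patient at the reference covariate
#' values, `p > 1` gives the characteristic rise-then-fall hazard, and each
#' `exp(alpha)` is the multiplicative effect of one covariate unit on the
#' survival-time scale (AF > 1 = longer survival). `alpha0` is fixed at 0
#' during fitting (it is not separately identifiable from `lambda`) and is
#' exposed only for simulation-side flexibility.
#'
#' @param p shape parameter, > 0.
#' @param lambda scale parameter (days), > 0.
#' @param alphas named numeric vector of covariate coefficients (log
#'   acceleration factors); names must be exactly [OS_COVARIATES].
#' @param alpha0 intercept adjustment, default 0.
#' @param centers named numeric vector of reference values subtracted from
#'   the covariate columns before entering the linear predictor.
#' @return an object of class `loglogistic_os_params`.
#' @export
loglogistic_os_params <- function(p, lambda, alphas, alpha0 = 0,
                                  centers = .os_default_centers) {
  assert_positive(p, "p")
  assert_positive(lambda, "lambda")
  if (!setequal(names(alphas), OS_COVARIATES)) {
    stop("`alphas` must be named exactly by OS_COVARIATES", call. = FALSE)
  }
  alphas <- alphas[OS_COVARIATES]
  centers <- centers[OS_COVARIATES]
  structure(list(p = p, lambda = lambda, alphas = alphas, alpha0 = alpha0,
                 centers = centers),
            class = "loglogistic_os_params")
}

#' Final published OS model parameters
#'
#' The final log-logistic OS model for lurbinectedin +/- doxorubicin in
#' relapsed SCLC: shape 2.4, scale 294.2 days, and per-covariate acceleration
#' factors 1.9 (CTFI >= 90 d), 0.5 (log LDH), 0.9 (NL ratio), 0.6 (brain
#' metastases), 1.4 (AUCu, per µg·h/L), 1.2 (AUCDOX, per mg·h/L) and 0.8
#' (AUCu x AUCDOX interaction). Used as simulation truth throughout the
#' package's recovery experiments.
#'
#' @return a [loglogistic_os_params()].
#' @export
os_params_published <- function() {
  af <- c(ctfi_ge90 = 1.9, log_ldh = 0.5, nl_ratio = 0.9, brain_mets = 0.6,
          auc_u = 1.4, auc_dox = 1.2, auc_u_auc_dox = 0.8)
  loglogistic_os_params(p = 2.4, lambda = 294.2, alphas = log(af))
}

#' Build the OS design matrix from a cohort and its exposures
#'
#' Joins patients and exposures by `id`, converts the exposure metrics to
#' their model scale (AUCu ng·h/L -> µg·h/L; AUCDOX µg·h/L -> mg·h/L, i.e.
#' both divided by 1000 so coefficients are plausible per-unit effects),
#' forms the interaction as the product of the model-scale exposures, and
#' centers continuous covariates at `centers`.
#'
#' @param patients cohort tibble from [generate_covariates()].
#' @param exposures exposure tibble from [assign_exposures()].
#' @param centers named centering vector (defaults to the package reference
#'   values).
#' @return numeric matrix with columns [OS_COVARIATES].
#' @export
os_design_matrix <- function(patients, exposures,
                             centers = .os_default_centers) {
  stopifnot(all(patients$id == exposures$id))
  if (any(exposures$auc_u < 0) || any(exposures$auc_dox < 0)) {
    stop("exposures must be non-negative", call. = FALSE)
  }
  au <- exposures$auc_u / 1000    # ng·h/L -> µg·h/L
  ad <- exposures$auc_dox / 1000  # µg·h/L -> mg·h/L
  X <- cbind(
    ctfi_ge90 = as.numeric(patients$ctfi_group == "sensitive"),
    log_ldh = log(patients$ldh),
    nl_ratio = patients$nl_ratio,
    brain_mets = as.numeric(patients$brain_mets),
    auc_u = au,
    auc_dox = ad,
    auc_u_auc_dox = au * ad
  )
  for (j in OS_COVARIATES) {
    if (any(!is.finite(X[, j]))) {
      stop(sprintf("non-finite values in covariate '%s'", j), call. = FALSE)
    }
  }
  sweep(X, 2, centers[OS_COVARIATES], "-")
}

# acceleration factor AF(x) for a design matrix (already centered)
.os_af <- function(params, X) {
  X <- rbind(X)  # promote a bare vector to a 1-row matrix
  unname(exp(params$alpha0 +
               drop(X[, OS_COVARIATES, drop = FALSE] %*% params$alphas)))
}

#' Log-logistic survivor function with covariates
#'
#' `S(t | x) = 1 / (1 + (t / (lambda * AF(x)))^p)`; equals 1 at `t = 0`,
#' decreases strictly, and `S(lambda * AF) = 0.5` (the scale times the
#' acceleration factor is the conditional median).
#'
#' @param t time in days, >= 0 (vectorized).
#' @param params a [loglogistic_os_params()].
#' @param x named covariate vector or matrix on the centered design scale
#'   (as produced by [os_design_matrix()]); all zeros = reference patient.
#' @return survival probabilities.
#' @export
loglogistic_survival <- function(t, params, x = numeric(0)) {
  stopifnot(all(t >= 0))
  af <- if (length(x)) .os_af(params, x) else 1
  1 / (1 + (t / (params$lambda * af))^params$p)
}

#' Log-logistic hazard function with covariates
#'
#' `h(t) = -d log S / dt`. For `p > 1` the hazard rises to a single maximum
#' and then falls; for `p = 1` it decreases monotonically from
#' `1 / (lambda * AF)`.
#'
#' @inheritParams loglogistic_survival
#' @param t time in days, > 0.
#' @return hazard rates (per day).
#' @export
loglogistic_hazard <- function(t, params, x = numeric(0)) {
  if (any(t <= 0)) stop("`t` must be > 0 for the hazard", call. = FALSE)
  af <- if (length(x)) .os_af(params, x) else 1
  s <- params$lambda * af
  z <- (t / s)^params$p
  (params$p / t) * z / (1 + z)
}

#' Simulate survival outcomes from the OS model
#'
#' Draws each patient's death time by inverse-transform sampling from their
#' conditional log-logistic survivor function
#' (`T = lambda * AF(x) * (1/U - 1)^(1/p)`, `U ~ Uniform(0,1)`), then applies
#' administrative censoring from a [censoring_spec()].
#'
#' @param patients,exposures cohort and exposure tibbles (joined by `id`).
#' @param os_params a [loglogistic_os_params()].
#' @param censoring a [censoring_spec()], or `NULL` for no censoring.
#' @param seed integer seed.
#' @return tibble with `id`, `time` (days), `event` (TRUE = death observed);
#'   attribute `"event_fraction"` reports the observed-death fraction.
#' @export
simulate_os_outcomes <- function(patients, exposures, os_params,
                                 censoring = censoring_spec(), seed = 1L) {
  stopifnot(inherits(os_params, "loglogistic_os_params"))
  X <- os_design_matrix(patients, exposures, os_params$centers)
  af <- .os_af(os_params, X)
  n <- nrow(patients)
  out <- with_seed(seed, {
    u <- stats::runif(n)
    tt <- os_params$lambda * af * (1 / u - 1)^(1 / os_params$p)
    if (is.null(censoring)) {
      tibble::tibble(id = patients$id, time = tt, event = rep(TRUE, n))
    } else {
      cens <- censoring$cutoff_days - stats::runif(n, 0, censoring$accrual_days)
      tibble::tibble(id = patients$id,
                     time = pmin(tt, cens), event = tt <= cens)
    }
  })
  attr(out, "event_fraction") <- mean(out$event)
  out
}

#' Assemble the OS model frame
#'
#' Convenience constructor of the analysis dataset: `time`, `event` and the
#' centered covariate columns of [OS_COVARIATES], ready for
#' [fit_parametric_os()] and [cox_fit()].
#'
#' @param patients,exposures,outcomes tibbles joined by `id`.
#' @param centers centering vector passed to [os_design_matrix()].
#' @return tibble with `id`, `time`, `event` and the seven covariates.
#' @export
os_model_frame <- function(patients, exposures, outcomes,
                           centers = .os_default_centers) {
  stopifnot(all(patients$id == outcomes$id))
  X <- os_design_matrix(patients, exposures, centers)
  tibble::tibble(id = patients$id, time = outcomes$time,
                 event = outcomes$event, tibble::as_tibble(X))
}
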