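#' Parameters of the sigmoid-Emax logistic ORR model
#'
#' Objective response is modeled on the logit scale as
#' `logit(p) = -10 + Emax(group) * auc_u^10 / (ec50^10 + auc_u^10)`,
#' where `auc_u` is the unbound lurbinectedin exposure (ng·h/L), `ec50` is
#' the exposure giving half the maximal logit shift, and the maximal
#' response `Emax` depends on the CTFI chemosensitivity group (resistant
#' < 90 d vs sensitive >= 90 d). The Hill coefficient (10) and intercept
#' (-10) are structural constants of the model, not free parameters: the
#' intercept pins the no-exposure response probability to
#' `plogis(-10) ~ 4.5e-5` and the steep Hill makes the curve an
#' almost-switch around `ec50`.
#'
#' @param emax_resistant,emax_sensitive maximal logit shifts for the two
#'   CTFI groups.
#' @param ec50 half-maximal unbound exposure (ng·h/L), > 0.
#' @return an object of class `emax_orr_params`.
#' @export
emax_orr_params <- function(emax_resistant, emax_sensitive, ec50) {
  assert_positive(ec50, "ec50")
  structure(list(emax_resistant = emax_resistant,
                 emax_sensitive = emax_sensitive,
                 ec50 = ec50, hill = 10, intercept = -10),
            class = "emax_orr_params")
}

#' Final published ORR model parameters
#'
#' Emax 8.5 (resistant), 10.8 (sensitive); EC50 877 ng·h/L. Used as
#' simulation truth in the package's recovery experiments.
#'
#' @return an [emax_orr_params()].
#' @export
orr_params_published <- function() {
  emax_orr_params(emax_resistant = 8.5, emax_sensitive = 10.8, ec50 = 877)
}

# Hill term auc^h / (ec50^h + auc^h) computed on the log scale:
# 1 / (1 + exp(h * (log ec50 - log auc))) — overflow-free for h = 10.
.hill_fraction <- function(auc_u, ec50, hill = 10) {
  out <- numeric(length(auc_u))
  pos <- auc_u > 0
  out[pos] <- stats::plogis(hill * (log(auc_u[pos]) - log(ec50)))
  out  # exact lower asymptote 0 at auc_u = 0
}

#' Response probability under the sigmoid-Emax logistic model
#'
#' @param auc_u unbound lurbinectedin exposure (ng·h/L), >= 0; vectorized.
#' @param ctfi_group `"resistant"` or `"sensitive"` (factor or character),
#'   recycled against `auc_u`.
#' @param params an [emax_orr_params()].
#' @return response probabilities, monotone non-decreasing in `auc_u` for
#'   positive Emax.
#' @export
orr_probability <- function(auc_u, ctfi_group, params = orr_params_published()) {
  if (any(auc_u < 0)) stop("`auc_u` must be >= 0", call. = FALSE)
  grp <- as.character(ctfi_group)
  if (!all(grp %in% c("resistant", "sensitive"))) {
    stop("`ctfi_group` must be 'resistant' or 'sensitive'", call. = FALSE)
  }
  emax <- ifelse(grp == "sensitive", params$emax_sensitive, params$emax_resistant)
  stats::plogis(params$intercept + emax * .hill_fraction(auc_u, params$ec50, params$hill))
}

#' Simulate binary response outcomes
#'
#' `responder ~ Bernoulli(p_i)` with `p_i` from [orr_probability()].
#'
#' @param patients,exposures cohort and exposure tibbles joined by `id`.
#' @param orr_params an [emax_orr_params()].
#' @param seed integer seed.
#' @return tibble with `id`, `responder` (logical).
#' @export
simulate_orr_outcomes <- function(patients, exposures,
                                  orr_params = orr_params_published(),
                                  seed = 1L) {
  stopifnot(all(patients$id == exposures$id))
  p <- orr_probability(exposures$auc_u, patients$ctfi_group, orr_params)
  with_seed(seed, tibble::tibble(id = patients$id,
                                 responder = stats::runif(nrow(patients)) < p))
}

#' Fit the sigmoid-Emax logistic ORR model by maximum likelihood
#'
#' Maximizes the Bernoulli log-likelihood over the three free parameters
#' (`emax_resistant`, `emax_sensitive`, `log ec50`) by BFGS; Hill (10) and
#' intercept (-10) stay fixed. EC50 is estimated on the log scale and its
#' RSE% is mapped back to the natural scale by the delta method.
#'
#' @param data tibble with `auc_u` (ng·h/L), `ctfi_group`, `responder`.
#' @return list of class `logistic_fit`: `estimates` (named:
#'   `emax_resistant`, `emax_sensitive`, `ec50`), `se`, `rse_percent`,
#'   `vcov` (internal scale), `minus2LL`, `aic`, `converged`.
#' @export
fit_emax_orr <- function(data) {
  stopifnot(all(c("auc_u", "ctfi_group", "responder") %in% names(data)))
  grp <- as.character(data$ctfi_group)
  if (!all(c("resistant", "sensitive") %in% grp)) {
    warning("one CTFI group absent: group-specific Emax not identifiable for it")
  }
  y <- as.numeric(data$responder)
  if (length(unique(y)) < 2) {
    stop("all outcomes identical: complete separation, model not estimable",
         call. = FALSE)
  }
  sens <- grp == "sensitive"
  auc <- data$auc_u
  negll <- function(th) {
    emax <- ifelse(sens, th[2], th[1])
    eta <- -10 + emax * .hill_fraction(auc, exp(th[3]))
    -sum(y * stats::plogis(eta, log.p = TRUE) +
           (1 - y) * stats::plogis(-eta, log.p = TRUE))
  }
  # heuristic starts: Emax from observed high-exposure response rates,
  # ec50 from the exposure median
  start_emax <- function(g) {
    r <- mean(y[grp == g & auc > stats::median(auc)])
    r <- min(max(r, 0.01), 0.99)
    stats::qlogis(r) + 10
  }
  st <- c(if (any(grp == "resistant")) start_emax("resistant") else 8,
          if (any(grp == "sensitive")) start_emax("sensitive") else 8,
          log(stats::median(auc[auc > 0])))
  fit <- NULL
  for (attempt in 1:3) {
    s <- if (attempt == 1) st else st + stats::rnorm(3, 0, 0.3)
    res <- try(stats::optim(s, negll, method = "BFGS",
                            control = list(maxit = 500, reltol = 1e-12)),
               silent = TRUE)
    if (!inherits(res, "try-error") && (is.null(fit) || res$value < fit$value)) fit <- res
    if (!is.null(fit) && fit$convergence == 0) break
  }
  if (is.null(fit)) stop("Emax ORR fit failed", call. = FALSE)
  H <- stats::optimHess(fit$par, negll)
  vcov <- try(solve(H), silent = TRUE)
  se_int <- if (inherits(vcov, "try-error")) rep(NA_real_, 3) else sqrt(pmax(diag(vcov), 0))
  est <- c(emax_resistant = fit$par[1], emax_sensitive = fit$par[2],
           ec50 = exp(fit$par[3]))
  se <- c(se_int[1], se_int[2], est[["ec50"]] * se_int[3])  # delta method for ec50
  names(se) <- names(est)
  m2ll <- 2 * fit$value
  structure(list(
    estimates = est, se = se,
    rse_percent = 100 * se / abs(est),
    vcov = if (inherits(vcov, "try-error")) NULL else vcov,
    minus2LL = m2ll, aic = m2ll + 2 * 3,
    n = nrow(data), converged = fit$convergence == 0
  ), class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("<logistic_fit> n=%d  -2LL=%.2f  AIC=%.2f%s\n", x$n, x$minus2LL,
              x$aic, if (x$converged) "" else "  [NOT CONVERGED]"))
  tab <- cbind(estimate = x$estimates, rse_percent = x$rse_percent)
  print(round(tab, 3))
  invisible(x)
}

#' Multivariate logistic regression comparator
#'
#' Standard maximum-likelihood logistic regression (IRLS via
#' [stats::glm()]) with odds ratios and Wald 95% CIs; the comparator model
#' class against which the sigmoid-Emax model was selected.
#'
#' @param data tibble with a logical/0-1 `responder` column and covariates.
#' @param covariates character vector of covariate names.
#' @return list of class `logistic_fit` with an additional `or` tibble
#'   (`covariate`, `or`, `lo`, `hi`, `p_value`).
#' @export
fit_logistic_multivariate <- function(data, covariates) {
  stopifnot(length(covariates) >= 1)
  for (cv in covariates) {
    if (length(unique(data[[cv]])) < 2) {
      stop(sprintf("covariate '%s' is constant", cv), call. = FALSE)
    }
  }
  y <- as.numeric(data$responder)
  if (length(unique(y)) < 2) stop("all outcomes identical: separation", call. = FALSE)
  fml <- stats::as.formula(paste("responder ~", paste(covariates, collapse = " + ")))
  fit <- stats::glm(fml, family = stats::binomial(), data = data)
  if (!fit$converged) warning("IRLS did not converge (possible separation)")
  if (any(abs(stats::coef(fit)) > 15, na.rm = TRUE)) {
    warning("very large coefficients: possible separation or collinearity")
  }
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  z <- beta / se
  idx <- setdiff(names(beta), "(Intercept)")
  m2ll <- -2 * as.numeric(stats::logLik(fit))
  structure(list(
    estimates = beta, se = se, rse_percent = 100 * se / abs(beta),
    vcov = stats::vcov(fit),
    or = tibble::tibble(covariate = idx, or = unname(exp(beta[idx])),
                        lo = unname(exp(beta[idx] - 1.96 * se[idx])),
                        hi = unname(exp(beta[idx] + 1.96 * se[idx])),
                        p_value = unname(2 * stats::pnorm(-abs(z[idx])))),
    minus2LL = m2ll, aic = m2ll + 2 * length(beta),
    n = nrow(data), converged = fit$converged, model = fit
  ), class = "logistic_fit")
}

#' Classification metrics at a probability threshold
#'
#' Accuracy, precision, recall and F1 from the confusion matrix obtained by
#' thresholding predicted probabilities — the metrics used to benchmark
#' candidate ORR models. When no positives are predicted, precision (and F1)
#' are reported as 0 with a warning.
#'
#' @param probabilities predicted response probabilities.
#' @param outcomes observed binary outcomes (logical or 0/1).
#' @param threshold classification threshold in (0, 1).
#' @return named list: `accuracy`, `precision`, `recall`, `f1`, plus the
#'   confusion counts `tp`, `fp`, `fn`, `tn`.
#' @export
classification_metrics <- function(probabilities, outcomes, threshold = 0.5) {
  if (length(probabilities) == 0) stop("empty input", call. = FALSE)
  stopifnot(length(probabilities) == length(outcomes),
            threshold > 0, threshold < 1)
  pred <- probabilities >= threshold
  obs <- as.logical(outcomes)
  tp <- sum(pred & obs); fp <- sum(pred & !obs)
  fn <- sum(!pred & obs); tn <- sum(!pred & !obs)
  precision <- if (tp + fp == 0) {
    warning("no predicted positives: precision undefined, reported as 0")
    0
  } else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  list(accuracy = (tp + tn) / length(obs), precision = precision,
       recall = recall, f1 = f1, tp = tp, fp = fp, fn = fn, tn = tn)
}
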