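#' Cohort covariate profile
#'
#' A `cohort_profile` describes the marginal distribution of every baseline
#' covariate used by the exposure-response models: chemotherapy-free interval
#' (CTFI), LDH, neutrophil/lymphocyte (NL) ratio, brain-metastases prevalence,
#' albumin, alpha-1-acid glycoprotein (AAG), body surface area (BSA), age and
#' platelet/lymphocyte (PL) ratio. Right-skewed laboratory values use
#' lognormal marginals matched to a published mean/SD; physiological
#' quantities with narrow ranges (age, BSA, albumin) use truncated normals;
#' brain metastases is Bernoulli. Covariates are sampled independently by
#' default; an optional Gaussian-copula rank-correlation matrix can couple
#' them for sensitivity analyses.
#'
#' @param covariates named list; each element is a list with `family`
#'   (`"lognormal"` or `"truncnorm"`), `mean`, `sd`, and for `truncnorm`
#'   optional `lower`/`upper` truncation bounds.
#' @param brain_mets_prev prevalence of brain metastases, in `[0, 1]`.
#' @param arm character label attached to every generated patient.
#' @param correlations optional symmetric rank-correlation matrix with
#'   dimnames drawn from the covariate names (plus `"brain_mets"`), used as a
#'   Gaussian copula.
#' @return an object of class `cohort_profile`.
#' @seealso [profile_atlantis_experimental()], [generate_covariates()]
#' @export
cohort_profile <- function(covariates, brain_mets_prev, arm = "cohort",
                           correlations = NULL) {
  stopifnot(is.list(covariates), length(covariates) > 0)
  for (nm in names(covariates)) {
    cv <- covariates[[nm]]
    if (!cv$family %in% c("lognormal", "truncnorm")) {
      stop(sprintf("unknown family '%s' for covariate '%s'", cv$family, nm),
           call. = FALSE)
    }
    if (!is.finite(cv$mean) || cv$mean <= 0) {
      stop(sprintf("covariate '%s': mean must be > 0", nm), call. = FALSE)
    }
    if (!is.finite(cv$sd) || cv$sd < 0) {
      stop(sprintf("covariate '%s': sd must be >= 0", nm), call. = FALSE)
    }
  }
  if (!is.finite(brain_mets_prev) || brain_mets_prev < 0 || brain_mets_prev > 1) {
    stop("`brain_mets_prev` must lie in [0, 1]", call. = FALSE)
  }
  if (!is.null(correlations)) {
    correlations <- as.matrix(correlations)
    if (!isSymmetric(unname(correlations))) {
      stop("`correlations` must be symmetric", call. = FALSE)
    }
  }
  structure(
    list(covariates = covariates, brain_mets_prev = brain_mets_prev,
         arm = arm, correlations = correlations),
    class = "cohort_profile"
  )
}

#' @export
print.cohort_profile <- function(x, ...) {
  cat("<cohort_profile> arm:", x$arm, "\n")
  for (nm in names(x$covariates)) {
    cv <- x$covariates[[nm]]
    cat(sprintf("  %-10s %-9s mean %-8.4g sd %.4g\n", nm, cv$family, cv$mean, cv$sd))
  }
  cat(sprintf("  brain_mets Bernoulli(%.3f)\n", x$brain_mets_prev))
  if (!is.null(x$correlations)) cat("  Gaussian-copula correlations supplied\n")
  invisible(x)
}

# Published mean (SD) baseline summaries for the pooled E-R population, by
# study/arm. Lab values are right-skewed and get lognormal marginals.
.profile_base <- function(age_mean, age_sd, ctfi_mean, ctfi_sd,
                          bsa_mean, bsa_sd, alb_mean, alb_sd,
                          aag_mean, aag_sd, ldh_mean, ldh_sd,
                          nl_mean, nl_sd, pl_mean, pl_sd,
                          brain_mets_prev, arm) {
  cohort_profile(
    covariates = list(
      age      = list(family = "truncnorm", mean = age_mean, sd = age_sd,
                      lower = 18, upper = 100),
      ctfi_days = list(family = "lognormal", mean = ctfi_mean, sd = ctfi_sd),
      bsa      = list(family = "truncnorm", mean = bsa_mean, sd = bsa_sd,
                      lower = 1.0, upper = 3.0),
      albumin  = list(family = "truncnorm", mean = alb_mean, sd = alb_sd,
                      lower = 1.5, upper = 6.0),
      aag      = list(family = "lognormal", mean = aag_mean, sd = aag_sd),
      ldh      = list(family = "lognormal", mean = ldh_mean, sd = ldh_sd),
      nl_ratio = list(family = "lognormal", mean = nl_mean, sd = nl_sd),
      pl_ratio = list(family = "lognormal", mean = pl_mean, sd = pl_sd)
    ),
    brain_mets_prev = brain_mets_prev,
    arm = arm
  )
}

#' Built-in cohort profiles
#'
#' Profiles matching the published baseline summaries of the two lurbinectedin
#' SCLC study populations and the comparator arm:
#' `profile_atlantis_experimental()` is the phase-3 combination arm
#' (lurbinectedin 2.0 mg/m2 + doxorubicin 40 mg/m2; CTFI mean 157.9 d,
#' brain-metastases prevalence 15.6%); `profile_b005()` is the phase-2
#' single-agent basket cohort (3.2 mg/m2; brain metastases excluded, so
#' prevalence 0); `profile_atlantis_control()` is the physician's-choice
#' control arm.
#'
#' @return a [cohort_profile()].
#' @export
profile_atlantis_experimental <- function() {
  .profile_base(63.0, 8.3, 157.9, 134.0, 1.8, 0.2, 4.1, 0.4,
                129.6, 50.3, 371.6, 402.1, 5.3, 4.8, 252.3, 212.8,
                brain_mets_prev = 0.156, arm = "atlantis_experimental")
}

#' @rdname profile_atlantis_experimental
#' @export
profile_b005 <- function() {
  .profile_base(61.0, 9.6, 116.6, 90.9, 1.8, 0.2, 4.0, 0.5,
                129.3, 45.1, 402.9, 355.3, 5.4, 4.6, 242.0, 129.9,
                brain_mets_prev = 0, arm = "b005")
}

#' @rdname profile_atlantis_experimental
#' @export
profile_atlantis_control <- function() {
  # AAG was not collected in the control arm; the pooled value stands in.
  .profile_base(62.8, 7.6, 153.5, 118.8, 1.9, 0.2, 4.1, 0.4,
                129.5, 49.0, 340.4, 223.6, 4.9, 3.9, 234.6, 149.9,
                brain_mets_prev = 0.159, arm = "atlantis_control")
}

# quantile function of each marginal, used both for independent sampling and
# for the Gaussian copula
.marginal_quantile <- function(cv, u) {
  switch(cv$family,
    lognormal = {
      lp <- lognormal_from_moments(cv$mean, cv$sd)
      stats::qlnorm(u, lp$meanlog, lp$sdlog)
    },
    truncnorm = {
      a <- stats::pnorm(cv$lower %||% 0, cv$mean, cv$sd)
      b <- stats::pnorm(cv$upper %||% Inf, cv$mean, cv$sd)
      stats::qnorm(a + u * (b - a), cv$mean, cv$sd)
    }
  )
}

#' Generate a virtual patient cohort
#'
#' Samples `n` patients from a [cohort_profile()]. The CTFI chemosensitivity
#' group is derived deterministically at the 90-day cut (`resistant` < 90 d,
#' `sensitive` >= 90 d); a `ctfi_ge180` flag is exposed as the additional
#' very-sensitive reporting threshold.
#'
#' @param n number of patients (>= 0).
#' @param profile a [cohort_profile()].
#' @param seed integer seed; the same `(n, profile, seed)` always yields the
#'   identical cohort.
#' @return a tibble with one row per patient: `id`, `age`, `ctfi_days`,
#'   `ctfi_group`, `ctfi_ge180`, `brain_mets`, `ldh`, `albumin`, `aag`,
#'   `bsa`, `nl_ratio`, `pl_ratio`, `arm`.
#' @export
generate_covariates <- function(n, profile, seed = 1L) {
  stopifnot(inherits(profile, "cohort_profile"), n >= 0)
  nms <- names(profile$covariates)
  all_nms <- c(nms, "brain_mets")
  u <- with_seed(seed, {
    if (is.null(profile$correlations)) {
      matrix(stats::runif(n * length(all_nms)), nrow = n,
             ncol = length(all_nms), dimnames = list(NULL, all_nms))
    } else {
      .copula_uniforms(n, all_nms, profile$correlations)
    }
  })
  vals <- lapply(nms, function(nm) .marginal_quantile(profile$covariates[[nm]], u[, nm]))
  names(vals) <- nms
  out <- tibble::tibble(
    id = sprintf("pt%05d", seq_len(n)),
    age = vals$age,
    ctfi_days = vals$ctfi_days,
    ctfi_group = factor(ifelse(vals$ctfi_days >= 90, "sensitive", "resistant"),
                        levels = c("resistant", "sensitive")),
    ctfi_ge180 = vals$ctfi_days >= 180,
    brain_mets = u[, "brain_mets"] < profile$brain_mets_prev,
    ldh = vals$ldh,
    albumin = vals$albumin,
    aag = vals$aag,
    bsa = vals$bsa,
    nl_ratio = vals$nl_ratio,
    pl_ratio = vals$pl_ratio,
    arm = rep(profile$arm, n)
  )
  if (n == 0) out$ctfi_group <- factor(character(0), levels = c("resistant", "sensitive"))
  out
}

# correlated uniforms via a Gaussian copula; missing entries of the
# correlation matrix default to independence
.copula_uniforms <- function(n, nms, corr) {
  k <- length(nms)
  R <- diag(k); dimnames(R) <- list(nms, nms)
  shared <- intersect(rownames(corr), nms)
  R[shared, shared] <- corr[shared, shared]
  diag(R) <- 1
  ev <- eigen(R, symmetric = TRUE)
  if (any(ev$values < -1e-8)) stop("correlation matrix is not positive semi-definite", call. = FALSE)
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), k)
  z <- matrix(stats::rnorm(n * k), nrow = n) %*% t(L)
  u <- stats::pnorm(z)
  dimnames(u) <- list(NULL, nms)
  u
}

#' Read or write a cohort profile as YAML
#'
#' Profiles round-trip losslessly through YAML so a pipeline run can be
#' reproduced from its config file alone.
#'
#' @param profile a [cohort_profile()].
#' @param path file path.
#' @return `read_profile()` returns a [cohort_profile()];
#'   `write_profile()` returns `path` invisibly.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "cohort_profile"))
  lst <- list(
    covariates = profile$covariates,
    brain_mets_prev = profile$brain_mets_prev,
    arm = profile$arm
  )
  if (!is.null(profile$correlations)) {
    lst$correlations <- list(names = rownames(profile$correlations),
                             values = as.vector(profile$correlations))
  }
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  lst <- yaml::read_yaml(path)
  corr <- NULL
  if (!is.null(lst$correlations)) {
    k <- length(lst$correlations$names)
    corr <- matrix(unlist(lst$correlations$values), k, k,
                   dimnames = list(lst$correlations$names, lst$correlations$names))
  }
  cohort_profile(lst$covariates, lst$brain_mets_prev, lst$arm, corr)
}

#' Administrative censoring specification
#'
#' Patients accrue uniformly over `accrual_days` and the database is locked
#' at `cutoff_days` after the first enrolment, so patient-level potential
#' follow-up is `cutoff_days - U(0, accrual_days)`. The default is tuned so
#' that simulating the final published OS model over the combination-arm
#' profile yields roughly 87% observed deaths.
#'
#' @param accrual_days length of the uniform accrual window (days).
#' @param cutoff_days time from first enrolment to data cutoff (days); must
#'   exceed `accrual_days` so every patient has positive follow-up.
#' @return an object of class `censoring_spec`.
#' @export
censoring_spec <- function(accrual_days = 365, cutoff_days = 1500) {
  stopifnot(accrual_days >= 0, is.finite(cutoff_days))
  if (cutoff_days <= 0) stop("censoring horizon must be positive: no observable follow-up", call. = FALSE)
  if (cutoff_days <= accrual_days) {
    stop("`cutoff_days` must exceed `accrual_days` so all patients have follow-up", call. = FALSE)
  }
  structure(list(accrual_days = accrual_days, cutoff_days = cutoff_days),
            class = "censoring_spec")
}
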