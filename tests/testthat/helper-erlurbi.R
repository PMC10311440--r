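# Fixture builders shared across the suite. All data are generated in code.

# patients sitting exactly at the model's reference covariate values, so the
# centered design matrix is all zeros (AF = 1)
reference_cohort <- function(n, group = "resistant") {
  ctfi <- if (group == "sensitive") 120 else 30
  tibble::tibble(
    id = sprintf("ref%05d", seq_len(n)),
    age = 63,
    ctfi_days = ctfi,
    ctfi_group = factor(group, levels = c("resistant", "sensitive")),
    ctfi_ge180 = FALSE,
    brain_mets = FALSE,
    ldh = 250, albumin = 4.1, aag = 121, bsa = 1.8,
    nl_ratio = 4.5, pl_ratio = 250, arm = "reference"
  )
}

# exposures at the model centering values (auc_u 1.0 ug.h/L, auc_dox 1.5 mg.h/L)
reference_exposures <- function(patients) {
  tibble::tibble(id = patients$id, dose_lrb = 2.0, dose_dox = 40,
                 auc_u = 1000, auc_dox = 1500)
}

# small simulated OS analysis dataset from the published truth
simulated_os_data <- function(n, seed = 1L, censoring = censoring_spec()) {
  seeds <- spawn_seeds(seed, 3)
  cohort <- generate_covariates(n, profile_atlantis_experimental(), seeds[1])
  expo <- assign_exposures(cohort, regimen_spec(2.0, 40), pk_defaults(), seeds[2])
  outc <- simulate_os_outcomes(cohort, expo, os_params_published(), censoring, seeds[3])
  os_model_frame(cohort, expo, outc)
}

# hand-rolled product-limit estimator used as the Kaplan-Meier oracle
product_limit_oracle <- function(times, events) {
  ut <- sort(unique(times[events]))
  surv <- numeric(length(ut))
  s <- 1
  for (i in seq_along(ut)) {
    n_risk <- sum(times >= ut[i])
    d <- sum(times == ut[i] & events)
    s <- s * (1 - d / n_risk)
    surv[i] <- s
  }
  list(time = ut, surv = surv)
}

# Cox partial log-likelihood (no ties) for the 1-covariate grid-search oracle
cox_partial_loglik <- function(beta, time, event, x) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]; x <- x[ord]
  eta <- beta * x
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + eta[i] - log(sum(exp(eta[risk])))
  }
  ll
}
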