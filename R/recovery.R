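#' Parameter-recovery experiment for the OS model
#'
#' Simulation-refit experiment over the final published OS model: for each
#' of `n_seeds` replicates, generate an ATLANTIS-like cohort of `n` patients
#' (combination-arm covariate profile), assign exposures under `regimen`,
#' simulate survival from `truth` with administrative censoring (~13%
#' censored under the defaults), refit the full covariate model by maximum
#' likelihood, and collect the recovered shape and per-covariate
#' acceleration factors. Medians over replicates are the package's core
#' recovery surface.
#'
#' @param n_seeds number of simulation replicates.
#' @param n patients per replicate.
#' @param seed master seed.
#' @param truth a [loglogistic_os_params()] used as simulation truth.
#' @param regimen a [regimen_spec()] (default 2.0 mg/m2 + doxorubicin
#'   40 mg/m2, the combination regimen).
#' @param censoring a [censoring_spec()].
#' @return list: `median` (named vector: `p`, `lambda` and AFs per
#'   covariate), `replicates` (matrix, one row per seed), `truth_af`,
#'   `event_fraction` (mean over replicates), `n`, `n_seeds`.
#' @export
os_recovery_experiment <- function(n_seeds = 20, n = 2000, seed = 1L,
                                   truth = os_params_published(),
                                   regimen = regimen_spec(2.0, 40),
                                   censoring = censoring_spec()) {
  seeds <- spawn_seeds(seed, 3 * n_seeds)
  profile <- profile_atlantis_experimental()
  rows <- vapply(seq_len(n_seeds), function(i) {
    s <- seeds[(3 * i - 2):(3 * i)]
    cohort <- generate_covariates(n, profile, s[1])
    expo <- assign_exposures(cohort, regimen, pk_defaults(), s[2])
    outc <- simulate_os_outcomes(cohort, expo, truth, censoring, s[3])
    d <- os_model_frame(cohort, expo, outc, truth$centers)
    fit <- fit_parametric_os(d, "loglogistic", OS_COVARIATES)
    c(p = fit$estimates[["p"]], lambda = fit$estimates[["lambda"]],
      exp(fit$coefficients), event_fraction = attr(outc, "event_fraction"))
  }, numeric(3 + length(OS_COVARIATES)))
  rows <- t(rows)
  med <- apply(rows, 2, stats::median)
  list(median = med[setdiff(names(med), "event_fraction")],
       replicates = rows,
       truth_af = exp(truth$alphas),
       event_fraction = mean(rows[, "event_fraction"]),
       n = n, n_seeds = n_seeds)
}

#' Parameter-recovery experiment for the ORR model
#'
#' Simulation-refit experiment over the final published sigmoid-Emax ORR
#' model: unbound exposures are drawn lognormally around the reported pooled
#' median (1063.7 ng·h/L) with a log-SD of 0.6 so the spread straddles the
#' EC50, CTFI groups are balanced, binary responses are simulated from
#' `truth`, and the three free parameters are refit by maximum likelihood.
#'
#' @param n_seeds number of simulation replicates.
#' @param n patients per replicate (split evenly between CTFI groups).
#' @param seed master seed.
#' @param truth an [emax_orr_params()] used as simulation truth.
#' @param auc_median,auc_sdlog lognormal exposure-spread parameters.
#' @return list: `median` (named: `emax_resistant`, `emax_sensitive`,
#'   `ec50`), `replicates` matrix, `truth`, `n`, `n_seeds`.
#' @export
orr_recovery_experiment <- function(n_seeds = 20, n = 2000, seed = 1L,
                                    truth = orr_params_published(),
                                    auc_median = 1063.7, auc_sdlog = 0.6) {
  seeds <- spawn_seeds(seed, 2 * n_seeds)
  grp <- factor(rep(c("resistant", "sensitive"), length.out = n),
                levels = c("resistant", "sensitive"))
  rows <- vapply(seq_len(n_seeds), function(i) {
    s <- seeds[(2 * i - 1):(2 * i)]
    auc <- with_seed(s[1], stats::rlnorm(n, log(auc_median), auc_sdlog))
    p <- orr_probability(auc, grp, truth)
    y <- with_seed(s[2], stats::runif(n) < p)
    fit <- fit_emax_orr(tibble::tibble(auc_u = auc, ctfi_group = grp,
                                       responder = y))
    fit$estimates
  }, numeric(3))
  rows <- t(rows)
  list(median = apply(rows, 2, stats::median), replicates = rows,
       truth = c(emax_resistant = truth$emax_resistant,
                 emax_sensitive = truth$emax_sensitive, ec50 = truth$ec50),
       n = n, n_seeds = n_seeds)
}
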