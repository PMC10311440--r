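#' Validate a pipeline configuration
#'
#' A pipeline config (YAML file or list) names the cohort profile, regimen,
#' sample sizes, seeds and output directory for an end-to-end run. Referenced
#' paths are checked before any computation.
#'
#' @param config list or path to a YAML file with fields `n`, `seed`,
#'   `out_dir`, `regimen` (`lrb_dose`, `dox_dose`), optional `profile`
#'   (built-in name or YAML path), `n_boot`, `n_replicates`,
#'   `test_fraction`, `counterfactual_lrb_dose`.
#' @return validated config list with defaults filled in.
#' @export
pipeline_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop(sprintf("config file '%s' not found", config), call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  config$n <- config$n %||% 300
  config$seed <- as.integer(config$seed %||% 1L)
  config$n_boot <- config$n_boot %||% 250
  config$n_replicates <- config$n_replicates %||% 50
  config$test_fraction <- config$test_fraction %||% 0.3
  config$profile <- config$profile %||% "atlantis_experimental"
  config$regimen <- config$regimen %||% list(lrb_dose = 2.0, dox_dose = 40)
  config$counterfactual_lrb_dose <- config$counterfactual_lrb_dose %||% 3.2
  if (is.null(config$out_dir)) stop("config must name `out_dir`", call. = FALSE)
  if (is.character(config$profile) &&
      !config$profile %in% c("atlantis_experimental", "b005", "atlantis_control")) {
    if (!file.exists(config$profile)) {
      stop(sprintf("cohort profile file '%s' not found", config$profile), call. = FALSE)
    }
  }
  config
}

.resolve_profile <- function(profile) {
  if (inherits(profile, "cohort_profile")) return(profile)
  switch(profile,
         atlantis_experimental = profile_atlantis_experimental(),
         b005 = profile_b005(),
         atlantis_control = profile_atlantis_control(),
         read_profile(profile))
}

.write_fit_json <- function(fit, path) {
  lst <- list(family = fit$family %||% "emax_orr",
              estimates = as.list(fit$estimates),
              se = as.list(fit$se),
              minus2LL = fit$minus2LL, aic = fit$aic,
              n = fit$n, converged = fit$converged)
  jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = 10)
  path
}

#' Run the end-to-end exposure-response pipeline
#'
#' Executes simulate -> fit -> validate -> compare from one config:
#' generates the cohort and exposures, simulates OS and ORR outcomes from
#' the final published models, splits train/test, refits both models on the
#' training set, runs univariate screens, a VPC and a bootstrap, and
#' performs the counterfactual single-agent head-to-head comparison at the
#' configured dose against the cohort's own observed (simulated) outcomes.
#' All randomness descends from `config$seed` via per-stage substreams, so a
#' rerun with the same config produces byte-identical artifacts.
#'
#' @param config list or YAML path, see [pipeline_config()].
#' @return the run manifest (list with `artifacts` — path + md5 checksum per
#'   output — `seeds`, `config`); also written to `manifest.json` in
#'   `out_dir`.
#' @export
run_pipeline <- function(config) {
  config <- pipeline_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  seeds <- spawn_seeds(config$seed, 8)
  names(seeds) <- c("cohort", "exposure", "os_sim", "orr_sim", "split",
                    "vpc", "bootstrap", "compare")
  log_path <- out("events.jsonl")
  unlink(log_path)
  log_event <- function(stage, ...) {
    cat(jsonlite::toJSON(c(list(stage = stage), list(...)), auto_unbox = TRUE),
        "\n", sep = "", file = log_path, append = TRUE)
  }
  artifacts <- character(0)
  emit <- function(obj, f) {
    p <- out(f)
    if (is.data.frame(obj)) utils::write.csv(obj, p, row.names = FALSE)
    else jsonlite::write_json(obj, p, auto_unbox = TRUE, digits = 10)
    artifacts <<- c(artifacts, p)
    p
  }
  stage <- "simulate"
  res <- try({
    profile <- .resolve_profile(config$profile)
    cohort <- generate_covariates(config$n, profile, seeds["cohort"])
    regimen <- regimen_spec(config$regimen$lrb_dose, config$regimen$dox_dose)
    expo <- assign_exposures(cohort, regimen, pk_defaults(), seeds["exposure"])
    os_out <- simulate_os_outcomes(cohort, expo, os_params_published(),
                                   censoring_spec(), seeds["os_sim"])
    orr_out <- simulate_orr_outcomes(cohort, expo, orr_params_published(),
                                     seeds["orr_sim"])
    emit(cohort, "cohort.csv"); emit(expo, "exposures.csv")
    emit(os_out, "os_outcomes.csv"); emit(orr_out, "orr_outcomes.csv")
    log_event("simulate", seed = unname(seeds["cohort"]), n = config$n,
              event_fraction = attr(os_out, "event_fraction"))

    stage <- "fit"
    osd <- os_model_frame(cohort, expo, os_out)
    orrd <- tibble::tibble(auc_u = expo$auc_u, ctfi_group = cohort$ctfi_group,
                           responder = orr_out$responder, event = os_out$event)
    sp <- train_test_split(osd, config$test_fraction, seeds["split"],
                           stratify_by = "event")
    os_fit <- fit_parametric_os(sp$train, "loglogistic", OS_COVARIATES)
    orr_fit <- fit_emax_orr(orrd)
    emit(acceleration_factors(os_fit), "os_acceleration_factors.csv")
    .write_fit_json(os_fit, out("os_fit.json"))
    .write_fit_json(orr_fit, out("orr_fit.json"))
    artifacts <- c(artifacts, out("os_fit.json"), out("orr_fit.json"))
    log_event("fit", os_converged = os_fit$converged,
              orr_converged = orr_fit$converged)

    stage <- "validate"
    scr <- univariate_screen_os(osd, OS_COVARIATES)
    emit(scr, "screen_os.csv")
    v <- vpc(os_fit, sp$test, n_replicates = config$n_replicates,
             seed = seeds["vpc"])
    emit(v$bands, "vpc_os.csv")
    bt <- bootstrap_fits(osd, function(d) {
      f <- fit_parametric_os(d, "loglogistic", OS_COVARIATES)
      f$estimates
    }, n_boot = config$n_boot, seed = seeds["bootstrap"])
    emit(bt$ci, "bootstrap_os.csv")
    log_event("validate", n_replicates = config$n_replicates,
              n_boot = config$n_boot, boot_failed = bt$n_failed)

    stage <- "compare"
    cf_reg <- regimen_spec(config$counterfactual_lrb_dose, 0)
    cf_expo <- scale_exposure(expo, regimen, cf_reg)
    cf_pop <- os_model_frame(cohort, cf_expo, os_out)
    cmp_os <- head_to_head_os(os_fit, cf_pop,
                              osd[, c("time", "event")],
                              n_boot = config$n_boot, seed = seeds["compare"])
    cf_orr_pop <- tibble::tibble(auc_u = cf_expo$auc_u,
                                 ctfi_group = cohort$ctfi_group)
    cmp_orr <- head_to_head_orr(orr_fit, cf_orr_pop, orrd,
                                n_boot = config$n_boot, seed = seeds["compare"])
    emit(list(os = list(hr = cmp_os$effect, pi = c(cmp_os$pi_lo, cmp_os$pi_hi),
                        median_pred_months = cmp_os$median_pred,
                        median_obs_months = cmp_os$median_obs),
              orr = list(or = cmp_orr$effect,
                         pi = c(cmp_orr$pi_lo, cmp_orr$pi_hi),
                         rate_pred = cmp_orr$rate_pred,
                         rate_obs = cmp_orr$rate_obs)),
         "comparison.json")
    log_event("compare", counterfactual_lrb_dose = config$counterfactual_lrb_dose)
    NULL
  }, silent = TRUE)
  if (inherits(res, "try-error")) {
    manifest <- list(status = "failed", failed_stage = stage,
                     error = as.character(res),
                     artifacts = .manifest_artifacts(artifacts),
                     seeds = as.list(seeds), config = config)
    jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE)
    stop(sprintf("pipeline failed in stage '%s': %s", stage, as.character(res)),
         call. = FALSE)
  }
  artifacts <- c(artifacts, log_path)
  manifest <- list(status = "ok",
                   artifacts = .manifest_artifacts(artifacts),
                   seeds = as.list(seeds), config = config)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = 10)
  invisible(manifest)
}

.manifest_artifacts <- function(paths) {
  lapply(paths, function(p) {
    list(path = p, md5 = unname(tools::md5sum(p)))
  })
}

#' Render a human-readable report from a run manifest
#'
#' Writes a Markdown summary with the fitted OS parameter table (AF with
#' 95% CI columns), ORR parameter estimates, VPC band table and the
#' counterfactual comparison. Artifacts missing from disk are listed as
#' unavailable; the report still renders.
#'
#' @param manifest manifest list from [run_pipeline()], or the path to a
#'   `manifest.json`.
#' @param path output file (default `report.md` next to the manifest
#'   artifacts).
#' @return the report path, invisibly.
#' @export
write_report <- function(manifest, path = NULL) {
  if (is.character(manifest)) manifest <- jsonlite::read_json(manifest)
  paths <- vapply(manifest$artifacts, function(a) a$path, "")
  dir <- if (length(paths)) dirname(paths[1]) else "."
  path <- path %||% file.path(dir, "report.md")
  find_art <- function(f) {
    hit <- paths[basename(paths) == f]
    if (length(hit) && file.exists(hit[1])) hit[1] else NA_character_
  }
  lines <- c("# Exposure-response pipeline report", "")
  warn <- character(0)
  af_p <- find_art("os_acceleration_factors.csv")
  if (!is.na(af_p)) {
    af <- utils::read.csv(af_p)
    lines <- c(lines, "## OS model acceleration factors", "",
               "| Covariate | AF | 95% CI |", "|---|---|---|",
               sprintf("| %s | %.2f | (%.2f, %.2f) |", af$covariate, af$af,
                       af$lo, af$hi), "")
  } else warn <- c(warn, "os_acceleration_factors.csv unavailable")
  orr_p <- find_art("orr_fit.json")
  if (!is.na(orr_p)) {
    of <- jsonlite::read_json(orr_p)
    lines <- c(lines, "## ORR model estimates", "",
               "| Parameter | Estimate |", "|---|---|",
               sprintf("| %s | %.3g |", names(of$estimates),
                       unlist(of$estimates)), "")
  } else warn <- c(warn, "orr_fit.json unavailable")
  vpc_p <- find_art("vpc_os.csv")
  if (!is.na(vpc_p)) {
    vb <- utils::read.csv(vpc_p)
    lines <- c(lines, "## OS visual predictive check (monthly bands)", "",
               "| Month | 2.5% | Median | 97.5% | Observed |", "|---|---|---|---|---|",
               sprintf("| %d | %.3f | %.3f | %.3f | %.3f |", vb$month, vb$lo,
                       vb$mid, vb$hi, vb$observed), "")
  } else warn <- c(warn, "vpc_os.csv unavailable")
  cmp_p <- find_art("comparison.json")
  if (!is.na(cmp_p)) {
    cmp <- jsonlite::read_json(cmp_p)
    lines <- c(lines, "## Counterfactual head-to-head comparison", "",
               sprintf("- OS: HR %.2f (95%% PI %.2f, %.2f); predicted median %.1f vs observed %.1f months",
                       cmp$os$hr, cmp$os$pi[[1]], cmp$os$pi[[2]],
                       cmp$os$median_pred_months, cmp$os$median_obs_months),
               sprintf("- ORR: OR %.2f (95%% PI %.2f, %.2f); predicted rate %.1f%% vs observed %.1f%%",
                       cmp$orr$or, cmp$orr$pi[[1]], cmp$orr$pi[[2]],
                       100 * cmp$orr$rate_pred, 100 * cmp$orr$rate_obs), "")
  } else warn <- c(warn, "comparison.json unavailable")
  if (length(warn)) {
    lines <- c(lines, "## Warnings", "", paste("-", warn), "")
  }
  writeLines(lines, path)
  invisible(path)
}
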