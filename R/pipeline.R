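# End-to-end pipeline orchestration: synthetic cohort (or supplied regional
# tables) -> energetics -> cross-validated rEP/rAG patterns -> PLSC ->
# disease-pattern comparison, with a deterministic manifest.

#' Pipeline configuration
#'
#' One master seed drives every stochastic stage through deterministic
#' sub-seeds (see [derive_seed()]), so any stage can be rerun in isolation
#' with identical results.
#'
#' @param seed Master integer seed (mandatory for stochastic stages).
#' @param n_subjects,n_regions,age_range,pattern_mode,age_slope,noise_sd
#'   Cohort generation parameters (see [cohort_config()]).
#' @param cutoff Younger/older cutoff age, years. Default 60.
#' @param n_iter,k_folds Cross-validation schedule. Defaults 500 and 5.
#' @param vaf_min,p_max Component filter thresholds. Defaults 5 (percent)
#'   and 0.2.
#' @param n_perm,n_boot PLSC inference sizes. Defaults 1000 and 500.
#' @param lc Lumped constant for CMRglu scaling. Default 0.65.
#' @param t_star Patlak linear-phase start, minutes. Default 20.
#' @param bonferroni_m Comparison family size. Default 6.
#' @return Named list of class `run_config`.
#' @export
pipeline_config <- function(seed = 1L, n_subjects = 24L, n_regions = 97L,
                            age_range = c(35, 80),
                            pattern_mode = "concordant", age_slope = 0.25,
                            noise_sd = 0.3, cutoff = 60, n_iter = 500L,
                            k_folds = 5L, vaf_min = 5, p_max = 0.2,
                            n_perm = 1000L, n_boot = 500L, lc = 0.65,
                            t_star = 20, bonferroni_m = 6L) {
  stopifnot(vaf_min >= 0, vaf_min <= 100, p_max > 0, p_max <= 1,
            n_iter >= 1, k_folds >= 2, lc > 0, bonferroni_m >= 1)
  structure(list(seed = as.integer(seed), n_subjects = n_subjects,
                 n_regions = n_regions, age_range = age_range,
                 pattern_mode = pattern_mode, age_slope = age_slope,
                 noise_sd = noise_sd, cutoff = cutoff, n_iter = n_iter,
                 k_folds = k_folds, vaf_min = vaf_min, p_max = p_max,
                 n_perm = n_perm, n_boot = n_boot, lc = lc, t_star = t_star,
                 bonferroni_m = bonferroni_m),
            class = "run_config")
}

write_config_json <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  path
}

#' Run the full analysis pipeline
#'
#' Stages: simulate (or load) a regional cohort; compute the energetics
#' table; derive cross-validated rEP and rAG age patterns; run PLSC on each
#' metric against age and sex; score subjects against three synthetic
#' disease patterns and build the comparison report. All artifacts plus a
#' manifest (config hash, package version, stage seeds, per-file checksums)
#' are written under `out_dir`. Rerunning with the same config is
#' bit-identical for every deterministic stage.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output run directory.
#' @param dataset Optional [regional_dataset()]; when supplied, the
#'   simulate stage is skipped and the data are used as-is.
#' @return Invisibly, a list with the in-memory stage results (`dataset`,
#'   `energetics`, `patterns`, `plsc`, `comparison`, `manifest_path`).
#' @export
run_pipeline <- function(config, out_dir, dataset = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- proc.time()[["elapsed"]]
  log_stage <- function(fmt, ...) {
    message(sprintf("[%6.1fs] %s", proc.time()[["elapsed"]] - t0,
                    sprintf(fmt, ...)))
  }

  config_path <- write_config_json(config, file.path(out_dir, "config.json"))

  log_stage("stage simulate")
  if (is.null(dataset)) {
    cc <- cohort_config(n_subjects = config$n_subjects,
                        n_regions = config$n_regions,
                        age_range = config$age_range,
                        pattern_mode = config$pattern_mode,
                        age_slope = config$age_slope,
                        noise_sd = config$noise_sd,
                        seed = derive_seed(config$seed, "cohort"))
    dataset <- generate_regional_cohort(cc)
  }
  write_regional_dataset(dataset, file.path(out_dir, "dataset"))

  log_stage("stage energetics")
  table <- build_energetics_table(dataset)
  write_energetics_table(table, file.path(out_dir, "energetics"),
                         sidecar = list(cutoff = config$cutoff,
                                        seed = config$seed))

  log_stage("stage derive-pattern (rEP, rAG; %d x %d-fold CV)",
            config$n_iter, config$k_folds)
  patterns <- list()
  for (metric in c("rep", "rag")) {
    pat <- tryCatch(
      crossvalidate_pattern(table[[metric]], ages = dataset$ages,
                            cutoff = config$cutoff, n_iter = config$n_iter,
                            k_folds = config$k_folds,
                            vaf_min = config$vaf_min, p_max = config$p_max,
                            seed = derive_seed(config$seed,
                                               paste0("folds_", metric)),
                            metric = metric),
      error = function(e) e)
    if (inherits(pat, "error")) {
      stop(sprintf("stage derive-pattern (%s): %s", metric,
                   conditionMessage(pat)), call. = FALSE)
    }
    patterns[[metric]] <- pat
    write_pattern_json(pat,
                       file.path(out_dir, sprintf("pattern_%s.json", metric)),
                       subject_ids = dataset$subject_ids)
  }

  log_stage("stage plsc")
  Y <- cbind(age = dataset$ages, sex = dataset$sex - 0.5)
  plsc <- list()
  for (metric in c("rep", "rag")) {
    sseed <- derive_seed(config$seed, paste0("plsc_", metric))
    fit <- plsc_fit(table[[metric]], Y)
    fit$perm_p <- plsc_permutation(table[[metric]], Y,
                                   n_perm = config$n_perm, seed = sseed)
    fit$bootstrap_ratios <- plsc_bootstrap(table[[metric]], Y,
                                           n_boot = config$n_boot,
                                           seed = sseed)
    plsc[[metric]] <- fit
    jsonlite::write_json(
      list(metric = metric, region_names = fit$region_names,
           brain_saliences = fit$brain_saliences,
           clinical_saliences = fit$clinical_saliences,
           clinical_names = c("age", "sex"),
           singular_values = fit$singular_values,
           perm_p = fit$perm_p,
           bootstrap_ratios = fit$bootstrap_ratios,
           inference = "permutation/bootstrap (standard substitution)",
           seed = sseed),
      file.path(out_dir, sprintf("plsc_%s.json", metric)),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  log_stage("stage compare")
  dseed <- derive_seed(config$seed, "disease")
  disease <- list(
    `synthetic-PDRP` = generate_disease_pattern(dataset$region_names,
                                                seed = dseed + 1L,
                                                label = "synthetic-PDRP"),
    `synthetic-PDCP` = generate_disease_pattern(dataset$region_names,
                                                seed = dseed + 2L,
                                                label = "synthetic-PDCP"),
    `synthetic-ADRP` = generate_disease_pattern(dataset$region_names,
                                                seed = dseed + 3L,
                                                label = "synthetic-ADRP"))
  for (dn in names(disease)) {
    write_disease_pattern_json(disease[[dn]],
                               file.path(out_dir, paste0(dn, ".json")))
  }
  comparison <- compare_patterns(patterns, disease, dataset$cmrglu,
                                 m = config$bonferroni_m)
  utils::write.table(comparison, file.path(out_dir, "comparison.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")

  log_stage("writing manifest")
  files <- sort(setdiff(list.files(out_dir, recursive = TRUE),
                        "manifest.json"))
  checksums <- as.list(tools::md5sum(file.path(out_dir, files)))
  names(checksums) <- files
  manifest <- list(
    package = "brainergetics",
    version = as.character(utils::packageVersion("brainergetics")),
    config_hash = unname(tools::md5sum(config_path)),
    seed = config$seed,
    stage_seeds = list(
      cohort = derive_seed(config$seed, "cohort"),
      folds_rep = derive_seed(config$seed, "folds_rep"),
      folds_rag = derive_seed(config$seed, "folds_rag"),
      plsc_rep = derive_seed(config$seed, "plsc_rep"),
      plsc_rag = derive_seed(config$seed, "plsc_rag"),
      disease = derive_seed(config$seed, "disease")),
    files = checksums)
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  log_stage("done")
  invisible(list(dataset = dataset, energetics = table, patterns = patterns,
                 plsc = plsc, disease = disease, comparison = comparison,
                 manifest_path = manifest_path))
}
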