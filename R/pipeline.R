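# End-to-end orchestration: train (stratify -> trajectories -> mine -> rules),
# replicate frozen rules on test cohorts, and serialize artifact bundles.

#' Pipeline configuration
#'
#' Collects every tunable decision point of the pipeline with its default:
#' mixture orders considered, path-selection fraction, significance level,
#' NIR comparator, criterion thresholds, and the master seed.
#'
#' @param k_range Candidate mixture orders per timepoint (default 1:6).
#' @param min_fraction Minimum baseline-stratum fraction for path selection
#'   (default 0.10).
#' @param alpha Significance level for mining and the minimum-count screen.
#' @param nir Null information rate comparator (default 0.53).
#' @param majority_threshold Criterion (a) majority cutoff (default 0.5).
#' @param seed Master seed for all stochastic stages.
#' @param use_weights Use mixing-weighted posteriors for stratum assignment?
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(k_range = 1:6, min_fraction = 0.10, alpha = 0.05,
                            nir = 0.53, majority_threshold = 0.5,
                            seed = 1L, use_weights = FALSE) {
  structure(list(k_range = k_range, min_fraction = min_fraction,
                 alpha = alpha, nir = nir,
                 majority_threshold = majority_threshold,
                 seed = as.integer(seed), use_weights = use_weights),
            class = "pipeline_config")
}

#' Run the training pipeline
#'
#' Executes the full training workflow on one cohort: per-timepoint mixture
#' stratification with BIC order selection, forward-transition estimation,
#' path likelihoods and symptom-dynamic-path selection, prognostic-symptom
#' mining, and rule derivation with evaluation against the NIR.
#'
#' @param cohort An `hdrs_cohort` or a path to a cohort CSV.
#' @param config A [pipeline_config()].
#' @return A `pgm_bundle`: `models`, `assignments`, `transitions`, `paths`,
#'   `selected_paths`, `symptoms`, `rules`, `evaluations`, `config`, `log`.
#' @export
run_training <- function(cohort, config = pipeline_config()) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  cohort <- complete_cohort(cohort)
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))

  strat <- stratify_cohort(cohort, k_range = config$k_range,
                           seed = config$seed,
                           use_weights = config$use_weights)
  for (tp in hdrs_timepoints())
    note("stratification %s: k = %d (BIC)", tp, strat$models[[tp]]$k)

  trans <- estimate_transitions(strat$assignments)
  paths <- forward_path_likelihoods(trans)
  selected <- select_symptom_dynamic_paths(paths,
                                           min_fraction = config$min_fraction)
  note("candidate paths: %d; selected symptom dynamic paths: %d",
       nrow(paths), nrow(selected))

  symptoms <- identify_prognostic_symptoms(cohort, strat$assignments,
                                           selected, config)
  note("prognostic symptoms: {%s}", paste(symptoms$items, collapse = ", "))

  rules <- list(); evaluations <- list()
  if (length(symptoms$items) > 0) {
    rules <- build_prognosis_rules(cohort, strat$assignments, selected,
                                   symptoms$items, alpha = config$alpha)
    evaluations <- lapply(rules, evaluate_rule, cohort = cohort,
                          assignments = strat$assignments, nir = config$nir)
    note("rules derived: %d", length(rules))
  } else {
    note("no prognostic symptoms; no rules derived")
  }

  structure(list(models = strat$models, assignments = strat$assignments,
                 transitions = trans, paths = paths,
                 selected_paths = selected, symptoms = symptoms,
                 rules = rules, evaluations = evaluations,
                 config = config, log = log),
            class = "pgm_bundle")
}

#' Replicate a trained bundle on test cohorts
#'
#' Assigns each test cohort's patients into the frozen training strata by
#' score-range lookup and re-evaluates every frozen rule.  When a placebo
#' cohort is supplied, the mining stage is additionally re-run on it (with
#' frozen stratum ranges but its own transitions) as a negative control: the
#' expected result is an empty prognostic set.
#'
#' @param bundle A `pgm_bundle` from [run_training()].
#' @param test_cohorts Named list of `hdrs_cohort`s (or CSV paths).
#' @param placebo_cohort Optional placebo `hdrs_cohort` (or CSV path).
#' @return List with per-cohort `evaluations`, a consolidated `table`, and —
#'   when a placebo cohort was given — `placebo` (its evaluations and mined
#'   symptom set).
#' @export
run_replication <- function(bundle, test_cohorts = list(),
                            placebo_cohort = NULL) {
  stopifnot(inherits(bundle, "pgm_bundle"))
  load_ <- function(x) if (is.character(x)) read_cohort(x) else x
  out <- list(evaluations = list(), table = NULL)
  for (nm in names(test_cohorts)) {
    co <- complete_cohort(load_(test_cohorts[[nm]]))
    evals <- replicate_rules(bundle$rules, co, bundle$models,
                             nir = bundle$config$nir)
    out$evaluations[[nm]] <- evals
    tab <- evaluation_table(evals)
    tab <- cbind(cohort = nm, tab)
    out$table <- rbind(out$table, tab)
  }
  if (!is.null(placebo_cohort)) {
    co <- complete_cohort(load_(placebo_cohort))
    assignments <- assign_cohort_by_range(bundle$models, co)
    trans <- estimate_transitions(assignments)
    paths <- forward_path_likelihoods(trans)
    selected <- select_symptom_dynamic_paths(
      paths, min_fraction = bundle$config$min_fraction)
    mined <- identify_prognostic_symptoms(co, assignments, selected,
                                          bundle$config)
    evals <- replicate_rules(bundle$rules, co, bundle$models,
                             nir = bundle$config$nir)
    out$placebo <- list(symptoms = mined, evaluations = evals,
                        table = evaluation_table(evals))
  }
  out
}

serialize_model <- function(m)
  list(timepoint = m$timepoint, k = m$k, weights = m$weights,
       means = m$means, sds = m$sds, labels = m$labels,
       ranges = if (is.null(m$ranges)) NULL else
         list(min = unname(m$ranges[, 1]), max = unname(m$ranges[, 2])))

#' Serialize a training bundle to versioned JSON artifacts
#'
#' Writes `model.json` (stratum models per timepoint + transition matrices),
#' `paths.json` (candidate and selected paths), `symptoms.json` (mined set
#' and evidence), `rules.json`, `assignments.csv` and `report.csv` (the
#' evaluation table) under `dir`.  Output is deterministic given the bundle.
#'
#' @param bundle A `pgm_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, f) jsonlite::write_json(
    x, file.path(dir, f), auto_unbox = TRUE, digits = 10, pretty = TRUE,
    na = "null")
  w(list(version = 1L,
         models = lapply(bundle$models, serialize_model),
         transitions = list(
           p_b_given_a = bundle$transitions$p_b_given_a,
           p_c_given_b = bundle$transitions$p_c_given_b,
           counts_ab = bundle$transitions$counts_ab,
           counts_bc = bundle$transitions$counts_bc)),
    "model.json")
  w(list(version = 1L, candidate = bundle$paths,
         selected = bundle$selected_paths), "paths.json")
  w(list(version = 1L, items = bundle$symptoms$items,
         evidence = bundle$symptoms$evidence), "symptoms.json")
  w(list(version = 1L,
         rules = lapply(unname(bundle$rules), unclass),
         nir = bundle$config$nir), "rules.json")
  write.csv(bundle$assignments, file.path(dir, "assignments.csv"),
            row.names = FALSE, quote = FALSE)
  if (length(bundle$evaluations) > 0)
    write.csv(evaluation_table(bundle$evaluations),
              file.path(dir, "report.csv"), row.names = FALSE)
  invisible(dir)
}

#' @export
print.pgm_bundle <- function(x, ...) {
  cat("PGM training bundle\n")
  for (line in x$log) cat(" -", line, "\n")
  invisible(x)
}
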