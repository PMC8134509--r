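# Per-timepoint patient stratification: 1-D Gaussian mixtures over HDRS total
# scores, model order selected by BIC ("the minimum number of Gaussians"),
# patients assigned to the component with maximal density.

#' Fit a per-timepoint stratum model by Gaussian mixture + BIC
#'
#' Fits univariate unequal-variance Gaussian mixtures (via \pkg{mclust}) for
#' each component count in `k_range` and returns the model minimising BIC.
#' Ties are broken toward the smaller k, so the selected model is the minimum
#' number of Gaussians that best approximates the score distribution.
#' Components are relabelled in ascending order of mean: label `"1"` is the
#' least severe stratum, the highest label the most severe.
#'
#' @param totals Numeric vector of total scores (at least `10 * max(k_range)`).
#' @param timepoint Which timepoint the totals come from.
#' @param k_range Integer vector of candidate component counts (default 1:6).
#' @param seed Integer seed (fitting is deterministic given the data; the seed
#'   is set for interface stability).
#' @return A `stratum_model`: timepoint, `k`, `weights`, `means`, `sds`,
#'   `labels`, `ranges` (filled by [derive_ranges()]), and the per-k BIC table.
#' @export
fit_strata <- function(totals, timepoint = "baseline", k_range = 1:6,
                       seed = 1L) {
  timepoint <- match.arg(timepoint, hdrs_timepoints())
  totals <- as.numeric(totals)
  if (length(totals) < 10 * max(k_range))
    stop(sprintf("need at least %d totals to consider k up to %d",
                 10 * max(k_range), max(k_range)))
  set.seed(seed)
  bic <- setNames(rep(NA_real_, length(k_range)), k_range)
  fits <- vector("list", length(k_range))
  for (i in seq_along(k_range)) {
    f <- tryCatch(
      mclust::Mclust(totals, G = k_range[i], modelNames = "V", verbose = FALSE),
      error = function(e) NULL)
    if (is.null(f) || is.na(f$bic)) next
    fits[[i]] <- f
    # mclust maximises 2*loglik - npar*log(n); convert to the minimised form
    bic[i] <- -f$bic
  }
  if (all(is.na(bic)))
    stop(sprintf("mixture fitting failed to converge for every k in [%d, %d]",
                 min(k_range), max(k_range)))
  best <- min(bic, na.rm = TRUE)
  sel <- which(!is.na(bic) & bic <= best + 1e-6)[1]  # ties -> smaller k
  f <- fits[[sel]]
  mu <- as.numeric(f$parameters$mean)
  sig <- sqrt(as.numeric(f$parameters$variance$sigmasq))
  if (length(sig) == 1) sig <- rep(sig, length(mu))
  pro <- as.numeric(f$parameters$pro)
  ord <- order(mu)
  structure(list(timepoint = timepoint, k = length(mu),
                 weights = pro[ord], means = mu[ord], sds = sig[ord],
                 labels = as.character(seq_along(mu)),
                 ranges = NULL, bic = bic, loglik = f$loglik,
                 n = length(totals)),
            class = "stratum_model")
}

#' Assign total scores to strata
#'
#' Each total is assigned to the component whose Gaussian density at that
#' score is maximal.  By default the density is unweighted — assignment uses
#' only the learned means and standard deviations; set `use_weights = TRUE`
#' for the mixing-weighted posterior alternative.  Ties go to the
#' lower-severity label.
#'
#' @param model A fitted `stratum_model`.
#' @param totals Numeric vector of totals.
#' @param use_weights Multiply densities by mixing weights before the argmax?
#' @return Character vector of stratum labels.
#' @export
assign_stratum <- function(model, totals, use_weights = FALSE) {
  stopifnot(inherits(model, "stratum_model"))
  dens <- vapply(seq_len(model$k), function(j) {
    d <- dnorm(as.numeric(totals), model$means[j], model$sds[j])
    if (use_weights) d * model$weights[j] else d
  }, numeric(length(totals)))
  dens <- matrix(dens, ncol = model$k)
  model$labels[max.col(dens, ties.method = "first")]
}

#' Empirical score ranges per stratum
#'
#' Assigns `totals` with [assign_stratum()] and records each stratum's
#' empirical `[min, max]` of assigned totals, verifying that the ranges of
#' adjacent strata do not overlap (assignment by maximal density with ordered
#' means is monotone on observed data; an overlap indicates a degenerate fit).
#'
#' @param model A `stratum_model`.
#' @param totals Totals used to derive the ranges.
#' @param use_weights Passed to [assign_stratum()].
#' @return The model with `ranges` set (k x 2 integer matrix, rownames are
#'   stratum labels).
#' @export
derive_ranges <- function(model, totals, use_weights = FALSE) {
  lab <- assign_stratum(model, totals, use_weights = use_weights)
  rng <- matrix(NA_real_, nrow = model$k, ncol = 2,
                dimnames = list(model$labels, c("min", "max")))
  for (l in model$labels) {
    x <- totals[lab == l]
    if (length(x) > 0) rng[l, ] <- c(min(x), max(x))
  }
  occ <- which(!is.na(rng[, 1]))
  if (length(occ) > 1) {
    for (i in seq_len(length(occ) - 1)) {
      if (rng[occ[i], "max"] >= rng[occ[i + 1], "min"])
        stop(sprintf("overlapping assigned ranges for strata %s and %s",
                     model$labels[occ[i]], model$labels[occ[i + 1]]))
    }
  }
  model$ranges <- rng
  model
}

#' Assign totals into frozen stratum ranges
#'
#' Used in replication: patients in a test cohort are assigned to the stratum
#' whose (training-derived) score range contains their total.  Totals falling
#' outside every range snap to the stratum with the nearest range boundary
#' (with a warning), so every test patient is covered.
#'
#' @param model A `stratum_model` with `ranges` derived.
#' @param totals Numeric totals.
#' @return Character vector of stratum labels.
#' @export
assign_by_range <- function(model, totals) {
  stopifnot(inherits(model, "stratum_model"), !is.null(model$ranges))
  rng <- model$ranges
  lab <- rep(NA_character_, length(totals))
  for (l in rownames(rng)) {
    if (is.na(rng[l, 1])) next
    lab[totals >= rng[l, 1] & totals <= rng[l, 2]] <- l
  }
  out <- which(is.na(lab))
  if (length(out) > 0) {
    warning(sprintf("%d total(s) outside all frozen ranges; snapping to nearest stratum",
                    length(out)))
    for (i in out) {
      d <- apply(rng, 1, function(r) min(abs(totals[i] - r)))
      lab[i] <- rownames(rng)[which.min(d)]
    }
  }
  lab
}

#' Stratify a cohort at all three timepoints
#'
#' Fits an independent stratum model per timepoint on the complete records'
#' totals, derives empirical ranges, and assigns every patient a stratum label
#' at each timepoint.
#'
#' @param cohort An `hdrs_cohort`.
#' @param k_range,seed,use_weights Passed to [fit_strata()] /
#'   [assign_stratum()].
#' @return List with `models` (named list of `stratum_model`s) and
#'   `assignments` (data frame: `patient_id`, `baseline`, `week4`, `week8`).
#' @export
stratify_cohort <- function(cohort, k_range = 1:6, seed = 1L,
                            use_weights = FALSE) {
  tots <- cohort_totals(cohort)
  models <- list()
  assignments <- data.frame(patient_id = tots$patient_id,
                            stringsAsFactors = FALSE)
  for (tp in hdrs_timepoints()) {
    m <- fit_strata(tots[[tp]], timepoint = tp, k_range = k_range, seed = seed)
    m <- derive_ranges(m, tots[[tp]], use_weights = use_weights)
    models[[tp]] <- m
    assignments[[tp]] <- assign_stratum(m, tots[[tp]], use_weights = use_weights)
  }
  list(models = models, assignments = assignments)
}

#' Assign a cohort into frozen per-timepoint models
#'
#' @param models Named list of `stratum_model`s with derived ranges
#'   (as produced by [stratify_cohort()]).
#' @param cohort Test cohort to assign.
#' @return Assignments data frame as in [stratify_cohort()].
#' @export
assign_cohort_by_range <- function(models, cohort) {
  tots <- cohort_totals(cohort)
  out <- data.frame(patient_id = tots$patient_id, stringsAsFactors = FALSE)
  for (tp in hdrs_timepoints())
    out[[tp]] <- assign_by_range(models[[tp]], tots[[tp]])
  out
}

#' @export
print.stratum_model <- function(x, ...) {
  cat(sprintf("Stratum model (%s): k = %d\n", x$timepoint, x$k))
  tab <- data.frame(label = x$labels, weight = round(x$weights, 3),
                    mean = round(x$means, 2), sd = round(x$sds, 2))
  if (!is.null(x$ranges)) {
    tab$min <- x$ranges[, "min"]; tab$max <- x$ranges[, "max"]
  }
  print(tab, row.names = FALSE)
  invisible(x)
}
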