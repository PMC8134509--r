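# Forward-transition hidden Markov model over severity strata: transition
# estimation, path likelihoods by the forward recursion, and selection of the
# "symptom dynamic paths" (maximum-likelihood paths carrying at least 10% of
# their baseline stratum's patients).

#' Construct a transition model from probability matrices
#'
#' Mostly used internally and in tests; [estimate_transitions()] builds one
#' from data, including the count matrices.
#'
#' @param p_b_given_a,p_c_given_b Row-stochastic matrices (rows may be all
#'   zero for unobserved strata; such rows are flagged, not normalised).
#' @param counts_ab,counts_bc,counts_abc Optional count matrices/array.
#' @return A `transition_model`.
#' @export
transition_model <- function(p_b_given_a, p_c_given_b,
                             counts_ab = NULL, counts_bc = NULL,
                             counts_abc = NULL) {
  for (M in list(p_b_given_a, p_c_given_b)) {
    rs <- rowSums(M)
    if (any(M < 0) || any(abs(rs[rs > 0] - 1) > 1e-12))
      stop("occupied rows must sum to 1 within 1e-12 and entries be >= 0")
  }
  lab <- function(M, d) if (is.null(dimnames(M)[[d]]))
    as.character(seq_len(dim(M)[d])) else dimnames(M)[[d]]
  structure(list(
    p_b_given_a = p_b_given_a, p_c_given_b = p_c_given_b,
    counts_ab = counts_ab, counts_bc = counts_bc, counts_abc = counts_abc,
    labels = list(baseline = lab(p_b_given_a, 1),
                  week4 = lab(p_b_given_a, 2),
                  week8 = lab(p_c_given_b, 2)),
    zero_rows = list(baseline = which(rowSums(p_b_given_a) == 0),
                     week4 = which(rowSums(p_c_given_b) == 0))),
    class = "transition_model")
}

#' Estimate forward transition probabilities from stratum assignments
#'
#' Transition probabilities are the fraction of patients moving from a
#' stratum at one timepoint to each stratum of the next timepoint: counts are
#' tallied and row-normalised.  Rows with zero count are left all-zero and
#' flagged in the returned model.
#'
#' @param assignments Data frame with columns `patient_id`, `baseline`,
#'   `week4`, `week8` (stratum labels), as from [stratify_cohort()].
#' @param labels Optional named list of label universes per timepoint
#'   (defaults to the sorted observed labels).
#' @return A `transition_model` with count matrices and the per-triple count
#'   array attached.
#' @export
estimate_transitions <- function(assignments, labels = NULL) {
  if (is.null(assignments) || nrow(assignments) == 0)
    stop("no assignments to tally")
  if (is.null(labels))
    labels <- lapply(hdrs_timepoints(),
                     function(tp) sort(unique(assignments[[tp]])))
  names(labels) <- hdrs_timepoints()
  fa <- factor(assignments$baseline, levels = labels$baseline)
  fb <- factor(assignments$week4, levels = labels$week4)
  fc <- factor(assignments$week8, levels = labels$week8)
  counts_ab <- unclass(table(fa, fb))
  counts_bc <- unclass(table(fb, fc))
  counts_abc <- unclass(table(fa, fb, fc))
  normrows <- function(cnt) {
    p <- cnt * 0
    rs <- rowSums(cnt)
    p[rs > 0, ] <- cnt[rs > 0, , drop = FALSE] / rs[rs > 0]
    p
  }
  transition_model(normrows(counts_ab), normrows(counts_bc),
                   counts_ab = counts_ab, counts_bc = counts_bc,
                   counts_abc = counts_abc)
}

# Forward recursion over an ordered list of transition matrices: starting
# from a point mass on `start`, partial-path likelihoods are extended one
# timepoint at a time.  Works for any number of timepoints; with the three
# trial timepoints it enumerates the N^2 continuations of each baseline
# stratum.
forward_recursion <- function(start, mats) {
  paths <- matrix(start, nrow = 1)
  lik <- 1
  for (M in mats) {
    nxt <- colnames(M)
    if (is.null(nxt)) nxt <- as.character(seq_len(ncol(M)))
    cur <- paths[, ncol(paths)]
    paths <- paths[rep(seq_len(nrow(paths)), each = length(nxt)), ,
                   drop = FALSE]
    step <- rep(nxt, times = length(cur))
    lik <- rep(lik, each = length(nxt)) *
      M[cbind(match(rep(cur, each = length(nxt)), rownames(M) %||% nxt),
              match(step, nxt))]
    paths <- cbind(paths, step)
  }
  list(paths = paths, likelihood = as.numeric(lik))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Likelihood of every candidate trajectory by the forward algorithm
#'
#' Enumerates all stratum triples (baseline, week 4, week 8) and computes each
#' path's likelihood conditional on its baseline stratum with the HMM forward
#' recursion (strata are directly observed, so the emission matrix is the
#' identity and the recursion reduces to the product of forward transition
#' probabilities).  With 3 strata per timepoint the candidate set has
#' 3^2 = 9 continuations per baseline stratum, 27 paths in all.  Conditioning
#' on the baseline stratum means likelihoods over all (week-4, week-8) pairs
#' sum to 1 for every occupied baseline stratum.
#'
#' @param model A `transition_model`.
#' @return Data frame (class `path_likelihoods`) with columns `baseline`,
#'   `week4`, `week8`, `likelihood`, and — when the model carries counts —
#'   `n_patients` (patients realising the full triple) and
#'   `fraction_of_baseline`.  Paths from zero-count baseline strata are
#'   omitted with a warning.
#' @export
forward_path_likelihoods <- function(model) {
  stopifnot(inherits(model, "transition_model"))
  P1 <- model$p_b_given_a
  P2 <- model$p_c_given_b
  rownames(P1) <- model$labels$baseline; colnames(P1) <- model$labels$week4
  rownames(P2) <- model$labels$week4;   colnames(P2) <- model$labels$week8
  starts <- model$labels$baseline
  drop <- intersect(seq_along(starts), model$zero_rows$baseline)
  if (!is.null(model$counts_ab) && length(drop) > 0) {
    warning(sprintf("baseline stratum/strata %s unobserved; paths omitted",
                    paste(starts[drop], collapse = ", ")))
    starts <- starts[-drop]
  }
  out <- NULL
  for (a in starts) {
    fw <- forward_recursion(a, list(P1, P2))
    out <- rbind(out, data.frame(baseline = fw$paths[, 1],
                                 week4 = fw$paths[, 2],
                                 week8 = fw$paths[, 3],
                                 likelihood = fw$likelihood,
                                 stringsAsFactors = FALSE))
  }
  if (!is.null(model$counts_abc)) {
    nb <- rowSums(model$counts_ab)
    idx <- cbind(match(out$baseline, model$labels$baseline),
                 match(out$week4, model$labels$week4),
                 match(out$week8, model$labels$week8))
    out$n_patients <- as.integer(model$counts_abc[idx])
    out$fraction_of_baseline <- out$n_patients / nb[idx[, 1]]
  }
  rownames(out) <- NULL
  class(out) <- c("path_likelihoods", "data.frame")
  out
}

week8_outcome_label <- function(week8, labels) {
  k <- length(labels)
  ifelse(week8 == labels[1], "remission",
         ifelse(week8 == labels[k], "nonresponse", "response"))
}

#' Select the symptom dynamic paths
#'
#' For every (baseline, week-8) stratum pair, among the candidate triples
#' carrying at least `min_fraction` of the baseline stratum's patients, the
#' maximum-likelihood triple is selected.  Pairs with no qualifying triple
#' yield no path.  Likelihood ties are broken toward the larger patient
#' fraction, then toward the less-severe week-4 stratum.
#'
#' @param paths A `path_likelihoods` data frame with `n_patients` and
#'   `fraction_of_baseline` (i.e. from a count-bearing model).
#' @param min_fraction Minimum fraction of the baseline stratum's patients a
#'   path must carry (default 0.10).
#' @return Data frame of selected paths with an `endpoint_outcome` column
#'   (the outcome the week-8 stratum's position implies: least severe =
#'   remission, most severe = nonresponse).
#' @export
select_symptom_dynamic_paths <- function(paths, min_fraction = 0.10) {
  stopifnot(is.data.frame(paths), "fraction_of_baseline" %in% names(paths))
  q <- paths[!is.na(paths$fraction_of_baseline) &
               paths$fraction_of_baseline >= min_fraction, , drop = FALSE]
  if (nrow(q) == 0) {
    out <- q
    out$endpoint_outcome <- character(0)
    return(out)
  }
  pick <- function(d) {
    d <- d[order(-d$likelihood, -d$fraction_of_baseline, d$week4), ,
           drop = FALSE]
    d[1, , drop = FALSE]
  }
  key <- paste(q$baseline, q$week8)
  sel <- do.call(rbind, lapply(split(q, key), pick))
  sel <- sel[order(sel$baseline, sel$week8), , drop = FALSE]
  w8 <- sort(unique(paths$week8))
  sel$endpoint_outcome <- week8_outcome_label(sel$week8, w8)
  rownames(sel) <- NULL
  sel
}

#' @export
print.transition_model <- function(x, ...) {
  cat("Forward transition model\n  baseline -> week4:\n")
  print(round(x$p_b_given_a, 3))
  cat("  week4 -> week8:\n")
  print(round(x$p_c_given_b, 3))
  invisible(x)
}
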