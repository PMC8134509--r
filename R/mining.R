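# Prognostic-symptom mining: items must carry (a) non-zero baseline severity
# in the majority of patients, (b) a grouping effect — similar severity to
# their cluster peers at every timepoint of every symptom dynamic path — and
# (c) a discriminatory effect — different severity dynamics between paths
# once the mechanical effect of the total score is removed.

#' Criterion (a): non-zero baseline severity in the majority of patients
#'
#' @param cohort An `hdrs_cohort`.
#' @param majority_threshold Items qualify when the fraction of patients with
#'   a strictly positive baseline score strictly exceeds this (default 0.5).
#' @return Integer vector of qualifying item indices.
#' @export
criterion_a_nonzero <- function(cohort, majority_threshold = 0.5) {
  X <- item_matrix(cohort, "baseline")
  if (nrow(X) == 0) stop("empty cohort")
  which(colMeans(X > 0) > majority_threshold)
}

#' Hierarchical symptom clusters within a stratum
#'
#' Clusters the 17 HDRS items by the similarity of their severity profiles
#' across the patients of one stratum at one timepoint: Euclidean distance
#' between item profiles, average-linkage agglomeration.  Unless `k` or `h`
#' is given, the dendrogram is cut at the number of clusters (2..`k_max`)
#' maximising the mean silhouette width.
#'
#' @param cohort An `hdrs_cohort`.
#' @param assignments Assignments data frame from [stratify_cohort()].
#' @param stratum Stratum label to condition on.
#' @param timepoint Timepoint of both the stratum definition and the scores.
#' @param k_max Largest cluster count considered by the silhouette search.
#' @param k,h Optional fixed cluster count / fixed cut height overriding the
#'   silhouette search.
#' @return List with `membership` (integer vector of length 17), `k`, and the
#'   `hclust` tree.
#' @export
cluster_symptoms <- function(cohort, assignments, stratum, timepoint,
                             k_max = 6, k = NULL, h = NULL) {
  timepoint <- match.arg(timepoint, hdrs_timepoints())
  ids <- assignments$patient_id[assignments[[timepoint]] == stratum]
  if (length(ids) < 2)
    stop(sprintf("fewer than 2 patients in stratum %s at %s", stratum, timepoint))
  X <- item_matrix(cohort, timepoint)
  X <- X[rownames(X) %in% ids, , drop = FALSE]
  profiles <- t(X)                      # 17 x n_patients
  d <- dist(profiles)
  if (max(d) == 0) {
    membership <- rep(1L, 17)
    return(list(membership = setNames(membership, item_cols()), k = 1L,
                tree = NULL))
  }
  tree <- hclust(d, method = "average")
  if (!is.null(h)) {
    membership <- cutree(tree, h = h)
  } else if (!is.null(k)) {
    membership <- cutree(tree, k = k)
  } else {
    best <- -Inf; membership <- cutree(tree, k = 2)
    for (kk in 2:min(k_max, 16)) {
      cm <- cutree(tree, k = kk)
      sil <- cluster::silhouette(cm, d)
      w <- mean(sil[, "sil_width"])
      if (w > best + 1e-12) { best <- w; membership <- cm }
    }
  }
  list(membership = setNames(as.integer(membership), item_cols()),
       k = length(unique(membership)), tree = tree)
}

#' Relative standing of an item's change among severity-matched items
#'
#' The symptom dynamic paths are defined by total scores, so every item's raw
#' severity moves with the path mechanically — a patient whose total halves
#' improves on most items.  This statistic isolates the item-specific part of
#' the change by an entirely within-patient comparison: for patient p and
#' item i, the peers of i are the patient's other items with the same
#' baseline score and the same item maximum (0-4 vs 0-2), and the statistic
#' is the midrank proportion of peers whose improvement at the follow-up
#' timepoint is smaller than item i's.  When an item's dynamics carry no information beyond the
#' patient's total, severity-matched items are exchangeable and the standing
#' has expectation 1/2 whatever the patient's trajectory; an item that
#' improves systematically more (less) than its matched peers stands above
#' (below) 1/2.  `NA` where a patient has no matched peer for the item.
#'
#' @param cohort An `hdrs_cohort` (complete records).
#' @param timepoint Follow-up timepoint of the change (default `"week4"`).
#' @return Numeric matrix (patients x 17), rownames are patient ids.
#' @export
relative_change_standing <- function(cohort, timepoint = "week4") {
  timepoint <- match.arg(timepoint, c("week4", "week8"))
  B <- item_matrix(cohort, "baseline")
  W <- item_matrix(cohort, timepoint)
  mx <- hdrs_item_max()
  U <- matrix(NA_real_, nrow(B), 17, dimnames = list(rownames(B), item_cols()))
  for (p in seq_len(nrow(B))) {
    b <- B[p, ]
    d <- b - W[p, ]
    key <- paste(b, mx)
    for (i in 1:17) {
      J <- which(key == key[i])
      J <- J[J != i]
      if (length(J) == 0) next
      U[p, i] <- (sum(d[J] < d[i]) + 0.5 * sum(d[J] == d[i])) / length(J)
    }
  }
  U
}

patients_on_path <- function(assignments, path) {
  assignments$patient_id[assignments$baseline == path$baseline &
                           assignments$week4 == path$week4 &
                           assignments$week8 == path$week8]
}

# Patients on the selected paths, labelled by their path's week-8 endpoint
# stratum; paths carrying fewer than min_path_n patients are dropped as
# underpowered.
endpoint_groups <- function(assignments, selected_paths, min_path_n) {
  ids <- character(0)
  endpoint <- character(0)
  for (j in seq_len(nrow(selected_paths))) {
    pid <- patients_on_path(assignments, selected_paths[j, ])
    if (length(pid) < min_path_n) next
    ids <- c(ids, pid)
    endpoint <- c(endpoint, rep(selected_paths$week8[j], length(pid)))
  }
  list(ids = ids, endpoint = endpoint)
}

# Welch one-way ANOVA of each item's standing across the endpoint groups.
endpoint_pvalues <- function(U, groups) {
  rows <- match(groups$ids, rownames(U))
  ep <- factor(groups$endpoint)
  vapply(seq_len(17), function(i) {
    u <- U[rows, i]
    ok <- !is.na(u)
    if (length(unique(ep[ok])) < 2) return(NA_real_)
    tryCatch(stats::oneway.test(u[ok] ~ droplevels(ep[ok]))$p.value,
             error = function(e) NA_real_)
  }, numeric(1)) |> setNames(item_cols())
}

# Fisher's combination over the follow-up timepoints.
combine_item_pvalues <- function(pmat) {
  apply(pmat, 1, function(p) {
    p <- p[!is.na(p)]
    if (length(p) == 0) return(NA_real_)
    p <- pmax(p, 1e-300)
    stats::pchisq(-2 * sum(log(p)), df = 2 * length(p), lower.tail = FALSE)
  })
}

# Spearman correlation between each item's standing and the severity of the
# path endpoint.  A prognostic item improves more than its peers along
# remitting paths and less along nonresponding paths, so its standing falls
# with endpoint severity (negative correlation).  A null item whose matched
# peers include genuinely prognostic items is dragged the opposite way, so
# the sign separates signal from peer contamination.
standing_direction <- function(U, groups) {
  endpoint <- as.integer(factor(groups$endpoint))
  if (length(unique(endpoint)) < 2)
    return(setNames(rep(NA_real_, 17), item_cols()))
  rows <- match(groups$ids, rownames(U))
  vapply(seq_len(17), function(i) {
    u <- U[rows, i]
    ok <- !is.na(u)
    if (sum(ok) < 3 || stats::sd(u[ok]) == 0) return(NA_real_)
    suppressWarnings(stats::cor(u[ok], endpoint[ok], method = "spearman"))
  }, numeric(1)) |> setNames(item_cols())
}

#' Criterion (c): discriminatory effect between symptom dynamic paths
#'
#' Patients on the selected symptom dynamic paths are pooled into groups by
#' their path's week-8 endpoint stratum (paths with fewer than `min_path_n`
#' patients are dropped as underpowered).  Each item's relative change
#' standing ([relative_change_standing()]) — at week 4 and at week 8 — is
#' compared across the endpoint groups with a Welch one-way ANOVA: the
#' standing has mean 1/2 under the null whatever the trajectory, so the test
#' compares means without assuming equal variances, and pooling across
#' baseline strata uses every path patient.  Per item, the two timepoints'
#' p-values are combined with Fisher's method and Holm-corrected across the
#' 17 items.  Significant items must also pass a direction gate: the item's
#' standing must decrease with the severity of the path endpoint (improve
#' more than its peers along remitting paths), which screens out items whose
#' apparent signal is a mirror image of genuinely prognostic peers in their
#' matched sets.
#'
#' @param cohort,assignments,selected_paths Pipeline objects.
#' @param alpha Significance level after correction (default 0.05).
#' @param min_path_n Minimum patients per path group (default 5).
#' @return List with `pass` (logical 17), `p_adjusted`, `p_raw` (items x
#'   timepoints matrix), `direction` (Spearman correlation of the week-4
#'   standing with endpoint severity) and `endpoints_tested`.
#' @export
criterion_c_discriminative <- function(cohort, assignments, selected_paths,
                                       alpha = 0.05, min_path_n = 5) {
  empty <- list(pass = setNames(rep(FALSE, 17), item_cols()),
                p_adjusted = setNames(rep(NA_real_, 17), item_cols()),
                p_raw = NULL,
                direction = setNames(rep(NA_real_, 17), item_cols()),
                endpoints_tested = character(0))
  if (nrow(selected_paths) == 0) return(empty)
  groups <- endpoint_groups(assignments, selected_paths, min_path_n)
  if (length(unique(groups$endpoint)) < 2) return(empty)
  U4 <- relative_change_standing(cohort, "week4")
  U8 <- relative_change_standing(cohort, "week8")
  pmat <- cbind(week4 = endpoint_pvalues(U4, groups),
                week8 = endpoint_pvalues(U8, groups))
  p_item <- combine_item_pvalues(pmat)
  p_adj <- p.adjust(p_item, method = "holm")
  direction <- standing_direction(U4, groups)
  gate <- is.na(direction) | direction < 0
  list(pass = setNames(!is.na(p_adj) & p_adj <= alpha & gate, item_cols()),
       p_adjusted = setNames(p_adj, item_cols()),
       p_raw = pmat, direction = direction,
       endpoints_tested = sort(unique(groups$endpoint)))
}

#' Criterion (b): grouping effect along symptom dynamic paths
#'
#' An item shows the grouping effect when some other symptom sits at a
#' similar severity level all along the trajectory: among the patients of
#' every selected symptom dynamic path (with at least `min_path_n` patients)
#' and at every timepoint of that path, at least one other item's median
#' severity lies within `tolerance` points of the item's own median.  Items
#' whose severity level is isolated anywhere along a path (no companion
#' within one scale point) show no grouping.  [cluster_symptoms()] exposes
#' the full per-stratum severity-profile dendrogram for inspection.
#'
#' @param cohort,assignments,selected_paths Pipeline objects.
#' @param min_path_n Minimum patients for a path to be evaluated (default 5).
#' @param tolerance Severity-point tolerance for a companion item (default
#'   1, the scale's resolution).
#' @return List with `pass` (logical 17) and per-path median severities.
#' @export
criterion_b_grouping <- function(cohort, assignments, selected_paths,
                                 min_path_n = 5, tolerance = 1) {
  pass <- rep(TRUE, 17)
  detail <- list()
  X <- lapply(setNames(nm = hdrs_timepoints()),
              function(tp) item_matrix(cohort, tp))
  for (j in seq_len(nrow(selected_paths))) {
    ids <- patients_on_path(assignments, selected_paths[j, ])
    if (length(ids) < min_path_n) next
    key <- paste(selected_paths$baseline[j], selected_paths$week4[j],
                 selected_paths$week8[j], sep = "-")
    for (tp in hdrs_timepoints()) {
      m <- X[[tp]]
      med <- apply(m[rownames(m) %in% ids, , drop = FALSE], 2, median)
      gap <- vapply(seq_len(17), function(i)
        min(abs(med[-i] - med[i])), numeric(1))
      detail[[paste(key, tp)]] <- med
      pass <- pass & (gap <= tolerance)
    }
  }
  list(pass = setNames(pass, item_cols()), detail = detail)
}

#' Identify the prognostic symptom set
#'
#' Intersects the three criteria: non-zero baseline severity in the majority
#' of patients (a), the grouping effect along all selected paths (b), and the
#' discriminatory effect between paths (c).  An empty set is a legal result —
#' it is the expected outcome on placebo-arm data, where no item's dynamics
#' carry path information beyond the total score.
#'
#' @param cohort,assignments,selected_paths Pipeline objects.
#' @param config A [pipeline_config()] (alpha, majority threshold, grouping
#'   tolerance).
#' @return A `prognostic_symptoms` object: `items` (integer indices) and an
#'   `evidence` data frame with the per-item criterion outcomes.
#' @export
identify_prognostic_symptoms <- function(cohort, assignments, selected_paths,
                                         config = pipeline_config()) {
  a_set <- criterion_a_nonzero(cohort, config$majority_threshold)
  b_res <- criterion_b_grouping(cohort, assignments, selected_paths)
  c_res <- criterion_c_discriminative(cohort, assignments, selected_paths,
                                      alpha = config$alpha)
  in_a <- seq_len(17) %in% a_set
  items <- which(in_a & b_res$pass & c_res$pass)
  evidence <- data.frame(item = 1:17,
                         criterion_a = in_a,
                         criterion_b = unname(b_res$pass),
                         criterion_c = unname(c_res$pass),
                         p_discriminative = unname(c_res$p_adjusted),
                         selected = seq_len(17) %in% items)
  structure(list(items = items, evidence = evidence,
                 endpoints_tested = c_res$endpoints_tested),
            class = "prognostic_symptoms")
}

#' @export
print.prognostic_symptoms <- function(x, ...) {
  if (length(x$items) == 0) {
    cat("No prognostic symptoms identified.\n")
  } else {
    cat(sprintf("Prognostic symptoms (%d): items %s\n", length(x$items),
                paste(x$items, collapse = ", ")))
  }
  invisible(x)
}
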