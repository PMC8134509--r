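# Prognosis rules: per-item change thresholds from path medians, minimum
# symptom counts from chi-square screens, and evaluation (coverage, accuracy,
# odds ratio, CI, significance against the null information rate).

#' Odds ratio of a 2x2 table with Haldane-Anscombe correction
#'
#' Computes the cross-product odds ratio `(a*d)/(b*c)` with 0.5 added to
#' every cell when any cell is zero, and a Woolf (log-normal) confidence
#' interval on the (corrected) table.
#'
#' @param a,b,c,d Cell counts: rows = covered / not covered, columns =
#'   outcome / not outcome (`a` = covered with the outcome).
#' @param conf_level Confidence level (default 0.95).
#' @return List: `or`, `ci` (length 2), `corrected` (logical).
#' @export
odds_ratio_2x2 <- function(a, b, c, d, conf_level = 0.95) {
  cells <- c(a, b, c, d)
  if (any(cells < 0)) stop("cell counts must be nonnegative")
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  z <- qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt(sum(1 / cells))
  ci <- exp(log(or) + c(-1, 1) * z * se)
  list(or = or, ci = ci, corrected = corrected)
}

rule_id <- function(rule)
  sprintf("%s->%s:%s", rule$baseline,
          paste(rule$week4_strata, collapse = "|"), rule$predicted_outcome)

#' Derive the per-item change threshold for a path
#'
#' The threshold is the rounded median, over the prognostic items, of the
#' absolute difference between the item's median baseline score and its
#' median week-4 score among the patients on the path, floored at 1 point.
#' Direction is `at_least` (improvement of at least delta) for rules
#' predicting remission or response and `at_most` (improvement of at most
#' delta, which includes worsening) for nonresponse rules.
#'
#' @param cohort,assignments Pipeline objects.
#' @param prognostic_items Integer item indices.
#' @param path_patients Character vector of patient ids on the path(s).
#' @param predicted_outcome One of the three outcome labels.
#' @return List: `delta` (integer points), `direction`.
#' @export
derive_threshold <- function(cohort, assignments, prognostic_items,
                             path_patients, predicted_outcome) {
  if (length(path_patients) == 0) stop("no patients on path")
  B <- item_matrix(cohort, "baseline")
  W <- item_matrix(cohort, "week4")
  rows <- rownames(B) %in% path_patients
  dmed <- vapply(prognostic_items, function(i)
    abs(median(B[rows, i]) - median(W[rows, i])), numeric(1))
  delta <- max(1L, as.integer(round(median(dmed))))
  direction <- if (predicted_outcome == "nonresponse") "at_most" else "at_least"
  list(delta = delta, direction = direction)
}

# Number of prognostic items per patient whose 4-week improvement satisfies
# the threshold (improvement = baseline - week4; at_least: >= delta,
# at_most: <= delta).
item_satisfaction_counts <- function(cohort, items, direction, delta) {
  B <- item_matrix(cohort, "baseline")
  W <- item_matrix(cohort, "week4")
  impr <- B[, items, drop = FALSE] - W[, items, drop = FALSE]
  sat <- if (direction == "at_least") impr >= delta else impr <= delta
  setNames(rowSums(sat), rownames(B))
}

#' Minimum number of symptoms needing the change
#'
#' For each candidate count m (1 to the number of prognostic items), forms
#' the 2x2 table of "at least m items satisfy the threshold" against "8-week
#' outcome is the predicted one" over the patients making the rule's
#' transition, and tests it with a chi-square test (Yates continuity
#' correction).  Only positively associated counts qualify — patients meeting
#' the count must be enriched for the predicted outcome, since the chi-square
#' statistic itself is direction-blind.  Returns the smallest significant
#' qualifying m; if none is significant, the qualifying m with the maximal
#' statistic is returned flagged (or m = 1 flagged when no count associates
#' positively).
#'
#' @param counts Named integer vector of satisfied-item counts (from
#'   `item_satisfaction_counts`), restricted to the transition patients.
#' @param is_outcome Logical vector aligned with `counts`.
#' @param n_items Number of prognostic items.
#' @param alpha Significance level (default 0.05).
#' @return List: `m`, `p_values`, `flagged`.
#' @export
derive_min_items <- function(counts, is_outcome, n_items, alpha = 0.05) {
  stopifnot(length(counts) == length(is_outcome))
  pvals <- stat <- rep(NA_real_, n_items)
  positive <- rep(FALSE, n_items)
  for (m in seq_len(n_items)) {
    meets <- counts >= m
    tab <- table(factor(meets, c(FALSE, TRUE)),
                 factor(is_outcome, c(FALSE, TRUE)))
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    ct <- suppressWarnings(chisq.test(tab, correct = TRUE))
    pvals[m] <- ct$p.value
    stat[m] <- unname(ct$statistic)
    positive[m] <- tab["TRUE", "TRUE"] * tab["FALSE", "FALSE"] >
      tab["TRUE", "FALSE"] * tab["FALSE", "TRUE"]
  }
  if (all(is.na(pvals)))
    stop("degenerate 2x2 table (empty margin) for every candidate m")
  sig <- which(!is.na(pvals) & pvals <= alpha & positive)
  if (length(sig) > 0)
    return(list(m = min(sig), p_values = pvals, flagged = FALSE))
  cand <- which(positive & !is.na(stat))
  if (length(cand) == 0)
    return(list(m = 1L, p_values = pvals, flagged = TRUE))
  list(m = cand[which.max(stat[cand])], p_values = pvals, flagged = TRUE)
}

#' Assemble prognosis rules from the selected paths
#'
#' One rule is built per (baseline stratum, week-4 stratum) transition
#' appearing in the selected symptom dynamic paths.  The predicted outcome is
#' the modal observed 8-week outcome among the patients making the transition
#' (ties broken toward the more severe outcome); the change threshold comes
#' from the path patients ([derive_threshold()]); the minimum symptom count
#' from [derive_min_items()].  Rules from the same baseline stratum with the
#' same predicted outcome, direction and threshold are merged, pooling their
#' week-4 strata (so a rule may read "B2 or B3").
#'
#' @param cohort,assignments,selected_paths Pipeline objects.
#' @param prognostic_items Integer item indices (must be non-empty).
#' @param alpha Chi-square significance level for the minimum count.
#' @return List of `prognosis_rule` objects.
#' @export
build_prognosis_rules <- function(cohort, assignments, selected_paths,
                                  prognostic_items, alpha = 0.05) {
  if (length(prognostic_items) == 0)
    stop("cannot build rules from an empty prognostic symptom set")
  tots <- cohort_totals(cohort)
  outcome <- setNames(as.character(tots$outcome), tots$patient_id)
  trans <- unique(selected_paths[, c("baseline", "week4")])
  protos <- list()
  for (r in seq_len(nrow(trans))) {
    a <- trans$baseline[r]; b <- trans$week4[r]
    on_tr <- assignments$patient_id[assignments$baseline == a &
                                      assignments$week4 == b]
    if (length(on_tr) == 0) next
    tab <- table(factor(outcome[on_tr], outcome_levels()))
    # modal observed outcome; ties toward the more severe outcome
    predicted <- outcome_levels()[max(which(tab == max(tab)))]
    sp <- selected_paths[selected_paths$baseline == a &
                           selected_paths$week4 == b, , drop = FALSE]
    on_path <- unique(unlist(lapply(seq_len(nrow(sp)), function(j)
      patients_on_path(assignments, sp[j, ]))))
    thr <- derive_threshold(cohort, assignments, prognostic_items,
                            on_path, predicted)
    protos[[length(protos) + 1]] <-
      list(baseline = a, week4_strata = b, predicted_outcome = predicted,
           direction = thr$direction, delta = thr$delta)
  }
  # merge same (baseline, outcome, direction, delta)
  keys <- vapply(protos, function(p)
    paste(p$baseline, p$predicted_outcome, p$direction, p$delta), "")
  rules <- list()
  for (k in unique(keys)) {
    grp <- protos[keys == k]
    rule <- grp[[1]]
    rule$week4_strata <- sort(unique(unlist(lapply(grp, `[[`, "week4_strata"))))
    on_tr <- assignments$patient_id[assignments$baseline == rule$baseline &
                                      assignments$week4 %in% rule$week4_strata]
    counts <- item_satisfaction_counts(cohort, prognostic_items,
                                       rule$direction, rule$delta)[on_tr]
    # a fully degenerate screen (e.g. every transition patient already has
    # the predicted outcome) carries no information about m; fall back to 1
    mi <- tryCatch(
      derive_min_items(counts, outcome[on_tr] == rule$predicted_outcome,
                       length(prognostic_items), alpha = alpha),
      error = function(e) list(m = 1L, p_values = NULL, flagged = TRUE))
    rule$min_items <- mi$m
    rule$min_items_flagged <- mi$flagged
    rule$items <- as.integer(prognostic_items)
    class(rule) <- "prognosis_rule"
    rules[[rule_id(rule)]] <- rule
  }
  rules[order(vapply(rules, function(r) r$baseline, ""))]
}

#' Apply a prognosis rule to patients
#'
#' A patient is not applicable when their (baseline, week-4) strata do not
#' match the rule's transition; otherwise they are covered when at least
#' `min_items` of the prognostic items show a 4-week improvement satisfying
#' the rule's threshold, in which case the rule predicts its outcome.
#'
#' @param rule A `prognosis_rule`.
#' @param cohort,assignments Pipeline objects.
#' @return Named character vector over complete patients with values
#'   `"not_applicable"`, `"not_covered"` or the predicted outcome.
#' @export
apply_rule <- function(rule, cohort, assignments) {
  counts <- item_satisfaction_counts(cohort, rule$items, rule$direction,
                                     rule$delta)
  ids <- names(counts)
  amap <- assignments[match(ids, assignments$patient_id), , drop = FALSE]
  applicable <- amap$baseline == rule$baseline &
    amap$week4 %in% rule$week4_strata
  out <- rep("not_applicable", length(ids))
  out[applicable] <- ifelse(counts[applicable] >= rule$min_items,
                            rule$predicted_outcome, "not_covered")
  setNames(out, ids)
}

#' Evaluate a prognosis rule on a cohort
#'
#' Restricted to the patients making the rule's transition: coverage is the
#' fraction covered by the rule's symptom-count condition; accuracy the
#' fraction of covered patients whose observed 8-week outcome is the
#' predicted one; the odds ratio compares the odds of the outcome in covered
#' versus uncovered patients ([odds_ratio_2x2()], Haldane-Anscombe corrected
#' when needed, Woolf 95% CI); and the p-value is a one-sided exact binomial
#' test of the accuracy against the null information rate.
#'
#' @param rule A `prognosis_rule`.
#' @param cohort,assignments Pipeline objects (the cohort supplies observed
#'   outcomes).
#' @param nir Null information rate comparator (default 0.53).
#' @return A `rule_evaluation` list.
#' @export
evaluate_rule <- function(rule, cohort, assignments, nir = 0.53) {
  status <- apply_rule(rule, cohort, assignments)
  tots <- cohort_totals(cohort)
  outcome <- setNames(as.character(tots$outcome), tots$patient_id)
  on_tr <- names(status)[status != "not_applicable"]
  if (length(on_tr) == 0)
    stop(sprintf("no patient makes the transition of rule %s", rule_id(rule)))
  covered <- status[on_tr] != "not_covered"
  hit <- outcome[on_tr] == rule$predicted_outcome
  a <- sum(covered & hit); b <- sum(covered & !hit)
  c_ <- sum(!covered & hit); d <- sum(!covered & !hit)
  orr <- odds_ratio_2x2(a, b, c_, d)
  n_cov <- a + b
  accuracy <- if (n_cov > 0) a / n_cov else NA_real_
  p_value <- if (n_cov > 0)
    binom.test(a, n_cov, p = nir, alternative = "greater")$p.value
  else NA_real_
  structure(list(rule = rule, n_transition = length(on_tr), n_covered = n_cov,
                 coverage = n_cov / length(on_tr), accuracy = accuracy,
                 odds_ratio = orr$or, ci95 = orr$ci,
                 or_corrected = orr$corrected,
                 p_value = p_value, nir = nir,
                 table = matrix(c(a, b, c_, d), 2, byrow = TRUE,
                                dimnames = list(c("covered", "uncovered"),
                                                c("outcome", "other")))),
            class = "rule_evaluation")
}

#' Tabulate rule evaluations
#'
#' @param evaluations List of `rule_evaluation`s.
#' @return Data frame mirroring the columns of a prognosis-rule report:
#'   transition, predicted outcome, threshold, minimum count, coverage,
#'   accuracy, OR, CI and p-value.
#' @export
evaluation_table <- function(evaluations) {
  do.call(rbind, lapply(evaluations, function(e) {
    r <- e$rule
    data.frame(baseline = r$baseline,
               week4 = paste(r$week4_strata, collapse = " or "),
               n_transition = e$n_transition,
               outcome = r$predicted_outcome,
               change = sprintf("%s%d",
                                if (r$direction == "at_least") ">=" else "<=",
                                r$delta),
               min_items = r$min_items,
               coverage = e$coverage, accuracy = e$accuracy,
               odds_ratio = e$odds_ratio,
               ci_low = e$ci95[1], ci_high = e$ci95[2],
               p_value = e$p_value,
               row.names = NULL, stringsAsFactors = FALSE)
  }))
}

#' Re-evaluate frozen rules on a test cohort
#'
#' Test patients are assigned to strata by range lookup into the frozen
#' training models (no refitting), and every rule is re-evaluated with its
#' parameters unchanged.
#'
#' @param rules List of `prognosis_rule`s from training.
#' @param test_cohort An `hdrs_cohort`.
#' @param frozen_models Named list of training `stratum_model`s.
#' @param nir Null information rate (default 0.53).
#' @return List of `rule_evaluation`s (rules whose transition is unobserved
#'   in the test cohort are skipped with a warning).
#' @export
replicate_rules <- function(rules, test_cohort, frozen_models, nir = 0.53) {
  before <- rules
  assignments <- assign_cohort_by_range(frozen_models, test_cohort)
  evals <- list()
  for (nm in names(rules)) {
    ev <- tryCatch(evaluate_rule(rules[[nm]], test_cohort, assignments,
                                 nir = nir),
                   error = function(e) { warning(conditionMessage(e)); NULL })
    if (!is.null(ev)) evals[[nm]] <- ev
  }
  stopifnot(identical(before, rules))  # frozen rules are never mutated
  evals
}

#' Demographic association checks
#'
#' Tests whether rule coverage or prognosis correctness is associated with
#' the common sociodemographic factors: a two-sample Kolmogorov-Smirnov test
#' for age, and chi-square tests for sex and race.  Tests whose margins are
#' degenerate (a single level, or no covered/uncovered split) are skipped
#' with a note.
#'
#' @param rules List of `prognosis_rule`s.
#' @param cohort,assignments Pipeline objects; the cohort must carry the
#'   demographic columns being tested.
#' @return Data frame: `variable`, `against`, `statistic`, `p_value`, `note`.
#' @export
demographic_association <- function(rules, cohort, assignments) {
  tots <- cohort_totals(cohort)
  status <- rep("not_applicable", nrow(tots))
  names(status) <- tots$patient_id
  for (rule in rules) {
    s <- apply_rule(rule, cohort, assignments)
    sel <- s != "not_applicable"
    status[names(s)[sel]] <- s[sel]
  }
  on_tr <- status != "not_applicable"
  covered <- on_tr & status != "not_covered"
  outcome <- setNames(as.character(tots$outcome), tots$patient_id)
  correct <- covered
  correct[covered] <- status[covered] == outcome[names(status)[covered]]
  res <- NULL
  add <- function(variable, against, statistic, p, note = "") {
    rbind(res, data.frame(variable = variable, against = against,
                          statistic = statistic, p_value = p, note = note,
                          stringsAsFactors = FALSE))
  }
  for (spec_ in list(list("coverage", on_tr, covered),
                     list("correctness", covered, correct))) {
    against <- spec_[[1]]; universe <- spec_[[2]]; flag <- spec_[[3]]
    if ("age" %in% names(tots)) {
      x <- tots$age[universe & flag]; y <- tots$age[universe & !flag]
      if (length(x) > 1 && length(y) > 1) {
        kt <- suppressWarnings(ks.test(x, y))
        res <- add("age", against, unname(kt$statistic), kt$p.value)
      } else res <- add("age", against, NA, NA, "degenerate split; skipped")
    }
    for (v in c("sex", "race")) {
      if (!v %in% names(tots)) next
      g <- tots[[v]][universe]; f <- flag[universe]
      if (length(unique(g)) < 2 || length(unique(f)) < 2) {
        res <- add(v, against, NA, NA, "degenerate margin; skipped")
        next
      }
      ct <- suppressWarnings(chisq.test(table(g, f)))
      res <- add(v, against, unname(ct$statistic), ct$p.value)
    }
  }
  res
}

#' @export
print.prognosis_rule <- function(x, ...) {
  cat(sprintf("Rule: %s -> %s : if >=%d of items {%s} improve %s%d points by week 4, predict %s\n",
              x$baseline, paste(x$week4_strata, collapse = " or "),
              x$min_items, paste(x$items, collapse = ","),
              if (x$direction == "at_least") ">=" else "<=",
              x$delta, x$predicted_outcome))
  invisible(x)
}

#' @export
print.rule_evaluation <- function(x, ...) {
  print(x$rule)
  cat(sprintf("  n=%d, coverage %.2f, accuracy %.2f, OR %.2f (%.2f, %.2f), p=%.3g vs NIR %.2f\n",
              x$n_transition, x$coverage, x$accuracy, x$odds_ratio,
              x$ci95[1], x$ci95[2], x$p_value, x$nir))
  invisible(x)
}
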