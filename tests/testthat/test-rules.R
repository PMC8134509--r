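test_that("the 2x2 odds ratio matches the worked cross-product example", {
  res <- odds_ratio_2x2(30, 10, 5, 10)
  expect_equal(res$or, 6.0)
  expect_false(res$corrected)
})

test_that("OR, CI, coverage and accuracy match independent direct formulas", {
  set.seed(14)
  for (rep_ in 1:200) {
    cells <- rpois(4, lambda = sample(c(0.5, 3, 20), 1))
    res <- odds_ratio_2x2(cells[1], cells[2], cells[3], cells[4])
    # oracle: direct formulas recomputed here
    cc <- if (any(cells == 0)) cells + 0.5 else cells
    or <- (cc[1] * cc[4]) / (cc[2] * cc[3])
    se <- sqrt(1 / cc[1] + 1 / cc[2] + 1 / cc[3] + 1 / cc[4])
    ci <- exp(log(or) + c(-1, 1) * qnorm(0.975) * se)
    expect_lt(abs(res$or - or), 1e-10)
    expect_true(all(abs(res$ci - ci) < 1e-10))
    expect_true(res$or > 0 && res$ci[1] <= res$or && res$or <= res$ci[2])
  }
})

# One transition subgroup (baseline stratum "3" -> week-4 stratum "2") with
# items {1, 2, 7, 10} prognostic.  Baseline total 22; covered patients improve
# those items by (3, 2, 3, 2) points, uncovered patients not at all; the
# week-8 total decides the outcome (9 -> response, 16 -> nonresponse).
mk_transition_patient <- function(covered, outcome) {
  m <- matrix(0L, 3, 17)
  m[1, c(1, 2, 7, 10)] <- c(4L, 3L, 4L, 3L)
  m[1, c(3, 8)] <- 4L
  m[2, c(1, 2, 7, 10)] <- if (covered) c(1L, 1L, 1L, 1L) else c(4L, 3L, 4L, 3L)
  m[2, 3] <- 2L
  m[3, ] <- spread_total(if (outcome) 9L else 16L)
  m
}

response_rule <- function() {
  structure(list(baseline = "3", week4_strata = "2",
                 predicted_outcome = "response", direction = "at_least",
                 delta = 2L, min_items = 2L, items = c(1L, 2L, 7L, 10L)),
            class = "prognosis_rule")
}

test_that("applying a rule covers exactly the patients meeting the threshold", {
  items <- list(mk_transition_patient(TRUE, TRUE),
                mk_transition_patient(TRUE, FALSE),
                mk_transition_patient(FALSE, FALSE))
  co <- build_cohort(items)
  assignments <- data.frame(patient_id = sprintf("P%03d", 1:3),
                            baseline = "3", week4 = "2", week8 = "2",
                            stringsAsFactors = FALSE)
  status <- apply_rule(response_rule(), co, assignments)
  expect_equal(unname(status["P001"]), "response")   # improves 4 items by >= 2
  expect_equal(unname(status["P003"]), "not_covered")
  assignments$baseline[2] <- "1"
  status <- apply_rule(response_rule(), co, assignments)
  expect_equal(unname(status["P002"]), "not_applicable")
  # covered + uncovered partition the transition subgroup
  on_tr <- status != "not_applicable"
  expect_equal(sum(status[on_tr] == "not_covered") +
                 sum(status[on_tr] == "response"), sum(on_tr))
})

test_that("rule evaluation reproduces hand-computed coverage/accuracy/OR", {
  items <- c(replicate(30, mk_transition_patient(TRUE, TRUE), simplify = FALSE),
             replicate(10, mk_transition_patient(TRUE, FALSE), simplify = FALSE),
             replicate(5, mk_transition_patient(FALSE, TRUE), simplify = FALSE),
             replicate(10, mk_transition_patient(FALSE, FALSE), simplify = FALSE))
  co <- build_cohort(items)
  assignments <- data.frame(patient_id = sprintf("P%03d", 1:55),
                            baseline = "3", week4 = "2", week8 = "2",
                            stringsAsFactors = FALSE)
  ev <- evaluate_rule(response_rule(), co, assignments)
  expect_equal(ev$n_transition, 55L)
  expect_equal(ev$coverage, 40 / 55)
  expect_equal(ev$accuracy, 0.75)
  expect_equal(ev$odds_ratio, 6.0)
  expect_equal(unname(ev$table["covered", ]), c(30, 10))
  # independent p-value oracle: exact binomial upper tail at the NIR
  expect_equal(ev$p_value, sum(dbinom(30:40, 40, 0.53)))
})

test_that("accuracy at the NIR itself is never significant", {
  ev_p <- binom.test(53, 100, p = 0.53, alternative = "greater")$p.value
  expect_gte(ev_p, 0.5)
})

test_that("thresholds follow the path medians with the nonresponse floor", {
  mk <- function(w4_items) {
    m <- matrix(0L, 3, 17)
    m[1, c(1, 2, 7, 10)] <- c(4L, 4L, 3L, 3L)
    m[1, c(3, 8)] <- 4L
    m[2, c(1, 2, 7, 10)] <- w4_items
    m[3, ] <- spread_total(8L)
    m
  }
  co <- build_cohort(replicate(6, mk(c(2L, 2L, 2L, 1L)), simplify = FALSE))
  thr <- derive_threshold(co, NULL, c(1, 2, 7, 10),
                          sprintf("P%03d", 1:6), "response")
  # per-item median drops are (2, 2, 1, 2) -> rounded median 2
  expect_equal(thr$delta, 2L)
  expect_equal(thr$direction, "at_least")
  # flat medians floor at 1 point for nonresponse rules ("improved by <= 1")
  co_flat <- build_cohort(replicate(6, mk(c(4L, 4L, 3L, 3L)), simplify = FALSE))
  thr <- derive_threshold(co_flat, NULL, c(1, 2, 7, 10),
                          sprintf("P%03d", 1:6), "nonresponse")
  expect_equal(thr$delta, 1L)
  expect_equal(thr$direction, "at_most")
  expect_error(derive_threshold(co, NULL, c(1, 2, 7, 10), character(0),
                                "response"), "no patients")
})

test_that("the minimum symptom count screen finds a perfect separator", {
  counts <- c(rep(3L, 20), rep(1L, 20))
  outcome <- c(rep(TRUE, 20), rep(FALSE, 20))
  res <- derive_min_items(counts, outcome, n_items = 4)
  expect_equal(res$m, 2L)  # m = 2 splits the groups perfectly
  expect_false(res$flagged)

  set.seed(21)
  counts <- sample(0:4, 200, replace = TRUE)
  outcome <- sample(c(TRUE, FALSE), 200, replace = TRUE)
  res <- derive_min_items(counts, outcome, n_items = 4)
  expect_true(res$flagged)  # independent outcome: no significant m

  expect_error(derive_min_items(rep(4L, 10), rep(TRUE, 10), 4), "degenerate")
})

test_that("frozen-rule replication on the training cohort is idempotent", {
  tr <- shared_drug_training()
  co <- attr(tr, "cohort")
  evals <- replicate_rules(tr$rules, co, tr$models)
  expect_equal(evaluation_table(evals), evaluation_table(tr$evaluations))
})

test_that("demographics independent by construction are not associated", {
  tr <- shared_drug_training()
  co <- attr(tr, "cohort")
  res <- demographic_association(tr$rules, co, tr$assignments)
  expect_true(all(c("age", "sex", "race") %in% res$variable))
  expect_true(all(is.finite(res$p_value[res$note == ""])))
  expect_gt(min(res$p_value[res$note == ""]), 0.01)
})

test_that("a planted age shift in covered patients is detected", {
  tr <- shared_drug_training()
  co <- attr(tr, "cohort")
  status <- rep(FALSE, length(unique(co$patient_id)))
  names(status) <- sort(unique(co$patient_id))
  for (rule in tr$rules) {
    s <- apply_rule(rule, co, tr$assignments)
    status[names(s)[!s %in% c("not_applicable", "not_covered")]] <- TRUE
  }
  co_shift <- co
  co_shift$age <- co$age + ifelse(status[co$patient_id], 20L, 0L)
  res <- demographic_association(tr$rules, co_shift, tr$assignments)
  p_age <- res$p_value[res$variable == "age" & res$against == "coverage"]
  expect_lt(p_age, 0.05)

  co_onesex <- co
  co_onesex$sex <- "female"
  res <- demographic_association(tr$rules, co_onesex, tr$assignments)
  expect_match(res$note[res$variable == "sex"][1], "degenerate")
})
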