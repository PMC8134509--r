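labels3 <- list(baseline = c("1", "2", "3"), week4 = c("1", "2", "3"),
                week8 = c("1", "2", "3"))

make_assignments <- function(triples) {
  data.frame(patient_id = sprintf("P%03d", seq_len(nrow(triples))),
             baseline = as.character(triples[, 1]),
             week4 = as.character(triples[, 2]),
             week8 = as.character(triples[, 3]),
             stringsAsFactors = FALSE)
}

test_that("transition probabilities are row-normalised counts", {
  tri <- cbind(rep(1, 10), c(rep(1, 6), rep(2, 4)), rep(1, 10))
  tm <- estimate_transitions(make_assignments(tri), labels = labels3)
  expect_equal(unname(tm$p_b_given_a["1", ]), c(0.6, 0.4, 0))
  # unoccupied baseline rows stay all-zero and are flagged
  expect_equal(unname(rowSums(tm$p_b_given_a)[c("2", "3")]), c(0, 0))
  expect_equal(tm$zero_rows$baseline, c(`2` = 2L, `3` = 3L))
})

test_that("a single realized path gives degenerate occupied rows", {
  tri <- cbind(rep(2, 5), rep(3, 5), rep(1, 5))
  tm <- estimate_transitions(make_assignments(tri), labels = labels3)
  expect_equal(unname(tm$p_b_given_a["2", ]), c(0, 0, 1))
  expect_equal(unname(tm$p_c_given_b["3", ]), c(1, 0, 0))
  expect_error(estimate_transitions(make_assignments(tri)[0, ]), "no assignments")
})

test_that("occupied rows of random cohorts always sum to one", {
  set.seed(11)
  for (rep_ in 1:10) {
    tri <- cbind(sample(1:3, 50, TRUE), sample(1:3, 50, TRUE),
                 sample(1:3, 50, TRUE))
    tm <- estimate_transitions(make_assignments(tri), labels = labels3)
    for (M in list(tm$p_b_given_a, tm$p_c_given_b)) {
      rs <- rowSums(M)
      expect_true(all(abs(rs[rs > 0] - 1) < 1e-12))
    }
  }
})

test_that("three strata and three timepoints give 27 candidate paths", {
  set.seed(5)
  tm <- transition_model(random_row_stochastic(), random_row_stochastic())
  paths <- forward_path_likelihoods(tm)
  expect_equal(nrow(paths), 27L)
  expect_equal(nrow(unique(paths[, c("baseline", "week4", "week8")])), 27L)
})

test_that("identity and uniform transitions give the forced likelihoods", {
  I3 <- diag(3); dimnames(I3) <- list(1:3, 1:3)
  tm <- transition_model(I3, I3)
  paths <- forward_path_likelihoods(tm)
  diagonal <- paths$baseline == paths$week4 & paths$week4 == paths$week8
  expect_equal(paths$likelihood[diagonal], rep(1, 3))
  expect_equal(paths$likelihood[!diagonal], rep(0, 24))

  U <- matrix(1 / 3, 3, 3)
  paths <- forward_path_likelihoods(transition_model(U, U))
  expect_equal(paths$likelihood, rep(1 / 9, 27))
  sums <- tapply(paths$likelihood, paths$baseline, sum)
  expect_equal(as.numeric(sums), rep(1, 3), tolerance = 1e-12)
})

test_that("the forward recursion matches brute-force enumeration", {
  set.seed(123)
  for (rep_ in 1:100) {
    P1 <- random_row_stochastic(); P2 <- random_row_stochastic()
    paths <- forward_path_likelihoods(transition_model(P1, P2))
    # independent oracle: direct product over explicit triples
    brute <- apply(paths, 1, function(r)
      P1[as.integer(r["baseline"]), as.integer(r["week4"])] *
        P2[as.integer(r["week4"]), as.integer(r["week8"])])
    expect_true(all(abs(paths$likelihood - brute) < 1e-12))
    sums <- tapply(paths$likelihood, paths$baseline, sum)
    expect_true(all(abs(sums - 1) < 1e-12))
  }
})

test_that("path selection keeps the best qualifying triple per endpoint pair", {
  base <- data.frame(baseline = "1", week4 = c("1", "2", "3"), week8 = "3",
                     likelihood = c(0.5, 0.3, 0.2),
                     n_patients = c(8L, 15L, 12L), stringsAsFactors = FALSE)
  base$fraction_of_baseline <- base$n_patients / 100
  sel <- select_symptom_dynamic_paths(base, min_fraction = 0.10)
  # the most likely triple carries only 8% and is skipped; next best wins
  expect_equal(nrow(sel), 1L)
  expect_equal(sel$week4, "2")

  none <- base; none$fraction_of_baseline <- rep(0.08, 3)
  expect_equal(nrow(select_symptom_dynamic_paths(none)), 0L)

  # likelihood tie: larger fraction wins, then the less severe week-4 stratum
  tie <- base; tie$likelihood <- rep(0.3, 3); tie$n_patients <- c(15L, 15L, 12L)
  tie$fraction_of_baseline <- tie$n_patients / 100
  expect_equal(select_symptom_dynamic_paths(tie)$week4, "1")
})

test_that("selected paths are invariant to patient order", {
  co <- simulate_cohort(sim_config(n_patients = 400, seed = 10))
  st <- stratify_cohort(co, seed = 10)
  sel1 <- select_symptom_dynamic_paths(
    forward_path_likelihoods(estimate_transitions(st$assignments)))
  set.seed(1)
  shuffled <- st$assignments[sample(nrow(st$assignments)), ]
  sel2 <- select_symptom_dynamic_paths(
    forward_path_likelihoods(estimate_transitions(shuffled)))
  expect_equal(sel1, sel2)
})
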