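test_that("criterion (a) keeps items with non-zero baseline severity in the majority", {
  co <- simulate_cohort(sim_config(n_patients = 200, seed = 31))
  # plant an item that is zero at baseline for 60% of patients
  ids <- sort(unique(co$patient_id))
  zero_ids <- ids[seq_len(120)]
  sel <- co$patient_id %in% zero_ids & co$timepoint == "baseline"
  co$item_13[sel] <- 0L
  keep <- criterion_a_nonzero(co, majority_threshold = 0.5)
  expect_false(13 %in% keep)
  # an item positive for everyone is kept
  co$item_1[co$timepoint == "baseline"] <- pmax(co$item_1[co$timepoint == "baseline"], 1L)
  expect_true(1 %in% criterion_a_nonzero(co))
  # an all-zero item is dropped
  co$item_16[co$timepoint == "baseline"] <- 0L
  expect_false(16 %in% criterion_a_nonzero(co))
  expect_error(criterion_a_nonzero(co[0, ]), "empty")
})

test_that("identical severity profiles always co-cluster; distinct ones split", {
  co <- simulate_cohort(sim_config(n_patients = 120, seed = 32))
  co$item_2 <- co$item_1  # byte-identical profiles
  st <- stratify_cohort(co, seed = 32)
  cl <- cluster_symptoms(co, st$assignments, "3", "baseline", h = 0)
  expect_equal(cl$membership[["item_1"]], cl$membership[["item_2"]])
  expect_error(cluster_symptoms(co, st$assignments[1, , drop = FALSE],
                                "3", "baseline"), "fewer than 2")
})

test_that("mutually distinct random profiles cut at height zero are singletons", {
  set.seed(7)
  items <- lapply(1:6, function(p) {
    m <- matrix(0L, 3, 17)
    m[1, ] <- vapply(hdrs_item_max(), function(mx) sample(0:mx, 1), integer(1))
    m[1, 1] <- max(m[1, 1], 1L)  # keep baseline total positive
    m[2, ] <- m[1, ]; m[3, ] <- m[1, ]
    m
  })
  co <- build_cohort(items)
  assignments <- data.frame(patient_id = sprintf("P%03d", 1:6),
                            baseline = "1", week4 = "1", week8 = "1",
                            stringsAsFactors = FALSE)
  cl <- cluster_symptoms(co, assignments, "1", "baseline", h = 0)
  d <- dist(t(item_matrix(co, "baseline")))
  expect_equal(cl$k, sum(!duplicated(as.matrix(t(item_matrix(co, "baseline"))))))
})

test_that("relative change standing has mean 1/2 for exchangeable items", {
  co <- simulate_cohort(sim_config(n_patients = 600, arm = "placebo", seed = 33))
  U <- relative_change_standing(co)
  expect_true(all(colMeans(U, na.rm = TRUE) > 0.42 &
                    colMeans(U, na.rm = TRUE) < 0.58))
})

test_that("criterion (c) finds planted items and rejects exchangeable ones", {
  tr <- shared_drug_training()
  co <- attr(tr, "cohort")
  cres <- criterion_c_discriminative(co, tr$assignments, tr$selected_paths)
  expect_true(all(cres$pass[c(1, 2, 7, 10)]))
  expect_false(any(cres$pass[-c(1, 2, 7, 10)]))
  # planted items improve more than peers along remitting paths
  expect_true(all(cres$direction[c(1, 2, 7, 10)] < 0))
})

test_that("a cohort of identical patients yields no discriminative items", {
  items <- rbind(spread_total(26), spread_total(12), spread_total(5))
  co <- build_cohort(rep(list(items), 30))
  assignments <- data.frame(patient_id = sprintf("P%03d", 1:30),
                            baseline = "1", week4 = "1", week8 = "1",
                            stringsAsFactors = FALSE)
  paths <- data.frame(baseline = "1", week4 = "1", week8 = "1",
                      likelihood = 1, n_patients = 30L,
                      fraction_of_baseline = 1, stringsAsFactors = FALSE)
  cres <- criterion_c_discriminative(co, assignments, paths)
  expect_false(any(cres$pass))  # a single path supports no contrast
})

test_that("the mined prognostic set is exactly the planted set on drug data", {
  tr <- shared_drug_training()
  expect_equal(unname(tr$symptoms$items), c(1L, 2L, 7L, 10L))
  ev <- tr$symptoms$evidence
  expect_true(all(ev$criterion_a[ev$selected]))
  expect_true(all(ev$criterion_b[ev$selected]))
})

test_that("no prognostic symptoms are identified on placebo data", {
  co <- simulate_cohort(sim_config(n_patients = 1800, arm = "placebo", seed = 2))
  tr <- run_training(co, pipeline_config(seed = 2))
  expect_length(tr$symptoms$items, 0)
  expect_length(tr$rules, 0)
})

test_that("mining is invariant to patient order", {
  tr <- shared_drug_training()
  co <- attr(tr, "cohort")
  set.seed(99)
  co_shuf <- co[sample(nrow(co)), ]
  class(co_shuf) <- c("hdrs_cohort", "data.frame")
  sy <- identify_prognostic_symptoms(co_shuf, tr$assignments,
                                     tr$selected_paths, tr$config)
  expect_equal(sy$items, tr$symptoms$items)
})
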