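# Shared fixtures, all generated in code.

# A tiny hand-built long-format cohort: `n` patients whose 17-item vectors at
# each timepoint are supplied per patient as a list of 3 x 17 matrices.
build_cohort <- function(item_list, arm = "drug",
                         age = NULL, sex = NULL, race = NULL) {
  rows <- lapply(seq_along(item_list), function(p) {
    m <- item_list[[p]]
    stopifnot(nrow(m) == 3, ncol(m) == 17)
    df <- data.frame(patient_id = sprintf("P%03d", p), arm = arm,
                     drug_label = "test", timepoint = hdrs_timepoints(),
                     stringsAsFactors = FALSE)
    colnames(m) <- paste0("item_", 1:17)
    cbind(df, as.data.frame(m))
  })
  df <- do.call(rbind, rows)
  if (!is.null(age)) df$age <- rep(age, each = 3)
  if (!is.null(sex)) df$sex <- rep(sex, each = 3)
  if (!is.null(race)) df$race <- rep(race, each = 3)
  co <- df
  class(co) <- c("hdrs_cohort", "data.frame")
  co
}

# Item vector with a given total spread over the first items (bounds-aware).
spread_total <- function(total) {
  maxima <- hdrs_item_max()
  x <- integer(17)
  for (i in seq_len(17)) {
    take <- min(total, maxima[i])
    x[i] <- take
    total <- total - take
    if (total == 0) break
  }
  x
}

# Random valid item matrix for one patient (3 timepoints).
random_patient_items <- function() {
  maxima <- hdrs_item_max()
  t(vapply(1:3, function(j) {
    vapply(maxima, function(m) sample(0:m, 1), integer(1))
  }, integer(17)))
}

random_row_stochastic <- function(k = 3) {
  m <- matrix(stats::runif(k * k), k)
  m / rowSums(m)
}

# Small drug-arm training cohort shared by the slower mining/pipeline tests.
shared_drug_training <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      co <- simulate_cohort(sim_config(n_patients = 1800, arm = "drug",
                                       seed = 2))
      cache <<- run_training(co, pipeline_config(seed = 2))
      attr(cache, "cohort") <<- co
    }
    cache
  }
})
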