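# Synthetic-cohort simulator: latent severity strata with forward transitions,
# truncated-Gaussian totals inside the reference stratum score ranges, and an
# item-level decomposition that can plant (drug arm) or withhold (placebo arm)
# a path-discriminating signal in a chosen set of prognostic items.

default_stratum_ranges <- function() {
  list(baseline = rbind(c(14, 18), c(19, 24), c(25, 39)),
       week4    = rbind(c(0, 8),  c(9, 15),  c(16, 31)),
       week8    = rbind(c(0, 7),  c(8, 15),  c(16, 34)))
}

#' Simulator configuration
#'
#' Defines the generative model of a synthetic antidepressant cohort: three
#' latent severity strata at each of three timepoints, row-stochastic forward
#' transitions between strata, truncated-Gaussian total scores inside each
#' stratum's score range, and a proportional item decomposition in which the
#' `prognostic_items` carry a path-coupled dynamic in the drug arm only.
#'
#' Default stratum means are the midpoints of the reference score ranges and
#' default SDs are range width / 6, so sampled totals concentrate well inside
#' their stratum.  Default baseline weights and transition matrices are chosen
#' so that the dominant paths from each baseline stratum are the "diagonal"
#' remission / response / nonresponse trajectories, no single path from the
#' least-severe baseline stratum reaches the most-severe endpoint with a 10%
#' patient share, and roughly a third of patients start in each baseline
#' stratum.
#'
#' @param n_patients Number of patients to simulate.
#' @param arm `"drug"` or `"placebo"`.  In the placebo arm the coupling is
#'   forced to zero: no item carries path information beyond the total.
#' @param seed Integer master seed; each patient draws from a substream
#'   derived from `(seed, patient index)`, so the cohort is reproducible and
#'   invariant to generation order.
#' @param stratum_means,stratum_sds 3x3 numeric matrices (timepoint x stratum)
#'   of total-score means/SDs.
#' @param stratum_ranges List of three 3x2 matrices of integer score ranges.
#' @param baseline_weights Length-3 probability vector over baseline strata.
#' @param transition_b_given_a,transition_c_given_b 3x3 row-stochastic
#'   matrices of forward transition probabilities.
#' @param prognostic_items Integer item indices receiving the planted
#'   path-coupled dynamic (default the four prognostic HDRS items: depressed
#'   mood 1, guilt 2, work/activities 7, psychic anxiety 10).
#' @param coupling_strength Fraction in `[0, 1]` blending proportional item
#'   dynamics (0) with fully path-determined dynamics (1) for the prognostic
#'   items in the drug arm.
#' @param noise_sd SD of the log-normal jitter multiplying item allocation
#'   weights (inter-patient symptom-profile heterogeneity at baseline,
#'   measurement noise at follow-ups).
#' @param drug_label Free-text drug label stored on each record.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_patients = 947,
                       arm = c("drug", "placebo"),
                       seed = 1L,
                       stratum_means = NULL,
                       stratum_sds = NULL,
                       stratum_ranges = default_stratum_ranges(),
                       baseline_weights = c(0.30, 0.37, 0.33),
                       transition_b_given_a = rbind(c(0.62, 0.28, 0.10),
                                                    c(0.30, 0.44, 0.26),
                                                    c(0.23, 0.40, 0.37)),
                       transition_c_given_b = rbind(c(0.85, 0.13, 0.02),
                                                    c(0.15, 0.75, 0.10),
                                                    c(0.05, 0.30, 0.65)),
                       prognostic_items = c(1L, 2L, 7L, 10L),
                       coupling_strength = 0.75,
                       noise_sd = 0.3,
                       drug_label = NULL) {
  arm <- match.arg(arm)
  rng <- stratum_ranges
  stopifnot(length(rng) == 3, all(vapply(rng, nrow, 0L) == 3L))
  mids <- t(vapply(rng, function(r) rowMeans(r), numeric(3)))
  wids <- t(vapply(rng, function(r) (r[, 2] - r[, 1]) / 6, numeric(3)))
  if (is.null(stratum_means)) stratum_means <- mids
  if (is.null(stratum_sds)) stratum_sds <- pmax(wids, 0.5)
  stopifnot(all(dim(stratum_means) == c(3, 3)), all(dim(stratum_sds) == c(3, 3)))
  if (abs(sum(baseline_weights) - 1) > 1e-12)
    stop("baseline_weights must sum to 1")
  for (M in list(transition_b_given_a, transition_c_given_b)) {
    if (any(M < 0) || any(abs(rowSums(M) - 1) > 1e-12))
      stop("transition matrices must be row-stochastic within 1e-12")
  }
  stopifnot(all(prognostic_items %in% 1:17),
            coupling_strength >= 0, coupling_strength <= 1, noise_sd >= 0)
  if (is.null(drug_label))
    drug_label <- if (arm == "drug") "citalopram" else "placebo"
  structure(list(n_patients = as.integer(n_patients), arm = arm,
                 seed = as.integer(seed),
                 stratum_means = stratum_means, stratum_sds = stratum_sds,
                 stratum_ranges = rng, baseline_weights = baseline_weights,
                 transition_b_given_a = transition_b_given_a,
                 transition_c_given_b = transition_c_given_b,
                 prognostic_items = as.integer(prognostic_items),
                 coupling_strength = coupling_strength, noise_sd = noise_sd,
                 drug_label = drug_label),
            class = "sim_config")
}

# Random integer decomposition of `total` severity points over items bounded
# by `maxima`, with expected allocation proportional to `targets` (systematic
# allocation: each item receives the integer part of its proportional share,
# and the remaining units are sampled with probability proportional to the
# fractional parts).  The allocation is unbiased up to the item caps — an
# item's expected score is proportional to its target, so items carry no
# systematic information about the total beyond proportionality — while the
# per-item randomness stays below one point.
allocate_total <- function(targets, total, maxima) {
  total <- as.integer(round(total))
  if (total < 0 || total > sum(maxima))
    stop(sprintf("infeasible decomposition: total %d outside [0, %d]",
                 total, sum(maxima)))
  n <- length(targets)
  x <- integer(n)
  if (total == 0) return(x)
  q <- pmax(targets, 0)
  repeat {
    rem <- total - sum(x)
    if (rem == 0) return(x)
    free <- maxima - x
    qq <- q * (free > 0)
    if (sum(qq) <= 0) qq <- as.numeric(free > 0)
    tgt <- pmin(rem * qq / sum(qq), free)
    base <- as.integer(floor(tgt + 1e-12))
    x <- x + base
    r <- rem - sum(base)
    if (r > 0) {
      frac <- tgt - base
      avail <- which(free - base > 0)
      if (length(avail) == 0) next
      w <- pmax(frac[avail], 1e-9)
      pick <- if (length(avail) == 1) avail else
        sample(avail, size = min(r, length(avail)), prob = w)
      x[pick] <- x[pick] + 1L
    }
  }
}

rtrunc_round <- function(mean, sd, lo, hi) {
  for (iter in 1:10000) {
    v <- round(rnorm(1, mean, sd))
    if (v >= lo && v <= hi) return(as.integer(v))
  }
  as.integer(round(mean))  # unreachable for any sane config
}

# Path-coupled shrinkage of prognostic items, indexed by the week-8 stratum:
# remitting paths drive the planted items to near-complete resolution,
# nonresponding paths keep them flat at their baseline severity.
coupling_targets <- function() {
  rbind(c(0.02, 0.01),   # week-8 stratum 1 (remission-range endpoint)
        c(0.50, 0.30),   # stratum 2
        c(1.00, 0.95))   # stratum 3 (nonresponse-range endpoint)
}

#' Simulate a synthetic HDRS cohort
#'
#' For each patient a latent stratum sequence is drawn from the baseline
#' weights and the two forward transition matrices; total scores are drawn
#' from each stratum's Gaussian by rejection inside the stratum's score range
#' (rounded to integers); and the total is decomposed into 17 item scores by
#' a capacity-respecting multinomial allocation, so items always re-sum to
#' the total and no item exceeds its bound.  Baseline allocation weights are
#' proportional to each item's maximum, with a mild up-weight (factor 1.3)
#' for the prognostic items so they present as prominent baseline complaints
#' while overlapping the severity range of the other items.  At weeks 4 and
#' 8 each item's weight is its realised baseline score scaled by the
#' patient's total-score ratio — proportional dynamics, under which no item
#' carries path information beyond the total; in the drug arm the prognostic
#' items' scale is blended (by `coupling_strength`) toward a path-determined
#' trajectory that shrinks along remitting paths and stays flat along
#' nonresponding paths.  Log-normal weight jitter adds patient-level profile
#' heterogeneity.  Age, sex and race are generated independently of
#' everything else.
#'
#' @param config A [sim_config()].
#' @return An `hdrs_cohort` with attributes `latent_paths` (data frame of the
#'   true stratum indices per patient) and `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_patients
  if (n < 1) stop("n_patients must be >= 1")
  maxima <- hdrs_item_max()
  planted <- seq_len(17) %in% config$prognostic_items
  # mild baseline up-weight: prognostic symptoms are prominent complaints at
  # intake, while still overlapping the other items' severity distribution
  w_base <- maxima * ifelse(planted, 1.3, 1)
  kappa <- if (config$arm == "drug") config$coupling_strength else 0
  g <- coupling_targets()
  tps <- hdrs_timepoints()

  items <- matrix(0L, nrow = 3L * n, ncol = 17L)
  tot <- integer(3L * n)
  lat <- matrix(0L, nrow = n, ncol = 3L)
  age <- integer(n); sex <- character(n); race <- character(n)

  for (p in seq_len(n)) {
    set.seed((config$seed %% 100000L) * 20011L + p)
    s <- integer(3)
    s[1] <- sample.int(3L, 1L, prob = config$baseline_weights)
    s[2] <- sample.int(3L, 1L, prob = config$transition_b_given_a[s[1], ])
    s[3] <- sample.int(3L, 1L, prob = config$transition_c_given_b[s[2], ])
    lat[p, ] <- s
    t3 <- integer(3)
    for (j in 1:3) {
      r <- config$stratum_ranges[[j]][s[j], ]
      t3[j] <- rtrunc_round(config$stratum_means[j, s[j]],
                            config$stratum_sds[j, s[j]], r[1], r[2])
    }
    # baseline decomposition
    tb <- w_base * exp(rnorm(17, 0, config$noise_sd))
    xb <- allocate_total(tb, t3[1], maxima)
    items[3L * (p - 1L) + 1L, ] <- xb
    # follow-up decompositions
    for (j in 2:3) {
      rho <- t3[j] / t3[1]
      scale <- rep(rho, 17)
      scale[planted] <- (1 - kappa) * rho + kappa * g[s[3], j - 1]
      tt <- xb * scale * exp(rnorm(17, 0, config$noise_sd))
      items[3L * (p - 1L) + j, ] <- allocate_total(tt, t3[j], maxima)
    }
    tot[3L * (p - 1L) + 1:3] <- t3
    age[p] <- max(18L, min(80L, as.integer(round(rnorm(1, 44, 12)))))
    sex[p] <- sample(c("female", "male"), 1L, prob = c(0.65, 0.35))
    race[p] <- sample(c("white", "black", "asian", "other"), 1L,
                      prob = c(0.80, 0.10, 0.05, 0.05))
  }

  ids <- sprintf("P%05d", seq_len(n))
  df <- data.frame(patient_id = rep(ids, each = 3L),
                   arm = config$arm, drug_label = config$drug_label,
                   timepoint = rep(tps, times = n),
                   stringsAsFactors = FALSE)
  colnames(items) <- item_cols()
  df <- cbind(df, as.data.frame(items))
  df$age <- rep(age, each = 3L)
  df$sex <- rep(sex, each = 3L)
  df$race <- rep(race, each = 3L)
  co <- validate_cohort(df)
  attr(co, "latent_paths") <- data.frame(patient_id = ids,
                                         baseline = lat[, 1], week4 = lat[, 2],
                                         week8 = lat[, 3],
                                         stringsAsFactors = FALSE)
  attr(co, "config") <- config
  co
}

#' Simulator self-test: empirical vs configured transition probabilities
#'
#' Recovers each patient's latent strata by range lookup of the total scores
#' (the configured stratum ranges are disjoint, so recovery is exact), tallies
#' empirical transition fractions, and reports the maximum elementwise
#' absolute deviation from the configured matrices over occupied rows.
#'
#' @param records An `hdrs_cohort` generated by [simulate_cohort()].
#' @param config The [sim_config()] used to generate it.
#' @return Maximum absolute probability deviation (a single number).
#' @export
empirical_transition_check <- function(records, config) {
  tots <- cohort_totals(records)
  if (nrow(tots) == 0) stop("no complete records to check")
  lookup <- function(tp, x) {
    r <- config$stratum_ranges[[tp]]
    s <- integer(length(x))
    for (k in 1:3) s[x >= r[k, 1] & x <= r[k, 2]] <- k
    if (any(s == 0)) stop("total outside all configured stratum ranges")
    s
  }
  a <- lookup("baseline", tots$baseline)
  b <- lookup("week4", tots$week4)
  c_ <- lookup("week8", tots$week8)
  dev <- 0
  emp_ab <- table(factor(a, 1:3), factor(b, 1:3))
  emp_bc <- table(factor(b, 1:3), factor(c_, 1:3))
  for (pair in list(list(emp_ab, config$transition_b_given_a),
                    list(emp_bc, config$transition_c_given_b))) {
    cnt <- pair[[1]]; ref <- pair[[2]]
    for (i in 1:3) {
      if (sum(cnt[i, ]) == 0) next
      dev <- max(dev, abs(cnt[i, ] / sum(cnt[i, ]) - ref[i, ]))
    }
  }
  as.numeric(dev)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("sim_config: %d patients, %s arm, seed %d, coupling %.2f, items {%s}\n",
              x$n_patients, x$arm, x$seed, x$coupling_strength,
              paste(x$prognostic_items, collapse = ",")))
  invisible(x)
}
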