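# Domain types and validation for HDRS-17 cohorts.

#' Timepoint labels used throughout the package
#'
#' The three fixed assessment timepoints of an 8-week antidepressant trial.
#'
#' @return Character vector `c("baseline", "week4", "week8")`.
#' @export
hdrs_timepoints <- function() c("baseline", "week4", "week8")

#' Per-item maxima of the HDRS-17 instrument
#'
#' Items 1, 2, 3, 7, 8, 9, 10, 11 and 15 are scored 0-4; the remaining items
#' (4, 5, 6, 12, 13, 14, 16, 17) are scored 0-2.  The maximum total is 52.
#'
#' @return Integer vector of length 17.
#' @export
hdrs_item_max <- function() {
  m <- rep(2L, 17)
  m[c(1L, 2L, 3L, 7L, 8L, 9L, 10L, 11L, 15L)] <- 4L
  m
}

item_cols <- function() paste0("item_", 1:17)

#' Classify the 8-week treatment outcome
#'
#' Outcomes partition all valid (baseline, week-8) total-score pairs:
#' remission is a week-8 total of 7 or less; response is a greater than 50
#' percent reduction from baseline with a week-8 total above 7; everything
#' else (at most 50 percent reduction) is nonresponse.  A reduction of exactly
#' 50 percent is classified nonresponse, keeping "response" strictly greater
#' than half.
#'
#' @param baseline_total,week8_total Integer total scores in `[0, 52]`;
#'   `baseline_total` must be at least 1.  Vectors are recycled.
#' @return Factor with levels `remission`, `response`, `nonresponse`.
#' @examples
#' classify_outcome(25, 7)   # remission
#' classify_outcome(20, 9)   # response (55% reduction, total > 7)
#' classify_outcome(20, 10)  # nonresponse (exactly 50%)
#' @export
classify_outcome <- function(baseline_total, week8_total) {
  n <- max(length(baseline_total), length(week8_total))
  b <- rep_len(as.numeric(baseline_total), n)
  w <- rep_len(as.numeric(week8_total), n)
  if (anyNA(b) || anyNA(w)) stop("totals must not contain NA")
  if (any(b < 1)) stop("baseline_total must be >= 1 (reduction undefined at 0)")
  if (any(b > 52) || any(w < 0) || any(w > 52)) stop("totals must lie in [0, 52]")
  out <- ifelse(w <= 7, "remission",
                ifelse((b - w) / b > 0.5, "response", "nonresponse"))
  factor(out, levels = c("remission", "response", "nonresponse"))
}

outcome_levels <- function() c("remission", "response", "nonresponse")

validate_cohort <- function(df, file = "<data.frame>") {
  req <- c("patient_id", "arm", "drug_label", "timepoint", item_cols())
  missing <- setdiff(req, names(df))
  if (length(missing) > 0)
    stop(sprintf("malformed cohort %s: missing column(s) %s", file,
                 paste(missing, collapse = ", ")))
  rowno <- seq_len(nrow(df)) + 1L  # header is row 1 in the file
  bad <- which(!df$timepoint %in% hdrs_timepoints())
  if (length(bad) > 0)
    stop(sprintf("row %d: invalid timepoint '%s'", rowno[bad[1]],
                 df$timepoint[bad[1]]))
  bad <- which(!df$arm %in% c("drug", "placebo"))
  if (length(bad) > 0)
    stop(sprintf("row %d: invalid arm '%s' (must be drug or placebo)",
                 rowno[bad[1]], df$arm[bad[1]]))
  maxima <- hdrs_item_max()
  for (i in 1:17) {
    v <- df[[item_cols()[i]]]
    if (nrow(df) == 0) { df[[item_cols()[i]]] <- integer(0); next }
    if (!is.numeric(v) || any(is.na(v)) || any(v != round(v)))
      stop(sprintf("column item_%d must be integer-valued with no NA", i))
    bad <- which(v < 0 | v > maxima[i])
    if (length(bad) > 0)
      stop(sprintf("row %d: item_%d score %s outside [0, %d]",
                   rowno[bad[1]], i, v[bad[1]], maxima[i]))
  }
  key <- paste(df$patient_id, df$timepoint)
  dup <- which(duplicated(key))
  if (length(dup) > 0)
    stop(sprintf("row %d: duplicate (patient_id, timepoint) = (%s, %s)",
                 rowno[dup[1]], df$patient_id[dup[1]], df$timepoint[dup[1]]))
  df$patient_id <- as.character(df$patient_id)
  df$timepoint <- factor(df$timepoint, levels = hdrs_timepoints())
  df <- df[order(df$patient_id, df$timepoint), , drop = FALSE]
  df$timepoint <- as.character(df$timepoint)
  rownames(df) <- NULL
  class(df) <- c("hdrs_cohort", "data.frame")
  df
}

#' Read a long-format HDRS cohort from CSV
#'
#' The file must contain one row per patient-timepoint with header
#' `patient_id,arm,drug_label,timepoint,item_1,...,item_17` and optionally
#' `age`, `sex`, `race`.  Item scores are validated against the HDRS-17
#' bounds, and duplicate (patient, timepoint) rows are rejected with the
#' offending row number.
#'
#' @param path Path to a CSV file.
#' @return An `hdrs_cohort` data frame (rows ordered by patient then
#'   timepoint) with a `"completeness"` attribute; see
#'   [completeness_report()].
#' @seealso [write_cohort()], [complete_cohort()]
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop(sprintf("cohort file '%s' does not exist", path))
  cc <- c(patient_id = "character", arm = "character",
          drug_label = "character", timepoint = "character",
          sex = "character", race = "character")
  hdr <- names(read.csv(path, nrows = 0))
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = cc[names(cc) %in% hdr])
  co <- validate_cohort(df, file = path)
  attr(co, "completeness") <- completeness_report(co)
  co
}

#' Completeness report for a cohort
#'
#' A patient record is complete when all three timepoints are present; only
#' complete records enter the analysis stages (no imputation is attempted).
#'
#' @param cohort An `hdrs_cohort`.
#' @return Data frame with `patient_id`, `n_timepoints`, `complete`.
#' @export
completeness_report <- function(cohort) {
  tab <- table(cohort$patient_id)
  ids <- names(tab)
  if (is.null(ids)) ids <- character(0)
  data.frame(patient_id = ids,
             n_timepoints = as.integer(tab),
             complete = as.integer(tab) == 3L,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Restrict a cohort to complete records
#'
#' @param cohort An `hdrs_cohort`.
#' @return The cohort restricted to patients observed at all three timepoints.
#' @export
complete_cohort <- function(cohort) {
  rep_ <- completeness_report(cohort)
  keep <- rep_$patient_id[rep_$complete]
  out <- cohort[cohort$patient_id %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("hdrs_cohort", "data.frame")
  out
}

#' Write a cohort in the dialect accepted by [read_cohort()]
#'
#' Rows are emitted deterministically, ordered by patient id and then by
#' timepoint (baseline, week4, week8).
#'
#' @param cohort An `hdrs_cohort` (or compatible data frame).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  co <- validate_cohort(as.data.frame(cohort))
  utils::write.csv(co, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-patient total scores in wide format
#'
#' Computes the HDRS total (sum of the 17 items) at each timepoint for every
#' complete record, carrying the arm and any demographic columns along.
#'
#' @param cohort An `hdrs_cohort`.
#' @return Data frame with one row per complete patient: `patient_id`, `arm`,
#'   `drug_label`, totals `baseline`, `week4`, `week8`, the derived 8-week
#'   `outcome`, plus `age`/`sex`/`race` when present.
#' @export
cohort_totals <- function(cohort) {
  co <- complete_cohort(cohort)
  tot <- rowSums(as.matrix(co[, item_cols()]))
  ids <- sort(unique(co$patient_id))
  wide <- data.frame(patient_id = ids, stringsAsFactors = FALSE)
  first <- co[!duplicated(co$patient_id), , drop = FALSE]
  first <- first[match(ids, first$patient_id), , drop = FALSE]
  wide$arm <- first$arm
  wide$drug_label <- first$drug_label
  for (tp in hdrs_timepoints()) {
    sel <- co$timepoint == tp
    wide[[tp]] <- tot[sel][match(ids, co$patient_id[sel])]
  }
  for (dem in c("age", "sex", "race"))
    if (dem %in% names(co)) wide[[dem]] <- first[[dem]]
  wide$outcome <- classify_outcome(wide$baseline, wide$week8)
  wide
}

#' Item-score matrix at one timepoint
#'
#' @param cohort An `hdrs_cohort`.
#' @param timepoint One of `"baseline"`, `"week4"`, `"week8"`.
#' @return Integer matrix (patients x 17) over complete records, rownames are
#'   patient ids sorted ascending.
#' @export
item_matrix <- function(cohort, timepoint) {
  timepoint <- match.arg(timepoint, hdrs_timepoints())
  co <- complete_cohort(cohort)
  sel <- co[co$timepoint == timepoint, , drop = FALSE]
  sel <- sel[order(sel$patient_id), , drop = FALSE]
  m <- as.matrix(sel[, item_cols()])
  rownames(m) <- sel$patient_id
  m
}

#' @export
print.hdrs_cohort <- function(x, ...) {
  rep_ <- completeness_report(x)
  cat(sprintf("HDRS-17 cohort: %d rows, %d patients (%d complete), arm(s): %s\n",
              nrow(x), nrow(rep_), sum(rep_$complete),
              paste(unique(x$arm), collapse = "/")))
  print(utils::head(as.data.frame(x), 4))
  invisible(x)
}
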