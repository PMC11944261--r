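#' Cohort data frames
#'
#' A cohort is a plain data frame with one row per visual-field exam and
#' the columns `patient_id`, `eye`, `date` (ISO-8601), `age`, `gender`,
#' `race`, `follow_up_years`, `fpr`, `md`, `s1..s52`, `td1..td52`,
#' `pd1..pd52`, and optionally `label` (`"GL"` / `"non-GL"`). Deviation
#' columns may be missing-valued (median-imputed downstream). Helper
#' accessors below extract the numeric blocks as matrices.
#'
#' @param cohort A cohort data frame.
#' @param prefix `"s"`, `"td"` or `"pd"`.
#' @return A numeric matrix with 52 columns in feature order.
#' @export
vf_field_matrix <- function(cohort, prefix = c("td", "pd", "s")) {
  prefix <- match.arg(prefix)
  cols <- paste0(prefix, 1:52)
  if (!all(cols %in% names(cohort))) {
    stop_vf("cohort lacks %s1..%s52 columns", prefix, prefix)
  }
  as.matrix(cohort[, cols])
}

#' Read / write a cohort CSV
#'
#' Comma-separated, UTF-8, header row mandatory, dot decimal, ISO-8601
#' dates.
#'
#' @param path File path.
#' @param cohort Cohort data frame (for writing).
#' @export
vf_read_cohort <- function(path) {
  ch <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "eye", "date", "age", "fpr")
  if (!all(need %in% names(ch))) {
    stop_vf("cohort CSV missing columns: %s",
            paste(setdiff(need, names(ch)), collapse = ", "))
  }
  ch$date <- as.Date(ch$date)
  ch[order(ch$patient_id, ch$date), , drop = FALSE]
}

#' @rdname vf_read_cohort
#' @export
vf_write_cohort <- function(cohort, path) {
  out <- cohort
  if (inherits(out$date, "Date")) out$date <- format(out$date, "%Y-%m-%d")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Reliability filter
#'
#' Excludes exams whose perimetric false-positive rate exceeds `max_fpr`
#' (strictly: an exam exactly at the threshold is retained). Exams with a
#' missing FPR are excluded with a warning.
#'
#' @param cohort Cohort data frame.
#' @param max_fpr Maximum tolerated false-positive rate (default 0.33).
#' @return The filtered cohort; the number of removed exams is reported via
#'   `message()` and stored in the `n_removed` attribute.
#' @export
vf_filter_reliability <- function(cohort, max_fpr = 0.33) {
  stopifnot(max_fpr >= 0, max_fpr <= 1)
  miss <- is.na(cohort$fpr)
  if (any(miss)) {
    warning(sprintf("%d exams with missing FPR excluded", sum(miss)))
  }
  keep <- !miss & cohort$fpr <= max_fpr
  out <- cohort[keep, , drop = FALSE]
  message(sprintf("reliability filter: removed %d of %d exams (FPR > %g)",
                  sum(!keep), nrow(cohort), max_fpr))
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Longitudinal inclusion filter
#'
#' Keeps patients with at least `min_tests` exams on distinct dates and a
#' first-to-last follow-up span of at least `min_follow_up` years
#' (boundary inclusive). All exams of failing patients are removed.
#'
#' @param cohort Cohort data frame.
#' @param min_tests Minimum number of distinct-date exams (default 2).
#' @param min_follow_up Minimum span in years (default 0.5).
#' @return The filtered cohort.
#' @export
vf_filter_longitudinal <- function(cohort, min_tests = 2, min_follow_up = 0.5) {
  dates <- as.Date(cohort$date)
  keep_patient <- vapply(split(dates, cohort$patient_id), function(d) {
    u <- unique(d)
    length(u) >= min_tests &&
      as.numeric(max(u) - min(u)) / 365.25 >= min_follow_up
  }, logical(1))
  out <- cohort[cohort$patient_id %in% names(keep_patient)[keep_patient], ,
                drop = FALSE]
  message(sprintf("longitudinal filter: kept %d of %d patients",
                  sum(keep_patient), length(keep_patient)))
  out
}

#' Severity stage of a mean deviation
#'
#' Stages follow the conventional MD bands: mild (MD > -4.20 dB), moderate
#' (-8.17 < MD <= -4.20) and severe (MD <= -8.17); the three intervals
#' partition the real line.
#'
#' @param md Mean deviation, dB (vectorised; must be finite).
#' @return Character vector of stages.
#' @export
vf_stage_severity <- function(md) {
  if (any(!is.finite(md))) stop_vf("MD must be finite")
  ifelse(md > -4.20, "mild", ifelse(md > -8.17, "moderate", "severe"))
}

#' Patient-level train/test split
#'
#' Deterministic given the seed; the training partition gets
#' `round(n * train_fraction)` ids.
#'
#' @param ids Vector of patient ids (or a single integer n, meaning
#'   `seq_len(n)`).
#' @param train_fraction Fraction in (0, 1); default 0.825.
#' @param seed Integer seed.
#' @return List with elements `train` and `test` (disjoint, exhaustive).
#' @examples
#' sp <- vf_split_train_test(160, 0.825, seed = 1)
#' lengths(sp)  # 132 / 28
#' @export
vf_split_train_test <- function(ids, train_fraction = 0.825, seed = 1) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  if (length(ids) == 1L && is.numeric(ids)) ids <- seq_len(ids)
  n <- length(ids)
  if (n < 2) stop_vf("need at least 2 ids to split")
  n_train <- round(n * train_fraction)
  n_train <- min(max(n_train, 1L), n - 1L)
  train <- with_local_seed(seed, sample(ids, n_train))
  list(train = sort(train), test = sort(setdiff(ids, train)))
}

#' Table-1-style cohort summary
#'
#' Computes patient counts, exam counts, mean (SD) age at baseline, gender
#' and race percentages, median \[IQR\] follow-up, mean (SD) visits per
#' eye, and mean (SD) baseline MD overall and per severity stage.
#'
#' @param cohort Cohort data frame.
#' @return A list of class `vf_cohort_summary`.
#' @export
vf_summarize_cohort <- function(cohort) {
  sd0 <- function(x) if (length(x) < 2) 0 else stats::sd(x)
  by_patient <- split(cohort, cohort$patient_id)
  baseline <- do.call(rbind, lapply(by_patient, function(d) {
    d[order(as.Date(d$date)), , drop = FALSE][1, , drop = FALSE]
  }))
  eye_visits <- as.vector(table(paste(cohort$patient_id, cohort$eye)))
  fup <- vapply(by_patient, function(d) {
    dd <- as.Date(d$date)
    as.numeric(max(dd) - min(dd)) / 365.25
  }, numeric(1))
  pct <- function(x) {
    t <- table(x)
    100 * as.vector(t) / sum(t) -> p
    stats::setNames(p, names(t))
  }
  md <- baseline$md
  stage <- vf_stage_severity(md)
  md_by_stage <- lapply(split(md, factor(stage, c("mild", "moderate", "severe"))),
                        function(v) c(mean = mean(v), sd = sd0(v)))
  out <- list(
    n_patients = length(by_patient),
    n_exams = nrow(cohort),
    age_mean = mean(baseline$age), age_sd = sd0(baseline$age),
    gender_pct = pct(baseline$gender),
    race_pct = pct(baseline$race),
    follow_up_median = stats::median(fup),
    follow_up_iqr = unname(stats::quantile(fup, c(0.25, 0.75))),
    visits_per_eye_mean = mean(eye_visits),
    visits_per_eye_sd = sd0(eye_visits),
    md_mean = mean(md), md_sd = sd0(md),
    md_by_stage = md_by_stage,
    stage_pct = pct(stage)
  )
  class(out) <- "vf_cohort_summary"
  out
}

#' @export
print.vf_cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort: %d patients, %d exams\n", x$n_patients, x$n_exams))
  cat(sprintf("Age at baseline, years, mean (SD): %.2f (%.2f)\n",
              x$age_mean, x$age_sd))
  cat("Gender, %:", paste(sprintf("%s %.1f", names(x$gender_pct),
                                  x$gender_pct), collapse = ", "), "\n")
  cat("Race, %:", paste(sprintf("%s %.1f", names(x$race_pct), x$race_pct),
                        collapse = ", "), "\n")
  cat(sprintf("Follow-up, years, median [IQR]: %.2f [%.2f, %.2f]\n",
              x$follow_up_median, x$follow_up_iqr[1], x$follow_up_iqr[2]))
  cat(sprintf("Visits per eye, mean (SD): %.2f (%.2f)\n",
              x$visits_per_eye_mean, x$visits_per_eye_sd))
  cat(sprintf("MD at baseline, dB, mean (SD): %.2f (%.2f)\n", x$md_mean, x$md_sd))
  for (s in names(x$md_by_stage)) {
    v <- x$md_by_stage[[s]]
    if (!is.na(v["mean"])) {
      cat(sprintf("  %s: %.2f (%.2f)\n", s, v["mean"], v["sd"]))
    }
  }
  invisible(x)
}
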