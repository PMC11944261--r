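#' Synthetic normative reference for 24-2 deviation analysis
#'
#' Builds a normative reference describing, for each of the 52 test
#' locations, the age-expected normal sensitivity (linear age model) and
#' the percentile cutoffs that turn total-deviation (TD) and
#' pattern-deviation (PD) values into probability-map categories.
#'
#' The reference is synthetic: expected sensitivity declines linearly with
#' eccentricity and with age, and between-subject variability grows with
#' eccentricity. TD cutoffs are Gaussian quantiles of the per-location
#' spread. PD cutoffs cannot be scaled TD cutoffs: subtracting the general
#' height shifts normal PD values negative, so PD limits are estimated as
#' empirical per-location quantiles of PD computed over Monte Carlo normal
#' fields (fixed internal seed), exactly as perimetric normative databases
#' derive them from normal cohorts. This preserves the structure of a
#' normative database (which is proprietary) without claiming its exact
#' values; a user-supplied reference can be loaded with
#' [vf_read_normative()].
#'
#' A normal-field pattern-standard-deviation (PSD) 95th percentile is
#' estimated from the same Monte Carlo draw and stored for criteria that
#' test PSD abnormality.
#'
#' @param grid A [vf_grid()] object (defaults to the OD grid).
#' @param reference_age Age (years) at which intercepts are quoted.
#' @param age_slope Sensitivity change per year, dB/year; must be <= 0.
#' @param intercept_fovea Expected sensitivity at fixation at the
#'   reference age, dB.
#' @param ecc_slope Sensitivity change per degree of eccentricity, dB/deg.
#' @param sd_center Between-subject SD at fixation, dB.
#' @param sd_ecc_slope SD increase per degree of eccentricity, dB/deg.
#' @param n_sim Monte Carlo normal fields used for the PD cutoffs and the
#'   PSD percentile (default 8000).
#' @param gh_rank Order statistic used for the general height (default 7,
#'   about the 85th percentile of 52 locations).
#' @param age_range Ages (years) over which the linear model is considered
#'   fitted; outside it the boundary value is used with a warning.
#' @return Object of class `vf_normative`: list with `table` (per-location
#'   intercept, slope and the 4 TD + 4 PD cutoffs), `gh_rank`, `age_range`,
#'   `psd_p95`, `levels`.
#' @examples
#' norm <- vf_normative()
#' head(norm$table)
#' @export
vf_normative <- function(grid = vf_grid("OD"),
                         reference_age = 45,
                         age_slope = -0.065,
                         intercept_fovea = 34,
                         ecc_slope = -0.1,
                         sd_center = 1.4,
                         sd_ecc_slope = 0.03,
                         n_sim = 8000,
                         gh_rank = 7,
                         age_range = c(18, 100)) {
  stopifnot(inherits(grid, "vf_grid"), age_slope <= 0, sd_center > 0,
            gh_rank >= 1, gh_rank <= 52, n_sim >= 1000)
  test <- grid[!grid$is_blind_spot, ]
  test <- test[order(test$feature_index), ]
  ecc <- sqrt(test$x^2 + test$y^2)
  sd_loc <- sd_center + sd_ecc_slope * ecc
  p_levels <- c(0.05, 0.02, 0.01, 0.005)
  td_cut <- outer(sd_loc, stats::qnorm(p_levels))     # negative, 52 x 4

  # Monte Carlo normal cohort: PD quantiles and the normal PSD percentile.
  mc <- with_local_seed(181063, {
    td_sim <- matrix(stats::rnorm(n_sim * 52, 0, rep(sd_loc, each = n_sim)),
                     n_sim, 52)
    pd_sim <- vf_pattern_deviation(td_sim, gh_rank)
    list(pd_cut = t(apply(pd_sim, 2, stats::quantile, probs = p_levels,
                          names = FALSE)),
         psd_p95 = as.numeric(stats::quantile(apply(td_sim, 1, vf_psd), 0.95)))
  })
  pd_cut <- mc$pd_cut
  # empirical quantiles can tie in the extreme tail; enforce strict order
  for (j in 2:4) {
    pd_cut[, j] <- pmin(pd_cut[, j], pd_cut[, j - 1] - 1e-6)
  }

  tab <- data.frame(
    feature = test$feature_index,
    x = test$x, y = test$y,
    intercept = intercept_fovea + ecc_slope * ecc,
    slope = rep(age_slope, nrow(test)),
    sd = sd_loc,
    td_p5 = td_cut[, 1], td_p2 = td_cut[, 2],
    td_p1 = td_cut[, 3], td_p05 = td_cut[, 4],
    pd_p5 = pd_cut[, 1], pd_p2 = pd_cut[, 2],
    pd_p1 = pd_cut[, 3], pd_p05 = pd_cut[, 4]
  )

  structure(
    list(table = tab, gh_rank = gh_rank, reference_age = reference_age,
         age_range = age_range, psd_p95 = mc$psd_p95,
         levels = c("normal", "p<5%", "p<2%", "p<1%", "p<0.5%")),
    class = "vf_normative"
  )
}

#' @export
print.vf_normative <- function(x, ...) {
  cat(sprintf(
    "vf_normative: 52 locations, slope %.3f dB/y, GH rank %d, PSD p95 %.2f dB\n",
    x$table$slope[1], x$gh_rank, x$psd_p95))
  invisible(x)
}

#' Read / write a normative reference as a plain-text table
#'
#' The serialized form is the per-location CSV schema of
#' `vf_normative()$table` plus header metadata rows are not used; `gh_rank`
#' and `age_range` travel as extra columns repeated per row.
#'
#' @param path File path.
#' @param norm A `vf_normative` object (for writing).
#' @return `vf_read_normative()` returns a `vf_normative` object.
#' @export
vf_write_normative <- function(norm, path) {
  stopifnot(inherits(norm, "vf_normative"))
  tab <- norm$table
  tab$gh_rank <- norm$gh_rank
  tab$reference_age <- norm$reference_age
  tab$age_min <- norm$age_range[1]
  tab$age_max <- norm$age_range[2]
  tab$psd_p95 <- norm$psd_p95
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' @rdname vf_write_normative
#' @export
vf_read_normative <- function(path) {
  tab <- utils::read.csv(path)
  need <- c("feature", "intercept", "slope", "td_p5", "td_p2", "td_p1",
            "td_p05", "pd_p5", "pd_p2", "pd_p1", "pd_p05")
  if (!all(need %in% names(tab))) {
    stop_vf("normative table missing columns: %s",
            paste(setdiff(need, names(tab)), collapse = ", "))
  }
  ok <- tab$td_p05 < tab$td_p1 & tab$td_p1 < tab$td_p2 &
    tab$td_p2 < tab$td_p5 & tab$td_p5 < 0 &
    tab$pd_p05 < tab$pd_p1 & tab$pd_p1 < tab$pd_p2 &
    tab$pd_p2 < tab$pd_p5 & tab$pd_p5 < 0
  if (!all(ok)) stop_vf("deviation cutoffs must be strictly ordered and negative")
  norm <- structure(
    list(table = tab[order(tab$feature),
                     setdiff(names(tab), c("gh_rank", "reference_age",
                                           "age_min", "age_max", "psd_p95"))],
         gh_rank = tab$gh_rank[1] %||% 7,
         reference_age = tab$reference_age[1] %||% 45,
         age_range = c(tab$age_min[1] %||% 18, tab$age_max[1] %||% 100),
         psd_p95 = tab$psd_p95[1] %||% NA_real_,
         levels = c("normal", "p<5%", "p<2%", "p<1%", "p<0.5%")),
    class = "vf_normative")
  norm
}

# Age-expected sensitivity per location (vector of 52), clamped to the
# fitted age range with a warning outside it.
expected_sensitivity <- function(norm, age) {
  stopifnot(inherits(norm, "vf_normative"), is.finite(age))
  rng <- norm$age_range
  if (age < rng[1] || age > rng[2]) {
    warning(sprintf("age %.1f outside fitted range [%g, %g]; using boundary",
                    age, rng[1], rng[2]))
    age <- min(max(age, rng[1]), rng[2])
  }
  norm$table$intercept + norm$table$slope * (age - norm$reference_age)
}

#' Total deviation of a visual field exam
#'
#' TD at each location is the measured sensitivity minus the age-expected
#' normal sensitivity from the normative reference.
#'
#' @param sensitivities Numeric vector of 52 sensitivities (dB, >= 0) in
#'   feature order, or a matrix with 52 columns (one row per exam).
#' @param age Age in years (scalar, or one per row for matrix input).
#' @param norm A [vf_normative()] object.
#' @return TD values, same shape as `sensitivities`.
#' @export
vf_total_deviation <- function(sensitivities, age, norm) {
  if (is.matrix(sensitivities)) {
    stopifnot(ncol(sensitivities) == 52, length(age) %in% c(1L, nrow(sensitivities)))
    age <- rep_len(age, nrow(sensitivities))
    exp_mat <- t(vapply(age, function(a) expected_sensitivity(norm, a),
                        numeric(52)))
    return(sensitivities - exp_mat)
  }
  if (length(sensitivities) != 52) stop_vf("expected 52 sensitivities")
  if (anyNA(sensitivities)) stop_vf("missing sensitivities; impute first")
  sensitivities - expected_sensitivity(norm, age)
}

#' General height of a total-deviation field
#'
#' The rank-th highest TD value; with the default rank 7 this is roughly
#' the 85th percentile of the 52 locations and captures diffuse loss.
#'
#' @param td Numeric vector of 52 TD values (dB).
#' @param rank Order statistic from the top, in 1..52.
#' @return General height, dB.
#' @export
vf_general_height <- function(td, rank = 7) {
  stopifnot(rank >= 1, rank <= length(td))
  sort(td, decreasing = TRUE)[rank]
}

#' Pattern deviation of a total-deviation field
#'
#' PD is TD minus the general height, isolating focal from diffuse loss.
#'
#' @param td Numeric vector of 52 TD values, or matrix with 52 columns.
#' @param rank General-height rank (default 7).
#' @return PD values, same shape as `td`.
#' @export
vf_pattern_deviation <- function(td, rank = 7) {
  if (is.matrix(td)) {
    gh <- apply(td, 1, vf_general_height, rank = rank)
    return(td - gh)
  }
  td - vf_general_height(td, rank)
}

#' Probability map of a deviation field
#'
#' Assigns each deviation the most extreme normative percentile category
#' whose cutoff it falls below; values at or above the 5% cutoff are
#' "normal". Categories are returned as integer codes 0 (normal), 1
#' (p<5%), 2 (p<2%), 3 (p<1%), 4 (p<0.5%); `vf_prob_levels()` gives the
#' labels.
#'
#' @param dev Numeric vector of 52 deviations, or matrix with 52 columns.
#' @param norm A [vf_normative()] object.
#' @param kind `"TD"` or `"PD"` — which cutoff family to use.
#' @return Integer codes, same shape as `dev`.
#' @export
vf_probability_map <- function(dev, norm, kind = c("TD", "PD")) {
  kind <- match.arg(kind)
  cols <- if (kind == "TD") c("td_p5", "td_p2", "td_p1", "td_p05") else
    c("pd_p5", "pd_p2", "pd_p1", "pd_p05")
  cuts <- as.matrix(norm$table[, cols])   # 52 x 4, decreasing across cols
  code_one <- function(v) {
    stopifnot(length(v) == 52)
    unname(rowSums(v < cuts))   # number of cutoffs the value falls below
  }
  if (is.matrix(dev)) {
    out <- t(apply(dev, 1, code_one))
    dimnames(out) <- dimnames(dev)
    return(out)
  }
  code_one(dev)
}

#' @rdname vf_probability_map
#' @export
vf_prob_levels <- function() c("normal", "p<5%", "p<2%", "p<1%", "p<0.5%")

#' Mean deviation of a field
#'
#' Weighted mean of the 52 TD values. The default is unweighted: the
#' instrument's proprietary variance weights are not published.
#'
#' @param td Numeric vector of 52 TD values.
#' @param weights Optional per-location weights.
#' @return Mean deviation, dB.
#' @export
vf_mean_deviation <- function(td, weights = NULL) {
  if (is.null(weights)) return(mean(td))
  stopifnot(length(weights) == length(td), all(weights >= 0))
  sum(td * weights) / sum(weights)
}

#' Pattern standard deviation (simplified)
#'
#' Unweighted standard deviation of TD about its mean, a dispersion
#' summary of localized loss. Uses the population (1/n) form so a
#' two-point field matches the half-range exactly.
#'
#' @param td Numeric vector of TD values.
#' @return PSD, dB.
#' @export
vf_psd <- function(td) {
  sqrt(mean((td - mean(td))^2))
}

#' Median imputation of missing values by column
#'
#' @param x Matrix or data frame of numeric columns; `NA` cells are filled
#'   with the column median (columns that are all-`NA` are left untouched).
#' @return Same shape as `x`.
#' @export
vf_impute_median <- function(x) {
  is_df <- is.data.frame(x)
  m <- as.matrix(x)
  for (j in seq_len(ncol(m))) {
    nas <- is.na(m[, j])
    if (any(nas) && !all(nas)) m[nas, j] <- stats::median(m[, j], na.rm = TRUE)
  }
  if (is_df) as.data.frame(m) else m
}
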