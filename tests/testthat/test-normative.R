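test_that("normative cutoffs are strictly ordered and negative everywhere", {
  tab <- fix_norm$table
  expect_true(all(tab$td_p05 < tab$td_p1))
  expect_true(all(tab$td_p1 < tab$td_p2))
  expect_true(all(tab$td_p2 < tab$td_p5))
  expect_true(all(tab$td_p5 < 0))
  expect_true(all(tab$pd_p05 < tab$pd_p1))
  expect_true(all(tab$pd_p1 < tab$pd_p2))
  expect_true(all(tab$pd_p2 < tab$pd_p5))
  expect_true(all(tab$pd_p5 < 0))
  expect_true(all(tab$slope <= 0))
})

test_that("total deviation is sensitivity minus the age-expected normal", {
  norm <- fix_norm
  expected <- norm$table$intercept + norm$table$slope * (60 - norm$reference_age)
  expect_equal(vf_total_deviation(expected, 60, norm), rep(0, 52))
  expect_equal(vf_total_deviation(expected - 5, 60, norm), rep(-5, 52))
  # generator stores ground truth; TD recovers it to machine precision
  ex <- vf_simulate_exam(71.3, 12 * fix_masks$IN_arcuate, 2, norm, seed = 5)
  expect_equal(vf_total_deviation(ex$sensitivities, 71.3, norm),
               ex$true_deviation, tolerance = 1e-12)
  expect_warning(vf_total_deviation(expected, 110, norm), "outside")
  expect_error(vf_total_deviation(c(NA, expected[-1]), 60, norm), "missing")
})

test_that("general height is the configured order statistic", {
  expect_equal(vf_general_height(rep(-3.2, 52)), -3.2)
  expect_equal(vf_general_height(52:1, rank = 7), 46)
  set.seed(1)
  td <- rnorm(52)
  expect_true(vf_general_height(td) %in% td)
})

test_that("pattern deviation removes diffuse loss and preserves shape", {
  expect_equal(vf_pattern_deviation(rep(-5, 52)), rep(0, 52))
  td <- rep(0, 52); td[10] <- -20
  pd <- vf_pattern_deviation(td)
  expect_equal(pd[10], -20)
  expect_equal(pd[-10], rep(0, 51))
  set.seed(2)
  td <- rnorm(52)
  expect_equal(sort(vf_pattern_deviation(td)),
               sort(td) - vf_general_height(td))
})

test_that("probability maps agree with a linear-scan oracle and are monotone", {
  norm <- fix_norm
  expect_equal(vf_probability_map(rep(0, 52), norm, "TD"), rep(0L, 52))
  # boundary: just below the most extreme cutoff
  dev <- rep(0, 52)
  dev[3] <- norm$table$td_p05[3] - 1e-9
  expect_equal(vf_probability_map(dev, norm, "TD")[3], 4)
  set.seed(3)
  for (kind in c("TD", "PD")) {
    cols <- if (kind == "TD") c("td_p5", "td_p2", "td_p1", "td_p05")
    else c("pd_p5", "pd_p2", "pd_p1", "pd_p05")
    for (r in 1:20) {
      dev <- rnorm(52, -3, 4)
      got <- vf_probability_map(dev, norm, kind)
      want <- vapply(1:52, function(i)
        oracle_prob_code(dev[i], as.numeric(norm$table[i, cols])), 0L)
      expect_equal(got, want)
    }
  }
  # monotonicity: deepening a deviation never moves toward normal
  set.seed(4)
  dev <- rnorm(52, -2, 3)
  base <- vf_probability_map(dev, norm, "TD")
  deeper <- vf_probability_map(dev - runif(52, 0, 5), norm, "TD")
  expect_true(all(deeper >= base))
})

test_that("MD and PSD behave as summary statistics", {
  expect_equal(vf_mean_deviation(rep(-5, 52)), -5)
  expect_equal(vf_mean_deviation(rep(0, 52)), 0)
  set.seed(5)
  td <- rnorm(52)
  bumped <- td; bumped[17] <- bumped[17] + 1
  expect_gt(vf_mean_deviation(bumped), vf_mean_deviation(td))
  w <- runif(52)
  expect_equal(vf_mean_deviation(td, w), sum(td * w) / sum(w))

  expect_equal(vf_psd(rep(-7, 52)), 0)
  expect_equal(vf_psd(td + 3), vf_psd(td))
  expect_equal(vf_psd(td), sqrt(mean((td - mean(td))^2)))
})

test_that("deviation pipeline round-trips back to sensitivities", {
  norm <- fix_norm
  ex <- vf_simulate_exam(58, 9 * fix_masks$paracentral, 1.5, norm, seed = 11)
  td <- vf_total_deviation(ex$sensitivities, 58, norm)
  pd <- vf_pattern_deviation(td, norm$gh_rank)
  gh <- vf_general_height(td, norm$gh_rank)
  expected <- norm$table$intercept + norm$table$slope * (58 - norm$reference_age)
  expect_equal(pd + gh + expected, ex$sensitivities, tolerance = 1e-12)
})

test_that("normative references survive a plain-text round trip", {
  path <- withr::local_tempfile(fileext = ".csv")
  vf_write_normative(fix_norm, path)
  back <- vf_read_normative(path)
  expect_equal(back$table$td_p5, fix_norm$table$td_p5)
  expect_equal(back$gh_rank, fix_norm$gh_rank)
  ex <- vf_simulate_exam(66, 14 * fix_masks$ST_arcuate, 1, fix_norm, seed = 3)
  expect_equal(vf_probability_map(ex$pd, back, "PD"),
               vf_probability_map(ex$pd, fix_norm, "PD"))
})

test_that("median imputation fills by column", {
  m <- matrix(c(1, 2, NA, 10, NA, 30), ncol = 2)
  out <- vf_impute_median(m)
  expect_equal(out[3, 1], 1.5)
  expect_equal(out[2, 2], 20)
  expect_false(anyNA(out))
})
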