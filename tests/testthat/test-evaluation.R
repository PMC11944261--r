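test_that("confusion counting agrees with a direct recount", {
  cm <- vf_confusion(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(c(cm$fp, cm$fn), c(0, 0))
  cm2 <- vf_confusion(rep(0, 5), rep(1, 5))
  expect_equal(c(cm2$tp, cm2$tn), c(0, 0))
  set.seed(1)
  for (r in 1:20) {
    y <- rbinom(30, 1, 0.4); p <- rbinom(30, 1, 0.6)
    cm <- vf_confusion(y, p)
    expect_equal(cm$tp, sum(y & p))
    expect_equal(cm$tn, sum(!y & !p))
    expect_equal(cm$n, 30)
  }
  expect_equal(vf_confusion(c("GL", "non-GL"), c("GL", "GL"))$fp, 1)
  expect_error(vf_confusion(1:3, 1:4), "length")
})

test_that("metrics reproduce the standard arithmetic and stay undefined at 0/0", {
  m <- vf_metrics_from_confusion(vf_confusion_counts(10, 1, 2, 15))
  expect_equal(m$accuracy, 25 / 28)
  expect_equal(m$precision, 10 / 11)
  expect_equal(m$sensitivity, 10 / 12)
  expect_equal(m$f_score, 20 / 23)
  deg <- vf_metrics_from_confusion(vf_confusion_counts(0, 0, 0, 5))
  expect_equal(deg$accuracy, 1)
  expect_true(is.na(deg$precision))
  expect_error(vf_metrics_from_confusion(vf_confusion_counts(0, 0, 0, 0)),
               "empty")
})

test_that("rank-based AUC equals the pairwise probability oracle", {
  r <- vf_roc_auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))
  expect_equal(r$auc, 1)
  set.seed(2)
  for (n in c(5, 20, 87, 200)) {
    y <- c(1, 0, rbinom(n - 2, 1, 0.5))
    p <- round(runif(n), 2)         # rounding forces ties
    expect_equal(vf_roc_auc(y, p)$auc, oracle_auc(y, p))
  }
  # chance level on independent labels
  y <- rbinom(4000, 1, 0.5); p <- runif(4000)
  expect_equal(vf_roc_auc(y, p)$auc, 0.5, tolerance = 0.05)
  # third route: an established ROC implementation agrees
  y2 <- rbinom(60, 1, 0.5); y2[1:2] <- c(0, 1)
  p2 <- round(runif(60), 1)
  expect_equal(vf_roc_auc(y2, p2)$auc,
               as.numeric(pROC::auc(pROC::roc(y2, p2, quiet = TRUE,
                                              direction = "<"))))
  expect_error(vf_roc_auc(rep(1, 5), runif(5)), "both classes")
  # curve is a valid staircase from (0,0) to (1,1)
  cr <- vf_roc_auc(c(0, 1, 0, 1, 1), c(0.2, 0.3, 0.3, 0.8, 0.9))$curve
  expect_equal(cr$fpr[1], 0)
  expect_equal(cr$tpr[nrow(cr)], 1)
  expect_true(all(diff(cr$fpr) >= 0) && all(diff(cr$tpr) >= 0))
})

test_that("prediction entropy has the binary-entropy shape", {
  expect_equal(vf_prediction_entropy(0), 0)
  expect_equal(vf_prediction_entropy(1), 0)
  expect_equal(vf_prediction_entropy(0.5), log(2))
  p <- seq(0, 1, by = 0.01)
  H <- vf_prediction_entropy(p)
  expect_equal(H, vf_prediction_entropy(1 - p))
  expect_true(all(H >= 0 & H <= log(2) + 1e-12))
  expect_equal(which.max(H), 51)   # p = 0.5
  expect_error(vf_prediction_entropy(1.2), "0, 1")
})

test_that("Tukey fences flag gross outliers and respect affine maps", {
  expect_false(any(vf_iqr_outlier_mask(rep(3, 10))))
  v <- c(1:99, 1000)
  expect_equal(which(vf_iqr_outlier_mask(v)), 100L)
  set.seed(3)
  x <- rnorm(50)
  expect_equal(vf_iqr_outlier_mask(3 * x - 7), vf_iqr_outlier_mask(x))
  expect_error(vf_iqr_outlier_mask(1:3), "at least 4")
})

test_that("the paired Wilcoxon comparison behaves under null and shift", {
  a <- rnorm(20)
  same <- vf_compare_wilcoxon(a, a)
  expect_true(is.na(same$p_value))
  expect_false(same$significant)
  set.seed(4)
  x <- rnorm(15)
  shifted <- vf_compare_wilcoxon(x, x + 5)
  expect_lt(shifted$p_value, 0.05)
  expect_true(shifted$significant)
  mixed <- vf_compare_wilcoxon(x, x + rnorm(15, 0, 0.001))
  expect_true(mixed$p_value >= 0 && mixed$p_value <= 1)
})

test_that("permutation importance isolates informative features", {
  set.seed(5)
  X <- matrix(rnorm(300 * 4), 300, 4,
              dimnames = list(NULL, c("td1", "td2", "td30", "age")))
  y <- as.integer(X[, "td30"] > 0)
  predict_fun <- function(M) as.integer(M[, "td30"] > 0)   # uses one feature
  imp <- vf_permutation_importance(predict_fun, X, y, n_repeats = 5, seed = 6)
  expect_equal(imp$feature[1], "td30")
  ignored <- imp$importance[imp$feature != "td30"]
  expect_true(all(abs(ignored) < 0.02))
  imp2 <- vf_permutation_importance(predict_fun, X, y, n_repeats = 5, seed = 6)
  expect_identical(imp, imp2)
  expect_error(vf_permutation_importance(predict_fun, X, y, n_repeats = 0),
               ">= 1")
  # sector roll-up via the grid's structure-function map
  sec <- vf_sector_importance(imp, fix_grid)
  expect_true(all(sec$sector %in% c("ST", "SN", "IT", "IN")))
  expect_equal(sec$sector[1], vf_sector(fix_grid,
                                        vf_location_of_feature(fix_grid, 30)))
})
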