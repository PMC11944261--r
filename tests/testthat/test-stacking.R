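# A small labelled cohort with learnable structure, shared by the
# stacking tests (built once).
stk <- local({
  cfg <- vf_sim_config(n_patients = 120, exams_per_patient = 1,
                       prevalence = 0.5, noise_sd = 1.5, seed = 404)
  sim <- vf_simulate_cohort(cfg, fix_grid, fix_norm)
  crit <- vf_run_all_criteria(sim$cohort, grid = fix_grid, norm = fix_norm)
  key <- paste(sim$cohort$patient_id, sim$cohort$eye, sep = "|")
  ck <- paste(crit$labels$patient_id, crit$labels$eye, sep = "|")
  list(cohort = sim$cohort, truth = sim$truth,
       crit = crit$labels[match(key, ck), names(vf_default_criteria())])
})

test_that("base features are 56-dimensional and standardized on train stats", {
  prep <- vf_feature_prep(stk$cohort)
  X <- vf_base_features(prep, stk$cohort, "TD")
  expect_equal(ncol(X), 56)
  expect_equal(nrow(X), nrow(stk$cohort))
  expect_true(all(is.finite(X)))
  expect_equal(mean(X[, 1]), 0, tolerance = 1e-10)
  expect_equal(sd(X[, 53]), 1, tolerance = 1e-10)   # age column
  # categorical encodings are explicit, persistent integer codes
  expect_true(all(X[, 54] %in% (seq_along(prep$gender) - 1)))
  # missing deviation cells are median-imputed from the prep
  ch <- stk$cohort
  ch$td7[3] <- NA
  X2 <- vf_base_features(prep, ch, "TD")
  expect_true(is.finite(X2[3, 7]))
})

test_that("base training is deterministic and reports early stopping", {
  b1 <- vf_train_base(stk$cohort, stk$crit, seed = 5, epochs = 6)
  b2 <- vf_train_base(stk$cohort, stk$crit, seed = 5, epochs = 6)
  expect_identical(b1$TD$net, b2$TD$net)
  expect_identical(b1$PD$net, b2$PD$net)
  expect_equal(b1$TD$heads, c("LoGTS", "UKGTS", "Kang"))
  expect_equal(b1$PD$heads, c("HAP2_p1", "Foster"))
  expect_true(b1$TD$stopped_epoch <= 6)
  # penultimate layer is 64 wide so meta-features land on 132
  expect_equal(ncol(b1$TD$net$layers[[2]]$W), 64)
})

test_that("meta-features are 132-dimensional with the documented provenance", {
  bundle <- vf_train_base(stk$cohort, stk$crit, seed = 5, epochs = 4)
  meta <- vf_extract_meta(bundle, stk$cohort)
  expect_equal(ncol(meta), 132)
  expect_equal(nrow(meta), nrow(stk$cohort))
  # identical exams give identical meta-features
  two <- stk$cohort[c(1, 1), ]
  m2 <- vf_extract_meta(bundle, two)
  expect_equal(m2[1, ], m2[2, ])
  # clinical tail is on the raw scale
  expect_equal(unname(meta[, 129]), stk$cohort$age)
  # zero output-layer weights zero the first 128 meta-features
  zb <- bundle
  zb$TD$net$layers[[3]]$W[] <- 0
  zb$PD$net$layers[[3]]$W[] <- 0
  mz <- vf_extract_meta(zb, stk$cohort[1:3, ])
  expect_true(all(mz[, 1:128] == 0))
  expect_false(all(mz[, 129:132] == 0))
  # alternative constructions stay 132-dimensional
  expect_equal(ncol(vf_extract_meta(bundle, stk$cohort[1:3, ],
                                    variant = "activations")), 132)
  expect_equal(ncol(vf_extract_meta(bundle, stk$cohort[1:3, ],
                                    variant = "weights")), 132)
})

test_that("meta-learners train, predict probabilities and separate classes", {
  bundle <- vf_train_base(stk$cohort, stk$crit, seed = 5, epochs = 8)
  meta <- vf_extract_meta(bundle, stk$cohort)
  y <- as.integer(stk$cohort$label == "GL")
  tr <- seq_len(90)
  for (kind in c("lr", "gbt", "mlp")) {
    m <- vf_train_meta(meta[tr, ], y[tr], kind, seed = 2)
    pred <- vf_predict_meta(m, meta[-tr, ])
    expect_true(all(pred$p >= 0 & pred$p <= 1), label = kind)
    expect_gt(mean(pred$p[y[-tr] == 1]), mean(pred$p[y[-tr] == 0]))
    # determinism
    m2 <- vf_train_meta(meta[tr, ], y[tr], kind, seed = 2)
    expect_equal(vf_predict_meta(m2, meta[-tr, ])$p, pred$p,
                 tolerance = 1e-12, label = kind)
  }
  expect_error(vf_train_meta(meta[tr, ], rep(1, length(tr)), "lr"),
               "single-class")
})

test_that("thresholding converts probabilities to labels", {
  bundle <- vf_train_base(stk$cohort, stk$crit, seed = 5, epochs = 4)
  meta <- vf_extract_meta(bundle, stk$cohort)
  y <- as.integer(stk$cohort$label == "GL")
  m <- vf_train_meta(meta, y, "lr", seed = 1)
  pred <- vf_predict_meta(m, meta)
  expect_equal(pred$label, ifelse(pred$p > 0.5, "GL", "non-GL"))
  strict <- vf_predict_meta(m, meta, threshold = 0.99)
  expect_lte(sum(strict$label == "GL"), sum(pred$label == "GL"))
})

test_that("gradient boosting scores chance-level on permuted labels", {
  set.seed(71)
  n <- 300
  X <- matrix(rnorm(n * 10), n, 10)
  y <- rbinom(n, 1, 0.5)          # labels independent of features
  tr <- 1:200
  m <- vf_train_meta(X[tr, ], y[tr], "gbt", seed = 3)
  acc <- mean((vf_predict_meta(m, X[-tr, ])$p > 0.5) == (y[-tr] == 1))
  expect_gt(acc, 0.35)
  expect_lt(acc, 0.65)
})

test_that("logistic regression drives accuracy to 1 on separable features", {
  set.seed(72)
  n <- 200
  X <- matrix(rnorm(n * 5), n, 5)
  y <- as.integer(X[, 2] > 0)
  X[, 2] <- X[, 2] + sign(X[, 2]) * 2       # widen the margin
  tr <- 1:140
  m <- vf_train_meta(X[tr, ], y[tr], "lr", seed = 4)
  acc <- mean((vf_predict_meta(m, X[-tr, ])$p > 0.5) == (y[-tr] == 1))
  expect_gt(acc, 0.95)
})

test_that("the hyperparameter grid is searched exhaustively", {
  set.seed(73)
  n <- 50
  X <- matrix(rnorm(n * 4), n, 4)
  y <- as.integer(X[, 1] + 0.3 * rnorm(n) > 0)
  res <- vf_hyperparameter_search(X, y, folds = 5, epochs = 2, seed = 9)
  expect_equal(nrow(res$table), 27)
  expect_equal(res$best$mean_score, max(res$table$mean_score))
  expect_error(vf_hyperparameter_search(X[1:8, ], y[1:8], folds = 5),
               "stratified")
})
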