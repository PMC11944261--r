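#' Feature preparation for the base models
#'
#' Builds, from a training cohort, the categorical encoders (gender, race
#' as 0-based integer codes over the sorted training categories) and the
#' z-score standardisation constants for the 52 deviation values plus the
#' continuous clinical covariates (age, follow-up). The same prep object
#' is then applied to any cohort so train statistics are never recomputed
#' on test data. Missing deviation cells are median-imputed per column
#' (imputation medians also come from the training cohort).
#'
#' @param cohort_train Training cohort data frame.
#' @return A `vf_feature_prep` object.
#' @export
vf_feature_prep <- function(cohort_train) {
  enc <- function(x) {
    lv <- sort(unique(as.character(x)))
    stats::setNames(seq_along(lv) - 1L, lv)
  }
  prep <- list(gender = enc(cohort_train$gender),
               race = enc(cohort_train$race))
  for (kind in c("td", "pd")) {
    m <- vf_field_matrix(cohort_train, kind)
    med <- apply(m, 2, stats::median, na.rm = TRUE)
    for (j in seq_len(ncol(m))) m[is.na(m[, j]), j] <- med[j]
    prep[[kind]] <- list(median = med, mean = colMeans(m),
                         sd = pmax(apply(m, 2, stats::sd), 1e-8))
  }
  prep$age <- c(mean = mean(cohort_train$age), sd = max(stats::sd(cohort_train$age), 1e-8))
  prep$follow_up <- c(mean = mean(cohort_train$follow_up_years),
                      sd = max(stats::sd(cohort_train$follow_up_years), 1e-8))
  structure(prep, class = "vf_feature_prep")
}

encode_cat <- function(codes, x) {
  v <- codes[as.character(x)]
  # unseen categories get the next free code
  v[is.na(v)] <- length(codes)
  unname(v)
}

#' Build the 56-dimensional base feature matrix
#'
#' 52 standardised deviation values (TD or PD) followed by standardised
#' age, encoded gender, encoded race and standardised follow-up time.
#'
#' @param prep A [vf_feature_prep()] object.
#' @param cohort Cohort data frame.
#' @param kind `"TD"` or `"PD"`.
#' @return Numeric matrix, n x 56.
#' @export
vf_base_features <- function(prep, cohort, kind = c("TD", "PD")) {
  kind <- match.arg(kind)
  key <- tolower(kind)
  m <- vf_field_matrix(cohort, key)
  p <- prep[[key]]
  for (j in seq_len(ncol(m))) m[is.na(m[, j]), j] <- p$median[j]
  m <- sweep(sweep(m, 2, p$mean), 2, p$sd, "/")
  clin <- cbind(
    age = (cohort$age - prep$age["mean"]) / prep$age["sd"],
    gender = encode_cat(prep$gender, cohort$gender),
    race = encode_cat(prep$race, cohort$race),
    follow_up = (cohort$follow_up_years - prep$follow_up["mean"]) /
      prep$follow_up["sd"])
  out <- cbind(m, clin)
  if (any(!is.finite(out))) stop_vf("non-finite base features after imputation")
  out
}

# Clinical covariates on their raw scale (for the meta-feature tail).
clinical_raw <- function(prep, cohort) {
  cbind(age = cohort$age,
        gender = encode_cat(prep$gender, cohort$gender),
        race = encode_cat(prep$race, cohort$race),
        follow_up = cohort$follow_up_years)
}

#' Train the two base MLPs
#'
#' One multi-head network per map kind: the TD net's heads are the
#' criteria configured on TD, the PD net's those on PD. Each network is 56
#' inputs, two hidden layers of 128 and 64 sigmoid units (the penultimate
#' width of 64 fixes the meta-feature dimension), one sigmoid output per
#' head, trained with Adam at learning rate 1e-3 for up to 25 epochs with
#' early stopping (patience 3) on a held-back validation fraction.
#'
#' @param cohort_train Training cohort.
#' @param criterion_labels Data frame or matrix with one 0/1 column per
#'   criterion name (rows aligned with `cohort_train`), as produced by
#'   [vf_run_all_criteria()] per eye.
#' @param specs Criterion specs (supplies each criterion's map kind).
#' @param prep A [vf_feature_prep()] (default: built from `cohort_train`).
#' @param seed Integer seed.
#' @param epochs,lr,batch_size,patience,val_fraction Training protocol.
#' @param activation Hidden activation (default `"sigmoid"`, the selected
#'   configuration of the packaged hyperparameter search).
#' @param optimizer `"adam"`, `"sgd"` or `"rmsprop"`.
#' @return A `vf_base_bundle`: list with `prep` and per-kind entries
#'   (`net`, `heads`, `log`, `stopped_epoch`).
#' @export
vf_train_base <- function(cohort_train, criterion_labels,
                          specs = vf_default_criteria(),
                          prep = vf_feature_prep(cohort_train),
                          seed = 1, epochs = 25, lr = 1e-3,
                          batch_size = 32, patience = 3,
                          val_fraction = 0.15,
                          activation = "sigmoid", optimizer = "adam") {
  criterion_labels <- as.matrix(as.data.frame(criterion_labels)[, names(specs),
                                                                drop = FALSE])
  bundle <- list(prep = prep, specs = specs)
  for (kind in c("TD", "PD")) {
    heads <- names(specs)[vapply(specs, function(s) s$map_kind, "") == kind]
    if (length(heads) == 0) next
    X <- vf_base_features(prep, cohort_train, kind)
    Y <- criterion_labels[, heads, drop = FALSE]
    fit <- nn_fit(ncol(X), c(128, 64, length(heads)),
                  c(activation, activation, "sigmoid"),
                  X, Y, epochs = epochs, batch_size = batch_size, lr = lr,
                  optimizer = optimizer, patience = patience,
                  val_fraction = val_fraction,
                  seed = substream_seed(seed, paste0("base-", kind)))
    bundle[[kind]] <- list(net = fit$net, heads = heads, log = fit$log,
                           stopped_epoch = fit$stopped_epoch)
  }
  structure(bundle, class = "vf_base_bundle")
}

#' Extract the 132-dimensional meta-feature vectors
#'
#' For each base network, takes the penultimate-layer activations (64 per
#' sample) weighted elementwise by the network's output-layer weight
#' vector averaged across heads; concatenating TD-net 64 + PD-net 64 + the
#' 4 raw clinical covariates gives 132 values per sample. `variant =
#' "activations"` drops the weighting; `variant = "weights"` uses the
#' weight vector alone (identical across samples) — both retained for
#' comparison with the default weighted construction.
#'
#' @param bundle A [vf_train_base()] bundle.
#' @param cohort Cohort data frame.
#' @param variant `"weighted"` (default), `"activations"` or `"weights"`.
#' @return Numeric matrix, n x 132.
#' @export
vf_extract_meta <- function(bundle, cohort,
                            variant = c("weighted", "activations", "weights")) {
  variant <- match.arg(variant)
  stopifnot(inherits(bundle, "vf_base_bundle"))
  blocks <- list()
  for (kind in c("TD", "PD")) {
    part <- bundle[[kind]]
    if (is.null(part)) stop_vf("bundle lacks a %s network", kind)
    X <- vf_base_features(bundle$prep, cohort, kind)
    A <- nn_penultimate(part$net, X)                       # n x 64
    Wout <- part$net$layers[[length(part$net$layers)]]$W   # 64 x heads
    wbar <- rowMeans(Wout)
    blocks[[kind]] <- switch(variant,
                             weighted = sweep(A, 2, wbar, "*"),
                             activations = A,
                             weights = matrix(wbar, nrow(A), length(wbar),
                                              byrow = TRUE))
    colnames(blocks[[kind]]) <- paste0(tolower(kind), "_w", seq_along(wbar))
  }
  meta <- cbind(blocks$TD, blocks$PD, clinical_raw(bundle$prep, cohort))
  stopifnot(ncol(meta) == 132)
  meta
}

#' Train a meta-learner on meta-features
#'
#' Three kinds: `"lr"` — L2-regularised logistic regression (ridge, C = 1,
#' via glmnet); `"gbt"` — gradient-boosted trees (xgboost, learning rate
#' 0.3, maximum depth 6, 25 rounds, tree booster); `"mlp"` — a 128/64/1
#' network with batch normalisation and ReLU between hidden layers,
#' dropout 0.08, Adam with learning rate 0.0031 and weight decay 1e-3,
#' batch size 32, 25 epochs. Meta-features are standardised with training
#' statistics for the lr and mlp kinds.
#'
#' @param meta Meta-feature matrix (training rows).
#' @param labels Binary clinical labels (0/1 or `"GL"`/`"non-GL"`).
#' @param kind `"lr"`, `"gbt"` or `"mlp"`.
#' @param seed Integer seed.
#' @param C Inverse regularisation strength for `"lr"`.
#' @param epochs,lr,batch_size,dropout,weight_decay MLP protocol.
#' @return A `vf_meta_model`.
#' @export
vf_train_meta <- function(meta, labels, kind = c("lr", "gbt", "mlp"),
                          seed = 1, C = 1.0, epochs = 25, lr = 0.0031,
                          batch_size = 32, dropout = 0.08,
                          weight_decay = 1e-3) {
  kind <- match.arg(kind)
  y <- as_binary_label(labels)
  if (length(unique(y)) < 2) stop_vf("training labels are single-class")
  model <- list(kind = kind)
  if (kind %in% c("lr", "mlp")) {
    model$center <- colMeans(meta)
    model$scale <- pmax(apply(meta, 2, stats::sd), 1e-8)
    Xs <- sweep(sweep(meta, 2, model$center), 2, model$scale, "/")
  }
  if (kind == "lr") {
    model$fit <- glmnet::glmnet(Xs, y, family = "binomial", alpha = 0,
                                lambda = 1 / (C * nrow(meta)),
                                standardize = FALSE)
  } else if (kind == "gbt") {
    dtrain <- xgboost::xgb.DMatrix(meta, label = y)
    params <- list(objective = "binary:logistic", eta = 0.3, max_depth = 6,
                   booster = "gbtree", nthread = 1,
                   seed = substream_seed(seed, "meta-gbt"))
    model$fit <- xgboost::xgb.train(params = params, data = dtrain,
                                    nrounds = 25, verbose = 0)
  } else {
    fit <- nn_fit(ncol(meta), c(128, 64, 1), c("relu", "relu", "sigmoid"),
                  Xs, matrix(y, ncol = 1),
                  batchnorm = c(TRUE, TRUE, FALSE),
                  dropout = c(dropout, dropout, 0),
                  epochs = epochs, batch_size = batch_size, lr = lr,
                  optimizer = "adam", weight_decay = weight_decay,
                  patience = Inf,
                  seed = substream_seed(seed, "meta-mlp"))
    model$fit <- fit$net
    model$log <- fit$log
  }
  structure(model, class = "vf_meta_model")
}

as_binary_label <- function(labels) {
  if (is.numeric(labels)) return(as.integer(labels > 0))
  as.integer(as.character(labels) %in% c("GL", "1", "TRUE", "glaucoma"))
}

#' Predict glaucoma probability from a meta-learner
#'
#' @param model A [vf_train_meta()] model.
#' @param meta Meta-feature matrix.
#' @param threshold Decision threshold on the GL probability (default 0.5).
#' @return Data frame with columns `p` (probability of GL, in \[0, 1\])
#'   and `label` (`"GL"` / `"non-GL"`).
#' @export
vf_predict_meta <- function(model, meta, threshold = 0.5) {
  stopifnot(inherits(model, "vf_meta_model"))
  if (is.null(model$fit)) stop_vf("meta model is untrained")
  p <- switch(model$kind,
              lr = {
                Xs <- sweep(sweep(meta, 2, model$center), 2, model$scale, "/")
                as.numeric(stats::predict(model$fit, Xs, type = "response"))
              },
              gbt = as.numeric(stats::predict(model$fit,
                                              xgboost::xgb.DMatrix(meta))),
              mlp = {
                Xs <- sweep(sweep(meta, 2, model$center), 2, model$scale, "/")
                as.numeric(nn_predict(model$fit, Xs))
              })
  p <- pmin(pmax(p, 0), 1)
  data.frame(p = p, label = ifelse(p > threshold, "GL", "non-GL"))
}

#' Grid search over base-model hyperparameters
#'
#' Exhaustive search over activation x learning rate x optimizer with
#' stratified k-fold cross-validation of a single-head base network,
#' scored by mean validation accuracy. Ties are broken in favour of
#' (sigmoid, 1e-3, adam), then first-seen order.
#'
#' @param X Feature matrix.
#' @param y Binary labels.
#' @param activations,learning_rates,optimizers The search grid (defaults:
#'   softmax/ReLU/sigmoid; 1e-2, 1e-3, 1e-5; SGD/RMSprop/Adam).
#' @param folds Number of CV folds (default 5).
#' @param epochs Training epochs per fit (default 25).
#' @param seed Integer seed.
#' @return List with `best` (named list activation/lr/optimizer) and
#'   `table` (the full score table, one row per configuration).
#' @export
vf_hyperparameter_search <- function(X, y,
                                     activations = c("softmax", "relu", "sigmoid"),
                                     learning_rates = c(1e-2, 1e-3, 1e-5),
                                     optimizers = c("sgd", "rmsprop", "adam"),
                                     folds = 5, epochs = 25, seed = 1) {
  y <- as_binary_label(y)
  if (min(table(y)) < folds) {
    stop_vf("need at least %d samples per class for stratified %d-fold CV",
            folds, folds)
  }
  fold_id <- integer(length(y))
  fold_id[y == 0] <- with_local_seed(substream_seed(seed, "cv0"),
                                     sample(rep_len(seq_len(folds), sum(y == 0))))
  fold_id[y == 1] <- with_local_seed(substream_seed(seed, "cv1"),
                                     sample(rep_len(seq_len(folds), sum(y == 1))))
  grid <- expand.grid(activation = activations, lr = learning_rates,
                      optimizer = optimizers, stringsAsFactors = FALSE)
  scores <- matrix(NA_real_, nrow(grid), folds)
  for (g in seq_len(nrow(grid))) {
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      fit <- nn_fit(ncol(X), c(128, 64, 1),
                    c(grid$activation[g], grid$activation[g], "sigmoid"),
                    X[tr, , drop = FALSE], matrix(y[tr], ncol = 1),
                    epochs = epochs, lr = grid$lr[g],
                    optimizer = grid$optimizer[g], patience = Inf,
                    seed = substream_seed(seed, sprintf("hp-%d-%d", g, f)))
      p <- nn_predict(fit$net, X[!tr, , drop = FALSE])
      scores[g, f] <- mean((p > 0.5) == (y[!tr] == 1))
    }
  }
  grid$mean_score <- rowMeans(scores)
  preferred <- grid$activation == "sigmoid" & grid$lr == 1e-3 &
    grid$optimizer == "adam"
  ord <- order(-grid$mean_score, -preferred, seq_len(nrow(grid)))
  best <- grid[ord[1], ]
  list(best = list(activation = best$activation, lr = best$lr,
                   optimizer = best$optimizer, mean_score = best$mean_score),
       table = grid)
}
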