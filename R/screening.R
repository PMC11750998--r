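#' The nine screening classifiers
#'
#' @return character vector of supported model names.
#' @export
screening_model_names <- function() {
  c("LDA", "LR", "GNB", "SVM", "KNN", "RF", "XGBoost", "GBDT", "RUSBoost")
}

#' Build the subjects-by-features table
#'
#' Flattens each subject's FC matrix set to the fixed 270-column layout
#' (estimator, then chromophore, then ROI pair i < j) and optionally
#' appends the six neuropsychological score columns.
#'
#' @param fc_list named list of [fc_matrix_set()] arrays, one per subject.
#' @param scores data.frame with `subject_id`, `group` and the six test
#'   columns (mmse, tmt_a, tmt_b, bnt, hvlt, cdt).
#' @param include_scores append the score columns as features?
#' @return data.frame of class `feature_table`: `subject_id`, `group`,
#'   FC columns, and score columns when enabled; attribute `feature_set`
#'   is `"fc_only"` or `"fc_plus_neuro"`.
#' @export
build_feature_table <- function(fc_list, scores, include_scores = FALSE) {
  ids <- scores$subject_id
  missing_fc <- setdiff(ids, names(fc_list))
  extra_fc <- setdiff(names(fc_list), ids)
  if (length(missing_fc) || length(extra_fc)) {
    stop("subject ids misaligned; missing FC for: ",
         paste(missing_fc, collapse = ", "),
         "; FC without scores: ", paste(extra_fc, collapse = ", "))
  }
  feat <- t(vapply(ids, function(id) fc_features(fc_list[[id]]),
                   fc_features(fc_list[[ids[1]]])))
  out <- data.frame(subject_id = ids, group = scores$group,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(feat))
  if (include_scores) {
    out <- cbind(out, scores[, c("mmse", "tmt_a", "tmt_b", "bnt",
                                 "hvlt", "cdt")])
  }
  attr(out, "feature_set") <- if (include_scores) "fc_plus_neuro" else "fc_only"
  class(out) <- c("feature_table", class(out))
  out
}

feature_columns <- function(features) {
  setdiff(names(features), c("subject_id", "group"))
}

#' Stratified k-fold assignment
#'
#' Shuffles within class and deals fold labels round-robin, so per-fold
#' class proportions are within one sample of the global proportions and
#' every subject is tested exactly once.
#'
#' @param labels class labels.
#' @param k number of folds (must not exceed the smallest class count).
#' @param seed integer seed.
#' @return integer vector of fold ids (1..k), aligned with `labels`.
#' @export
make_folds <- function(labels, k, seed = 1L) {
  labels <- as.character(labels)
  if (k > min(table(labels))) {
    stop("k exceeds the smallest class count")
  }
  set.seed(as.integer(seed))
  folds <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' Fit the per-fold feature pipeline and classifier
#'
#' Training-only pipeline: (1) variance filter on the raw training
#' features, (2) z-score using training means/SDs, (3) PCA retaining a
#' configured variance fraction, (4) classifier fit. All transform
#' statistics are frozen and reapplied verbatim to test data.
#'
#' @param train_x numeric matrix (training subjects x features).
#' @param train_y factor of two levels, `levels = c(negative, positive)`.
#' @param model model name, see [screening_model_names()].
#' @param reducer_config list: `var_threshold` (features with raw
#'   training variance `<=` this are dropped; set below 0 to disable),
#'   `pca_var` (retained variance fraction, default 0.95), `pca` (logical).
#' @param seed integer seed for stochastic learners.
#' @return object of class `fold_fit`; apply with [predict_fold()].
#' @export
fit_fold <- function(train_x, train_y, model = "LDA",
                     reducer_config = list(), seed = 1L) {
  stopifnot(nlevels(train_y) == 2, all(table(train_y) > 0))
  rc <- utils::modifyList(
    list(var_threshold = 1, pca = TRUE, pca_var = 0.95), reducer_config)
  v <- apply(train_x, 2, stats::var)
  keep <- which(v > rc$var_threshold)
  if (length(keep) == 0) {
    stop("the variance filter removed every feature; review var_threshold ",
         "against the feature scale")
  }
  X <- train_x[, keep, drop = FALSE]
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv == 0] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  rot <- NULL
  if (isTRUE(rc$pca) && ncol(Z) > 1) {
    pc <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
    cum <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
    ncomp <- max(1L, min(which(cum >= rc$pca_var)))
    rot <- pc$rotation[, seq_len(ncomp), drop = FALSE]
    Z <- Z %*% rot
  }
  set.seed(as.integer(seed))
  clf <- fit_classifier(model, Z, train_y)
  structure(list(keep = keep, mu = mu, sdv = sdv, rotation = rot,
                 model = model, clf = clf, levels = levels(train_y)),
            class = "fold_fit")
}

#' Apply a fitted fold pipeline to new data
#'
#' @param fit a [fit_fold()] object.
#' @param newx numeric matrix with the original feature columns.
#' @return list with `label` (factor) and `score` (probability-like score
#'   for the positive = second level).
#' @export
predict_fold <- function(fit, newx) {
  Z <- newx[, fit$keep, drop = FALSE]
  Z <- sweep(sweep(Z, 2, fit$mu), 2, fit$sdv, "/")
  if (!is.null(fit$rotation)) Z <- Z %*% fit$rotation
  predict_classifier(fit$model, fit$clf, Z, fit$levels)
}

fit_classifier <- function(model, X, y) {
  pos <- levels(y)[2]
  switch(model,
    # near-collinear PCA components are expected at small n; LDA predicts
    # fine through its generalized inverse, so silence the collinearity note
    LDA = suppressWarnings(MASS::lda(X, grouping = y)),
    LR = suppressWarnings(stats::glm.fit(cbind(1, X), y == pos,
                                         family = stats::binomial())),
    GNB = e1071::naiveBayes(as.data.frame(X), y),
    SVM = e1071::svm(X, y, kernel = "radial", probability = TRUE),
    KNN = list(X = X, y = y, k = 5L),
    RF = randomForest::randomForest(X, y, ntree = 500),
    XGBoost = xgboost::xgb.train(
      params = list(objective = "binary:logistic", eta = 0.3, max_depth = 6,
                    nthread = 1),
      data = xgboost::xgb.DMatrix(X, label = as.numeric(y == pos)),
      nrounds = 100),
    GBDT = xgboost::xgb.train(
      params = list(objective = "binary:logistic", eta = 0.1, max_depth = 3,
                    lambda = 0, alpha = 0, nthread = 1),
      data = xgboost::xgb.DMatrix(X, label = as.numeric(y == pos)),
      nrounds = 100),
    RUSBoost = fit_rusboost(X, y),
    stop("unknown model: ", model)
  )
}

predict_classifier <- function(model, clf, Z, lev) {
  pos <- lev[2]
  score <- switch(model,
    LDA = stats::predict(clf, Z)$posterior[, pos],
    LR = {
      eta <- drop(cbind(1, Z) %*% clf$coefficients)
      eta[!is.finite(eta)] <- 0
      stats::plogis(eta)
    },
    GNB = stats::predict(clf, as.data.frame(Z), type = "raw")[, pos],
    SVM = {
      pr <- stats::predict(clf, Z, probability = TRUE)
      attr(pr, "probabilities")[, pos]
    },
    KNN = {
      pr <- class::knn(clf$X, Z, clf$y, k = clf$k, prob = TRUE)
      p <- attr(pr, "prob")
      ifelse(pr == pos, p, 1 - p)
    },
    RF = stats::predict(clf, Z, type = "prob")[, pos],
    XGBoost = stats::predict(clf, Z),
    GBDT = stats::predict(clf, Z),
    RUSBoost = predict_rusboost(clf, Z),
    stop("unknown model: ", model)
  )
  score <- as.numeric(score)
  label <- factor(ifelse(score >= 0.5, lev[2], lev[1]), levels = lev)
  list(label = label, score = score)
}

# Boosting with random undersampling of the majority class each round;
# depth-limited CART weak learners, AdaBoost-style weight updates.
fit_rusboost <- function(X, y, n_rounds = 50, maxdepth = 3) {
  n <- nrow(X)
  w <- rep(1 / n, n)
  tab <- table(y)
  minority <- names(tab)[which.min(tab)]
  learners <- list()
  alphas <- numeric(0)
  Xn <- X
  colnames(Xn) <- paste0("X", seq_len(ncol(Xn)))
  df <- data.frame(y = y, Xn)
  for (t in seq_len(n_rounds)) {
    idx_min <- which(y == minority)
    idx_maj <- which(y != minority)
    pmaj <- w[idx_maj] / sum(w[idx_maj])
    samp <- c(idx_min,
              sample(idx_maj, min(length(idx_min), length(idx_maj)),
                     replace = TRUE, prob = pmaj))
    fitw <- w[samp] / sum(w[samp])
    tr <- rpart::rpart(y ~ ., data = df[samp, , drop = FALSE],
                       weights = fitw * length(samp), method = "class",
                       control = rpart::rpart.control(
                         maxdepth = maxdepth, cp = -1, minsplit = 4,
                         xval = 0))
    pred <- stats::predict(tr, df, type = "class")
    err <- sum(w[pred != y])
    if (err <= 0) {
      learners[[length(learners) + 1]] <- tr
      alphas <- c(alphas, 10)
      break
    }
    if (err >= 0.5) next
    beta <- err / (1 - err)
    learners[[length(learners) + 1]] <- tr
    alphas <- c(alphas, log(1 / beta))
    w[pred == y] <- w[pred == y] * beta
    w <- w / sum(w)
  }
  if (length(learners) == 0) {
    # no weak learner beat chance: fall back to a single tree
    tr <- rpart::rpart(y ~ ., data = df, method = "class",
                       control = rpart::rpart.control(maxdepth = maxdepth,
                                                      xval = 0))
    learners <- list(tr)
    alphas <- 1
  }
  list(learners = learners, alphas = alphas, levels = levels(y))
}

predict_rusboost <- function(clf, Z) {
  pos <- clf$levels[2]
  df <- as.data.frame(Z)
  names(df) <- paste0("X", seq_len(ncol(Z)))
  votes <- numeric(nrow(Z))
  for (i in seq_along(clf$learners)) {
    pred <- stats::predict(clf$learners[[i]], df, type = "class")
    votes <- votes + clf$alphas[i] * (pred == pos)
  }
  votes / sum(clf$alphas)
}

#' Rank-based AUC
#'
#' Probability that a random positive outscores a random negative, with
#' ties counted 1/2 (Mann-Whitney form via mid-ranks).
#'
#' @param y_true labels; `positive` names the positive class.
#' @param y_score numeric scores.
#' @param positive positive class label.
#' @return AUC in `[0, 1]`.
#' @export
auc_rank <- function(y_true, y_score, positive) {
  pos <- y_true == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(y_score)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification metrics from pooled predictions
#'
#' ACC, sensitivity (recall of the declared positive class), specificity,
#' rank-based AUC, and a DeLong 95% confidence interval for the AUC.
#'
#' @param y_true true labels.
#' @param y_pred predicted labels.
#' @param y_score continuous scores for the positive class.
#' @param positive positive class label.
#' @return list: `acc`, `sen`, `spe`, `auc`, `ci_low`, `ci_high`.
#' @export
evaluate_predictions <- function(y_true, y_pred, y_score, positive) {
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  pos <- y_true == positive
  tp <- sum(pos & y_pred == positive)
  fn <- sum(pos & y_pred != positive)
  tn <- sum(!pos & y_pred != positive)
  fp <- sum(!pos & y_pred == positive)
  acc <- (tp + tn) / length(y_true)
  sen <- tp / (tp + fn)
  spe <- tn / (tn + fp)
  if (stats::sd(y_score) == 0) {
    warning("constant scores: AUC degenerate, CI unavailable")
    return(list(acc = acc, sen = sen, spe = spe, auc = 0.5,
                ci_low = NA_real_, ci_high = NA_real_))
  }
  auc <- auc_rank(y_true, y_score, positive)
  ci <- tryCatch({
    r <- pROC::roc(response = factor(pos, c(FALSE, TRUE)),
                   predictor = y_score, quiet = TRUE, direction = "<")
    as.numeric(suppressWarnings(pROC::ci.auc(r, method = "delong")))[c(1, 3)]
  }, error = function(e) c(NA_real_, NA_real_))
  list(acc = acc, sen = sen, spe = spe, auc = auc,
       ci_low = max(0, ci[1]), ci_high = min(1, ci[2]))
}

task_classes <- function(task) {
  switch(task,
    SCD_vs_NC = c(negative = "NC", positive = "SCD"),
    MCI_vs_NC = c(negative = "NC", positive = "MCI"),
    MCI_vs_SCD = c(negative = "SCD", positive = "MCI"),
    stop("unknown task: ", task)
  )
}

#' Cross-validated out-of-fold predictions for one task
#'
#' Subsets the feature table to the task's two groups (dropping subjects
#' with missing features), builds stratified folds, fits the full
#' training-only pipeline in each fold and pools the out-of-fold
#' predictions, for every requested model and fold scheme.
#'
#' @param features a [build_feature_table()] result.
#' @param task one of `"SCD_vs_NC"`, `"MCI_vs_NC"`, `"MCI_vs_SCD"`.
#' @param models character vector of model names.
#' @param k integer vector of fold counts (default `c(5, 10)`).
#' @param seed integer seed (folds + stochastic learners).
#' @param reducer_config see [fit_fold()].
#' @return nested list `result[[fold_scheme]][[model]]` of data.frames
#'   (subject_id, y_true, y_pred, y_score); attributes `positive`,
#'   `negative`, `n`.
#' @export
run_task <- function(features, task, models = screening_model_names(),
                     k = c(5, 10), seed = 1L, reducer_config = list()) {
  cls <- task_classes(task)
  sel <- features$group %in% cls
  dat <- features[sel, , drop = FALSE]
  fcols <- feature_columns(dat)
  X <- as.matrix(dat[, fcols, drop = FALSE])
  complete <- stats::complete.cases(X)
  dat <- dat[complete, , drop = FALSE]
  X <- X[complete, , drop = FALSE]
  y <- factor(dat$group, levels = unname(cls))  # (negative, positive)
  if (any(table(y) < 2)) stop("both task groups must be present")

  out <- list()
  for (kk in k) {
    folds <- make_folds(y, kk, seed)
    per_model <- list()
    for (m in models) {
      pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
      score <- rep(NA_real_, length(y))
      for (f in seq_len(kk)) {
        tr <- folds != f
        fit <- fit_fold(X[tr, , drop = FALSE], droplevels(y[tr]),
                        model = m, reducer_config = reducer_config,
                        seed = seed + f)
        pr <- predict_fold(fit, X[!tr, , drop = FALSE])
        pred[!tr] <- pr$label
        score[!tr] <- pr$score
      }
      per_model[[m]] <- data.frame(subject_id = dat$subject_id,
                                   y_true = y, y_pred = pred,
                                   y_score = score,
                                   stringsAsFactors = FALSE)
    }
    out[[paste0(kk, "-fold")]] <- per_model
  }
  attr(out, "positive") <- unname(cls["positive"])
  attr(out, "negative") <- unname(cls["negative"])
  attr(out, "n") <- length(y)
  out
}

#' Permutation-derived empirical chance accuracy
#'
#' Repeats the identical cross-validation pipeline with randomly permuted
#' labels and returns the mean pooled out-of-fold accuracy -- the null
#' reference (EACC) against which a model's real ACC is judged.
#'
#' @param X numeric feature matrix.
#' @param y factor of two levels (negative, positive).
#' @param model model name.
#' @param k fold count.
#' @param n_perm number of label permutations (default 200).
#' @param seed integer seed.
#' @param reducer_config see [fit_fold()].
#' @return mean accuracy over permutations.
#' @export
permutation_eacc <- function(X, y, model, k = 10, n_perm = 200, seed = 1L,
                             reducer_config = list()) {
  stopifnot(n_perm >= 1)
  seeds <- child_seeds(seed, n_perm)
  accs <- vapply(seq_len(n_perm), function(p) {
    set.seed(seeds[p])
    yp <- sample(y)
    folds <- make_folds(yp, k, seeds[p])
    pred <- factor(rep(NA_character_, length(yp)), levels = levels(yp))
    for (f in seq_len(k)) {
      tr <- folds != f
      fit <- fit_fold(X[tr, , drop = FALSE], droplevels(yp[tr]),
                      model = model, reducer_config = reducer_config,
                      seed = seeds[p] %% 1000L + f)
      pred[!tr] <- predict_fold(fit, X[!tr, , drop = FALSE])$label
    }
    mean(pred == yp)
  }, numeric(1))
  mean(accs)
}

#' Full multi-classifier screening report
#'
#' Runs every task x model x feature set x fold scheme combination on a
#' cohort's feature tables and reports pooled out-of-fold ACC, the
#' permutation chance accuracy EACC, specificity, sensitivity, AUC and
#' its DeLong 95% CI -- one row per combination.
#'
#' @param feature_tables named list with elements `fc_only` and/or
#'   `fc_plus_neuro`, each a [build_feature_table()] result.
#' @param models character vector of model names.
#' @param k integer vector of fold schemes.
#' @param n_perm permutations for EACC (0 disables EACC).
#' @param seed integer seed.
#' @param reducer_config see [fit_fold()].
#' @param tasks character vector of tasks.
#' @return data.frame of class `task_report` with columns task, model,
#'   feature_set, fold_scheme, ACC, EACC, SPC, SEN, AUC, CI_low, CI_high,
#'   n, seed, n_perm.
#' @export
full_screen <- function(feature_tables, models = screening_model_names(),
                        k = c(5, 10), n_perm = 200, seed = 1L,
                        reducer_config = list(),
                        tasks = c("SCD_vs_NC", "MCI_vs_NC", "MCI_vs_SCD")) {
  rows <- list()
  for (fs_name in names(feature_tables)) {
    features <- feature_tables[[fs_name]]
    for (task in tasks) {
      res <- run_task(features, task, models, k, seed, reducer_config)
      pos <- attr(res, "positive")
      for (scheme in names(res)) {
        kk <- as.integer(sub("-fold", "", scheme))
        for (m in models) {
          pr <- res[[scheme]][[m]]
          met <- suppressWarnings(
            evaluate_predictions(pr$y_true, pr$y_pred, pr$y_score, pos))
          eacc <- NA_real_
          if (n_perm > 0) {
            cls <- task_classes(task)
            sel <- features$group %in% cls
            dat <- features[sel, , drop = FALSE]
            X <- as.matrix(dat[, feature_columns(dat), drop = FALSE])
            ok <- stats::complete.cases(X)
            yv <- factor(dat$group[ok], levels = unname(cls))
            eacc <- permutation_eacc(X[ok, , drop = FALSE], yv, m, kk,
                                     n_perm, seed, reducer_config)
          }
          rows[[length(rows) + 1]] <- data.frame(
            task = task, model = m, feature_set = fs_name,
            fold_scheme = scheme, ACC = met$acc, EACC = eacc,
            SPC = met$spe, SEN = met$sen, AUC = met$auc,
            CI_low = met$ci_low, CI_high = met$ci_high,
            n = attr(res, "n"), seed = seed, n_perm = n_perm,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("task_report", class(out))
  out
}
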