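test_that("feature tables carry 270 FC columns plus optional scores", {
  coh <- make_tiny_cohort(c(NC = 1, SCD = 1, MCI = 1), seed = 31)
  ft <- cohort_feature_table(coh)
  fc_cols <- setdiff(names(ft$fc_only), c("subject_id", "group"))
  expect_length(fc_cols, 270)
  full_cols <- setdiff(names(ft$fc_plus_neuro), c("subject_id", "group"))
  expect_length(full_cols, 276)
  expect_true(all(c("mmse", "cdt") %in% full_cols))
  expect_false(anyDuplicated(full_cols) > 0)

  # misaligned ids are reported
  bad_scores <- coh$scores
  bad_scores$subject_id[1] <- "GHOST"
  expect_error(build_feature_table(ft$fc_list, bad_scores), "GHOST")
})

test_that("stratified folds cover every subject once with balance", {
  y <- rep(c("A", "B"), each = 5)
  f <- make_folds(y, 5, seed = 2)
  expect_equal(sort(unique(f)), 1:5)
  for (k in 1:5) {
    expect_equal(as.vector(table(y[f == k])), c(1, 1))
  }
  expect_identical(make_folds(y, 5, seed = 2), f)
  y2 <- c(rep("A", 20), rep("B", 9))
  f2 <- make_folds(y2, 3, seed = 1)
  tab <- table(f2, y2)
  expect_true(all(abs(tab[, "A"] - 20 / 3) < 1))
  expect_error(make_folds(y2, 10), "smallest class")
})

test_that("the fold pipeline freezes training statistics only", {
  set.seed(12)
  n <- 40
  X <- matrix(rnorm(n * 6, 5, 3), n, 6)
  colnames(X) <- paste0("f", 1:6)
  y <- factor(rep(c("NC", "MCI"), each = 20), levels = c("NC", "MCI"))
  fit <- fit_fold(X, y, "LDA", list(var_threshold = 0, pca = FALSE))
  Z <- sweep(sweep(X[, fit$keep, drop = FALSE], 2, fit$mu), 2, fit$sdv, "/")
  expect_lt(max(abs(colMeans(Z))), 1e-10)
  expect_equal(unname(apply(Z, 2, sd)), rep(1, ncol(Z)))

  # perturbing "test" rows never touches the fitted transform
  fit2 <- fit_fold(X, y, "LDA", list(var_threshold = 0, pca = FALSE))
  expect_identical(fit$mu, fit2$mu)
  Xtest <- matrix(rnorm(10 * 6), 10, 6)
  p1 <- predict_fold(fit, Xtest)
  Xtest2 <- Xtest
  Xtest2[10, ] <- Xtest2[10, ] + 100
  p2 <- predict_fold(fit, Xtest2)
  expect_identical(p1$score[1:9], p2$score[1:9])
})

test_that("the variance filter uses the documented boundary", {
  set.seed(3)
  mk <- function(v) {
    x <- rnorm(30)
    (x - mean(x)) / sd(x) * sqrt(v)
  }
  X <- cbind(a = mk(0.5), b = mk(1.0), c = mk(2.0))
  y <- factor(rep(c("N", "P"), 15), levels = c("N", "P"))
  fit <- fit_fold(X, y, "LDA", list(var_threshold = 1, pca = FALSE))
  expect_identical(names(fit$keep), "c")
  expect_error(fit_fold(X[, 1:2], y, "LDA", list(var_threshold = 1)),
               "variance filter")
  # two perfectly correlated kept features collapse to one PCA component
  X2 <- cbind(u = mk(4), v = NA)
  X2[, "v"] <- 2 * X2[, "u"]
  fit2 <- fit_fold(X2, y, "LDA", list(var_threshold = 1, pca_var = 0.95))
  expect_equal(ncol(fit2$rotation), 1)
})

test_that("all nine classifiers run and separable data is easy", {
  set.seed(41)
  n <- 36
  X <- matrix(rnorm(n * 5), n, 5)
  colnames(X) <- paste0("f", 1:5)
  y <- rep(c("NC", "MCI"), each = n / 2)
  X[y == "MCI", ] <- X[y == "MCI", ] + 4
  ft <- data.frame(subject_id = sprintf("s%02d", 1:n), group = y,
                   stringsAsFactors = FALSE)
  colnames(X) <- paste0("COH_HbO_ROI1_ROI", 2:6)
  ft <- cbind(ft, X)
  res <- run_task(ft, "MCI_vs_NC", models = screening_model_names(),
                  k = 3, seed = 5, reducer_config = list(var_threshold = 0))
  for (m in screening_model_names()) {
    pr <- res[["3-fold"]][[m]]
    expect_false(any(is.na(pr$y_pred)), info = m)
    expect_true(all(pr$y_score >= 0 & pr$y_score <= 1), info = m)
    met <- suppressWarnings(
      evaluate_predictions(pr$y_true, pr$y_pred, pr$y_score, "MCI"))
    expect_gte(met$acc, 0.8)
  }
  # the linear learners nail a linearly separable problem
  for (m in c("LDA", "LR", "SVM")) {
    pr <- res[["3-fold"]][[m]]
    expect_equal(mean(pr$y_pred == pr$y_true), 1, info = m)
  }
  expect_identical(
    res,
    run_task(ft, "MCI_vs_NC", models = screening_model_names(), k = 3,
             seed = 5, reducer_config = list(var_threshold = 0)))
})

test_that("metrics match hand arithmetic and the AUC pairwise oracle", {
  yt <- c(rep("P", 4), rep("N", 4))
  yp <- c("P", "P", "P", "N", "P", "P", "N", "N")
  sc <- c(0.9, 0.8, 0.7, 0.4, 0.6, 0.55, 0.3, 0.2)
  m <- evaluate_predictions(yt, yp, sc, "P")
  expect_equal(m$acc, 0.625)
  expect_equal(m$sen, 0.75)
  expect_equal(m$spe, 0.5)
  expect_true(m$ci_low <= m$auc && m$auc <= m$ci_high)

  # all-positive predictor
  m2 <- evaluate_predictions(yt, rep("P", 8), sc, "P")
  expect_equal(m2$sen, 1)
  expect_equal(m2$spe, 0)
  expect_equal(m2$acc, 0.5)

  # perfect predictions
  m3 <- evaluate_predictions(yt, yt, c(4:1, -(1:4)) / 10, "P")
  expect_equal(c(m3$acc, m3$sen, m3$spe, m3$auc), rep(1, 4))

  # constant scores degrade gracefully
  expect_warning(m4 <- evaluate_predictions(yt, yp, rep(0.5, 8), "P"),
                 "constant")
  expect_equal(m4$auc, 0.5)

  # rank AUC == exhaustive pairwise oracle on random small vectors
  set.seed(9)
  for (case in 1:1000) {
    nv <- sample(4:12, 1)
    yy <- c("P", "N", sample(c("P", "N"), nv - 2, replace = TRUE))
    ss <- round(runif(nv), 2)   # coarse grid forces ties
    a <- auc_rank(yy, ss, "P")
    pos <- ss[yy == "P"]; neg <- ss[yy == "N"]
    wins <- 0
    for (p in pos) for (q in neg) wins <- wins + (p > q) + 0.5 * (p == q)
    expect_identical(a, wins / (length(pos) * length(neg)))
  }
})

test_that("EACC sits at chance for uninformative balanced data", {
  set.seed(70)
  X <- matrix(rnorm(40 * 10), 40, 10)
  y <- factor(rep(c("NC", "MCI"), 20), levels = c("NC", "MCI"))
  e <- permutation_eacc(X, y, "LDA", k = 5, n_perm = 200, seed = 11,
                        reducer_config = list(var_threshold = 0))
  expect_lt(abs(e - 0.5), 0.03)
  # reproducible single permutation
  e1 <- permutation_eacc(X, y, "LDA", k = 5, n_perm = 1, seed = 3,
                         reducer_config = list(var_threshold = 0))
  e2 <- permutation_eacc(X, y, "LDA", k = 5, n_perm = 1, seed = 3,
                         reducer_config = list(var_threshold = 0))
  expect_identical(e1, e2)
})

test_that("real ACC matches EACC when features are uninformative", {
  set.seed(71)
  accs <- replicate(10, {
    n <- 40
    X <- matrix(rnorm(n * 8), n, 8)
    colnames(X) <- paste0("COH_HbO_ROI1_ROI", 2:9)
    ft <- data.frame(subject_id = sprintf("s%02d", 1:n),
                     group = sample(rep(c("NC", "MCI"), n / 2)))
    ft <- cbind(ft, X)
    pr <- run_task(ft, "MCI_vs_NC", models = "LDA", k = 5,
                   seed = sample.int(1e6, 1),
                   reducer_config = list(var_threshold = 0))
    mean(pr[["5-fold"]]$LDA$y_pred == pr[["5-fold"]]$LDA$y_true)
  })
  expect_lt(abs(mean(accs) - 0.5), 0.08)
})

test_that("strong effects push ACC well above chance", {
  set.seed(72)
  n <- 60
  X <- matrix(rnorm(n * 6), n, 6)
  colnames(X) <- paste0("PLV_HbR_ROI1_ROI", 2:7)
  g <- rep(c("NC", "MCI"), each = n / 2)
  X[g == "MCI", 1:3] <- X[g == "MCI", 1:3] + 3
  ft <- cbind(data.frame(subject_id = sprintf("s%02d", 1:n), group = g), X)
  pr <- run_task(ft, "MCI_vs_NC", models = "LDA", k = 5, seed = 8,
                 reducer_config = list(var_threshold = 0))$`5-fold`$LDA
  acc <- mean(pr$y_pred == pr$y_true)
  Xo <- as.matrix(ft[, 3:8])
  e <- permutation_eacc(Xo, factor(g, c("NC", "MCI")), "LDA", k = 5,
                        n_perm = 30, seed = 8,
                        reducer_config = list(var_threshold = 0))
  expect_gt(acc, e + 0.2)
})

test_that("full_screen enumerates tasks x models x schemes x feature sets", {
  set.seed(90)
  ft_fc <- make_feature_table(n_per_group = 10, n_feat = 6, effect = 2.5,
                              seed = 51)
  ft_both <- make_feature_table(n_per_group = 10, n_feat = 6, effect = 2.5,
                                seed = 51, with_scores = TRUE)
  rep_tab <- full_screen(list(fc_only = ft_fc, fc_plus_neuro = ft_both),
                         models = c("LDA", "GNB", "KNN"), k = c(5, 10),
                         n_perm = 2, seed = 4,
                         reducer_config = list(var_threshold = 0))
  # 3 tasks x 3 models x 2 schemes x 2 feature sets
  expect_equal(nrow(rep_tab), 36)
  expect_equal(sum(rep_tab$feature_set == "fc_only" &
                     rep_tab$fold_scheme == "10-fold"), 9)
  metrics <- rep_tab[, c("ACC", "EACC", "SPC", "SEN", "AUC")]
  expect_true(all(metrics >= 0 & metrics <= 1, na.rm = TRUE))
  expect_true(all(rep_tab$CI_low <= rep_tab$AUC + 1e-12, na.rm = TRUE))
  expect_true(all(rep_tab$AUC <= rep_tab$CI_high + 1e-12, na.rm = TRUE))
})

test_that("adding informative scores does not hurt the linear models", {
  set.seed(91)
  wins <- 0
  nseeds <- 8
  for (s in seq_len(nseeds)) {
    fc_eff <- 1.0
    ft_fc <- make_feature_table(n_per_group = 20, n_feat = 6,
                                effect = fc_eff, seed = 500 + s)
    ft_both <- make_feature_table(n_per_group = 20, n_feat = 6,
                                  effect = fc_eff, seed = 500 + s,
                                  with_scores = TRUE)
    aucs <- vapply(list(ft_fc, ft_both), function(ft) {
      pr <- run_task(ft, "MCI_vs_NC", models = "LDA", k = 5, seed = s,
                     reducer_config = list(var_threshold = 0))$`5-fold`$LDA
      auc_rank(pr$y_true, pr$y_score, "MCI")
    }, numeric(1))
    wins <- wins + (aucs[2] >= aucs[1] - 0.02)
  }
  expect_gte(wins / nseeds, 0.8)
})
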