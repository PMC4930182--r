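test_that("reduction standardizes, centers and matches an eigen oracle", {
  set.seed(42)
  X <- matrix(rnorm(60 * 8), 60, 8) %*% diag(c(5, 4, 3, 2, 1, 1, 1, 1))
  colnames(X) <- paste0("f", 1:8)
  red <- fit_reduction(X, 4)
  # projecting the column-mean vector gives the zero vector
  expect_equal(as.numeric(project_reduction(red, colMeans(X))),
               rep(0, 4), tolerance = 1e-10)
  # explained variances equal the eigenvalues of the standardized covariance
  ev <- eigen(stats::cov(scale(X)), symmetric = TRUE)$values
  expect_equal(red$sdev^2, ev, tolerance = 1e-8)
  # sign convention: largest-magnitude loading of each component positive
  for (j in 1:4) expect_gt(red$rotation[which.max(abs(red$rotation[, j])), j], 0)
})

test_that("data in an exact k-dim subspace reconstructs with ~zero error", {
  set.seed(7)
  basis <- qr.Q(qr(matrix(rnorm(10 * 4), 10, 4)))
  X <- matrix(rnorm(50 * 4), 50, 4) %*% t(basis)
  colnames(X) <- paste0("f", 1:10)
  red <- fit_reduction(X, 4)
  Z <- project_reduction(red, X)
  recon <- sweep(Z %*% t(red$rotation), 2, red$scale, `*`)
  recon <- sweep(recon, 2, red$center, `+`)
  expect_equal(unname(recon), unname(X), tolerance = 1e-8)
  expect_error(fit_reduction(X, 8), "rank error")
})

test_that("oversampling balances to the majority using only existing rows", {
  sep <- separable_features(n_per_class = 10)
  keep <- c(1:2, 11:15, 21:30)  # counts 2 / 5 / 10
  bal <- balance_classes(sep$X[keep, ], sep$y[keep], seed = 3)
  expect_equal(as.integer(table(bal$y)), rep(10L, 3))
  # membership oracle: every resampled row appears in the input
  key <- apply(sep$X[keep, ], 1, paste, collapse = ",")
  expect_true(all(apply(bal$X, 1, paste, collapse = ",") %in% key))
  # already balanced input is unchanged
  bal2 <- balance_classes(sep$X, sep$y, seed = 3)
  expect_equal(nrow(bal2$X), 30L)
  expect_error(balance_classes(sep$X[0, ], integer(0)), "empty")
})

test_that("training separates clusters, is deterministic and serializable", {
  sep <- separable_features(n_per_class = 20)
  cfg <- score_model_config(n_components = 4)
  m1 <- train_item_model(sep$X, sep$y, config = cfg, seed = 5)
  m2 <- train_item_model(sep$X, sep$y, config = cfg, seed = 5)
  pred <- predict_item_score(m1, sep$X)
  expect_equal(pred, sep$y)  # linearly separable -> 100% training accuracy
  expect_identical(predict_item_score(m2, sep$X), pred)
  expect_true(all(pred %in% 0:2))
  # class-2 cluster centroid scores 2
  centroid <- colMeans(sep$X[sep$y == 2, ])
  names(centroid) <- colnames(sep$X)
  expect_equal(predict_item_score(m1, centroid), 2L)
  # save -> load -> identical predictions
  path <- withr::local_tempfile(fileext = ".rds")
  saveRDS(m1, path)
  expect_identical(predict_item_score(readRDS(path), sep$X), pred)
  # feature roster contract
  Xbad <- sep$X
  colnames(Xbad)[3] <- "other"
  expect_error(predict_item_score(m1, Xbad), "feature names")
})

test_that("single-class training data yields a constant predictor", {
  sep <- separable_features(n_per_class = 15)
  only1 <- train_item_model(sep$X[sep$y == 1, ], rep(1, 15), seed = 2)
  expect_equal(predict_item_score(only1, sep$X), rep(1L, 45))
})

test_that("component selection recovers a known intrinsic dimension", {
  set.seed(31)
  # the 20 observed features mix 4 latent factors that determine the class,
  # plus weak isotropic noise: the signal lives in the top 4 components.
  # classes are margin-separated so accuracy saturates for every k >= 4 and
  # the tie-break toward the smallest k decides
  Z <- matrix(rnorm(400 * 4), 400, 4)
  s <- rowSums(Z)
  keep <- which(abs(s - 1) > 0.5 & abs(s + 1) > 0.5)[1:120]
  Z <- Z[keep, ]
  n <- nrow(Z)
  y <- (rowSums(Z) > 1) + (rowSums(Z) > -1)  # 0/1/2 by signal only
  X <- Z %*% matrix(rnorm(4 * 20), 4, 20) +
    matrix(rnorm(n * 20, sd = 0.02), n, 20)
  colnames(X) <- paste0("f", 1:20)
  k <- select_k(X, y, seed = 4)
  expect_true(k %in% 4:10)
  expect_equal(k, 4)
  expect_error(select_k(X, rep(2, n)), "two classes")
})

test_that("cross-validation partitions exactly and reports honest accuracy", {
  sep <- separable_features(n_per_class = 18)
  cfg <- score_model_config(n_components = 4)
  cv <- cross_validate(sep$X, sep$y, k_folds = 9, seed = 6, config = cfg)
  # folds are disjoint and cover every record exactly once
  expect_equal(sort(unique(cv$fold)), 1:9)
  expect_equal(length(cv$fold), 54L)
  expect_equal(as.integer(table(cv$fold)), rep(6L, 9))
  # stratification: every fold carries each class
  expect_true(cv$stratified)
  for (f in 1:9) expect_setequal(unique(sep$y[cv$fold == f]), 0:2)
  # recompute oracle: mean accuracy is the mean of per-fold accuracies
  oracle <- vapply(1:9, function(f)
    mean(cv$predictions[cv$fold == f] == sep$y[cv$fold == f]), numeric(1))
  expect_equal(cv$per_fold_accuracy, oracle)
  expect_equal(cv$mean_accuracy, mean(oracle))
  expect_gte(cv$mean_accuracy, 0.95)  # separable fixture
  expect_equal(sum(cv$confusion), 54)
  # fold-count contract
  expect_error(cross_validate(sep$X, sep$y, k_folds = 5), "\\[8, 10\\]")
  expect_s3_class(cross_validate(sep$X, sep$y, k_folds = 5, seed = 1,
                                 config = cfg, allow_any_k = TRUE),
                  "cv_report")
})

test_that("determinism: identical seed and inputs give identical reports", {
  sep <- separable_features(n_per_class = 12)
  cfg <- score_model_config(n_components = 4)
  cv1 <- cross_validate(sep$X, sep$y, seed = 11, config = cfg)
  cv2 <- cross_validate(sep$X, sep$y, seed = 11, config = cfg)
  expect_identical(cv1$fold, cv2$fold)
  expect_identical(cv1$predictions, cv2$predictions)
  expect_identical(cv1$mean_accuracy, cv2$mean_accuracy)
})

test_that("summed scores respect the 13-item scale", {
  expect_equal(summed_score(rep(2, 13)), 26L)
  expect_equal(summed_score(rep(0, 13)), 0L)
  expect_equal(summed_score(c(rep(2, 6), rep(1, 4), rep(0, 3))), 16L)
  expect_error(summed_score(rep(2, 12)), "exactly 13")
  expect_error(summed_score(c(rep(2, 12), 3)), "0, 1 or 2")
})

test_that("cohort evaluation matches textbook correlation oracles", {
  df <- toy_cohort_df()
  df <- rbind(df, df, df)  # 9 arms for stable tests
  df$subject_id <- paste0("S", 1:9)
  df$brunnstrom_stage <- c(2, 3, 4, 6, 6, 1, 5, 3, 4)
  cohort <- cohort_table(df)
  pred <- data.frame(subject_id = df$subject_id,
                     predicted_sum_13 = cohort$data$sum_13)  # predicted == real
  jerk <- data.frame(subject_id = df$subject_id,
                     log_jerk_hemiplegic = c(2.1, 1.9, 1.6, 1.2, 1.3, 2.6, 1.4, 1.8, 1.7),
                     log_jerk_nonhemiplegic = rep(1.2, 9))
  ev <- evaluate_cohort(pred, cohort, jerk)
  expect_equal(ev$pearson_sum13, 1.0)
  # stage-3..6 filter: stages {2,3,4,6,6,1,5,3,4} -> 7 arms qualify
  expect_equal(ev$n_stage_3_6, 7L)
  # direct-formula oracles on the merged vectors
  d <- merge(cohort$data, jerk, by = "subject_id")
  r_oracle <- sum(scale(d$sum_13) * scale(d$total_33)) / (nrow(d) - 1)
  expect_equal(ev$pearson_total, r_oracle, tolerance = 1e-12)
  dd <- d[d$brunnstrom_stage %in% 3:6, ]
  rho_oracle <- stats::cor(rank(dd$log_jerk_hemiplegic),
                           rank(dd$brunnstrom_stage))
  expect_equal(ev$spearman_stage, rho_oracle, tolerance = 1e-12)
  expect_lt(ev$spearman_stage, 0)
  # unmatched subjects are excluded with a warning, not silently dropped
  expect_warning(
    ev2 <- evaluate_cohort(pred[1:8, ], cohort, jerk),
    "excluding 1 subject")
  expect_equal(ev2$n, 8L)
  expect_equal(ev2$excluded, "S9")
})
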