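#' Model configuration shared across items
#'
#' One identical network architecture is used for every item: a single hidden
#' layer of logistic units feeding a 3-way softmax over the scores 0/1/2,
#' trained with an L2 weight penalty. Only the number of retained principal
#' components may vary per item, within 4--10.
#'
#' @param n_components Principal components kept after standardization
#'   (default 6; must lie in 4--10).
#' @param hidden Hidden-layer size (default 16).
#' @param decay L2 weight penalty (default 1e-3).
#' @param maxit Maximum optimizer iterations (default 2000).
#' @return List of class `score_model_config`.
#' @export
score_model_config <- function(n_components = 6L, hidden = 16L,
                               decay = 1e-3, maxit = 2000L) {
  if (n_components < 4L || n_components > 10L) {
    stop("n_components must lie in [4, 10]")
  }
  structure(list(n_components = as.integer(n_components),
                 hidden = as.integer(hidden), decay = decay,
                 maxit = as.integer(maxit)),
            class = "score_model_config")
}

#' Standardization + PCA reduction of a feature matrix
#'
#' Columns are standardized to zero mean and unit variance (constant columns
#' are centered only), then projected onto the top `k` principal components.
#' Component signs are fixed by convention — the largest-magnitude loading of
#' each component is made positive — so the basis is deterministic.
#'
#' @param X Numeric feature matrix (rows = recordings), no missing values.
#' @param k Number of components; must not exceed the matrix rank.
#' @return List of class `feature_reduction`: `center`, `scale`, `rotation`
#'   (p x k), `sdev` (all singular values / sqrt(n-1)), `k`.
#' @export
fit_reduction <- function(X, k) {
  X <- as.matrix(X)
  if (anyNA(X)) stop("feature matrix contains missing values")
  if (nrow(X) < k + 1L) stop("need at least k+1 = ", k + 1L, " rows")
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  scl[scl < 1e-12] <- 1
  Xs <- scale(X, center = ctr, scale = scl)
  pc <- stats::prcomp(Xs, center = FALSE, scale. = FALSE)
  rank <- sum(pc$sdev > max(pc$sdev) * 1e-8)
  if (k > rank) stop("rank error: requested ", k, " components, rank ", rank)
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    if (rot[which.max(abs(rot[, j])), j] < 0) rot[, j] <- -rot[, j]
  }
  structure(list(center = ctr, scale = scl, rotation = rot,
                 sdev = pc$sdev, k = as.integer(k)),
            class = "feature_reduction")
}

#' Project features onto a fitted reduction
#' @param reduction A [fit_reduction()] result.
#' @param X Feature matrix (or single named vector) with matching columns.
#' @return Score matrix, n x k.
#' @export
project_reduction <- function(reduction, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L, dimnames = list(NULL, names(X)))
  X <- as.matrix(X)
  scale(X, center = reduction$center, scale = reduction$scale) %*%
    reduction$rotation
}

#' Oversample minority classes to balance a training set
#'
#' Therapist scores are heavily imbalanced across a cohort; minority classes
#' are randomly oversampled with replacement up to the majority count. Only
#' rows present in the input are emitted; intended for training folds only —
#' never applied to held-out data.
#'
#' @param X Feature matrix. @param y Labels (factor or vector).
#' @param seed Integer seed for the resampling draw.
#' @return List `X`, `y` with equal class counts.
#' @export
balance_classes <- function(X, y, seed = 1L) {
  X <- as.matrix(X)
  if (nrow(X) == 0L) stop("empty training set")
  y <- as.factor(y)
  counts <- table(droplevels(y))
  target <- max(counts)
  idx <- unlist(with_seed(seed, lapply(names(counts), function(cl) {
    rows <- which(y == cl)
    if (length(rows) == target) rows
    else c(rows, sample(rows, target - length(rows), replace = TRUE))
  })))
  list(X = X[idx, , drop = FALSE], y = y[idx])
}

#' Train the score predictor for one item
#'
#' Fits the full per-item pipeline on labeled feature vectors:
#' standardization and PCA ([fit_reduction()]) on the training data, optional
#' class balancing ([balance_classes()]), then the shared neural network
#' ([nnet::nnet]). Deterministic given `seed`. Degenerate single-class data
#' yields a constant predictor.
#'
#' @param X Feature matrix (columns named per the feature roster).
#' @param y Scores in \{0,1,2\}.
#' @param config A [score_model_config()].
#' @param seed Integer seed (weight initialization + resampling).
#' @param balance Oversample minority classes before fitting (default TRUE).
#' @param item Item code stored in the model metadata.
#' @return An `item_score_model`.
#' @export
train_item_model <- function(X, y, config = score_model_config(), seed = 1L,
                             balance = TRUE, item = NULL) {
  X <- as.matrix(X)
  y <- factor(y, levels = 0:2)
  if (anyNA(y)) stop("labels must be 0, 1 or 2")
  classes <- unique(as.character(y))
  if (length(classes) == 1L) {
    return(structure(list(item = item, feature_names = colnames(X),
                          version = FEATURE_ROSTER_VERSION, config = config,
                          constant = as.integer(classes), reduction = NULL,
                          net = NULL, seed = seed, converged = TRUE,
                          class_counts = table(y)),
                     class = "item_score_model"))
  }
  red <- fit_reduction(X, config$n_components)
  Z <- project_reduction(red, X)
  yb <- y
  if (balance) {
    bal <- balance_classes(Z, y, seed = seed)
    Z <- bal$X
    yb <- bal$y
  }
  targets <- nnet::class.ind(factor(yb, levels = 0:2))
  net <- with_seed(seed,
    nnet::nnet(Z, targets, size = config$hidden, softmax = TRUE,
               decay = config$decay, maxit = config$maxit, trace = FALSE))
  converged <- net$convergence == 0L
  if (!converged) {
    warning("network did not converge within ", config$maxit,
            " iterations; returning the max-iteration model")
  }
  structure(list(item = item, feature_names = colnames(X),
                 version = FEATURE_ROSTER_VERSION, config = config,
                 constant = NULL, reduction = red, net = net, seed = seed,
                 converged = converged, class_counts = table(y)),
            class = "item_score_model")
}

#' Predict an item score
#'
#' Returns the argmax class of the network's softmax outputs; ties break
#' toward the lower (more conservative) score.
#'
#' @param model An [train_item_model()] result.
#' @param X A single [extract_features()] vector or a feature matrix whose
#'   columns match `model$feature_names`.
#' @return Integer score(s) in \{0, 1, 2\}.
#' @export
predict_item_score <- function(model, X) {
  stopifnot(inherits(model, "item_score_model"))
  if (is.null(dim(X))) {
    if (!identical(names(X), model$feature_names)) {
      stop("feature names do not match the model's feature roster")
    }
    X <- matrix(as.numeric(X), nrow = 1L,
                dimnames = list(NULL, model$feature_names))
  } else if (!identical(colnames(X), model$feature_names)) {
    stop("feature names do not match the model's feature roster")
  }
  if (!is.null(model$constant)) {
    return(rep(model$constant, nrow(X)))
  }
  probs <- stats::predict(model$net, project_reduction(model$reduction, X))
  as.integer(apply(probs, 1L, which.max)) - 1L
}

#' Choose the component count by inner cross-validation
#'
#' Evaluates each candidate `k` with a small seeded cross-validation and
#' returns the one with the best mean accuracy; ties break toward the
#' smallest `k`.
#'
#' @param X,y Labeled training features.
#' @param grid Candidate component counts (default 4:10).
#' @param n_folds Inner folds (default 5).
#' @param config Base [score_model_config()]; `n_components` is overridden.
#' @param seed Integer seed.
#' @return The selected `k`.
#' @export
select_k <- function(X, y, grid = 4:10, n_folds = 5L,
                     config = score_model_config(), seed = 1L) {
  y <- factor(y, levels = 0:2)
  if (length(unique(as.character(y))) < 2L) {
    stop("component selection needs at least two classes")
  }
  acc <- vapply(grid, function(k) {
    cfg <- config
    cfg$n_components <- as.integer(k)
    cv <- cross_validate(X, y, k_folds = n_folds, seed = seed, config = cfg,
                         allow_any_k = TRUE)
    cv$mean_accuracy
  }, numeric(1))
  grid[which.max(acc)]  # which.max takes the first maximum: smallest k wins ties
}

#' Cross-validate the per-item score predictor
#'
#' Partitions the records into `k_folds` folds (stratified by class whenever
#' every class has at least `k_folds` members, plain random otherwise); each
#' fold serves once as test data while a model is trained on the remainder
#' with minority oversampling applied to the training fold only. Fold
#' accuracy is the fraction of test records whose predicted score agrees
#' exactly with the therapist's.
#'
#' @param X,y Labeled feature matrix for one item.
#' @param k_folds Number of folds, 8--10 (default 10).
#' @param seed Integer seed (fold assignment, balancing, network init).
#' @param config A [score_model_config()].
#' @param allow_any_k Permit fold counts outside 8--10 (for inner loops).
#' @return A `cv_report`: fold assignment, per-fold and mean accuracy, 3x3
#'   confusion counts, and the out-of-fold prediction for every record.
#' @export
cross_validate <- function(X, y, k_folds = 10L, seed = 1L,
                           config = score_model_config(),
                           allow_any_k = FALSE) {
  X <- as.matrix(X)
  y <- factor(y, levels = 0:2)
  n <- nrow(X)
  if (!allow_any_k && (k_folds < 8L || k_folds > 10L)) {
    stop("k_folds must lie in [8, 10] (set allow_any_k = TRUE to override)")
  }
  if (n < k_folds) stop("need at least k_folds = ", k_folds, " records")
  counts <- table(droplevels(y))
  stratified <- all(counts >= k_folds)
  fold <- integer(n)
  with_seed(seed, {
    if (stratified) {
      for (cl in names(counts)) {
        rows <- which(y == cl)
        fold[rows] <- sample(rep_len(seq_len(k_folds), length(rows)))
      }
    } else {
      fold <- sample(rep_len(seq_len(k_folds), n))
    }
  })
  pred <- integer(n)
  fold_acc <- numeric(k_folds)
  for (f in seq_len(k_folds)) {
    test <- fold == f
    model <- train_item_model(X[!test, , drop = FALSE], y[!test],
                              config = config, seed = seed + f,
                              balance = TRUE)
    pred[test] <- predict_item_score(model, X[test, , drop = FALSE])
    fold_acc[f] <- mean(pred[test] == as.integer(as.character(y[test])))
  }
  structure(list(k_folds = as.integer(k_folds), fold = fold,
                 predictions = pred, labels = as.integer(as.character(y)),
                 per_fold_accuracy = fold_acc,
                 mean_accuracy = mean(fold_acc),
                 confusion = table(factor(as.integer(as.character(y)), 0:2),
                                   factor(pred, 0:2),
                                   dnn = c("real", "predicted")),
                 stratified = stratified, seed = seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d-fold%s, mean accuracy %.1f%%\n", x$k_folds,
              if (x$stratified) " (stratified)" else "",
              100 * x$mean_accuracy))
  invisible(x)
}

#' Sum the 13 item scores
#'
#' @param scores Exactly 13 scores, each in \{0, 1, 2\}.
#' @return Integer sum in \[0, 26\].
#' @export
summed_score <- function(scores) {
  if (length(scores) != 13L) {
    stop("expected exactly 13 item scores, got ", length(scores))
  }
  if (!all(scores %in% 0:2)) stop("item scores must be 0, 1 or 2")
  as.integer(sum(scores))
}

#' Cohort-level validity statistics
#'
#' Computes the headline agreement statistics between predicted and therapist
#' scoring, and the smoothness contrasts: Pearson correlation of the
#' predicted 13-item sum against the therapist 13-item sum and against the
#' full 33-item total; a paired t-test of log-jerk between hemiplegic and
#' non-hemiplegic arms; and Spearman correlation between the hemiplegic
#' log-jerk and the Brunnstrom arm stage restricted to stages 3--6.
#'
#' @param predicted data.frame with `subject_id` and either
#'   `predicted_sum_13` or the 13 predicted `score_<item>` columns.
#' @param cohort A [cohort_table()].
#' @param jerk data.frame with `subject_id`, `log_jerk_hemiplegic`,
#'   `log_jerk_nonhemiplegic`.
#' @return List of class `cohort_evaluation`; unmatched subjects are listed
#'   in `$excluded` and dropped with a warning.
#' @export
evaluate_cohort <- function(predicted, cohort, jerk) {
  stopifnot(inherits(cohort, "cohort_table"))
  score_cols <- paste0("score_", fma_items())
  predicted <- as.data.frame(predicted)
  if (!"predicted_sum_13" %in% names(predicted)) {
    if (!all(score_cols %in% names(predicted))) {
      stop("predicted needs 'predicted_sum_13' or all 13 score_<item> columns")
    }
    predicted$predicted_sum_13 <- apply(predicted[score_cols], 1L, summed_score)
  }
  d <- merge(cohort$data, predicted[c("subject_id", "predicted_sum_13")],
             by = "subject_id")
  d <- merge(d, jerk, by = "subject_id")
  excluded <- setdiff(cohort$data$subject_id, d$subject_id)
  if (length(excluded) > 0L) {
    warning("excluding ", length(excluded),
            " subject(s) without matching predictions/jerk: ",
            paste(utils::head(excluded, 5L), collapse = ", "))
  }
  p13 <- stats::cor.test(d$predicted_sum_13, d$sum_13, method = "pearson")
  ptot <- stats::cor.test(d$predicted_sum_13, d$total_33, method = "pearson")
  tt <- stats::t.test(d$log_jerk_hemiplegic, d$log_jerk_nonhemiplegic,
                      paired = TRUE)
  sub <- d[d$brunnstrom_stage %in% 3:6, ]
  sp <- stats::cor.test(sub$log_jerk_hemiplegic, sub$brunnstrom_stage,
                        method = "spearman", exact = FALSE)
  structure(list(
    n = nrow(d), excluded = excluded,
    pearson_sum13 = unname(p13$estimate), pearson_sum13_p = p13$p.value,
    pearson_total = unname(ptot$estimate), pearson_total_p = ptot$p.value,
    log_jerk_hemiplegic_mean = mean(d$log_jerk_hemiplegic),
    log_jerk_hemiplegic_sd = stats::sd(d$log_jerk_hemiplegic),
    log_jerk_nonhemiplegic_mean = mean(d$log_jerk_nonhemiplegic),
    log_jerk_nonhemiplegic_sd = stats::sd(d$log_jerk_nonhemiplegic),
    paired_t = unname(tt$statistic), paired_t_p = tt$p.value,
    spearman_stage = unname(sp$estimate), spearman_stage_p = sp$p.value,
    n_stage_3_6 = nrow(sub)),
    class = "cohort_evaluation")
}

#' @export
print.cohort_evaluation <- function(x, ...) {
  cat(sprintf(paste0(
    "<cohort_evaluation> n=%d\n",
    "  Pearson r (pred vs 13-item sum):  %.3f (p=%.2g)\n",
    "  Pearson r (pred vs 33-item total): %.3f (p=%.2g)\n",
    "  log-jerk hemiplegic %.2f +/- %.2f vs non-hemiplegic %.2f +/- %.2f",
    " (paired t=%.2f, p=%.2g)\n",
    "  Spearman rho (log-jerk vs stage 3-6, n=%d): %.3f (p=%.2g)\n"),
    x$n, x$pearson_sum13, x$pearson_sum13_p, x$pearson_total, x$pearson_total_p,
    x$log_jerk_hemiplegic_mean, x$log_jerk_hemiplegic_sd,
    x$log_jerk_nonhemiplegic_mean, x$log_jerk_nonhemiplegic_sd,
    x$paired_t, x$paired_t_p, x$n_stage_3_6, x$spearman_stage,
    x$spearman_stage_p))
  invisible(x)
}

# evaluate `expr` under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}
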