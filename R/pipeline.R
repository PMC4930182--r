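#' Preprocess and featurize a set of recordings, per item
#'
#' Runs [preprocess_recording()] and [extract_features()] over the
#' hemiplegic-arm recordings of a [synth_cohort()] result (or any equally
#' shaped list + index), grouping rows by item.
#'
#' @param sim A [synth_cohort()] result, or a list with `$recordings` and
#'   `$index` in the same shape.
#' @param items Items to featurize (default: all present).
#' @return Named list per item: `$X` (feature matrix), `$y` (scores),
#'   `$subject_id`.
#' @export
pipeline_features <- function(sim, items = NULL) {
  idx <- sim$index[sim$index$role == "hemiplegic", ]
  items <- items %||% unique(idx$item)
  out <- list()
  for (it in items) {
    rows <- idx[idx$item == it, ]
    fvs <- lapply(rows$name, function(nm) {
      extract_features(preprocess_recording(sim$recordings[[nm]])$recording,
                       item = it)
    })
    out[[it]] <- list(X = feature_matrix(fvs), y = rows$score,
                      subject_id = rows$subject_id)
  }
  out
}

#' Per-subject smoothness statistics from paired recordings
#'
#' Computes the log normalized jerk of the flexor-synergy motion for each
#' subject's hemiplegic and non-hemiplegic arm, from the clipped,
#' pose-normalized recordings.
#'
#' @param sim A [synth_cohort()] result.
#' @param item Item used for the smoothness analysis (default
#'   `"elbow_flexion"`, the flexor-synergy reach).
#' @return data.frame: `subject_id`, `log_jerk_hemiplegic`,
#'   `log_jerk_nonhemiplegic`.
#' @export
pipeline_jerk <- function(sim, item = "elbow_flexion") {
  idx <- sim$index[sim$index$item == item, ]
  one <- function(role) {
    rows <- idx[idx$role == role, ]
    lj <- vapply(rows$name, function(nm) {
      normalized_jerk(preprocess_recording(sim$recordings[[nm]])$recording)$log_jerk
    }, numeric(1))
    data.frame(subject_id = rows$subject_id, log_jerk = lj)
  }
  h <- one("hemiplegic")
  nh <- one("nonhemiplegic")
  names(h)[2L] <- "log_jerk_hemiplegic"
  names(nh)[2L] <- "log_jerk_nonhemiplegic"
  merge(h, nh, by = "subject_id")
}

#' Cross-validate every item and assemble per-subject predicted sums
#'
#' Runs [cross_validate()] on each item's feature matrix and collects the
#' out-of-fold predicted score of every subject, summed over items into the
#' predicted 13-item score.
#'
#' @param feats A [pipeline_features()] result covering all 13 items.
#' @param k_folds,seed,config Passed to [cross_validate()].
#' @return List: `$cv` (per-item `cv_report`s), `$predicted` (data.frame of
#'   `subject_id`, predicted `score_<item>` columns, `predicted_sum_13`),
#'   `$mean_accuracy_by_item`.
#' @export
score_cohort_cv <- function(feats, k_folds = 10L, seed = 1L,
                            config = score_model_config()) {
  cvs <- list()
  pred_cols <- list()
  subjects <- feats[[1L]]$subject_id
  for (it in names(feats)) {
    f <- feats[[it]]
    cv <- cross_validate(f$X, f$y, k_folds = k_folds, seed = seed,
                         config = config)
    cvs[[it]] <- cv
    pred_cols[[paste0("score_", it)]] <-
      cv$predictions[match(subjects, f$subject_id)]
  }
  predicted <- data.frame(subject_id = subjects, pred_cols,
                          check.names = FALSE)
  if (length(feats) == 13L) {
    predicted$predicted_sum_13 <- apply(
      predicted[paste0("score_", names(feats))], 1L, summed_score)
  }
  list(cv = cvs,
       predicted = predicted,
       mean_accuracy_by_item = vapply(cvs, `[[`, numeric(1), "mean_accuracy"))
}

#' Run the full synthetic validation study
#'
#' End-to-end driver: generate a synthetic cohort, preprocess and featurize
#' all recordings, cross-validate the 13 per-item score predictors, compute
#' per-subject smoothness pairs, and evaluate cohort-level statistics.
#'
#' @param n_per_class Subjects per score class (cohort size is 3x this).
#' @param seed Integer seed controlling generation, folds and training.
#' @param k_folds Cross-validation folds (default 10).
#' @param config A [score_model_config()].
#' @return List: `$sim`, `$feats`, `$scored` ([score_cohort_cv()] result),
#'   `$jerk`, `$evaluation` ([evaluate_cohort()] result).
#' @export
run_validation_study <- function(n_per_class, seed = 1L, k_folds = 10L,
                                 config = score_model_config()) {
  sim <- synth_cohort(n_per_class, seed = seed)
  feats <- pipeline_features(sim)
  scored <- score_cohort_cv(feats, k_folds = k_folds, seed = seed,
                            config = config)
  jerk <- pipeline_jerk(sim)
  evaluation <- evaluate_cohort(scored$predicted, sim$cohort, jerk)
  list(sim = sim, feats = feats, scored = scored, jerk = jerk,
       evaluation = evaluation)
}
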