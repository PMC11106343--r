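#' Experiment plan for cross-validated decoding
#'
#' Names one train-task/test-task condition.  The three study conditions are
#' overt->overt and covert->covert (in-sample: same speech for training and
#' testing) and overt->covert (out-of-sample transfer).  A shuffle-control
#' plan trains on temporally shuffled features to establish the chance floor.
#'
#' @param train_task,test_task `"overt"` or `"covert"`.
#' @param architecture `"transformer"` or `"blstm"`.
#' @param shuffle_control Train on time-shuffled features (test features are
#'   left intact).
#' @param folds Cross-validation folds (default 5).
#' @param repeats Independently seeded trainings per fold (default 10).
#' @return An object of class `experiment_plan`.
#' @export
experiment_plan <- function(train_task = c("overt", "covert"),
                            test_task = c("overt", "covert"),
                            architecture = c("transformer", "blstm"),
                            shuffle_control = FALSE, folds = 5L,
                            repeats = 10L) {
  structure(list(train_task = match.arg(train_task),
                 test_task = match.arg(test_task),
                 architecture = match.arg(architecture),
                 shuffle_control = shuffle_control,
                 folds = as.integer(folds), repeats = as.integer(repeats)),
            class = "experiment_plan")
}

plan_label <- function(plan) {
  paste0(plan$train_task, "->", plan$test_task,
         if (plan$shuffle_control) " (shuffle)" else "",
         if (plan$architecture != "transformer")
           paste0(" [", plan$architecture, "]") else "")
}

# Sentence-stratified fold assignment: within each sentence the trials are
# shuffled (seeded) and dealt round-robin, so an 80-trial schedule yields
# 5 folds of 16 trials holding 2 of each sentence.
make_folds <- function(schedule, n_folds, seed = 1L) {
  fold <- integer(schedule$n_trials)
  assign_one <- local_rng(seed, {
    for (s in unique(schedule$sentence)) {
      idx <- which(schedule$sentence == s)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
    fold
  })
  assign_one
}

#' Run a cross-validated decoding experiment
#'
#' Executes one [experiment_plan()]: sentence-stratified trial folds, per fold
#' `repeats` independently seeded trainings of [ecog_decoder()] on the
#' training task's pairs, and greedy decoding of every held-out test-task
#' segment by every repeat's model.  With 80 trials, 5 folds and 10 repeats
#' this yields 800 decode results (10 models x 5 folds x 16 test sentences).
#' Splits are by trial, so a trial is never simultaneously in training and
#' test (violations raise a hard error); per-segment z-scoring means no
#' normalization statistics cross the fold boundary.
#'
#' @param plan An [experiment_plan()].
#' @param dataset A [synth_dataset()] (or compatible recorded dataset).
#' @param features Precomputed [extract_features()] list covering the plan's
#'   train and test tasks; computed on the fly when NULL.
#' @param config A [model_config()] (architecture is taken from the plan).
#' @param control A [train_config()]; repeat seeds are derived from
#'   `control$seed`, the fold and the repeat index, so the whole experiment is
#'   reproducible.
#' @param keep_models Retain the trained model of the first repeat of each
#'   fold (needed for saliency analysis).
#' @param verbose Print per-fold progress.
#' @return An object of class `decode_cv`: list with `results` (one entry per
#'   model x fold x test segment: reference, hypothesis, condition, fold,
#'   repeat_id, trial), `fold_assignment`, `plan`, and `models` (when kept).
#' @export
run_cv <- function(plan, dataset, features = NULL, config = model_config(),
                   control = train_config(), keep_models = FALSE,
                   verbose = FALSE) {
  stopifnot(inherits(plan, "experiment_plan"))
  config$architecture <- plan$architecture
  tasks <- unique(c(plan$train_task, plan$test_task))
  if (is.null(features))
    features <- extract_features(dataset, tasks = unique(c(tasks, "perception")))
  pairing <- if (plan$train_task == "overt") "overt_model" else "covert_model"
  pairs <- pair_for_training(dataset, features, pairing)
  n_trials <- dataset$schedule$n_trials
  fold_of <- make_folds(dataset$schedule, plan$folds, control$seed)
  results <- list()
  models <- list()
  for (fold in seq_len(plan$folds)) {
    test_trials <- which(fold_of == fold)
    train_trials <- which(fold_of != fold)
    if (length(intersect(train_trials, test_trials)) > 0L)
      stop("fold leakage: trial in both train and test", call. = FALSE)
    train_pairs <- pairs[train_trials]
    if (plan$shuffle_control) {
      for (k in seq_along(train_pairs)) {
        train_pairs[[k]]$features <- shuffle_features(
          train_pairs[[k]]$features,
          seed = control$seed + 7919L * fold + train_pairs[[k]]$trial)
      }
    }
    test_feats <- lapply(test_trials, function(tr) {
      f <- features[[paste0(tr, "_", plan$test_task)]]
      if (is.null(f)) stop("missing ", plan$test_task,
                           " features for trial ", tr, call. = FALSE)
      unclass(f)[, , drop = FALSE]
    })
    refs <- lapply(test_trials, function(tr)
      dataset$sentences[[dataset$schedule$sentence[tr]]]$tokens)
    for (rep_i in seq_len(plan$repeats)) {
      ctl <- control
      ctl$seed <- control$seed + 1009L * fold + rep_i
      model <- ecog_decoder(train_pairs, config, ctl)
      if (keep_models && rep_i == 1L) models[[fold]] <- model
      for (s in seq_along(test_trials)) {
        hyp <- decode_greedy(model, test_feats[[s]])
        results[[length(results) + 1L]] <- list(
          reference = refs[[s]], hypothesis = as.integer(hyp),
          condition = plan_label(plan), fold = fold, repeat_id = rep_i,
          trial = test_trials[s])
      }
      if (verbose) {
        fold_ter <- mean(vapply(utils::tail(results, length(test_trials)),
                                function(r) ter(r$reference, r$hypothesis)$ter,
                                numeric(1)))
        message(sprintf("fold %d repeat %d: TER %.1f%%", fold, rep_i, fold_ter))
      }
    }
  }
  structure(list(results = results, fold_assignment = fold_of, plan = plan,
                 models = if (keep_models) models else NULL),
            class = "decode_cv")
}

#' @export
print.decode_cv <- function(x, ...) {
  rep <- aggregate_ter(x$results)
  cat(sprintf("Cross-validated decoding [%s]: %d folds x %d repeats, %d decodes\n",
              plan_label(x$plan), x$plan$folds, x$plan$repeats,
              length(x$results)))
  print(rep$summary, row.names = FALSE)
  invisible(x)
}
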