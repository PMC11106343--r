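#' Scaled synthetic recovery study
#'
#' Runs the package's end-to-end verification study on one synthetic
#' participant-surrogate: generate a session with planted token codes,
#' extract high-gamma features, train Transformer decoders under
#' cross-validation for the three study conditions (overt->overt,
#' covert->covert, overt->covert via the overt-trained models) plus a
#' temporal-shuffle control, score everything by token error rate, and
#' compute saliency-based electrode contributions for comparison against the
#' planted ground truth.
#'
#' The default problem size (32 electrodes, 80 trials, 2 folds, 1 repeat,
#' 100 epochs, 10 dB planted SNR, covert gain 0.7, full electrode overlap)
#' is the package's desk-scale recovery condition: large enough that a
#' successful pipeline decodes well above chance in-sample and transfers
#' overt -> covert, small enough to run on one CPU core in minutes.
#'
#' @param seed Integer master seed for the data, folds and trainings.
#' @param n_trials Trials per task (multiple of 8).
#' @param folds,repeats Cross-validation shape.
#' @param epochs Training epochs per model.
#' @param n_electrodes,snr_db,covert_gain,alpha Generator settings (see
#'   [synth_config()]).
#' @param max_saliency_maps Cap on saliency maps averaged for the electrode
#'   contribution score.
#' @param verbose Progress messages.
#' @return A list with per-condition mean TERs (`ter_overt_overt`,
#'   `ter_covert_covert`, `ter_overt_covert`, `ter_shuffle`), the constant-guess
#'   chance level and the 95% interval half-width implied by the number of
#'   shuffle decodes, `saliency_rho` (Spearman correlation of electrode
#'   contributions with planted informativeness), decode counts, and the raw
#'   `decode_cv` objects.
#' @export
run_recovery_study <- function(seed = 1L, n_trials = 80L, folds = 2L,
                               repeats = 1L, epochs = 100L,
                               n_electrodes = 32L, snr_db = 10,
                               covert_gain = 0.7, alpha = 1,
                               max_saliency_maps = 40L, verbose = FALSE) {
  seed <- as.integer(seed) %% 1000000L
  cfg <- synth_config(n_electrodes = n_electrodes, snr_db = snr_db,
                      covert_gain = covert_gain, alpha = alpha, seed = seed)
  sch <- make_schedule(n_trials, seed = seed)
  ds <- synth_dataset(cfg, sch)
  feats <- extract_features(ds, tasks = c("overt", "covert"))
  ds$recordings <- NULL   # raw signals are no longer needed; free the memory
  mcfg <- model_config(n_electrodes = n_electrodes)
  ctl <- train_config(epochs = epochs, seed = seed)

  cv_oo <- run_cv(experiment_plan("overt", "overt", folds = folds,
                                  repeats = repeats),
                  ds, feats, mcfg, ctl, keep_models = TRUE, verbose = verbose)
  # overt -> covert reuses the overt-trained fold models on covert test data
  res_oc <- list()
  for (fold in seq_len(folds)) {
    model <- cv_oo$models[[fold]]
    for (tr in which(cv_oo$fold_assignment == fold)) {
      f <- unclass(feats[[paste0(tr, "_covert")]])[, , drop = FALSE]
      res_oc[[length(res_oc) + 1L]] <- list(
        reference = ds$sentences[[sch$sentence[tr]]]$tokens,
        hypothesis = as.integer(decode_greedy(model, f)),
        condition = "overt->covert", fold = fold, repeat_id = 1L, trial = tr)
    }
  }
  cv_cc <- run_cv(experiment_plan("covert", "covert", folds = folds,
                                  repeats = repeats),
                  ds, feats, mcfg, ctl, verbose = verbose)
  cv_sh <- run_cv(experiment_plan("covert", "covert", shuffle_control = TRUE,
                                  folds = folds, repeats = repeats),
                  ds, feats, mcfg, ctl, verbose = verbose)

  contrib <- cv_electrode_contribution(cv_oo, ds, feats,
                                       max_maps = max_saliency_maps)
  rho <- stats::cor(contrib$mean_z, ds$ground_truth$informativeness,
                    method = "spearman")

  n_sh <- length(cv_sh$results)
  # constant-guess chance: three independent binary slots, 50% each; the 95%
  # band reflects binomial noise over 3 * n scored slots
  chance <- 50
  half_width <- 100 * 1.96 * sqrt(0.25 / (3 * n_sh))
  list(
    ter_overt_overt = aggregate_ter(cv_oo$results)$summary$mean_ter,
    ter_covert_covert = aggregate_ter(cv_cc$results)$summary$mean_ter,
    ter_overt_covert = aggregate_ter(res_oc)$summary$mean_ter,
    ter_shuffle = aggregate_ter(cv_sh$results)$summary$mean_ter,
    chance_level = chance, chance_half_width = half_width,
    saliency_rho = unname(rho),
    n_decodes = length(cv_oo$results),
    contrib = contrib,
    cv = list(overt_overt = cv_oo, covert_covert = cv_cc, shuffle = cv_sh,
              overt_covert = res_oc),
    dataset_truth = ds$ground_truth$informativeness)
}
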