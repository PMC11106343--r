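#' Gradient saliency map for one decode
#'
#' Computes the absolute gradient of the summed log-probability of a token
#' sequence with respect to every input feature value (time point x
#' electrode).  The map has exactly the shape of the input feature segment.
#' By default the differentiated scalar uses the teacher-forced reference
#' tokens; passing `target = NULL` differentiates the model's own greedy
#' hypothesis instead.  Dropout is inactive (inference mode).
#'
#' @param model A fitted [ecog_decoder()].
#' @param features L x K feature matrix.
#' @param target Reference token sequence `c(6, t1, t2, t3, 7)`, or NULL to
#'   use the decoded hypothesis.
#' @return An L x K matrix of absolute gradients.
#' @export
saliency_map <- function(model, features, target = NULL) {
  features <- unclass(features)[, , drop = FALSE]
  if (is.null(target)) {
    hyp <- decode_greedy(model, features)
    target <- c(6L, as.integer(hyp))
    if (target[length(target)] != 7L) target <- c(target, 7L)
  }
  tp <- ad_tape()
  pn <- push_params(tp, model$params)
  fwd <- forward_segment(tp, pn, model$config, features, target,
                         training = FALSE)
  score <- ad_logprob_sum(fwd$logits, fwd$targets)
  grads <- ad_backward(score)
  g <- grads[[fwd$input$id]]
  if (is.null(g)) g <- matrix(0, nrow(features), ncol(features))
  abs(g)
}

#' Per-electrode contribution scores from saliency maps
#'
#' For each map the saliency variance along the time axis is computed per
#' electrode, z-scored across electrodes (normalizing scale within the trial),
#' and the per-trial z-scores are averaged across all maps.  Scores are
#' scale-free (multiplying one map by a positive constant leaves its z-scores
#' unchanged) and equivariant under electrode relabeling.
#'
#' @param maps A list of saliency maps (equal column counts), or one matrix.
#' @return An object of class `electrode_contribution`: data.frame with
#'   columns `electrode_id`, `mean_z`, `n_maps`.
#' @export
electrode_contribution <- function(maps) {
  if (is.matrix(maps)) maps <- list(maps)
  if (length(maps) == 0L) stop("no saliency maps", call. = FALSE)
  K <- ncol(maps[[1L]])
  if (K < 2L)
    stop("z-scoring across electrodes needs at least 2 electrodes",
         call. = FALSE)
  zs <- vapply(maps, function(m) {
    stopifnot(ncol(m) == K)
    v <- apply(m, 2L, stats::var)
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0)
      stop("degenerate saliency map: zero variance across electrodes",
           call. = FALSE)
    (v - mean(v)) / s
  }, numeric(K))
  out <- data.frame(electrode_id = seq_len(K),
                    mean_z = rowMeans(matrix(zs, nrow = K)),
                    n_maps = length(maps))
  class(out) <- c("electrode_contribution", "data.frame")
  out
}

#' Electrode contributions for a cross-validated experiment
#'
#' Convenience wrapper: computes teacher-forced saliency maps for every decode
#' result produced by the kept fold models of a [run_cv()] run and averages
#' their per-trial z-scored time-variances into one score per electrode.
#'
#' @param cv A `decode_cv` object from [run_cv()] with `keep_models = TRUE`.
#' @param dataset The dataset the experiment ran on.
#' @param features The [extract_features()] list used for the experiment.
#' @param max_maps Optional cap on the number of maps (first `max_maps`
#'   results) to bound compute.
#' @return An `electrode_contribution` data.frame.
#' @export
cv_electrode_contribution <- function(cv, dataset, features, max_maps = Inf) {
  if (is.null(cv$models))
    stop("run_cv must be called with keep_models = TRUE", call. = FALSE)
  maps <- list()
  for (r in cv$results) {
    if (r$repeat_id != 1L) next
    if (length(maps) >= max_maps) break
    model <- cv$models[[r$fold]]
    f <- features[[paste0(r$trial, "_", cv$plan$test_task)]]
    maps[[length(maps) + 1L]] <- saliency_map(model, f, target = r$reference)
  }
  electrode_contribution(maps)
}

#' Write electrode contribution scores as CSV
#'
#' @param contrib An `electrode_contribution` data.frame.
#' @param path Output CSV path (columns electrode_id, mean_z, n_maps).
#' @return `path`, invisibly.
#' @export
write_contribution_csv <- function(contrib, path) {
  utils::write.csv(contrib, path, row.names = FALSE)
  invisible(path)
}
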