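#' Training configuration
#'
#' Defaults follow the published training recipe: Adam at learning rate
#' 0.0005, MFCC-penalty weight lambda = 0.1, batch size 16 and 800 training
#' epochs, with no early stopping or schedule.  `epochs` is exposed so tests
#' and scaled-down runs can shorten training.
#'
#' @param learning_rate Adam step size.
#' @param mfcc_lambda Weight of the MFCC mean-squared-error term in the loss.
#' @param batch_size Segments per gradient step.
#' @param epochs Number of passes over the training pairs.
#' @param seed Integer seed controlling initialization, data order and dropout.
#' @param clip_norm Global gradient-norm clip (numerical safeguard; `Inf`
#'   disables).
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 5e-4, mfcc_lambda = 0.1,
                         batch_size = 16L, epochs = 800L, seed = 1L,
                         clip_norm = 5) {
  if (mfcc_lambda < 0) stop("mfcc_lambda must be >= 0", call. = FALSE)
  structure(list(learning_rate = learning_rate, mfcc_lambda = mfcc_lambda,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 clip_norm = clip_norm, optimizer = "adam"),
            class = "train_config")
}

#' Dual training loss
#'
#' The scalar the network is trained on: categorical cross-entropy between the
#' decoder logits and the reference token sequence, plus `lambda` times the
#' mean squared error between the encoder's MFCC head output and the reference
#' MFCCs.  Both terms are also returned separately.
#'
#' @param logits M x vocab matrix of decoder output scores.
#' @param targets Integer 0-based reference token ids, length M.
#' @param mfcc_pred,mfcc_target N x 13 matrices (may both be NULL to drop the
#'   auxiliary term).
#' @param lambda MFCC-penalty weight (default 0.1).
#' @return Scalar loss with attributes `ce` and `mse`.
#' @examples
#' lg <- matrix(c(2, 0, 0, 2), 2, 2)  # 2-class, 2-position toy case
#' decoder_loss(lg, c(0, 1), lambda = 0)
#' @export
decoder_loss <- function(logits, targets, mfcc_pred = NULL, mfcc_target = NULL,
                         lambda = 0.1) {
  if (anyNA(logits) || (!is.null(mfcc_pred) && anyNA(mfcc_pred)))
    stop("NaN/NA in loss inputs", call. = FALSE)
  stopifnot(nrow(logits) == length(targets))
  P <- softmax_rows(logits)
  ce <- -mean(log(pmax(P[cbind(seq_len(nrow(P)), as.integer(targets) + 1L)],
                       1e-12)))
  mse <- if (is.null(mfcc_pred)) 0 else {
    stopifnot(!is.null(mfcc_target), all(dim(mfcc_pred) == dim(mfcc_target)))
    mean((mfcc_pred - mfcc_target)^2)
  }
  structure(ce + lambda * mse, ce = ce, mse = mse)
}

#' Temporal shuffle control
#'
#' Permutes the time frames of a feature segment with a seeded permutation,
#' independently of other segments.  The electrode axis and each electrode's
#' marginal value distribution are untouched; only temporal structure is
#' destroyed.  Models trained on shuffled features provide the chance floor.
#'
#' @param features L x K feature matrix.
#' @param seed Integer seed for the permutation.
#' @return The row-permuted matrix.
#' @export
shuffle_features <- function(features, seed) {
  perm <- local_rng(seed, sample.int(nrow(features)))
  features[perm, , drop = FALSE]
}

adam_new <- function(params, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0L,
       m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0))
}

adam_step <- function(opt, params, grads) {
  opt$t <- opt$t + 1L
  # bias correction folded into the step size (epsilon on the corrected scale)
  lr_t <- opt$lr * sqrt(1 - opt$beta2^opt$t) / (1 - opt$beta1^opt$t)
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    m <- opt$beta1 * opt$m[[nm]] + (1 - opt$beta1) * g
    v <- opt$beta2 * opt$v[[nm]] + (1 - opt$beta2) * (g * g)
    opt$m[[nm]] <- m
    opt$v[[nm]] <- v
    params[[nm]] <- params[[nm]] - lr_t * m / (sqrt(v) + opt$eps)
  }
  list(opt = opt, params = params)
}

#' Fit a sequence-to-sequence sentence decoder to ECoG features
#'
#' Trains the temporal-convolution + encoder-decoder network on a list of
#' training pairs under teacher forcing, minimizing token cross-entropy plus
#' the auxiliary MFCC regression term (see [decoder_loss()]).  The MFCC head
#' regularizes the encoder during training only; decoding bypasses it.
#'
#' @param pairs A list of training pairs; each pair is a list with `features`
#'   (L x K matrix of z-scored high-gamma envelopes at 200 Hz), `tokens`
#'   (integer sequence `c(6, t1, t2, t3, 7)`) and optionally `mfcc` (N x 13
#'   MFCC target aligned to the encoder time axis, N = ceil(L / 12)).
#' @param config A [model_config()]; `n_electrodes` is inferred from the data
#'   when NA.
#' @param control A [train_config()].
#' @param verbose Print per-epoch losses.
#' @return An object of class `ecog_decoder`: list with `params` (named weight
#'   matrices), `config`, `control`, `history` (per-epoch data.frame of ce,
#'   mse, loss) and `n_train`.
#' @seealso [decode_greedy()], [predict.ecog_decoder()], [run_cv()]
#' @export
ecog_decoder <- function(pairs, config = model_config(),
                         control = train_config(), verbose = FALSE) {
  if (length(pairs) == 0L) stop("no training pairs", call. = FALSE)
  K <- ncol(pairs[[1L]]$features)
  L <- nrow(pairs[[1L]]$features)
  for (p in pairs) {
    if (ncol(p$features) != K)
      stop("all pairs must have the same electrode count", call. = FALSE)
    if (nrow(p$features) != L)
      stop("all pairs must have equal segment length (trim to the maximum ",
           "sentence duration first)", call. = FALSE)
    if (length(p$tokens) < 2L)
      stop("token sequences must contain start and end markers", call. = FALSE)
  }
  if (is.na(config$n_electrodes)) config$n_electrodes <- K
  has_mfcc <- !is.null(pairs[[1L]]$mfcc) && control$mfcc_lambda > 0
  n <- length(pairs)
  t0 <- proc.time()[3L]
  fit <- local_rng(control$seed, {
    params <- init_params(config)
    opt <- adam_new(params, control$learning_rate)
    history <- data.frame(epoch = seq_len(control$epochs),
                          ce = rep(NA_real_, control$epochs),
                          mse = rep(NA_real_, control$epochs),
                          loss = rep(NA_real_, control$epochs))
    for (epoch in seq_len(control$epochs)) {
      ord <- sample.int(n)
      ep_ce <- ep_mse <- 0
      starts <- seq(1L, n, by = control$batch_size)
      for (bs in starts) {
        idx <- ord[bs:min(bs + control$batch_size - 1L, n)]
        tp <- ad_tape()
        pn <- push_params(tp, params)
        fwd <- forward_batch(tp, pn, config, pairs[idx],
                             if (has_mfcc) control$mfcc_lambda else 0,
                             training = TRUE)
        ep_ce <- ep_ce + fwd$ce * length(idx)
        if (has_mfcc) ep_mse <- ep_mse + fwd$mse * length(idx)
        grads_all <- ad_backward(fwd$loss)
        grads <- lapply(pn, function(node) grads_all[[node$id]])
        if (is.finite(control$clip_norm)) {
          gn <- sqrt(sum(vapply(grads, function(g)
            if (is.null(g)) 0 else sum(g^2), numeric(1))))
          if (gn > control$clip_norm)
            grads <- lapply(grads, function(g)
              if (is.null(g)) NULL else g * (control$clip_norm / gn))
        }
        st <- adam_step(opt, params, grads)
        opt <- st$opt; params <- st$params
      }
      history$ce[epoch] <- ep_ce / n
      history$mse[epoch] <- if (has_mfcc) ep_mse / n else NA_real_
      history$loss[epoch] <- history$ce[epoch] +
        if (has_mfcc) control$mfcc_lambda * history$mse[epoch] else 0
      if (verbose)
        message(sprintf("epoch %d: ce=%.4f mse=%s", epoch, history$ce[epoch],
                        format(history$mse[epoch], digits = 4)))
    }
    list(params = params, history = history)
  })
  structure(list(params = fit$params, config = config, control = control,
                 history = fit$history, n_train = n,
                 elapsed = unname(proc.time()[3L] - t0)),
            class = "ecog_decoder")
}

#' @export
print.ecog_decoder <- function(x, ...) {
  cat(sprintf("ECoG sentence decoder (%s): K=%d electrodes, %s parameters\n",
              x$config$architecture, x$config$n_electrodes,
              format(count_params(x$params), big.mark = ",")))
  cat(sprintf("trained %d epochs on %d segments; final loss %.4f (ce %.4f)\n",
              x$control$epochs, x$n_train,
              utils::tail(x$history$loss, 1), utils::tail(x$history$ce, 1)))
  invisible(x)
}

#' @export
summary.ecog_decoder <- function(object, ...) {
  cat("Architecture:", object$config$architecture, "\n")
  cat("Electrodes (K):", object$config$n_electrodes, "\n")
  cat("Parameters:", count_params(object$params), "\n")
  cat("Training:", object$control$epochs, "epochs, batch",
      object$control$batch_size, ", lr", object$control$learning_rate,
      ", lambda", object$control$mfcc_lambda, "\n")
  cat("Loss trajectory (first/last 3 epochs):\n")
  h <- object$history
  show <- unique(c(utils::head(seq_len(nrow(h)), 3), utils::tail(seq_len(nrow(h)), 3)))
  print(h[show, ], row.names = FALSE)
  invisible(object)
}

#' @export
coef.ecog_decoder <- function(object, ...) object$params

#' Decode token sequences from new feature segments
#'
#' @param object A fitted [ecog_decoder].
#' @param newdata A single L x K feature matrix or a list of them.
#' @param ... Passed to [decode_greedy()].
#' @return A list of decoded integer token vectors (a single vector when
#'   `newdata` is one matrix).
#' @export
predict.ecog_decoder <- function(object, newdata, ...) {
  if (is.matrix(newdata)) return(decode_greedy(object, newdata, ...))
  lapply(newdata, function(f) decode_greedy(object, f, ...))
}

#' @export
plot.ecog_decoder <- function(x, ...) {
  h <- x$history
  graphics::plot(h$epoch, h$loss, type = "l", xlab = "epoch", ylab = "loss",
                 main = "Training loss", ...)
  graphics::lines(h$epoch, h$ce, lty = 2)
  graphics::legend("topright", legend = c("total", "cross-entropy"),
                   lty = c(1, 2), bty = "n")
  invisible(x)
}
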