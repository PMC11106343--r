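#' Network configuration
#'
#' Hyperparameters of the decoding network.  Defaults are the published
#' architecture: a temporal convolution with 100 filters, kernel (12, K) and
#' stride (12, 1) with dropout 0.1; a 2-layer Transformer encoder (10 heads,
#' width 100, dropout 0.5) with a 13-unit MFCC regression head; a 1-layer
#' Transformer decoder (10 heads, width 500, token embedding dimension 500,
#' dropout 0.5) over an 8-token vocabulary.  `n_electrodes` (K) is set from the
#' data at fit time when `NA`.
#'
#' The feed-forward sub-layers use an inner width of `ff_mult` times the model
#' width (conventional 4x).  Sinusoidal positional encodings are added after
#' the convolution front end and after the token embedding; attention is
#' order-blind without them.
#'
#' @param architecture `"transformer"` (default) or `"blstm"` (bidirectional
#'   LSTM encoder + LSTM decoder baseline; same convolution front end, same
#'   heads, same losses, widths 100/500 mirroring the Transformer).
#' @param n_electrodes Number of input electrodes K (NA = infer from data).
#' @param conv_filters,conv_kernel,conv_stride,conv_dropout Temporal-conv
#'   front end (C = 100 filters; kernel width W = 12 time steps over all K
#'   electrodes; time stride W, so output length N = ceil(L / W)).
#' @param encoder_layers,encoder_heads,encoder_hidden,encoder_dropout
#'   Transformer encoder stack (X = 2 layers).
#' @param mfcc_units Width of the auxiliary MFCC head (13).
#' @param embed_dim Token embedding dimension (500).
#' @param decoder_layers,decoder_heads,decoder_hidden,decoder_dropout
#'   Transformer decoder stack (Y = 1 layer).
#' @param vocab_size Token vocabulary (8: six phrases + start + end).
#' @param ff_mult Feed-forward inner width multiplier.
#' @param max_target_len Maximum decoded length including the start token (5).
#' @return An object of class `model_config` (a list of the above).
#' @export
model_config <- function(architecture = c("transformer", "blstm"),
                         n_electrodes = NA_integer_,
                         conv_filters = 100L, conv_kernel = 12L,
                         conv_stride = 12L, conv_dropout = 0.1,
                         encoder_layers = 2L, encoder_heads = 10L,
                         encoder_hidden = 100L, encoder_dropout = 0.5,
                         mfcc_units = 13L, embed_dim = 500L,
                         decoder_layers = 1L, decoder_heads = 10L,
                         decoder_hidden = 500L, decoder_dropout = 0.5,
                         vocab_size = 8L, ff_mult = 4L,
                         max_target_len = 5L) {
  architecture <- match.arg(architecture)
  if (conv_kernel != conv_stride)
    stop("the front end uses non-overlapping windows: conv_kernel must equal conv_stride",
         call. = FALSE)
  if (encoder_hidden %% encoder_heads != 0L ||
      decoder_hidden %% decoder_heads != 0L)
    stop("attention width must be divisible by the head count", call. = FALSE)
  if (conv_filters != encoder_hidden)
    stop("encoder width must match the number of conv filters", call. = FALSE)
  structure(list(
    architecture = architecture, n_electrodes = as.integer(n_electrodes),
    conv_filters = as.integer(conv_filters),
    conv_kernel = as.integer(conv_kernel),
    conv_stride = as.integer(conv_stride), conv_dropout = conv_dropout,
    encoder_layers = as.integer(encoder_layers),
    encoder_heads = as.integer(encoder_heads),
    encoder_hidden = as.integer(encoder_hidden),
    encoder_dropout = encoder_dropout,
    mfcc_units = as.integer(mfcc_units), embed_dim = as.integer(embed_dim),
    decoder_layers = as.integer(decoder_layers),
    decoder_heads = as.integer(decoder_heads),
    decoder_hidden = as.integer(decoder_hidden),
    decoder_dropout = decoder_dropout,
    vocab_size = as.integer(vocab_size), ff_mult = as.integer(ff_mult),
    max_target_len = as.integer(max_target_len)), class = "model_config")
}

# Sinusoidal positional encoding (rows = positions, cols = model dims).
positional_encoding <- function(n, d) {
  pos <- seq_len(n) - 1L
  i <- seq_len(d) - 1L
  ang <- outer(pos, 10000^(-(i %/% 2L * 2L) / d))
  pe <- matrix(0, n, d)
  even <- (i %% 2L) == 0L
  pe[, even] <- sin(ang[, even, drop = FALSE])
  pe[, !even] <- cos(ang[, !even, drop = FALSE])
  pe
}

glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

zeros <- function(nin, nout) matrix(0, nin, nout)
ones_row <- function(d) matrix(1, 1L, d)

# Parameter matrices for either architecture, keyed by name.  Consumes the RNG
# (call under a seed for reproducible initialization).
init_params <- function(cfg) {
  K <- cfg$n_electrodes
  stopifnot(!is.na(K), K >= 1L)
  C <- cfg$encoder_hidden; Dd <- cfg$decoder_hidden
  p <- list(
    conv_w = glorot(cfg$conv_kernel * K, cfg$conv_filters),
    conv_b = zeros(1L, cfg$conv_filters),
    mfcc_w = glorot(C, cfg$mfcc_units),
    mfcc_b = zeros(1L, cfg$mfcc_units),
    embed = glorot(cfg$vocab_size, cfg$embed_dim),
    out_w = glorot(Dd, cfg$vocab_size),
    out_b = zeros(1L, cfg$vocab_size)
  )
  if (cfg$architecture == "transformer") {
    for (l in seq_len(cfg$encoder_layers)) {
      pre <- paste0("enc", l, "_")
      p[[paste0(pre, "wq")]] <- glorot(C, C)
      p[[paste0(pre, "wk")]] <- glorot(C, C)
      p[[paste0(pre, "wv")]] <- glorot(C, C)
      p[[paste0(pre, "wo")]] <- glorot(C, C)
      p[[paste0(pre, "ln1_g")]] <- ones_row(C)
      p[[paste0(pre, "ln1_b")]] <- zeros(1L, C)
      p[[paste0(pre, "ff_w1")]] <- glorot(C, cfg$ff_mult * C)
      p[[paste0(pre, "ff_b1")]] <- zeros(1L, cfg$ff_mult * C)
      p[[paste0(pre, "ff_w2")]] <- glorot(cfg$ff_mult * C, C)
      p[[paste0(pre, "ff_b2")]] <- zeros(1L, C)
      p[[paste0(pre, "ln2_g")]] <- ones_row(C)
      p[[paste0(pre, "ln2_b")]] <- zeros(1L, C)
    }
    for (l in seq_len(cfg$decoder_layers)) {
      pre <- paste0("dec", l, "_")
      p[[paste0(pre, "self_wq")]] <- glorot(Dd, Dd)
      p[[paste0(pre, "self_wk")]] <- glorot(Dd, Dd)
      p[[paste0(pre, "self_wv")]] <- glorot(Dd, Dd)
      p[[paste0(pre, "self_wo")]] <- glorot(Dd, Dd)
      p[[paste0(pre, "ln1_g")]] <- ones_row(Dd)
      p[[paste0(pre, "ln1_b")]] <- zeros(1L, Dd)
      p[[paste0(pre, "cross_wq")]] <- glorot(Dd, Dd)
      p[[paste0(pre, "cross_wk")]] <- glorot(C, Dd)
      p[[paste0(pre, "cross_wv")]] <- glorot(C, Dd)
      p[[paste0(pre, "cross_wo")]] <- glorot(Dd, Dd)
      p[[paste0(pre, "ln2_g")]] <- ones_row(Dd)
      p[[paste0(pre, "ln2_b")]] <- zeros(1L, Dd)
      p[[paste0(pre, "ff_w1")]] <- glorot(Dd, cfg$ff_mult * Dd)
      p[[paste0(pre, "ff_b1")]] <- zeros(1L, cfg$ff_mult * Dd)
      p[[paste0(pre, "ff_w2")]] <- glorot(cfg$ff_mult * Dd, Dd)
      p[[paste0(pre, "ff_b2")]] <- zeros(1L, Dd)
      p[[paste0(pre, "ln3_g")]] <- ones_row(Dd)
      p[[paste0(pre, "ln3_b")]] <- zeros(1L, Dd)
    }
  } else {  # blstm
    H <- C %/% 2L  # per-direction hidden width; concat gives encoder width C
    p$enc_fw_wx <- glorot(C, 4L * H); p$enc_fw_wh <- glorot(H, 4L * H)
    p$enc_fw_b <- zeros(1L, 4L * H)
    p$enc_bw_wx <- glorot(C, 4L * H); p$enc_bw_wh <- glorot(H, 4L * H)
    p$enc_bw_b <- zeros(1L, 4L * H)
    p$dec_h0_w <- glorot(C, Dd); p$dec_h0_b <- zeros(1L, Dd)
    p$dec_c0_w <- glorot(C, Dd); p$dec_c0_b <- zeros(1L, Dd)
    p$dec_wx <- glorot(cfg$embed_dim, 4L * Dd)
    p$dec_wh <- glorot(Dd, 4L * Dd)
    p$dec_b <- zeros(1L, 4L * Dd)
  }
  p
}

# Push every parameter matrix onto a tape, returning a named list of nodes.
push_params <- function(tp, params) {
  lapply(params, function(m) ad_node(tp, m))
}

# Encoder forward pass over `n_seg` stacked equal-length segments.  Returns
# list(input = input node, enc = encoder-output node ((n_seg*N) x C), mfcc =
# MFCC-head node ((n_seg*N) x 13)).
forward_encoder <- function(tp, pn, cfg, features, training = FALSE,
                            n_seg = 1L) {
  K <- ncol(features)
  if (K != cfg$n_electrodes)
    stop("feature matrix has ", K, " electrodes but the model expects ",
         cfg$n_electrodes, call. = FALSE)
  x <- ad_node(tp, features)
  h <- ad_conv_time(x, pn$conv_w, pn$conv_b, cfg$conv_kernel, n_seg = n_seg)
  n_out <- nrow(ad_value(h)) %/% n_seg
  pe <- positional_encoding(n_out, cfg$conv_filters)
  h <- ad_add_const(h, pe[rep(seq_len(n_out), n_seg), , drop = FALSE])
  h <- ad_dropout(h, cfg$conv_dropout, training)
  if (cfg$architecture == "transformer") {
    for (l in seq_len(cfg$encoder_layers)) {
      pre <- paste0("enc", l, "_")
      a <- ad_mha(h, h, pn[[paste0(pre, "wq")]], pn[[paste0(pre, "wk")]],
                  pn[[paste0(pre, "wv")]], pn[[paste0(pre, "wo")]],
                  cfg$encoder_heads, n_blocks = n_seg)
      h <- ad_layernorm(ad_add(h, ad_dropout(a, cfg$encoder_dropout, training)),
                        pn[[paste0(pre, "ln1_g")]], pn[[paste0(pre, "ln1_b")]])
      f <- ad_add_bias(ad_matmul(ad_relu(ad_add_bias(
             ad_matmul(h, pn[[paste0(pre, "ff_w1")]]),
             pn[[paste0(pre, "ff_b1")]])),
             pn[[paste0(pre, "ff_w2")]]), pn[[paste0(pre, "ff_b2")]])
      h <- ad_layernorm(ad_add(h, ad_dropout(f, cfg$encoder_dropout, training)),
                        pn[[paste0(pre, "ln2_g")]], pn[[paste0(pre, "ln2_b")]])
    }
  } else {
    fw <- ad_lstm(h, pn$enc_fw_wx, pn$enc_fw_wh, pn$enc_fw_b,
                  reverse = FALSE, n_seg = n_seg)
    bw <- ad_lstm(h, pn$enc_bw_wx, pn$enc_bw_wh, pn$enc_bw_b,
                  reverse = TRUE, n_seg = n_seg)
    h <- ad_concat_cols(fw, bw)
    h <- ad_dropout(h, cfg$encoder_dropout, training)
  }
  mfcc <- ad_add_bias(ad_matmul(h, pn$mfcc_w), pn$mfcc_b)
  list(input = x, enc = h, mfcc = mfcc)
}

# Decoder forward pass under teacher forcing over `n_seg` stacked segments.
# `tokens_in` are 0-based token ids (the shifted-right targets of all
# segments, segment-major).  Returns the logits node ((n_seg*M) x vocab).
forward_decoder <- function(tp, pn, cfg, enc_out, tokens_in, training = FALSE,
                            n_seg = 1L) {
  rows <- as.integer(tokens_in) + 1L
  m_len <- length(rows) %/% n_seg
  h <- ad_embed(pn$embed, rows)
  if (cfg$architecture == "transformer") {
    pe <- positional_encoding(m_len, cfg$embed_dim)
    h <- ad_add_const(h, pe[rep(seq_len(m_len), n_seg), , drop = FALSE])
    h <- ad_dropout(h, cfg$decoder_dropout, training)
    for (l in seq_len(cfg$decoder_layers)) {
      pre <- paste0("dec", l, "_")
      a <- ad_mha(h, h, pn[[paste0(pre, "self_wq")]],
                  pn[[paste0(pre, "self_wk")]], pn[[paste0(pre, "self_wv")]],
                  pn[[paste0(pre, "self_wo")]], cfg$decoder_heads,
                  causal = TRUE, n_blocks = n_seg)
      h <- ad_layernorm(ad_add(h, ad_dropout(a, cfg$decoder_dropout, training)),
                        pn[[paste0(pre, "ln1_g")]], pn[[paste0(pre, "ln1_b")]])
      a2 <- ad_mha(h, enc_out, pn[[paste0(pre, "cross_wq")]],
                   pn[[paste0(pre, "cross_wk")]], pn[[paste0(pre, "cross_wv")]],
                   pn[[paste0(pre, "cross_wo")]], cfg$decoder_heads,
                   n_blocks = n_seg)
      h <- ad_layernorm(ad_add(h, ad_dropout(a2, cfg$decoder_dropout, training)),
                        pn[[paste0(pre, "ln2_g")]], pn[[paste0(pre, "ln2_b")]])
      f <- ad_add_bias(ad_matmul(ad_relu(ad_add_bias(
             ad_matmul(h, pn[[paste0(pre, "ff_w1")]]),
             pn[[paste0(pre, "ff_b1")]])),
             pn[[paste0(pre, "ff_w2")]]), pn[[paste0(pre, "ff_b2")]])
      h <- ad_layernorm(ad_add(h, ad_dropout(f, cfg$decoder_dropout, training)),
                        pn[[paste0(pre, "ln3_g")]], pn[[paste0(pre, "ln3_b")]])
    }
  } else {
    summ <- ad_block_mean(enc_out, n_seg)
    h0 <- ad_tanh(ad_add_bias(ad_matmul(summ, pn$dec_h0_w), pn$dec_h0_b))
    c0 <- ad_tanh(ad_add_bias(ad_matmul(summ, pn$dec_c0_w), pn$dec_c0_b))
    h <- ad_dropout(h, cfg$decoder_dropout, training)
    h <- ad_lstm(h, pn$dec_wx, pn$dec_wh, pn$dec_b, h0 = h0, c0 = c0,
                 n_seg = n_seg)
  }
  ad_add_bias(ad_matmul(h, pn$out_w), pn$out_b)
}

# Full teacher-forced forward pass for one segment.  `tokens` is the complete
# 0-based sequence c(6, t1, t2, t3, 7); input is tokens[-length] and the
# cross-entropy target tokens[-1].
forward_segment <- function(tp, pn, cfg, features, tokens, training = FALSE) {
  enc <- forward_encoder(tp, pn, cfg, features, training)
  tokens <- as.integer(tokens)
  logits <- forward_decoder(tp, pn, cfg, enc$enc,
                            tokens[-length(tokens)], training)
  list(input = enc$input, enc = enc$enc, mfcc = enc$mfcc, logits = logits,
       targets = tokens[-1L] + 1L)
}

# Teacher-forced forward pass over a whole mini-batch of equal-length
# segments, stacked segment-major into single matrix ops (block-diagonal
# attention).  Returns the combined loss node plus the separate loss values.
forward_batch <- function(tp, pn, cfg, batch, lambda, training = TRUE) {
  B <- length(batch)
  feats <- do.call(rbind, lapply(batch, `[[`, "features"))
  tok_in <- unlist(lapply(batch, function(p) {
    tk <- as.integer(p$tokens); tk[-length(tk)]
  }))
  targets <- unlist(lapply(batch, function(p) {
    tk <- as.integer(p$tokens); tk[-1L] + 1L
  }))
  enc <- forward_encoder(tp, pn, cfg, feats, training, n_seg = B)
  logits <- forward_decoder(tp, pn, cfg, enc$enc, tok_in, training, n_seg = B)
  ce <- ad_ce(logits, targets)
  has_mfcc <- !is.null(batch[[1L]]$mfcc) && lambda > 0
  if (has_mfcc) {
    mfcc_t <- do.call(rbind, lapply(batch, `[[`, "mfcc"))
    mse <- ad_mse(enc$mfcc, mfcc_t)
    list(loss = ad_axpy(ce, mse, lambda), ce = ad_value(ce)[1L],
         mse = ad_value(mse)[1L])
  } else {
    list(loss = ce, ce = ad_value(ce)[1L], mse = NA_real_)
  }
}

#' Greedy autoregressive decoding of one feature segment
#'
#' Runs the encoder once, then decodes autoregressively from the start token
#' (6), appending the argmax token at each step (ties broken toward the lowest
#' token ID) until the end token (7) is produced or the length cap is reached.
#'
#' @param object A fitted [ecog_decoder] model.
#' @param features An L x K feature matrix.
#' @param max_len Length cap including the start token (default from config).
#' @return Integer token vector excluding the start token (the end token is
#'   included when produced).  If the cap was hit without an end token the
#'   result carries attribute `truncated = TRUE`.
#' @export
decode_greedy <- function(object, features, max_len = NULL) {
  cfg <- object$config
  if (is.null(max_len)) max_len <- cfg$max_target_len
  tp <- ad_tape()
  pn <- push_params(tp, object$params)
  enc <- forward_encoder(tp, pn, cfg, features, training = FALSE)
  seq_tok <- 6L
  truncated <- FALSE
  repeat {
    logits <- ad_value(forward_decoder(tp, pn, cfg, enc$enc, seq_tok,
                                       training = FALSE))
    nxt <- which.max(logits[nrow(logits), ]) - 1L   # first max = lowest ID
    seq_tok <- c(seq_tok, nxt)
    if (nxt == 7L) break
    if (length(seq_tok) >= max_len) { truncated <- TRUE; break }
  }
  out <- seq_tok[-1L]
  if (truncated) attr(out, "truncated") <- TRUE
  out
}

# Parameter count (reported by summary methods and logs).
count_params <- function(params) {
  sum(vapply(params, length, integer(1)))
}
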