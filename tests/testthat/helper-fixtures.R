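# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

# Small Table-2-architecture config for unit tests of the network code
# (reduced widths so finite-difference checks stay fast; dropout off so
# forward passes are deterministic).
tiny_config <- function(architecture = "transformer") {
  model_config(architecture = architecture, n_electrodes = 4L,
               conv_filters = 8L, conv_kernel = 3L, conv_stride = 3L,
               conv_dropout = 0, encoder_layers = 2L, encoder_heads = 2L,
               encoder_hidden = 8L, encoder_dropout = 0, mfcc_units = 3L,
               embed_dim = 6L, decoder_layers = 1L, decoder_heads = 2L,
               decoder_hidden = 6L, decoder_dropout = 0, ff_mult = 2L)
}

# Compact high-SNR synthetic session: 16 trials, 24 electrodes, 1.2 s
# sentences, identical covert sets (alpha = 1) at gain 0.7.
tiny_session <- function() {
  if (is.null(.fixtures$session)) {
    cfg <- synth_config(n_electrodes = 24L, segment_duration = 1.2,
                        dummy_duration = 0.3, pad_duration = 0.15,
                        snr_db = 10, covert_gain = 0.7, alpha = 1, seed = 42L)
    sch <- make_schedule(16L, seed = 42L)
    ds <- synth_dataset(cfg, sch)
    feats <- extract_features(ds, tasks = c("overt", "covert"))
    pairs <- pair_for_training(ds, feats, "overt_model")
    .fixtures$session <- list(dataset = ds, features = feats, pairs = pairs)
  }
  .fixtures$session
}

# A decoder trained to convergence on the tiny session's overt pairs.
trained_decoder <- function(architecture = "transformer", epochs = 60L) {
  key <- paste0("model_", architecture)
  if (is.null(.fixtures[[key]])) {
    sess <- tiny_session()
    cfg <- model_config(architecture = architecture,
                        n_electrodes = ncol(sess$pairs[[1L]]$features))
    .fixtures[[key]] <- ecog_decoder(sess$pairs, cfg,
                                     train_config(epochs = epochs, seed = 7L))
  }
  .fixtures[[key]]
}

# Central-difference numerical gradient for autodiff verification.
num_gradient <- function(f, x, eps = 1e-5) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

max_rel_err <- function(a, b) {
  max(abs(a - b)) / max(1e-8, max(abs(b)))
}
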