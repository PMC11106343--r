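test_that("layer output shapes conform to the published parameter table", {
  set.seed(3)
  cfg <- model_config(n_electrodes = 32L)   # full-size architecture
  params <- ecogdecode:::init_params(cfg)
  B <- 2L; L <- 700L; K <- 32L
  batch <- lapply(seq_len(B), function(i) list(
    features = matrix(stats::rnorm(L * K), L, K),
    tokens = c(6L, 0L, 2L, 4L, 7L)))
  Nn <- as.integer(ceiling(L / 12))
  tp <- ecogdecode:::ad_tape()
  pn <- ecogdecode:::push_params(tp, params)
  feats <- do.call(rbind, lapply(batch, `[[`, "features"))
  enc <- ecogdecode:::forward_encoder(tp, pn, cfg, feats, FALSE, n_seg = B)
  # temporal conv / encoder: (B, N, 100); mfcc head: (B, N, 13)
  expect_equal(dim(ecogdecode:::ad_value(enc$enc)), c(B * Nn, 100L))
  expect_equal(dim(ecogdecode:::ad_value(enc$mfcc)), c(B * Nn, 13L))
  tok_in <- unlist(lapply(batch, function(p) p$tokens[-5L]))
  logits <- ecogdecode:::forward_decoder(tp, pn, cfg, enc$enc, tok_in, FALSE,
                                         n_seg = B)
  # decoder logits: (B, M, 8)
  expect_equal(dim(ecogdecode:::ad_value(logits)), c(B * 4L, 8L))
})

test_that("temporal conv length follows N = ceil(L / W) with zero padding", {
  cfg <- tiny_config()
  params <- ecogdecode:::init_params(cfg)
  for (L in c(12L, 3L, 7L)) {
    tp <- ecogdecode:::ad_tape()
    pn <- ecogdecode:::push_params(tp, params)
    x <- ecogdecode:::ad_node(tp, matrix(stats::rnorm(L * 4), L, 4))
    h <- ecogdecode:::ad_conv_time(x, pn$conv_w, pn$conv_b, 3L)
    expect_equal(nrow(ecogdecode:::ad_value(h)), as.integer(ceiling(L / 3)))
  }
  tp <- ecogdecode:::ad_tape()
  pn <- ecogdecode:::push_params(tp, params)
  x <- ecogdecode:::ad_node(tp, matrix(0, 2, 4))
  expect_error(ecogdecode:::ad_conv_time(x, pn$conv_w, pn$conv_b, 3L),
               "shorter than")
  # electrode-count mismatch caught at the encoder boundary
  expect_error(ecogdecode:::forward_encoder(tp, pn, cfg,
                                            matrix(0, 12, 5), FALSE),
               "electrodes")
})

test_that("inference is deterministic and dropout only acts in training", {
  set.seed(1)
  cfg <- tiny_config()
  cfg$encoder_dropout <- 0.5; cfg$conv_dropout <- 0.1
  params <- ecogdecode:::init_params(cfg)
  feat <- matrix(stats::rnorm(12 * 4), 12, 4)
  run <- function(training) {
    tp <- ecogdecode:::ad_tape()
    pn <- ecogdecode:::push_params(tp, params)
    ecogdecode:::ad_value(
      ecogdecode:::forward_encoder(tp, pn, cfg, feat, training)$mfcc)
  }
  expect_identical(run(FALSE), run(FALSE))
  set.seed(2); a <- run(TRUE)
  set.seed(3); b <- run(TRUE)
  expect_false(identical(a, b))
})

test_that("positional encoding makes the encoder order-sensitive", {
  set.seed(4)
  cfg <- tiny_config()
  params <- ecogdecode:::init_params(cfg)
  feat <- matrix(stats::rnorm(12 * 4), 12, 4)
  run <- function(f) {
    tp <- ecogdecode:::ad_tape()
    pn <- ecogdecode:::push_params(tp, params)
    ecogdecode:::ad_value(
      ecogdecode:::forward_encoder(tp, pn, cfg, f, FALSE)$mfcc)
  }
  base <- run(feat)
  perm <- run(feat[c(7:12, 1:6), ])
  # permuting whole conv windows would commute without positional encoding
  expect_gt(max(abs(base[1:2, ] - perm[3:4, ])), 1e-6)
})

test_that("decoder self-attention is causal: future tokens cannot leak back", {
  set.seed(8)
  cfg <- tiny_config()
  params <- ecogdecode:::init_params(cfg)
  feat <- matrix(stats::rnorm(12 * 4), 12, 4)
  logits_for <- function(tokens_in) {
    tp <- ecogdecode:::ad_tape()
    pn <- ecogdecode:::push_params(tp, params)
    enc <- ecogdecode:::forward_encoder(tp, pn, cfg, feat, FALSE)
    ecogdecode:::ad_value(
      ecogdecode:::forward_decoder(tp, pn, cfg, enc$enc, tokens_in, FALSE))
  }
  a <- logits_for(c(6L, 0L, 2L, 4L))
  b <- logits_for(c(6L, 0L, 3L, 5L))   # perturb positions 3..4
  expect_equal(a[1:2, ], b[1:2, ], tolerance = 1e-12)
  expect_gt(max(abs(a[3:4, ] - b[3:4, ])), 1e-8)
})

test_that("the MFCC head shapes training gradients but is bypassed in decoding", {
  set.seed(12)
  cfg <- tiny_config()
  params <- ecogdecode:::init_params(cfg)
  feat <- matrix(stats::rnorm(12 * 4), 12, 4)
  tokens <- c(6L, 0L, 2L, 4L, 7L)
  grad_of <- function(lambda) {
    tp <- ecogdecode:::ad_tape()
    pn <- ecogdecode:::push_params(tp, params)
    fwd <- ecogdecode:::forward_segment(tp, pn, cfg, feat, tokens, FALSE)
    l <- if (lambda > 0)
      ecogdecode:::ad_axpy(ecogdecode:::ad_ce(fwd$logits, fwd$targets),
                           ecogdecode:::ad_mse(fwd$mfcc, matrix(0, 4, 3)),
                           lambda)
    else ecogdecode:::ad_ce(fwd$logits, fwd$targets)
    g <- ecogdecode:::ad_backward(l)
    g[[pn$mfcc_w$id]]
  }
  expect_null(grad_of(0))            # CE alone never touches the head
  expect_gt(max(abs(grad_of(0.1))), 0)
  # decoding ignores the head entirely: zeroing it changes nothing
  model <- structure(list(params = params, config = cfg), class = "ecog_decoder")
  p2 <- params; p2$mfcc_w[] <- 0; p2$mfcc_b[] <- 99
  model2 <- structure(list(params = p2, config = cfg), class = "ecog_decoder")
  expect_identical(decode_greedy(model, feat), decode_greedy(model2, feat))
})

test_that("greedy decoding breaks ties toward the lowest token ID and caps length", {
  cfg <- tiny_config()
  set.seed(5)
  params <- ecogdecode:::init_params(cfg)
  # force uniform logits: zero output projection and bias
  params$out_w[] <- 0; params$out_b[] <- 0
  model <- structure(list(params = params, config = cfg),
                     class = "ecog_decoder")
  feat <- matrix(stats::rnorm(12 * 4), 12, 4)
  out <- decode_greedy(model, feat)
  expect_equal(as.integer(out), rep(0L, 4L))   # argmax tie -> token 0, cap at 4
  expect_true(isTRUE(attr(out, "truncated")))
  # biasing the end token ends the sequence immediately
  params$out_b[1, 8L] <- 5
  model2 <- structure(list(params = params, config = cfg),
                      class = "ecog_decoder")
  expect_equal(as.integer(decode_greedy(model2, feat)), 7L)
})

test_that("the BLSTM variant honours the same interface contracts", {
  set.seed(6)
  cfg <- tiny_config("blstm")
  params <- ecogdecode:::init_params(cfg)
  feat <- matrix(stats::rnorm(12 * 4), 12, 4)
  tp <- ecogdecode:::ad_tape()
  pn <- ecogdecode:::push_params(tp, params)
  enc <- ecogdecode:::forward_encoder(tp, pn, cfg, feat, FALSE)
  expect_equal(dim(ecogdecode:::ad_value(enc$enc)), c(4L, 8L))
  expect_equal(dim(ecogdecode:::ad_value(enc$mfcc)), c(4L, 3L))
  logits <- ecogdecode:::forward_decoder(tp, pn, cfg, enc$enc,
                                         c(6L, 0L, 2L, 4L), FALSE)
  expect_equal(dim(ecogdecode:::ad_value(logits)), c(4L, 8L))
  expect_gt(ecogdecode:::count_params(params), 0L)
})

test_that("config invariants are enforced", {
  expect_error(model_config(conv_kernel = 10L, conv_stride = 12L),
               "kernel must equal")
  expect_error(model_config(encoder_hidden = 100L, encoder_heads = 7L),
               "divisible")
  expect_error(model_config(conv_filters = 64L), "match")
  cfg <- model_config()
  expect_equal(cfg$conv_filters, 100L)
  expect_equal(cfg$conv_kernel, 12L)
  expect_equal(cfg$encoder_layers, 2L)
  expect_equal(cfg$decoder_layers, 1L)
  expect_equal(cfg$encoder_heads, 10L)
  expect_equal(cfg$mfcc_units, 13L)
  expect_equal(cfg$embed_dim, 500L)
  expect_equal(cfg$vocab_size, 8L)
})
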