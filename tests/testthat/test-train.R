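test_that("the dual loss matches hand arithmetic on a two-token toy case", {
  # 2 positions, 2 live classes: logits give softmax probabilities by hand
  logits <- matrix(c(2, 0,
                     0, 2), nrow = 2, byrow = TRUE)
  # targets: class 0 then class 1 -> picked probs both exp(2)/(exp(2)+exp(0))
  p <- exp(2) / (exp(2) + exp(0))
  ce_hand <- -mean(log(c(p, p)))
  mfcc_pred <- matrix(c(1, 2, 3, 4), 2, 2)
  mfcc_tgt <- matrix(c(0, 2, 3, 2), 2, 2)
  mse_hand <- mean(c(1, 0, 0, 4))
  l <- decoder_loss(logits, c(0L, 1L), mfcc_pred, mfcc_tgt, lambda = 0.1)
  expect_equal(as.numeric(l), ce_hand + 0.1 * mse_hand, tolerance = 1e-12)
  expect_equal(attr(l, "ce"), ce_hand, tolerance = 1e-12)
  expect_equal(attr(l, "mse"), mse_hand, tolerance = 1e-12)
  # lambda = 0 reduces to the cross-entropy term exactly
  l0 <- decoder_loss(logits, c(0L, 1L), mfcc_pred, mfcc_tgt, lambda = 0)
  expect_equal(as.numeric(l0), ce_hand)
  # near-perfect logits and exact MFCCs drive the loss to the floor
  big <- matrix(c(50, 0, 0, 50), 2, byrow = TRUE)
  lp <- decoder_loss(big, c(0L, 1L), mfcc_tgt, mfcc_tgt, lambda = 0.1)
  expect_lt(as.numeric(lp), 1e-8)
  expect_error(decoder_loss(matrix(NaN, 1, 2), 0L), "NaN")
})

test_that("temporal shuffling permutes rows only, reproducibly", {
  set.seed(6)
  f <- matrix(stats::rnorm(50 * 4), 50, 4)
  s1 <- shuffle_features(f, seed = 3L)
  s2 <- shuffle_features(f, seed = 3L)
  expect_identical(s1, s2)
  expect_false(identical(s1, f))
  for (k in 1:4) expect_equal(sort(s1[, k]), sort(f[, k]))
  # lag-1 autocorrelation of a smooth envelope collapses under shuffling
  smooth <- matrix(sin(2 * pi * seq_len(200) / 50), ncol = 1)
  ac_orig <- stats::cor(smooth[-1, 1], smooth[-200, 1])
  sh <- shuffle_features(smooth, seed = 9L)
  ac_sh <- stats::cor(sh[-1, 1], sh[-200, 1])
  expect_gt(ac_orig, 0.95)
  expect_lt(abs(ac_sh), 0.3)
})

test_that("fold assignment partitions trials and stratifies sentences", {
  sch <- make_schedule(80L, seed = 2L)
  fold <- ecogdecode:::make_folds(sch, 5L, seed = 1L)
  expect_length(fold, 80L)
  expect_equal(as.integer(table(fold)), rep(16L, 5L))
  for (f in 1:5)
    expect_equal(as.integer(table(sch$sentence[fold == f])), rep(2L, 8L))
})

test_that("cross-validated decoding produces complete, leak-free bookkeeping", {
  sess <- tiny_session()
  plan <- experiment_plan("overt", "overt", folds = 2L, repeats = 2L)
  cv <- run_cv(plan, sess$dataset, sess$features,
               model_config(n_electrodes = 24L),
               train_config(epochs = 2L, seed = 3L))
  # 2 models x 2 folds x 8 test segments
  expect_length(cv$results, 2L * 2L * 8L)
  tested <- vapply(Filter(function(r) r$repeat_id == 1L, cv$results),
                   `[[`, integer(1), "trial")
  expect_setequal(tested, 1:16)              # every trial in exactly one fold
  expect_equal(sum(cv$fold_assignment == 1L), 8L)
  refs <- vapply(cv$results, function(r) length(r$reference), integer(1))
  expect_true(all(refs == 5L))
  rep <- aggregate_ter(cv$results)
  expect_equal(nrow(rep$per_result), length(cv$results))
  expect_true(all(rep$per_result$ter >= 0))
})

test_that("fitting validates its inputs", {
  expect_error(ecog_decoder(list()), "no training pairs")
  p1 <- list(features = matrix(0, 24, 4), tokens = c(6L, 0L, 2L, 4L, 7L))
  p2 <- list(features = matrix(0, 24, 5), tokens = c(6L, 0L, 2L, 4L, 7L))
  expect_error(ecog_decoder(list(p1, p2)), "electrode count")
  p3 <- list(features = matrix(0, 12, 4), tokens = c(6L, 0L, 2L, 4L, 7L))
  expect_error(ecog_decoder(list(p1, p3)), "equal segment length")
  expect_error(train_config(mfcc_lambda = -1), "mfcc_lambda")
})

test_that("model objects expose the standard methods", {
  m <- trained_decoder("transformer")
  expect_s3_class(m, "ecog_decoder")
  expect_output(print(m), "ECoG sentence decoder")
  expect_output(summary(m), "Architecture: transformer")
  expect_type(coef(m), "list")
  expect_true("conv_w" %in% names(coef(m)))
  sess <- tiny_session()
  hyp <- predict(m, sess$pairs[[1L]]$features)
  expect_true(all(hyp %in% 0:7))
  hyps <- predict(m, lapply(sess$pairs[1:2], `[[`, "features"))
  expect_length(hyps, 2L)
  pdf(NULL)
  expect_silent(plot(m))
  dev.off()
  # loss history decreased over training
  h <- m$history
  expect_lt(mean(utils::tail(h$ce, 5)), mean(utils::head(h$ce, 5)))
})

test_that("a trained decoder emits valid sentences on its task", {
  m <- trained_decoder("transformer")
  sess <- tiny_session()
  hyps <- lapply(sess$pairs, function(p) as.integer(decode_greedy(m, p$features)))
  valid <- vapply(hyps, function(h)
    length(h) == 4L && h[1] %in% 0:1 && h[2] %in% 2:3 && h[3] %in% 4:5 &&
      h[4] == 7L, logical(1))
  expect_gte(mean(valid), 0.9)
})

test_that("the BLSTM baseline also learns the planted code", {
  m <- trained_decoder("blstm", epochs = 60L)
  sess <- tiny_session()
  res <- lapply(sess$pairs, function(p)
    list(reference = p$tokens, hypothesis = as.integer(decode_greedy(m, p$features))))
  # training-set TER well below the 50% constant-guess chance level
  expect_lt(aggregate_ter(res)$summary$mean_ter, 35)
})

test_that("covert-to-overt transfer degrades as the shared electrode fraction shrinks", {
  # overt-trained models tested on covert data: TER should be non-increasing
  # in the overlap alpha (averaged over seeds); scaled-down sessions keep the
  # check affordable
  ters <- sapply(c(0, 0.5, 1), function(alpha) {
    mean(sapply(1:5, function(seed) {
      cfg <- synth_config(n_electrodes = 24L, segment_duration = 1,
                          dummy_duration = 0.3, pad_duration = 0.15,
                          snr_db = 10, covert_gain = 0.7, alpha = alpha,
                          seed = 100L + seed)
      ds <- synth_dataset(cfg, make_schedule(16L, seed = 200L + seed))
      feats <- extract_features(ds, tasks = c("overt", "covert"))
      pairs <- pair_for_training(ds, feats, "overt_model")
      m <- ecog_decoder(pairs, model_config(n_electrodes = 24L),
                        train_config(epochs = 25L, seed = seed))
      res <- lapply(seq_len(16L), function(tr) list(
        reference = ds$sentences[[ds$schedule$sentence[tr]]]$tokens,
        hypothesis = as.integer(decode_greedy(
          m, unclass(feats[[paste0(tr, "_covert")]])[, , drop = FALSE]))))
      aggregate_ter(res)$summary$mean_ter
    }))
  })
  expect_true(ters[1] >= ters[2] - 5 && ters[2] >= ters[3] - 5)
  expect_gt(ters[1], ters[3])   # no overlap decodes worse than full overlap
})
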