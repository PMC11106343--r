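# small helper: per-trial recordings with a dummy prefix and a known sentence
make_recordings <- function(n_trials, tasks, fs = 400, dummy = 0.2,
                            sent = 1.0, K = 3, gen = function(n) stats::rnorm(n)) {
  recs <- list(); trig <- list()
  n_tot <- round((dummy + sent + 0.1) * fs)
  for (tr in seq_len(n_trials)) for (task in tasks) {
    recs[[length(recs) + 1L]] <- list(
      signal = matrix(gen(K * n_tot), K, n_tot), fs = fs,
      trial = tr, task = task)
    trig[[length(trig) + 1L]] <- data.frame(
      trial = tr, task = task, label = c("dummy", "sentence"),
      t_start = c(0, dummy), t_end = c(dummy, dummy + sent))
  }
  list(recordings = recs, triggers = do.call(rbind, trig))
}

test_that("trimming yields one equal-length segment per trial and task", {
  set.seed(1)
  d <- make_recordings(4, c("overt", "covert", "perception"))
  segs <- trim_segments(d$recordings, d$triggers)
  expect_length(segs, 12L)   # trials x tasks
  lens <- vapply(segs, function(s) ncol(s$signal), integer(1))
  expect_true(all(lens == 400L))   # 1.0 s at 400 Hz
  # missing trigger names the trial
  d2 <- d
  d2$triggers <- d2$triggers[!(d2$triggers$trial == 3 &
                               d2$triggers$task == "covert" &
                               d2$triggers$label == "sentence"), ]
  expect_error(trim_segments(d2$recordings, d2$triggers), "trial 3")
  # negative interval rejected
  d3 <- d
  d3$triggers$t_end[2] <- d3$triggers$t_start[2] - 0.1
  expect_error(trim_segments(d3$recordings, d3$triggers), "negative|empty")
})

test_that("resampling reaches 400 Hz and the notches suppress line noise", {
  fs <- 1200
  t <- seq_len(fs * 2) / fs
  seg <- structure(list(signal = rbind(sin(2 * pi * 50 * t),
                                       sin(2 * pi * 100 * t),
                                       rep(1, length(t))),
                        fs = fs, trial = 1L, task = "overt"),
                   class = "ecog_segment")
  out <- resample_and_notch(seg)
  expect_equal(out$fs, 400)
  mid <- 150:650   # avoid filter edge transients
  for (k in 1:2) {
    atten <- 20 * log10(stats::sd(out$signal[k, mid]) / stats::sd(seg$signal[k, ]))
    expect_lt(atten, -20)
  }
  # DC passes through unchanged up to transients
  expect_equal(mean(out$signal[3, mid]), 1, tolerance = 1e-3)
  # 9600 Hz input: output length exact to within one sample
  seg2 <- structure(list(signal = matrix(stats::rnorm(9600 * 2), 1), fs = 9600,
                         trial = 1L, task = "overt"), class = "ecog_segment")
  out2 <- resample_and_notch(seg2)
  expect_lte(abs(ncol(out2$signal) - 800L), 1L)
  seg3 <- structure(list(signal = matrix(0, 1, 100), fs = 200,
                         trial = 1L, task = "overt"), class = "ecog_segment")
  expect_error(resample_and_notch(seg3), "below")
})

test_that("the envelope tracks a known 2 Hz amplitude modulation at 100 Hz", {
  fs <- 400
  t <- seq_len(fs * 3.5) / fs
  mod <- 1 + 0.5 * sin(2 * pi * 2 * t)
  x <- mod * sin(2 * pi * 100 * t)
  seg <- structure(list(signal = rbind(x, stats::rnorm(length(t))), fs = fs,
                        trial = 1L, task = "overt"), class = "ecog_segment")
  env <- highgamma_features(seg, zscore = FALSE)
  mod200 <- mod[seq(1, length(mod), by = 2)]
  mid <- 50:(nrow(env) - 50)
  expect_gte(stats::cor(env[mid, 1], mod200[mid]), 0.9)
  # out-of-band tone leaves only a vestige of envelope power
  x30 <- sin(2 * pi * 30 * t)
  seg30 <- structure(list(signal = rbind(x30, stats::rnorm(length(t))),
                          fs = fs, trial = 1L, task = "overt"),
                     class = "ecog_segment")
  env30 <- highgamma_features(seg30, zscore = FALSE)
  expect_lt(mean(env30[mid, 1]^2), 0.01 * mean(env[mid, 1]^2))
})

test_that("z-scored features have unit per-electrode moments and reject flat channels", {
  set.seed(2)
  seg <- structure(list(signal = matrix(stats::rnorm(400 * 3 * 4), 4), fs = 400,
                        trial = 1L, task = "overt"), class = "ecog_segment")
  f <- highgamma_features(seg)
  expect_true(all(abs(colMeans(f)) < 1e-6))
  expect_true(all(abs(apply(f, 2, stats::sd) - 1) < 1e-6))
  expect_equal(attr(f, "fs"), 200)
  seg$signal[2, ] <- 5
  expect_error(highgamma_features(seg), "electrode 2")
})

test_that("the FIR bank covers 70-150 Hz with -6 dB edges at the printed passbands", {
  bands <- highgamma_bands()
  expect_equal(nrow(bands), 8L)
  expect_lte(bands[1, "low"], 70)
  expect_gte(bands[8, "high"], 150)
  # adjacent bands overlap or nearly touch (the printed edges leave a 1 Hz
  # seam at 136-137 Hz that the filter transition skirts cover)
  expect_true(all(bands[-1, "low"] <= bands[-8, "high"] + 1))
  taps <- ecogdecode:::design_fir_bank(400, 120L)
  freqs <- seq(0, 200, by = 0.25)
  response <- function(h, f, fs) {
    abs(exp(-1i * 2 * pi * outer(f / fs, seq_along(h) - 1)) %*% h)[, 1]
  }
  for (b in seq_len(8L)) {
    H <- response(taps[[b]], freqs, 400)
    # -6 dB (half-amplitude) crossings sit within 2 Hz of the printed edges
    lo_cross <- freqs[min(which(H >= 0.5))]
    hi_cross <- freqs[max(which(H >= 0.5))]
    expect_lt(abs(lo_cross - bands[b, "low"]), 2)
    expect_lt(abs(hi_cross - bands[b, "high"]), 2)
    # passband centre is essentially unity gain
    centre <- mean(bands[b, ])
    expect_equal(H[which.min(abs(freqs - centre))], 1, tolerance = 0.05)
  }
})

test_that("trimming before filtering is not interchangeable with filtering first", {
  # a large step artifact just before the sentence onset leaks into the
  # segment if filtering precedes trimming; the mandated order confines it
  set.seed(3)
  fs <- 400
  dummy <- 0.3; sent <- 1.0
  n_tot <- round((dummy + sent + 0.1) * fs)
  sig <- matrix(stats::rnorm(2 * n_tot), 2)
  sig[, 1:round(dummy * fs)] <- sig[, 1:round(dummy * fs)] + 40  # artifact
  rec <- list(list(signal = sig, fs = fs, trial = 1L, task = "overt"))
  trig <- data.frame(trial = 1L, task = "overt",
                     label = c("dummy", "sentence"),
                     t_start = c(0, dummy), t_end = c(dummy, dummy + sent))
  seg <- trim_segments(rec, trig)[[1L]]
  feat_correct <- highgamma_features(resample_and_notch(seg), zscore = FALSE)
  # wrong order: filter the whole recording, then cut the same window
  whole <- structure(list(signal = sig, fs = fs, trial = 1L, task = "overt"),
                     class = "ecog_segment")
  filt <- resample_and_notch(whole)
  i0 <- round(dummy * filt$fs) + 1L
  cut <- structure(list(signal = filt$signal[, i0:(i0 + round(sent * filt$fs) - 1L)],
                        fs = filt$fs, trial = 1L, task = "overt"),
                   class = "ecog_segment")
  feat_wrong <- highgamma_features(cut, zscore = FALSE)
  expect_gt(max(abs(feat_correct - feat_wrong)), 1e-3)
})
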