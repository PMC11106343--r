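test_that("generation is a deterministic function of config and schedule", {
  cfg <- synth_config(n_electrodes = 12L, segment_duration = 0.9,
                      dummy_duration = 0.2, pad_duration = 0.1,
                      electrodes_per_token = 1L, seed = 5L)
  sch <- make_schedule(8L, seed = 2L)
  a <- synth_dataset(cfg, sch)
  b <- synth_dataset(cfg, sch)
  expect_identical(a$recordings[[1]]$signal, b$recordings[[1]]$signal)
  expect_identical(a$audio[[1]]$wave, b$audio[[1]]$wave)
  expect_length(a$recordings, 8L * 3L)
  # audio exists only for overt and perception tasks
  expect_setequal(unique(sub("^[0-9]+_", "", names(a$audio))),
                  c("overt", "perception"))
  # per-trial sentence trigger intervals share one duration
  sen <- a$triggers[a$triggers$label == "sentence", ]
  expect_equal(length(unique(sen$t_end - sen$t_start)), 1L)
})

test_that("configuration invariants are enforced", {
  expect_error(synth_config(alpha = 1.2), "alpha")
  expect_error(synth_config(covert_gain = 0), "covert_gain")
  expect_error(synth_config(electrodes_per_token = 0L), "non-empty")
  expect_error(synth_config(n_electrodes = 10L, electrodes_per_token = 2L),
               "not enough electrodes")
  sets <- ecogdecode:::informative_sets(synth_config(alpha = 1))
  expect_identical(sets$covert, sets$overt)   # alpha = 1: identical sets
  sets0 <- ecogdecode:::informative_sets(synth_config(alpha = 0))
  for (tok in 1:6)
    expect_length(intersect(sets0$covert[[tok]], sets0$overt[[tok]]), 0L)
})

test_that("planted bursts raise high-gamma band power by the configured SNR", {
  snr <- 6
  cfg <- synth_config(n_electrodes = 24L, segment_duration = 1.5,
                      dummy_duration = 0.2, pad_duration = 0.1,
                      snr_db = snr, seed = 11L)
  sch <- make_schedule(8L, seed = 4L)
  ds <- synth_dataset(cfg, sch)
  fs <- cfg$fs_raw
  i0 <- round(cfg$dummy_duration * fs) + 1L
  i1 <- i0 + round(cfg$segment_duration * fs) - 1L
  # every informative electrode bursts once per trial, so the whole union is
  # elevated relative to the background electrodes
  elevation <- function(task, sets, expected) {
    inf <- unlist(sets)
    noninf <- setdiff(seq_len(cfg$n_electrodes), inf)
    elev <- c()
    for (rec in ds$recordings) {
      if (rec$task != task) next
      p_inf <- mean(vapply(inf, function(k)
        ecogdecode:::band_power(rec$signal[k, i0:i1], fs), numeric(1)))
      p_non <- mean(vapply(noninf, function(k)
        ecogdecode:::band_power(rec$signal[k, i0:i1], fs), numeric(1)))
      elev <- c(elev, 10 * log10(p_inf / p_non))
    }
    expect_lt(abs(mean(elev) - expected), 1)
  }
  elevation("overt", ds$ground_truth$informative$overt, snr)
  # covert bursts are attenuated by the square of the gain
  elevation("covert", ds$ground_truth$informative$covert,
            10 * log10(1 + (10^(snr / 10) - 1) * cfg$covert_gain^2))
})

test_that("disabling the bursts produces a token-uninformative null generator", {
  cfg <- synth_config(n_electrodes = 12L, segment_duration = 1,
                      dummy_duration = 0.2, pad_duration = 0.1,
                      electrodes_per_token = 1L, snr_db = -Inf, seed = 3L)
  ds <- synth_dataset(cfg, make_schedule(8L, seed = 1L))
  fs <- cfg$fs_raw
  i0 <- round(cfg$dummy_duration * fs) + 1L
  i1 <- i0 + round(cfg$segment_duration * fs) - 1L
  rec <- ds$recordings[[which(vapply(ds$recordings, `[[`, character(1), "task") == "overt")[1]]]
  p <- vapply(seq_len(12L), function(k)
    ecogdecode:::band_power(rec$signal[k, i0:i1], fs), numeric(1))
  inf <- unlist(ds$ground_truth$informative$overt)
  diff_db <- 10 * log10(mean(p[inf]) / mean(p[-inf]))
  expect_lt(abs(diff_db), 1)
})

test_that("synthetic audio is well-formed and validated", {
  expect_error(synth_audio(c(0L, 2L, 4L), fs_audio = 4000), "8000")
  set.seed(2)
  w <- synth_audio(c(1L, 3L, 5L), 16000, 1.2)
  expect_length(w, round(1.2 * 16000))
  expect_gt(stats::sd(w), 0)
  # accepts a full token sequence with markers
  w2 <- synth_audio(c(6L, 1L, 3L, 5L, 7L), 16000, 1.2)
  expect_length(w2, round(1.2 * 16000))
})

test_that("a dataset round-trips through the plain-directory container", {
  cfg <- synth_config(n_electrodes = 6L, segment_duration = 0.5,
                      dummy_duration = 0.1, pad_duration = 0.05,
                      electrodes_per_token = 1L, seed = 8L)
  ds <- synth_dataset(cfg, make_schedule(8L, seed = 6L))
  d <- withr::local_tempdir()
  write_container(ds, d)
  expect_true(file.exists(file.path(d, "meta.json")))
  back <- read_container(d)
  expect_equal(back$schedule$sentence, ds$schedule$sentence)
  k1 <- back$recordings[[1]]
  orig <- Filter(function(r) r$trial == k1$trial && r$task == k1$task,
                 ds$recordings)[[1]]
  expect_equal(unname(k1$signal), unname(orig$signal), tolerance = 1e-6)
  expect_equal(back$ground_truth$informativeness, ds$ground_truth$informativeness)
})
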