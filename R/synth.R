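#' Configuration of the synthetic ECoG generator
#'
#' The generator emulates one participant-surrogate session: per trial and task
#' (overt / covert / perception) a multichannel raw recording with a dummy-word
#' prefix and a sentence interval, trigger intervals, and paired audio for the
#' overt and perception tasks.  Token information is planted as
#' amplitude-modulated 70-150 Hz bursts on token-specific electrode subsets
#' during the equal thirds of the sentence interval (one third per phrase
#' slot).  Covert trials follow the attenuation premise: the same generative
#' law with burst amplitude scaled by `covert_gain` and an electrode set
#' sharing a fraction `alpha` with the overt set (the remainder drawn from
#' otherwise-background electrodes, modelling broader covert recruitment).
#'
#' @param n_electrodes Electrode count K (default 32).
#' @param fs_raw Raw sampling rate in Hz (1200 or 9600; default 1200).
#' @param fs_audio Audio sampling rate in Hz (default 16000).
#' @param segment_duration Sentence interval length in seconds (default 3.5).
#' @param dummy_duration Dummy-word prefix in seconds (default 0.5).
#' @param pad_duration Post-sentence padding in seconds (default 0.25).
#' @param electrodes_per_token Informative electrodes planted per token
#'   (default 3; the six phrase tokens then occupy 18 of 32 electrodes).
#' @param alpha Fraction of each covert informative set shared with the overt
#'   set, in [0, 1]; `alpha = 1` makes the covert sets identical to overt.
#' @param covert_gain Covert burst amplitude as a fraction of overt, in (0, 1].
#' @param snr_db Planted elevation of 70-150 Hz band power on an informative
#'   electrode over background, in dB averaged over the sentence interval
#'   (`-Inf` disables the bursts entirely: a null generator).
#' @param line_noise_amp Amplitude of the 50 Hz line component (the 100 Hz
#'   harmonic gets half), relative to unit-sd pink background.
#' @param seed Integer seed; the generated dataset is a deterministic function
#'   of the config (including the seed) and the schedule.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_electrodes = 32L, fs_raw = 1200, fs_audio = 16000,
                         segment_duration = 3.5, dummy_duration = 0.5,
                         pad_duration = 0.25, electrodes_per_token = 3L,
                         alpha = 1, covert_gain = 0.7, snr_db = 3,
                         line_noise_amp = 0.5, seed = 1L) {
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]", call. = FALSE)
  if (covert_gain <= 0 || covert_gain > 1)
    stop("covert_gain must be in (0, 1]", call. = FALSE)
  if (electrodes_per_token < 1L)
    stop("informative sets must be non-empty", call. = FALSE)
  if (6L * electrodes_per_token > n_electrodes)
    stop("not enough electrodes for 6 disjoint informative sets", call. = FALSE)
  structure(list(n_electrodes = as.integer(n_electrodes), fs_raw = fs_raw,
                 fs_audio = fs_audio, segment_duration = segment_duration,
                 dummy_duration = dummy_duration, pad_duration = pad_duration,
                 electrodes_per_token = as.integer(electrodes_per_token),
                 alpha = alpha, covert_gain = covert_gain, snr_db = snr_db,
                 line_noise_amp = line_noise_amp, seed = as.integer(seed)),
            class = "synth_config")
}

# 1/f (pink) noise of unit sd via spectral shaping of white Gaussian noise.
pink_noise <- function(n) {
  X <- stats::fft(stats::rnorm(n))
  f <- c(1, seq_len(n - 1L))
  f <- pmin(f, n - f + 1)          # symmetric frequency index
  X <- X / sqrt(f)
  x <- Re(stats::fft(X, inverse = TRUE)) / n
  x / stats::sd(x)
}

# Unit-sd noise band-limited to [lo, hi] Hz via an FFT mask.
band_noise <- function(n, fs, lo = 70, hi = 150) {
  X <- stats::fft(stats::rnorm(n))
  f <- (seq_len(n) - 1L) * fs / n
  f <- pmin(f, fs - f)
  X[f < lo | f > hi] <- 0
  x <- Re(stats::fft(X, inverse = TRUE)) / n
  x / stats::sd(x)
}

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1L))

# Band power in [lo, hi] Hz via the periodogram.
band_power <- function(x, fs, lo = 70, hi = 150) {
  n <- length(x)
  P <- Mod(stats::fft(x))^2 / n^2
  f <- (seq_len(n) - 1L) * fs / n
  sel <- (f >= lo & f <= hi) | (f >= fs - hi & f <= fs - lo)
  sum(P[sel])
}

# Token-specific informative electrode sets.  Overt sets are disjoint blocks;
# covert sets share round(alpha * m) electrodes with overt, the rest sampled
# (seeded) from electrodes informative for no token.
informative_sets <- function(cfg) {
  m <- cfg$electrodes_per_token
  overt <- lapply(0:5, function(tok) (tok * m + 1L):(tok * m + m))
  spare <- setdiff(seq_len(cfg$n_electrodes), unlist(overt))
  covert <- local_rng(cfg$seed + 104729L, {
    lapply(0:5, function(tok) {
      keep <- round(cfg$alpha * m)
      extra <- m - keep
      kept <- if (keep > 0L) overt[[tok + 1L]][seq_len(keep)] else integer(0)
      if (extra > 0L) {
        if (length(spare) < extra)
          stop("not enough background electrodes for alpha-overlap sets",
               call. = FALSE)
        c(kept, sample(spare, extra))
      } else kept
    })
  })
  list(overt = overt, covert = covert)
}

#' Synthetic audio for one sentence
#'
#' Concatenates three equal-duration token sounds, each a harmonic complex
#' with a token-specific fundamental and formant-like spectral envelope, plus
#' weak noise, so MFCC trajectories discriminate tokens.
#'
#' @param tokens The sentence's phrase token ids (length 3, values 0-5); a
#'   `sentence_spec` or its full `c(6, t1, t2, t3, 7)` sequence is accepted.
#' @param fs_audio Sampling rate in Hz (>= 8000).
#' @param duration Total duration in seconds.
#' @param noise_sd Additive noise sd relative to unit-RMS harmonic part.
#' @return Numeric waveform of `round(duration * fs_audio)` samples.
#' @export
synth_audio <- function(tokens, fs_audio = 16000, duration = 3.5,
                        noise_sd = 0.05) {
  if (fs_audio < 8000) stop("fs_audio must be >= 8000 Hz", call. = FALSE)
  if (inherits(tokens, "sentence_spec")) tokens <- tokens$tokens
  tokens <- tokens[tokens %in% 0:5]
  stopifnot(length(tokens) == 3L)
  n <- round(duration * fs_audio)
  per <- ceiling(n / 3)
  wave <- numeric(0)
  for (tok in tokens) {
    f0 <- 110 + 25 * tok
    formants <- c(450 + 120 * tok, 1400 + 180 * tok, 2600 + 120 * tok)
    t <- seq_len(per) / fs_audio
    s <- numeric(per)
    for (h in seq_len(floor(3800 / f0))) {
      fh <- h * f0
      amp <- sum(exp(-((fh - formants) / 220)^2))
      if (amp > 1e-4) s <- s + amp * sin(2 * pi * fh * t)
    }
    s <- s / max(stats::sd(s), 1e-12)
    s <- s * hann_window(per)^0.25       # soften on/offsets
    wave <- c(wave, s)
  }
  wave <- wave[seq_len(n)]
  wave + stats::rnorm(n, sd = noise_sd)
}

#' Generate a synthetic multichannel session
#'
#' Produces the full per-trial, per-task recording set for one
#' participant-surrogate (see [synth_config()] for the generative law), with
#' ground truth retained so downstream recovery can be verified.
#'
#' Background is pink (1/f) noise plus 50 and 100 Hz sinusoidal line
#' components.  Token information is planted as a purely temporal code: every
#' informative electrode receives exactly one Hann-enveloped 70-150 Hz noise
#' burst per trial, and only WHEN it bursts codes the sentence -- the chosen
#' option of slot j bursts during the j-th third of the sentence interval,
#' while the unchosen option's electrodes burst in one of the other thirds at
#' random.  Per-electrode marginal distributions are therefore identical
#' across sentences, so a temporal shuffle leaves no decodable information
#' (the premise of the shuffle control).  Burst power is calibrated per
#' electrode so the average 70-150 Hz band power over the sentence interval
#' sits `snr_db` above background.  The perception task carries background
#' plus weak auditory-band bursts only; its role is to supply the audio used
#' as the covert model's MFCC source.
#'
#' @param config A [synth_config()].
#' @param schedule A [make_schedule()] trial schedule.
#' @return An object of class `synth_dataset`: list with `recordings` (one
#'   entry per trial x task: `signal` K x samples, `fs`, `trial`, `task`),
#'   `triggers` (data.frame trial/task/label/t_start/t_end), `audio` (named
#'   `"<trial>_<task>"`, overt and perception only), `sentences` (the corpus),
#'   `schedule`, `config` and `ground_truth` (informative sets per condition
#'   and a per-electrode 0/1 informativeness vector).
#' @export
synth_dataset <- function(config = synth_config(), schedule = make_schedule()) {
  stopifnot(inherits(config, "synth_config"), inherits(schedule, "trial_schedule"))
  sentences <- build_sentences()
  sets <- informative_sets(config)
  fs <- config$fs_raw
  n_dummy <- round(config$dummy_duration * fs)
  n_sent <- round(config$segment_duration * fs)
  n_pad <- round(config$pad_duration * fs)
  n_tot <- n_dummy + n_sent + n_pad
  K <- config$n_electrodes
  r_lin <- if (is.infinite(config$snr_db) && config$snr_db < 0) 1
           else 10^(config$snr_db / 10)
  third <- floor(n_sent / 3)
  t_all <- seq_len(n_tot) / fs

  recordings <- list(); triggers <- list(); audio <- list()
  local_rng(config$seed, {
    for (tr in seq_len(schedule$n_trials)) {
      sent <- sentences[[schedule$sentence[tr]]]
      toks <- sent$tokens[2:4]
      for (task in c("perception", "overt", "covert")) {
        sig <- matrix(0, K, n_tot)
        for (k in seq_len(K)) {
          sig[k, ] <- pink_noise(n_tot) +
            config$line_noise_amp * sin(2 * pi * 50 * t_all + stats::runif(1, 0, 2 * pi)) +
            0.5 * config$line_noise_amp * sin(2 * pi * 100 * t_all + stats::runif(1, 0, 2 * pi))
        }
        if (task %in% c("overt", "covert") && r_lin > 1) {
          use_sets <- if (task == "overt") sets$overt else sets$covert
          gain <- if (task == "overt") 1 else config$covert_gain
          # Purely temporal token code: the chosen option of slot j bursts in
          # third j, while the unchosen option's electrodes burst in one of
          # the other two thirds (drawn at random).  Every informative
          # electrode is thus active exactly once per trial, so per-electrode
          # marginal distributions carry no sentence information and only
          # burst TIMING codes the tokens -- a temporal shuffle destroys it.
          placement <- integer(6L)
          for (j in 1:3) {
            chosen <- toks[j]
            placement[chosen + 1L] <- j
            placement[bitwXor(chosen, 1L) + 1L] <- sample(setdiff(1:3, j), 1L)
          }
          win <- hann_window(third)
          duty <- mean(win^2) * third / n_sent
          for (tok0 in 0:5) {
            j <- placement[tok0 + 1L]
            i0 <- n_dummy + (j - 1L) * third
            for (k in use_sets[[tok0 + 1L]]) {
              pbg <- band_power(sig[k, (n_dummy + 1L):(n_dummy + n_sent)], fs)
              amp <- gain * sqrt((r_lin - 1) * pbg / duty)
              burst <- amp * win * band_noise(third, fs)
              sig[k, (i0 + 1L):(i0 + third)] <-
                sig[k, (i0 + 1L):(i0 + third)] + burst
            }
          }
        }
        if (task == "perception") {
          # weak auditory-band activity, uninformative about the tokens
          aud <- 0.15 * band_noise(n_tot, fs, 70, 150) *
            hann_window(n_tot)
          sig[K, ] <- sig[K, ] + aud
        }
        recordings[[length(recordings) + 1L]] <-
          list(signal = sig, fs = fs, trial = tr, task = task)
        triggers[[length(triggers) + 1L]] <- data.frame(
          trial = tr, task = task,
          label = c("dummy", "sentence"),
          t_start = c(0, config$dummy_duration),
          t_end = c(config$dummy_duration,
                    config$dummy_duration + config$segment_duration))
        if (task %in% c("overt", "perception")) {
          audio[[paste0(tr, "_", task)]] <-
            list(wave = synth_audio(toks, config$fs_audio,
                                    config$segment_duration),
                 fs = config$fs_audio)
        }
      }
    }
  })
  informativeness <- as.integer(seq_len(K) %in% unlist(sets$overt))
  structure(list(recordings = recordings,
                 triggers = do.call(rbind, triggers),
                 audio = audio, sentences = sentences, schedule = schedule,
                 config = config,
                 ground_truth = list(informative = sets,
                                     informativeness = informativeness)),
            class = "synth_dataset")
}

#' @export
print.synth_dataset <- function(x, ...) {
  cat(sprintf("Synthetic ECoG session: %d trials x 3 tasks, K=%d electrodes at %g Hz\n",
              x$schedule$n_trials, x$config$n_electrodes, x$config$fs_raw))
  cat(sprintf("sentence %gs + dummy %gs; snr=%g dB, covert gain=%g, alpha=%g\n",
              x$config$segment_duration, x$config$dummy_duration,
              x$config$snr_db, x$config$covert_gain, x$config$alpha))
  invisible(x)
}

#' Write a synthetic dataset as a plain-directory container
#'
#' Serializes the logical container layout to a directory of plain-text files:
#' `raw/<trial>_<task>.csv` (electrodes x samples), `triggers.csv`,
#' `audio/<trial>_<task>.csv` (one sample per line) and `meta.json` (config,
#' seed and schedule).  The matching reader restores a `synth_dataset`.
#'
#' @param dataset A `synth_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_container <- function(dataset, dir) {
  dir.create(file.path(dir, "raw"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "audio"), showWarnings = FALSE)
  for (rec in dataset$recordings)
    utils::write.table(rec$signal,
                       file.path(dir, "raw", paste0(rec$trial, "_", rec$task, ".csv")),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  utils::write.csv(dataset$triggers, file.path(dir, "triggers.csv"),
                   row.names = FALSE)
  for (nm in names(dataset$audio))
    writeLines(format(dataset$audio[[nm]]$wave, digits = 8),
               file.path(dir, "audio", paste0(nm, ".csv")))
  meta <- list(config = unclass(dataset$config),
               schedule = list(sentence = dataset$schedule$sentence,
                               seed = dataset$schedule$seed),
               fs_raw = dataset$config$fs_raw, fs_audio = dataset$config$fs_audio)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname write_container
#' @export
read_container <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  cfg <- do.call(synth_config, meta$config[setdiff(names(meta$config), NULL)])
  schedule <- structure(list(sentence = as.integer(meta$schedule$sentence),
                             n_trials = length(meta$schedule$sentence),
                             seed = as.integer(meta$schedule$seed)),
                        class = "trial_schedule")
  triggers <- utils::read.csv(file.path(dir, "triggers.csv"))
  raw_files <- list.files(file.path(dir, "raw"), full.names = TRUE)
  recordings <- lapply(raw_files, function(f) {
    base <- sub("\\.csv$", "", basename(f))
    parts <- strsplit(base, "_")[[1L]]
    list(signal = as.matrix(utils::read.csv(f, header = FALSE)),
         fs = meta$fs_raw, trial = as.integer(parts[1L]), task = parts[2L])
  })
  audio_files <- list.files(file.path(dir, "audio"), full.names = TRUE)
  audio <- lapply(audio_files, function(f)
    list(wave = as.numeric(readLines(f)), fs = meta$fs_audio))
  names(audio) <- sub("\\.csv$", "", basename(audio_files))
  structure(list(recordings = recordings, triggers = triggers, audio = audio,
                 sentences = build_sentences(), schedule = schedule,
                 config = cfg,
                 ground_truth = list(informative = informative_sets(cfg),
                                     informativeness = as.integer(
                                       seq_len(cfg$n_electrodes) %in%
                                         unlist(informative_sets(cfg)$overt)))),
            class = "synth_dataset")
}
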