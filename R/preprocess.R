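#' The eight high-gamma passbands
#'
#' Adjacent bands spanning 70-150 Hz used by the feature extractor; their
#' envelopes are averaged into a single high-gamma amplitude per electrode.
#'
#' @return An 8 x 2 matrix of (low, high) passband edges in Hz:
#'   68-78, 74-84, 82-92, 91-102, 101-112, 112-124, 124-136, 137-150.
#' @export
highgamma_bands <- function() {
  matrix(c(68, 78, 74, 84, 82, 92, 91, 102,
           101, 112, 112, 124, 124, 136, 137, 150),
         ncol = 2L, byrow = TRUE,
         dimnames = list(NULL, c("low", "high")))
}

# Windowed-sinc (Hamming) linear-phase band-pass taps via signal::fir1.
# fir1 cutoffs are the -6 dB edges of the windowed design.
design_fir_bank <- function(fs = 400, order = 120L) {
  nyq <- fs / 2
  apply(highgamma_bands(), 1L, function(b)
    signal::fir1(order, c(b[1], b[2]) / nyq, type = "pass"),
    simplify = FALSE)
}

# Zero-phase FIR filtering by FFT convolution.  For symmetric (linear-phase)
# taps, a single pass with the (ntaps-1)/2 group delay removed is exactly
# zero-phase, so envelopes stay time-aligned with the raw signal.
fft_filt <- function(x, taps) {
  n <- length(x); nt <- length(taps)
  nfft <- stats::nextn(n + nt - 1L, 2L)
  y <- Re(stats::fft(stats::fft(c(x, numeric(nfft - n))) *
                     stats::fft(c(taps, numeric(nfft - nt))),
                     inverse = TRUE)) / nfft
  delay <- (nt - 1L) %/% 2L
  y[(delay + 1L):(delay + n)]
}

# Analytic signal via the frequency-domain construction; Mod() of the result
# is the instantaneous amplitude envelope.
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1; h[n %/% 2L + 1L] <- 1; h[2L:(n %/% 2L)] <- 2
  } else {
    h[1L] <- 1; h[2L:((n + 1L) %/% 2L)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# RBJ-style second-order IIR notch coefficients.
notch_coefficients <- function(f0, fs, Q = 30) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1L], a = a / a[1L])
}

#' Trim sentence segments from raw recordings
#'
#' Cuts the sentence interval of every trial out of the raw per-trial
#' recordings, discarding the dummy-word period, BEFORE any filtering (the
#' mandated order: trimming first prevents time-correlated filter artifacts
#' from leaking across period boundaries).  All segments are cut to the same
#' length -- the maximum sentence duration over the whole recording -- so the
#' decoder cannot read the sentence identity off the segment length.
#'
#' @param recordings A list of per-trial recordings, each a list with `signal`
#'   (electrodes K x samples matrix), `fs`, `trial`, `task`.
#' @param triggers A data.frame with columns `trial`, `task`, `label`
#'   (`"dummy"` or `"sentence"`), `t_start`, `t_end` (seconds, relative to the
#'   recording start of that trial).
#' @return A list of `ecog_segment` objects: `signal` (K x S), `fs`, `trial`,
#'   `task`.
#' @export
trim_segments <- function(recordings, triggers) {
  sen <- triggers[triggers$label == "sentence", , drop = FALSE]
  if (any(sen$t_end <= sen$t_start))
    stop("negative or empty sentence interval in trigger table", call. = FALSE)
  max_dur <- max(sen$t_end - sen$t_start)
  lapply(recordings, function(rec) {
    hit <- sen$trial == rec$trial & sen$task == rec$task
    if (!any(hit))
      stop("missing sentence trigger for trial ", rec$trial, " task ",
           rec$task, call. = FALSE)
    tr <- sen[which(hit)[1L], ]
    i0 <- round(tr$t_start * rec$fs) + 1L
    ns <- round(max_dur * rec$fs)
    if (i0 + ns - 1L > ncol(rec$signal))
      stop("sentence interval for trial ", rec$trial,
           " extends past the recording", call. = FALSE)
    structure(list(signal = rec$signal[, i0:(i0 + ns - 1L), drop = FALSE],
                   fs = rec$fs, trial = rec$trial, task = rec$task),
              class = "ecog_segment")
  })
}

#' Anti-alias, downsample to 400 Hz and notch-filter a segment
#'
#' Low-pass filters at 200 Hz (zero-phase windowed-sinc FIR), decimates to
#' 400 Hz (the source rate must be an integer multiple of 400), then applies
#' second-order IIR notch filters at 50 and 100 Hz (Q = 30, forward-backward)
#' to suppress line noise and its harmonic.
#'
#' @param segment An `ecog_segment` (K x S matrix at `fs` >= 400 Hz).
#' @param fs_out Target rate, 400 Hz.
#' @param notch_freqs Notch centre frequencies in Hz.
#' @param Q Notch quality factor.
#' @return The segment resampled to `fs_out` with line noise suppressed.
#' @export
resample_and_notch <- function(segment, fs_out = 400, notch_freqs = c(50, 100),
                               Q = 30) {
  fs <- segment$fs
  if (fs < fs_out) stop("sampling rate ", fs, " is below ", fs_out, " Hz",
                        call. = FALSE)
  x <- segment$signal
  if (fs > fs_out) {
    if (fs %% fs_out != 0)
      stop("sampling rate must be an integer multiple of ", fs_out, " Hz",
           call. = FALSE)
    r <- fs %/% fs_out
    lp <- signal::fir1(120L, (fs_out / 2) / (fs / 2))
    x <- t(apply(x, 1L, function(ch) fft_filt(ch, lp)[seq(1L, length(ch), by = r)]))
  }
  for (f0 in notch_freqs) {
    co <- notch_coefficients(f0, fs_out, Q)
    x <- t(apply(x, 1L, function(ch)
      signal::filtfilt(signal::Arma(b = co$b, a = co$a), ch)))
  }
  structure(list(signal = x, fs = fs_out, trial = segment$trial,
                 task = segment$task), class = "ecog_segment")
}

#' High-gamma envelope features at 200 Hz
#'
#' For each electrode: band-pass the 400 Hz signal through the eight FIR
#' filters of [highgamma_bands()], take the amplitude of the analytic signal
#' in each band, average the eight envelopes, low-pass at 100 Hz and decimate
#' to 200 Hz, and z-score per electrode over the segment.  The result is the
#' L x K `feature sequence` the network consumes.
#'
#' @param segment An `ecog_segment` at 400 Hz (from [resample_and_notch()]).
#' @param fir_order FIR band-pass order (taps = order + 1).
#' @param zscore Apply the per-electrode z-scoring (TRUE for network input;
#'   FALSE exposes the raw averaged envelope, used by calibration checks).
#' @return An L x K matrix of class `feature_sequence` with attributes
#'   `fs` (200), `center` and `scale` (the per-electrode mean/sd used).
#' @export
highgamma_features <- function(segment, fir_order = 120L, zscore = TRUE) {
  if (segment$fs != 400)
    stop("highgamma_features expects a 400 Hz segment; run resample_and_notch first",
         call. = FALSE)
  x <- segment$signal                     # K x S
  K <- nrow(x)
  sds <- apply(x, 1L, stats::sd)
  if (any(sds == 0))
    stop("constant (zero-variance) channel: electrode ",
         paste(which(sds == 0), collapse = ", "), call. = FALSE)
  bank <- design_fir_bank(400, fir_order)
  env <- matrix(0, ncol(x), K)
  for (k in seq_len(K)) {
    acc <- numeric(ncol(x))
    for (taps in bank)
      acc <- acc + Mod(analytic_signal(fft_filt(x[k, ], taps)))
    env[, k] <- acc / length(bank)
  }
  # envelope anti-alias at 100 Hz, then 400 -> 200 Hz decimation
  lp <- signal::fir1(60L, 100 / 200)
  env <- apply(env, 2L, function(ch) fft_filt(ch, lp)[seq(1L, length(ch), by = 2L)])
  ctr <- colMeans(env); scl <- apply(env, 2L, stats::sd)
  out <- if (zscore) {
    if (any(scl == 0))
      stop("constant envelope: electrode ", paste(which(scl == 0), collapse = ", "),
           call. = FALSE)
    sweep(sweep(env, 2L, ctr), 2L, scl, "/")
  } else env
  structure(out, fs = 200, center = ctr, scale = scl,
            trial = segment$trial, task = segment$task,
            class = c("feature_sequence", "matrix", "array"))
}

#' Full feature-extraction pipeline for a dataset
#'
#' Convenience wrapper running trim -> resample/notch -> high-gamma envelope ->
#' z-score over every trial and task of a recorded (or synthetic) dataset, in
#' that mandated order.
#'
#' @param dataset A dataset as produced by [synth_dataset()] (fields
#'   `recordings`, `triggers`, `schedule`).
#' @param tasks Which tasks to featurize (default the tasks present).
#' @param ... Passed to [highgamma_features()].
#' @return A list of feature matrices with attributes `trial`, `task`; named
#'   `"<trial>_<task>"`.
#' @export
extract_features <- function(dataset, tasks = NULL, ...) {
  recs <- dataset$recordings
  if (!is.null(tasks)) recs <- Filter(function(r) r$task %in% tasks, recs)
  segs <- trim_segments(recs, dataset$triggers)
  out <- lapply(segs, function(s)
    highgamma_features(resample_and_notch(s), ...))
  names(out) <- vapply(segs, function(s) paste0(s$trial, "_", s$task),
                       character(1))
  out
}
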