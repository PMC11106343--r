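hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

# Triangular mel filterbank (n_filters x (nfft/2 + 1)).
mel_filterbank <- function(n_filters, nfft, fs, f_low = 0, f_high = fs / 2) {
  mels <- seq(hz_to_mel(f_low), hz_to_mel(f_high), length.out = n_filters + 2L)
  bins <- floor((nfft + 1L) * mel_to_hz(mels) / fs)
  fb <- matrix(0, n_filters, nfft %/% 2L + 1L)
  for (m in seq_len(n_filters)) {
    lo <- bins[m]; ce <- bins[m + 1L]; hi <- bins[m + 2L]
    if (ce > lo) for (k in lo:(ce - 1L))
      fb[m, k + 1L] <- (k - lo) / (ce - lo)
    if (hi > ce) for (k in ce:(hi - 1L))
      fb[m, k + 1L] <- (hi - k) / (hi - ce)
  }
  fb
}

# Orthonormal DCT-II matrix (n_out x n_in).
dct_matrix <- function(n_out, n_in) {
  M <- outer(seq_len(n_out) - 1L, seq_len(n_in) - 0.5,
             function(k, n) cos(pi * k * n / n_in))
  M * sqrt(2 / n_in) * ifelse(seq_len(n_out) == 1L, sqrt(0.5), 1)
}

#' Mel-frequency cepstral coefficients
#'
#' Standard MFCC front end: pre-emphasis, 20 ms Hamming-windowed frames at a
#' 5 ms step, power spectrum, 26-filter mel bank, log, orthonormal DCT-II
#' keeping 13 coefficients (including c0), sinusoidal liftering.  These serve
#' only as the encoder's auxiliary regression target during training.
#'
#' @param wave Numeric audio waveform.
#' @param fs Sampling rate in Hz (>= 8000).
#' @param window_length Frame length in seconds (default 0.020).
#' @param window_step Frame step in seconds (default 0.005).
#' @param n_coef Number of cepstral coefficients (13).
#' @param n_filters Mel filters (26).
#' @param preemph Pre-emphasis coefficient (0.97).
#' @param lifter Cepstral lifter parameter (22; 0 disables).
#' @return A T x `n_coef` matrix of class `mfcc_sequence` with attributes
#'   `fs`, `window_step`.
#' @export
compute_mfcc <- function(wave, fs, window_length = 0.020, window_step = 0.005,
                         n_coef = 13L, n_filters = 26L, preemph = 0.97,
                         lifter = 22) {
  if (fs < 8000) stop("fs must be >= 8000 Hz", call. = FALSE)
  if (all(wave == 0)) stop("all-zero waveform has no spectral content",
                           call. = FALSE)
  x <- c(wave[1L], wave[-1L] - preemph * wave[-length(wave)])
  wl <- round(window_length * fs)
  st <- round(window_step * fs)
  n_frames <- if (length(x) <= wl) 1L else
    1L + as.integer(ceiling((length(x) - wl) / st))
  pad_to <- (n_frames - 1L) * st + wl
  if (pad_to > length(x)) x <- c(x, numeric(pad_to - length(x)))
  nfft <- stats::nextn(wl, 2L)
  win <- 0.54 - 0.46 * cos(2 * pi * (seq_len(wl) - 1L) / (wl - 1L))
  fb <- mel_filterbank(n_filters, nfft, fs)
  dct <- dct_matrix(n_coef, n_filters)
  lift <- if (lifter > 0) 1 + (lifter / 2) * sin(pi * (seq_len(n_coef) - 1L) / lifter)
          else rep(1, n_coef)
  # all frames at once: wl x n_frames windowed matrix, one multi-column FFT
  idx <- outer(seq_len(wl), (seq_len(n_frames) - 1L) * st, `+`)
  frames <- matrix(x[idx], wl) * win
  frames <- rbind(frames, matrix(0, nfft - wl, n_frames))
  spec <- Mod(stats::mvfft(frames))^2 / nfft
  fbe <- fb %*% spec[seq_len(nfft %/% 2L + 1L), , drop = FALSE]
  out <- t(dct %*% log(pmax(fbe, 1e-10))) * rep(lift, each = n_frames)
  if (anyNA(out)) stop("NaN frames in MFCC output", call. = FALSE)
  structure(out, fs = fs, window_step = window_step,
            class = c("mfcc_sequence", "matrix", "array"))
}

#' Align an MFCC sequence to the encoder time axis
#'
#' The encoder's MFCC head predicts one 13-vector per temporal-convolution
#' output step, so the MFCC frames are downsampled with the same stride W:
#' every W-th frame starting at frame 1 is kept, then the result is
#' edge-padded (repeating the last row) or truncated to exactly `target_len`
#' rows.
#'
#' @param mfcc A T x 13 [compute_mfcc()] matrix.
#' @param stride Decimation stride W (>= 1; 12 matches the conv front end).
#' @param target_len Required output rows N = ceil(L / W).
#' @return An N x 13 matrix; attribute `padded` gives the number of
#'   edge-repeated rows (0 when none).
#' @export
align_to_encoder <- function(mfcc, stride = 12L, target_len) {
  if (stride < 1L) stop("stride must be >= 1", call. = FALSE)
  if (target_len <= 0L) stop("target_len must be positive", call. = FALSE)
  dec <- mfcc[seq(1L, nrow(mfcc), by = stride), , drop = FALSE]
  n_pad <- max(0L, target_len - nrow(dec))
  out <- if (nrow(dec) >= target_len) dec[seq_len(target_len), , drop = FALSE]
         else rbind(dec, dec[rep(nrow(dec), n_pad), , drop = FALSE])
  attr(out, "padded") <- n_pad
  out
}

#' Assemble training pairs for a model variant
#'
#' Pairs each trial's ECoG feature segment with its MFCC target and token
#' sequence.  The overt model pairs overt-task ECoG with MFCCs from the same
#' trial's overt audio; the covert model pairs covert-task ECoG with MFCCs
#' from that trial's perception audio (the covert task has no audio; the
#' perception recording carries the same sentence content).  An explicit
#' `audio_substitute` map supports sourcing MFCCs from another session's
#' audio, mirroring low-sample-rate audio replacement; substitution is never
#' silent.
#'
#' @param dataset A [synth_dataset()] (or any dataset with the same fields).
#' @param features Output of [extract_features()] covering the required task.
#' @param pairing `"overt_model"` or `"covert_model"`.
#' @param stride Conv stride W for MFCC alignment.
#' @param audio_substitute Optional named list mapping `"<trial>_<task>"` audio
#'   keys to replacement keys.
#' @param normalize_mfcc Z-score each MFCC coefficient within the segment so
#'   the auxiliary regression target is scale-matched to the z-scored ECoG
#'   features and the MSE term sits on a comparable scale to the
#'   cross-entropy (default TRUE).
#' @return A list of training pairs: `features` (L x K), `mfcc` (N x 13),
#'   `tokens` (length 5), `trial`, `sentence`.
#' @export
pair_for_training <- function(dataset, features,
                              pairing = c("overt_model", "covert_model"),
                              stride = 12L, audio_substitute = NULL,
                              normalize_mfcc = TRUE) {
  pairing <- match.arg(pairing)
  ecog_task <- if (pairing == "overt_model") "overt" else "covert"
  audio_task <- if (pairing == "overt_model") "overt" else "perception"
  out <- list()
  for (tr in seq_len(dataset$schedule$n_trials)) {
    fkey <- paste0(tr, "_", ecog_task)
    feat <- features[[fkey]]
    if (is.null(feat))
      stop("missing ", ecog_task, " features for trial ", tr,
           "; extract_features must cover the task", call. = FALSE)
    akey <- paste0(tr, "_", audio_task)
    if (!is.null(audio_substitute) && !is.null(audio_substitute[[akey]]))
      akey <- audio_substitute[[akey]]
    au <- dataset$audio[[akey]]
    if (is.null(au))
      stop("missing ", audio_task, " audio for trial ", tr,
           " (required by the ", pairing, ")", call. = FALSE)
    mf <- compute_mfcc(au$wave, au$fs)
    if (normalize_mfcc) {
      scl <- apply(mf, 2L, stats::sd)
      mf <- sweep(sweep(mf, 2L, colMeans(mf)), 2L, pmax(scl, 1e-8), "/")
    }
    n_enc <- as.integer(ceiling(nrow(feat) / stride))
    sent_idx <- dataset$schedule$sentence[tr]
    out[[length(out) + 1L]] <- list(
      features = unclass(feat)[, , drop = FALSE],
      mfcc = align_to_encoder(mf, stride, n_enc),
      tokens = dataset$sentences[[sent_idx]]$tokens,
      trial = tr, sentence = sent_idx)
  }
  out
}
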