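---
title: "Decoding sentences from ECoG high-gamma activity: models, parameters and verification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding sentences from ECoG high-gamma activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ecogdecode)
```

## The problem

During both overt (spoken) and covert (imagined) speech, the amplitude of
high-gamma activity (~70–150 Hz) over speech-related cortex carries
information about what is being said. `ecogdecode` implements a full pipeline
that maps multichannel ECoG recordings of short, structured sentences to
token sequences: feature extraction, a sequence-to-sequence neural decoder
trained per participant, cross-validated evaluation by token error rate
(TER), paired statistics, and gradient-saliency electrode attribution. The
scientific question the pipeline is built around is *transfer*: can a decoder
trained on overt speech decode covert speech, as the motor hypothesis (covert
speech as attenuated overt speech) predicts?

Because clinical ECoG of this kind cannot be redistributed, the package ships
a synthetic-data generator that emulates the recording protocol with planted,
condition-dependent token codes. Every claim the test suite and the
acceptance script make is a *recovery* claim on those synthetic sessions, not
a reproduction of patient-level results.

## The corpus

Sentences have three slots with two Japanese phrases each
(2 × 2 × 2 = 8 sentences). Each phrase has a token ID:

| token | phrase | gloss |
|---|---|---|
| 0 | watashiwa | I |
| 1 | kimito | with you |
| 2 | gakko:e | to school |
| 3 | shokubani | to the office |
| 4 | itta | went |
| 5 | mukau | head |
| 6 | — | start of sentence |
| 7 | — | end of sentence |

A session presents each sentence ten times in a randomized balanced order
(80 trials), in tracks of three tasks: perception (listen), overt (read
aloud), covert (read silently). `make_schedule()` implements the
balanced-then-shuffled reading of "presented at random": an i.i.d. uniform
draw would not put every sentence exactly ten times into 80 trials, so the
balanced multiset is the only schedule consistent with the design counts.

## Feature extraction

`extract_features()` runs, in this fixed order:

1. **Trim** each trial to the sentence interval (dummy-word period
   discarded), all segments cut to the maximum sentence duration. Trimming
   comes *before* any filtering so that filter transients from preceding
   periods cannot leak into the segment; a regression test pins this order.
2. **Anti-alias and downsample** to 400 Hz (zero-phase windowed-sinc FIR,
   cutoff 200 Hz), then **notch** 50 and 100 Hz (second-order IIR, Q = 30,
   forward–backward). Q is a package choice; only "IIR notch" is inherent to
   the design.
3. **High-gamma envelope**: eight FIR band-passes with passbands 68–78,
   74–84, 82–92, 91–102, 101–112, 112–124, 124–136, 137–150 Hz; per band the
   analytic-signal amplitude; the eight envelopes averaged; low-passed at
   100 Hz and decimated to 200 Hz. Filters are Hamming windowed-sinc designs
   (order 120 at 400 Hz) applied as delay-compensated FFT convolution, which
   for symmetric taps is exactly zero-phase — envelopes stay aligned with the
   raw signal. The printed passbands leave a 1 Hz seam at 136–137 Hz; the
   transition skirts cover it.
4. **Z-scoring** per electrode *within each segment*. The normalization
   window was a genuinely open choice; per-segment is used because it needs
   no cross-trial state and therefore cannot leak statistics across
   cross-validation folds.

The result is the L × K feature matrix (L ≈ 700 at 200 Hz for 3.5 s, K
electrodes) the network consumes.

## Audio features

MFCCs are computed with a 20 ms window and 5 ms step (26 mel filters,
DCT-II, 13 coefficients including c0, lifter 22) — the auxiliary target for
the encoder, nothing else; decoding never touches audio. Two package
choices worth noting:

* **13 coefficients including c0**: the MFCC head of the network is 13 units
  wide, which fixes the coefficient count; whether c0 or log-energy leads is
  not determined by that width, and plain c0 is used.
* **Per-segment z-scoring of the MFCC target** (`normalize_mfcc = TRUE` in
  `pair_for_training()`): raw MFCCs have magnitudes of order 10–100, which
  with the 0.1 penalty weight would let the regression term dwarf the token
  cross-entropy. Scale-matching the target to the (unit-variance) features
  keeps the two loss terms on comparable scales.
* The window step is exposed in `compute_mfcc()` because the source design
  is ambiguous between 5 ms and 50 ms; 5 ms is the default here, and
  `align_to_encoder()` decimates by the conv stride (every 12th frame,
  edge-padded or truncated to exactly N rows) in either case.

The covert model cannot use covert-task audio (there is none); it pairs
covert ECoG with MFCCs from the *perception* task of the same trial, which
carries the same sentence content. `pair_for_training()` encodes both
pairings and supports explicit audio substitution across sessions.

## The network

`model_config()` defaults are the full published architecture:

* **Temporal convolution**: 100 filters, kernel (12, K), stride (12, 1),
  dropout 0.1. With non-overlapping windows this is an unfold-plus-matmul;
  input is right-padded with zeros when 12 does not divide L, so the output
  length is N = ceil(L/12).
* **Transformer encoder**: 2 layers, 10 heads, width 100, dropout 0.5;
  post-norm residual sub-layers; feed-forward inner width 4 × 100 ("hidden
  units" is read as model width; the 4× inner width is the conventional
  choice).
* **MFCC head** ("feed-forward 1"): linear 100 → 13 on every encoder step.
  It shapes training gradients only; `decode_greedy()` bypasses it, and a
  gradient-flow test verifies both directions.
* **Transformer decoder**: token embedding width 500, 1 layer, 10 heads,
  masked self-attention, cross-attention with encoder output as key and
  value, output head 500 → 8. (The source text says the encoder output
  enters as "key and query"; read literally that would make the decoder
  output N-long, contradicting its own (B, M, 500) output shape, so the
  standard key/value reading is implemented.)
* **Positional encodings** (sinusoidal) are added after the convolution and
  after the embedding. The source never mentions them, but attention without
  them is order-blind, so they are a forced addition; a test shows the
  encoder is order-sensitive.
* **BLSTM baseline**: same conv front end, bidirectional LSTM encoder
  (50 + 50 = 100 wide, matching the MFCC head), LSTM decoder (500) whose
  initial state is a projected encoder summary, same heads and losses.

Everything is implemented on a small tape-based reverse-mode autodiff engine
in base R (BLAS-backed); all layer gradients are verified against central
finite differences at 1e-5 relative tolerance, and the batched
(stacked-segment, block-diagonal-attention) training path is verified to be
numerically identical to per-segment averaging.

## Training

`train_config()` defaults: Adam at learning rate 5e-4, MFCC penalty
λ = 0.1, batch size 16, 800 epochs, no schedule or early stopping. The loss
is `CE + λ·MSE` (`decoder_loss()`), with teacher forcing (shifted-right
targets) — standard seq2seq training. Two numerical safeguards are package
choices: global gradient-norm clipping at 5, and ties in greedy decoding
broken toward the lowest token ID. Training, initialization, dropout and
data order all derive from a single integer seed; repeat seeds in
cross-validation are derived as base + fold/repeat offsets, making every
experiment bit-reproducible on CPU.

`run_cv()` evaluates a train-task/test-task condition with
sentence-stratified trial folds (80/5 = 16 test trials = 2 per sentence;
stratification is the only split that balances the per-fold sentence
counts), 10 independently seeded trainings per fold, and hard errors on any
train/test trial overlap. 10 × 5 × 16 = 800 decodes per condition. The
shuffle control permutes the time frames of each *training* segment
(per-segment seeded permutations; marginals preserved exactly) and leaves
test segments intact.

## Evaluation and statistics

`ter()` scores a decode by unit-cost minimum-edit-distance alignment:
TER = 100·(S + D + I)/n_tok, with start/end markers excluded (n_tok = 3
here). The total S + D + I is checked against an independent C
implementation on random pairs; note the (S, D, I) *decomposition* of a
minimal alignment is not unique, only the total and D − I are.

`compare_ter()` is the one-sided paired Wilcoxon signed-rank test (exact for
n ≤ 25 without ties, zeros dropped), Holm–Bonferroni adjusted over m = 6
planned comparisons (`adjust_comparisons()` does the joint step-down), with
Cohen's d. Pooled-sd d is the default and a paired (mean diff / sd diff)
variant is available, since the source does not state which form it used.
A 2000-replicate null simulation at n = 16 keeps the one-sided type-I error
within [0.035, 0.065].

## The synthetic generator

`synth_dataset()` emulates one participant-surrogate session. Defaults: 32
electrodes at 1200 Hz, 3.5 s sentence intervals with a 0.5 s dummy prefix,
pink (1/f) background plus 50/100 Hz line components, 3 dB planted SNR.
Token information is planted as Hann-enveloped 70–150 Hz noise bursts on
3 electrodes per token, placed in the equal thirds of the sentence interval
(equal thirds are consistent with the constant 5-characters/s presentation
rate; true phrase durations are unknown). The code is deliberately *purely
temporal*: every informative electrode bursts exactly once per trial — the
chosen option of slot j during third j, the unchosen option's electrodes in
one of the other thirds at random. Per-electrode marginal distributions are
then identical across sentences, which is what makes the temporal-shuffle
control informationless by construction; a code based on *which* electrodes
burst would survive shuffling through marginal statistics and let the
shuffle model beat chance. Burst power is calibrated per electrode so the
average 70–150 Hz band power over the sentence interval sits exactly
`snr_db` above that electrode's background; a spectral test verifies ±1 dB.

Covert trials implement the attenuation premise: the same code at amplitude
`covert_gain` (default 0.7) on electrode sets sharing a fraction `alpha`
(default 1) with the overt sets, the remainder drawn from otherwise-silent
electrodes to model broader covert recruitment. The perception task carries
background plus weak auditory-band activity only; its role is to supply the
covert model's audio. Pink noise (not white) was chosen so the notch and
band-pass stages are exercised against a realistic 1/f spectrum.

What the generator does *not* emulate: biophysical volume conduction,
electrode-specific noise floors, artifacts (eye movement, movement), session
drift, or realistic speech acoustics. Passing recovery tests therefore show
the pipeline is correct and sensitive under its stated generative law — not
that real covert speech is decodable at any particular accuracy.

## Saliency

`saliency_map()` differentiates the summed log-probability of a token
sequence with respect to every input feature value (teacher-forced reference
by default; the decoded hypothesis optionally) and takes absolute values —
the map has exactly the input's time × electrode shape.
`electrode_contribution()` compresses maps to per-electrode scores: variance
over time, z-scored across electrodes within each trial (making scores
scale-free per trial), averaged across maps. Cortical-surface projection is
out of scope — no electrode coordinates exist for synthetic sessions — so
the deliverable is the per-electrode score table.

## Verification scale and known limitations

The desk-scale recovery study (`run_recovery_study()`, also what
`scripts/acceptance.R` runs) uses 32 electrodes, 80 trials, 2 folds,
1 repeat, 100 epochs and 10 dB planted SNR with covert gain 0.7 and full
electrode overlap: sizes chosen so the whole study runs in minutes on one
CPU core while still being decisively above/below its thresholds (in-sample
TER far below the 50% constant-guess chance; shuffle control within the
binomial 95% band of chance; overt-trained and covert-trained covert-test
TERs within 10 points). The full-scale protocol (5 folds, 10 repeats,
800 epochs) is the package default and runs unchanged, just longer.

One verification result deserves emphasis because it is negative.
Gradient-based electrode contributions do **not** recover the planted
informative electrodes on synthetic sessions (Spearman ρ against planted
informativeness ≈ 0, at any training length we ran, including the full
800-epoch protocol). The mechanism is structural: electrode attribution of
an input gradient is mediated entirely by the temporal-convolution weights
(per window, `g_input = Wᵀ g_filters`), and that layer is a compressive
(12·K → 100), randomly initialized map. On these small, cleanly separable
training sets the loss converges before the convolution specializes, so the
per-electrode gradient pattern remains the random initialization's — the
planted-selectivity tests show the contribution pipeline itself is exact
(a model with graded per-electrode kernel norms is recovered perfectly),
but a lightly-trained model simply carries no electrode-selective gradient
signal. Saliency readouts from models of this family should therefore be
interpreted with care: they reflect first-layer weight structure, which
tracks task-relevant electrodes only after far more optimization pressure
than small-session training provides.

Known limitations:

* Greedy decoding only; no beam search (the source describes none).
* The Wilcoxon test falls back to the normal approximation when TER ties
  occur across paired units (ties are common with only 8 sentences).
* The autodiff engine materializes per-layer intermediates; memory scales
  with batch size × segment length, fine at this problem scale but not
  intended for larger vocabularies or hour-scale recordings.
* EDF ingestion is not implemented; recorded data enter through the
  documented plain-directory container (`write_container()` /
  `read_container()`) or directly as in-memory recordings.
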