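---
title: "Decoding birdsong syllables and closing the loop: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding birdsong syllables and closing the loop: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(songloop)
```

`songloop` re-creates, as a self-contained and fully testable toolchain, a
quasi-real-time birdsong syllable decoder and the closed-loop
operant-conditioning engine that sits on top of it. This vignette explains
the model behind each stage, the tunable parameters and why their defaults
are what they are, the numerical choices that were genuinely open, and what
the synthetic test corpus does and does not demonstrate.

## The segmentation front end

Audio arrives as mono PCM at 44.1 kHz. Frames are non-overlapping 256-sample
windows (5.8 ms), Hamming-weighted and Fourier-transformed; the magnitudes of
the 128 lower half-spectrum bands form the spectrogram. The lowest 8 and
highest 40 bands — which carry mostly cage noise and little song — are
dropped, keeping 80 bands spanning roughly 1.4–15.2 kHz.

**Magnitude normalization.** Magnitudes are divided by half the Hamming
window sum, so a full-scale sine registers near 1.0 in its band. We
deliberately chose a *causal*, clip-independent scale rather than
normalizing by the clip's peak: peak normalization cannot be computed until
a recording has ended, and it would make streamed and offline decodings of
the same audio diverge. The cost is that the edge threshold is expressed in
fractions of full scale and must be tuned to the recording chain's gain; the
benefit is that one threshold means the same thing in every mode.

**Edge detection.** Syllables are found with the two 3×3 Prewitt kernels.
The response at each cell is the larger absolute value of the time-gradient
and frequency-gradient responses; the kernels are equivalent up to
orientation, so combining them by a maximum treats onsets/offsets (vertical
edges) and spectral contours (horizontal edges) symmetrically. A narrowband
syllable has strong frequency-direction edges on *every* frame of its
duration, so a syllable appears as an unbroken run of edge-bearing frames.
Runs shorter than 5 frames ("more than 4") are rejected as transients. The
default threshold of 0.1 suits the synthetic corpus (syllable amplitudes
near 0.6 of full scale, 20 dB SNR); for other material it should be set just
above the Prewitt response of the noise floor, which is the same per-corpus
tuning any recording chain requires.

**Bout grouping.** A rise/decay accumulator separates song from isolated
noise detections: +1 per detected syllable, −0.5 per second of silence,
bout opening at 3.0. These constants are exposed but their ratio is what
matters: with the defaults, four syllables inside one second open a bout,
while occasional single detections never do. The bout is backdated to the
first syllable of the activity run that opened it, and closes exactly 2 s
after its last syllable.

**Features.** Each syllable yields a fixed 40-frame × 80-band window
anchored at its onset — 3200 dimensions. Shorter syllables are zero-padded
at the tail (the window never leaks spectrogram content past the syllable's
end, which keeps features independent of what follows); longer ones are
truncated. Onset anchoring (rather than centering) was chosen because run
onset is the only boundary available before a syllable has finished, so the
same window definition works in streaming mode.

## Unsupervised syllable discovery

Up to 20,000 syllables sampled from up to 2000 songs are embedded in 2-D by
exact t-SNE at perplexity 30 (inner loops in C++; features are first
reduced to 50 principal components). DBSCAN then clusters the layout with
`eps = 2.25`, `min_pts = 27` — the midpoints of the ranges that, adjusted
per corpus, give 10–20 clusters whose member spectrograms look distinct.
Letters are assigned by descending cluster size, and `/` is reserved for
silent gaps.

**Layout standardization.** The raw t-SNE canvas grows with the number of
embedded points, while the DBSCAN radius is an absolute distance; clustering
the raw layout would make `eps` mean different things at different corpus
sizes. `embed_2d()` therefore rescales the final layout to a fixed per-axis
standard deviation of 10. On the default synthetic corpus the resulting
cluster count is insensitive to this target over at least 6–12, so the
choice is not delicate; it simply pins a unit for `eps`.

**Noise handling.** Noise-labelled syllables are excluded from classifier
training. At decode time every detected syllable receives its arg-max
letter — there is no reject class, because a conditioning engine needs a
decision for every bout in real time.

## The classifier

A single-hidden-layer softmax network maps the flattened 3200-dim window to
a letter. Capacity is selected by AIC: for every candidate hidden size from
10 up to the number of discovered classes, the network is trained and
`AIC = 2k − 2 log L` recorded, with `k` the total weight-and-bias count and
`log L` the training-set multinomial log-likelihood at the restored best
epoch; the arg-min size wins. Training uses full-batch Adam with a
stratified 10 % validation split and stops once validation cross-entropy has
risen for six consecutive epochs, restoring the best epoch. The trainer is
written in-package because the procedure needs per-epoch validation hooks
and an AIC trace; `nnet` serves as an independent cross-check in the test
suite, not as the implementation.

## Decoding, offline and streamed

Offline decoding runs segmentation, classifies every syllable, inserts `/`
after every 50 consecutive syllable-free frames (290 ms), and closes bouts
2 s after their last syllable. It is exactly deterministic.

The streaming decoder consumes chunks of arbitrary size, reassembles
256-sample frames, and maintains the edge-run, gap-counter and
bout-accumulator state machines incrementally. A letter is emitted as soon
as the syllable's trailing edge plus one syllable-free frame are seen (the
Prewitt kernel needs one frame of lookahead), which puts the per-event
decision latency at two frame durations (~11.6 ms) on a simulated stream;
real deployments add device I/O on top, so latency is logged per event and
never asserted. The streamed symbol sequence equals the offline one — the
test suite checks this for frame-aligned and arbitrary chunkings.

Two decisions the gap marker needed that no single rule fixed: the counter
*resets* after each emission, so a 120-frame silence yields two markers;
and marking stops once the 2-s bout tail after the last syllable has
elapsed, so trailing silence yields at most six markers instead of an
endless stream. Both choices apply identically offline and streamed.

## Evaluation

Annotations are compared by global alignment at unit edit costs, with a
deterministic tie-break (match > substitution > deletion > insertion).
Sequence identity is 100 × matches / *reference* length; the denominator
choice is documented and tested because the measure is asymmetric. The
alignment's non-match columns partition exactly into substitutions,
insertions and deletions. Per-letter match rates are normalized by the
letter's reference occurrences and reported with their support, since rates
over a handful of occurrences are weak evidence. Reproducibility across
runs is summarized as a coefficient of variation, and two Pearson
correlations are compared by the Fisher-Z equality test. Because two
decoders letter the same bird differently, `map_labels_by_overlap()`
derives the letter bijection from temporal overlap majority votes before
alignment.

## The conditioning engine

Each bout's maximum target-syllable run length `R` is judged at bout end
against the active rule: `REWARD` pays iff `R ≥ x`; `NOT_TOO_MUCH` pays on
`x ≤ R ≤ x + 1` and explicitly omits above; `EXCESS_REWARD` ignores the
song and pays once per full minute of the block, anchored at block start;
`NO_REWARD` never pays. The threshold-at-`x` convention (reward when the
threshold is reached, not strictly exceeded) matches the rewarded-range
convention of the omission window. Rewarded bouts schedule feedback 2 s
after bout end — a deliberate delay, mirroring a natural social-response
latency. Thresholds are chosen from a baseline corpus as the smallest `x`
rewarded by at most a small fraction of songs (a few percent).

Schedules are ordered, non-overlapping blocks of (rule, cue); a bout
spanning a boundary is judged by the rule active when it *ends*, because
that is when the decision physically happens. Overlapping rewards are
logged without suppression. The hourly cue design (10-min colored frame,
50-min blank, colors alternating hourly) is provided as a constructor.

The closed loop is tested with a simulated singer: run lengths follow a
shifted geometric law whose mean steps up after each reward, down after
each omission, and is clamped to `[1, 12]`. This is a deliberately minimal
learner — enough to show that the engine, and nothing else, produces the
repetition increase under `REWARD` and its absence under `NO_REWARD`, each
over 20 seeded runs.

## Song-syntax statistics

N-gram transition matrices count windows strictly inside bouts, with no
padding symbols; rows are (n−1)-gram contexts, normalized by row totals.
Display pruning hides entries below 1 % share in *both* their row and their
column — an AND rule — and is purely presentational: counts are retained
and unpruning restores the original exactly. Share is computed on counts;
whether the 1 % refers to count share or probability share was an open
choice and count share was adopted (they coincide for rows, and count share
keeps the column criterion well-defined when column probabilities are not
normalized). Matrix similarity is Pearson correlation over the union label
space (a Spearman option exists, since rank correlation is sometimes wanted
for heavy-tailed usage distributions), optionally restricted to the top-k
transitions of the first matrix with lexicographic tie-breaking.

## The synthetic corpus: what it shows and what it cannot

The generator renders songs from 12 spectrally distinct syllable types
(within the 10–20 range typical of Bengalese finch song): one broadband
noise-burst introductory note plus 11 song types alternating harmonic
stacks, tones, chirps and a noise burst, spread over 1.6–9.4 kHz with at
least ~400 Hz between fundamentals. Each rendition jitters pitch (±2 %),
duration (±8 %) and amplitude (±10 %): real syllables vary between
renditions, and this variability is load-bearing — without it every
rendition of a type is bit-identical up to frame phase, and the type's
feature cloud collapses into disconnected micro-lobes that density
clustering rightly refuses to merge. Gaps of 30–80 ms separate syllables;
every song ends with 2.5 s of silence so the bout closes; white noise is
added at a stated SNR (20 dB by default, measured against the rms of the
active samples).

Repetition of the target syllable is drawn from an explicit shifted
geometric run-length law rather than left to emerge from the first-order
transition table, and the chain never re-enters the target immediately
after a run (adjacent runs would otherwise concatenate and distort the
law). This mirrors the empirical finding that repetition counts in real
song are not first-order Markov, and it gives conditioning simulations a
single knob that shifts run lengths directly.

Passing end-to-end tests on this corpus demonstrates that the pipeline —
segmentation through classification through rule evaluation — is correct
and internally consistent at realistic noise levels. It does *not*
demonstrate performance on real recordings: real syllables have richer
spectro-temporal structure, amplitude modulation, reverberation and
overlapping cage noise, and real repertoires contain confusable type pairs
on purpose. Accuracy figures obtained on the synthetic corpus are
upper bounds, not predictions.

## Problem sizes and numerical choices

The packaged tests train on a 200-song, ~3500-syllable corpus at 20 dB SNR
(t-SNE over 500 iterations, DBSCAN at defaults, hidden sizes 10–12), which
exercises every stage at a scale where clustering structure is genuinely
non-trivial; the acceptance script uses an 80-song corpus for the
reproducibility figure, which is insensitive to corpus size. Determinism
throughout comes from explicit seeding: the same seed yields byte-identical
corpora, identical embeddings and identical selected models. Degenerate
inputs (audio shorter than one window, empty masks, empty bout streams,
all-noise clusterings) return typed empty results or instructive errors
rather than propagating `NaN`s; ties (equal cluster sizes, equal alignment
costs, equal maximum runs) all have documented deterministic resolutions.

## Known limitations

- Exact t-SNE is quadratic in the number of syllables; 20,000 points are
  feasible but slow, and larger corpora would need a Barnes-Hut
  approximation.
- The DBSCAN parameters are exposed, not auto-tuned; the per-corpus manual
  adjustment loop is part of the method.
- The streaming decoder simulates a stream from chunk iterators; it does
  not talk to audio hardware, and its latency figures exclude device I/O.
- Identity scoring needs a letter correspondence between two annotations;
  the overlap-vote mapping assumes the two annotations segment the audio
  broadly alike and can be fooled when one side merges adjacent syllables.
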