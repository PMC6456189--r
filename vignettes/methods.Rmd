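---
title: "Methods: non-verbal speech cues from dyadic clinical interviews"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: non-verbal speech cues from dyadic clinical interviews}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadcues)
```

## The measurement problem

Negative symptoms of schizophrenia — alogia, blunted affect, avolition,
anhedonia, asociality — are assessed by semi-structured interview on
ordinal scales such as the NSA-16: sixteen items on a 1–6 Likert scale
(higher = more impaired), a global rating, the item total, and five domain
sums (communication = items 1–4, emotion/affect = 5–7, social involvement =
8–10, motivation = 11–14, retardation = 15–16). `validate_ratings()`
enforces these arithmetic identities on every ratings table.

The package operationalizes the interview itself as the measurement
instrument: both participants wear lapel microphones, the session is a
2-channel PCM WAV (one channel per speaker), and two families of objective
cues are extracted — *conversational* cues (who speaks, when, and how the
floor is exchanged) and *prosodic* cues (how the voice sounds). These are
then correlated with the clinical ratings and used to classify symptom
observability and group membership.

## Voice activity detection

No VAD algorithm is canonical for close-talk lapel recordings, so the
package uses the simplest deterministic one that is adequate for them:
a frame (30 ms window, 10 ms hop; frame *i* covers the half-open interval
[*i*·hop, *i*·hop + window)) is provisionally active when its RMS level
exceeds `threshold_db` (default −40 dBFS). Smoothing then runs
**fill-then-delete**: inactive gaps shorter than `min_pause` (default
200 ms) lying between active runs are filled, and only afterwards are
active runs shorter than `min_speech` (default 100 ms) deleted. Filling
first matters: a fragmented utterance whose pieces are individually short
survives as one run instead of being deleted piecemeal. The composite is
idempotent — after filling, every interior gap is at least `min_pause`, and
deleting a short run only ever merges gaps that are already long enough —
which the test suite checks by property. Leading and trailing silence is
never filled. All three parameters are exposed; none is inferred from the
audio.

The two lapel channels are processed independently on a shared frame grid.
Cross-talk cancellation is deliberately out of scope: the prosodic stage
instead masks each channel to its *own* active frames, so the faint image
of the other speaker never contributes descriptors.

## Conversational cues

Utterances are maximal active runs. Each utterance *u* of speaker X is
assigned exactly one category by a fixed rule cascade against the other
speaker Y (`interjection_max` defaults to 1 s, since back-channels like
"okay"/"hmm" are sub-second tokens):

1. *speaking interjection* — shorter than `interjection_max` and entirely
   inside an utterance of Y;
2. *natural interjection* — shorter than `interjection_max`, no overlap
   with Y, and both nearest neighbouring utterances belong to Y (ties in
   neighbour distance resolve in Y's favour, a convention the brute-force
   test oracle shares);
3. *interruption* — *u* starts while Y's utterance *v* is ongoing
   (v.start < u.start < v.end on the frame grid) and outlasts it; *u* is a
   turn and X is credited one interruption;
4. *failed interruption* — starts during *v* but ends no later; not a turn.
   This is an operational definition: the cue is named in the field but
   rarely defined, and "overlapping utterance that fails to take the floor"
   is the version a frame-level detector can decide;
5. *natural turn* — otherwise.

Turns are individual qualifying utterances, not merged floor spans, so that
the *speech gap* (pause between one speaker's consecutive turns) remains
measurable within a long floor hold. *Response time* is the latency of a
clean floor exchange: a turn of Y ending at t_e followed, with no
intervening turn, by a turn of X starting at t_s ≥ t_e contributes
t_s − t_e; exchanges taken by interruption are excluded, which makes
response times non-negative by construction (the quantity is a latency, not
a signed overlap).

Percentages (speaking, mutual silence, overlap, between-speaker
differences) are frame fractions and satisfy
speaking_A + speaking_B − overlap + mutual_silence = 100 exactly on the
grid. Event counts are normalized per minute of *recording* (not of
speaking time — the sources that report such cues normalize to session
length, and the alternative is noted as ambiguous). The "difference turn"
cue is defined here as |natural turns A − natural turns B| per minute; like
the failed-interruption rule this is the package's own choice where the
field's tables name a cue without defining it. Means over empty event sets
are reported missing (`NA`), never zero — a subject with no clean floor
exchange has no response time, not a zero-second one.

Speaking rate is estimated as syllable nuclei per second of speaking time:
within each active run, the smoothed (≈50 ms) RMS envelope registers a
nucleus on each upward crossing of half the run's envelope peak, re-armed
only after dipping below a quarter of it, with nuclei at least 150 ms
apart. The hysteresis is the prominence criterion: steady voicing shows a
small phase ripple in frame RMS that naive peak picking counts as
syllables, whereas a genuine syllable cycle dips deeply between nuclei. On
a 4 Hz amplitude-modulated tone the estimator reads ≈4 syllables/s; on an
unmodulated tone, at most one nucleus. Run-relative thresholds trade
robustness to loudness differences between utterances against undercounting
within runs whose loudness drifts; the estimate is treated as a relative,
not absolute, cue.

## Prosodic cues and functionals

Per frame (the speaker's own active frames only): volume as RMS in dBFS;
F0 by the normalized autocorrelation method in a 70–400 Hz search band with
a voicing decision at an autocorrelation peak ratio of 0.45; formants
F1–F3 as LPC root angles (order 2 + sample_rate/1000, pre-emphasis 0.97,
Hamming window), keeping roots with bandwidth under 600 Hz and sorting
ascending; 13 MFCCs from a 26-band mel filterbank log-energy DCT (the
minimal standard set covering the coefficients that appear in published
best-feature lists).

F0 is reported at the *integer* autocorrelation lag, without parabolic
refinement. This is a deliberate numerical choice: session functionals
include a histogram entropy whose bins span the observed range of the
track, and sub-bin interpolation jitter on a stationary signal would smear
a degenerate (essentially constant) track across bins, turning an entropy
of exactly 0 bits into an arbitrary positive number. Integer-lag
quantization costs at most about half a lag step of accuracy (≈1.5 Hz at
220 Hz and 16 kHz, well inside the ±3 Hz the tests demand) and makes the
estimator exactly constant on stationary input.

Session functionals are min/max/mean plus Shannon entropy (log base 2) over
50 equal-width bins spanning [min, max] of the track; 50 bins is a
configurable default recorded in the output, chosen as fine enough to
resolve F0 dispersion differences at a few thousand voiced frames per
session yet coarse enough not to be dominated by estimator quantization.
A constant track has entropy 0 (one occupied bin); values uniform over two
occupied bins give exactly 1 bit. Whether functionals should be computed
per session or in windows of a few seconds is genuinely ambiguous in the
source material; the package computes session-level functionals and leaves
windowing to the caller. MFCCs are summarized by per-coefficient means.
Empty or single-frame tracks yield `NA` functionals, propagated rather than
imputed.

## Association

Pearson r between each cue and each NSA item (ordinal items treated as
numeric, as is conventional in this literature), pairwise-complete, with
p-values from the t transform on n−2 degrees of freedom; cells with a
constant variable report `NA`, never 0. No multiplicity correction is
applied by default — mirroring how such per-cell tables are reported — and
a Benjamini–Hochberg option exists but is off. The cohort used for the
correlation table (patients only vs everyone) is an explicit argument,
because pooling groups inflates correlations through the group contrast
itself. Group comparisons use `stats::kruskal.test` (rank H with tie
correction); features significant at p < 0.01 carry five-number boxplot
summaries, matching how such contrasts are usually displayed.

## Classification

NSA items binarize as 1–2 → non-observable, 3–6 → observable. Two
selectors are provided: correlation ranking (top-k |r| with the 0/1 label,
name-order tie-break) and CFS, merit = k·r̄_cf / √(k + k(k−1)·r̄_ff) over
absolute Pearson correlations, searched best-first with a stop after five
consecutive non-improving expansions and deterministic name-order
tie-breaks.

Leave-one-subject-out cross-validation refits median imputation,
standardization, and feature selection on every training fold — the
workflow that produced the published numbers is silent on this, and
non-nested selection leaks the held-out subject, so nesting is the default
behaviour (the leakage probe in the test suite injects a feature
informative only at a single subject and checks it buys nothing).
Classifier settings are fixed and recorded rather than tuned: linear SVM
with C = 1; 100-tree random forest; one hidden layer of 16 units
(decay 0.01, 200 iterations); 50 bootstrap-aggregated trees. Stochastic
learners are reseeded per fold from the caller's seed. AUC is the rank
statistic over held-out decision scores pooled across folds, midranks on
ties. Class imbalance is left unweighted, matching the baseline-like
behaviour of the published reports; a fold whose training labels collapse
to one class is skipped with a warning, and a fold with no usable features
falls back to a majority vote with an uninformative score (so constant
features yield majority accuracy and chance AUC, rather than an artifact
of the leave-one-out prior).

## The synthetic cohort generator

Real interview corpora of this kind are not publicly deposited, so the
package ships a generator whose *directions* — not magnitudes — encode the
clinical structure: with rising latent severity in [0, 1], turns shorten
(lognormal, mean ≈12 s down to ≈3.6 s), response latencies lengthen
(gamma, mean 0.5 s up to 3 s), interruptions and back-channels become
rarer, and the rendered voice narrows in F0 and volume dispersion and slows
its syllable rate. Controls draw severity from Uniform(0, 0.2), patients
from Uniform(0.2, 1.0); the default study scale is 54 patients and 26
controls. Ratings are clamp(round(1 + 5·severity + noise), 1, 6) per item
with SD-0.5 noise, and totals/domains are computed from items, never drawn.
The interviewer profile is held fixed across subjects, isolating subject
effects as a single trained interviewer would. One fixed master seed
reproduces a cohort bit-for-bit; per-subject seeds are integers derived
from it.

Audio is rendered as a harmonic pulse train (five harmonics, 1/h rolloff)
with per-200 ms F0 and amplitude draws and a sinusoidal syllabic
amplitude modulation. What this emulates is the *statistical* structure the
pipeline consumes: periodicity for F0, resonance-free spectra, dispersion
differences for the entropy functionals, envelope rhythm for speaking rate.
What it does not emulate: real formant structure (rendered audio has no
vocal-tract filter, so formant tracks on synthetic speech are not
meaningful — formant recovery is instead tested on constructed two-pole
resonators), lexical content, cross-talk between lapel channels, room
acoustics, or overlapping-speech spectra. Passing tests on synthetic
cohorts therefore demonstrate that the machinery recovers known structure,
not that real clinical effect sizes are reproduced; the generator's
couplings are far cleaner than clinical data, and observed correlations
near ±0.9 on synthetic cohorts should not be read as attainable on real
interviews (where ±0.3–0.5 is typical).

Default session length is 300 s rather than a realistic ≈30 min; the
conversational cues are rates and means whose estimators stabilize well
below that, and the test suite's cohort-scale checks (twenty master seeds
of 54 + 26 subjects at 300 s, conversational cues only) complete in a few
minutes at that size. Audio-bearing checks use 10–20 subject cohorts at
60–120 s or single constructed signals of a few seconds.

## Degenerate inputs and edge conventions

All-silent recordings are valid: zero rates, 100 % mutual silence, missing
means. Mono or >2-channel WAVs are rejected by name with the channel count.
A signal shorter than one analysis window is an error; exactly one window
is one frame (frame count = floor((N − W)/H) + 1). WAV writing quantizes
to 16-bit with round(x·32767), and a written file reads back to exactly the
quantized samples. Entropy of fewer than two finite values is an error at
the primitive level and `NA` at the functional level. Correlation cells
need at least three complete pairs. `loocv` requires at least four subjects
and both classes present overall.

## Known limitations

The VAD has no hysteresis or noise tracking and assumes close-talk SNR.
Speaking rate is envelope-based and undercounts when loudness drifts within
a run. The F0 estimator's lag quantization limits absolute accuracy at high
F0 (the step grows quadratically with frequency). CFS best-first search is
greedy and may miss the global merit optimum on adversarial correlation
structures. The generator's severity couplings are monotone by
construction, so it cannot probe the pipeline's behaviour under null or
sign-reversed couplings except by setting them so explicitly.
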