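---
title: "Simulating lexical-stress discrimination experiments: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating lexical-stress discrimination experiments: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stresslab)
```

`stresslab` is a simulation and analysis pipeline for go/no-go operant
experiments on lexical-stress perception: subjects learn to respond to
two-syllable nonsense words of one stress pattern (trochaic,
STRONG–weak, or iambic, weak–STRONG) and withhold to the other, and are
then probed with unreinforced novel words and cue-stripped words. This
vignette documents the models, the tunable parameters, the numerical
choices, and what the simulated components can and cannot tell you about
real subjects.

## The lexicon

Each of the two training sets holds 12 CV.CV nonsense words built from 6
syllables, every syllable appearing in four words — twice in first and
twice in second position — and the two sets share no syllables, so novel
probe words are novel at the syllable level as well. The printed
word table flows four columns of syllables row-wise; `build_training_sets()`
freezes the unique column-interleaved reading that satisfies all of
those structural constraints, and `validate_word_set()` re-derives every
constraint so the transcription cannot silently drift. The reading order
of a flowed table is in principle ambiguous; the structural invariants
cut the candidates down sharply (a row-sequential reading, for instance,
yields 12 distinct syllables per set and is rejected), and the frozen
transcription is documented here as one consistent reading rather than a
claim of uniqueness.

Stressed syllables carry the full vowel (A → [ɔ], E → [eɪ], I → [i:],
O → [oʊ], U → [u:]); unstressed syllables the reduced vowel ([ə] for A,
O, U; [ɛ] for E; [ɪ] for I). `vowel_realization()` exposes the table.

## Stimulus synthesis

Stress is realized by four independent acoustic cues, each with fixed
stressed values and randomized unstressed values (or vice versa for
pitch):

| cue | stressed draw | unstressed draw |
|---|---|---|
| pitch | starts 194 Hz, ramps linearly to a peak ~ U(230, 280) Hz | flat 194 Hz |
| duration | 0.5 s | ~ U(0.3, 0.4) s |
| amplitude | RMS 0.1 | ~ U(0.0316, 0.0447), i.e. 7–10 dB down |
| vowel | full realization | reduced realization |

Random values are drawn independently per syllable occurrence at
bank-generation time; a seed freezes the bank, and regeneration is
bit-identical. Whether the original experiments shared the unstressed
draws within a word is not documented; independence is assumed here and
is the more conservative choice (it adds within-category variability).

Because no speech recordings are distributed with the package, audio is
produced from scratch by classical source–filter formant synthesis: an
impulse-train glottal source with −6 dB/oct spectral tilt (white noise
for voiceless segments), a cascade of three two-pole resonators
realizing F1–F3 targets per vowel (editable CSV in
`inst/extdata/formants.csv`), and stylized consonant onsets — closure
plus burst for stops, shaped noise for fricatives, a low murmur for
nasals, formant glides for approximants. This is not a claim of
naturalness: the scientific content of the stimuli is the four cue
manipulations, which are controlled exactly, and synthetic stimuli make
every parameter reproducible.

Numerical choices:

* sample rate 44100 Hz, 16-bit PCM mono WAV (stimulus energy lies below
  5 kHz, so this is generous);
* the pitch ramp spans the voiced portion and peaks at syllable end;
* each syllable gets 5 ms raised-cosine edge ramps to prevent
  concatenation clicks; ramping happens before the final RMS
  normalization, so the duration contract (exactly
  `round(duration × sample_rate)` samples) and the RMS contract (syllable
  RMS equals its target) hold exactly;
* syllables are concatenated with zero gap;
* synthesis tolerances asserted in the test suite: duration ±1 sample,
  RMS ±1 %, f0 ±2 Hz for the flat unstressed contour (median over voiced
  frames) and ±5 Hz at the stressed contour end, where the
  frame-averaged autocorrelation estimate necessarily lags a ramp whose
  slope reaches ~200 Hz/s.

The `duration_removed` manipulation forces both syllables to 0.5 s while
`vowel_removed` forces both to the full vowel; the two axes are
independent (whether the original stimuli also equalized the vowel's
intrinsic duration under vowel removal is not documented).

## Trial scheduling and phase criteria

The protocol is: preliminary training (single syllables, sound vs
no-sound, blocks of 10 with 5/5 composition, syllables cycling without
replacement) → discrimination training (words, 50/50 trochee/iamb per
block) → pre-testing (S+ reinforcement drops to 85 % to blur the
contrast with unreinforced probes) → novel-word test (120 trials: 12
blocks of 2 probes + 4 S+ + 4 S−; each of the 24 novel stimuli exactly
once, each trained stimulus exactly 4×) → pre-testing again → cue-removal
test (240 trials, 24 blocks, the 48-probe bank — 3 exemplars × 8
manipulations × 2 patterns — each probe exactly once). Probes are never
rewarded or punished; responses on S− trials earn a penalty (humans:
−10 points and a 5 s delay; budgerigars: a 30 s delay).

All progression criteria use the discrimination ratio with threshold
0.8. Humans run trial-counted phases: advance at the first trial ≥ 10
where the phase-cumulative DR reaches 0.8, fail at the phase maximum
(100 preliminary / 150 discrimination / 50 pre-testing). "Overall DR" is
read as phase-cumulative rather than windowed; that is the natural
reading of a criterion phrased as "a minimum of 10 trials with an
overall DR of 0.8", and it is the stricter interpretation early in a
phase. Budgerigars run daily sessions of variable length, modelled as
Poisson with mean 103 trials and a floor of 40 (sessions are
time-limited in the operant box, not trial-limited); they advance on 2
sessions at criterion (preliminary), 4 consecutive sessions
(discrimination), ≥ 3 sessions with the last 2 at criterion
(pre-testing), or 1 session (second pre-testing), and fail at a session
cap (130 for discrimination, matching the point at which real
non-learners were abandoned; 40 elsewhere). The birds' visual
shape-training that precedes the auditory task involves no auditory
computation and is not simulated. A budgerigar may split a fixed-length
test over sessions; the schedule cursor resumes where it stopped.

Within-block probe positions are uniformly random (only the
2-per-10 composition is constrained); nothing in the protocol
description suggests further constraints.

## The simulated observer

The observer is deliberately the simplest mechanism that produces
go/no-go logs with the statistical structure the analysis assumes; it
makes no claim of cognitive realism and is not fitted to any subject
data (none is available at trial level).

**Perception.** Each syllable's cues are normalized to comparable
scales: pitch as semitones above 194 Hz divided by the maximum excursion
(12·log₂(280/194) ≈ 6.35 st), amplitude as dB re 0.1 divided by the
10 dB range, duration as (d − 0.3)/0.2, vowel fullness as 0/1. Cue
values come from the stimulus manifest, not from audio — simulation must
be fast — and the test suite separately verifies that audio-derived
measurements agree with the manifest within the stated tolerances, so
the shortcut is sound. Stress salience per syllable is the weighted cue
sum plus independent Gaussian noise (`sigma`); the slot with higher
salience is perceived as stressed. When the salience difference falls
below the profile's `ambiguity` floor, perception is ambiguous and a
fair coin decides.

The ambiguity floor deserves a note, because it is the one place where
the model is more than a linear-Gaussian readout. With `ambiguity = 0`
(the default) the probability of a correct percept is Φ(Δ/σ√2), so
performance ratios across conditions are pinned to evidence ratios:
single-cue probes carry roughly a third of the evidence of
three-cue probes, and no value of `sigma` can put single-cue performance
near chance while keeping three-cue performance near ceiling. A
perceptual floor breaks that coupling: evidence below the floor is
discarded entirely, so a profile can be robust to losing one cue yet at
chance when only one cue remains — which is precisely the budgerigar-like
pattern. Humans-like profiles do not need it.

**Response and learning.** The perceived category drives a learned
association `a ∈ [0,1]`:
`P(go) = lapse·go_bias + (1 − lapse)·a[category]`, capped by a response
ceiling. After a rewarded response the association moves toward 1, after
a penalty toward 0, by `learn_rate · (target − current)`; probes and
no-feedback trials leave it unchanged. Learning operates on the percept,
not on raw cues or word identities — the simplest mechanism that both
acquires the discrimination and transfers it to novel words, which is
exactly what generalization testing demonstrates. Timeouts are simply
the complement of the go probability; latencies are decorative.

**Presets.** `human_like` (pitch 1.0, amplitude 0.9, duration 0.03,
vowel 0.03; σ = 0.28; no floor) encodes reliance on pitch and loudness;
`budgie_like` (0.40/0.50/0.40/0.50; σ = 0.15; floor 0.75) spreads weight
across cues behind a high floor; `nonlearner` has zero weights and zero
learning rate and is excluded at the first criterion phase. The presets
were calibrated — by simulation sweeps over replicate cohorts — solely
to reproduce the qualitative significance signatures (humans: all
one-cue-removed conditions plus pitch-only and amplitude-only
significant, duration-only and vowel-only at chance; budgerigars:
duration-removed and pitch-removed significant, no single-cue condition
significant) and should be read as demonstrations of those signatures,
not as measurements of any species.

## Statistics

The discrimination ratio is `%R(S+) / (%R(S+) + %R(S−))`; it is
undefined (flagged, not numeric) when the subject responds to nothing.
Category tests are binomial against p₀ = 0.5 with the uncorrected
normal approximation `z = (x − n/2)/√(n/4)` alongside exact tails, and
the exact test is treated as authoritative for n < 30, where discreteness
matters most. Two conventions for the counted n are reported throughout,
since either is defensible: go-responses to probes (the default for
pooled tests) and probe trials scored correct/incorrect (the default for
per-individual tests, whose 24-trial denominators give the familiar
z = 4.899 for a perfect subject). The uncorrected z approximates the
exact *mid-p* tail — at the null centre the plain exact tail is
0.5 + P(X = x)/2, which no uncorrected normal tail can match — so the
machinery's agreement check compares the normal tail with mid-p, where
agreement is within 0.01 for n ≥ 30.

`criterion_trace()` closes the loop: it recomputes cumulative and
per-session DRs from raw trial logs and re-applies every phase criterion,
verifying that the simulator's recorded phase decisions are reproducible
from its own logs.

## What the tests do and do not show

The test suite exercises synthesis acoustics against their printed
targets, the protocol's trial arithmetic, the reinforcement rates, the
statistical machinery against enumeration oracles, observer calibration
(type-I error of the per-individual test on guessing observers matches
the attained size of the discrete test), cue-weight recovery by logistic
regression on 5000 simulated percepts (problem sizes chosen to keep the
default run in minutes: 20-subject human cohorts, 3-subject budgerigar
cohorts, 10³–10⁴ Monte-Carlo draws). Passing tests show the pipeline is
internally consistent and reproduces the *structure* of such
experiments. They do not show that any real species behaves like a
preset: the observer omits attention drift, motivation, session-order
effects, stimulus-specific memorization and every other nuisance process
a real subject brings, and the synthetic voice omits coarticulation and
natural prosodic covariation. Subject-level outcomes (how many
individuals learn, pooled z values) depend on real populations and are
deliberately out of scope.

## Known limitations

* Diphthongs are realized with static mid-target formants; vowel quality
  is a categorical cue here, not a phonetic study.
* The autocorrelation f0 tracker is frame-based and lags fast ramps;
  endpoint checks use 20 ms frames for that reason.
* Budgerigar session lengths are Poisson by assumption; only the mean
  (103) is documented.
* The ambiguity floor is a stylized stand-in for whatever makes real
  budgerigars insensitive to isolated cues; nothing in the package
  distinguishes it empirically from alternatives such as multiplicative
  cue gating.
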