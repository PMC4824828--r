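# stresslab

Tools for studying the perception of **lexical stress** — the trochaic
(STRONG–weak) versus iambic (weak–STRONG) prominence patterns of
two-syllable words — with go/no-go operant methods, in humans and in
non-human animals such as budgerigars.

Experiments of this kind train a subject to respond to nonsense words of
one stress pattern (S+) and withhold to the other (S−), then probe with
unreinforced test stimuli: novel words (did the subject learn an abstract
stress rule?) and words with acoustic cues removed (which cues carry the
rule?). `stresslab` implements the full pipeline:

* **lexicon** — two disjoint 12-word sets of CV.CV nonsense words built
  from 6 syllables each (every syllable used in 4 words, twice initially
  and twice finally), with a stressed/reduced vowel-realization table and
  structural validators.
* **synthesis** — parametric source–filter formant synthesis of every
  syllable and word. Stress is carried by four independent cues:

  | cue | stressed | unstressed |
  |---|---|---|
  | pitch | 194 Hz rising linearly to a peak in [230, 280] Hz | flat 194 Hz |
  | duration | 0.5 s | uniform in [0.3, 0.4] s |
  | amplitude (RMS) | 0.1 | uniform in [0.0316, 0.0447] (7–10 dB down) |
  | vowel quality | full vowel | reduced vowel (schwa) |

  plus the 8 cue-removal manipulations used in probe testing
  (`pitch_removed`, …, `vowel_only`), WAV stimulus banks with CSV
  manifests that are bit-identical under a fixed seed, and acoustic QC
  (RMS, dB attenuation, autocorrelation f0 tracking).
* **schedule** — the phase state machine (preliminary → discrimination →
  pre-testing → novel-word test → pre-testing → cue-removal test), block
  composition (5/5 sound trials, 50/50 patterns, 2-probes-per-10 tests of
  120 and 240 trials), reinforcement contingencies (85 % partial
  reinforcement in pre-testing; probes never reinforced) and the
  species-specific progression criteria built on the discrimination
  ratio.
* **observer** — simulated subjects: per-syllable stress salience is a
  weighted sum of normalized cues plus Gaussian noise (optionally behind
  an ambiguity floor), mapped to go/no-go through a delta-rule learned
  association. Presets `human_like`, `budgie_like`, `nonlearner`.
* **analysis** — the discrimination ratio
  `DR = %R(S+) / (%R(S+) + %R(S−))` (0.5 = no discrimination, 1 =
  perfect), binomial category tests `z = (x − n/2) / √(n/4)` with exact
  tails, generalization and cue-removal reports, and an audit that
  recomputes every phase decision from the raw logs.

## Worked example

Simulate one budgerigar-like subject through the whole protocol and
score it:

```r
library(stresslab)
run <- simulate_subject("budgie_like", "budgerigar", seed = 42)
run
#> <stress_run: subject s01 (budgerigar), passed, set 1, S+ = trochaic>
#>            phase  status        dr trials_used sessions_used
#> 1    preliminary advance 0.9824561         332             3
#> 2 discrimination advance 0.9491525         426             4
#> 3     pretesting advance 0.9636364         301             3
#> 4 generalization advance 0.9574468         120             2
#> 5    pretesting2 advance 0.9677419         117             1
#> 6       cue_test advance 0.9793814         240             3
```

The subject advanced through every phase: e.g. discrimination training
ended after 4 consecutive sessions with a session DR ≥ 0.8, and the two
probe tests ran their fixed 120 and 240 trials. Generalization to novel
words:

```r
generalization_report(run)$per_subject
#>   subject_id trained_splus trained_sminus novel_splus novel_sminus
#> 1        s01         93.75       4.166667         100            0
```

The subject responded to 100 % of novel S+-pattern probes and 0 % of
novel S−-pattern probes — it transferred the stress rule to words it had
never heard (per-individual z = 4.90 over the 24 probe trials). The
cue-removal report (`cue_test_report(run)`) gives, per manipulation, the
percent of probe responses directed to the rewarded category with its
binomial test; cohort-level calls (`simulate_cohort`) reproduce the
qualitative species signatures: a `human_like` cohort stays significant
whenever pitch or amplitude is available but falls to chance with only
duration or only vowel quality, while a `budgie_like` cohort is at
chance on every single-cue probe yet significant with duration or pitch
removed.

A stimulus bank for listening or external use:

```r
ws <- build_training_sets()[[1]]
manifest <- write_stimulus_bank(ws, seed = 7, dir = "bank", cue_probes = TRUE)
nrow(manifest)   # 24 training WAVs + 48 cue-removal probes
```

A thin command-line wrapper with verbs `synth`, `simulate` and `analyze`
is installed at `inst/scripts/stresslab`.

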