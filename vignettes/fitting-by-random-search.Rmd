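---
title: "Fitting simulated hearing aids by genetic random search"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fitting simulated hearing aids by genetic random search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oprars)
```

## The fitting problem

A multichannel hearing aid is parameterized, per frequency channel, by
insertion gains (IGs) specified for 65- and 85-dB SPL speech inputs
(IGSP65, IGSP85) and by a compression threshold (CT), the input level above
which the compressor reduces its gain with slope 1/CR (CR = compression
ratio). A prescription rule maps an audiogram to initial settings; the
fine-tuning that follows in the clinic is expensive, because every candidate
setting must be evaluated with a speech-intelligibility test on the patient.

`oprars` replaces the patient with a simulation loop: candidate settings are
applied by a five-channel dynamic-range-compression hearing-aid simulator,
the amplified speech is degraded by a loudness-recruitment hearing-loss
simulator driven by the same audiogram, and a pluggable intelligibility
objective scores the result. Three seeded genetic random-search algorithms
(GEN1, GEN2, GEN3) tune one IG offset and one CT per channel — ten
parameters — against that objective. On the 0.1-dB gain grid over ±10 dB
and the 1-dB CT grid over 20–50 dB SPL this search space holds
`count_search_space()` = 6000^5 ≈ 7.78 × 10^18 configurations, which is why
a random search rather than enumeration is used.

## The processing chain

**Channel structure.** Five channels with edges 0.1, 0.7, 1.4, 2.8, 5.6 and
8 kHz. Each channel's centre frequency is the geometric mean of its edges
snapped to the nearest of the 11 audiometric frequencies (250, 1000, 2000,
4000, 6000 Hz); the centre is where the two-level gains are read when the
channel's CR is derived. The bank maps the 11 prescription frequencies onto
channels as 3, 2, 2, 2, 2.

**Baseline prescription.** Proprietary loudness-model rules are not
re-derived here. The default rule is a deliberately simple stand-in,
IGSP65 = 0.45·HL and IGSP85 = 0.30·HL (floored at 0, capped at 55 dB): it
is monotone in hearing loss and compressive (IGSP85 < IGSP65), which is all
the downstream stages need to operate on realistic values. Real
prescription output can be supplied through the `"external"` rule as a CSV
gain table. The baseline CT is 35 dB SPL, the midpoint of the search range.

**Compression-ratio constraint.** Each channel's CR is
`20 / (20 + IGSP85 − IGSP65)`. Candidates are repaired by 0.5-dB rules
re-evaluated per pass: if CR < 0, IGSP85 is raised; if 0 ≤ CR < 1, IGSP65
is raised; if CR > 10, IGSP65 is lowered. A zero denominator (infinite CR)
is handled by the CR > 10 rule, a case the three rules do not name.
Enforcement runs at the channel centre and the resulting correction is
applied to every frequency of the channel, keeping within-channel gain
shapes coherent.

**SII equalization.** The surrogate objective, like a speech recognizer
with input normalization, is insensitive to overall level, so a candidate
could drift to audibility levels a patient would never accept. Candidates
are therefore shifted by a uniform offset, in 0.1-dB quanta, until the
absolute difference between their Speech Intelligibility Index and the
baseline prescription's SII stops decreasing (the first non-improving step
is reverted). The SII is the band-audibility index
`sum(I_b * clamp((S_b - D_b + 15)/30, 0, 1))` over octave bands (250–8000
Hz, 6 bands; a third-octave scheme is available), with importance weights
`I_b` summing to 1 and the disturbance `D_b` equal to the listener's hearing
level plus the band's equivalent internal noise. The speech band levels are
measured once from the actual clean fixture tokens; the candidate's
insertion gains (65-dB level), interpolated at the band centres, are then
applied in the band domain. With the slow compressors used here the gain is
quasi-static at the operating point, so this matches the long-term spectrum
of the amplified waveform while keeping the 0.1-dB loop cheap. The shift is
applied to both IGSP65 and IGSP85, preserving the channel CRs; a final CR
pass guards the cap interactions. Equalization may push effective offsets
beyond the ±10 dB search bounds; this is permitted and flagged in the
configuration's provenance.

**Hearing-aid simulator.** The channel split is a zero-phase Butterworth
crossover tree (order 4 per pass, Linkwitz–Riley-like rolloff after
forward–backward filtering): adjacent channels are exactly
power-complementary, so the channels sum back to the band-limited input to
numerical precision. Each channel runs a feed-forward compressor — RMS
level detector (one-pole smoothing of instantaneous power with a 5-ms
symmetric pre-smoother, then attack/release constants of 200/2000 ms in
channel 1 and 100/1500, 100/1200, 100/1000, 100/1000 ms in channels 2–5;
only slow compression is modelled) and the static curve `out = in + gain`
below CT, slope 1/CR above — followed by an output limiter (second
compressor in series; input-referred CT 100 dB SPL, CR 10, 5/50 ms, all
configurable; these limiter values are conventional choices, not taken from
any measurement). The below-threshold gain is anchored so the 65-dB SPL
operating point receives exactly IGSP65. Calibration is fixed at unit
RMS ≡ 100 dB SPL.

**Hearing-loss simulator.** Two consequences of sensorineural loss are
modelled: threshold elevation and loudness recruitment. Both are realized
by a single expansive map applied to each band's envelope in dB:
`mapped = (level − HL) · ceiling/(ceiling − HL)`, which sends the elevated
threshold to 0 dB SPL and fixes the ceiling (default 100 dB SPL, a
configurable convention). A separate linear attenuation stage exists but
defaults to 0 dB, since nothing fixes the split between attenuation and
expansion; the expansion alone already enforces threshold elevation. Band
envelopes are RMS envelopes — one-pole smoothing of instantaneous power
with a 1-ms time constant — rather than analytic-signal magnitudes: for
tones the RMS envelope is exact whereas a rectified analytic magnitude
carries a ~0.9-dB bias, and the level-mapping tests (threshold, ceiling
fixed point, modulation-depth doubling) hold tighter this way. Loss of
frequency selectivity is deliberately not simulated.

## The objective

The reference listener of the original method — a GMM-HMM word recognizer
with a 50-item lexicon — is out of scope; two replacements are provided.

The **surrogate objective** scores each processed token by a short-time
objective-intelligibility-style metric: processed and clean token are
level-aligned (the recognizer-normalization analogue, making the metric
gain-invariant within ±12 dB), decomposed into the five channel bands, and
the per-band log-envelope frame sequences (16-ms frames) are correlated,
correlations clipped to [0, 1] and averaged. A token is "recognized" when
its metric reaches a threshold (default 0.5); the score is the percentage
recognized — for 50 tokens, a 2 % granularity — and the tie-breaking
likelihood is the mean metric over recognized tokens (over all tokens when
none is recognized, so the tie-breaker is total).

For speed inside the search loop the objective evaluates the chain in the
block-envelope domain: the channel decomposition, 1-ms block powers and
smoothed input-level traces of the clean tokens are precomputed once (none
of them depend on the candidate), and per candidate only the compressor
gain curve, limiter, recruitment map and frame correlations are applied to
those envelopes. `amplify()` and `simulate_loss()` are the waveform-domain
reference implementations of the same stages and remain the public API; a
test checks the two paths agree on presentation levels.

An **external recognizer** can be plugged in instead: processed tokens are
written as WAV files with a manifest, a user command is invoked, and a
result CSV (`token_id, recognized, log_likelihood`) is read back, restoring
the original top-5 decision rule when a real recognizer is available.

A third, audio-free **quadratic oracle** exists purely to validate the
optimizers: a Gaussian score bump around a hidden optimum, floor-quantized
to the 2 % grid, with likelihood equal to minus the distance. Distances are
computed on parameters expressed in units of their search stepsize (0.1 dB
for gains, 1 dB for CTs). Range-normalization was considered and rejected:
it makes one CT step count 6.7 gain steps, so late CT proposals dominate
the distance and stall the final gain refinement; stepsize units weigh
every coordinate at its own resolution. The bump width `tau` only scales
the printed score, never the search trajectory (acceptance compares scores
and then distances).

## The search algorithms

All three algorithms use four deterministic search "threads" (sequential
workers with independent seeded RNG streams — results are independent of
physical concurrency), 750 evaluations of the objective per thread in the
standard budget, and the same rollback rule: a candidate replaces the
incumbent only with a strictly higher score, or an equal score and strictly
higher likelihood; exact ties keep the incumbent.

* **GEN1** tunes all ten parameters at once in four independent threads,
  each starting from its own uniform random configuration. The half-range
  explored around the thread's best decays by a constant per-iteration
  decrement from half the search range (10 dB for gains, 15 dB for CTs)
  down to the parameter stepsize at the final iteration.
* **GEN2** tunes one channel at a time (channels 1→5, 150 iterations each),
  with the four threads synchronized each iteration on the cross-thread
  best (lowest thread index wins exact ties). Its half-range shrinks
  linearly to zero, indexed by the global iteration counter 1–750 — so a
  later channel starts with an already-narrowed range; per-phase indexing
  is a plausible alternative reading, but the fixed 750 denominator of the
  decay law is only consistent with the global counter. Untuned channels
  sit at the baseline prescription with the 35-dB SPL default CT;
  previously tuned channels are frozen at their best values.
* **GEN3** tunes all five CTs for 250 iterations with gains pinned to the
  baseline, then all five gain offsets for 500 iterations with CTs frozen,
  thread-synchronized like GEN2, same global-index linear decay.

Initialization evaluations (the random starting configurations) are not
counted against the iteration budget. Perturbations are uniform on
[−Δ, +Δ] — matching the uniform initialization — then rounded to the
parameter grid and clipped to the global ranges.

`run_experiment()` adds one deliberate deviation from pure random
initialization: it seeds one thread (GEN1) or the starting incumbent
(GEN2/GEN3) with the baseline configuration, so by the rollback guarantee
an optimized fitting can never be worse than the prescription it started
from. Pure random initialization remains the default of the `gen*_run()`
functions themselves.

## Synthetic fixtures and what they do (not) show

The speech tokens are seeded synthetic disyllables — a sawtooth source with
declining f0 (100–140 Hz), two random three-formant "syllables", a noise
burst at the second syllable onset, 0.4–0.8 s, calibrated to 65 dB SPL.
They give the objective matched clean/processed pairs of mutually distinct
items with speech-like spectro-temporal structure. They are not French
words, carry no lexicon, and the surrogate metric is not a recognizer:
absolute scores are not comparable to word-recognition percentages, and
passing tests demonstrate the mechanics and reproducibility of the chain,
not clinical benefit.

Synthetic audiograms emulate age-related high-frequency sloping losses at
severity levels 4–7: fixed monotone base profiles (PTA ordered by level)
plus a seeded overall shift (SD 2.5 dB), optional per-frequency jitter for
"individual-like" erratic shapes, rounded to the 5-dB audiometric grid.
The base profiles are this package's own choices of plausible mild through
moderately-severe losses, not any published cohort's means.

## Numerical choices

* Polynomial completion of audiograms fits the least-squares cubic in
  log2(frequency) — the audiometric axis; a cubic in linear Hz extrapolates
  wildly at 125 Hz — over all present points (≥ 4 required), and clamps
  filled values to [−10, 120] dB HL.
* The compressor's level detector works on block powers (`block` samples
  per control value; the search objective uses 1-ms blocks, `block = 1` is
  the per-sample default of the public API).
* Correlations on zero-variance reference segments are skipped; a flat
  processed envelope against a varying reference scores 0; digital silence
  has level −Inf and a metric of 0.
* `eq2` is floored at the stepsize and `eq3` at zero, so the off-by-one
  between "the range during iteration 750" and "after 750 decrements"
  vanishes at the limit.
* Problem sizes in the test suite are chosen for a desk run: the
  reproducibility experiment uses 12 synthetic audiograms, GEN1 at 75
  iterations, 50 tokens at 16 kHz; the optimizer-recovery checks run the
  full 750 iterations on the audio-free quadratic oracle.

## Known limitations

No real-ear acoustics (microphone, vent, receiver), no frequency lowering,
no masking spread or high-level distortion terms in the SII, no
speech-in-noise objective, no dead regions or broadened auditory filters in
the loss simulator. The baseline rule is a stand-in: fitted settings are
relative to it, and conclusions about a real prescription rule require
plugging its gains in through the `"external"` rule.
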