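---
title: "Segmenting phonocardiograms and detecting systolic murmurs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting phonocardiograms and detecting systolic murmurs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

murmurscan analyses phonocardiograms (PCGs) — stethoscope recordings of the
heart — and answers three questions at once: *where* are the fundamental
heart sounds (S1, systole, S2, diastole), *is there a systolic murmur and of
what timing*, and *how trustworthy is the recording*. A fourth, downstream
question — is the patient's clinical outcome normal or abnormal — is
answered by a gradient-boosted model fed with the per-site murmur evidence.

This vignette explains the model, its assumptions, the tunable parameters,
and the choices made where the design was genuinely open.

## The hybrid architecture

A PCG is a quasi-periodic sequence of S1 ("lub") and S2 ("dub") transients
separated by the systolic and diastolic intervals. Murmurs of interest here
are band-limited noise in systole. Classical segmentation decodes an
envelope with a hidden semi-Markov model (HSMM) that assumes a *healthy*
cycle, which is exactly what breaks when a loud murmur masks S1 or S2.
murmurscan instead:

1. converts the recording to a normalised log-spectrogram `x_{1:T}`;
2. predicts per-frame posteriors `P(q_t = ξ_i | x_{1:T}, θ)` over five
   states (S1, systole, S2, diastole, murmur) with a bidirectional
   recurrent network;
3. decodes the posteriors under **four competing duration-explicit HSMMs**
   `ω_1..ω_4` — no murmur, holosystolic, early-systolic, mid-systolic —
   each producing a segmentation `q̂^{(ω)}_{1:T}` and a confidence

   `C(ω) = (1/T) Σ_t P(q_t = q̂_t^{(ω)} | x_{1:T}, θ)`;

4. selects `ω̂ = argmax_ω C(ω)`. A murmur is called iff `ω̂` is a murmur
   model; `C(M) = max(C(ω_2), C(ω_3), C(ω_4))`, `C(N) = C(ω_1)` and the
   murmur likelihood is `C(M−N) = C(M) − C(N)`; `C(ω̂)` doubles as a
   signal-quality estimate.

Detection is therefore a *model-selection* problem: which interpretation of
the whole recording explains the frame classifier best.

## Feature extraction

The recording (4 kHz, mono) is mean-removed and peak-normalised — absolute
PCG amplitude depends on stethoscope pressure and carries no diagnostic
information. The spectrogram uses a 50 ms Hann window stepped by 20 ms:
long enough for 20 Hz frequency resolution, short against the ~100 ms S1.
Bins above 800 Hz are discarded (no heart-sound energy, a known overfitting
vector), leaving 41 bins at 4 kHz. Each frequency row is then z-scored
across time, which lifts quiet broadband murmur energy onto the same scale
as the loud transients.

Numerical choices:

* power (magnitude-squared) spectrum before the log; power is the
  conventional choice and the z-scoring absorbs the factor of two anyway;
* log floor `1e-10` so silent frames stay finite;
* frames are left-aligned, trailing part-windows dropped, and the frame
  count is `T = floor((N − 200)/80) + 1`;
* z-scoring divides by the *population* standard deviation (a two-point row
  maps to ±1); constant rows map to zero. A `scale = "var"` switch divides
  by the variance instead for compatibility with envelope-style pipelines.

The composition normalise → log → z-score makes the features exactly
invariant to rescaling the input amplitude, which the test suite asserts.

## The recurrent frame classifier

Ground-truth interval annotations give only the four classical states;
murmur frames are synthesised from the clinician's murmur-*timing* label:
within each systolic period, an early-systolic murmur claims the first 50%
of frames, mid-systolic the middle 50%, holosystolic all of them. The 50%
rule on an odd run rounds up, and the mid placement starts at `floor(L/4)`;
both are unstated in the source labelling conventions and fixed here once.
Expansion treats a maximal systole-or-murmur run as one systolic period, so
it is idempotent and never touches S1, S2 or diastole. Diastolic murmurs
are deliberately out of scope — they are rare, barely represented in
available data, and the label alphabet has no place for them.

The network is a three-layer bidirectional GRU, hidden size 60 per
direction; forward and backward streams are concatenated and passed through
fully connected layers of 60 and 40 units with Tanh activations and a
softmax over the five states. Dropout 0.1 sits between the GRU stack and
the FC head (and only there). There is no deep-learning framework in this
package's dependency set, so the network — forward pass,
backpropagation-through-time and Adam — is implemented directly in
RcppArmadillo; a finite-difference gradient check is part of the test
suite.

Training minimises cross-entropy weighted per class by inverse frequency
(weights rescaled to mean 1), otherwise diastole dominates the loss and the
rare murmur/S1/S2 frames are ignored. Optimiser settings are not dictated
by the architecture and default to: Adam at learning rate 1e-3, batches of
16 equal-length recordings (grouping by length avoids padding frames that
would distort the class weights), up to 30 epochs with early stopping on a
15% validation split (patience 5). The seed fixes initialisation, batch
order and dropout, making training bit-reproducible.

## Heart-rate estimation

State durations scale with heart rate, so decoding starts from an HR
estimate. Rather than the classical homomorphic envelope (kept in the
package as `estimate_heart_rate_envelope()` for comparison), the estimate
autocorrelates the *not-in-diastole* probability `1 − P(q_t = diastole)` —
a denoised, binary-ish version of the envelope. The search covers 30–180
bpm (paediatric rates run high). Peak picking is deliberately simple: the
biased, lag-0-normalised autocorrelation of the mean-removed series; a peak
is a strict local maximum; ties break to the smaller lag; and a candidate
whose *doubled* lag scores more than 5% higher is rejected as the classic
S1–S2 half-period alias. A constant series (no rhythm) is an error, not a
guess.

## The four decoders

All four HSMMs share Gaussian state-duration distributions whose means are
scaled so one full cycle sums to `60/bpm` seconds: S1 = 0.122 s and
S2 = 0.092 s are fixed, and the remaining cycle time is split
systole : diastole = 1 : 1.7 — values chosen once from the physiological
literature's typical ranges and exposed as arguments. The murmur sub-states
of `ω_3`/`ω_4` split the systolic share exactly as the 50% labelling rule
does (half, or quarter–half–quarter). Duration sd is 25% of the mean, and
the support is truncated to mean ± 3 sd (min 1 frame), which also bounds
the decoder's inner loop.

Topologies and observation columns:

| model | cycle | observations |
|---|---|---|
| `ω_1` no murmur | S1→sys→S2→dia | murmur column discarded, remaining four renormalised per frame |
| `ω_2` holosystolic | S1→sys→S2→dia | systole state reads the **murmur** column |
| `ω_3` early-systolic | S1→murmur→sys→S2→dia | raw columns |
| `ω_4` mid-systolic | S1→sysA→murmur→sysB→S2→dia | sysA/sysB read the systole column |

Two open points were settled as follows. First, a *single* systole state in
a cyclic chain cannot hold a mid-systolic murmur, so `ω_4` duplicates
systole around the murmur state. Second, after discarding the murmur
column for `ω_1` the remaining four posteriors are renormalised per frame,
keeping `C(ω_1)` on the same [0, 1] scale as the five-state models — without
this, murmur-heavy frames would handicap the normal model's confidence
rather than its fit.

The decoder itself is an exact duration-explicit Viterbi over segment
boundaries: path score = Σ log observation + Σ log Normal duration density
per complete segment, states forced around the cycle. Recordings start and
end mid-state, so the first and last segments are *partial*: they pay
observation cost but no duration penalty (capped at the duration-support
maximum). Arithmetic is in the log domain with observations floored at
1e-12. The implementation is verified against an exhaustive enumeration of
every segmentation on small instances (score *and* path), and the reported
confidence is recomputed independently from the path and posteriors in the
tests.

## Decision rules

Per recording, ties in the argmax break toward the lower model index
(conservative: `ω_1` first). Per patient: murmur in **any** recording ⇒
`present`; otherwise, if the aggregated `C(ω̂)` falls below 0.65 the
patient is `unknown` (unclassifiable signal); otherwise `absent`. The
aggregate across a patient's recordings is not pinned down by the
per-recording rule; the package uses the mean (symmetric, robust to one
borderline site) and exposes `aggregate = "min"` for the stricter reading.

## Clinical-outcome model

Per patient, the murmur likelihood `C(M−N)` and quality `C(ω̂)` are
averaged per auscultation site (aortic, pulmonic, tricuspid, mitral);
absent sites are *missing*, not zero — the tree learner handles missing
values natively. Recordings from non-standard sites are pooled into the
mitral slot with a warning. Age group (ordinal), pregnancy flag and the
recording count complete the eleven-dimensional feature vector. The
classifier is a gradient-boosted tree ensemble of depth 9 with class weight
1.8 on abnormal examples (sensitivity is the screening priority) and a
decision threshold of 0.4738, all configurable; boosting runs up to 200
rounds at learning rate 0.1 with early stopping on a 20% fold. Murmurs and
outcomes correlate imperfectly by design of the problem: many abnormal
hearts produce no audible murmur, which is why the outcome model sees
likelihoods rather than binary murmur calls.

## Evaluation metrics

The murmur task is scored with the 5:3:1 weighted accuracy (true classes
present : unknown : absent), per-class sensitivity/PPV/F1 (degenerate
denominators are reported as undefined, never 0, and excluded from the
macro F1 with a warning), micro accuracy, ROC/AUC using `C(M−N)` as the
continuous statistic (thresholds sweep the unique scores, a positive call
is `score ≥ threshold`, AUC by trapezoid, optional seeded percentile
bootstrap CI), Youden's index, and reliability bins (equal-width, empty
bins dropped). `unknown` patients must be removed before ROC analysis and
the functions refuse them.

## The synthetic generator

Real labelled PCG data cannot ship with a package, so every stage is
exercised on simulated recordings. `simulate_pcg()` emulates exactly the
structure the pipeline assumes: per cycle, a Gaussian-windowed tone burst
for S1 (~100 ms, 60–150 Hz) and S2 (~80 ms, 80–200 Hz, slightly quieter),
an optional murmur as 100–400 Hz band-passed noise over the configured
portion of systole with 10 ms cosine ramps, cycle lengths jittered ±5%,
plus white broadband noise. Murmur loudness is set relative to the S1
burst (grade tiers quiet/moderate/loud = −12/−6/0 dB). Ground-truth
intervals are exact by construction. `simulate_cohort()` adds the patient
layer: 1–4 sites sharing heart rate and murmur timing, a small fraction of
`unknown` patients rendered with heavy noise, and outcomes drawn from a
logistic model in murmur grade so that some abnormal patients have no
murmur. Cohort heart rates are drawn in 60–174 bpm so every recording sits
inside the 30–180 bpm search window.

What the generator does **not** model: S3/S4 extra sounds, diastolic
murmurs, split S1/S2, frequency-swept murmur envelopes, respiration and
sensor artefacts, or device transfer functions. Passing tests on this
generator therefore demonstrate that the machinery is correct and that the
method's assumptions imply its conclusions — not that real-world accuracy
matches; the published clinical figures come from a large curated dataset
that cannot be bundled here.

The feature-level `simulate_outcome_cohort()` plants a known
likelihood-to-outcome relationship (logistic in the patient's best site
likelihood, slope chosen so the signal is actually recoverable above label
noise) to test the outcome model without running audio through the whole
pipeline.

## Problem sizes and reproducibility

The package's simulated study uses 200 training and 100 held-out 8 s
recordings for the end-to-end experiment, 10 s recordings for heart-rate
recovery (the 30 bpm search bound needs a 2 s autocorrelation lag), and a
600-patient feature-level cohort for the outcome model. These sizes were
chosen once as a desk-scale experiment; `scripts/acceptance.R` re-runs the
whole study from a single seed, and the test suite asserts the study's
target properties (held-out frame accuracy ≥ 0.85, murmur AUROC ≥ 0.90,
median HR error ≤ 5 bpm, outcome AUROC > 0.8, and a positive
loudness/likelihood rank correlation). Every stochastic component —
generator, network training, bootstrap — is seeded, and equal seeds
reproduce results bit-for-bit.

## Known limitations

* Only systolic murmurs are representable; a diastolic murmur will at best
  lower `C(ω̂)`.
* The duration priors assume a roughly constant rate within a recording;
  severe arrhythmia violates the cyclic topology itself.
* `C(M−N)` saturates for very loud murmurs (once the murmur model wins
  every cycle there is little headroom), so it is a likelihood, not a
  grade estimate.
* The recurrent classifier is trained per corpus; applying a model trained
  on the synthetic generator to real recordings is not expected to work
  without retraining.
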