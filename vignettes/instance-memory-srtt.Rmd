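---
title: "An instance-based memory model of serial response time tasks with two uncorrelated sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An instance-based memory model of serial response time tasks with two uncorrelated sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srtecho)
```

## The scientific question

In a serial response time task (SRTT), participants respond to a stream
of stimuli whose order follows a hidden sequence; sequence knowledge
shows up as faster and more accurate responses on sequence-consistent
trials.  When a *stimulus* sequence (e.g., colours) and an independent
*response* sequence (e.g., key locations) are presented together,
participants can acquire both in parallel.  That observation is often
taken as evidence that sequence learning proceeds in encapsulated,
dimension-specific modules — if stimulus and response streams were
processed jointly in a single store, the two uncorrelated sequences
should interfere destructively and neither should be learned.

`srtecho` implements a simulation that probes this inference: a single,
non-modular, instance-based (global-matching, MINERVA-2-family) memory
that stores stimulus and response features *jointly* in each trace, run
through a full SRTT with two uncorrelated probabilistic sequences.  If
this single-store model nevertheless acquires both sequences, parallel
acquisition per se cannot discriminate modular from unitary
architectures.

## The model

### Task environment

Each trial presents one of 7 stimuli and requires one of 6 responses.
Each stream follows its own cyclic successor permutation: with
probability `p_regular` (default .5) the next item is the cycle
successor ("regular"); otherwise it is drawn uniformly from the items
that are neither the previous item (no direct repetitions) nor the
successor, so the regularity label is exact rather than probabilistic —
the way SRTT trial types are scored.  The two streams are generated
independently and run continuously across the 6 blocks × 180 trials of
a session.  Crossing the two regularity flags yields four trial types
(`both_regular`, `stimulus_only`, `response_only`, `neither`); under the
defaults each occurs on about a quarter of trials.

A disabled stream (`stimulus_sequence_enabled = FALSE`, etc.) draws
uniformly subject only to no-repetition; its flag then records chance
coincidence with the successor (probability 1/6 for 7 items, 1/5 for
6).  This is the building block for null and single-sequence designs.

### Representation

Items are fixed random binary feature vectors: 13 vectors (7 stimulus +
6 response) of length 30 with entries ±1, drawn as fair coins and
accepted only if all 78 pairwise cosines are ≤ .4.  The whole bank is
redrawn on a violation, so accepted banks are i.i.d. fair-coin vectors
conditioned on the acceptance region (acceptance probability ≈ .5, so
rejection is cheap).  The cap is applied to the *signed* cosine, the
literal reading of the constraint; `cap_mode = "absolute"` bounds the
magnitude instead for sensitivity analyses.  Feature vectors stay fixed
within a dataset — fixed feature-to-position assignment is what makes
similarity across instances computable at all.

### Instance memory and retrieval

Each completed trial is encoded as one 120-wide trace: the
concatenation `[current stimulus | previous stimulus | current given
response | previous given response]`, each feature independently stored
with learning rate `L = .8` and replaced by 0 otherwise.  Memory starts
with 200 pre-experimental traces of uniformly drawn items (no sequential
structure).  Crucially, the trace holds the response *actually given* —
after an error, the wrong key enters memory and the next trial's probe.

Before a response, memory is probed with what is already available: the
exact concatenation `[current stimulus | previous stimulus | previous
given response]` (width J = 90, never degraded by `L`).  For each trace
i,

* similarity: `S_i = (1/J) Σ_j P_j M_ij` over the 90 probe-aligned
  positions (trace segments 1, 2 and 4).  J is fixed at 90: unstored
  features lower similarity rather than shrinking the normaliser, which
  is what the flat `1/J` in the defining formula implies (the classical
  alternative normalises by the number of relevant features);
* activation: `A_i = S_i^3`, sign-preserving, so near-zero similarities
  are strongly down-weighted;
* echo content: `C_j = Σ_i A_i M_ij` over all 120 positions; its
  third segment `C*` is the model's belief about the current response;
* probe-content match: `I = Σ_j P_j C_j` over the probe-aligned
  positions, identically `90 Σ_i S_i^4 ≥ 0` (an algebraic identity the
  test suite asserts to 1e-9);
* summed activation: `ΣA = Σ_i A_i = Σ_i S_i^3`, the classical
  global-matching echo intensity.

The correct response's share of unsigned echo–response similarity gives
the signal-to-noise ratio

`SNR = (1 + cos(C*, R_m)) / Σ_k (1 + cos(C*, R_k))`,

with `R_m` the required response among the K = 6 candidates; SNR ∈
(0, 1) and an uninformative echo gives 1/6.  An exactly zero `C*`
(possible only in pathological tiny-memory settings) falls back to 1/6.

### Decision stage

The drift rate of a two-boundary Wiener diffusion is the retrieval
strength times the SNR, bounded below: `δ = max(3, SNR × strength)`,
with boundary separation α = 1.5, relative start β = .2, non-decision
time τ = .3 s, unit diffusion coefficient.  Accuracy coding maps the
upper boundary to the correct key; a lower-boundary absorption picks one
of the five wrong keys uniformly.  Note that β = .2 starts the process
nearer the error boundary; it is implemented as specified.  The floor is
exposed as `{floor | cap | none}` because a *lower* bound of 3 on drift
is an unusual modelling choice worth probing.

### Which retrieval strength drives the drift

Two definitions of "echo intensity" circulate for global-matching
models: the probe-content match `I = Σ P_j C_j` and the summed
activation `ΣA`.  They behave very differently as memory grows.  Because
`I = 90 ΣS_i^4` is a sum of fourth powers, every trace contributes
positively: the partial matches that any probe has with unrelated traces
(a shared stimulus here, a shared previous response there, plus the ≤ .4
background cosines) accumulate into a floor that grows linearly with the
trace count.  Measured under the default design, `I` is already ≈ 270 on
trial 1 (200 pre-experimental traces) and exceeds 1,000 by block 6, so
`SNR × I ≥ ~37` throughout — the drift floor never binds, responses
saturate at ceiling accuracy (error rates below 1e-9), and the
error-rate panel of the learning figure degenerates to zero.  The summed
activation, by contrast, is signed: activations of unrelated traces
cancel, and `ΣA` tracks the accumulation of genuinely matching episodes.
With `δ = max(3, SNR × ΣA)` the floor binds early (memory uninformative,
error rate ≈ .16 at δ = 3) and releases as matching traces accumulate,
producing declining RTs, declining error rates, and the
`both < single-regular < neither` trial-type ordering on both measures.

`drift_coupling = "activation"` is therefore the default study
condition; `"content"` (the literal probe-content match) and
`"content_normalized"` (`ΣS^4`) are retained as configuration options so
the saturation behaviour can be reproduced and explored.  The echo
object always reports both measures.

## Numerical choices

* **Exact first-passage sampling.** `sample_wiener()` draws the
  absorbing boundary from the closed form
  `P(upper) = (1 − e^{−2δz}) / (1 − e^{−2δα})` (z = βα) and the decision
  time by inverse-CDF sampling of the exact conditional first-passage
  distribution, using the spectral series of the defective CDF
  `F_0(t) = P_0 − (π/α²) e^{−zδ} Σ_k k sin(kπz/α) e^{−λ_k t}/λ_k`,
  `λ_k = (δ² + k²π²/α²)/2` (the upper boundary via the reflection
  z → α − z, δ → −δ).  The series is truncated adaptively so the
  neglected tail is below ~1e-15 at the smallest time evaluated, and the
  quantile is bracketed below by the time before which total absorption
  mass is < 2e-15, then bisected to 1e-9 s.  Crude Euler time-stepping
  would bias first-passage times upward by O(√step); it exists only as
  `euler_oracle()`, an independent cross-check used by the test suite.
  First-passage times above 10 s process time (practically impossible
  with δ ≥ 3) are resampled once, then flagged censored and excluded
  from RT means.
* **Zero-padded trace store.** The session loop preallocates the trace
  matrix at its final size; all-zero rows have zero similarity and
  activation and therefore contribute nothing to any echo quantity, so
  no per-trial subsetting or reallocation is needed.  An exported
  functional API (`run_trial()`, `encode_instance()`, …) executes the
  identical cycle; the test suite verifies the two agree draw-for-draw
  under a common seed.
* **Seeding.** The master seed yields per-dataset seeds, each dataset
  seed yields its bank, its two successor cycles and per-participant
  seeds, and every participant re-seeds its own stream — results are
  bit-reproducible and independent of scheduling order.  All seeds are
  recorded in the per-dataset metadata.
* **Warm-up.** Trial 1 has no meaningful previous trial; one unanalysed
  uniform draw initialises the previous-trial registers, and trial 1 is
  excluded from classification and analysis.
* **Successor cycles** are drawn once per dataset and shared by its
  participants, keeping a dataset internally comparable; whether the
  cycle should vary across participants is not determined by the design,
  and per-dataset redraw is this package's choice.

## Analysis

Per participant and cell (block × trial type), the mean RT over correct,
non-censored trials and the error proportion are computed first; cell
means are then averaged with *equal weight per participant* (pooled
across datasets), so participants with unbalanced cell counts do not
tilt the grand means.  Error rates and RT means come from disjoint trial
subsets.

The 95% within-subject intervals use Cousineau participant-mean
centring with the Morey bias correction `sqrt(C/(C−1))` over the C cells
of each measure's block × type grid, and a normal quantile on the
corrected standard error.  "Within-subjects confidence interval" names a
family of procedures; this variant is the common default, and it is
isolated in `within_subject_ci()` so alternatives can be swapped.

`learning_contrasts()` reports, per block and pooled over blocks
(`block = "all"`), the paired contrasts of each trial type against the
fully regular baseline for both measures, with CIs over participants.
Under the null (both sequences disabled) the pooled contrasts are the
appropriate summary: at 95%, one of 36 per-block intervals is expected
to exclude zero by chance alone.

## Problem sizes and what the tests show

The package's replication runs use 5 datasets × 40 participants
(200 participants, ≈ 216,000 trials) — a scale at which the trial-type
ordering and its growth across blocks are decided far outside
Monte-Carlo noise, and which a laptop completes in a few minutes.  The
full 1,000-dataset design is a documented configuration
(`experiment_config()` defaults) rather than the default test scale.

The generator emulates the *design* of such experiments — probabilistic
sequences, no repetitions, trial-wise remapping implicit in separate
stimulus and response codes.  It does not emulate human data: no
fatigue, practice effects outside memory growth, response-key biases,
post-error slowing, or explicit strategy shifts.  Passing tests
therefore show that the single-store model *can* produce parallel
acquisition of uncorrelated sequences under the stated design, not that
human parallel acquisition has this mechanism.

## Known limitations

* The iterative-resonance retrieval loop of older instance models is
  deliberately absent; the diffusion stage replaces it.
* No forgetting, decay or trace-strength weighting; memory only grows.
* Correlated stimulus–response sequences (where the model predicts
  *better* learning, a discriminating prediction against modular
  accounts) are reserved as a configuration hook but not implemented.
* The diffusion stage has no inter-trial parameter variability and is
  not meant for fitting empirical RT distributions.

## A minimal session

```{r example, eval = FALSE}
cfg <- experiment_config(n_datasets = 2, n_participants = 8,
                         master_seed = 11)
ex <- run_experiment(cfg)
ex$summary$summary          # 24 rows: block x trial type
lc <- learning_contrasts(ex$summary)
lc[lc$block == "all", ]     # pooled contrasts vs the both-regular baseline
render_summary(ex$summary, out_dir = "srtecho-out")
```
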