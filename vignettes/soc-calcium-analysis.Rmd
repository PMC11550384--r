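---
title: "Models and design choices in the soccal SOC analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in the soccal SOC analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

soccal analyzes one-photon calcium-imaging and freezing data recorded
during second-order fear conditioning (SOC): a light CS1 is first paired
with a foot-shock US, a tone CS2 is then paired with the CS1, and the
animal's fear of the tone — together with the cue responses of the imaged
neurons — is measured on a final test day. This vignette documents the
models the package implements, the parameters that matter, and the design
choices made where the procedure was genuinely open. The companion
`analysis/` scripts run the full workflow on the synthetic study;
`scripts/acceptance.R` recomputes the headline quantities.

## Normalization

Raw fluorescence is converted neuron-by-neuron to fractional change about
the whole-trace mean,

$$\Delta F/F = \frac{F - \overline{F}}{\overline{F}},$$

so each output row has zero mean and the transform is invariant to
positive rescaling of the raw signal (gain, LED power). Rows with
non-positive mean fluorescence are an error naming the neuron.

For cross-animal comparison, peri-event slices are standardized against
their own pre-onset baseline,

$$Z(t) = \frac{x(t) - \mu_{F_0}}{\sigma_{F_0}},$$

where $F_0$ is the half-open window $[-10, 0)$ s before event onset.
Choices worth making explicit:

* **SD estimator.** $\sigma_{F_0}$ is the population SD (divisor $N$).
  The source formula does not name an estimator; we fix one and use the
  same convention in every test, so baselines come out with mean 0 and SD
  exactly 1.
* **Order of operations.** Z-scoring is applied to the $\Delta F/F$
  trace, not to raw $F$ — the standardization makes the result identical
  either way up to the affine invariance $z(aF+b) = z(F)$, which the test
  suite asserts.
* **Per-trial baselines.** Each trial is standardized by its own $F_0$
  (the formula reads per event); a `per_trial = FALSE` flag pools the
  baseline across trials for users who prefer a per-session reference.
* **Degenerate trials.** A constant baseline (zero SD) would produce
  infinities; such neuron-trials are set to `NA`, counted, and reported
  with a warning rather than propagated.

## Alignment and AUC

Event onset maps to the first sample with $t \ge$ onset; the baseline is
the half-open window $[-\text{pre}, 0)$ and the response is $[0,
\text{post}]$. Trials whose window does not fit inside the session are
excluded and enumerated — never padded. Trial averages are pointwise
means; population traces add the SEM across neurons.

Response magnitude is the area under the trial-averaged $\Delta F/F$
trace, integrated by the trapezoidal rule (standard and refinement
stable: doubling the sampling rate of a band-limited trace moves the
integral by well under 1%). Three windows are tabulated: `auc_pre`
($-10..0$ s), `auc_post` ($0..10$ s) and `auc_late` ($10..20$ s); the
late window supports the analyses of activity sustained for ~10 s beyond
cue offset. Per-trial AUCs are available via `trial_auc()` for
trial-course comparisons (early vs late conditioning trials).

## Responsive-neuron classification

A neuron is `increased` when its post/pre AUC ratio exceeds 1.5 (a >50%
increase), `decreased` below 0.5, `no_change` otherwise, with strict
inequalities at both boundaries. The open design question is what to do
when the baseline AUC is near zero or negative — $\Delta F/F$ integrates
to values of either sign, and a ratio against a near-zero denominator is
meaningless. The package uses one robust threshold,

$$\varepsilon = 3 \cdot \mathrm{MAD}(\text{auc}_\text{pre}),$$

falling back to 1% of the baseline-window length when the spread is zero
(e.g. a single record). When $\text{auc}_\text{pre} > \varepsilon$ the
ratio rule applies; otherwise the neuron is classified by the difference
$\text{auc}_\text{post} - \text{auc}_\text{pre}$ against the same
$\varepsilon$. Because both branches scale with the data, the rule is
invariant to positive rescaling of the AUC pair. The factor 3 keeps the
false-call rate among genuinely unresponsive neurons at the percent
level: the null difference has SD $\approx \sqrt{2}$ times the pre-AUC
noise, so a threshold much below ~3 robust SDs would flag a large
fraction of noise as responses, while a much larger one would miss weak
but real ones. `degenerate` is reserved for non-finite AUC records;
near-zero baselines are legitimate `no_change` candidates, not errors.

Population percentages are printed with one decimal, rounded half-up
(`percent1()`), matching the reporting convention of the study (53 of
122 prints as 43.4%). `encode_overlap()` partitions a common neuron
universe by responsiveness to two cues (e.g. CS1/CS2-encoding vs
CS2-only neurons).

## Response-archetype clustering

Trial-averaged z-scored traces over $-10..+20$ s are clustered with
Euclidean K-means (k = 5 in the study), 50 random restarts, best
within-cluster sum of squares kept, under a fixed seed. Cluster quality
is the mean silhouette width on the same trace vectors (no embedding);
`select_k()` scans k = 2..8 and takes the argmax, breaking ties toward
the smallest k. A scan whose silhouette never exceeds 0.2 triggers a
"no cluster structure" warning. All-identical traces are rejected
(silhouette undefined). On the synthetic test day the scan may prefer a
smaller k than 5 — the generator plants fewer effective archetypes than
real data exhibits — and the workflow reports both the k = 5 solution
and the scan.

## Longitudinal registration and tracking

Neurons are matched across sessions greedily, one-to-one, on a
similarity score in $[0, 1]$ with the study's acceptance threshold 0.5.
Two feature channels are supported:

* **Centroid proximity** $\exp(-(d/\sigma_c)^2)$ with length scale
  $\sigma_c = 10\ \mu m$ — the primary channel, analogous to spatial
  longitudinal registration.
* **Reference-trace correlation.** When combined with centroids the
  Pearson r is rescaled to $[0,1]$ as $(1+r)/2$, so an uninformative
  correlation ($r \approx 0$, the norm for neurons without a cue
  response, whose trial averages are noise) is neutral rather than a
  veto; with trace-only features the raw r is the score, preserving
  "minimum correlation 0.5" semantics.

Cross-phase tracking in the pipeline scores centroids only: response
tuning changes across learning are the phenomenon under study, so trace
correlation across phases would penalize exactly the neurons of
interest. Matching is deterministic (ties broken by neuron id,
symmetrically in the two sessions) and symmetric in its arguments.
Optimal-assignment matching is not implemented; greedy matching is
simple, reproducible, and recovers >95% of true correspondences at the
simulator's footprint density. The shock day is excluded from tracking
(motion artifacts in the study; the chain is habituation -> CS2-CS1 ->
test). `track_categories()` reports per-neuron category trajectories,
the first-vs-last-phase transition matrix (whose marginals equal the
per-phase category counts of tracked neurons), and group-wise mean AUC
per phase for neurons grouped by their habituation category.

## State correlations and effect size

`max_pairwise_corr()` concatenates the sample windows of a behavioral
state (baseline: the 5 min before the first event; tone/light: the cue
windows), computes zero-lag Pearson correlations between all neuron
pairs, and keeps each neuron's maximum over partners — "maximum pairwise
correlation" is read as max over partners, not over lags (no lagged
variant is implied by the procedure). Zero-variance neurons are excluded
with a record. States are compared by Cohen's d with the usual pooled,
$N-1$-weighted SD; the estimator is antisymmetric and calibrated (on
exchangeable synthetic data the baseline-vs-baseline |d| stays below
0.1 when averaged over seeds).

## Freezing and memory metrics

A motion sample counts as frozen when its magnitude is below a threshold
for at least `min_bout_s` contiguous seconds (runs measured on the whole
trace, so bouts spanning a window edge still count). The bout floor
(default 1 s) suppresses single-frame noise in thresholded real traces;
`min_bout_s = 0` reproduces pure thresholding and is the mode used when
validating recovery of planted freeze fractions, since a bout floor by
construction discards genuine sub-second freeze time. Freezing percent is
the frozen share of each 10-s cue window, with an optional post-cue
(offset to +10 s) percent.

The second-order memory-strength ratio is each mouse's mean test-day CS2
freezing divided by its reference CS1 freezing (by convention the CS1
trials of the CS2-CS1 pairing session), times 100; mice with zero CS1
reference are excluded with a warning, and the ratio is invariant to a
common rescaling of both percentages. Extinction series are summarized
by trial-ordered means plus the rate of an exponential fitted by least
squares on `log(pmax(y, floor))` (floor 0.5 percentage points); the
per-trial means are the primary output and the rate is a convenience
summary — a constant curve has rate 0, an all-zero curve has no defined
rate and is flagged.

## The synthetic-data generator

Every downstream stage is validated against seeded synthetic experiments
because the study's raw miniscope recordings are not recomputable at
desk scale. The generator emulates:

* **Paradigm.** Habituation (10 CS1 + 10 CS2, randomized order, 1-2 min
  intervals), CS1-US (10 trials, 0.5 s shock co-terminating with the
  10 s light), CS2-CS1 (4 pairings, 0.5 s gap), test (3 tones), 2-min
  ITIs, 10 Hz sampling, a 300 s pre-session baseline and a 30 s tail.
  Stimulus intensities (lux, dB, mA) are metadata, not simulated.
* **Transients.** Event boxcars (extended 10 s past offset for the
  sustained class) convolved with a double-exponential kernel, rise
  $\tau = 0.2$ s and decay $\tau = 1.2$ s — published GCaMP6m-like
  kinetics, configurable and not a claim about the recordings. The
  convolved shape is peak-normalized so a neuron's gain is its peak
  $\Delta F/F$; inhibited neurons receive the negated drive at half
  gain. Gains jitter in [0.7, 1.3], onset latencies in [0, 0.2] s.
* **Nuisance structure.** Multiplicative baseline drift (70% slow
  sinusoid, 300 s period, random phase; 30% linear trend; amplitude 10%
  of baseline) plus i.i.d. Gaussian noise on the $\Delta F/F$ scale
  (default SD 0.05; "SNR" in the tests is kernel amplitude over this
  SD).
* **Planted classes.** Per-phase class fractions default to the
  reported population proportions (e.g. ~41% tone-responsive at test, a
  quarter of them sustained, 6% inhibited); assignment is a
  deterministic block partition over the neuron index so cross-phase
  trajectories are reproducible.
* **Footprints and dropout.** Centroids are uniform over a field whose
  side scales as $300\sqrt{n/26}\ \mu m$, matching the study's ~26
  neurons per 300 um field of view (simulated cohorts pool animals);
  per-session observation jitter is 2 um and per-session dropout 20%.
* **Behavior.** A two-state freeze/move Markov chain at the imaging
  rate whose stationary freeze probability equals the planted fraction
  (baseline 0.05; cue-window fractions default to CS1 0.6 during
  pairing and CS2 0.4 at test, a planted memory-strength ratio of
  66.7%). Mean freeze-bout length is 1.5 s, and the state is redrawn
  from the new stationary distribution whenever the planted level
  changes — cue-evoked freezing onset is effectively immediate — which
  keeps window-level fractions unbiased. A deterministic mode freezes
  exactly the first planted fraction of each window for exactness
  tests. Motion is 0 while frozen, a floor of 1 plus half-normal jitter
  while moving.

What the generator does **not** emulate: motion artifacts, photobleaching,
neuropil contamination or crosstalk between cells, non-stationary noise,
real inter-animal variability in SNR (no recording-level SNR statistics
are available to fit),
pixel-level movies, or video-based freezing annotation. Passing tests
therefore demonstrate that the pipeline's arithmetic, conventions, and
recovery behavior are correct under a faithful schedule and plausible
signal model — not that the biological conclusions of any particular
recording would be reproduced.

## Problem sizes and numerical conventions

The test suite and acceptance script run scaled sessions (shorter
pre-session baselines and intervals, 30-200 neurons, 3-20 seeds per
Monte-Carlo claim) chosen so each property is measured with comfortable
margin: classifier recovery uses 20 replicate 200-neuron cohorts;
freezing recovery averages 10 replicate 100-window cohorts (a single
100-window realization has ~1.9-point Monte-Carlo SE from bout
autocorrelation alone); the baseline-vs-baseline effect size averages 20
seeds of 100 exchangeable neurons. Floating-point assertions use 1e-12
for element-wise identities, 1e-9 for accumulated reductions. All
randomness flows from explicit integer seeds; the full pipeline is
byte-identical across reruns with the same configuration.

## Known limitations

* The matcher's composite score is a documented stand-in for image-based
  registration; it is validated only against synthetic correspondences.
* Freezing semantics (threshold + bout floor) stand in for frame-by-frame
  human annotation; they are validated against planted two-state
  behavior, not video.
* The silhouette scan can prefer fewer clusters than a fixed k = 5 when
  the population genuinely contains fewer archetypes; both outputs are
  reported.
* Statistical hypothesis testing (ANOVA, t-tests) is out of scope; the
  package computes descriptive summaries and effect sizes only.
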