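---
title: "Methods: ensembles, behavior relevance and functional networks from calcium traces"
author: "CalciumEnsembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensembles, behavior relevance and functional networks from calcium traces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CalciumEnsembles)
```

# Scope and data model

This package operates downstream of miniscope signal extraction. Its
inputs are per-session matrices of extracted calcium activity (one row
per accepted neuron, one column per 10 Hz frame), hand-scored behavior
bout intervals in seconds, and — when several sessions of the same
animal are analysed together — cross-session neuron identity maps
produced by multi-session registration. Motion correction, source
extraction and registration themselves are out of scope; the identity
maps are consumed, never computed.

The central container, `TraceMatrix`, extends `SummarizedExperiment`:
the `"activity"` assay holds the matrix, rowData carries per-neuron
flags (and ground-truth labels for simulated sessions), and the object
records its frame rate and normalization state. Traces exist in two
states: `raw_nonneg` (as extracted, all values ≥ 0) and `zscore`
(each row transformed to mean 0, population SD 1). The distinction is
load-bearing: the relevance and network statistics use the cosine
similarity, which is only guaranteed to lie in [0, 1] for non-negative
inputs, so they consume raw traces, while clustering and activity
summaries consume z-scored traces. `classifyNeurons()` therefore
refuses z-scored input rather than silently computing a statistic with
a different range.

Behavior is represented as a binary per-frame vector. Frame `f`
(0-based) is in-bout when its midpoint `(f + 0.5)/rate` falls inside a
half-open interval `[start, end)`. The bout times are scored in
seconds with no statement about frame alignment; midpoint membership
is this package's convention, chosen because it is symmetric and
off-by-one-safe at 10 Hz. The number of ones equals the total bout
duration times the frame rate within one frame per bout.

# Ensemble detection

Neurons are clustered with k-means (Euclidean distance, best of 20
restarts by within-cluster sum of squares) on their z-scored traces.
For z-scored rows the squared Euclidean distance is `2 n (1 − r)`
with `r` the Pearson correlation, so clustering on traces is
clustering by activity-pattern correlation, consistent with
correlation clustermaps of the same data. An alternative would be to
cluster the correlation matrix itself; traces were chosen as the more
direct object (one design decision exposed rather than hidden:
`wcssCurve()`/`clusterNeurons()` take the trace matrix, and any
precomputed similarity stays in the network module).

The number of ensembles is read off the WCSS curve. The curve is
non-increasing in `k` (asserted in the tests); the selection rule is
the maximal discrete second difference
`WCSS(k−1) − 2·WCSS(k) + WCSS(k+1)` over interior `k`, ties to the
smaller `k`. A curve with no convex elbow (all second differences
non-positive, e.g. linear decay) yields `k = 1` with a warning rather
than an arbitrary interior answer. WCSS is named as the model-selection
device in the source methodology without a stated rule; the second
difference is the standard elbow formalisation and is deliberately
cheap to override — `runPipeline(k = 2)` fixes the count directly, as
analyses of these recordings conventionally use two ensembles.

Per-ensemble mean traces are correlated with the behavior vector, and
each neuron with its own ensemble mean. Whether the neuron should be
excluded from its ensemble mean before correlating is not specified in
the source methodology; the package includes it by default (matching
the plain reading of "correlation with the mean activity of the
ensemble to which it belonged") and exposes `excludeSelf = TRUE`.
Singleton ensembles are flagged because their self-inclusive r is
identically 1; constant neurons get `NA` rather than a propagated
`NaN`. Cumulative distributions of these coefficients are compared
between groups with the asymptotic two-sample Kolmogorov–Smirnov test,
and dual-recorded neurons' coefficients across paired sessions with a
two-sided Pearson test (`cor.test`), requiring at least three pairs.

# Behavior-relevance classification

For each neuron the raw statistic is the cosine similarity between its
non-negative trace and the behavior vector. The null distribution is
built from 1,000 random circular shifts of the trace by offsets drawn
uniformly from `{1, …, n−1}`. The source methodology says only
"randomly shuffled"; circular shifting is the conservative reading
because it preserves the trace's autocorrelation — a plain frame
permutation destroys the calcium-kernel structure, deflates the null's
spread and inflates significance. The plain permutation remains
available (`mode = "permutation"`) for exactly that comparison.

Percentiles use R's default linear interpolation (type 7), and the
label rule is strict: positive iff `R >` the 95th percentile, negative
iff `R <` the 5th, irrelevant otherwise — a statistic exactly at a
percentile is irrelevant. No multiple-testing correction is applied
across neurons; the 5% tails per neuron are the stated design, and the
package's calibration check verifies that behavior-independent neurons
are labelled positive and negative at 5% each (within three binomial
standard errors over 20 seeds × 400 neurons).

Implementation note: the dot products of all circular shifts are
computed at once through the FFT cross-correlation identity
(`O(n log n)` per neuron instead of `O(n · nPerm)`), and the sampled
offsets index into that vector. The tests pin this against brute-force
enumeration of every shift on a 100-frame toy at 1e-9.

# Functional networks

Pairwise cosine similarity between raw traces is thresholded against
phase-randomization surrogates: the Fourier phases of all non-DC,
non-Nyquist bins are replaced by i.i.d. uniform(0, 2π) draws with
Hermitian symmetry enforced, so the surrogate keeps the original
amplitude spectrum exactly — hence the original mean, norm and
autocorrelation — while scrambling temporal alignment. Both members of
a pair are randomized independently (the reading of randomizing "each
pair"). Surrogates may dip slightly below zero after randomization and
are used as-is; since raw similarities of non-negative traces are
≥ 0, link decisions are unaffected. A pair is linked when its raw
similarity strictly exceeds the 99.17th percentile of the surrogate
distribution. That percentile is taken as a parameter, exactly as
printed in the source methodology (it is consistent with a corrected
one-sided level but is not derived here), and is configurable.

The default construction pools surrogates for tractability: `S = 100`
surrogates per neuron are paired across each neuron pair, giving
`S² = 10,000` pair similarities from `n·S` Fourier transforms instead
of `pairs × 2 × 10,000`. Because every surrogate is independently
phase-randomized, a pooled pair similarity follows the same null law
as a freshly drawn pair; the estimated threshold differs only through
the mild dependence among the `S²` combinations, and a full
per-pair mode (`mode = "full"`) exists and is compared against the
pooled mode in the tests. On 50 independent-noise neurons the realised
edge density matches the design rate `1 − 0.9917` within three
binomial standard errors of the 1,225 pairs.

Degree centrality is `links/(n − 1)` per neuron, computed through
igraph, and is summarised for all neurons, behavior-linked neurons
(positive or negative) and irrelevant neurons; an empty subgroup is
reported as missing, not an error.

# The synthetic-session generator

The generator exists so that every stage has inputs with known ground
truth. Its defaults are the package's reference conditions, fixed
once:

| parameter | default | meaning |
|---|---|---|
| `frameRate` | 10 Hz | acquisition rate of the recordings |
| `nFrames` | 6,000 | a 10-minute session |
| `meanBoutS` / `meanGapS` | 2 s / 10 s | exponential bout/gap means (bouts truncated at 0.5 s), ≈ 17% of frames in-bout, typical of a 10-minute interaction session |
| `rateOnHz` / `rateOffHz` | 2 / 0.2 Hz | event rates in preferred vs non-preferred state for positive/negative neurons — the generator's detectable effect size |
| `rateBaseHz` | 0.5 Hz | constant rate of irrelevant neurons |
| `classMix` | 0.10 / 0.05 / 0.85 | positive/negative/irrelevant fractions, of the order seen in these recordings |
| `nEnsembles` | 2 | ensembles, assigned round-robin |
| `ensembleDriveRateHz` | 0.3 Hz | shared drive events per ensemble |
| `participationP` | 0.9 | probability a drive event fires a member |
| `kernelTauS` | 1 s | exponential calcium decay (GCaMP7-like at 10 Hz; kinetics are not specified upstream, so this is a knob) |
| `noiseSd` | 0.1 | additive Gaussian noise before rectification |
| `crossSessionOverlapP` | 0.5 | probability a neuron reappears in the paired session |

A trace is an inhomogeneous Bernoulli event train (per-frame
probability `rate/frameRate`), plus ensemble drive events shared with
probability `participationP`, convolved with `exp(−t/τ)`, plus noise,
rectified at zero. Rectification keeps traces valid for the
non-negative cosine statistic. The `hyperconnectivityConfig()` preset
raises participation to 0.97 and the drive rate to 1.0 Hz, emulating a
phenotype of tightly synchronised, densely connected populations for
network-discrimination tests.

What the generator does **not** emulate: photon/imaging noise
statistics, spatial footprints and crosstalk between neighbouring
cells, slow drift and bleaching, biophysical spike dynamics, and
behavioral structure beyond an alternating renewal process. Passing
recovery tests on synthetic sessions therefore demonstrates the
correctness and calibration of the statistics under the stated
generative assumptions, not performance on any particular recording.

Determinism: every stochastic function takes a seed and restores the
caller's RNG state (`withr::with_seed`); identical seeds give
bit-identical sessions, null bands and networks.

# Numerical conventions and degenerate inputs

* Population (ddof 0) SD for z-scores; constant rows become zeros and
  are flagged, never `NaN`.
* Percentile estimates use linear interpolation (quantile type 7).
* Displayed percentages round half-up to one decimal (49/300 → 16.3),
  with integer display when exact (27/300 → "9"); full precision is
  retained internally. Half-up is implemented with a 1e-9 guard
  against binary representation artefacts (0.15 must round to 0.2).
* Zero-norm vectors are domain errors for the cosine; constant traces
  or behavior vectors are degenerate-null errors for classification;
  empty bout sets are domain errors for in-bout activity summaries.
* k-means restarts that collide on duplicated rows fall back to
  seeding centers from the distinct rows; `k = n` returns singleton
  clusters with WCSS 0 directly.
* On-disk numbers are serialised as `%.17g`, so write/load round trips
  are bit-identical. Because no R HDF5 binding is a dependency here,
  the hierarchical session container is a plain-text directory
  (`traces/`, `bouts/`, `identity/`, `groundtruth.json`) with the same
  structure; single matrices use CSV plus a JSON metadata sidecar.

# Dose arithmetic

The supplement cocktails are drinking-water mixtures of BCAA
(Leu:Ile:Val = 2:1:1), L-serine and zinc. With average intakes of 3 g
chow and 4.8 ml water per mouse per day and water density 1 g/ml, the
chow-equivalent concentration of a nutrient is
`chow_conc + water_conc × 4.8/3`, identically for % w/w and ppm. The
half-cocktail Ile and Val water concentrations are stored as 0.225% —
half of the 0.45% full BCAA dose — rather than the rounded 0.25%,
because only 0.225 reproduces all published effective values
simultaneously (Ile 1.10%, Val 1.23%). Displayed values round half-up
to two decimals for percentages and whole ppm for zinc.

# Problem sizes used by the checks

The test suite and acceptance script run at desk scale, chosen as the
smallest sizes at which each property is statistically decidable:
tail calibration on 20 seeds × 400 neurons × 6,000 frames (pooled
binomial 3-SE band), ensemble-count and ARI recovery on 20 seeds of
the 60 × 6,000 default preset, network null edge rate on 50 neurons ×
2,000 frames with 100 pooled surrogates per neuron, and the
hyperconnectivity contrast on 20 seeds of 20 neurons × 1,000 frames
with 2,500 pair surrogates (one-sided Mann–Whitney). Oracle
equivalences (brute-force shift enumeration, spectrum preservation,
hand-counted centralities) run on toys of ≤ 100 frames.

# Known limitations

* The elbow rule is a convention; WCSS curves from weakly structured
  sessions can be nearly linear, in which case the package warns and
  returns one ensemble rather than guessing.
* The 99.17th percentile is inherited as a constant; nothing in the
  package derives it from a target family-wise rate.
* Circular-shift and phase-randomization nulls both assume
  within-session stationarity; strong slow drift would violate the
  exchangeability they rely on.
* The pooled surrogate mode shares surrogates across pairs involving
  the same neuron, so edge decisions are not independent across pairs;
  the null edge *rate* is unaffected, but pair-level dependence should
  be kept in mind when aggregating.
* `sessionOverlapTable()` aligns sessions through maps to the first
  (reference) session; chained maps between non-reference sessions are
  not composed.
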