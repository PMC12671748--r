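# CalciumEnsembles

Analysis of single-neuron calcium traces from miniscope recordings made
during social-interaction (RSI) and object-exploration (OE) sessions.
Starting from extracted per-neuron activity (neurons × frames at 10 Hz)
and hand-scored behavior bout times, the package answers three questions
about a session:

1. **Which neuronal ensembles are present, and do they track behavior?**
   Neurons are clustered by k-means on their z-scored traces; the
   within-cluster sum of squares (WCSS) curve over candidate cluster
   counts picks the number of ensembles at its elbow (maximal discrete
   second difference). Each ensemble's mean trace is correlated
   (Pearson) with the binary behavior vector, and each neuron with its
   own ensemble mean; ensemble coherence across groups is compared by
   two-sample Kolmogorov–Smirnov tests on those correlation CDFs.
2. **Which single neurons are behavior-relevant?** For each neuron the
   cosine similarity `R = (x·b)/(‖x‖‖b‖)` between its raw non-negative
   trace `x` and the binary behavior vector `b` is compared with a
   permutation null built from 1,000 random circular shifts of the
   trace (circular shifting preserves the calcium-kernel
   autocorrelation). `R` above the null's 95th percentile marks a
   positively correlated neuron, below the 5th percentile a negatively
   correlated one, otherwise the neuron is irrelevant.
3. **How connected is the functional network?** Pairwise cosine
   similarity between neurons is thresholded against phase-randomization
   surrogates — Fourier-phase-scrambled copies that keep each trace's
   amplitude spectrum (hence mean, norm and autocorrelation) exactly.
   A pair whose raw similarity exceeds the 99.17th percentile of 10,000
   surrogate pairs is linked; per-neuron degree centrality
   (links ÷ (n − 1)) summarises connectivity, overall and within
   behavior-linked versus irrelevant subgroups.

A seeded synthetic-session generator (`simConfig()` /
`simulateSession()` / `simulatePairedSessions()`) produces GCaMP-like
traces — Bernoulli event trains with behavior-state-modulated rates,
ensemble-shared drive events, an exponential decay kernel, Gaussian
noise, rectification — with known ground-truth neuron classes,
ensembles and cross-session identity, so every stage is testable
without any recording. A small companion module computes chow-equivalent
dietary concentrations for nutrient-supplement cocktails
(`cocktailTable()`), an exactly checkable piece of arithmetic:
`effective = chow + water_conc × 4.8 ml / 3 g`.

## Worked example

```r
library(CalciumEnsembles)

cfg <- simConfig(seed = 7)            # 60 neurons x 6,000 frames @ 10 Hz
s   <- simulateSession(cfg)           # traces + bouts + behavior + truth
z   <- zscoreTraces(s$traces)

curve <- wcssCurve(z, kRange = 1:5, seed = 1)
round(curve)
#>      1      2      3      4      5
#> 304988 245340 231708 224349 218353
selectK(curve)
#> [1] 2
```

The WCSS drop from k = 1 to 2 dwarfs later drops, so the elbow picks
two ensembles — the generator's ground truth. Relevance classification
then labels each neuron against its circular-shift null:

```r
model <- clusterNeurons(z, 2, seed = 1)
calls <- classifyNeurons(s$traces, s$behavior, nPerm = 1000, seed = 2)
relevanceRatios(calls)
#>        label count     ratio percent
#> 1   positive     7 0.1166667    11.7
#> 2   negative     3 0.0500000     5.0
#> 3 irrelevant    50 0.8333333    83.3
```

Seven neurons exceed the 95th null percentile (the session held six
true positive-class neurons plus one false positive, consistent with
the 5% tail), three fall below the 5th. The functional network links
pairs whose similarity beats the surrogate threshold:

```r
net <- buildNetwork(s$traces, nSurrogates = 10000, seed = 3)
net
#> FunctionalNetwork: 60 neurons, 873 link(s), density 0.4932
#>   threshold percentile 99.17 over 10000 surrogate pairs
```

At this session length nearly every within-ensemble pair is detected
(2 × C(30,2) = 870 of the 873 links), giving degree centralities near
0.49. Finally, the dose arithmetic for the quarter-strength cocktail:

```r
cocktailTable("quarter")
#>   nutrient unit  chow   water effective display
#> 1      Ile    %  0.74  0.1125      0.92    0.92
#> 2      Leu    %  1.49  0.2250      1.85    1.85
#> 3      Val    %  0.87  0.1125      1.05    1.05
#> 4      Ser    %  0.83  1.0000      2.43    2.43
#> 5       Zn  ppm 81.00 20.0000    113.00  113.00
```

`runPipeline()` chains all stages over one or more sessions (with
optional cross-session identity maps) and writes every table plus a
reproducibility manifest to an output directory.

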