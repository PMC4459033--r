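# thetaPLF

Phase alignment, cross-frequency coupling, and group statistics for epoched
intracranial EEG.

## What it measures

During memory encoding, slow oscillations in thalamus and cortex do not just
change *power* — their *phase* becomes reorganised relative to the stimulus.
`thetaPLF` quantifies that reorganisation and its downstream signatures:

* **Phase alignment index (PAI / phase-locking factor).** For each
  time-frequency point, the length of the mean unit phasor across trials,
  `|mean(exp(i*phi_k))|`. It is 0 for phases scattered at random (expectation
  `~sqrt(pi/(4K))` for `K` trials) and 1 for perfect stimulus-locked
  alignment, independent of amplitude.
* **Cluster-size permutation contrast.** Whether alignment differs between
  successfully encoded (SE) and unsuccessfully encoded (UE) trials, tested
  over the whole time-frequency map with a cluster-based permutation test
  that controls the family-wise error rate without picking bins in advance.
* **Theta-gamma coupling.** A Canolty-style modulation index
  `|mean(A(t) * exp(i*phi(t)))|` between theta phase (7–8 Hz) and gamma
  amplitude (40–50 Hz), z-scored against per-epoch circularly time-shifted
  surrogates so the reported value is an excess over chance.
* **Between-channel synchrony (PLV)**, **ERPs** (zero-phase Butterworth
  band-pass plus trial averaging), and a **participant-level correlation
  battery** (Pearson r, Benjamini–Hochberg FDR across the family, Fisher z
  comparison of SE vs UE correlations).

Patient recordings of this kind cannot be redistributed, so the package also
ships a fully seeded **synthetic cohort generator**: 1/f background plus an
early broadband phase reset, a late theta reset whose von Mises concentration
differs by condition, theta-phase-modulated gamma, and an ERP transient, with
participant-level effect sizes drawn from a shared latent factor so that true
across-participant correlations are known. Every estimator in the package is
validated end to end against this generator and against analytic oracles.

## Worked example

Simulate a 5-participant cohort (two channels, 20 trials per condition at
250 Hz) and run the full pipeline:

```r
library(thetaPLF)
cfg <- runConfig(
  synth = synthConfig(nParticipants = 5L, nTrialsPerCondition = 20L,
                      channelRoles = c("frontal", "RATN"),
                      samplingRate = 250, seed = 42L),
  decim = 3L, nPermutations = 500L, nSurrogates = 200L,
  outputDir = "results")
res <- runFullAnalysis(cfg)
```

```
[   0.00s] generating synthetic cohort (seed 42)
[   4.67s] participant P01: decomposition, PAI, CFC, PLV, ERP done
[   7.22s] participant P02: decomposition, PAI, CFC, PLV, ERP done
[   9.48s] participant P03: decomposition, PAI, CFC, PLV, ERP done
[  11.67s] participant P04: decomposition, PAI, CFC, PLV, ERP done
[  14.27s] participant P05: decomposition, PAI, CFC, PLV, ERP done
[  14.80s] cluster test frontal: 60 cluster(s), min p = 0.05389
[  15.31s] cluster test RATN: 49 cluster(s), min p = 0.06188
[  15.36s] correlation battery: 14 correlations, BH-FDR at q = 0.05
[  16.78s] outputs written to results
```

The late theta reset is simulated with concentration 1.5 in SE trials and 0
(uniform phase) in UE trials, and the per-participant window-averaged PAI
recovers exactly that: clearly higher SE alignment in the late window
(0.9–1.1 s, 4–8 Hz) and none in the early window, where both conditions share
the same reset:

```r
str(res$summary$windowPAI[[4]])
```

```
List of 5
 $ name  : chr "lateRATN"
 $ band  : num [1:2] 4 8
 $ window: num [1:2] 0.9 1.1
 $ SE    : num [1:5] 0.371 0.467 0.402 0.486 0.363
 $ UE    : num [1:5] 0.2118 0.0673 0.2712 0.2203 0.3487
```

The cluster test finds one large SE > UE cluster per channel (size 205 and
261 points, max |t| 15.5 and 16.4). With only 5 participants a sign-flip
permutation null has just 2^5 = 32 distinct relabellings, so the smallest
attainable p is limited and the observed p ≈ 0.054–0.062; at the package's
study size of 7 participants the same contrast is detected with p < 0.05 in
over 90% of simulated cohorts (see `lateThetaDetection()`).

```r
str(res$summary$clusterTests$RATN)
```

```
List of 6
 $ channel     : chr "RATN"
 $ nClusters   : int 49
 $ clusterSizes: int [1:49] 261 27 22 19 18 16 13 11 9 9 ...
 $ clusterSigns: num [1:49] 1 -1 -1 1 -1 -1 -1 -1 1 1 ...
 $ clusterP    : num [1:49] 0.0619 0.6248 0.9281 0.9281 1 ...
 $ maxAbsT     : num 16.4
```

Theta-gamma coupling z-scores per participant and condition (the generator
injects coupling in both conditions, mean modulation depth 0.5):

```r
sapply(res$cfc, function(cond) sapply(cond, function(x) x@miZ))
```

```
           SE       UE
[1,] 3.997183 4.258585
[2,] 6.212251 5.884702
[3,] 4.620852 3.995583
[4,] 6.473676 7.929875
[5,] 6.389046 5.931943
```

Each correlation in the battery prints its statistics and FDR-adjusted
p-value:

```r
show(res$correlations[[1]])
```

```
CorrelationResult [earlyFrontal PAI vs RATN CFC miZ (SE)]: r = 0.006, n = 5, t = 0.010, p = 0.9926, p.FDR = 0.9926
```

(Across-participant correlations at n = 5 are essentially noise — that is the
honest answer at this cohort size; `effectCorrelationRecovery()` shows the
pipeline recovers a true correlation of 0.9 at the study size.)

`runFullAnalysis()` with `outputDir` set also writes `pai_maps.tsv`,
`cfc.tsv`, `erp.tsv`, `correlations.tsv`, `ground_truth.tsv`, `summary.json`
and `run.log`.

### Command line

The same pipeline is available as a CLI (installed under
`system.file("cli", "thetaplf.R", package = "thetaPLF")`):

```sh
CLI=$(Rscript -e 'cat(system.file("cli","thetaplf.R",package="thetaPLF"))')
Rscript "$CLI" simulate --out cohort --config generator.yaml --seed 42
Rscript "$CLI" analyze  --data cohort/epochs.h5 --out results \
                        --permutations 500 --decim 3
Rscript "$CLI" report   --out results
```

where `generator.yaml` holds `synthConfig()` fields (e.g. `nParticipants: 5`,
`nTrialsPerCondition: 20`).

Cohorts travel as HDF5 containers (`writeEpochContainer()` /
`readEpochContainer()`), one float32 dataset per participant/condition with
sampling-rate and channel attributes.

## Validation and reproducibility

The test suite (`tests/testthat/`) checks every module against independent
oracles: a triple-loop PAI implementation, the von Mises resultant
`I1(kappa)/I0(kappa)`, brute-force connected-component search, the analytic
modulation index of `A = 1 + cos(phi)` (exactly 0.5), a step-up BH
implementation, `stats::t.test`/`cor.test`/`p.adjust`, and closed-form Fisher
z examples. Run it with:

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "thetaPLF", load_package = "installed")'
```

Larger seeded simulation studies (type-I error calibration of the cluster
test, detection rate of the late theta contrast, coupling null calibration
and gain monotonicity, correlation recovery at known effect correlation) are
exported as `nullClusterCalibration()`, `lateThetaDetection()`,
`couplingGainSweep()` and `effectCorrelationRecovery()`, and are exercised by
`tests/testthat/test-acceptance.R`.

To reproduce the headline numbers in one run (writes a flat JSON of computed
quantities; takes roughly 15 minutes on one CPU):

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

All randomness in the package flows from integer seeds: the cohort from
`synthConfig(seed = )`, balancing/permutations/surrogates from
`runConfig(seeds = )`, and the acceptance script derives every sub-seed from
its `--seed` argument.

See `vignettes/theta-phase-alignment.Rmd` for the signal model, estimator
definitions, surrogate design (per-epoch rotations and evoked-amplitude
removal), numerical choices, and limitations.
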