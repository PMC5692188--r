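# circaBench

Benchmarking toolkit for genome-scale detection of biological rhythms in
omics time courses (bulk or single-cell transcriptomics, proteomics,
metabolomics). It is aimed at people who design circadian time-series
experiments or develop/evaluate rhythmicity statistics and want to know,
before spending money on samples, what a given design can and cannot
detect — and how badly common analysis malpractice (above all, duplicating
and concatenating a time series to fake a longer experiment) corrupts
p-values.

The package provides four pieces that work together:

1. **A synthetic-data generator with ground truth.** Each simulated series is

   *y(t, r) = M + A · cos(2π (t − φ)/T) + ε*,  ε ~ N(0, σ²),

   with mesor *M*, signed amplitude *A* ~ U[A_min, A_max], period
   *T* ~ U[T_min, T_max], acrophase φ ~ U[0, T), and independent Gaussian
   noise per (timepoint, replicate) cell; arrhythmic series are mesor +
   noise. The fraction of rhythmic series is exact, optional symmetric
   outlier spikes can be injected, and the true (class, T, φ, A) of every
   series is stored alongside the values.

2. **A JTK-style exact nonparametric rhythmicity test.** A series is
   compared against cosine-derived rank templates on a grid of (period,
   phase) alternatives with the tie-aware Kendall statistic
   *S = Σ sign(y_j − y_i) · sign(r_j − r_i)* over column pairs in distinct
   template tie groups. The null distribution of *S* is computed exactly by
   generating-function convolution over the tie groups, so p-values are
   exact at any series length, not asymptotic. `p_adj` multiplies the
   minimal exact p by the number of alternatives (Bonferroni); `q_bh` adds
   Benjamini–Hochberg FDR control across series. Mesor, amplitude,
   peak/trough fold change and variance explained are refined by cosinor
   regression at the best period.

3. **Cautionary data manipulations** — `duplicateConcatenate()`,
   `downsampleDataset()`, `truncateDataset()` — provenance-logged operations
   used to build degraded or fraudulent designs on purpose.

4. **A benchmark harness** — confusion metrics against ground truth,
   parameter-recovery statistics (circular phase error, period error,
   relative amplitude error), and `runFig2Experiment()`, a packaged
   experiment quantifying false-positive inflation under
   duplication-and-concatenation across three sampling designs.

## Worked example

```r
library(circaBench)

cfg <- simulationConfig(n_series = 200, frac_rhythmic = 0.5,
                        amp_min = 1, amp_max = 4, noise_sd = 1, seed = 20)
d   <- synthesizeDataset(cfg)      # 48 h sampled every 2 h, one replicate
res <- jtkTest(d, period_set = 24)
head(as.data.frame(res), 4)
```

```
               p_adj     q_bh best_period_h best_phase_h amplitude_est fold_change_est r_squared
series_0001 1.03e-08 1.37e-07            24           21          3.69            2.26     0.917
series_0002 1.03e-08 1.37e-07            24           23          3.37            2.04     0.883
series_0003 2.93e-03 7.41e-03            24           13          1.61            1.38     0.590
series_0004 4.25e-06 1.74e-05            24            0          2.57            1.70     0.757
```

Each row is one series: the Bonferroni-adjusted exact p over all (period,
phase) alternatives, its across-series FDR, the best-matching period and
peak phase on the search grid, and the cosinor estimates of amplitude,
peak-to-trough fold change and variance explained.

Scoring against the simulated truth at `q_bh < 0.05`:

```r
cm  <- confusionMetrics(classifyHits(res, 0.05, "q_bh"), groundTruth(d))
rec <- parameterRecovery(res, groundTruth(d),
                         hits = classifyHits(res, 0.05, "q_bh"))
```

gives `tpr = 0.89`, `fpr = 0.01`, observed FDR `0.011`; among detected
rhythmic series the median circular phase error is `0.37 h`, the median
period error `0 h` and the median relative amplitude error `7.4%` — i.e.
with amplitudes 1–4× the noise SD, a 2 h / 48 h design recovers phase to
well under an hour.

The same operations are available from a shell:

```sh
CLI=$(Rscript -e 'cat(system.file("cli","circabench",package="circaBench"))')
$CLI generate --seed 11 --out dataset.csv
$CLI detect   --in dataset.csv --period 24 --out results.csv
$CLI fig2     --seed 11 --n-series 1000 --out fig2.csv
```

Every output CSV is paired with a JSON run manifest (config, seed, version,
operation log) sufficient to regenerate it bit-identically.

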