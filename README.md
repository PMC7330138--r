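# mdisten

Complexity estimators for single-channel EEG time series, built around
**modified-distribution entropy (mDistEn)** and its two reference
measures, fuzzy entropy (FuzzyEn) and distribution entropy (DistEn),
together with the full evaluation pipeline used in epileptic-seizure
discrimination studies: prefix windowing, rank-based AUC sweeps,
leave-one-set-out five-fold cross-validation with a threshold
classifier, and confusion-matrix metrics. A seeded surrogate generator
produces Bonn-style five-set EEG datasets (normal / interictal /
ictal), so everything runs end to end with no external data.

## The measures

All three estimators start from delay-coordinate state-space
reconstruction of a series *x*(1), …, *x*(N) with embedding dimension
*m* and delay *τ*:

* **FuzzyEn** removes the local mean from consecutive-sample vectors,
  converts pairwise Chebyshev distances to similarity degrees with the
  exponential membership `exp(-(d^n)/r)` (width `r = 0.2 × SD`,
  gradient `n = 2`), averages them at orders *m* and *m* + 1, and
  reports `ln φ^m − ln φ^(m+1)`.
* **DistEn** histograms all pairwise Chebyshev distances between delay
  vectors into *B* equal-width bins and reports the normalized Shannon
  entropy `−(1/log2 B) Σ Pt log2 Pt ∈ [0, 1]`.
* **mDistEn** does the same on *Euclidean* distances after rescaling
  each as `(d/r)^n` before binning — importing the fuzzy parameters
  (r, n) into the distance distribution. Like DistEn it lies in
  [0, 1], and the transform makes it exactly amplitude-invariant.

Defaults throughout: `m = 3`, `τ = 1`, `r = 0.2 × SD`, `n = 2`,
`B = 64` (see `?entropy_params` and the methods vignette,
`vignettes/mdisten-methods.Rmd`).

## Worked example

```r
library(mdisten)

ictal <- surrogate_record("ictal", seed = 7)   # 4096 samples @ 173.61 Hz
win   <- window_signal(ictal, 4)               # first 4 s (694 samples)

fuzzy_entropy(win)$value   # 1.413122
dist_entropy(win)$value    # 0.920619
mdist_entropy(win)$value   # 0.671102
# the same 4-s window of a normal background record scores lower:
mdist_entropy(window_signal(surrogate_record("normal", seed = 7), 4))$value
                           # 0.5665927
```

The sustained 3–5 Hz spike-wave rhythm of the ictal surrogate spreads
the inter-vector distance distribution, raising mDistEn relative to the
1/f background — the separation the AUC sweep quantifies:

```r
ds <- make_bonn_like(seed = 1, records_per_set = 20)
auc_sweep(ds, methods = "mdist", contrasts = "normal-vs-ictal",
          window_lengths_s = c(2, 4, 8))
#>   method        contrast window_s   auc     direction auc_raw n_neg n_pos
#> 1  mdist normal-vs-ictal        2 0.868 positive-high   0.868    40    20
#> 2  mdist normal-vs-ictal        4 0.975 positive-high   0.975    40    20
#> 3  mdist normal-vs-ictal        8 1.000 positive-high   1.000    40    20
```

Each row is the oriented Mann-Whitney AUC between per-record entropies
of the two groups at that window length: at 4 s a randomly chosen ictal
record out-scores a normal one 97.5% of the time, and 8-s windows
separate perfectly on this surrogate. `cross_validate(ds, "mdist",
window_s = 4)` adds the five-fold leave-one-set-out confusion-matrix
summary (sensitivity, specificity, accuracy), including the flagged
fold-E fallback discussed in the vignette.

## Command line

A thin Rscript front end is installed at
`system.file("scripts", "mdisten", package = "mdisten")`:

```sh
mdisten simulate --seed 1 --records-per-set 100 --out data/
mdisten entropy  --method mdist --window-s 4 data/E/E001.txt
mdisten sweep    --data data/ --methods fuzzy,dist,mdist --windows 1:23 --out sweep.csv
mdisten evaluate --data data/ --method mdist --window-s 4 --out summary.json
```

Estimator parameters can be given as flags (`--m --tau --r-factor --n
--bins --r-scope`) or a YAML config (`--config`); flags win. The
`sweep`/`evaluate` subcommands also run unchanged on a directory of
real Bonn-layout records (subdirectories `A`–`E`, one ASCII sample per
line).

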