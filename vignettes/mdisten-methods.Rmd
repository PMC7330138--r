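---
title: "Distribution-based complexity estimators for EEG: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distribution-based complexity estimators for EEG: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdisten)
```

## The problem

Epileptic seizures change the character of the electroencephalogram:
ictal (seizure) EEG is dominated by high-amplitude rhythmic spike-wave
activity, whereas interictal EEG shows sporadic epileptiform transients
over an irregular background. Complexity measures summarize a
single-channel record as one number that is sensitive to this shift
between irregular and regular dynamics, and can feed a simple classifier
for seizure detection. `mdisten` implements three such estimators and
the full evaluation pipeline around them: windowing, rank-based AUC,
leave-one-set-out cross-validation, and confusion-matrix metrics.

## The estimators

All three start from delay-coordinate reconstruction of the state
space. For a series $x(1), \dots, x(N)$, embedding dimension $m$ and
delay $\tau$, the delay vectors are

$$X(i) = \{x(i), x(i+\tau), \dots, x(i+(m-1)\tau)\},
\qquad 1 \le i \le N-(m-1)\tau .$$

**Fuzzy entropy (FuzzyEn).** Consecutive-sample vectors of order $m$
are formed and each has its own mean (the local baseline) removed.
Pairwise Chebyshev distances $d_{ij}^m$ are mapped to similarity
degrees through the exponential membership function

$$D_{ij}^m = \exp\!\left(-\frac{(d_{ij}^m)^n}{r}\right),$$

with width $r$ and gradient $n$. Averaging the degrees over all ordered
pairs $i \ne j$ gives $\phi^m$, the same at order $m+1$ gives
$\phi^{m+1}$, and

$$\mathrm{FuzzyEn} = \ln \phi^m - \ln \phi^{m+1}.$$

Both $\phi$ sums run over the same $N-m$ vectors (the order-$(m+1)$
construction yields $N-m$ vectors and the first $N-m$ order-$m$ vectors
are used), so the log-ratio is taken on matched support. The
construction uses consecutive samples; passing $\tau \ne 1$ is an error
rather than being silently ignored.

**Distribution entropy (DistEn).** All $\binom{n_v}{2}$ pairwise
Chebyshev distances between the plain delay vectors are collected, their
empirical probability density is estimated by a histogram with $B$
equal-width bins, and the result is the normalized Shannon entropy

$$\mathrm{DistEn} = -\frac{1}{\log_2 B}\sum_{t=1}^{B} P_t \log_2 P_t
\in [0, 1].$$

**Modified-distribution entropy (mDistEn).** The same
distance-distribution idea, with two changes imported from the fuzzy
framework: distances are *Euclidean*, and each distance is rescaled as

$$D_{ij} \mapsto \left(\frac{D_{ij}}{r}\right)^{n}$$

*before* the histogram is taken, with $r$ and $n$ as in FuzzyEn. The
entropy of the binned, transformed distances is normalized exactly as
for DistEn.

Note the deliberate asymmetry in where the exponent sits: the fuzzy
membership divides $d^n$ by $r$, while the mDistEn transform raises the
*ratio* $d/r$ to $n$. Each form follows its estimator's standard
definition. A consequence worth knowing: because $d^2$ scales
quadratically with amplitude but $r \propto \mathrm{SD}$ only linearly,
FuzzyEn is **not** invariant under amplitude rescaling of the input
(it is exactly invariant under additive offsets, which the baseline
removal cancels). DistEn (adaptive bin edges) and mDistEn (scale-free
$(d/r)^n$) are invariant under both, and the test suite asserts exactly
these properties.

## Parameters

`entropy_params()` carries the five-tuple used throughout, with the
conventional defaults for epileptic EEG:

| parameter | default | meaning |
|-----------|---------|---------|
| `m`        | 3    | embedding dimension |
| `tau`      | 1    | delay (samples); FuzzyEn requires 1 |
| `r_factor` | 0.2  | $r = 0.2 \times$ SD of the series |
| `n`        | 2    | gradient of the similarity boundary |
| `B`        | 64   | histogram bins for the distance ePDF |

`r` is resolved per analyzed window by default (`r_scope = "window"`),
which keeps each window's estimate self-contained; `r_scope = "global"`
instead resolves it from the full record the window was cut from, for
workflows that prefer one width per record. The SD is the population
standard deviation (divisor $N$) of the exact samples analyzed.

## Numerical choices

* **Condensed distances, no diagonal.** Distance matrices are stored as
  the $n_v(n_v-1)/2$ unordered pairs $i<j$. Self-distances are always
  zero and would spike the first histogram bin, so they are excluded
  everywhere.
* **Histogram.** $B$ equal-width bins spanning $[0, \max d]$, last bin
  right-closed so the maximum is counted; for mDistEn the $(d/r)^n$
  transform is applied before binning, so bins are equal-width in the
  transformed scale. A degenerate distance set (all zero) puts all mass
  in bin 1 and yields entropy 0.
* **$0 \log 0 := 0$.** Empty bins contribute nothing; with one bin
  ($B = 1$) the normalized entropy is defined as 0.
* **Degenerate input.** A constant window resolves $r = 0$; FuzzyEn and
  mDistEn then raise an explicit error ("constant signal") distinct
  from the too-short-signal error, rather than returning NaN — constant
  EEG windows indicate upstream data problems.
* **Indexing.** The public API is plain R (1-based vectors); the
  classical 1-based formulas translate directly.

## Evaluation pipeline

Records are windowed by **prefix**: the first
$\lfloor \text{length}_s \cdot f_s \rfloor$ samples. Anchoring every
window at the record start makes each (record, window length) cell of a
sweep comparable.

**AUC.** `rank_auc()` is the Mann-Whitney statistic computed from
midranks (ties count one half), hence exact under ties and invariant
under monotone transforms. Since whether pathology raises or lowers a
given entropy differs by estimator, `oriented_auc()` reports
$\max(A, 1-A)$ with an explicit direction flag.

**Threshold classifier.** The paper-style summary metrics require a
decision rule; a single threshold on the entropy feature is the
simplest rule consistent with the AUC analysis. `fit_threshold()`
searches all midpoints between consecutive distinct training scores
(plus the two all-one-class extremes) in both orientations. The default
training objective is **balanced accuracy** (the Youden-style mean of
sensitivity and specificity): with the five-set layout the training
data are 3:1 or 4:1 negative:positive, and maximizing raw accuracy
under that imbalance degenerates to the majority class whenever the
feature separates weakly — on a null dataset it yields ~0.8 pooled
accuracy (the majority rate) instead of chance. The balanced objective
keeps the null at chance and matches the balanced
sensitivity/specificity operating points typically reported for these
estimators. Raw-accuracy maximization remains available via
`objective = "accuracy"`. Ties prefer the lower threshold, then the
positive-scores-high orientation.

**Cross-validation.** `cross_validate()` implements leave-one-set-out
five-fold CV: each set A–E is held out once, the threshold is fit on
the other four, ictal is the positive class. Two structural caveats are
worth stating plainly:

* *Fold E has no ictal training data.* The documented fallback fits the
  threshold on interictal (positive) vs normal and flags the fold. If
  the estimator moves interictal records in the *opposite* direction
  from ictal ones — which happens on the bundled surrogate, where
  sporadic heavy-tailed transients compress the distance histogram
  while sustained rhythm spreads it — the fallback direction is wrong
  and fold E misclassifies, dragging pooled sensitivity down even when
  the ictal-vs-normal AUC is excellent. The flag makes this visible
  rather than hiding it.
* *Pooled accuracy is not a binomial proportion.* All test predictions
  within a fold share one fitted threshold, so the sampling variance of
  pooled accuracy is dominated by threshold placement, not by
  per-record noise; on null data its spread across seeds is several
  times the binomial standard error. Chance-level behavior should be
  judged by AUC (which is rank-based and stable) rather than by tight
  bands on pooled accuracy.

`confusion_metrics()` computes the exact ratios
$\mathrm{Se} = TP/(TP+FN)$, $\mathrm{Sp} = TN/(TN+FP)$,
$\mathrm{Acc} = (TP+TN)/(TP+FP+TN+FN)$ and refuses zero denominators by
name.

## The surrogate generator

`make_bonn_like()` emulates the five-set, 100-records-per-set layout of
the classical Bonn EEG distribution (4,096 samples per record at
173.61 Hz) so the entire pipeline runs without any download:

* **normal** (sets A, B): band-limited $1/f$-shaped Gaussian background
  (0.5–40 Hz), synthesized by FFT filtering;
* **interictal** (C, D): background plus sporadic biphasic Ricker
  transients (~100 ms), Poisson-placed at about 0.5 per second, with
  rate and amplitude scaled by `effect`;
* **ictal** (E): background plus a sustained rhythmic spike-wave
  component with fundamental drawn in 3–5 Hz plus harmonics, amplitude
  `effect` × 3 background SD — the canonical generalized-seizure
  signature.

`effect = 0` removes every class-specific component, collapsing all
classes onto the same background generator (the null dataset used for
chance-level checks); `effect = 1` is the default regime. Per-record
seeds are derived from the master seed through a set/record counter, so
generating fewer records never changes the ones that are generated.

The generator is a controlled fixture, not a physiological model: it
has no eye-blink or muscle artifacts, no nonstationary background, no
multichannel structure, and a single stereotyped discharge morphology
per class. Passing pipeline tests on it demonstrates that the
estimators and the evaluation machinery behave as specified under a
known effect size — not that any particular accuracy will be attained
on clinical recordings.

## Sinusoid consistency

`sinusoid_consistency()` sweeps data length (50–1000 samples) and bin
count (2–50) for two pure sinusoids (50 and 100 Hz, 2 s at 500 Hz) and
reports the per-cell entropy gap. One numerical phenomenon dominates
this experiment: at a sampling rate that is an exact multiple of both
frequencies, the 50 Hz sine visits exactly 10 distinct sample values
per cycle and the 100 Hz sine only 5, so their embeddings produce about
45 vs 10 distinct inter-vector distances. The attainable normalized
entropy is capped at $\log_2(\#\text{distinct})/\log_2 B$, and at fine
bin resolutions the two frequencies keep a structural gap (up to ~0.15
for DistEn and ~0.20 for mDistEn on this grid) even though the two
curves track each other closely in shape. The gap is a property of
phase-locked sampling, not an implementation artifact; it persists
under alternative binning ranges and embedding dimensions.

## Problem sizes used by the test suite

The bundled checks run the full-geometry surrogate (100 records per
set, 4,096 samples) for the headline AUC and cross-validation
quantities, 40 records per set for the five-level effect-size
monotonicity sweep, and 4-s analysis windows (691 delay vectors,
~238,000 distance pairs per record at the defaults) — small enough to
run in minutes on one core while keeping every stage of the pipeline
exercised at realistic per-record geometry. Oracle-equivalence checks
run at $N \le 50$ against literal nested-loop transcriptions of the
definitions, and agree to $10^{-12}$.

## Known limitations

* FuzzyEn's amplitude-scale dependence (above) means records should be
  compared on a common gain, or via the two distribution-based
  estimators, when absolute amplitude is not meaningful.
* The histogram estimators depend on $B$; values are comparable only at
  a fixed bin count.
* Leave-one-set-out CV with set-pure classes makes pooled sensitivity
  rest entirely on the fold-E fallback (above).
* The CLI reads single-channel plain-text records only; EDF/BDF and
  multichannel montages are out of scope.
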