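---
title: "Random-sampling features and least-squares SVMs for two-class EEG"
author: "srseeg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Random-sampling features and least-squares SVMs for two-class EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srseeg)
```

## The problem and the model

Scalp EEG during a generalized seizure looks very different from healthy
background activity: amplitudes grow several-fold and the signal locks
into a rhythmic ~3 Hz spike-and-wave pattern. This package classifies
single-channel records as healthy or ictal using nothing but descriptive
statistics of randomly chosen observations — no spectral, wavelet or
non-linear features — followed by a filter-style feature selection and a
least-squares SVM. The pipeline has four stages, each exported on its own.

### Hierarchical simple random sampling

A record is a population of $N$ integer amplitudes (4097 in the Bonn
layout). The number of observations to draw is Cochran's sample size for
a proportion with finite-population correction,
$$ss_0 = \frac{z^2 p (1-p)}{c^2}, \qquad
  ss = \frac{ss_0}{1 + (ss_0 - 1)/N},$$
rounded half-up. The defaults $z = 2.58$, $p = 0.5$, $c = 0.01$ encode a
99 % confidence level with a one-percentage-point half-width and the
conservative $p = 0.5$; they give 3288 from $N = 4097$, and, reapplying
the formula with the sample as the population, 2746 from $N = 3288$:

```{r}
cochran_sample_size(4097)
cochran_sample_size(3288)
```

Each record yields `samples_per_record = 10` samples (drawn independently,
without replacement within a sample, kept in ascending temporal order),
and each sample `subsamples_per_sample = 5` subsamples of 2746. Sampling
is *per record*, not per dataset: only this reading produces one feature
row per (record, sample), i.e. $2 \times 100 \times 10 = 2000$ rows for
the two-class Bonn layout.

### Features

Every subsample is reduced to nine order-invariant statistics — min, max,
mean, median, mode, first and third quartile, inter-quartile range and
sample standard deviation — so a row has $5 \times 9 = 45$ named columns
(`s1_min`, …, `s5_std`). A variant list with `range` in place of `iqr`
can be selected through `feature_spec()`; exactly nine statistics are
always used.

Numerical conventions, fixed once for reproducibility:

* quartiles use linear interpolation between order statistics
  (`quantile(..., type = 7)`);
* the mode of a continuous sample is ill-defined, so it is taken over
  integer-rounded values (Bonn amplitudes are integers anyway) with ties
  broken toward the smallest value;
* the standard deviation uses divisor $n - 1$ and is defined as 0 for a
  single observation.

### Threshold feature selection

The selection stage is a single forward filter pass, not a wrapper search:
the criterion never consults the classifier. Every column $j$ is reduced
to a scalar summary $r_j$ (default: the column mean) and the threshold
$\delta$ is a base statistic of $\{r_1, \dots, r_n\}$ (default: their
mean). Scanning columns in ascending order from an empty set, column $j$
is kept when $\delta \ge r_j$ (direction `ge`) or $\delta \le r_j$
(`le`). The configured direction is non-strict and its complement
(`lt`/`gt`) strict, so the two directions partition the columns exactly,
with boundary columns ($r_j = \delta$) belonging to the non-strict side.
If nothing qualifies the result is flagged degenerate and all columns are
retained, with a warning, so the pipeline cannot silently lose its input.

The selection is fitted on the training rows only and then applied
unchanged to the test rows; recomputing $\delta$ on test data would leak
label-correlated information across the split.

```{r}
set.seed(1)
fm <- feature_matrix(matrix(rnorm(60), 10,
                            dimnames = list(NULL, paste0("c", 1:6))),
                     rep(c(-1, 1), 5),
                     data.frame(class = rep(c("healthy", "ictal"), 5),
                                record = 1:10, sample = 1L))
select_features(fm, sfs_criterion("mean", "ge"))
```

### The least-squares SVM

Training a binary LS-SVM reduces to one dense linear solve. With labels
$y_i \in \{-1, +1\}$, kernel $K(x, y) = \exp(-\|x-y\|^2/\sigma^2)$ and
$\Omega_{ij} = y_i y_j K(x_i, x_j)$:
$$\begin{pmatrix} 0 & y^\top \\ y & \Omega + I/\gamma \end{pmatrix}
  \begin{pmatrix} b \\ \alpha \end{pmatrix} =
  \begin{pmatrix} 0 \\ \mathbf 1 \end{pmatrix},
\qquad f(x) = \sum_i \alpha_i y_i K(x, x_i) + b.$$
A decision value of exactly 0 maps to $+1$ (ictal), the positive class.
The kernel divisor is $\sigma^2$ (the LS-SVMlab convention); the
$2\sigma^2$ variant is available as `kernel_scale = "half"`. Defaults are
$\gamma = 10$, $\sigma^2 = 1$.

Numerical safeguards: every solve is verified by a relative-residual
check at $10^{-8}$; an ill-conditioned system receives one round of
diagonal jitter ($10^{-10} \cdot \mathrm{trace}/n$) and then fails loudly
rather than returning a silently bad fit.

### Why the pipeline standardizes features

`lssvm()` itself uses raw features unless asked otherwise, but the
end-to-end `srs_sfs_classify()` defaults to `standardize = TRUE`
(z-scoring with the training means and standard deviations, reapplied at
prediction time). The reason is quantitative: subsample statistics live
on the raw ADC amplitude scale, so squared distances between feature rows
are of order $10^3$–$10^5$. With $\sigma^2$ of order 1,
$\exp(-\|x-y\|^2/\sigma^2)$ underflows to zero for every off-diagonal
pair, the kernel matrix becomes the identity, every test decision value
collapses to the bias $b$, and the classifier degenerates to a constant.
After z-scoring, within-class distances are of order 1 and the same
$\gamma = 10$, $\sigma^2 = 1$ settings separate the classes. Users who
want the raw-feature behaviour can pass `standardize = FALSE`.

### Evaluation

The feature matrix is split 50/50, stratified by class — an even division
into a training and a testing group; the fraction is adjustable, and
stratified $k$-fold cross-validation is available through the `folds`
argument, in which case the reported confusion counts pool all folds so
that every row is scored exactly once. Metrics are percentages:
accuracy $= 100(TP+TN)/(P+N)$, sensitivity $= 100\,TP/P$ over the ictal
class, specificity $= 100\,TN/N$ over the healthy class, which satisfy
the exact identity
$\mathrm{acc}\cdot(P+N) = \mathrm{sens}\cdot P + \mathrm{spec}\cdot N$.

## The synthetic generator

`generate_synthetic_dataset()` emulates the statistical contrast the
pipeline exploits, in the exact Bonn file layout (integer amplitudes,
4097 per record, 173.61 Hz metadata):

* **healthy**: a band-limited oscillation with per-record frequency drawn
  from 8–13 Hz (the alpha band of relaxed, eyes-open recordings),
  peak amplitude ≈ 100 ADC units (jittered ±20 % per record), plus
  Gaussian noise with SD 30;
* **ictal**: a 3 Hz spike-and-wave discharge — a slow sinusoid with one
  sharp Gaussian transient per cycle — with peak amplitude 6 × the
  healthy amplitude, same noise.

These defaults were chosen once as a caricature of the healthy/seizure
amplitude-and-rhythm contrast; with them the two classes differ in the
per-record spread statistics (SD, range) by far more than three pooled
standard deviations, so the pipeline separates them nearly perfectly.

What the generator does **not** emulate: 1/f background spectra,
eye-blink and electrode artifacts, inter-ictal spikes, amplitude
non-stationarity within a record, or the inter-subject variability of
real EEG. Passing tests on synthetic data therefore demonstrates that the
implementation is correct and that the pipeline separates classes whose
spread statistics differ strongly — not that it attains any particular
accuracy on clinical recordings. Real Bonn records can be analysed with
the same functions via `read_bonn_dataset()`.

## Randomness and reproducibility

All randomness flows from one master seed. Every (class, record, sample)
triple gets a deterministic substream seed (an LCG-style fold of the id
path), and drawing functions restore the caller's RNG state, so the full
sampling plan is bit-reproducible and independent of evaluation order.
The train/test split and fold assignment use their own substreams of the
same master seed.

## Problem sizes used by the test suite

Most unit tests run a proportionally scaled design (600-point records,
3 samples of 579, 2 subsamples of 560) whose shape algebra is identical
to the full design. The end-to-end checks run the full study conditions:
100 records per class of 4097 points, the 3288/2746 sampling hierarchy,
a 2000 × 45 matrix, and ten independently seeded pipeline runs.

## Known limitations

* The threshold criterion compares column summaries on the raw feature
  scale, so its selected set depends on the measurement units of the
  features; it is a heuristic filter, not an optimality criterion.
* The dense LS-SVM solve is $O(n^3)$ in the number of training rows;
  at the package's study size ($n = 1000$) this is well under a second,
  but the approach does not scale to very large training sets.
* Binary classification only; the healthy/ictal label convention
  (+1 = ictal) is fixed throughout.
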