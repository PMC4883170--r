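# srseeg

Classification of single-channel EEG records as **healthy** or **ictal**
(seizure) from descriptive statistics of randomly sampled observations.
The package is aimed at biomedical-signal researchers who want a compact,
fully reproducible baseline for two-class EEG discrimination — e.g. on the
public Bonn epilepsy corpus (sets A and E: 100 records per class, 4097
integer amplitudes per record at 173.61 Hz) — and at anyone who needs its
building blocks: finite-population sample-size calculation, hierarchical
simple random sampling, threshold feature selection, and a least-squares
SVM solved as one linear system.

## The method

1. **Simple random sampling (SRS).** For a record of N observations, the
   sample size is Cochran's formula with finite-population correction,

       ss0 = z² p (1 − p) / c²,   ss = ss0 / (1 + (ss0 − 1) / N),

   rounded half-up. At the 99 % settings (z = 2.58, p = 0.5, c = 0.01)
   this gives 3288 of 4097 observations per sample, and — applying the
   same formula again with the sample as population — 2746 per subsample.
   Each record yields 10 samples, each sample 5 subsamples.

2. **Features.** Every subsample is reduced to nine statistics
   {min, max, mean, median, mode, Q1, Q3, IQR, SD}, giving one row of
   5 × 9 = 45 features per (record, sample): a 2000 × 45 matrix for the
   Bonn-sized two-class layout.

3. **Sequential feature selection (SFS).** Each column j is summarised by
   a scalar r_j (default: its mean); the threshold δ is a base statistic
   of {r_1, …, r_45} (default: their mean). Starting from an empty set,
   column j is kept when δ ≥ r_j (direction `ge`) or δ ≤ r_j (`le`).
   Selection is fitted on the training rows only.

4. **LS-SVM.** A binary least-squares SVM with RBF kernel
   K(x, y) = exp(−‖x − y‖²/σ²). With Ω_ij = y_i y_j K(x_i, x_j), training
   solves the (n+1) × (n+1) saddle system

       [ 0   yᵀ        ] [ b ]   [ 0 ]
       [ y   Ω + I/γ   ] [ α ] = [ 1 ]

   and classifies by sign of f(x) = Σ_i α_i y_i K(x, x_i) + b.
   Defaults γ = 10, σ² = 1.

5. **Evaluation.** Stratified 50/50 split; accuracy = 100(TP+TN)/(P+N),
   sensitivity = 100·TP/P (ictal = positive), specificity = 100·TN/N.

## Worked example

```r
library(srseeg)

ds  <- generate_synthetic_dataset(synthetic_config(seed = 3))
fit <- srs_sfs_classify(ds, seed = 3)
fit
```

```
SRS + SFS + LS-SVM classification
  feature matrix : 2000 x 45
  SFS            : kept 25 of 45 columns (delta = 80.4636)
  LS-SVM         : gamma = 10, sigma2 = 1
Accuracy    : 100.00 %
Sensitivity : 100.00 %
Specificity : 100.00 %
Confusion counts: TP 500  FN 0  |  TN 500  FP 0  (P = 500, N = 500)
```

The synthetic dataset emulates the Bonn A-versus-E contrast (moderate
alpha-band oscillations vs. high-amplitude 3 Hz spike-and-wave); the
2000 × 45 matrix is the full SRS feature extraction, the `mean ≥ r_j`
criterion keeps 25 of the 45 columns on this split's training rows, and
the LS-SVM separates the 1000 held-out rows perfectly. On real Bonn data,
place the files under `<root>/healthy/` and `<root>/ictal/` and run the
same pipeline via `read_bonn_dataset()` or the CLI:

```sh
Rscript inst/cli/srseeg.R --data-dir <root> --criterion mean --direction ge
```

The individual stages are exported too:

```r
cochran_sample_size(4097, 2.58, 0.5, 0.01)  # 3288
cochran_sample_size(3288, 2.58, 0.5, 0.01)  # 2746
m <- lssvm(cls ~ ., data = df, gamma = 10, sigma2 = 1)  # formula interface
predict(m, newdata, type = "decision")
```

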