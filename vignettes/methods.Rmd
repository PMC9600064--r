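---
title: "Textural multilevel features and hybrid selection for EEG sleep staging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Textural multilevel features and hybrid selection for EEG sleep staging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Sleep staging assigns one of six Rechtschaffen–Kales classes — wake (W),
light-to-deep sleep (S1–S4) and rapid eye movement (REM) — to every 30-second
window ("epoch") of an overnight EEG recording. Manual scoring is slow and
rater-dependent, so a long line of work classifies epochs automatically from
a single EEG channel. `ltetrolet` implements a fully handcrafted pipeline of
that kind: a textural pattern operator generates a large fixed-length feature
vector per epoch, a hybrid selector reduces it to an informative subset, and
a cubic-kernel SVM classifies under 10-fold cross-validation. No step is
learned end-to-end; every stage is deterministic given its seed, which makes
the pipeline cheap, auditable and exactly reproducible.

## The L-tetrolet pattern

The textural operator belongs to the local-binary-pattern family. A
16-sample window slides over the signal with stride 1; each window is
arranged row-major into a 4×4 matrix with cells `V1..V16`. Two templates
built from L-shaped tetrominoes, P1 and P2, each partition the 16 cells into
four roles `a, b, c, d` of four cells (see `tetrolet_pattern_table()`).
Eight binary comparisons per template — role `a` against role `c` cellwise,
then `b` against `d`, with ties counted as 1 — give an 8-bit code in which
bit *k* carries weight $2^{k-1}$:

$$\mathrm{bit}_t(k) = \mathbf{1}[a_t(k) - c_t(k) \ge 0], \quad
  \mathrm{bit}_t(k{+}4) = \mathbf{1}[b_t(k) - d_t(k) \ge 0], \quad
  \mathrm{code}_t = \sum_{k=1}^{8} \mathrm{bit}_t(k)\, 2^{k-1}.$$

The two code streams over all $L-15$ windows are histogrammed into
$2 \times 256$ raw counts: the 512-length textural block. Because only
pairwise orderings enter, the block is invariant under any strictly
increasing affine rescaling of the signal — amplitude calibration of the
EEG cannot change it. Histograms are raw counts (each half sums to
$L-15$); downstream min–max normalization makes count-versus-frequency
immaterial.

The row-major matrix fill is a package convention: the operator definition
leaves the fill order open, and every golden value in the tests (e.g. codes
(12, 0) for a rising ramp, (243, 255) for a falling one) is derived under
this convention with an independent scalar-loop oracle.

## Pooling decomposition and the multilevel hierarchy

Four pairwise pooling operators halve a signal over non-overlapping blocks
of two samples: maximum, average (M1), absolute average $|{\cdot}|$ of the
pair mean (M2), and absolute maximum $\max(|x_i|, |x_{i+1}|)$ (M3). A
trailing unpaired sample is discarded — padding would inject artificial
amplitudes into the histograms. At each level the current signal is
decomposed into {raw, M1, M2, M3}; each of the four contributes 512
textural features, 18 statistical moments of the signal and 18 moments of
its textural vector ($548 \times 4 = 2192$ per level). The signal is then
max-pooled and the process repeats for 5 levels: $2192 \times 5 = 10{,}960$
features per epoch. Repeated pooling exposes progressively coarser temporal
structure, so the deeper levels act as high-level features in the sense of
a decimating filter bank.

The 18 moments include location/scale summaries (mean, median, extremes,
variance, mean absolute deviation) and nonlinear energy/entropy terms. The
entropy terms use the normalized-energy distribution
$p_j = x_j^2 / \sum_k x_k^2$ (the standard choice for log-energy and
Shannon entropies of wavelet subbands), natural logarithm, with
$0 \log 0 = 0$ and all-zero inputs yielding 0. Three of the 18 entries
duplicate earlier ones; they are kept so the per-signal block length is
fixed at 548, which the selected-index layout depends on. Minimum input
lengths are enforced strictly (≥ 512 samples for 5 levels) so every pooled
branch at every level still hosts at least one 16-sample window; any 30-s
epoch sampled at ≥ 100 Hz qualifies.

Concatenation orders — within signal (textural, signal moments, textural
moments), across signals (raw, M1, M2, M3) and across levels (1..5) — are
frozen as the package's canonical layout (`feature_layout_names()`);
selected-feature indices are only meaningful against it.

## Three-stage feature selection

1. **Threshold pruning.** Features are min–max normalized per column
   (constant columns map to zero) and any column whose sum is not above the
   threshold β = 0 is dropped. On normalized data this removes exactly the
   constant features.
2. **Positive-ReliefF pruning.** Multiclass ReliefF weights each surviving
   feature by how well it separates nearest same-class from nearest
   different-class observations; only strictly positive weights survive.
   ReliefF hyperparameters are not dictated by the procedure itself, so the
   package fixes them: k = 10 nearest hits/misses, every observation used
   as a reference instance (exhaustive, hence deterministic without a
   sampling seed), Manhattan distance on range-scaled features, miss
   contributions weighted by class priors.
3. **Iterative NCA (INCA).** Diagonal neighborhood component analysis
   learns one nonnegative weight per feature by maximizing expected
   leave-one-out soft-neighbor accuracy with an $L_2$ penalty
   ($\lambda = 1/n$). Features are ranked once by descending weight, and
   for every candidate size $k = 100, \dots, 1000$ (901 candidates) the
   top-$k$ subset is scored by the misclassification rate of the cubic SVM
   under seeded stratified 10-fold cross-validation — the same folds for
   every $k$. The minimum-loss subset wins; ties break toward the smallest
   $k$, and equal NCA weights keep original column order. NCA weights are
   computed once on the ReliefF survivors, not re-fit per candidate size.

Two numerical choices in the NCA stage deserve note. First, the
optimization starts from a common weight scaled so the mean pairwise
weighted distance is 1; with thousands of features and unit starting
weights the soft-neighbor softmax would saturate (distances in the
thousands), leaving a flat objective in which only the penalty gradient
acts. Second, L-BFGS-B (bounded below by zero) runs to a projected-gradient
tolerance of 1e-6 with an iteration cap of 60; both are fixed, so the
optimization is a pure function of its inputs.

The 901-candidate sweep trains each SVM on an $n$-column factor $Z$ of the
subset's Gram matrix ($ZZ^\top = X_k X_k^\top$, via a symmetric
eigendecomposition). A polynomial-kernel machine depends on the data only
through the Gram matrix, so this is an exact reformulation, not an
approximation; it makes the per-candidate cost independent of $k$, which is
what keeps the full sweep to minutes on one CPU.

## Classification and metrics

The classifier is a support vector machine with the inhomogeneous cubic
kernel $(u \cdot v + 1)^3$ (kernel scale and offset 1), box constraint
C = 1, one-vs-one multiclass (libsvm via `e1071`). Evaluation is seeded,
stratified 10-fold cross-validation; test-fold predictions are pooled into
one confusion matrix. The six summary metrics — accuracy, macro F1, average
(macro) precision, geometric mean of per-class recalls, macro sensitivity
and macro one-vs-rest specificity — use unweighted macro averaging, the
natural choice for the balanced designs this pipeline targets. A class that
is never predicted contributes precision 0 with a warning rather than an
error. `compare_classifiers()` is an optional harness running eight shallow
classifiers under identical folds; bagged trees are realised as a
random forest with `mtry = p` (bagging is the `mtry = p` special case).

## The synthetic dataset

`gen_dataset()` emulates a balanced six-class sleep-EEG corpus without any
external download: 30-s epochs at 128 Hz (3,840 samples), 50 epochs per
class by default, each epoch a sum of stage-specific band-limited sinusoids
with random phases plus 1/f background noise of amplitude 1. The band
assignments loosely follow sleep physiology — alpha-dominated wake
(10 Hz), theta S1 (6 Hz), spindle-like 13 Hz bursts in S2 (50%-duty
amplitude modulation at 0.5 Hz), slow delta S3 (2.5 Hz), high-amplitude
1 Hz S4, and a mixed 5 + 20 Hz REM profile. Amplitudes are fixed so that
no single feature classifies the six stages on its own while the full
pipeline does, which keeps end-to-end tests non-vacuous. Every epoch is a
pure function of (seed, class, index), so any subset can be regenerated.

What the generator does *not* emulate matters for interpreting green tests:
real polysomnography has nonstationary stage transitions, movement and
ocular artifacts, inter-subject variability and imbalanced stage
prevalence. Passing the synthetic recovery test demonstrates that the
pipeline's machinery — extraction, selection, evaluation, persistence — is
correct and discriminates spectrally distinct classes; it does not certify
clinical-grade accuracy on real recordings.

## Problem sizes and runtime

The default study condition for end-to-end runs is 300 epochs
(50 per class) of 3,840 samples: extraction ≈ 20 s, ReliefF ≈ 40 s, NCA
≈ 3 min, the 901-candidate sweep ≈ 4 min on a single CPU. The unit tests
exercise the same code paths at smaller sizes (fewer epochs, 2 levels,
narrow INCA bounds), which is sufficient because every operation's
contracts are size-parametric and checked independently.

## Known limitations

* The EDF reader covers continuous single-rate recordings with a text
  annotation sidecar; EDF+ embedded annotation streams and discontinuous
  files are out of scope.
* ReliefF and NCA hyperparameters (neighbor count, regularization,
  iteration budget) are fixed package choices, documented above; the
  selection procedure itself does not prescribe them.
* Case-specific results on clinical corpora (selected subset sizes,
  per-cohort accuracies) depend on data that must be supplied by the user;
  the package reproduces the pipeline, not any particular cohort's
  numbers.
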