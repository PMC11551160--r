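---
title: "Predicting RNA 5hmC sites from hybrid sequence features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting RNA 5hmC sites from hybrid sequence features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

5-hydroxymethylcytosine (5hmC) is an oxidized cytosine modification that
occurs on RNA as well as DNA, is produced by TET-mediated oxidation, and has
been linked to RNA splicing, translation and decay. Wet-lab detection
(LC--MS/MS, HPLC, chemical labelling) is accurate but slow and expensive, so
sequence-based predictors are used to triage candidate sites: given a short
RNA window, predict whether its central context carries 5hmC.

`hmcpred` implements one family of such predictors end to end: hand-crafted
sequence descriptors fused into a hybrid feature vector, unsupervised
dimension reduction, and a small feed-forward neural network, evaluated with
stratified K-fold cross-validation.

# The model

## Seven sequence encodings, 174 dimensions

Every sequence is a validated string over {A, C, G, U} (T on input is read
as U). Seven encoders each map a sequence to a fixed-length block, and the
hybrid vector is their concatenation in a fixed order:

| block | encoder | dimension |
|---|---|---|
| 1 | k-mer composition (k = 2) | 16 |
| 2 | canonical reverse-complement k-mer composition (k = 2) | 10 |
| 3 | pseudo dinucleotide composition (composition tier) | 16 |
| 4 | pseudo trinucleotide composition (composition tier) | 64 |
| 5 | trinucleotide auto-covariance (TAC) | 4 |
| 6 | trinucleotide cross-covariance (TCC) | 4 |
| 7 | dinucleotide cross-covariance (DCC) | 60 |

Total: 174 features.

The composition encoders are sliding-window frequencies,
`count(word) / (L - k + 1)`, so each block is non-negative and sums to 1.
The canonical reverse-complement variant first merges each k-word with its
reverse complement (for k = 2 this leaves 10 classes), making the block
invariant under reverse complementation of the whole sequence. The pseudo
di-/tri-nucleotide blocks are the pure composition tier (no lambda
correlation terms): their printed dimensions (16 and 64) are exactly the
plain composition sizes, and the package treats the classic lambda > 0 tier
as out of scope.

The covariance encoders read a *property profile*: position i of the profile
is the value of property u for the k-word starting at i, giving a series of
length N (N = L - 1 for dinucleotides, L - 2 for trinucleotides). For
properties u1, u2 and lag l,

$$\mathrm{cov}_{u_1,u_2}(l) \;=\; \frac{1}{N-l} \sum_{i=1}^{N-l}
  \bigl(P_{u_1}(i)-\bar P_{u_1}\bigr)\bigl(P_{u_2}(i+l)-\bar P_{u_2}\bigr).$$

TAC is the auto case (u1 = u2) over trinucleotide properties; TCC the cross
case over ordered pairs of distinct trinucleotide properties; DCC the cross
case over dinucleotide properties. All three are exactly zero on
homopolymers (constant profile) and are checked against a brute-force
double-loop oracle in the test suite.

## Property tables

DCC uses six RNA dinucleotide helical step parameters (shift, slide, rise,
tilt, roll, twist) shipped as a versioned CSV under `extdata`, as compiled
in the pseudo-nucleotide-composition descriptor literature. There is no
comparably standard trinucleotide table for RNA, so the two trinucleotide
properties (roll, twist) are *lifted* from the dinucleotide table: the value
of a trinucleotide is the mean of its two overlapping dinucleotide steps,
computed in code at load time so the two tables can never drift apart.
Every property is standardized to zero mean and unit (population) variance
over its k-words before profiles are built, which makes the covariance
blocks comparable across properties and invariant to the units of the raw
table.

With this configuration (6 dinucleotide properties, 2 trinucleotide
properties, maximum lag 2) the covariance dimensions are 2×2 = 4,
2×1×2 = 4 and 6×5×2 = 60. Other property-count/lag combinations could
produce the same dimensions; since the source descriptor family fixes only
the dimensions, exact numeric parity with any particular earlier
implementation is not claimed, and both tables and the lag are configurable
through `encoder_config()`.

## PCA feature selection

The hybrid matrix is reduced by centred (covariance, not correlation) PCA;
75 components are retained by default. Two choices deserve comment:

* **Per-fold fitting.** Inside cross-validation the PCA basis is refitted on
  each fold's training rows only; fitting on pooled data before CV leaks
  test-set structure into the representation and inflates CV estimates. A
  `pca_pooled = TRUE` flag reproduces the leaky variant for comparison, and
  an integration test asserts that fold-specific bases actually differ.
* **No variance scaling by default.** The composition and covariance blocks
  are already on comparable, bounded scales, and covariance PCA is what
  "eigenvectors of the covariance matrix" means; `standardize = TRUE`
  switches to correlation PCA.

Component signs are fixed deterministically (the largest-magnitude loading
of every component is positive) so serialized models are comparable across
runs. `n_components` also accepts a fraction in (0, 1), interpreted as a
variance-retention target.

## The classifier

A feed-forward network with four hidden layers of 64, 32, 16 and 8 neurons,
ReLU hidden activations (tanh as the documented alternative), and a sigmoid
output unit; binary cross-entropy loss with an L2 weight penalty
(lambda = 1e-4), inverted dropout (rate 0.4) on hidden activations during
training, He-uniform initialization, and the Adam optimizer (learning rate
0.01) over shuffled mini-batches of 32 for 700 epochs with no early
stopping. Defaults follow the tuned configuration of the source predictor
family; where its description is internally inconsistent (three vs four
hidden layers, tanh vs ReLU in hidden layers) the package follows the
configuration that the tuning table and reported optimum support — four
layers, ReLU — and exposes the alternative. Batch size and the loss are not
stated there at all; 32 and cross-entropy-with-sigmoid are the standard
pairing and are documented as this package's choices.

Inputs to the network are standardized column-wise on training statistics
(stored in the model and re-applied at prediction). Principal-component
scores arrive with per-column variances spanning orders of magnitude, and a
fixed-learning-rate optimizer conditions badly on such inputs; the scaler
is part of the model so serialized networks remain self-contained.

Everything stochastic (initialization, shuffling, dropout) runs under a
local RNG seeded from `dnn_config(seed=)` (default 1234), so training is
bit-reproducible on a fixed platform and never perturbs the caller's RNG
stream. Training records one mean loss per epoch.

The learning-rate x activation grid search evaluates the full Cartesian
product (by default 9 learning rates x 2 activations = 18 cells) by mean
K-fold CV accuracy of the *entire* pipeline; ties break towards the lower
learning rate, then the first-listed activation, and a cell whose
configuration fails validation is recorded as a failed cell rather than
aborting the sweep.

# Evaluation protocol

Accuracy, sensitivity and specificity are reported on the x100 (percent)
scale, MCC raw in [-1, 1], and precision/recall/F1 as proportions (F1 is
also conventionally quoted x100). Sensitivity is identically recall x 100;
both are reported to avoid the common conflation of the two names. A ratio
with a zero denominator is reported as `NA` with a warning, never silently
as 0 — silent zeros would corrupt the grid-search argmax. The ROC is a
threshold sweep with tied scores grouped into single steps, and the
trapezoidal AUC is checked in the tests against exhaustive Mann-Whitney
pair counting (ties counted one half).

Cross-validation is stratified: each class is shuffled (seeded) and dealt
round-robin, so per-fold class ratios stay within one sequence of the
global ratio. The fold count is configurable and recorded in every report;
K = 10 is the default, since the protocol this package re-implements leaves
K unreported. The 10% independent hold-out is likewise stratified per class
(`make_split`), which for a balanced 662 + 662 input yields the familiar
132-sequence test set.

# The synthetic benchmark generator

`synthetic_spec()` defaults describe the emulated benchmark shape: 662
positives and 662 negatives of 41 nt (a typical site-centred window; the
emulated benchmark never states its window length). Positives carry a
planted 5-mer motif (`GCCAC`) at a uniformly random position with
probability `motif_prob` (default 1) *and* a first-order composition bias:
the probability of repeating the previous nucleotide is tilted up by
`composition_shift` (default 0.1) before renormalisation. The bias inflates
AA/CC/GG/UU steps and therefore moves the property profiles, so the
covariance blocks — not only the k-mer counts — carry class signal.
Negatives are i.i.d. background (uniform by default). `null_dataset()`
removes both signals for calibration checks.

What passing tests on this generator do show: the pipeline recovers planted
composition/covariance signal far above chance, and reports chance-level
accuracy and near-zero MCC when no signal exists. What they do not show:
performance on real 5hmC data, whose discriminative structure (motif
grammar, positional effects, sequence redundancy) the generator does not
attempt to model. Published benchmark numbers therefore cannot be validated
from the generator; the CLI will compute them directly when pointed at the
deposited FASTA files.

One property of the defaults is worth understanding before changing them:
the hybrid descriptors are position-free summaries, so a single planted
5-mer in a 41-nt window moves each affected composition feature by only
about one count in forty. The strong end of the default signal dial
(`motif_prob = 1` plus the composition bias) is therefore recovered at
around 85% CV accuracy by the full pipeline — far above chance but not
near-perfect, much as real modification predictors built on these
descriptor families plateau in the mid-80s. Longer motifs or larger
`composition_shift` values make the synthetic problem arbitrarily easy, at
the cost of realism.

# Numerical choices and degenerate inputs

* Covariance denominators are `1/(N - l)` (per-lag averaging), matching the
  averaging shape of the descriptor family.
* Sequences shorter than `3 + lag` are rejected with the required minimum
  named; ambiguity codes (N, ...) are rejected rather than skipped, because
  silently dropping positions would distort the normalised compositions.
* Probabilities are clipped to [1e-12, 1 - 1e-12] inside the cross-entropy
  only; predictions are raw sigmoid outputs.
* `classify` calls a sample positive when p >= threshold, so threshold 0
  yields all-positive and threshold 1 positives only at p = 1 exactly.
* Problem sizes used by the shipped verification runs were chosen to keep a
  laptop-scale run comfortable: the planted-motif recovery run uses 200+200
  sequences with 10-fold CV at the full 700-epoch budget, the null
  calibration 100+100 over five seeds, and the grid-shape check a reduced
  epoch budget (the grid check is about structure and argmax, not about the
  training budget).

# Known limitations

* The physicochemical configuration reproduces the published descriptor
  dimensions, but numeric parity with other implementations of the same
  descriptor names is not guaranteed (property sets and lags differ across
  toolkits).
* Training is single-threaded R matrix arithmetic: ample for the benchmark
  scale (~1.3k sequences, 75 inputs), not for genome-scale scans.
* No redundancy reduction is built in; inputs are assumed pre-deduplicated
  (e.g. with CD-HIT), and the split manifest records that flag verbatim.
* The baseline adapters (NB, SVM, KNN, RF, DT) are intentionally thin glue
  over standard implementations for comparison tables, not tuned baselines.
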