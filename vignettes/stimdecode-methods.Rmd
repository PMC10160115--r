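---
title: "Methods: from subtitle annotations to multi-voxel sentiment decoding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from subtitle annotations to multi-voxel sentiment decoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stimdecode)
```

`stimdecode` decodes the sentiment of movie dialogue from concurrent fMRI
activity. Because naturalistic viewing has no trial structure, the class
labels are manufactured from the stimulus itself: the subtitle stream is
scored for sentiment, and those per-sentence labels are projected onto the
fMRI volume grid. This vignette describes each model component, the
parameters that matter, the synthetic data the package tests itself on,
and the design choices made where the procedure is genuinely
underdetermined.

## Sentence reconstruction

Word-annotation files give one row per spoken word with onset and offset
in seconds. Sentences are the unit of sentiment, so the word stream is
partitioned either at an explicit sentence-end column or at terminal
punctuation — both supported because in the original workflow sentence
boundaries were placed by hand, and an explicit, file-borne marker makes
that manual step reproducible.

A sentence's duration is last-word offset minus first-word onset, so
pauses *inside* a sentence count toward its duration. This is the natural
reading of "duration from the word timings" and matters downstream: the
volume-claiming rule uses exactly this duration. Onsets are expected to be
non-decreasing; because real annotation files contain jitter, a violation
warns rather than errors. Corpus statistics (`subtitle_stats()`) default
to the sample (n−1) standard deviation; the population convention is a
switch, since summary tables in the literature rarely state which was
used.

## Compound sentiment scoring

Scoring is lexicon-based: tokens are lower-cased and looked up in a table
of signed valences. The raw sum S of matched valences is normalized to

$$\mathrm{compound} = \frac{S}{\sqrt{S^2 + \alpha}}, \qquad \alpha = 15,$$

which is strictly inside (−1, +1), shares the sign of S, is odd under
valence negation, and saturates monotonically as |S| grows. A lexicon word
preceded within `window = 3` tokens by a negation word ("not", "never",
…) contributes valence × (−0.74): the flip-and-damp convention of the
lexicon-analyzer family this scorer follows. α, the negation factor, the
window and the negation set are all configurable; the defaults are the
de-facto standards for this style of scorer rather than fitted values.
Capitalization and punctuation intensity boosts, which some analyzers
apply heuristically, are deliberately **not** implemented — there is no
agreed formula for them — and this is a documented limitation for users
comparing against such analyzers.

Polarity is the sign of the compound; exactly zero is neutral. Neutral
sentences are folded into classes in three ways (Binary Case 1: neutral
with positive; Binary Case 2: neutral with negative; or kept as a third
class), encoded as integers neutral = 0, negative = 1, positive = 2.
Agreement between two analyzers' label vectors is the element-wise match
count and fraction (`similarity_score()`); third-party analyzers plug in
through a registry (`register_analyzer()`) and are never required.

The bundled demo lexicon (~55 words) exists so that examples and tests run
self-contained; real analyses should point `read_lexicon()` at a full
published valence lexicon.

## TR alignment

The scan window [t_start, t_end) is divided into half-open volumes
[t, t + TR). Each sentence, taken in onset order, claims
⌈duration / TR⌉ volumes beginning at the volume containing its onset
(floor((onset − t_start)/TR)); a sentence whose duration is not a whole
number of TRs therefore claims the partially covered volume too. Three
situations are underdetermined by that rule and resolved as follows:

* **Overlaps** (the ceiling extends a sentence into the next one's onset
  volume): the later sentence overwrites — the result of a single
  sequential pass in time order, which is also the simplest rule to reason
  about. Alignment error of this kind is inherent to the labeling scheme.
* **Gaps** (silence between dialogues): the previous label is carried
  forward (`gap_policy = "carry_previous"`); a `"neutral"` policy exists
  for sensitivity analyses.
* **Lead-in** (volumes before the first sentence): backfilled with the
  first sentence's label by default. In the motivating design this case is
  moot because the un-annotated lead-in is discarded outright:
  `discard_lead_in(n, lead_in, tr)` drops floor(lead_in/TR) volumes (1805
  volumes minus 61 s at TR = 1 s → 1744).

Hemodynamic-lag shifting or HRF convolution of the labels is out of scope:
labels are aligned to stimulus time, exactly as the procedure being
modeled does.

## ROI features

ROIs are spheres of fixed radius (default 5 mm) around MNI seed
coordinates. A voxel belongs to the sphere when its *center*, mapped
through the image affine, lies within the radius (boundary inclusive) —
the simplest discretization, and one that an exhaustive distance scan can
verify independently, which the test suite does on random affines. Seeds
are used exactly as given; no snapping to the voxel grid. The six-region
sentiment network of the motivating study (L_ACC, R_STG, L_cere, L_medFG,
R_IFG, L_ch; 19/20/20/20/16/16 voxels, 111 total) ships as a reference
table of names and counts only: the seed coordinates come from prior
literature and must be user-supplied, so the package does not hard-code
coordinates it cannot source.

Per-subject, per-ROI time-series matrices are stacked into the decoding
matrix: rows are (subject × volume) time points with subjects contiguous,
columns the concatenated ROI voxels, plus one trailing label column. A TSV
directory bypass (`read_roi_timeseries_dir()`) runs the decoding half
without any NIfTI input.

## Balancing

Subtitle-derived labels are heavily imbalanced, so two oversamplers are
provided. Random oversampling duplicates minority rows uniformly with
replacement; SMOTE interpolates x + u·(z − x) between a minority point x
and one of its k = 5 nearest minority neighbors (Euclidean metric,
neighbors within the class only, k capped at class size − 1). Every
synthetic point thus lies on a segment between two minority points — a
property the tests check geometrically.

Balancing is applied **before** the train/test split by default, because
that is the procedure being modeled; it leaks duplicated (ROS) or
correlated (SMOTE) rows across the split and inflates test accuracy,
which is the parsimonious explanation for near-ceiling ROS accuracies in
this kind of pipeline. The README shows the effect on synthetic data
(0.875 → 0.995 at d = 0.1). Users wanting honest generalization estimates
should balance the training partition only, by calling
`balance_classes()` on it after splitting.

## Classifiers and evaluation

Random forest (100 trees), RBF-kernel SVM (C = 1, γ = 1/p), and a gini
CART tree are delegated to randomForest, e1071 and rpart; the resolved
parameter values are stored in the fitted object so that "library
defaults" remain reproducible across versions. The MLP is implemented in
the package: seven ReLU hidden layers (100, 90, 70, 50, 30, 20, 10), a
single logistic output unit with binary cross-entropy for two classes or
a softmax layer with categorical cross-entropy for three, trained with
Adam (learning rate 10⁻³, 50 epochs, batch 64 by default — the
architecture is fixed by the design being modeled, the optimizer settings
are ordinary choices). Features are standardized to training-set zero
mean/unit variance before SVM and MLP fitting. On separable data the
training loss decays toward zero, which the tests assert.

Evaluation reports the confusion matrix, accuracy, and per-class
precision/recall/F1 with **macro** averages — chosen because the headline
experiments run on balanced data, where macro and micro coincide, and
macro degrades more informatively on imbalanced data. Hold-out splits
default to 70/20/10 train/test/validation everywhere (stated for the
subtitle experiments, unstated for fMRI; one convention is used for
both); the validation partition is reserved for MLP monitoring and is
otherwise unused. K-fold cross-validation defaults to k = 10. Shuffled
label controls permute the label column under a named seed, preserving
the class histogram while destroying the signal.

## Synthetic data: what it does and does not emulate

The generator exists so that every stage, and the acceptance checks, run
without neuroimaging downloads. Its defaults reproduce the motivating
design: 20 subjects, 1744 volumes at TR = 1 s, the 111-voxel ROI layout,
sentence lengths with mean 6.05/sd 4.81 words and durations with mean
3.8/sd 5.5 s — drawn from log-normals matched to those moments (the
moments are reported in the literature, the family is not; log-normal is
the standard positive, right-skewed choice) and rejection-truncated at
≥ 1 word / ≥ 1 s. The sentence mix defaults to 45% positive / 22%
negative / 33% neutral, matching the 3-class label proportions of the
motivating corpus. Sentences are realised as words from the demo lexicon
(sentiment words of the correct sign plus out-of-lexicon filler, no
negations), so the internal scorer provably recovers the generating
polarity — the identifiability the end-to-end tests rely on.

Voxel data follow μ_class(t) + ε: one fixed random pattern per class,
drawn once per dataset from a standard normal and scaled by d·σ, where d
is the class effect size in noise-sd units, plus iid Gaussian or
stationary AR(1)(ρ) noise. Expected per-voxel class separation is
therefore d·σ·√2. This is sufficient to test decoders — accuracy is
chance at d = 0, monotone in d, and ≥ 0.95 by d = 5σ
(`parameter_recovery_experiment()`) — but it emulates none of the
structure of real fMRI: no hemodynamic response, no spatial correlation,
no physiological or motion artifacts, no inter-subject pattern
variability. Passing tests on this data demonstrates the pipeline's
bookkeeping and statistical behavior, not that real brains are decodable
at any particular accuracy.

## Numerical choices and problem sizes

Timing comparisons use a 10⁻⁹ s guard so that exactly-integer durations
claim exactly duration/TR volumes while 8.3 s still rounds up to 9.
Sphere membership uses a 10⁻⁹ mm guard to keep the boundary inclusive
under floating-point error. Zero-variance feature columns get unit scale
during standardization. All randomness flows through named integer seeds
(`split_seed`, `balance_seed`, `model_seed`, `shuffle_seed`), and same
seed means identical output, bit for bit where the operation is
deterministic.

The test suite exercises the full 20 × 1744 × 111 bookkeeping once, and
otherwise runs statistical checks at reduced sizes the package considers
sufficient for the properties tested: chance-level controls at 400 × 20
over 10 seeds, hold-out-vs-k-fold stability at 1500 × 50 over 3 seeds,
recovery curves at 2 subjects × 250 volumes × 20 voxels. The acceptance
script uses 2000 × 111 over 5 seeds.

## Known limitations

* The compound scorer implements the valence-sum core only; intensity
  heuristics of specific third-party analyzers are not reproduced, so
  adapter-based comparisons measure those analyzers, not this scorer.
* Label alignment ignores hemodynamic lag by design.
* The default oversample-then-split order leaks information across the
  evaluation split; it is retained as the modeled procedure, with the
  leakage-free alternative documented above.
* SMOTE's O(n²) within-class distance matrix is fine at the tens of
  thousands of rows this pipeline sees, but not beyond.
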