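---
title: "Loss-difference filtering of noisy patch labels: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Loss-difference filtering of noisy patch labels: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Patch-based classification of whole-slide images (WSIs) inherits its labels
from coarse manual annotations: a slide is tiled into fixed-size patches and
each patch takes the class of the annotated region it falls in, with
unannotated tissue treated as benign. Because lesion boundaries are drawn
quickly and generously, annotations routinely over-cover: benign tissue
inside or beside an annotated region becomes a *false-positive patch* — a
patch whose training label disagrees with its true tissue class. A
classifier trained on such data first learns the consistent class structure
and then starts memorizing the mislabeled patches, which degrades both its
probability estimates and its accuracy on clean data.

`lossdiff` implements a training-time remedy. During training we keep, per
class, the running average of the cross-entropy losses of *correctly
classified* instances, accumulated over every iteration so far. A sample
whose loss reaches `alpha` times its class's running average satisfies the
*abstain condition*; boundary equality triggers it. The filter then acts in
one of two modes:

* **discard** — remove the sample from the training set permanently. By
  default the action additionally requires the sample to be correctly
  classified (`require_correct = TRUE`): the filter targets samples the
  model "gets right" only at abnormally high loss, the typical signature of
  a memorized wrong label.
* **flip** — replace the training label of a high-loss *misclassified*
  sample with the model's current prediction. The record stays in the
  training set and may be flipped again later. (The literal two-case rule
  conditions on correct classification, but flipping a correctly classified
  sample to its own prediction is a no-op; flip mode therefore triggers on
  misclassified samples, which is the only reading that acts at all.)

Filtering is suspended for `warmup_epochs` initial epochs (default 2) while
the loss statistics accumulate. Decisions in a batch are always evaluated
against the tracker state *before* that batch is recorded, so a sample's
own loss never inflates the threshold it is judged by. Statistics
accumulate across the whole run rather than resetting each epoch: the
running average is the mean over all recorded iterations.

## What feeds the condition

Two contract details matter and are worth stating precisely:

* Only correctly classified samples are recorded into the tracker, each
  under its ground-truth (possibly noisy) class. The class average is the
  running sum over the running count for that class; a class with no
  recorded instance yet has no statistics and can never trigger the
  condition. A `global` tracker scope that pools all classes is available;
  the default is per-class, so a sample is compared with its own class's
  loss level and systematically easier or harder classes do not distort
  each other's thresholds.
* The iteration counter advances once per batch. It is bookkeeping — the
  averages divide by the per-class counts of recorded losses, the only
  normalization under which the quantity is an average of those losses.

`alpha` defaults to 1: filter anything at or above the class's own average.
Larger values are more conservative and protect difficult-but-clean cases;
the parameter is exposed everywhere and nested monotonically (the discard
set at a larger `alpha` is a subset of the set at a smaller one, for a
frozen model).

## The reference classifier

The training loop is written against a small contract (`clf_featurize`,
`clf_train_step`, `clf_predict`), so any backbone that reports per-sample
cross-entropy losses and class probabilities can be plugged in. The
packaged reference backbone is a random-feature network chosen to be
CPU-trainable in seconds while *reproducing the loss dynamics that the
filter assumes*:

* images are block-averaged to 16 × 16 pixels per channel;
* a **linear channel** passes the pooled pixels through at scale 2 —
  class-coherent gradients accumulate over the whole training set, so the
  softmax head fits the class structure quickly and confidently;
* a **high-frequency random Fourier channel** (4096 units,
  `cos(x %*% Omega + phase)` with frequencies at standard deviation 8 in
  pooled-pixel units, scale 1) renders even near-duplicate patches nearly
  orthogonal — it supplies per-sample capacity with which the Adam-trained
  head can fit individual mislabeled samples, but only gradually, one
  visit at a time.

The resulting dynamics mirror what deep backbones do on noisy labels:
within the first couple of epochs the class signal is learned and clean
samples become confident; mislabeled samples are then memorized slowly,
each passing through a window in which it is correctly classified at a
loss far above its class average — exactly what the abstain condition
detects. The two scale parameters set the pace of the two phases; the
bandwidth sets how much memorizing one sample drags its neighbors (and
hence how much harm baseline overfitting does to validation loss). These
are architecture defaults of the reference backbone, not tuning knobs of
the method.

Optimization follows standard practice for this problem family:
cross-entropy, Adam at learning rate 0.001, 30 epochs, batch size 32. All
randomness (initialization, epoch shuffles, generator draws) is seeded and
the run is bit-reproducible.

## The synthetic study conditions

The real WSI collections this method is aimed at are not redistributable,
so the package ships a generator whose defaults define the study
conditions used by the tests:

* `K` texture classes rendered as tinted, oriented, blob-speckled patches;
  a `difficulty` parameter interpolates all class recipes toward their mean
  (0 = maximally separated, 1 = identical). At difficulty 0 a
  nearest-centroid classifier on channel means exceeds 95% accuracy; at 1
  it is at chance.
* Patches live on virtual slides (about 200 per slide, at least 3 slides)
  and splits are assigned per slide, 80/10/10, so the slide-level
  independence of train/validation/test is exercised.
* Symmetric label noise is injected into the training split only, flipping
  exactly `round(rate * n)` labels chosen by a seeded permutation — the
  stated percentage is exact, binary flips go to the opposite class,
  multiclass flips draw uniformly from the other classes. The injection
  mask makes recovery measurable (precision/recall/enrichment of any
  acted-on set against the truly flipped set).
* Whole synthetic slides emulate the annotation mechanism itself: regions
  are painted on a white canvas and the emitted annotations are the true
  polygons dilated outward by `annotation_dilation` pixels. Tiling and
  labeling against the dilated polygons then mislabels benign tissue near
  lesion borders at a rate that is zero at dilation 0 and non-decreasing
  in the dilation — measured, not assumed, by `annotation_noise_rate()`.

The study scale used by the acceptance-style tests is K = 3 classes,
64 × 64 patches, roughly 3,000 training patches, difficulty 0.2, noise
rates 0.3–0.4, five seeds — large enough for the dynamics to be stable,
small enough to train in under half a minute per run on one CPU.

What the generator does *not* emulate: stain variation, magnification
pyramids, instance-dependent or class-conditional noise, and real
morphological intra-class diversity. Passing tests show the filtering
mechanism works where its assumptions hold; they do not certify
performance on any particular clinical dataset.

## Numerical and design choices

* Coordinates are 0-based with a top-left origin; tiles are half-open
  `[x, x + size)` squares. Tiling enumerates only fully contained tiles,
  row-major.
* A pixel is background when all three channels are at or above 220 of
  255; a tile is dropped when more than 70% of its pixels are background.
  Both thresholds are arguments.
* A tile inherits the class of the annotation with maximal overlap
  fraction if that fraction reaches 0.5 (configurable; a center-point mode
  exists), otherwise it is benign. Ties break toward the smaller class
  index with a warning. Border behaviour at partial overlap is a
  deliberate package choice — the upstream practice it models leaves it
  unspecified.
* Slide splitting floors the validation and test slide counts and gives
  the remainder to train, maximizing training data under the 80/10/10
  convention.
* Discards are permanent; flips are revisited. The filter's undefined
  corner (over-threshold *and* misclassified, in discard mode) defaults to
  *keep*, per the literal two-case rule; `require_correct = FALSE` exposes
  the broader behaviour.
* McNemar comparisons use the continuity-corrected chi-square when the
  discordant count reaches 25 and the exact two-sided binomial below
  that — the standard small-sample practice. AUCs use rank statistics with
  averaged ties (equivalent to trapezoidal integration); macro averaging
  is unweighted and skips classes absent from the truth with a warning.
* t-SNE export delegates to scikit-learn's implementation at default
  parameters with a fixed `random_state`, via the system `python`; the
  HDF5 patch-archive reader likewise delegates to `h5py`. Both are I/O
  conveniences, not method components.

## Known limitations

* With `alpha = 1` the filter is aggressive by construction: a fraction of
  clean samples whose losses sit above their class average is discarded
  along with the noise (the runs in the tests discard at roughly 70%
  precision at 30% injected noise). That trade-off is inherent to the
  rule; raising `alpha` trades recall for precision.
* The reference backbone's memorization pace is calibrated for the
  generator's texture family at the study scale. A backbone that cannot
  memorize at all (e.g., a purely linear model) never produces the
  correct-but-high-loss signature, and the default discard rule then has
  nothing to act on — the mechanism, not the implementation, requires
  overfitting capacity.
* Slide-level aggregation (patient-level diagnosis) and stain
  normalization are out of scope.
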