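# lossdiff

Training-time denoising of patch labels for whole-slide image (WSI)
classification.

## The problem

Patch classifiers for digital pathology inherit their labels from coarse
manual annotations: slides are tiled into fixed-size patches (256 × 256 by
convention; configurable) and each patch takes the class of the annotated
region it overlaps, with unannotated tissue treated as benign. Hand-drawn
annotations over-cover, so benign tissue near lesion borders enters
training with a non-benign label — *false-positive patches*. Networks
trained on such data first learn the class structure, then memorize the
mislabeled patches; validation loss rises and clean-data accuracy drops.

## The method

During training, `lossdiff` tracks for each class $c$ the running average
loss $\bar\ell_c$ of **correctly classified** instances, accumulated over
all iterations so far. After a warm-up of $w$ epochs (default 2), a sample
with loss $\ell$, label $y$ and prediction $\hat y$ is screened by the
abstain condition

$$\ell \ge \alpha \,\bar\ell_{y},$$

with $\alpha > 0$ (default 1) protecting difficult-but-clean cases. Two
actions are provided:

* **discard** — remove the sample permanently when the condition holds
  *and* $y = \hat y$: the sample is classified correctly yet at an
  abnormal loss, the signature of a memorized wrong label;
* **flip** — when the condition holds and $y \ne \hat y$, replace the
  training label with the model's prediction $\hat y$ and keep the record.

The surviving (possibly re-labeled) records form the cleaned training set
$D_c$ from the noisy baseline $D_b$. A pluggable classifier contract
separates the filter from the backbone; the packaged reference backbone is
a seeded random-feature network (linear + high-frequency Fourier channels
with a softmax head, Adam, cross-entropy) that reproduces deep-net
memorization dynamics while training in seconds on one CPU.

Around the core the package provides slide tiling with white-background
filtering, polygon-annotation labeling, slide-level 80/10/10 splits, class
balancing, manifest/HDF5 archive I/O, exact symmetric label-noise
injection with recovery metrics, a seeded synthetic patch/slide generator
(including dilated annotations that *induce* measurable label noise), and
an evaluation suite: accuracy, confusion matrices, micro/macro ROC-AUC,
McNemar paired tests, t-SNE feature export, and slide heatmap
reconstruction.

## Worked example

```r
library(lossdiff)

# a synthetic 3-class study: ~3,700 patches on 19 virtual slides,
# 30% symmetric label noise injected into the training split
ds <- generate_patch_dataset(K = 3, n_per_class = 1250, size = 64,
                             difficulty = 0.2, noise_rate = 0.3, seed = 101)

fit <- train_lossdiff(ds$manifest, ds$images,
                      policy = filter_policy(alpha = 1, mode = "discard",
                                             warmup_epochs = 2),
                      config = train_config(epochs = 30, seed = 101))
print(fit)
#> lossdiff_fit: 30 epochs, mode=discard alpha=1
#>   final: train_loss=0.0006 val_loss=0.0157 val_acc=99.5%
#>   train remaining: 2016; discarded: 1339; flipped: 0

# how much of the discarded set was truly mislabeled?
disc <- unique(fit$decisions$patch_id[fit$decisions$action == "discard"])
noise_recovery_metrics(disc, ds$mask, n_train = 3355)
#> $precision
#> [1] 0.712472
#> $recall
#> [1] 0.9483101
#> $enrichment
#> [1] 2.376087
```

The filter removed 1,339 of 3,355 training patches; 71% of them were
genuinely mislabeled (2.4× the 30% noise prior) and it caught 95% of all
injected noise. A baseline trained on the same data without filtering
reaches 73.7% clean-test accuracy versus 100% after filtering (seed 101;
see the acceptance script for the full comparison).

A thin command-line front end is included:

```sh
Rscript inst/scripts/run_lossdiff.R --config run.yaml --out outdir/
```

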