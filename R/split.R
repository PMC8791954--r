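#' Assign splits at the slide (patient) level
#'
#' Patches from one slide are highly correlated, so train/val/test splits
#' are assigned to whole slides: slides are shuffled with `seed`, counts per
#' split are the floors of the fractions times the number of slides, and
#' leftover slides go to train. Every patch inherits its slide's split, so
#' no slide ever straddles two splits.
#'
#' @param manifest A `patch_manifest`.
#' @param fractions Numeric length-3 `(train, val, test)`, summing to 1.
#'   Default `c(0.8, 0.1, 0.1)`.
#' @param seed Integer seed for the slide shuffle.
#' @return The manifest with `split` reassigned.
#' @export
split_by_slide <- function(manifest, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  stopifnot(inherits(manifest, "patch_manifest"))
  if (length(fractions) != 3L || abs(sum(fractions) - 1) > 1e-9)
    stopf("fractions must be length 3 and sum to 1")
  slides <- unique(manifest$records$slide_id)
  S <- length(slides)
  if (S < 3L) stopf("need at least 3 slides to form 3 splits, got %d", S)
  n_val <- floor(fractions[2] * S)
  n_test <- floor(fractions[3] * S)
  n_train <- S - n_val - n_test            # remainder goes to train
  if (n_train < 1L || n_val < 1L || n_test < 1L)
    stopf("split would leave an empty partition (train=%d val=%d test=%d slides)",
          n_train, n_val, n_test)
  ord <- with_seed(seed, sample(slides))
  assign <- setNames(rep(c("train", "val", "test"),
                         times = c(n_train, n_val, n_test)), ord)
  r <- manifest$records
  r$split <- unname(assign[r$slide_id])
  patch_manifest(r, manifest$classes, manifest$provenance)
}

#' Balance class counts by random down-sampling
#'
#' Keeps `min(class counts)` patches per class, sampled without replacement
#' with `seed`, so comparisons are not biased toward over-represented
#' classes.
#'
#' @param manifest A `patch_manifest` (typically one split).
#' @param seed Integer seed.
#' @return A balanced `patch_manifest`; its records are a subset of the
#'   input's.
#' @export
balance_classes <- function(manifest, seed = 1L) {
  stopifnot(inherits(manifest, "patch_manifest"))
  r <- manifest$records
  K <- length(manifest$classes)
  counts <- tabulate(r$label + 1L, nbins = K)
  if (any(counts == 0L))
    stopf("class '%s' has no patches; cannot balance",
          manifest$classes[which(counts == 0L)[1]])
  m <- min(counts)
  keep <- with_seed(seed, {
    unlist(lapply(0:(K - 1L), function(k) {
      ids <- r$patch_id[r$label == k]
      if (length(ids) == m) ids else sample(ids, m)
    }), use.names = FALSE)
  })
  out <- r[match(keep, r$patch_id), , drop = FALSE]
  rownames(out) <- NULL
  patch_manifest(out, manifest$classes, manifest$provenance)
}
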