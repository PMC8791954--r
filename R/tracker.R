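#' Per-class running loss tracker
#'
#' Accumulates, over all training iterations so far, the cross-entropy
#' losses of *correctly classified* instances, per ground-truth class.
#' The class average (running sum over running count) is the reference
#' level the abstain condition scales by `alpha`: samples whose loss sits
#' far above what the model achieves on instances it already gets right
#' are suspicious, even when classified correctly.
#'
#' @param K Number of classes.
#' @param scope `"per_class"` (default: each sample is compared to its own
#'   class's average) or `"global"` (one pooled average).
#' @return An object of class `loss_tracker` with fields `sums`, `counts`
#'   (per class) and `k`, the batch-iteration counter.
#' @export
new_loss_tracker <- function(K, scope = c("per_class", "global")) {
  scope <- match.arg(scope)
  structure(list(K = as.integer(K), scope = scope,
                 sums = numeric(K), counts = integer(K), k = 0L),
            class = "loss_tracker")
}

#' Bundle one batch's per-sample outcomes
#'
#' @param patch_id Character ids.
#' @param loss Nonnegative per-sample losses.
#' @param y Ground-truth (possibly noisy) 0-based labels.
#' @param y_hat Predicted 0-based labels.
#' @return A `batch_outcome` data frame with a derived `correct` column
#'   (`y == y_hat`).
#' @export
batch_outcome <- function(patch_id, loss, y, y_hat) {
  if (any(loss < 0)) stopf("losses must be nonnegative")
  structure(data.frame(patch_id = as.character(patch_id), loss = loss,
                       y = as.integer(y), y_hat = as.integer(y_hat),
                       correct = as.integer(y) == as.integer(y_hat),
                       stringsAsFactors = FALSE),
            class = c("batch_outcome", "data.frame"))
}

#' Record a batch into the tracker
#'
#' Adds each correctly classified sample's loss to its ground-truth class's
#' running sum and count; misclassified samples are not recorded. The
#' iteration counter `k` advances by one per batch.
#'
#' @param tracker A `loss_tracker`.
#' @param outcome A [batch_outcome()].
#' @return The updated tracker.
#' @export
update_tracker <- function(tracker, outcome) {
  stopifnot(inherits(tracker, "loss_tracker"))
  if (any(outcome$loss < 0)) stopf("losses must be nonnegative")
  ok <- outcome$correct
  if (any(ok)) {
    cls <- outcome$y[ok] + 1L
    add <- tapply(outcome$loss[ok], factor(cls, levels = seq_len(tracker$K)), sum)
    add[is.na(add)] <- 0
    tracker$sums <- tracker$sums + as.numeric(add)
    tracker$counts <- tracker$counts +
      tabulate(cls, nbins = tracker$K)
  }
  tracker$k <- tracker$k + 1L
  tracker
}

#' Running average loss for a class
#'
#' Running sum over running count for the class (pooled over classes when
#' the tracker scope is `"global"`). Returns `NA` when no correct instance
#' of the class has been recorded yet — in that case the abstain condition
#' never triggers for the class.
#'
#' @param tracker A `loss_tracker`.
#' @param class 0-based class index.
#' @return Numeric average, or `NA_real_` if no statistics.
#' @export
class_average <- function(tracker, class) {
  stopifnot(inherits(tracker, "loss_tracker"))
  if (tracker$scope == "global") {
    tot <- sum(tracker$counts)
    return(if (tot > 0) sum(tracker$sums) / tot else NA_real_)
  }
  i <- as.integer(class) + 1L
  if (i < 1L || i > tracker$K) stopf("class %d out of range", class)
  if (tracker$counts[i] == 0L) return(NA_real_)
  tracker$sums[i] / tracker$counts[i]
}
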