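#' Training configuration
#'
#' Defaults follow standard practice for patch classifiers: 30 epochs,
#' batch size 32, Adam with learning rate 0.001, cross-entropy loss.
#'
#' @param epochs Number of epochs (default 30).
#' @param batch_size Mini-batch size (default 32).
#' @param learning_rate Optimizer step size (default 0.001).
#' @param seed Seed controlling epoch shuffles (and, via
#'   [train_lossdiff()]'s default backbone, initialization).
#' @return A `train_config` object.
#' @export
train_config <- function(epochs = 30L, batch_size = 32L,
                         learning_rate = 0.001, seed = 1L) {
  if (epochs < 1L || batch_size < 1L || learning_rate <= 0)
    stopf("epochs, batch_size and learning_rate must be positive")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "train_config")
}

#' Train a classifier with loss-based label filtering
#'
#' The label-denoising training loop. Each epoch shuffles the surviving
#' training records and steps through mini-batches; every batch yields
#' per-sample losses and predictions, which (after the warm-up epochs)
#' are screened by the filter policy against the running per-class average
#' loss of correctly classified instances, accumulated over all iterations
#' so far. Filter decisions are applied immediately — discarded records
#' never return; flipped records carry their new label into subsequent
#' epochs and remain re-examinable — and the batch is then recorded into
#' the tracker. Decisions are always evaluated against the tracker state
#' before the batch's own update.
#'
#' @param manifest A `patch_manifest` with non-empty train and val splits.
#' @param images Named list of RGB arrays covering at least the train and
#'   val patch ids.
#' @param classifier A classifier honoring the [classifier-contract], or
#'   `NULL` for the default [random_feature_classifier()] seeded from
#'   `config$seed`.
#' @param policy A [filter_policy()]; use `filter_policy(enabled = FALSE)`
#'   for a plain baseline run.
#' @param config A [train_config()].
#' @param keep_loss_log If `TRUE`, also log every recorded
#'   correct-classification loss (class, loss, epoch, iteration) so the
#'   tracker can be audited against a brute-force mean.
#' @return A `lossdiff_fit` list: `classifier` (trained), `manifest` (the
#'   cleaned dataset: surviving, possibly re-labeled train records plus
#'   untouched val/test), `decisions` (non-keep decision log), `metrics`
#'   (per-epoch data frame: `epoch`, `train_loss`, `val_loss`, `train_acc`,
#'   `val_acc`, `n_train_remaining`, `n_discarded`, `n_flipped`),
#'   `tracker`, and `loss_log` (if requested).
#' @export
train_lossdiff <- function(manifest, images, classifier = NULL,
                           policy = filter_policy(), config = train_config(),
                           keep_loss_log = FALSE) {
  stopifnot(inherits(manifest, "patch_manifest"),
            inherits(policy, "filter_policy"),
            inherits(config, "train_config"))
  K <- length(manifest$classes)
  r <- manifest$records
  if (!any(r$split == "train") || !any(r$split == "val"))
    stopf("train and val splits must be non-empty")
  if (is.null(classifier))
    classifier <- random_feature_classifier(K, learning_rate = config$learning_rate,
                                            seed = derive_seed(config$seed, 77L))
  need <- r$patch_id[r$split %in% c("train", "val")]
  missing_imgs <- setdiff(need, names(images))
  if (length(missing_imgs))
    stopf("images missing for %d patches (first: %s)", length(missing_imgs),
          missing_imgs[1])
  feats <- clf_featurize(classifier, images[need])
  val_ids <- r$patch_id[r$split == "val"]
  val_y <- r$label[match(val_ids, r$patch_id)]

  tracker <- new_loss_tracker(K, policy$tracker_scope)
  cur <- manifest
  logs <- list(); loss_log <- list(); metrics <- vector("list", config$epochs)

  with_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      tr <- cur$records[cur$records$split == "train", , drop = FALSE]
      if (!nrow(tr))
        stopf("all training records were discarded by epoch %d; aborting (alpha too aggressive?)", epoch)
      ids <- sample(tr$patch_id)
      labels <- setNames(tr$label, tr$patch_id)
      nb <- ceiling(length(ids) / config$batch_size)
      ep_loss <- 0; ep_correct <- 0; ep_n <- 0
      n_disc <- 0L; n_flip <- 0L
      for (b in seq_len(nb)) {
        bid <- ids[((b - 1L) * config$batch_size + 1L):min(b * config$batch_size, length(ids))]
        y <- unname(labels[bid])
        step <- clf_train_step(classifier, feats[bid, , drop = FALSE], y)
        classifier <- step$classifier
        outcome <- batch_outcome(bid, step$losses, y, step$pred)
        k_iter <- tracker$k + 1L
        if (policy$enabled && epoch > policy$warmup_epochs) {
          dec <- filter_batch(outcome, tracker, policy, epoch = epoch,
                              iteration = k_iter)
          ad <- apply_decisions(cur, dec, policy$mode)
          cur <- ad$manifest
          if (nrow(ad$log)) {
            logs[[length(logs) + 1L]] <- ad$log
            n_disc <- n_disc + sum(ad$log$action == "discard" & !ad$log$stale)
            n_flip <- n_flip + sum(ad$log$action == "flip" & !ad$log$stale)
          }
        }
        tracker <- update_tracker(tracker, outcome)
        if (keep_loss_log && any(outcome$correct)) {
          ok <- outcome$correct
          loss_log[[length(loss_log) + 1L]] <-
            data.frame(epoch = epoch, iteration = k_iter,
                       class = outcome$y[ok], loss = outcome$loss[ok])
        }
        ep_loss <- ep_loss + sum(step$losses)
        ep_correct <- ep_correct + sum(outcome$correct)
        ep_n <- ep_n + length(bid)
      }
      val_scores <- clf_predict(classifier, feats[val_ids, , drop = FALSE])
      vp <- pmax(val_scores[cbind(seq_along(val_ids), val_y + 1L)], 1e-12)
      metrics[[epoch]] <- data.frame(
        epoch = epoch,
        train_loss = ep_loss / ep_n,
        val_loss = mean(-log(vp)),
        train_acc = 100 * ep_correct / ep_n,
        val_acc = 100 * mean((max.col(val_scores, ties.method = "first") - 1L) == val_y),
        n_train_remaining = sum(cur$records$split == "train"),
        n_discarded = n_disc, n_flipped = n_flip
      )
    }
  })
  decisions <- if (length(logs)) do.call(rbind, logs) else empty_decisions()
  rownames(decisions) <- NULL
  structure(list(classifier = classifier, manifest = cur,
                 decisions = decisions,
                 metrics = do.call(rbind, metrics), tracker = tracker,
                 loss_log = if (keep_loss_log && length(loss_log))
                   do.call(rbind, loss_log) else NULL,
                 policy = policy, config = config),
            class = "lossdiff_fit")
}

#' @export
print.lossdiff_fit <- function(x, ...) {
  m <- x$metrics[nrow(x$metrics), ]
  cat(sprintf("lossdiff_fit: %d epochs, mode=%s alpha=%g %s\n",
              nrow(x$metrics), x$policy$mode, x$policy$alpha,
              if (x$policy$enabled) "" else "(filtering disabled)"))
  cat(sprintf("  final: train_loss=%.4f val_loss=%.4f val_acc=%.1f%%\n",
              m$train_loss, m$val_loss, m$val_acc))
  cat(sprintf("  train remaining: %d; discarded: %d; flipped: %d\n",
              m$n_train_remaining, sum(x$metrics$n_discarded),
              sum(x$metrics$n_flipped)))
  invisible(x)
}

#' Read a YAML run configuration
#'
#' Recognized keys: `alpha`, `mode`, `warmup_epochs`, `require_correct`,
#' `tracker_scope`, `epochs`, `batch_size`, `learning_rate`, `seed`,
#' `patch_size`. Missing keys take the package defaults.
#'
#' @param path YAML file path.
#' @return List with elements `policy` ([filter_policy()]), `config`
#'   ([train_config()]) and `patch_size`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  policy <- filter_policy(
    alpha = y$alpha %||% 1,
    mode = y$mode %||% "discard",
    warmup_epochs = y$warmup_epochs %||% 2L,
    require_correct = y$require_correct,
    tracker_scope = y$tracker_scope %||% "per_class"
  )
  config <- train_config(
    epochs = y$epochs %||% 30L,
    batch_size = y$batch_size %||% 32L,
    learning_rate = y$learning_rate %||% 0.001,
    seed = y$seed %||% 1L
  )
  list(policy = policy, config = config, patch_size = y$patch_size %||% 256L)
}
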