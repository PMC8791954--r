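#' Inject symmetric label noise into the training split
#'
#' Flips the labels of exactly `round(rate * n_train)` training patches,
#' chosen by a seeded permutation, so the stated noise percentage is exact.
#' With two classes a flip goes to the opposite class; with more, the new
#' label is drawn uniformly from the other `K - 1` classes. `clean_label`
#' and `is_noisy` are populated for every training record; validation and
#' test records are untouched.
#'
#' @param manifest A `patch_manifest` with a non-empty train split.
#' @param rate Noise fraction in `[0, 1)`.
#' @param seed Integer seed.
#' @return List with elements `manifest` (labels corrupted) and `mask`
#'   (a `noise_mask`: the flip bookkeeping needed to score recovery).
#' @export
inject_symmetric_noise <- function(manifest, rate, seed = 1L) {
  stopifnot(inherits(manifest, "patch_manifest"))
  if (rate < 0 || rate >= 1) stopf("rate must be in [0, 1)")
  K <- length(manifest$classes)
  if (K < 2L) stopf("need at least 2 classes to inject label noise")
  r <- manifest$records
  tr <- which(r$split == "train")
  n <- length(tr)
  if (!n) stopf("train split is empty")
  n_flip <- round(rate * n)
  if (n_flip >= n && n_flip > 0) stopf("rate %.2f would flip every training patch", rate)
  r$clean_label[tr] <- r$label[tr]
  flips <- empty_flips()
  if (n_flip > 0) {
    sel <- with_seed(seed, {
      idx <- tr[sample(n)[seq_len(n_flip)]]
      from <- r$label[idx]
      to <- if (K == 2L) 1L - from else {
        vapply(from, function(f) sample(setdiff(0:(K - 1L), f), 1L), integer(1))
      }
      list(idx = idx, from = from, to = to)
    })
    r$label[sel$idx] <- sel$to
    flips <- data.frame(patch_id = r$patch_id[sel$idx], from = sel$from,
                        to = sel$to, stringsAsFactors = FALSE)
  }
  r$is_noisy[tr] <- r$clean_label[tr] != r$label[tr]
  mask <- structure(list(rate = rate, seed = as.integer(seed), flips = flips),
                    class = "noise_mask")
  list(manifest = patch_manifest(r, manifest$classes, manifest$provenance),
       mask = mask)
}

empty_flips <- function() {
  data.frame(patch_id = character(0), from = integer(0), to = integer(0),
             stringsAsFactors = FALSE)
}

#' Undo an injected noise mask
#'
#' Restores each flipped record's original label, making injection an
#' involution: `restore_labels(inject(...))` reproduces the input manifest.
#'
#' @param manifest The corrupted `patch_manifest`.
#' @param mask The `noise_mask` returned by [inject_symmetric_noise()].
#' @param drop_bookkeeping If `TRUE` (default) also clears `clean_label` /
#'   `is_noisy` on the train split, recovering the pre-injection manifest
#'   exactly.
#' @return A `patch_manifest`.
#' @export
restore_labels <- function(manifest, mask, drop_bookkeeping = TRUE) {
  stopifnot(inherits(mask, "noise_mask"))
  r <- manifest$records
  if (nrow(mask$flips)) {
    idx <- match(mask$flips$patch_id, r$patch_id)
    if (anyNA(idx)) stopf("mask references unknown patch ids")
    r$label[idx] <- mask$flips$from
  }
  tr <- r$split == "train"
  if (drop_bookkeeping) {
    r$clean_label[tr] <- NA_integer_
    r$is_noisy[tr] <- NA
  } else {
    r$is_noisy[tr] <- r$clean_label[tr] != r$label[tr]
  }
  patch_manifest(r, manifest$classes, manifest$provenance)
}

#' Score how well filtering recovered injected noise
#'
#' Given the set of patch ids a filter acted on (discarded or flipped) and
#' the injection mask, reports precision (fraction of acted patches that
#' were truly noise), recall (fraction of injected noise acted on), and
#' enrichment (precision over the noise prior `|flipped| / n_train`).
#' Undefined quantities (empty acted set, empty mask) are `NA`, never zero.
#'
#' @param acted_ids Character vector of patch ids acted on.
#' @param mask The injection `noise_mask`.
#' @param n_train Number of training patches at injection time.
#' @return Named list `precision`, `recall`, `enrichment`.
#' @export
noise_recovery_metrics <- function(acted_ids, mask, n_train) {
  stopifnot(inherits(mask, "noise_mask"))
  acted <- unique(as.character(acted_ids))
  flipped <- mask$flips$patch_id
  hit <- length(intersect(acted, flipped))
  # an empty acted set leaves every quantity undefined, not zero
  precision <- if (length(acted)) hit / length(acted) else NA_real_
  recall <- if (length(acted) && length(flipped)) hit / length(flipped)
            else NA_real_
  prior <- if (length(flipped)) length(flipped) / n_train else NA_real_
  enrichment <- if (!is.na(precision) && !is.na(prior) && prior > 0)
    precision / prior else NA_real_
  list(precision = precision, recall = recall, enrichment = enrichment)
}

#' Serialize a noise mask to JSON
#'
#' @param mask A `noise_mask`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_noise_mask <- function(mask, path) {
  stopifnot(inherits(mask, "noise_mask"))
  jsonlite::write_json(
    list(rate = mask$rate, seed = mask$seed, flips = mask$flips),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a noise mask from JSON
#'
#' @param path JSON path written by [write_noise_mask()].
#' @return A `noise_mask`.
#' @export
read_noise_mask <- function(path) {
  o <- jsonlite::fromJSON(path)
  flips <- if (length(o$flips)) {
    data.frame(patch_id = as.character(o$flips$patch_id),
               from = as.integer(o$flips$from), to = as.integer(o$flips$to),
               stringsAsFactors = FALSE)
  } else empty_flips()
  structure(list(rate = o$rate, seed = as.integer(o$seed), flips = flips),
            class = "noise_mask")
}
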