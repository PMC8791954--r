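#' Patch manifest: the dataset container
#'
#' A patch manifest holds one row per patch (the unit of classification and
#' of label noise) plus the ordered class vocabulary. It is the container
#' for both the baseline (noisy) training data and the cleaned data the
#' filter produces.
#'
#' Record columns:
#' \describe{
#'   \item{patch_id}{unique character id}
#'   \item{slide_id}{id of the source slide; splits are assigned per slide}
#'   \item{x, y}{0-based pixel offset of the tile's top-left corner}
#'   \item{size}{tile side length in pixels (tiles are square)}
#'   \item{label}{0-based class index into `classes`}
#'   \item{split}{one of `"train"`, `"val"`, `"test"`}
#'   \item{image_ref}{path or archive index locating the pixels}
#'   \item{clean_label}{optional 0-based original label (NA if unknown)}
#'   \item{is_noisy}{TRUE iff `clean_label` is present and differs from
#'     `label`; NA when `clean_label` is unknown}
#' }
#'
#' @param records Data frame with the columns above.
#' @param classes Character vector of class names; `label` indexes into it
#'   (0-based).
#' @param provenance Free-text provenance string.
#' @return An object of class `patch_manifest`.
#' @export
patch_manifest <- function(records, classes, provenance = "") {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  # canonical column types, so manifests compare identical after round trips
  for (col in c("x", "y", "size", "label", "clean_label"))
    if (col %in% names(records)) records[[col]] <- as.integer(records[[col]])
  for (col in c("patch_id", "slide_id", "split", "image_ref"))
    if (col %in% names(records)) records[[col]] <- as.character(records[[col]])
  if ("is_noisy" %in% names(records))
    records$is_noisy <- as.logical(records$is_noisy)
  m <- structure(
    list(records = records, classes = as.character(classes),
         provenance = as.character(provenance)[1]),
    class = "patch_manifest"
  )
  validate_patch_manifest(m)
  m
}

#' Validate patch-manifest invariants
#'
#' Checks id uniqueness, label range, coordinate sanity, the slide-to-split
#' partition (every slide belongs to exactly one split), and consistency of
#' the `is_noisy` flag with `clean_label`.
#'
#' @param m A `patch_manifest`.
#' @return `m`, invisibly.
#' @export
validate_patch_manifest <- function(m) {
  stopifnot(inherits(m, "patch_manifest"))
  r <- m$records
  need <- c("patch_id", "slide_id", "x", "y", "size", "label", "split",
            "image_ref", "clean_label", "is_noisy")
  miss <- setdiff(need, names(r))
  if (length(miss)) stopf("manifest records missing column(s): %s",
                          paste(miss, collapse = ", "))
  if (anyDuplicated(r$patch_id))
    stopf("duplicate patch_id: %s", r$patch_id[duplicated(r$patch_id)][1])
  if (nrow(r)) {
    if (any(r$x < 0 | r$y < 0)) stopf("negative tile coordinates")
    if (any(r$size < 1)) stopf("tile size must be >= 1")
    K <- length(m$classes)
    if (any(r$label < 0 | r$label >= K))
      stopf("label out of range for %d classes", K)
    cl <- r$clean_label[!is.na(r$clean_label)]
    if (length(cl) && any(cl < 0 | cl >= K))
      stopf("clean_label out of range for %d classes", K)
    if (!all(r$split %in% c("train", "val", "test")))
      stopf("split must be one of train/val/test")
    tab <- unique(r[, c("slide_id", "split")])
    if (anyDuplicated(tab$slide_id))
      stopf("slide '%s' appears in more than one split",
            tab$slide_id[duplicated(tab$slide_id)][1])
    known <- !is.na(r$clean_label)
    expect_noisy <- ifelse(known, r$clean_label != r$label, NA)
    # is_noisy is TRUE exactly when a known clean label disagrees with label
    bad <- which(isTRUE_vec(r$is_noisy) != isTRUE_vec(expect_noisy))
    if (length(bad))
      stopf("is_noisy inconsistent with clean_label/label at patch '%s'",
            r$patch_id[bad[1]])
  }
  invisible(m)
}

isTRUE_vec <- function(x) !is.na(x) & x

#' @export
print.patch_manifest <- function(x, ...) {
  r <- x$records
  cat(sprintf("patch_manifest: %d patches, %d slides, %d classes (%s)\n",
              nrow(r), length(unique(r$slide_id)), length(x$classes),
              paste(x$classes, collapse = ", ")))
  if (nrow(r)) {
    sp <- table(factor(r$split, levels = c("train", "val", "test")))
    cat(sprintf("  splits: train=%d val=%d test=%d\n", sp[1], sp[2], sp[3]))
    nn <- sum(isTRUE_vec(r$is_noisy))
    if (nn) cat(sprintf("  flagged noisy: %d\n", nn))
  }
  invisible(x)
}

#' Subset a manifest by split or by patch id
#'
#' @param m A `patch_manifest`.
#' @param split Optional split name(s) to keep.
#' @param ids Optional patch ids to keep.
#' @return A `patch_manifest` containing the selected records.
#' @export
manifest_subset <- function(m, split = NULL, ids = NULL) {
  r <- m$records
  if (!is.null(split)) r <- r[r$split %in% split, , drop = FALSE]
  if (!is.null(ids)) r <- r[r$patch_id %in% ids, , drop = FALSE]
  rownames(r) <- NULL
  patch_manifest(r, m$classes, m$provenance)
}

# Blank record skeleton; used by builders so every manifest carries the
# same column set.
empty_records <- function(n = 0L) {
  data.frame(
    patch_id = character(n), slide_id = character(n),
    x = integer(n), y = integer(n), size = integer(n),
    label = integer(n), split = rep("train", n),
    image_ref = character(n),
    clean_label = rep(NA_integer_, n), is_noisy = rep(NA, n),
    stringsAsFactors = FALSE
  )
}
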