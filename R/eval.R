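#' Classification accuracy in percent
#'
#' @param predictions,truths Equal-length 0-based label vectors.
#' @return `100 * #correct / #total`.
#' @export
accuracy <- function(predictions, truths) {
  if (!length(predictions) || length(predictions) != length(truths))
    stopf("predictions and truths must be equal-length and non-empty")
  100 * mean(as.integer(predictions) == as.integer(truths))
}

#' Confusion matrix (rows = truth, columns = prediction)
#'
#' @param predictions,truths 0-based label vectors in `[0, K)`.
#' @param K Number of classes.
#' @return K x K integer matrix; entry `(i, j)` counts samples of true
#'   class `i - 1` predicted as class `j - 1`.
#' @export
confusion_matrix <- function(predictions, truths, K) {
  p <- as.integer(predictions); t <- as.integer(truths)
  if (length(p) != length(t)) stopf("length mismatch")
  if (any(c(p, t) < 0L | c(p, t) >= K)) stopf("labels must lie in [0, %d)", K)
  m <- table(factor(t, levels = 0:(K - 1L)), factor(p, levels = 0:(K - 1L)))
  matrix(as.integer(m), K, K, dimnames = list(truth = 0:(K - 1L),
                                              pred = 0:(K - 1L)))
}

# Binary AUC by the rank (Mann-Whitney) statistic; ties get average ranks,
# equivalent to trapezoidal integration of the ROC curve.
auc_binary <- function(scores, labels) {
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' One-vs-rest ROC-AUC with per-class, micro and macro averaging
#'
#' Per-class: the AUC of each class's score column against its one-vs-rest
#' labels. Micro: all one-vs-rest label/score pairs pooled across classes
#' before computing a single AUC (the "sum of all true positives" view).
#' Macro: the unweighted mean of the per-class AUCs. A class absent from
#' `truths` has undefined AUC (`NA`); macro skips it with a warning.
#'
#' @param class_scores n x K matrix of class probabilities (rows sum to 1).
#' @param truths 0-based truth labels.
#' @param averaging `"per_class"`, `"micro"`, or `"macro"`.
#' @return Numeric vector (per-class) or single value (micro/macro).
#' @export
roc_auc <- function(class_scores, truths,
                    averaging = c("per_class", "micro", "macro")) {
  averaging <- match.arg(averaging)
  S <- as.matrix(class_scores)
  K <- ncol(S)
  if (K < 2L) stopf("need scores for at least 2 classes")
  t <- as.integer(truths)
  if (length(t) != nrow(S)) stopf("length mismatch")
  onehot <- function(k) as.integer(t == k)
  if (averaging == "micro")
    return(auc_binary(as.vector(S),
                      as.vector(vapply(0:(K - 1L), onehot, integer(length(t))))))
  per <- vapply(0:(K - 1L), function(k) auc_binary(S[, k + 1L], onehot(k)),
                numeric(1))
  names(per) <- colnames(S) %||% paste0("class", 0:(K - 1L))
  if (averaging == "per_class") return(per)
  if (anyNA(per))
    warnf("macro AUC: skipping %d class(es) absent from truths", sum(is.na(per)))
  mean(per, na.rm = TRUE)
}

#' McNemar paired comparison of two classifiers
#'
#' Counts the discordant pairs on the same samples — `b` (A correct, B
#' wrong) and `c` (A wrong, B correct) — and tests symmetry. For
#' `b + c >= 25` the continuity-corrected chi-square statistic
#' `(|b - c| - 1)^2 / (b + c)` is used with a chi-square(1) p-value; for
#' smaller counts the exact two-sided binomial test on `min(b, c)`
#' successes in `b + c` trials at probability one half.
#'
#' @param preds_a,preds_b Predictions of the two classifiers.
#' @param truths Shared truth labels.
#' @param variant `"auto"` (branch on `b + c`), `"continuity"`, or
#'   `"exact"` to force a branch.
#' @return List: `statistic` (NA for the exact branch), `p_value`, `b`,
#'   `c`, `method`, and `degenerate` (`TRUE` when `b + c = 0`).
#' @export
mcnemar_test <- function(preds_a, preds_b, truths,
                         variant = c("auto", "continuity", "exact")) {
  variant <- match.arg(variant)
  if (length(preds_a) != length(truths) || length(preds_b) != length(truths))
    stopf("prediction vectors must match truths in length")
  ca <- as.integer(preds_a) == as.integer(truths)
  cb <- as.integer(preds_b) == as.integer(truths)
  b <- sum(ca & !cb)
  c_ <- sum(!ca & cb)
  n <- b + c_
  if (n == 0L)
    return(list(statistic = 0, p_value = 1.0, b = b, c = c_,
                method = "degenerate", degenerate = TRUE))
  use_cont <- switch(variant, auto = n >= 25L, continuity = TRUE, exact = FALSE)
  if (use_cont) {
    stat <- (abs(b - c_) - 1)^2 / n
    list(statistic = stat,
         p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
         b = b, c = c_, method = "continuity-corrected chi-square",
         degenerate = FALSE)
  } else {
    p <- min(1, 2 * stats::pbinom(min(b, c_), n, 0.5))
    list(statistic = NA_real_, p_value = p, b = b, c = c_,
         method = "exact binomial", degenerate = FALSE)
  }
}

#' Reconstruct a slide-level class grid from patch predictions
#'
#' Places each patch prediction into the cell of a
#' `ceiling(height / patch_size)` x `ceiling(width / patch_size)` grid.
#' Cells with no patch carry the background marker `NA`. Two patches
#' mapping to one cell is an error (duplicate tiling).
#'
#' @param coords Data frame with tile-aligned `x`, `y` columns.
#' @param predictions 0-based predicted class per patch.
#' @param width,height Slide dimensions in pixels.
#' @param patch_size Tile side length.
#' @return Integer matrix (rows = tile rows) of predicted classes, `NA`
#'   for background cells.
#' @export
slide_heatmap <- function(coords, predictions, width, height, patch_size) {
  if (nrow(coords) != length(predictions))
    stopf("one prediction per coordinate required")
  nr <- ceiling(height / patch_size)
  nc <- ceiling(width / patch_size)
  grid <- matrix(NA_integer_, nr, nc)
  if (!nrow(coords)) return(grid)
  if (any(coords$x %% patch_size != 0 | coords$y %% patch_size != 0))
    stopf("coordinates must be tile-aligned to patch_size %d", patch_size)
  ri <- coords$y %/% patch_size + 1L
  ci <- coords$x %/% patch_size + 1L
  if (any(ri > nr | ci > nc)) stopf("coordinate outside slide bounds")
  cell <- (ci - 1L) * nr + ri
  if (anyDuplicated(cell))
    stopf("duplicate tiling: two patches map to cell (%d, %d)",
          ri[duplicated(cell)][1], ci[duplicated(cell)][1])
  grid[cell] <- as.integer(predictions)
  grid
}

#' Render a heatmap grid as an RGB overlay
#'
#' Background cells are white; classes use the conventional benign/lesion
#' palette (green, red, blue, yellow, then recycled rainbow hues).
#'
#' @param grid Class grid from [slide_heatmap()].
#' @param palette Character vector of R colors, one per class.
#' @return Array `nrow(grid)` x `ncol(grid)` x 3 in `[0, 255]` (one pixel
#'   per tile; scale up for display).
#' @export
heatmap_overlay <- function(grid, palette = NULL) {
  K <- max(grid, na.rm = TRUE) + 1L
  if (is.null(palette)) {
    base <- c("green", "red", "blue", "yellow")
    palette <- if (K <= length(base)) base[seq_len(K)]
               else c(base, grDevices::rainbow(K - length(base)))
  }
  rgb <- grDevices::col2rgb(palette)
  out <- array(255, dim = c(nrow(grid), ncol(grid), 3))
  for (k in seq_len(K)) {
    m <- !is.na(grid) & grid == (k - 1L)
    for (ch in 1:3) {
      plane <- out[, , ch]
      plane[m] <- rgb[ch, k]
      out[, , ch] <- plane
    }
  }
  out
}

#' Two-dimensional t-SNE embedding of feature vectors
#'
#' Delegates to scikit-learn's `TSNE` (default parameters, fixed
#' `random_state`) through the system `python`. Perplexity is reduced
#' automatically (with a warning) when the sample count is too small for
#' the default.
#'
#' @param features Numeric matrix, one row per sample (e.g. the penultimate
#'   features from [clf_featurize()]).
#' @param labels Optional per-sample labels, carried into the output.
#' @param seed Integer seed (`random_state`).
#' @param perplexity t-SNE perplexity (default 30, the library default).
#' @param path Optional CSV path; when given, coordinates and labels are
#'   written alongside for plotting.
#' @return Data frame with columns `x`, `y` (and `label` when provided),
#'   one row per input row.
#' @export
tsne_export <- function(features, labels = NULL, seed = 1L, perplexity = 30,
                        path = NULL) {
  X <- as.matrix(features)
  n <- nrow(X)
  if (n < 5L) stopf("t-SNE needs at least 5 samples, got %d", n)
  if (perplexity >= n / 3) {
    perplexity <- max(2, floor((n - 1) / 3))
    warnf("perplexity reduced to %g for n = %d samples", perplexity, n)
  }
  py <- Sys.which("python")
  if (!nzchar(py)) py <- Sys.which("python3")
  if (!nzchar(py)) stopf("no python interpreter found for t-SNE")
  tmp_in <- tempfile(fileext = ".csv"); tmp_out <- tempfile(fileext = ".csv")
  on.exit(unlink(c(tmp_in, tmp_out)))
  utils::write.table(X, tmp_in, sep = ",", row.names = FALSE, col.names = FALSE)
  code <- sprintf(paste0(
    "import numpy as np\n",
    "from sklearn.manifold import TSNE\n",
    "X = np.loadtxt(%s, delimiter=',', ndmin=2)\n",
    "emb = TSNE(n_components=2, perplexity=%g, random_state=%d).fit_transform(X)\n",
    "np.savetxt(%s, emb, delimiter=',')\n"),
    deparse(tmp_in), perplexity, as.integer(seed), deparse(tmp_out))
  res <- system2(py, "-", input = code, stdout = TRUE, stderr = TRUE)
  if (!file.exists(tmp_out))
    stopf("t-SNE failed: %s", paste(res, collapse = " "))
  emb <- utils::read.table(tmp_out, sep = ",")
  out <- data.frame(x = emb[[1]], y = emb[[2]])
  if (!is.null(labels)) out$label <- labels
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}

#' Full evaluation report for one model on one split
#'
#' @param class_scores n x K probability matrix.
#' @param truths 0-based truth labels.
#' @param classes Class names (length K).
#' @return An `eval_report` list: `accuracy` (percent), `per_class`
#'   (precision/recall data frame), `confusion`, `auc_per_class`,
#'   `auc_micro`, `auc_macro`.
#' @export
eval_report <- function(class_scores, truths, classes) {
  S <- as.matrix(class_scores)
  K <- length(classes)
  pred <- max.col(S, ties.method = "first") - 1L
  cm <- confusion_matrix(pred, truths, K)
  per <- data.frame(
    class = classes,
    precision = vapply(seq_len(K), function(j) {
      s <- sum(cm[, j]); if (s) cm[j, j] / s else NA_real_
    }, numeric(1)),
    recall = vapply(seq_len(K), function(i) {
      s <- sum(cm[i, ]); if (s) cm[i, i] / s else NA_real_
    }, numeric(1))
  )
  structure(list(
    accuracy = accuracy(pred, truths),
    per_class = per,
    confusion = cm,
    auc_per_class = roc_auc(S, truths, "per_class"),
    auc_micro = roc_auc(S, truths, "micro"),
    auc_macro = suppressWarnings(roc_auc(S, truths, "macro"))
  ), class = "eval_report")
}

#' Write an evaluation report as JSON (confusion also as TSV)
#'
#' @param report An [eval_report()].
#' @param path JSON output path; the confusion matrix is additionally
#'   written next to it with suffix `.confusion.tsv`.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  o <- unclass(report)
  o$confusion <- unname(apply(report$confusion, 1, as.integer, simplify = FALSE))
  jsonlite::write_json(o, path, auto_unbox = TRUE, digits = NA, na = "null",
                       dataframe = "columns")
  utils::write.table(report$confusion,
                     sub("\\.json$", "", path) |> paste0(".confusion.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}
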