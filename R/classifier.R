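#' Classifier contract
#'
#' The training loop is agnostic to the backbone: any object implementing
#' these generics can be plugged in.
#'
#' * `clf_featurize(clf, images)` — map a named list of RGB arrays to the
#'   penultimate feature matrix (one row per image, rownames = ids). The
#'   feature representation is what [tsne_export()] visualizes.
#' * `clf_train_step(clf, x, y)` — one optimization step on a batch.
#'   `x` is a feature matrix (or list of images, featurized on the fly),
#'   `y` a 0-based label vector. Returns `list(classifier, losses, pred,
#'   scores)` where `losses` are the per-sample cross-entropy losses of the
#'   pre-update model and `scores` rows sum to 1.
#' * `clf_predict(clf, x)` — class-probability matrix, rows summing to 1.
#'
#' @param clf A classifier object.
#' @param images Named list of H x W x 3 arrays.
#' @param x Feature matrix (rows = samples) or list of images.
#' @param y Integer vector of 0-based labels.
#' @name classifier-contract
NULL

#' @rdname classifier-contract
#' @export
clf_featurize <- function(clf, images) UseMethod("clf_featurize")

#' @rdname classifier-contract
#' @export
clf_train_step <- function(clf, x, y) UseMethod("clf_train_step")

#' @rdname classifier-contract
#' @export
clf_predict <- function(clf, x) UseMethod("clf_predict")

#' Random-feature reference classifier
#'
#' The package's CPU-trainable reference backbone. Images are block-pooled
#' to `pool` x `pool` pixels and mapped to a two-channel feature vector:
#'
#' * a *linear channel* — the pooled pixels themselves, scaled by
#'   `feature_scale[1]`. Coherent class-level gradients accumulate over
#'   the whole training set, so the softmax head fits the class structure
#'   quickly and confidently (low loss on cleanly labeled data within the
#'   first couple of epochs);
#' * a *high-frequency random Fourier channel* —
#'   `feature_scale[2] * cos(x %*% Omega + phase)` with frequency entries
#'   drawn at standard deviation `bandwidth`, under which distinct patches
#'   are nearly orthogonal. This channel supplies per-sample capacity: it
#'   lets the head fit individual mislabeled samples, but only gradually,
#'   because those gradients are incoherent and the channel's small scale
#'   bounds the per-visit logit movement under Adam.
#'
#' Together the channels reproduce the label-noise loss dynamics of deep
#' backbones at desk scale: the class signal is learned first, mislabeled
#' samples are memorized slowly afterwards — each passing through the
#' correctly-classified, high-loss window that loss-based filtering
#' screens for.
#'
#' @param K Number of classes.
#' @param pool Pooled image side length (default 16).
#' @param hidden Width of the random Fourier channel (default 4096); total
#'   feature width is `3 * pool^2 + hidden`.
#' @param bandwidth Standard deviation of the random frequency entries
#'   (default 8, in pooled-pixel units: several times the inverse of the
#'   typical within-class distance, so that even near-duplicate patches
#'   decorrelate and memorizing one sample barely moves its neighbours).
#' @param feature_scale Length-2 amplitudes `(linear, fourier)`, default
#'   `c(2, 1)`; the first sets how fast the class structure is fit, the
#'   second the memorization pace.
#' @param learning_rate Adam step size (default 0.001).
#' @param seed Seed for the random projection.
#' @return An object of class `random_feature_classifier`.
#' @export
random_feature_classifier <- function(K, pool = 16L, hidden = 4096L,
                                      bandwidth = 8,
                                      feature_scale = c(2, 1),
                                      learning_rate = 0.001, seed = 1L) {
  d_in <- 3L * pool * pool
  d_tot <- d_in + hidden
  init <- with_seed(seed, list(
    A = matrix(stats::rnorm(d_in * hidden, sd = bandwidth), d_in, hidden),
    b0 = stats::runif(hidden, 0, 2 * pi)
  ))
  structure(list(
    K = as.integer(K), pool = as.integer(pool), hidden = as.integer(hidden),
    d_tot = as.integer(d_tot), bandwidth = bandwidth,
    feature_scale = rep_len(feature_scale, 2L),
    lr = learning_rate, seed = as.integer(seed),
    A = init$A, b0 = init$b0,
    W = matrix(0, d_tot, K), bW = numeric(K),
    mW = matrix(0, d_tot, K), vW = matrix(0, d_tot, K),
    mb = numeric(K), vb = numeric(K), t = 0L,
    beta1 = 0.9, beta2 = 0.999, eps = 1e-8
  ), class = c("random_feature_classifier", "lossdiff_classifier"))
}

# Block-average an image down to pool x pool per channel and flatten,
# centered to roughly [-0.5, 0.5].
pool_image <- function(img, pool) {
  h <- dim(img)[1]; w <- dim(img)[2]
  gy <- ceiling(seq_len(h) / h * pool)
  gx <- ceiling(seq_len(w) / w * pool)
  out <- numeric(3L * pool * pool)
  k <- 1L
  for (ch in 1:3) {
    a <- rowsum(img[, , ch], gy, reorder = TRUE)
    a <- t(rowsum(t(a), gx, reorder = TRUE))
    cnt <- tabulate(gy, pool) %o% tabulate(gx, pool)
    out[k:(k + pool * pool - 1L)] <- as.vector(a / cnt)
    k <- k + pool * pool
  }
  out / 255 - 0.5
}

#' @export
clf_featurize.random_feature_classifier <- function(clf, images) {
  X <- t(vapply(images, pool_image, numeric(3L * clf$pool^2), pool = clf$pool))
  H <- cbind(clf$feature_scale[1] * X,
             clf$feature_scale[2] * cos(sweep(X %*% clf$A, 2, clf$b0, "+")))
  rownames(H) <- names(images)
  attr(H, "lossdiff_features") <- TRUE
  H
}

as_features <- function(clf, x) {
  if (is.matrix(x) && ncol(x) == clf$d_tot) return(x)
  if (is.list(x)) return(clf_featurize(clf, x))
  stopf("x must be a feature matrix from clf_featurize() or a list of images")
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

#' @export
clf_predict.random_feature_classifier <- function(clf, x) {
  H <- as_features(clf, x)
  S <- softmax_rows(sweep(H %*% clf$W, 2, clf$bW, "+"))
  rownames(S) <- rownames(H)
  S
}

#' @export
clf_train_step.random_feature_classifier <- function(clf, x, y) {
  H <- as_features(clf, x)
  n <- nrow(H)
  if (length(y) != n) stopf("batch size mismatch: %d features, %d labels", n, length(y))
  if (any(y < 0L | y >= clf$K)) stopf("label out of range [0, %d)", clf$K)
  S <- softmax_rows(sweep(H %*% clf$W, 2, clf$bW, "+"))
  p_true <- pmax(S[cbind(seq_len(n), y + 1L)], 1e-12)
  losses <- -log(p_true)
  pred <- max.col(S, ties.method = "first") - 1L
  Yh <- matrix(0, n, clf$K)
  Yh[cbind(seq_len(n), y + 1L)] <- 1
  G <- (S - Yh) / n
  dW <- crossprod(H, G)
  db <- colSums(G)
  clf$t <- clf$t + 1L
  b1 <- clf$beta1; b2 <- clf$beta2
  clf$mW <- b1 * clf$mW + (1 - b1) * dW
  clf$vW <- b2 * clf$vW + (1 - b2) * dW^2
  clf$mb <- b1 * clf$mb + (1 - b1) * db
  clf$vb <- b2 * clf$vb + (1 - b2) * db^2
  corr1 <- 1 - b1^clf$t
  corr2 <- 1 - b2^clf$t
  clf$W <- clf$W - clf$lr * (clf$mW / corr1) / (sqrt(clf$vW / corr2) + clf$eps)
  clf$bW <- clf$bW - clf$lr * (clf$mb / corr1) / (sqrt(clf$vb / corr2) + clf$eps)
  list(classifier = clf, losses = unname(losses), pred = pred, scores = S)
}
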