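test_that("accuracy is the percentage of exact label matches", {
  expect_equal(accuracy(c(rep(0, 95), rep(1, 5)), rep(0, 100)), 95)
  expect_equal(accuracy(0:4, 0:4), 100)
  expect_equal(accuracy(c(0, 1, 1), c(0, 0, 1)), 200 / 3)
  expect_error(accuracy(integer(0), integer(0)), "non-empty")
})

test_that("confusion matrices count truth rows against prediction columns", {
  cm <- confusion_matrix(c(0, 1, 2), c(0, 1, 2), 3)
  expect_equal(diag(cm), c(`0` = 1L, `1` = 1L, `2` = 1L), ignore_attr = TRUE)
  expect_equal(sum(cm), 3L)

  pred <- c(0, 0, 1, 2, 2, 1); truth <- c(0, 1, 1, 2, 0, 2)
  cm <- confusion_matrix(pred, truth, 3)
  # brute-force tally
  for (i in 0:2) for (j in 0:2)
    expect_equal(cm[i + 1, j + 1], sum(truth == i & pred == j))
  expect_equal(sum(cm), length(pred))
  expect_error(confusion_matrix(c(0, 3), c(0, 1), 3), "lie in")
})

test_that("ROC-AUC handles perfect, chance and hand-enumerable rankings", {
  mk2 <- function(s1) cbind(1 - s1, s1)
  truths <- c(1, 1, 0, 0)
  expect_equal(unname(roc_auc(mk2(c(0.9, 0.8, 0.3, 0.2)), truths)[2]), 1.0)
  # swap one positive/negative pair of scores: 3 of 4 pairs ordered
  expect_equal(unname(roc_auc(mk2(c(0.9, 0.3, 0.8, 0.2)), truths)[2]), 0.75)
  # identical scores: chance
  expect_equal(unname(roc_auc(mk2(rep(0.5, 4)), truths)[2]), 0.5)
  # binary micro-AUC equals the single-class AUC
  s <- mk2(c(0.7, 0.4, 0.6, 0.1))
  expect_equal(roc_auc(s, truths, "micro"),
               unname(roc_auc(s, truths, "per_class")[2]))
  # absent class: NA per class, macro warns and skips
  s3 <- cbind(c(0.6, 0.3), c(0.3, 0.6), c(0.1, 0.1))
  expect_true(is.na(roc_auc(s3, c(0, 1), "per_class")[3]))
  expect_warning(m <- roc_auc(s3, c(0, 1), "macro"), "absent")
  expect_equal(m, 1.0)
})

test_that("metrics agree with independent reference implementations", {
  skip_if_not_installed("pROC")
  set.seed(1234)
  for (rep in 1:25) {
    K <- sample(2:4, 1)
    n <- 40
    truths <- sample(0:(K - 1), n, replace = TRUE)
    raw <- matrix(stats::rexp(n * K), n, K)
    scores <- raw / rowSums(raw)
    pred <- max.col(scores, ties.method = "first") - 1L
    expect_equal(accuracy(pred, truths), 100 * mean(pred == truths),
                 tolerance = 1e-12)
    for (k in 0:(K - 1)) {
      if (length(unique(truths == k)) < 2) next
      ref <- suppressMessages(pROC::auc(pROC::roc(
        response = as.integer(truths == k), predictor = scores[, k + 1],
        direction = "<", quiet = TRUE)))
      expect_equal(unname(roc_auc(scores, truths, "per_class")[k + 1]),
                   as.numeric(ref), tolerance = 1e-9)
    }
  }
})

test_that("McNemar branches match closed forms and reference tests", {
  # continuity-corrected closed form: (|15-5|-1)^2 / 20
  m <- mcnemar_test(c(rep(0, 15), rep(1, 5)), c(rep(1, 15), rep(0, 5)),
                    truths = rep(0, 20), variant = "continuity")
  expect_equal(m$b, 15); expect_equal(m$c, 5)
  expect_equal(m$statistic, 4.05)
  ref <- stats::mcnemar.test(matrix(c(0, 15, 5, 0), 2), correct = TRUE)
  expect_equal(m$p_value, ref$p.value, tolerance = 1e-12)

  # exact branch against binom.test; b = c gives p = 1
  set.seed(2)
  truths <- sample(0:1, 30, TRUE)
  pa <- sample(0:1, 30, TRUE); pb <- sample(0:1, 30, TRUE)
  e <- mcnemar_test(pa, pb, truths, variant = "exact")
  if (e$b + e$c > 0) {
    ref <- stats::binom.test(min(e$b, e$c), e$b + e$c, 0.5)
    expect_equal(e$p_value, ref$p.value, tolerance = 1e-9)
  }
  sym <- mcnemar_test(c(0, 1, 0, 1), c(1, 0, 1, 0), c(0, 0, 1, 1))
  expect_equal(sym$b, sym$c)
  expect_equal(sym$p_value, 1.0)

  # swapping the classifiers leaves the test invariant
  a <- mcnemar_test(pa, pb, truths)
  b <- mcnemar_test(pb, pa, truths)
  expect_equal(a$p_value, b$p_value)
  expect_equal(a$statistic, b$statistic)

  d <- mcnemar_test(c(0, 1), c(0, 1), c(0, 1))
  expect_true(d$degenerate)
  expect_equal(d$p_value, 1.0)
  expect_equal(d$statistic, 0)
})

test_that("slide heatmaps place predictions on the tile grid", {
  g <- slide_heatmap(data.frame(x = c(0, 256), y = c(0, 0)),
                     predictions = c(1L, 0L),
                     width = 512, height = 256, patch_size = 256)
  expect_equal(dim(g), c(1L, 2L))
  expect_equal(g[1, ], c(1L, 0L))

  empty <- slide_heatmap(data.frame(x = numeric(0), y = numeric(0)),
                         integer(0), 512, 512, 256)
  expect_true(all(is.na(empty)))
  expect_equal(dim(empty), c(2L, 2L))

  expect_error(slide_heatmap(data.frame(x = c(0, 0), y = c(0, 0)), c(1L, 2L),
                             512, 512, 256), "duplicate tiling")
  expect_error(slide_heatmap(data.frame(x = 13, y = 0), 1L, 512, 512, 256),
               "tile-aligned")

  ov <- heatmap_overlay(g)
  expect_equal(dim(ov), c(1L, 2L, 3L))
  expect_equal(ov[1, 1, ], unname(grDevices::col2rgb("red")[, 1]))
  expect_equal(ov[1, 2, ], unname(grDevices::col2rgb("green")[, 1]))
})

test_that("heatmaps reconstruct the synthetic ground-truth region map", {
  recs <- make_recipes(2, 0, seed = 4)
  layout <- slide_layout(192, 128, list(
    list(label = 0L, polygon = rect_poly(0, 0, 192, 128)),
    list(label = 1L, polygon = rect_poly(64, 32, 128, 96))),
    annotation_dilation = 0)
  slide <- generate_synthetic_slide(layout, recs, seed = 2)
  size <- 32
  res <- annotation_noise_rate(slide, size)
  g <- slide_heatmap(res$tiles[, c("x", "y")], res$tiles$truth,
                     192, 128, size)
  # each tissue cell equals the region map's class at the tile center
  for (i in seq_len(nrow(res$tiles))) {
    cx <- res$tiles$x[i] + size / 2; cy <- res$tiles$y[i] + size / 2
    expect_equal(g[cy %/% size + 1, cx %/% size + 1],
                 slide$region_map[cy, cx])
  }
})

test_that("t-SNE export is deterministic and separates distinct clouds", {
  set.seed(7)
  X <- rbind(matrix(stats::rnorm(40 * 4, 0), ncol = 4),
             matrix(stats::rnorm(40 * 4, 8), ncol = 4))
  lab <- rep(0:1, each = 40)
  e1 <- suppressWarnings(tsne_export(X, labels = lab, seed = 5))
  e2 <- suppressWarnings(tsne_export(X, labels = lab, seed = 5))
  expect_equal(nrow(e1), 80)
  expect_equal(e1$x, e2$x, tolerance = 1e-8)
  within_ <- mean(dist(e1[lab == 0, c("x", "y")]))
  between <- mean(as.matrix(dist(e1[, c("x", "y")]))[lab == 0, lab == 1])
  expect_gt(between, within_)

  expect_warning(tsne_export(X[1:8, ], seed = 1), "perplexity reduced")
  expect_error(tsne_export(X[1:3, ], seed = 1), "at least 5")
})

test_that("evaluation reports tie the pieces together coherently", {
  set.seed(11)
  truths <- sample(0:2, 60, TRUE)
  raw <- matrix(stats::rexp(180), 60, 3)
  scores <- raw / rowSums(raw)
  rep_ <- eval_report(scores, truths, classes = c("benign", "mal", "dys"))
  expect_equal(rep_$accuracy, 100 * sum(diag(rep_$confusion)) / sum(rep_$confusion),
               tolerance = 1e-12)
  expect_equal(sum(rep_$confusion), 60L)
  expect_equal(rep_$auc_macro, mean(rep_$auc_per_class), tolerance = 1e-12)
  path <- withr::local_tempfile(fileext = ".json")
  write_eval_report(rep_, path)
  o <- jsonlite::fromJSON(path)
  expect_equal(o$accuracy, rep_$accuracy)
  expect_true(file.exists(paste0(sub("\\.json$", "", path), ".confusion.tsv")))
})
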