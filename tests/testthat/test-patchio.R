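test_that("tiling enumerates full tiles in row-major order", {
  g <- tile_image(width = 512, height = 512, patch_size = 256)
  expect_equal(g$x, c(0L, 256L, 0L, 256L))
  expect_equal(g$y, c(0L, 0L, 256L, 256L))

  g <- tile_image(width = 300, height = 256, patch_size = 256)
  expect_equal(nrow(g), 1L)
  expect_equal(c(g$x, g$y), c(0L, 0L))

  g <- tile_image(width = 512, height = 512, patch_size = 256, stride = 128)
  expect_equal(nrow(g), 9L)  # floor((512-256)/128)+1 = 3 per axis

  expect_error(tile_image(width = 100, height = 100, patch_size = 256),
               "smaller than patch_size")
})

test_that("non-overlapping tiling covers floor(W/s)*floor(H/s) disjoint in-bounds tiles", {
  for (dims in list(c(130, 97), c(64, 64), c(50, 33))) {
    s <- 16L
    g <- tile_image(width = dims[1], height = dims[2], patch_size = s)
    expect_equal(nrow(g), (dims[1] %/% s) * (dims[2] %/% s))
    expect_true(all(g$x + s <= dims[1] & g$y + s <= dims[2]))
    expect_false(anyDuplicated(paste(g$x, g$y)) > 0)
    # disjoint: origins differ by multiples of the size
    expect_true(all(g$x %% s == 0 & g$y %% s == 0))
  }
})

test_that("tissue filter drops background-dominated tiles", {
  expect_false(tissue_filter(solid_image(8, 8, c(255, 255, 255))))
  expect_true(tissue_filter(solid_image(8, 8, c(0, 0, 0))))

  # exactly 80% background at threshold 0.7: reject
  img <- solid_image(10, 10, c(255, 255, 255))
  img[1:2, , ] <- 50          # 20 tissue pixels of 100
  expect_false(tissue_filter(img, max_bg_fraction = 0.7))
  expect_true(tissue_filter(img, max_bg_fraction = 0.8))

  # background requires all three channels at/above the threshold
  pink <- solid_image(4, 4, c(255, 100, 255))
  expect_true(tissue_filter(pink))

  expect_error(tissue_filter(matrix(1, 4, 4)), "RGB")
})

test_that("tile labels follow maximal polygon overlap with benign fallback", {
  region <- function(poly, label) annotation_region("s1", poly, label)
  inside <- region(rect_poly(-10, -10, 100, 100), 1L)
  expect_equal(assign_label(0, 0, 16, list(inside)), 1L)

  # 40% overlap below a 0.5 threshold falls back to benign
  part <- region(rect_poly(0, 0, 4, 10), 2L)
  expect_equal(assign_label(0, 0, 10, list(part), overlap_min = 0.5), 0L)
  expect_equal(assign_label(0, 0, 10, list(part), overlap_min = 0.4), 2L)

  # no annotations at all: benign by convention
  expect_equal(assign_label(0, 0, 16, list()), 0L)

  # two classes above threshold: max overlap wins, warning emitted
  big <- region(rect_poly(0, 0, 10, 10), 2L)
  small <- region(rect_poly(0, 0, 6, 10), 1L)
  expect_warning(lab <- assign_label(0, 0, 10, list(big, small),
                                     overlap_min = 0.5), "overlap")
  expect_equal(lab, 2L)

  # exact tie broken toward the earlier class index (tie is warned about)
  a <- region(rect_poly(0, 0, 5, 10), 3L)
  b <- region(rect_poly(5, 0, 10, 10), 1L)
  expect_warning(tie <- assign_label(0, 0, 10, list(a, b), overlap_min = 0.5),
                 "overlap")
  expect_equal(tie, 1L)

  # center mode
  ctr <- region(rect_poly(4, 4, 12, 12), 1L)
  expect_equal(assign_label(0, 0, 16, list(ctr), mode = "center"), 1L)
  expect_equal(assign_label(8, 8, 16, list(ctr), mode = "center"), 0L)
})

test_that("slide-level splitting partitions slides 8/1/1 and is deterministic", {
  m <- tiny_manifest(n_slides = 10, per_slide = 5)
  s1 <- split_by_slide(m, c(0.8, 0.1, 0.1), seed = 7)
  tab <- unique(s1$records[, c("slide_id", "split")])
  expect_equal(sum(tab$split == "train"), 8L)
  expect_equal(sum(tab$split == "val"), 1L)
  expect_equal(sum(tab$split == "test"), 1L)
  # no slide in two splits, union preserved
  expect_false(anyDuplicated(tab$slide_id) > 0)
  expect_setequal(s1$records$patch_id, m$records$patch_id)

  s2 <- split_by_slide(m, c(0.8, 0.1, 0.1), seed = 7)
  expect_identical(s1$records$split, s2$records$split)
  s3 <- split_by_slide(m, c(0.8, 0.1, 0.1), seed = 8)
  expect_false(identical(s1$records$split, s3$records$split))

  expect_error(split_by_slide(tiny_manifest(n_slides = 2), c(0.8, 0.1, 0.1)),
               "at least 3 slides")
  expect_error(split_by_slide(m, c(0.99, 0.005, 0.005)), "empty")
  expect_error(split_by_slide(m, c(0.5, 0.2, 0.2)), "sum to 1")
})

test_that("class balancing downsamples to the minimum class count", {
  m <- tiny_manifest(n_slides = 2, per_slide = 7, K = 2)
  r <- m$records
  r$label <- c(rep(0L, 10), rep(1L, 4))
  m <- patch_manifest(r, m$classes)
  b <- balance_classes(m, seed = 1)
  expect_equal(unname(tabulate(b$records$label + 1L, 2)), c(4L, 4L))
  expect_true(all(b$records$patch_id %in% m$records$patch_id))

  # already balanced: identical id multiset
  b2 <- balance_classes(b, seed = 99)
  expect_setequal(b2$records$patch_id, b$records$patch_id)

  # three classes, reproducible selection
  m3 <- tiny_manifest(n_slides = 3, per_slide = 5, K = 3)
  r <- m3$records
  r$label <- rep(c(0L, 1L, 2L), times = c(7, 5, 3))
  m3 <- patch_manifest(r, m3$classes)
  b3a <- balance_classes(m3, seed = 5)
  b3b <- balance_classes(m3, seed = 5)
  expect_equal(nrow(b3a$records), 9L)
  expect_equal(unname(tabulate(b3a$records$label + 1L, 3)), c(3L, 3L, 3L))
  expect_setequal(b3a$records$patch_id, b3b$records$patch_id)

  r$label <- rep(c(0L, 2L), times = c(10, 5))
  expect_error(balance_classes(patch_manifest(r, m3$classes)), "class1")
})

test_that("manifest TSV round-trips exactly and rejects malformed files", {
  m <- tiny_manifest(n_slides = 4, per_slide = 3, K = 3)
  r <- m$records
  r$split <- rep(c("train", "val", "test", "train"), each = 3)
  r$clean_label[1] <- 1L
  r$label[1] <- 2L
  r$is_noisy[1] <- TRUE
  m <- patch_manifest(r, m$classes, provenance = "unit fixture")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_manifest(m, path)
  m2 <- read_manifest(path)
  expect_identical(m2$records, m$records)
  expect_identical(m2$classes, m$classes)
  expect_identical(m2$provenance, m$provenance)

  # missing label column
  lines <- readLines(path)
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(gsub("\tlabel\t", "\tlabelz\t", lines), bad)
  expect_error(read_manifest(bad), "missing column")

  # unknown class name, with line number (line 4 = first record row)
  lines2 <- lines
  lines2[4] <- sub("class2", "classX", lines2[4])
  writeLines(lines2, bad)
  expect_error(read_manifest(bad), "line 4.*unknown label")

  # duplicated id
  lines3 <- c(lines, lines[4])
  writeLines(lines3, bad)
  expect_error(read_manifest(bad), "duplicate patch_id")

  # is_noisy inconsistent with labels
  r_bad <- m$records
  r_bad$is_noisy[2] <- TRUE
  expect_error(patch_manifest(r_bad, m$classes), "is_noisy inconsistent")
})

test_that("HDF5 patch archives load with labels and pixels intact", {
  tmp <- withr::local_tempdir()
  h5 <- file.path(tmp, "toy_split.h5")
  status <- system2("python", c("-", shQuote(h5)), input = paste(
    "import sys, numpy as np, h5py",
    "rng = np.random.default_rng(0)",
    "x = rng.integers(0, 256, size=(8, 6, 6, 3), dtype=np.uint8)",
    "y = np.array([0,1,0,1,1,0,0,1], dtype=np.int64)",
    "with h5py.File(sys.argv[1], 'w') as f:",
    "    f['x'] = x; f['y'] = y",
    "np.savetxt(sys.argv[1] + '.first.csv', x[0].reshape(-1, 3), fmt='%d')",
    sep = "\n"))
  expect_equal(status, 0L)

  arch <- read_patch_archive(h5)
  expect_equal(nrow(arch$manifest$records), 8L)
  expect_equal(arch$manifest$records$label, c(0L, 1L, 0L, 1L, 1L, 0L, 0L, 1L))
  expect_equal(length(arch$images), 8L)
  expect_equal(dim(arch$images[[1]]), c(6L, 6L, 3L))
  # pixel values survive the trip (compare against numpy's own dump)
  ref <- as.matrix(utils::read.table(paste0(h5, ".first.csv")))
  img1 <- arch$images[[1]]
  flat <- cbind(as.vector(t(img1[, , 1])), as.vector(t(img1[, , 2])),
                as.vector(t(img1[, , 3])))
  expect_equal(unname(flat), unname(ref))

  # labels outside the binary vocabulary
  h5bad <- file.path(tmp, "bad.h5")
  system2("python", c("-", shQuote(h5bad)), input = paste(
    "import sys, numpy as np, h5py",
    "with h5py.File(sys.argv[1], 'w') as f:",
    "    f['x'] = np.zeros((3, 4, 4, 3), dtype=np.uint8)",
    "    f['y'] = np.array([0, 1, 2])",
    sep = "\n"))
  expect_error(read_patch_archive(h5bad), "labels outside")

  # image/label count mismatch
  h5mis <- file.path(tmp, "mis.h5")
  system2("python", c("-", shQuote(h5mis)), input = paste(
    "import sys, numpy as np, h5py",
    "with h5py.File(sys.argv[1], 'w') as f:",
    "    f['x'] = np.zeros((3, 4, 4, 3), dtype=np.uint8)",
    "    f['y'] = np.array([0, 1])",
    sep = "\n"))
  expect_error(read_patch_archive(h5mis), "mismatch")
})

test_that("images survive a PNG write/read round trip", {
  img <- solid_image(8, 10, c(10, 200, 30))
  img[1, 1, ] <- c(255, 0, 5)
  path <- withr::local_tempfile(fileext = ".png")
  write_image(img, path)
  back <- read_image(path)
  expect_equal(back, img, tolerance = 1e-8, ignore_attr = TRUE)
})
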