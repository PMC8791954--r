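#' Read an HDF5 patch archive (PatchCamelyon layout)
#'
#' The archive must hold an `N x H x W x 3` uint8 image array under key
#' `"x"` and a length-`N` label vector under key `"y"` (the layout of the
#' public lymph-node patch benchmark: 96 x 96 RGB patches with binary
#' positive/negative labels). Reading is delegated to the system `python`
#' with `h5py`, which streams the arrays through a temporary binary dump.
#'
#' @param path HDF5 file path.
#' @param classes Class vocabulary the labels index into (default
#'   `c("negative", "positive")`).
#' @param split Split to assign to every record (default `"train"`; archive
#'   files are per-split, one synthetic slide id per file).
#' @return List with elements `manifest` (a `patch_manifest`) and `images`
#'   (named list of H x W x 3 arrays keyed by patch id).
#' @export
read_patch_archive <- function(path, classes = c("negative", "positive"),
                               split = "train") {
  if (!file.exists(path)) stopf("archive not found: %s", path)
  py <- Sys.which("python")
  if (!nzchar(py)) py <- Sys.which("python3")
  if (!nzchar(py)) stopf("no python interpreter found for HDF5 reading")
  tmp <- tempfile("pcam")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE))
  script <- file.path(tmp, "dump.py")
  writeLines(c(
    "import sys, json",
    "import numpy as np",
    "import h5py",
    "path, out = sys.argv[1], sys.argv[2]",
    "with h5py.File(path, 'r') as f:",
    "    if 'x' not in f or 'y' not in f:",
    "        sys.exit('archive must contain keys x and y')",
    "    x = np.asarray(f['x'])",
    "    y = np.asarray(f['y']).reshape(-1)",
    "if x.ndim != 4 or x.shape[3] != 3:",
    "    sys.exit('x must be N x H x W x 3, got %r' % (x.shape,))",
    "if x.shape[0] != y.shape[0]:",
    "    sys.exit('shape mismatch: %d images vs %d labels' % (x.shape[0], y.shape[0]))",
    "x.astype(np.uint8).tofile(out + '/x.bin')",
    "np.savetxt(out + '/y.csv', y.astype(int), fmt='%d')",
    "json.dump({'n': int(x.shape[0]), 'h': int(x.shape[1]), 'w': int(x.shape[2])},",
    "          open(out + '/dims.json', 'w'))"
  ), script)
  res <- suppressWarnings(system2(py, c(script, shQuote(path), shQuote(tmp)),
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(res, "status") %||% 0L
  if (status != 0L)
    stopf("archive read failed: %s", paste(res, collapse = " "))
  dims <- jsonlite::fromJSON(file.path(tmp, "dims.json"))
  y <- as.integer(readLines(file.path(tmp, "y.csv")))
  K <- length(classes)
  if (any(y < 0L | y >= K))
    stopf("labels outside [0, %d) for vocabulary (%s)", K,
          paste(classes, collapse = ", "))
  n <- dims$n; h <- dims$h; w <- dims$w
  raw <- readBin(file.path(tmp, "x.bin"), what = "integer", n = n * h * w * 3,
                 size = 1L, signed = FALSE)
  # numpy C-order (n, h, w, 3) is channel-fastest: matches column-major
  # dim (3, w, h, n)
  a4 <- array(as.numeric(raw), dim = c(3L, w, h, n))
  slide <- tools::file_path_sans_ext(basename(path))
  ids <- sprintf("%s_%06d", slide, seq_len(n) - 1L)
  images <- setNames(lapply(seq_len(n), function(i) aperm(a4[, , , i], c(3, 2, 1))),
                     ids)
  r <- empty_records(n)
  r$patch_id <- ids
  r$slide_id <- slide
  r$x <- 0L; r$y <- 0L; r$size <- as.integer(h)
  r$label <- y
  r$split <- split
  r$image_ref <- sprintf("%s#%d", path, seq_len(n) - 1L)
  list(manifest = patch_manifest(r, classes,
                                 sprintf("hdf5 archive %s", basename(path))),
       images = images)
}
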