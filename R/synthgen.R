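#' Build texture recipes for K synthetic tissue classes
#'
#' Each class is rendered as a tinted, oriented, blob-speckled texture:
#' a stand-in for morphologically distinct tissue types that a small
#' classifier can learn. `difficulty` linearly pulls every recipe toward
#' the across-class mean recipe: 0 gives maximally separated classes, 1
#' makes all classes identical (chance-level problem).
#'
#' @param K Number of classes (>= 2).
#' @param difficulty Fraction in `[0, 1]`.
#' @param seed Integer seed (controls the hue rotation of the palette).
#' @return List of `K` `class_recipe` objects with fields `class`,
#'   `base_color` (RGB means), `stripe_deg`, `stripe_freq` (cycles per
#'   patch), `stripe_amp`, `blob_density` (expected blobs per patch), and
#'   `jitter` (`color` and `pixel` standard deviations).
#' @export
make_recipes <- function(K, difficulty = 0, seed = 1L) {
  if (K < 2L) stopf("need K >= 2 classes")
  if (difficulty < 0 || difficulty > 1) stopf("difficulty must be in [0, 1]")
  rot <- with_seed(seed, runif(1))
  hues <- (seq(0, 1, length.out = K + 1L)[seq_len(K)] + rot) %% 1
  base <- t(sapply(hues, function(h) grDevices::col2rgb(grDevices::hsv(h, 0.55, 0.75))[, 1]))
  stripe_deg <- (seq_len(K) - 1L) * 180 / K
  stripe_freq <- 3 + 2 * (seq_len(K) - 1L)
  blob_density <- 2 * (seq_len(K) - 1L)
  blend <- function(v) (1 - difficulty) * v + difficulty * mean(v)
  base_b <- apply(base, 2, blend)
  if (K == 1L) base_b <- matrix(base_b, nrow = 1)
  freq_b <- blend(stripe_freq)
  dens_b <- blend(blob_density)
  # orientation is circular; interpolate the angle toward the mean angle
  deg_b <- blend(stripe_deg)
  lapply(seq_len(K), function(k) {
    structure(list(
      class = k - 1L,
      base_color = unname(base_b[k, ]),
      stripe_deg = deg_b[k],
      stripe_freq = freq_b[k],
      stripe_amp = 18,
      blob_density = dens_b[k],
      jitter = c(color = 6, pixel = 5)
    ), class = "class_recipe")
  })
}

#' Render one synthetic patch
#'
#' Deterministic per `(recipe, seed)`: base color, plus an oriented
#' sinusoidal stripe texture, plus randomly placed dark blobs, plus
#' per-patch color jitter and per-pixel Gaussian noise, clipped to
#' `[0, 255]`.
#'
#' @param recipe A `class_recipe` from [make_recipes()].
#' @param size Patch side length in pixels (>= 16).
#' @param seed Integer seed.
#' @return RGB array `size` x `size` x 3.
#' @export
render_patch <- function(recipe, size, seed = 1L) {
  if (size < 16L) stopf("patch size must be >= 16")
  render_texture(recipe, size, size, seed)
}

# Rectangular texture field; render_patch is the square wrapper and
# generate_synthetic_slide uses full-slide fields.
render_texture <- function(recipe, height, width, seed) {
  with_seed(seed, {
    col_j <- recipe$base_color + stats::rnorm(3, 0, recipe$jitter[["color"]])
    xs <- matrix(rep(seq_len(width) - 0.5, each = height), height, width)
    ys <- matrix(rep(seq_len(height) - 0.5, times = width), height, width)
    th <- recipe$stripe_deg * pi / 180
    phase <- (xs * cos(th) + ys * sin(th)) * 2 * pi * recipe$stripe_freq / max(height, width)
    stripes <- recipe$stripe_amp * sin(phase)
    blob <- matrix(0, height, width)
    n_blobs <- round(recipe$blob_density * (height * width) / (64 * 64))
    if (n_blobs > 0) {
      bx <- stats::runif(n_blobs, 0, width)
      by <- stats::runif(n_blobs, 0, height)
      rad <- stats::runif(n_blobs, 2, max(3, min(height, width) / 12))
      for (i in seq_len(n_blobs)) {
        d2 <- (xs - bx[i])^2 + (ys - by[i])^2
        blob <- blob - 35 * exp(-d2 / (2 * rad[i]^2))
      }
    }
    out <- array(0, dim = c(height, width, 3))
    for (ch in 1:3) {
      noise <- if (recipe$jitter[["pixel"]] > 0)
        matrix(stats::rnorm(height * width, 0, recipe$jitter[["pixel"]]), height, width)
      else 0
      out[, , ch] <- col_j[ch] + stripes + blob + noise
    }
    pmin(pmax(out, 0), 255)
  })
}

#' Generate a complete synthetic patch dataset
#'
#' Renders `K * n_per_class` patches on virtual slides (about
#' `patches_per_slide` patches each, at least 3 slides so slide-level
#' splitting is meaningful), splits 80/10/10 by slide, and injects
#' symmetric label noise into the training split.
#'
#' @param K Number of classes.
#' @param n_per_class Patches per class.
#' @param size Patch side length (default 64: large enough for texture,
#'   small enough for desk-scale training).
#' @param difficulty Class-separability control in `[0, 1]` (see
#'   [make_recipes()]).
#' @param noise_rate Symmetric train-split noise fraction in `[0, 1)`.
#' @param seed Integer master seed; everything downstream derives from it.
#' @param patches_per_slide Approximate patches per virtual slide
#'   (default 200).
#' @param fractions Train/val/test slide fractions (default 0.8/0.1/0.1).
#' @return List with `manifest` (a `patch_manifest`), `images` (named list
#'   of arrays), `mask` (the injection `noise_mask`), and `recipes`.
#' @export
generate_patch_dataset <- function(K, n_per_class, size = 64L, difficulty = 0,
                                   noise_rate = 0, seed = 1L,
                                   patches_per_slide = 200L,
                                   fractions = c(0.8, 0.1, 0.1)) {
  recipes <- make_recipes(K, difficulty, seed = derive_seed(seed, 1L))
  n <- K * n_per_class
  # enough slides that every split receives at least one under the floors
  min_slides <- max(3L, ceiling(1 / fractions[2]), ceiling(1 / fractions[3]))
  n_slides <- max(min_slides, as.integer(round(n / patches_per_slide)))
  labels <- rep(0:(K - 1L), each = n_per_class)
  slide_of <- with_seed(derive_seed(seed, 2L), sample(rep_len(seq_len(n_slides), n)))
  ids <- sprintf("p%05d", seq_len(n))
  # lay patches out on a per-slide grid so coordinates are tile-aligned
  grid_w <- ceiling(sqrt(patches_per_slide))
  pos_in_slide <- unlist(lapply(split(seq_len(n), slide_of), seq_along),
                         use.names = FALSE)
  ord <- order(slide_of)  # pos_in_slide follows slide order
  pos <- integer(n); pos[ord] <- pos_in_slide
  r <- empty_records(n)
  r$patch_id <- ids
  r$slide_id <- sprintf("slide%03d", slide_of)
  r$x <- as.integer(((pos - 1L) %% grid_w) * size)
  r$y <- as.integer(((pos - 1L) %/% grid_w) * size)
  r$size <- as.integer(size)
  r$label <- labels
  r$image_ref <- sprintf("synthetic://%s", ids)
  m <- patch_manifest(r, sprintf("class%d", 0:(K - 1L)),
                      sprintf("synthetic K=%d difficulty=%.2f seed=%d", K, difficulty, seed))
  m <- split_by_slide(m, fractions, seed = derive_seed(seed, 3L))
  patch_seeds <- with_seed(derive_seed(seed, 4L),
                           sample.int(2147483646L, n))
  images <- setNames(lapply(seq_len(n), function(i)
    render_patch(recipes[[labels[i] + 1L]], size, patch_seeds[i])), ids)
  inj <- inject_symmetric_noise(m, noise_rate, seed = derive_seed(seed, 5L))
  list(manifest = inj$manifest, images = images, mask = inj$mask,
       recipes = recipes)
}

#' Describe a synthetic slide layout
#'
#' A slide is a white canvas with textured polygonal tissue regions.
#' `annotation_dilation` models over-drawn annotations: emitted annotation
#' polygons are the true non-benign polygons dilated outward by that many
#' pixels, which makes surrounding benign tissue inherit a non-benign
#' label when tiled, i.e. annotation-induced false-positive label noise.
#'
#' @param width,height Slide dimensions in pixels.
#' @param regions List of `list(label =, polygon =)` entries; polygons are
#'   n x 2 vertex matrices in slide coordinates, convex, within bounds.
#'   Regions are painted in order, later over earlier.
#' @param annotation_dilation Outward annotation margin in pixels (>= 0).
#' @return A `slide_layout` object.
#' @export
slide_layout <- function(width, height, regions, annotation_dilation = 0) {
  if (annotation_dilation < 0) stopf("annotation_dilation must be >= 0")
  for (rg in regions) {
    p <- as.matrix(rg$polygon)
    if (any(p[, 1] < 0 | p[, 1] > width | p[, 2] < 0 | p[, 2] > height))
      stopf("region polygon exceeds slide bounds")
  }
  structure(list(width = as.integer(width), height = as.integer(height),
                 regions = regions,
                 annotation_dilation = annotation_dilation),
            class = "slide_layout")
}

#' Render a synthetic slide with over-drawn annotations
#'
#' Paints each region's class texture onto a white canvas and emits, for
#' every non-benign region, an [annotation_region()] whose polygon is the
#' true polygon dilated by the layout's `annotation_dilation` (clipped to
#' the slide, with a message when clipping occurs). With dilation 0 the
#' annotations coincide with the truth; with positive dilation, tiling plus
#' [assign_label()] yields some benign-truth tiles labeled non-benign,
#' reproducing the false-positive mechanism of sloppy manual annotation.
#'
#' @param layout A [slide_layout()].
#' @param recipes Recipes from [make_recipes()]; region labels index them.
#' @param seed Integer seed.
#' @param slide_id Id for the emitted annotations (default "synthetic").
#' @return List with `image` (H x W x 3), `region_map` (H x W integer
#'   matrix of true class per pixel, `NA` = white background),
#'   `annotations` (dilated regions), `truth_regions` (undilated
#'   non-benign regions), and `layout`.
#' @export
generate_synthetic_slide <- function(layout, recipes, seed = 1L,
                                     slide_id = "synthetic") {
  stopifnot(inherits(layout, "slide_layout"))
  H <- layout$height; W <- layout$width
  image <- array(255, dim = c(H, W, 3))
  region_map <- matrix(NA_integer_, H, W)
  px <- cbind(rep(seq_len(W) - 0.5, each = H), rep(seq_len(H) - 0.5, times = W))
  for (i in seq_along(layout$regions)) {
    rg <- layout$regions[[i]]
    inside <- points_in_polygon(as.matrix(rg$polygon), px)
    mask <- matrix(inside, H, W)          # column-major: (y, x) order matches px
    tex <- render_texture(recipes[[rg$label + 1L]], H, W,
                          derive_seed(seed, i))
    for (ch in 1:3) {
      plane <- image[, , ch]
      plane[mask] <- tex[, , ch][mask]
      image[, , ch] <- plane
    }
    region_map[mask] <- rg$label
  }
  delta <- layout$annotation_dilation
  annotations <- list()
  for (rg in layout$regions) {
    if (rg$label == 0L) next              # benign needs no annotation
    poly <- as.matrix(rg$polygon)
    if (delta > 0) {
      poly <- polygon_dilate(poly, delta)
      clipped <- clip_polygon_rect(poly, 0, 0, W, H)
      if (!isTRUE(all.equal(dim(clipped), dim(poly))) ||
          max(abs(clipped - poly)) > 1e-9)
        message(sprintf("dilated annotation clipped to slide bounds (delta=%g)", delta))
      poly <- clipped
    }
    annotations[[length(annotations) + 1L]] <-
      annotation_region(slide_id, poly, rg$label)
  }
  truth <- lapply(Filter(function(r) r$label != 0L, layout$regions),
                  function(r) annotation_region(slide_id, as.matrix(r$polygon),
                                                r$label))
  list(image = image, region_map = region_map, annotations = annotations,
       truth_regions = truth, layout = layout)
}

#' Measure annotation-induced label noise on a synthetic slide
#'
#' Tiles the slide, drops background tiles, labels every kept tile twice:
#' once against the true region polygons and once against the emitted
#' (possibly dilated) annotations, and reports the disagreement rate: the
#' fraction of tiles whose annotation-derived label differs from truth.
#'
#' @param slide Result of [generate_synthetic_slide()].
#' @param patch_size Tile side length.
#' @param overlap_min Overlap threshold passed to [assign_label()].
#' @param bg_intensity,max_bg_fraction Tissue-filter settings.
#' @return List with `rate`, `n_tiles`, and a per-tile data frame `tiles`
#'   (`x`, `y`, `truth`, `annotated`).
#' @export
annotation_noise_rate <- function(slide, patch_size, overlap_min = 0.5,
                                  bg_intensity = 220, max_bg_fraction = 0.7) {
  coords <- tile_image(width = slide$layout$width,
                       height = slide$layout$height,
                       patch_size = patch_size)
  keep <- vapply(seq_len(nrow(coords)), function(i) {
    tissue_filter(extract_tile(slide$image, coords$x[i], coords$y[i], patch_size),
                  bg_intensity, max_bg_fraction)
  }, logical(1))
  coords <- coords[keep, , drop = FALSE]
  if (!nrow(coords)) return(list(rate = NA_real_, n_tiles = 0L,
                                 tiles = cbind(coords, truth = integer(0),
                                               annotated = integer(0))))
  lab <- function(regions) vapply(seq_len(nrow(coords)), function(i)
    assign_label(coords$x[i], coords$y[i], patch_size, regions,
                 overlap_min = overlap_min, benign_class = 0L), integer(1))
  truth <- lab(slide$truth_regions)
  annotated <- lab(slide$annotations)
  tiles <- data.frame(x = coords$x, y = coords$y, truth = truth,
                      annotated = annotated)
  list(rate = mean(truth != annotated), n_tiles = nrow(tiles), tiles = tiles)
}
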