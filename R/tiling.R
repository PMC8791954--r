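#' Enumerate tile coordinates over an image
#'
#' Tiles are square, half-open `[x, x + size) x [y, y + size)`, with a
#' 0-based top-left origin. Only tiles lying fully inside the image are
#' returned, in row-major order (x varies fastest).
#'
#' @param image RGB array (height x width x 3), or `NULL` if `width`/
#'   `height` are given directly.
#' @param patch_size Tile side length in pixels (default 256, the usual
#'   working size for whole-slide images at full magnification).
#' @param stride Step between tile origins in pixels; `stride = patch_size`
#'   gives non-overlapping tiles.
#' @param width,height Image dimensions, used when `image` is `NULL`.
#' @return Data frame with integer columns `x`, `y`.
#' @export
#' @examples
#' tile_image(width = 512, height = 512, patch_size = 256)
tile_image <- function(image = NULL, patch_size = 256L, stride = patch_size,
                       width = NULL, height = NULL) {
  if (!is.null(image)) {
    check_image(image)
    height <- dim(image)[1]
    width <- dim(image)[2]
  }
  patch_size <- as.integer(patch_size)
  stride <- as.integer(stride)
  if (patch_size < 1L || stride < 1L) stopf("patch_size and stride must be >= 1")
  if (width < patch_size || height < patch_size)
    stopf("image (%dx%d) is smaller than patch_size %d: no tile fits",
          width, height, patch_size)
  xs <- seq.int(0L, width - patch_size, by = stride)
  ys <- seq.int(0L, height - patch_size, by = stride)
  out <- expand.grid(x = xs, y = ys, KEEP.OUT.ATTRS = FALSE)  # x fastest
  out$x <- as.integer(out$x); out$y <- as.integer(out$y)
  out
}

#' Decide whether a tile contains enough tissue to keep
#'
#' Whole-slide backgrounds are near-white; a pixel is treated as background
#' when all three channels are at or above `bg_intensity`. A tile is kept
#' when its background fraction does not exceed `max_bg_fraction`.
#'
#' @param tile_pixels RGB array (height x width x 3), values in \[0, 255\].
#' @param bg_intensity Background intensity threshold (default 220 of 255).
#' @param max_bg_fraction Maximum tolerated background fraction (default 0.7).
#' @return `TRUE` to keep the tile, `FALSE` to drop it.
#' @export
tissue_filter <- function(tile_pixels, bg_intensity = 220,
                          max_bg_fraction = 0.7) {
  check_image(tile_pixels)
  bg <- tile_pixels[, , 1] >= bg_intensity &
        tile_pixels[, , 2] >= bg_intensity &
        tile_pixels[, , 3] >= bg_intensity
  mean(bg) <= max_bg_fraction
}

#' Extract one tile from an image
#'
#' @param image RGB array.
#' @param x,y 0-based tile origin.
#' @param size Tile side length.
#' @return RGB array `size` x `size` x 3.
#' @export
extract_tile <- function(image, x, y, size) {
  check_image(image)
  if (x < 0 || y < 0 || x + size > dim(image)[2] || y + size > dim(image)[1])
    stopf("tile [%d,%d)+%d outside image bounds", x, y, size)
  image[(y + 1):(y + size), (x + 1):(x + size), , drop = FALSE]
}
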