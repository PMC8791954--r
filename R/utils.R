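#' Evaluate code under a temporary RNG state
#'
#' Seeds the session RNG, runs `code`, and restores the previous RNG state,
#' so seeded operations never disturb a caller's random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  code
}

# Deterministic child seed, kept inside 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed %% 100003L) * 30011 + as.double(offset) * 101 + 17) %% 2147483629)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate an RGB image array
#'
#' Images are numeric arrays of dimension height x width x 3 with values
#' in \[0, 255\] (0 = black, 255 = white).
#'
#' @param image Candidate object.
#' @return The image, invisibly, after validation.
#' @keywords internal
check_image <- function(image) {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] != 3L ||
      !is.numeric(image))
    stopf("expected an RGB image: numeric array of dim (height, width, 3)")
  invisible(image)
}

#' Read a PNG or TIFF image as an RGB array
#'
#' @param path File path ending in .png, .tif or .tiff.
#' @return Numeric array height x width x 3 with values in \[0, 255\].
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    stopf("unsupported image format '.%s' (use PNG or TIFF)", ext)
  )
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  img * 255
}

#' Write an RGB array as PNG or TIFF
#'
#' @param image Numeric array height x width x 3, values in \[0, 255\].
#' @param path Output path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  check_image(image)
  scaled <- pmin(pmax(image / 255, 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png  = png::writePNG(scaled, path),
    tif  = ,
    tiff = tiff::writeTIFF(scaled, path),
    stopf("unsupported image format '.%s' (use PNG or TIFF)", ext)
  )
  invisible(path)
}
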