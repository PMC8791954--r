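# Small in-code fixtures shared across tests.

solid_image <- function(h, w, rgb = c(0, 0, 0)) {
  array(rep(rgb, each = h * w), dim = c(h, w, 3))
}

# A hand-built manifest: `per_slide` patches on each of `n_slides` slides,
# labels cycling over K classes, all in the train split unless reassigned.
tiny_manifest <- function(n_slides = 4, per_slide = 6, K = 2,
                          split = "train", size = 16L) {
  n <- n_slides * per_slide
  r <- data.frame(
    patch_id = sprintf("t%03d", seq_len(n)),
    slide_id = rep(sprintf("s%02d", seq_len(n_slides)), each = per_slide),
    x = rep(seq_len(per_slide) - 1L, n_slides) * size,
    y = 0L, size = size,
    label = as.integer((seq_len(n) - 1L) %% K),
    split = split,
    image_ref = "none",
    clean_label = NA_integer_, is_noisy = NA,
    stringsAsFactors = FALSE
  )
  patch_manifest(r, sprintf("class%d", 0:(K - 1L)))
}

# Axis-aligned rectangle polygon (half-open pixel semantics line up with
# pixel centers at +0.5).
rect_poly <- function(x0, y0, x1, y1) {
  matrix(c(x0, y0, x1, y0, x1, y1, x0, y1), ncol = 2, byrow = TRUE)
}

# A quick small synthetic dataset for training tests.
small_dataset <- function(K = 2, n_per_class = 60, noise_rate = 0.2,
                          seed = 42, difficulty = 0.1) {
  generate_patch_dataset(K = K, n_per_class = n_per_class, size = 16L,
                         difficulty = difficulty, noise_rate = noise_rate,
                         seed = seed, patches_per_slide = 20L)
}

# A fast low-capacity classifier for plumbing tests.
small_classifier <- function(K, seed = 1L) {
  random_feature_classifier(K, pool = 8L, hidden = 256L, seed = seed)
}
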