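MANIFEST_COLUMNS <- c("patch_id", "slide_id", "x", "y", "size", "label",
                      "split", "image_ref", "clean_label", "is_noisy")

#' Write a patch manifest to a tab-separated file
#'
#' The file starts with `#`-prefixed metadata lines carrying the class
#' vocabulary and provenance, then a header row and one tab-separated row
#' per patch. Labels are written as class names.
#'
#' @param manifest A `patch_manifest`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  validate_patch_manifest(manifest)
  r <- manifest$records
  enc_label <- function(idx) ifelse(is.na(idx), "", manifest$classes[idx + 1L])
  out <- data.frame(
    patch_id = r$patch_id, slide_id = r$slide_id,
    x = r$x, y = r$y, size = r$size,
    label = enc_label(r$label), split = r$split, image_ref = r$image_ref,
    clean_label = enc_label(r$clean_label),
    is_noisy = ifelse(is.na(r$is_noisy), "", ifelse(r$is_noisy, "true", "false")),
    stringsAsFactors = FALSE
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# classes: %s", paste(manifest$classes, collapse = ",")), con)
  writeLines(sprintf("# provenance: %s", manifest$provenance), con)
  writeLines(paste(MANIFEST_COLUMNS, collapse = "\t"), con)
  if (nrow(out))
    writeLines(do.call(paste, c(unname(as.list(out)), sep = "\t")), con)
  invisible(path)
}

#' Read a patch manifest from a tab-separated file
#'
#' Inverse of [write_manifest()]. Parse failures (missing column, duplicate
#' id, unknown label, malformed row) report the offending 1-based file line.
#'
#' @param path Manifest file path.
#' @return A validated `patch_manifest`.
#' @export
read_manifest <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines)
  classes <- character(0); provenance <- ""
  for (i in meta) {
    if (grepl("^# classes:", lines[i]))
      classes <- trimws(strsplit(sub("^# classes:", "", lines[i]), ",")[[1]])
    if (grepl("^# provenance:", lines[i]))
      provenance <- trimws(sub("^# provenance:", "", lines[i]))
  }
  if (!length(classes)) stopf("%s: missing '# classes:' metadata line", path)
  body_idx <- setdiff(seq_along(lines), meta)
  body_idx <- body_idx[nzchar(lines[body_idx])]
  if (!length(body_idx)) stopf("%s: no header row", path)
  hline <- body_idx[1]
  header <- strsplit(lines[hline], "\t", fixed = TRUE)[[1]]
  miss <- setdiff(MANIFEST_COLUMNS, header)
  if (length(miss))
    stopf("%s line %d: missing column(s) %s", path, hline,
          paste(miss, collapse = ", "))
  dec_label <- function(s, line, col) {
    if (!nzchar(s)) return(NA_integer_)
    k <- match(s, classes)
    if (is.na(k)) stopf("%s line %d: unknown %s '%s'", path, line, col, s)
    k - 1L
  }
  rows <- lapply(body_idx[-1], function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < length(header))
      f <- c(f, rep("", length(header) - length(f)))
    if (length(f) != length(header))
      stopf("%s line %d: expected %d fields, got %d", path, i,
            length(header), length(f))
    v <- setNames(as.list(f), header)
    data.frame(
      patch_id = v$patch_id, slide_id = v$slide_id,
      x = as.integer(v$x), y = as.integer(v$y), size = as.integer(v$size),
      label = dec_label(v$label, i, "label"),
      split = v$split, image_ref = v$image_ref,
      clean_label = dec_label(v$clean_label, i, "clean_label"),
      is_noisy = if (!nzchar(v$is_noisy)) NA else identical(v$is_noisy, "true"),
      stringsAsFactors = FALSE
    )
  })
  records <- if (length(rows)) do.call(rbind, rows) else empty_records()
  if (anyDuplicated(records$patch_id)) {
    d <- which(duplicated(records$patch_id))[1]
    stopf("%s line %d: duplicate patch_id '%s'", path, body_idx[-1][d],
          records$patch_id[d])
  }
  patch_manifest(records, classes, provenance)
}
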