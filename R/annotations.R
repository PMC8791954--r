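#' Polygonal class annotation on a slide
#'
#' Annotations mark non-benign regions; benign tissue needs no annotation
#' and is the default label for unannotated area. Vertices are in slide
#' pixel coordinates.
#'
#' @param slide_id Slide the region belongs to.
#' @param polygon Numeric matrix n x 2 of (x, y) vertices, n >= 3.
#' @param label 0-based class index; must not be the benign class.
#' @return An object of class `annotation_region`.
#' @export
annotation_region <- function(slide_id, polygon, label) {
  polygon <- as.matrix(polygon)
  if (ncol(polygon) != 2L || nrow(polygon) < 3L)
    stopf("polygon must be an n x 2 matrix with n >= 3")
  structure(list(slide_id = as.character(slide_id), polygon = polygon,
                 label = as.integer(label)),
            class = "annotation_region")
}

# Point-in-polygon for a closed loop; pts is m x 2.
points_in_polygon <- function(polygon, pts) {
  bnd <- rbind(polygon, polygon[1, , drop = FALSE])
  mgcv::in.out(bnd, as.matrix(pts))
}

# Fraction of the tile's pixel centers covered by the polygon.
tile_overlap_fraction <- function(x, y, size, polygon) {
  cx <- x + seq_len(size) - 0.5
  cy <- y + seq_len(size) - 0.5
  pts <- cbind(rep(cx, times = size), rep(cy, each = size))
  mean(points_in_polygon(polygon, pts))
}

#' Label a tile from polygon annotations
#'
#' The tile takes the class of the annotation with the largest overlap
#' fraction, provided that fraction reaches `overlap_min`; otherwise it is
#' labeled benign (unannotated area is benign by convention). Overlap is
#' measured as the fraction of the tile's pixel centers inside the polygon.
#' Ties between classes are broken toward the smaller class index, with a
#' warning when two classes both clear the threshold.
#'
#' @param x,y 0-based tile origin in slide coordinates.
#' @param size Tile side length.
#' @param regions List of [annotation_region()] objects for this slide.
#' @param overlap_min Minimum overlap fraction to inherit an annotation's
#'   class (default 0.5).
#' @param benign_class 0-based index of the benign class.
#' @param mode `"area"` (overlap fraction, default) or `"center"` (the
#'   tile's center point decides).
#' @return 0-based class index.
#' @export
assign_label <- function(x, y, size, regions, overlap_min = 0.5,
                         benign_class = 0L, mode = c("area", "center")) {
  mode <- match.arg(mode)
  if (!length(regions)) return(as.integer(benign_class))
  sid <- unique(vapply(regions, function(r) r$slide_id, character(1)))
  if (length(sid) > 1L)
    stopf("regions span multiple slides: %s", paste(sid, collapse = ", "))
  if (mode == "center") {
    ctr <- matrix(c(x + size / 2, y + size / 2), ncol = 2)
    hit <- vapply(regions, function(r) points_in_polygon(r$polygon, ctr),
                  logical(1))
    if (!any(hit)) return(as.integer(benign_class))
    labs <- vapply(regions[hit], function(r) r$label, integer(1))
    return(min(labs))
  }
  ov <- vapply(regions, function(r) tile_overlap_fraction(x, y, size, r$polygon),
               numeric(1))
  labs <- vapply(regions, function(r) r$label, integer(1))
  pass <- ov >= overlap_min
  if (!any(pass)) return(as.integer(benign_class))
  if (length(unique(labs[pass])) > 1L)
    warnf("tile (%d,%d): annotations of classes %s all reach overlap %.2f; using max overlap",
          x, y, paste(sort(unique(labs[pass])), collapse = ","), overlap_min)
  best <- max(ov[pass])
  cand <- labs[pass][ov[pass] >= best - 1e-12]
  as.integer(min(cand))
}

# --- convex polygon geometry -------------------------------------------------

shoelace <- function(p) {
  n <- nrow(p)
  j <- c(2:n, 1)
  sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2]) / 2
}

ensure_ccw <- function(p) {
  # image coordinates have y pointing down, so "ccw" here just means a
  # consistent orientation: positive shoelace area in (x, y) terms
  if (shoelace(p) < 0) p[rev(seq_len(nrow(p))), , drop = FALSE] else p
}

is_convex <- function(p) {
  n <- nrow(p)
  s <- 0
  for (i in seq_len(n)) {
    a <- p[i, ]; b <- p[(i %% n) + 1, ]; cc <- p[((i + 1) %% n) + 1, ]
    cr <- (b[1] - a[1]) * (cc[2] - b[2]) - (b[2] - a[2]) * (cc[1] - b[1])
    if (abs(cr) < 1e-12) next
    if (s == 0) s <- sign(cr) else if (sign(cr) != s) return(FALSE)
  }
  TRUE
}

#' Dilate a convex polygon outward by a fixed margin
#'
#' Each edge is offset outward by `delta` pixels and adjacent offset edges
#' are re-intersected, the exact Minkowski offset for convex polygons. This
#' models sloppy over-drawn annotations: a pathologist's boundary drawn
#' `delta` pixels outside the true lesion.
#'
#' @param polygon n x 2 vertex matrix of a convex polygon.
#' @param delta Outward margin in pixels (>= 0).
#' @return Dilated n x 2 vertex matrix.
#' @export
polygon_dilate <- function(polygon, delta) {
  if (delta < 0) stopf("delta must be >= 0")
  if (delta == 0) return(polygon)
  p <- ensure_ccw(as.matrix(polygon))
  if (!is_convex(p)) stopf("polygon_dilate requires a convex polygon")
  n <- nrow(p)
  nxt <- c(2:n, 1)
  e <- p[nxt, , drop = FALSE] - p
  len <- sqrt(rowSums(e^2))
  if (any(len < 1e-12)) {
    keep <- len >= 1e-12
    return(polygon_dilate(p[keep, , drop = FALSE], delta))
  }
  # with y down and positive-shoelace orientation, the outward normal of
  # edge (dx, dy) is (dy, -dx) / len
  nx <- e[, 2] / len
  ny <- -e[, 1] / len
  a <- p + delta * cbind(nx, ny)          # shifted edge start points
  d <- e                                   # edge directions unchanged
  out <- matrix(NA_real_, n, 2)
  prev <- c(n, 1:(n - 1))
  for (i in seq_len(n)) {
    j <- prev[i]
    # intersect shifted edge j with shifted edge i; solve a_j + t d_j = a_i + s d_i
    A <- cbind(d[j, ], -d[i, ])
    if (abs(det(A)) < 1e-9) {
      out[i, ] <- (a[i, ] + a[j, ] + d[j, ]) / 2  # parallel: midpoint fallback
    } else {
      t <- solve(A, a[i, ] - a[j, ])[1]
      out[i, ] <- a[j, ] + t * d[j, ]
    }
  }
  out
}

#' Clip a polygon to a rectangle
#'
#' Sutherland–Hodgman clipping against the axis-aligned rectangle
#' `[xmin, xmax] x [ymin, ymax]`.
#'
#' @param polygon n x 2 vertex matrix.
#' @param xmin,ymin,xmax,ymax Rectangle bounds.
#' @return Clipped vertex matrix (possibly with 0 rows).
#' @export
clip_polygon_rect <- function(polygon, xmin, ymin, xmax, ymax) {
  p <- as.matrix(polygon)
  clip_edge <- function(p, inside, intersect) {
    if (!nrow(p)) return(p)
    out <- list()
    n <- nrow(p)
    for (i in seq_len(n)) {
      cur <- p[i, ]; prv <- p[if (i == 1) n else i - 1, ]
      ci <- inside(cur); pi <- inside(prv)
      if (ci) {
        if (!pi) out[[length(out) + 1]] <- intersect(prv, cur)
        out[[length(out) + 1]] <- cur
      } else if (pi) {
        out[[length(out) + 1]] <- intersect(prv, cur)
      }
    }
    if (!length(out)) matrix(numeric(0), 0, 2) else do.call(rbind, out)
  }
  ix <- function(a, b, val, k) {  # cross axis k at val
    t <- (val - a[k]) / (b[k] - a[k])
    a + t * (b - a)
  }
  p <- clip_edge(p, function(q) q[1] >= xmin, function(a, b) ix(a, b, xmin, 1))
  p <- clip_edge(p, function(q) q[1] <= xmax, function(a, b) ix(a, b, xmax, 1))
  p <- clip_edge(p, function(q) q[2] >= ymin, function(a, b) ix(a, b, ymin, 2))
  p <- clip_edge(p, function(q) q[2] <= ymax, function(a, b) ix(a, b, ymax, 2))
  p
}
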