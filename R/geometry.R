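#' Polygon area by the shoelace formula
#'
#' Signed-area magnitude of a simple closed polygon given as an ordered vertex
#' matrix. Vertices may or may not repeat the first point at the end; a
#' repeated closing vertex is ignored.
#'
#' @param vertices two-column numeric matrix of (x, y) vertex coordinates in
#'   level-0 pixels, ordered along the boundary.
#' @return polygon area in pixels squared (non-negative scalar).
#' @export
polygon_area <- function(vertices) {
  v <- drop_closing_vertex(as_vertex_matrix(vertices))
  x <- v[, 1L]; y <- v[, 2L]
  xs <- c(x[-1L], x[1L]); ys <- c(y[-1L], y[1L])
  abs(sum(x * ys - xs * y)) / 2
}

as_vertex_matrix <- function(vertices) {
  v <- as.matrix(vertices)
  if (ncol(v) != 2L) stop("polygon vertices must be a two-column (x, y) matrix")
  storage.mode(v) <- "double"
  if (anyNA(v) || any(!is.finite(v))) stop("polygon vertices must be finite")
  v
}

drop_closing_vertex <- function(v) {
  n <- nrow(v)
  if (n >= 2L && all(v[1L, ] == v[n, ])) v <- v[-n, , drop = FALSE]
  if (nrow(v) < 3L) stop("polygon needs at least 3 distinct vertices")
  v
}

# Proper/improper intersection test for two closed segments, used by the
# simplicity check. Shared endpoints of adjacent edges are handled by the
# caller.
segments_cross <- function(p1, p2, q1, q2) {
  orient <- function(a, b, c) {
    v <- (b[1L] - a[1L]) * (c[2L] - a[2L]) - (b[2L] - a[2L]) * (c[1L] - a[1L])
    if (abs(v) < 1e-12) 0 else sign(v)
  }
  on_seg <- function(a, b, c) {
    min(a[1L], b[1L]) - 1e-12 <= c[1L] && c[1L] <= max(a[1L], b[1L]) + 1e-12 &&
      min(a[2L], b[2L]) - 1e-12 <= c[2L] && c[2L] <= max(a[2L], b[2L]) + 1e-12
  }
  o1 <- orient(p1, p2, q1); o2 <- orient(p1, p2, q2)
  o3 <- orient(q1, q2, p1); o4 <- orient(q1, q2, p2)
  if (o1 != o2 && o3 != o4) return(TRUE)
  (o1 == 0 && on_seg(p1, p2, q1)) || (o2 == 0 && on_seg(p1, p2, q2)) ||
    (o3 == 0 && on_seg(q1, q2, p1)) || (o4 == 0 && on_seg(q1, q2, p2))
}

#' Test whether a polygon is simple (non-self-intersecting)
#'
#' Pairwise segment-intersection check over all non-adjacent boundary edges.
#' Quadratic in the number of vertices, which is ample for manually traced
#' region annotations (tens to hundreds of vertices).
#'
#' @inheritParams polygon_area
#' @return logical scalar.
#' @export
polygon_is_simple <- function(vertices) {
  v <- drop_closing_vertex(as_vertex_matrix(vertices))
  n <- nrow(v)
  edge <- function(i) list(v[i, ], v[if (i == n) 1L else i + 1L, ])
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      # skip adjacent edges (they legitimately share a vertex)
      if (j == i + 1L || (i == 1L && j == n)) next
      ei <- edge(i); ej <- edge(j)
      if (segments_cross(ei[[1L]], ei[[2L]], ej[[1L]], ej[[2L]])) return(FALSE)
    }
  }
  TRUE
}

#' Point-in-polygon containment with inclusive boundary
#'
#' Even-odd ray-casting containment for a batch of query points. Points lying
#' on a polygon edge or vertex count as inside: centroids sitting exactly on a
#' manually traced region boundary are assigned to that region rather than
#' dropped, which is the deterministic tie rule used throughout the package.
#'
#' @param x,y numeric vectors of query coordinates (level-0 pixels).
#' @param vertices polygon vertex matrix as in [polygon_area()].
#' @return logical vector, one element per query point.
#' @export
point_in_polygon <- function(x, y, vertices) {
  v <- drop_closing_vertex(as_vertex_matrix(vertices))
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) == 0L) return(logical(0L))
  if (anyNA(x) || anyNA(y) || any(!is.finite(c(x, y))))
    stop("query coordinates must be finite")
  px <- v[, 1L]; py <- v[, 2L]
  qx <- c(px[-1L], px[1L]); qy <- c(py[-1L], py[1L])
  dx <- qx - px; dy <- qy - py
  lox <- pmin(px, qx) - 1e-9; hix <- pmax(px, qx) + 1e-9
  loy <- pmin(py, qy) - 1e-9; hiy <- pmax(py, qy) + 1e-9
  n <- length(x)
  inside <- logical(n)
  # blockwise over query points: edge-wise vector work per block keeps memory
  # bounded while avoiding a per-point interpreted loop
  block <- 4096L
  m <- length(px)
  for (b0 in seq(1L, n, by = block)) {
    idx <- b0:min(b0 + block - 1L, n)
    nb <- length(idx)
    X <- matrix(x[idx], nb, m)
    Y <- matrix(y[idx], nb, m)
    PX <- matrix(px, nb, m, byrow = TRUE); PY <- matrix(py, nb, m, byrow = TRUE)
    QY <- matrix(qy, nb, m, byrow = TRUE)
    DX <- matrix(dx, nb, m, byrow = TRUE); DY <- matrix(dy, nb, m, byrow = TRUE)
    crs <- DX * (Y - PY) - DY * (X - PX)
    on_edge <- abs(crs) < 1e-9 &
      X >= matrix(lox, nb, m, byrow = TRUE) &
      X <= matrix(hix, nb, m, byrow = TRUE) &
      Y >= matrix(loy, nb, m, byrow = TRUE) &
      Y <= matrix(hiy, nb, m, byrow = TRUE)
    straddle <- (PY > Y) != (QY > Y)
    xint <- PX + (Y - PY) * DX / DY
    hit <- straddle & !is.na(xint) & xint > X
    odd <- (rowSums(hit) %% 2L) == 1L
    inside[idx] <- odd | (rowSums(on_edge) > 0L)
  }
  inside
}

#' Construct and validate a region annotation
#'
#' A region annotation is one manually segmented anatomical region of a
#' hippocampal whole-slide image: the hippocampus proper (dentate gyrus, cornu
#' ammonis, subiculum) or the adjacent entorhinal cortex. The polygon must be
#' simple with at least three vertices; its pixel area is derived by the
#' shoelace formula.
#'
#' @param label region label, `"hippocampus"` or `"entorhinal"`.
#' @param vertices ordered vertex matrix in level-0 pixel coordinates.
#' @return object of class `region_annotation` with fields `label`,
#'   `vertices` and `area_px`.
#' @export
region_annotation <- function(label, vertices) {
  label <- match.arg(label, c("hippocampus", "entorhinal"))
  v <- drop_closing_vertex(as_vertex_matrix(vertices))
  if (!polygon_is_simple(v))
    stop("region polygon is self-intersecting (label: ", label, ")")
  a <- polygon_area(v)
  if (a <= 0) stop("region polygon has zero area (label: ", label, ")")
  structure(list(label = label, vertices = v, area_px = a),
            class = "region_annotation")
}

#' @export
print.region_annotation <- function(x, ...) {
  cat(sprintf("<region_annotation> %s: %d vertices, area %.4g px^2\n",
              x$label, nrow(x$vertices), x$area_px))
  invisible(x)
}

#' Approximate overlap area of two convex-or-not polygons by grid sampling
#'
#' Used only for the slide-level sanity check that the two region annotations
#' do not overlap; a Monte-Carlo/grid estimate is sufficient at the tolerance
#' involved (0.1% of the smaller region).
#' @noRd
polygon_overlap_area <- function(a, b, n_grid = 200L) {
  va <- a$vertices; vb <- b$vertices
  xr <- range(c(va[, 1L], vb[, 1L])); yr <- range(c(va[, 2L], vb[, 2L]))
  gx <- seq(xr[1L], xr[2L], length.out = n_grid)
  gy <- seq(yr[1L], yr[2L], length.out = n_grid)
  pts <- expand.grid(x = gx, y = gy)
  ina <- point_in_polygon(pts$x, pts$y, va)
  inb <- point_in_polygon(pts$x, pts$y, vb)
  cell <- diff(xr) * diff(yr) / (n_grid^2)
  sum(ina & inb) * cell
}

#' Convert a pixel length to microns
#'
#' @param length_px length in level-0 pixels (non-negative).
#' @param pixel_size_um microns per pixel; the default 0.5066 corresponds to
#'   the 40x scan resolution at which 100 px = 50.66 um.
#' @return length in microns.
#' @examples
#' px_to_micron(800)   # 405.28
#' px_to_micron(5000)  # 2533
#' @export
px_to_micron <- function(length_px, pixel_size_um = 0.5066) {
  if (any(length_px < 0) || any(pixel_size_um < 0))
    stop("lengths and pixel sizes must be non-negative")
  length_px * pixel_size_um
}

#' Region area in square millimetres
#'
#' Shoelace pixel area scaled by the pixel pitch:
#' `area_px * (pixel_size_um / 1000)^2`.
#'
#' @param region a [region_annotation()].
#' @param pixel_size_um microns per pixel.
#' @return area in mm^2.
#' @export
region_area_mm2 <- function(region, pixel_size_um = 0.5066) {
  stopifnot(inherits(region, "region_annotation"))
  if (pixel_size_um <= 0) stop("pixel_size_um must be positive")
  a <- region$area_px * (pixel_size_um / 1000)^2
  if (a <= 0) stop("degenerate region: zero area")
  a
}
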