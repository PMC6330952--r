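# Polygon primitives shared by delineation, evaluation and alignment.
#
# A polygon is a two-column numeric matrix of vertices (x, y) in map meters,
# open ring (first vertex not repeated).  Boolean operations are delegated to
# polyclip (Clipper); point-in-polygon to sp, with points on the boundary
# counted as inside because crown hull vertices are themselves pixel centers.

AREA_EPS <- 1e-9  # areas below this (m^2) are treated as zero

# Integer-grid spacing for Clipper: fine enough for 1e-9 m^2 area agreement
# on local coordinates, coarsened for very large (projected) coordinates so
# the 64-bit integer grid cannot overflow.
clip_eps <- function(rings) {
  cmax <- max(1, vapply(rings, function(r) max(abs(c(r$x, r$y))), numeric(1)))
  max(1e-12, cmax / 1e15)
}

# Counter-clockwise orientation, required so the nonzero fill rule unions
# overlapping rings instead of cancelling them.
orient_ccw <- function(ring) {
  s <- sum(ring$x * c(ring$y[-1], ring$y[1]) -
             c(ring$x[-1], ring$x[1]) * ring$y)
  if (s < 0) list(x = rev(ring$x), y = rev(ring$y)) else ring
}

clip <- function(a, b, op) {
  a <- lapply(a, orient_ccw)
  b <- lapply(b, orient_ccw)
  polyclip::polyclip(a, b, op = op, eps = clip_eps(c(a, b)),
                     fillA = "nonzero", fillB = "nonzero")
}

as_ring <- function(poly) {
  if (is.list(poly) && !is.null(poly$x)) return(poly)
  list(x = poly[, 1], y = poly[, 2])
}

ring_to_matrix <- function(ring) cbind(x = ring$x, y = ring$y)

#' Polygon area (shoelace formula)
#'
#' @param poly Two-column matrix of vertices (x, y), open ring.
#' @return Area in squared map units (non-negative).
#' @export
poly_area <- function(poly) {
  r <- as_ring(poly)
  n <- length(r$x)
  if (n < 3) return(0)
  abs(sum(r$x * c(r$y[-1], r$y[1]) - c(r$x[-1], r$x[1]) * r$y)) / 2
}

#' Polygon centroid
#'
#' Area-weighted centroid; falls back to the vertex mean for degenerate
#' (near-zero-area) rings.
#'
#' @inheritParams poly_area
#' @return Numeric c(x, y).
#' @export
poly_centroid <- function(poly) {
  r <- as_ring(poly)
  x <- r$x; y <- r$y
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  cr <- x * y2 - x2 * y
  a <- sum(cr) / 2
  if (abs(a) < AREA_EPS) return(c(mean(x), mean(y)))
  c(sum((x + x2) * cr) / (6 * a), sum((y + y2) * cr) / (6 * a))
}

poly_bbox <- function(poly) {
  r <- as_ring(poly)
  c(xmin = min(r$x), ymin = min(r$y), xmax = max(r$x), ymax = max(r$y))
}

bbox_overlaps <- function(a, b) {
  a["xmin"] <= b["xmax"] && b["xmin"] <= a["xmax"] &&
    a["ymin"] <= b["ymax"] && b["ymin"] <= a["ymax"]
}

#' Area of intersection of two polygons
#'
#' @param a,b Two-column vertex matrices (open rings).
#' @return Intersection area; exactly 0 when bounding boxes are disjoint.
#' @export
poly_intersection_area <- function(a, b) {
  if (!bbox_overlaps(poly_bbox(a), poly_bbox(b))) return(0)
  pieces <- clip(list(as_ring(a)), list(as_ring(b)), "intersection")
  ar <- sum(vapply(pieces, poly_area, numeric(1)))
  if (ar < AREA_EPS) 0 else ar
}

# Dissolve a list of polygons into a union (list of rings); [] for empty input.
poly_union <- function(polys) {
  polys <- polys[vapply(polys, function(p) poly_area(p) > AREA_EPS, logical(1))]
  if (length(polys) == 0) return(list())
  rings <- lapply(polys, as_ring)
  clip(rings, rings, "union")
}

# Total area of a dissolved union of polygons.
union_area <- function(polys) {
  sum(vapply(poly_union(polys), poly_area, numeric(1)))
}

# Area of intersection between two dissolved unions of polygons.
union_intersection_area <- function(polys_a, polys_b) {
  ua <- poly_union(polys_a); ub <- poly_union(polys_b)
  if (length(ua) == 0 || length(ub) == 0) return(0)
  pieces <- clip(ua, ub, "intersection")
  ar <- sum(vapply(pieces, poly_area, numeric(1)))
  if (ar < AREA_EPS) 0 else ar
}

#' Jaccard overlap of two polygons
#'
#' J(A, B) = |A intersect B| / (|A| + |B| - |A intersect B|).  1 means the
#' polygons coincide, 0 means they are disjoint.  By convention 0 when both
#' polygons have zero area.
#'
#' @param a,b Two-column vertex matrices (open rings).
#' @return Fraction in \[0, 1\].
#' @export
jaccard <- function(a, b) {
  ia <- poly_intersection_area(a, b)
  un <- poly_area(a) + poly_area(b) - ia
  if (un < AREA_EPS) return(0)
  max(0, min(1, ia / un))
}

#' Test whether points fall inside a polygon (boundary inclusive)
#'
#' @param x,y Point coordinates.
#' @param poly Two-column vertex matrix (open ring).
#' @return Logical vector; points on an edge or vertex count as inside.
#' @export
points_in_polygon <- function(x, y, poly) {
  r <- as_ring(poly)
  sp::point.in.polygon(x, y, r$x, r$y) > 0
}

#' Convex hull of a point set
#'
#' @param x,y Point coordinates (at least one point).
#' @return Two-column matrix of hull vertices in counter-clockwise order, or
#'   NULL when the points are fewer than 3 or collinear.
#' @export
convex_hull <- function(x, y) {
  pts <- unique(cbind(x, y))
  if (nrow(pts) < 3) return(NULL)
  idx <- grDevices::chull(pts[, 1], pts[, 2])
  hull <- pts[idx, , drop = FALSE]
  if (poly_area(hull) < AREA_EPS) return(NULL)
  # chull returns clockwise order; store counter-clockwise
  hull[rev(seq_len(nrow(hull))), , drop = FALSE]
}
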