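# Planar geometry for quadrat-local polygons (cm coordinates, origin at the
# lower-left corner of a 1-m^2 quadrat). Polygons are plain 2-column matrices
# of vertices (x, y), implicitly closed. Buffered geometries are kept implicit
# (original vertices + dilation distance); areas and overlaps of buffered
# shapes are integrated on a fine raster, which handles non-convex outlines
# without polygon-clipping machinery.

#' Area mapped for plants recorded as points (cm^2)
#'
#' Very small plants are mapped as single points; they are represented as
#' circles with this fixed basal area.
#' @export
POINT_AREA_CM2 <- 0.25

#' Polygon area by the shoelace formula
#'
#' @param xy Two-column numeric matrix of vertices (implicitly closed).
#' @return Area in squared coordinate units (always non-negative).
#' @export
poly_area <- function(xy) {
  xy <- as.matrix(xy)
  if (nrow(xy) < 3) return(0)
  x <- xy[, 1]; y <- xy[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  abs(sum(x * y2 - x2 * y)) / 2
}

#' Polygon centroid
#'
#' Centroid of the enclosed region; degenerate polygons (zero area) fall back
#' to the vertex mean.
#' @inheritParams poly_area
#' @return Numeric length-2 vector (x, y).
#' @export
poly_centroid <- function(xy) {
  xy <- as.matrix(xy)
  if (nrow(xy) < 3) return(colMeans(xy))
  x <- xy[, 1]; y <- xy[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  cross <- x * y2 - x2 * y
  a <- sum(cross) / 2
  if (abs(a) < 1e-12) return(colMeans(xy))
  c(sum((x + x2) * cross), sum((y + y2) * cross)) / (6 * a)
}

#' Regular polygon with an exact target area
#'
#' Used to render circle-represented genets (and point plants) as polygon
#' vertex lists; the circumradius is chosen so the shoelace area equals
#' `area` exactly.
#'
#' @param cx,cy Centre coordinates.
#' @param area Target area.
#' @param n Number of vertices.
#' @return Two-column vertex matrix.
#' @export
regular_polygon <- function(cx, cy, area, n = 24L) {
  stopifnot(area > 0, n >= 3)
  r <- sqrt(2 * area / (n * sin(2 * pi / n)))
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(x = cx + r * cos(th), y = cy + r * sin(th))
}

# Vectorised point-in-polygon (boundary counts as inside). Degenerate
# "polygons" with < 3 vertices enclose no area.
points_in_poly <- function(px, py, xy) {
  xy <- as.matrix(xy)
  if (nrow(xy) < 3) return(rep(FALSE, length(px)))
  pracma::inpolygon(px, py, xy[, 1], xy[, 2], boundary = TRUE)
}

# Minimum distance from each query point to the polygon boundary segments.
dist_to_boundary <- function(px, py, xy) {
  xy <- as.matrix(xy)
  n <- nrow(xy)
  x1 <- xy[, 1]; y1 <- xy[, 2]
  x2 <- c(x1[-1], x1[1]); y2 <- c(y1[-1], y1[1])
  dx <- x2 - x1; dy <- y2 - y1
  len2 <- dx^2 + dy^2
  len2[len2 == 0] <- 1e-300
  dmin <- rep(Inf, length(px))
  for (s in seq_len(n)) {
    t <- ((px - x1[s]) * dx[s] + (py - y1[s]) * dy[s]) / len2[s]
    t <- pmin(1, pmax(0, t))
    d2 <- (px - (x1[s] + t * dx[s]))^2 + (py - (y1[s] + t * dy[s]))^2
    dmin <- pmin(dmin, d2)
  }
  sqrt(dmin)
}

# Does any pair of non-adjacent edges intersect? (simple-polygon check)
poly_is_simple <- function(xy) {
  xy <- as.matrix(xy)
  n <- nrow(xy)
  if (n < 3) return(FALSE)
  seg <- cbind(xy, rbind(xy[-1, , drop = FALSE], xy[1, , drop = FALSE]))
  ccw <- function(ax, ay, bx, by, cx, cy) (cy - ay) * (bx - ax) - (by - ay) * (cx - ax)
  for (i in seq_len(n - 2)) {
    jmax <- if (i == 1) n - 1 else n
    for (j in (i + 2):jmax) {
      a <- seg[i, ]; b <- seg[j, ]
      d1 <- ccw(a[1], a[2], a[3], a[4], b[1], b[2])
      d2 <- ccw(a[1], a[2], a[3], a[4], b[3], b[4])
      d3 <- ccw(b[1], b[2], b[3], b[4], a[1], a[2])
      d4 <- ccw(b[1], b[2], b[3], b[4], a[3], a[4])
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(FALSE)
    }
  }
  TRUE
}

#' Construct a (possibly buffered) quadrat geometry
#'
#' A `qd_geom` keeps the original vertex list together with a dilation
#' distance; membership tests treat the shape as the Minkowski sum of the
#' polygon with a disc of that radius.
#'
#' @param xy Two-column vertex matrix.
#' @param buffer Dilation distance (cm), `>= 0`.
#' @return Object of class `qd_geom`.
#' @export
qd_geom <- function(xy, buffer = 0) {
  xy <- as.matrix(xy)
  stopifnot(ncol(xy) == 2, buffer >= 0)
  structure(list(vertices = xy, buffer = buffer), class = "qd_geom")
}

#' @export
print.qd_geom <- function(x, ...) {
  cat(sprintf("<qd_geom: %d vertices, buffer %.2f cm, core area %.2f cm^2>\n",
              nrow(x$vertices), x$buffer, poly_area(x$vertices)))
  invisible(x)
}

geom_bbox <- function(g) {
  v <- g$vertices
  c(xmin = min(v[, 1]) - g$buffer, xmax = max(v[, 1]) + g$buffer,
    ymin = min(v[, 2]) - g$buffer, ymax = max(v[, 2]) + g$buffer)
}

geom_contains <- function(g, px, py) {
  inside <- points_in_poly(px, py, g$vertices)
  if (g$buffer > 0) {
    near <- !inside
    if (any(near)) {
      d <- dist_to_boundary(px[near], py[near], g$vertices)
      inside[near] <- d <= g$buffer
    }
  }
  inside
}

# Grid of cell centres covering a bbox at resolution `res`; boxes narrower
# than one cell yield an empty grid.
bbox_grid <- function(bb, res) {
  if (bb["xmax"] - bb["xmin"] < res / 2 || bb["ymax"] - bb["ymin"] < res / 2) {
    return(list(px = numeric(0), py = numeric(0)))
  }
  xs <- seq(bb["xmin"] + res / 2, bb["xmax"], by = res)
  ys <- seq(bb["ymin"] + res / 2, bb["ymax"], by = res)
  list(px = rep(xs, times = length(ys)), py = rep(ys, each = length(xs)))
}

#' Area of a (buffered) geometry
#'
#' Exact (shoelace) for unbuffered polygons; raster-integrated at resolution
#' `res` for dilated shapes.
#'
#' @param g A [qd_geom()].
#' @param res Raster resolution (cm) for buffered shapes.
#' @return Area in cm^2.
#' @export
geom_area <- function(g, res = 0.1) {
  if (g$buffer == 0) return(poly_area(g$vertices))
  bb <- geom_bbox(g)
  gr <- bbox_grid(bb, res)
  sum(geom_contains(g, gr$px, gr$py)) * res^2
}

#' Overlap area of two geometries
#'
#' Raster-integrated intersection area over the shared bounding box; returns 0
#' when the boxes are disjoint.
#'
#' @param a,b [qd_geom()] objects (either may carry a buffer).
#' @param res Raster resolution (cm).
#' @return Overlap area in cm^2.
#' @export
geom_overlap <- function(a, b, res = 0.25) {
  ba <- geom_bbox(a); bb <- geom_bbox(b)
  lo <- c(max(ba["xmin"], bb["xmin"]), max(ba["ymin"], bb["ymin"]))
  hi <- c(min(ba["xmax"], bb["xmax"]), min(ba["ymax"], bb["ymax"]))
  if (any(hi <= lo)) return(0)
  box <- c(xmin = lo[1], xmax = hi[1], ymin = lo[2], ymax = hi[2])
  gr <- bbox_grid(box, res)
  if (length(gr$px) == 0) return(0)
  ina <- geom_contains(a, gr$px, gr$py)
  if (!any(ina)) return(0)
  inb <- geom_contains(b, gr$px[ina], gr$py[ina])
  sum(inb) * res^2
}

#' Dilate mapped polygons by a buffer distance
#'
#' Applies the tracking algorithm's buffering step: each polygon becomes the
#' set of points within `buffer` cm of the original shape. Self-intersecting
#' polygons are either replaced by their convex hull (`repair = TRUE`) or
#' dropped with a warning.
#'
#' @param geoms List of vertex matrices or [qd_geom()] objects.
#' @param buffer Buffer distance in cm, `>= 0`.
#' @param repair Replace self-intersecting polygons by their convex hull
#'   instead of dropping them.
#' @return List of [qd_geom()] objects (possibly shorter than the input if
#'   invalid polygons were dropped).
#' @export
buffer_polygons <- function(geoms, buffer, repair = TRUE) {
  stopifnot(buffer >= 0)
  out <- list()
  for (g in geoms) {
    v <- if (inherits(g, "qd_geom")) g$vertices else as.matrix(g)
    if (nrow(v) >= 3 && !poly_is_simple(v)) {
      if (repair) {
        v <- v[grDevices::chull(v[, 1], v[, 2]), , drop = FALSE]
        warn("self-intersecting polygon replaced by its convex hull")
      } else {
        warn("self-intersecting polygon dropped")
        next
      }
    }
    out[[length(out) + 1]] <- qd_geom(v, buffer = buffer)
  }
  out
}
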