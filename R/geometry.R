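# Exact 2-D region construction and measurement for ablation prediction.
#
# Conventions: coordinates in mm, Cartesian, y-up, frame-local; polar angles in
# degrees, counter-clockwise from the +x axis.  A polygon is a single simple
# closed ring (counter-clockwise, closure implicit); a region is a set of rings
# with even-odd fill, where holes carry negative signed area (the convention
# the Clipper engine emits).

## ---- polygons ----------------------------------------------------------

#' Construct a simple polygon
#'
#' Builds a validated simple polygon from vertex coordinates.  Vertices are
#' stored counter-clockwise with implicit closure (the first vertex is not
#' repeated).  Clockwise input is reoriented.
#'
#' @param x,y Numeric vertex coordinates in mm (length >= 3, finite).
#' @param check_simple Verify that no two non-adjacent edges intersect
#'   (O(n^2); disable for contours that are simple by construction).
#' @return An object of class `ra_polygon`: a list with elements `x` and `y`.
#' @export
polygon2d <- function(x, y, check_simple = TRUE) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("polygon needs >= 3 (x, y) vertices")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("polygon vertices must be finite")
  # drop an explicitly repeated closing vertex
  n <- length(x)
  if (x[1] == x[n] && y[1] == y[n]) {
    x <- x[-n]; y <- y[-n]
    if (length(x) < 3L) stop("polygon needs >= 3 distinct vertices")
  }
  a <- signed_ring_area(list(x = x, y = y))
  if (abs(a) < 1e-12) stop("degenerate polygon (zero area)")
  if (a < 0) { x <- rev(x); y <- rev(y) }
  p <- structure(list(x = x, y = y), class = "ra_polygon")
  if (check_simple && !is_simple_ring(p))
    stop("polygon is self-intersecting")
  p
}

#' @export
print.ra_polygon <- function(x, ...) {
  cat(sprintf("<ra_polygon: %d vertices, area %.4f mm^2>\n",
              length(x$x), abs(signed_ring_area(x))))
  invisible(x)
}

signed_ring_area <- function(ring) {
  x <- ring$x; y <- ring$y
  0.5 * sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)
}

ring_centroid <- function(ring) {
  x <- ring$x; y <- ring$y
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  cr <- x * y2 - x2 * y
  a <- 0.5 * sum(cr)
  c(x = sum((x + x2) * cr) / (6 * a), y = sum((y + y2) * cr) / (6 * a))
}

#' Polygon centroid
#' @param poly An `ra_polygon`.
#' @return Named numeric vector `c(x, y)` in mm.
#' @export
polygon_centroid <- function(poly) ring_centroid(poly)

#' Polygon area (shoelace)
#' @param poly An `ra_polygon` or bare ring `list(x, y)`.
#' @return Area in mm^2 (absolute value).
#' @export
polygon_area <- function(poly) abs(signed_ring_area(poly))

# Segment-crossing test for simplicity: any pair of non-adjacent edges that
# properly intersect or overlap makes the ring non-simple.
is_simple_ring <- function(ring) {
  x1 <- ring$x; y1 <- ring$y
  n <- length(x1)
  x2 <- c(x1[-1], x1[1]); y2 <- c(y1[-1], y1[1])
  for (i in seq_len(n - 2L)) {
    # skip adjacent edges (i-1, i, i+1); for i = 1 also the closing edge n
    js <- (i + 2L):n
    if (i == 1L) js <- js[js != n]
    ax <- x1[i]; ay <- y1[i]; bx <- x2[i]; by <- y2[i]
    cx <- x1[js]; cy <- y1[js]; dx <- x2[js]; dy <- y2[js]
    d1 <- (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
    d2 <- (bx - ax) * (dy - ay) - (by - ay) * (dx - ax)
    d3 <- (dx - cx) * (ay - cy) - (dy - cy) * (ax - cx)
    d4 <- (dx - cx) * (by - cy) - (dy - cy) * (bx - cx)
    if (any(d1 * d2 < 0 & d3 * d4 < 0)) return(FALSE)
  }
  TRUE
}

## ---- device circles ----------------------------------------------------

#' Construct a device circle
#'
#' Represents a burr, imaging catheter, or guidewire cross-section as a circle,
#' polygonized for clipping with a configurable vertex count (the inscribed
#' regular n-gon underestimates the disc area by less than 0.02% at the
#' default n = 360).
#'
#' @param center Numeric `c(x, y)` in mm.
#' @param diameter Diameter in mm (> 0).  Defaults to the nominal device size
#'   for `kind` "catheter" (0.9 mm) and "wire" (0.229 mm).
#' @param kind One of "burr", "catheter", "wire".
#' @param n_vertices Number of polygon vertices (default 360).
#' @return An object of class `ra_circle` with fields `center`, `diameter`,
#'   `kind`, and `ring` (the polygonized boundary, counter-clockwise).
#' @export
make_device_circle <- function(center, diameter = NULL,
                               kind = c("burr", "catheter", "wire"),
                               n_vertices = 360L) {
  kind <- match.arg(kind)
  if (is.null(diameter))
    diameter <- switch(kind, catheter = ra_catheter_diameter,
                       wire = ra_wire_diameter,
                       stop("burr diameter must be given"))
  if (!is.numeric(diameter) || length(diameter) != 1L || !is.finite(diameter) ||
      diameter <= 0)
    stop("diameter must be a positive finite number")
  if (length(center) != 2L || !all(is.finite(center)))
    stop("center must be finite c(x, y)")
  if (n_vertices < 12L) stop("n_vertices must be >= 12")
  th <- 2 * pi * (seq_len(n_vertices) - 1L) / n_vertices
  r <- diameter / 2
  structure(list(center = c(x = unname(center[1]), y = unname(center[2])),
                 diameter = diameter, kind = kind,
                 ring = list(x = unname(center[1]) + r * cos(th),
                             y = unname(center[2]) + r * sin(th))),
            class = "ra_circle")
}

#' @export
print.ra_circle <- function(x, ...) {
  cat(sprintf("<ra_circle %s: d = %.3f mm at (%.3f, %.3f)>\n",
              x$kind, x$diameter, x$center[1], x$center[2]))
  invisible(x)
}

## ---- regions -----------------------------------------------------------

# Internal: normalize any shape to a list of rings for clipping.
as_rings <- function(shape) {
  if (inherits(shape, "ra_region")) return(unclass(shape))
  if (inherits(shape, "ra_circle")) return(list(shape$ring))
  if (inherits(shape, "ra_polygon")) return(list(unclass(shape)))
  if (is.list(shape) && !is.null(shape$x)) return(list(shape))
  if (is.list(shape)) return(shape)
  stop("cannot interpret shape as polygon ring(s)")
}

new_region <- function(rings) structure(rings, class = "ra_region")

#' @export
print.ra_region <- function(x, ...) {
  cat(sprintf("<ra_region: %d ring(s), area %.4f mm^2>\n",
              length(unclass(x)), region_area(x)))
  invisible(x)
}

region_clip <- function(a, b, op) {
  ra <- as_rings(a); rb <- as_rings(b)
  # short-circuit empty operands (polyclip warns on empty coordinate ranges)
  if (length(ra) == 0L)
    return(new_region(if (op == "union") rb else list()))
  if (length(rb) == 0L)
    return(new_region(if (op == "intersection") list() else ra))
  out <- polyclip::polyclip(ra, rb, op, fillA = "evenodd", fillB = "evenodd")
  # clipping two shapes with (nearly) coincident boundary stretches can emit
  # hairline sliver rings: negligible area but a wide angular footprint
  out <- out[vapply(out, function(r) abs(signed_ring_area(r)) > 1e-8, logical(1))]
  new_region(out)
}

#' Predicted ablation region
#'
#' The part of a burr-sized circle that lies within the vessel wall on the
#' pre-procedural frame: the burr circle minus the lumen interior.  The circle
#' is centered at the imaging catheter (catheter-based prediction) or at the
#' guidewire (wire-based prediction); the caller chooses by constructing the
#' circle at the corresponding center.
#'
#' @param burr An `ra_circle` (burr-sized, at the prediction center).
#' @param pre_lumen The pre-procedural lumen contour (`ra_polygon`).
#' @return An `ra_region` (possibly empty).
#' @export
predicted_region <- function(burr, pre_lumen) {
  if (!inherits(burr, "ra_circle")) stop("burr must be an ra_circle")
  if (!inherits(pre_lumen, "ra_polygon")) stop("pre_lumen must be an ra_polygon")
  region_clip(burr, pre_lumen, "minus")
}

#' Actual ablation region
#'
#' Tissue removed by the burr: the post-procedural lumen minus the registered
#' pre-procedural lumen.  Any part of the pre lumen lying outside the post
#' lumen (apparent lumen loss, e.g. tissue prolapse) is not ablation; its area
#' is attached as attribute `lumen_loss_area` for diagnostics.
#'
#' @param pre_lumen,post_lumen Registered lumen contours (`ra_polygon`).
#' @return An `ra_region` with attribute `lumen_loss_area` (mm^2).
#' @export
actual_region <- function(pre_lumen, post_lumen) {
  if (!inherits(pre_lumen, "ra_polygon") || !inherits(post_lumen, "ra_polygon"))
    stop("pre_lumen and post_lumen must be ra_polygon objects")
  r <- region_clip(post_lumen, pre_lumen, "minus")
  attr(r, "lumen_loss_area") <- region_area(region_clip(pre_lumen, post_lumen, "minus"))
  r
}

#' Overlap of predicted and actual ablation
#'
#' @param p,a `ra_region` objects in the same frame coordinates.
#' @return Their intersection as an `ra_region`.
#' @export
overlap_region <- function(p, a) region_clip(p, a, "intersection")

#' Region area
#'
#' Sum of component ring areas with holes subtracted (holes carry negative
#' signed area).
#'
#' @param r An `ra_region`, `ra_polygon`, or `ra_circle`.
#' @return Area in mm^2 (>= 0).
#' @export
region_area <- function(r) {
  rings <- as_rings(r)
  if (length(rings) == 0L) return(0)
  a <- sum(vapply(rings, signed_ring_area, numeric(1)))
  max(a, 0)
}

## ---- angular extent ----------------------------------------------------

#' Angular extent of a region about a center
#'
#' Measure, in degrees, of the union of angular intervals subtended by the
#' region at `center` (typically the pre-procedural lumen centroid).  The
#' region must not contain the center.  Disconnected components contribute the
#' union of their intervals; wrap-around at 0/360 is merged.  The subtended
#' set of a filled polygon (holes included) equals the union over its boundary
#' edges of the short arcs between the edge-endpoint angles, which is computed
#' exactly here.
#'
#' @param r An `ra_region` (or polygon/circle).
#' @param center Numeric `c(x, y)` in mm.
#' @return Extent in degrees, in `[0, 360]`; 0 for an empty region.
#' @export
angular_extent <- function(r, center) {
  rings <- as_rings(r)
  if (length(rings) == 0L) return(0)
  if (point_in_region(center[1], center[2], rings))
    stop("center lies inside the region: angular extent undefined")
  iv <- NULL
  for (ring in rings) {
    dx <- ring$x - center[1]; dy <- ring$y - center[2]
    if (min(dx^2 + dy^2) < 1e-20)
      stop("region boundary passes through the center")
    ang <- atan2(dy, dx) * 180 / pi                 # (-180, 180]
    a1 <- ang; a2 <- c(ang[-1], ang[1])
    d <- (a2 - a1 + 180) %% 360 - 180               # signed short difference
    if (any(abs(abs(d) - 180) < 1e-9))
      stop("degenerate edge subtending 180 degrees at the center")
    lo <- ifelse(d >= 0, a1, a2) %% 360
    iv <- rbind(iv, cbind(lo, lo + abs(d)))
  }
  angular_union_measure(iv)
}

# Total measure of a union of circular intervals given as rows [start, end]
# with start in [0, 360) and end possibly > 360 (wrap).
angular_union_measure <- function(iv) {
  iv <- iv[iv[, 2] - iv[, 1] > 0, , drop = FALSE]
  if (nrow(iv) == 0L) return(0)
  if (any(iv[, 2] - iv[, 1] >= 360)) return(360)
  # split wrapped intervals at 360
  wrap <- iv[, 2] > 360
  if (any(wrap)) {
    split1 <- cbind(iv[wrap, 1], 360)
    split2 <- cbind(0, iv[wrap, 2] - 360)
    iv <- rbind(iv[!wrap, , drop = FALSE], split1, split2)
  }
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  tot <- 0; cur_lo <- iv[1, 1]; cur_hi <- iv[1, 2]
  for (i in seq_len(nrow(iv))[-1]) {
    if (iv[i, 1] <= cur_hi) cur_hi <- max(cur_hi, iv[i, 2])
    else { tot <- tot + cur_hi - cur_lo; cur_lo <- iv[i, 1]; cur_hi <- iv[i, 2] }
  }
  min(tot + cur_hi - cur_lo, 360)
}

## ---- point classification (also used by test oracles) ------------------

#' Point-in-region test (even-odd rule)
#'
#' Crossing-number classification of points against a set of rings.  Exposed
#' because Monte-Carlo validation of the clipping-based areas relies on it as
#' an independent primitive.
#'
#' @param px,py Point coordinates (vectors, mm).
#' @param shape Rings in any of the accepted shape forms.
#' @return Logical vector.
#' @export
point_in_region <- function(px, py, shape) {
  rings <- as_rings(shape)
  inside <- rep(FALSE, length(px))
  for (ring in rings)
    inside <- xor(inside, .pip_ring(px, py, ring$x, ring$y))
  inside
}

## ---- clearances --------------------------------------------------------

# Minimum distance from points to a polyline boundary (segments), vectorized
# over segments for each point set chunk.
dist_points_to_ring <- function(px, py, ring) {
  x1 <- ring$x; y1 <- ring$y
  x2 <- c(x1[-1], x1[1]); y2 <- c(y1[-1], y1[1])
  ex <- x2 - x1; ey <- y2 - y1
  len2 <- ex^2 + ey^2
  out <- numeric(length(px))
  for (i in seq_along(px)) {
    t <- ((px[i] - x1) * ex + (py[i] - y1) * ey) / len2
    t <- pmin(pmax(t, 0), 1)
    out[i] <- sqrt(min((px[i] - (x1 + t * ex))^2 + (py[i] - (y1 + t * ey))^2))
  }
  out
}

# do any segments of ring a cross segments of ring b?
rings_cross <- function(a, b) {
  ax1 <- a$x; ay1 <- a$y; ax2 <- c(ax1[-1], ax1[1]); ay2 <- c(ay1[-1], ay1[1])
  bx1 <- b$x; by1 <- b$y; bx2 <- c(bx1[-1], bx1[1]); by2 <- c(by1[-1], by1[1])
  for (i in seq_along(ax1)) {
    d1 <- (ax2[i] - ax1[i]) * (by1 - ay1[i]) - (ay2[i] - ay1[i]) * (bx1 - ax1[i])
    d2 <- (ax2[i] - ax1[i]) * (by2 - ay1[i]) - (ay2[i] - ay1[i]) * (bx2 - ax1[i])
    d3 <- (bx2 - bx1) * (ay1[i] - by1) - (by2 - by1) * (ax1[i] - bx1)
    d4 <- (bx2 - bx1) * (ay2[i] - by1) - (by2 - by1) * (ax2[i] - bx1)
    if (any(d1 * d2 <= 0 & d3 * d4 <= 0)) return(TRUE)
  }
  FALSE
}

min_ring_ring_dist <- function(a, b) {
  if (rings_cross(a, b)) return(0)
  min(min(dist_points_to_ring(a$x, a$y, b)),
      min(dist_points_to_ring(b$x, b$y, a)))
}

#' Minimum device clearance
#'
#' Edge-to-edge (surface-to-surface) minimum distance between two shapes,
#' clamped at zero on contact.  Device circles are treated as solid discs
#' (two overlapping devices have clearance 0); a bare polygon stands for a
#' boundary curve such as the intimal border, so the clearance of a device
#' lying inside the lumen is the gap between the device surface and the
#' contour.  Circles are handled analytically; polygon pairs by exact
#' segment-segment distance.
#'
#' @param a,b `ra_circle` or `ra_polygon` objects.
#' @return Clearance in mm (>= 0).
#' @export
min_clearance <- function(a, b) {
  ca <- inherits(a, "ra_circle"); cb <- inherits(b, "ra_circle")
  if (ca && cb) {
    d <- sqrt(sum((a$center - b$center)^2))
    return(max(0, d - a$diameter / 2 - b$diameter / 2))
  }
  if (ca || cb) {
    circ <- if (ca) a else b
    poly <- if (ca) b else a
    d <- min(dist_points_to_ring(circ$center[1], circ$center[2], as_rings(poly)[[1]]))
    return(max(0, d - circ$diameter / 2))
  }
  min_ring_ring_dist(as_rings(a)[[1]], as_rings(b)[[1]])
}

## ---- lumen diameters ---------------------------------------------------

#' Lumen diameters through the centroid
#'
#' Full chord lengths through the lumen centroid at 1 degree steps over
#' 0-179 degrees.  For a non-convex contour a chord may exit and re-enter the
#' lumen; the total in-lumen length is used and the occurrence counted.
#'
#' @param lumen An `ra_polygon`.
#' @param step_deg Angular step of the chord fan (default 1 degree).
#' @return List with `min_diameter`, `mean_diameter` (mm), `area` (mm^2), and
#'   `n_reentrant` (number of chords that crossed the boundary more than
#'   twice).
#' @export
lumen_diameters <- function(lumen, step_deg = 1) {
  if (!inherits(lumen, "ra_polygon")) stop("lumen must be an ra_polygon")
  area <- polygon_area(lumen)
  if (area < 1e-6) stop("degenerate lumen (area < 1e-6 mm^2)")
  ctr <- ring_centroid(lumen)
  x1 <- lumen$x - ctr[1]; y1 <- lumen$y - ctr[2]
  x2 <- c(x1[-1], x1[1]); y2 <- c(y1[-1], y1[1])
  angles <- seq(0, 180 - step_deg, by = step_deg) * pi / 180
  chords <- numeric(length(angles))
  n_reentrant <- 0L
  for (i in seq_along(angles)) {
    cth <- cos(angles[i]); sth <- sin(angles[i])
    p1 <- x1 * sth - y1 * cth
    p2 <- x2 * sth - y2 * cth
    hit <- (p1 > 0) != (p2 > 0)
    if (!any(hit)) { chords[i] <- 0; next }
    t <- p1[hit] / (p1[hit] - p2[hit])
    r <- (x1[hit] + t * (x2[hit] - x1[hit])) * cth +
         (y1[hit] + t * (y2[hit] - y1[hit])) * sth
    r <- sort(r)
    m <- length(r) %/% 2L * 2L   # guard odd counts from grazing hits
    if (m == 0L) { chords[i] <- 0; next }
    r <- r[seq_len(m)]
    if (m > 2L) n_reentrant <- n_reentrant + 1L
    chords[i] <- sum(r[seq(2, m, by = 2)] - r[seq(1, m, by = 2)])
  }
  list(min_diameter = min(chords), mean_diameter = mean(chords),
       area = area, n_reentrant = n_reentrant)
}
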