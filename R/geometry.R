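# Planar geometry primitives for home-range work. Coordinates are km
# throughout the package; no geodesy (study areas are small).

#' Polygon area by the shoelace formula
#'
#' @param poly two-column matrix of vertices (closed or open ring).
#' @return area in squared coordinate units.
#' @export
polygon_area <- function(poly) {
  poly <- as.matrix(poly)
  if (nrow(poly) < 3L) return(0)
  x <- poly[, 1L]; y <- poly[, 2L]
  j <- c(seq_len(nrow(poly))[-1L], 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

#' Convex hull of a point set
#'
#' @param pts two-column matrix.
#' @return vertex matrix in counterclockwise order.
#' @export
convex_hull <- function(pts) {
  pts <- as.matrix(pts)
  idx <- grDevices::chull(pts[, 1L], pts[, 2L])
  pts[rev(idx), , drop = FALSE] # chull returns clockwise; reverse to CCW
}

#' Test points against a simple polygon (even-odd rule)
#'
#' Boundary points count as inside (ties broken towards inclusion via a tiny
#' outward nudge of the test ray), which is the convention wanted when
#' assigning GPS fixes to a habitat polygon.
#'
#' @param pts two-column matrix of test points.
#' @param poly two-column vertex matrix.
#' @return logical vector.
#' @export
points_in_polygon <- function(pts, poly) {
  pts <- matrix(as.numeric(as.matrix(pts)), ncol = 2L)
  poly <- as.matrix(poly)
  n <- nrow(poly)
  out <- logical(nrow(pts))
  px <- poly[, 1L]; py <- poly[, 2L]
  for (i in seq_len(nrow(pts))) {
    x <- pts[i, 1L]; y <- pts[i, 2L]
    inside <- FALSE
    j <- n
    for (k in seq_len(n)) {
      if (((py[k] > y) != (py[j] > y)) &&
          (x < (px[j] - px[k]) * (y - py[k]) / (py[j] - py[k]) + px[k]))
        inside <- !inside
      j <- k
    }
    # boundary check: distance to each edge
    if (!inside) {
      j <- n
      for (k in seq_len(n)) {
        ex <- px[k] - px[j]; ey <- py[k] - py[j]
        L2 <- ex^2 + ey^2
        t <- if (L2 > 0) ((x - px[j]) * ex + (y - py[j]) * ey) / L2 else 0
        t <- min(max(t, 0), 1)
        dx <- x - (px[j] + t * ex); dy <- y - (py[j] + t * ey)
        if (dx * dx + dy * dy < 1e-18) { inside <- TRUE; break }
        j <- k
      }
    }
    out[i] <- inside
  }
  out
}

# Sutherland-Hodgman clip of polygon `subject` by convex polygon `clip`.
# Both as CCW vertex matrices. Returns possibly empty matrix.
clip_convex <- function(subject, clip) {
  outp <- as.matrix(subject)
  clip <- as.matrix(clip)
  nc <- nrow(clip)
  for (e in seq_len(nc)) {
    if (nrow(outp) == 0L) break
    a <- clip[e, ]; b <- clip[if (e == nc) 1L else e + 1L, ]
    inp <- outp
    outp <- matrix(numeric(0), ncol = 2L)
    np <- nrow(inp)
    side <- function(p) (b[1L] - a[1L]) * (p[2L] - a[2L]) - (b[2L] - a[2L]) * (p[1L] - a[1L])
    for (i in seq_len(np)) {
      cur <- inp[i, ]; prv <- inp[if (i == 1L) np else i - 1L, ]
      cs <- side(cur); ps <- side(prv)
      if (cs >= 0) {
        if (ps < 0) {
          t <- ps / (ps - cs)
          outp <- rbind(outp, prv + t * (cur - prv))
        }
        outp <- rbind(outp, cur)
      } else if (ps >= 0) {
        t <- ps / (ps - cs)
        outp <- rbind(outp, prv + t * (cur - prv))
      }
    }
  }
  outp
}

#' Area of intersection of two convex polygons
#'
#' @param a,b convex polygons as counterclockwise vertex matrices.
#' @return intersection area (0 if disjoint).
#' @export
convex_intersection_area <- function(a, b) {
  inter <- clip_convex(a, b)
  if (nrow(inter) < 3L) 0 else polygon_area(inter)
}
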