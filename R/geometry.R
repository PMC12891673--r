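#' Planar geometry for river-crossing analysis
#'
#' Primitives used throughout the pipeline: proper intersection counts
#' between a dispersal segment and a river polyline, the odd-parity
#' crossing rule, Euclidean dispersal distances, and dispersal angles
#' folded against a reference line.
#'
#' All coordinates are planar metres in a projected CRS (x = easting,
#' y = northing). No geodesy is performed here.
#'
#' @name geometry
NULL

# 2D cross product of (b - a) x (c - a)
.cross2 <- function(ax, ay, bx, by, cx, cy) {
  (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
}

# Batch proper-intersection counts: N segments vs one polyline.
# x1,y1,x2,y2: numeric vectors (segment endpoints); poly: matrix (k x 2).
# Half-open orientation rule (">0" vs "<=0") makes a crossing through a
# shared polyline vertex count exactly once; collinear overlap counts 0.
# Segment endpoints lying exactly on the polyline are perturbed 1 mm
# toward the opposite endpoint before counting (documented degeneracy
# rule), applied recursively at most 3 times.
.seg_poly_count <- function(x1, y1, x2, y2, poly, .depth = 0L) {
  n <- length(x1)
  px <- poly[, 1]; py <- poly[, 2]
  k <- length(px)
  if (k < 2L) return(integer(n))
  hx <- px[-k]; hy <- py[-k]          # edge heads
  tx <- px[-1]; ty <- py[-1]          # edge tails
  ex <- tx - hx; ey <- ty - hy

  dx <- x2 - x1; dy <- y2 - y1

  # side of each polyline *vertex* w.r.t. each segment's supporting line
  dvert <- outer(dx, py) - outer(dy, px) + (dy * x1 - dx * y1)  # n x k
  s <- dvert > 0
  straddle_seg <- s[, -k, drop = FALSE] != s[, -1, drop = FALSE]  # n x (k-1)

  # side of each segment endpoint w.r.t. each polyline edge
  cc <- ey * hx - ex * hy  # constant per edge
  d3 <- outer(y1, ex) - outer(x1, ey) + rep(cc, each = n)
  d4 <- outer(y2, ex) - outer(x2, ey) + rep(cc, each = n)

  # endpoint exactly on an edge (collinear and inside edge bounding box)
  if (.depth < 3L) {
    scale <- abs(ex) + abs(ey)
    tol <- rep(1e-9 * pmax(scale, 1), each = n)
    on1 <- abs(d3) <= tol &
      outer(x1, pmin(hx, tx), ">=") & outer(x1, pmax(hx, tx), "<=") &
      outer(y1, pmin(hy, ty), ">=") & outer(y1, pmax(hy, ty), "<=")
    on2 <- abs(d4) <= tol &
      outer(x2, pmin(hx, tx), ">=") & outer(x2, pmax(hx, tx), "<=") &
      outer(y2, pmin(hy, ty), ">=") & outer(y2, pmax(hy, ty), "<=")
    bad1 <- rowSums(on1) > 0
    bad2 <- rowSums(on2) > 0
    if (any(bad1) || any(bad2)) {
      len <- sqrt(dx^2 + dy^2)
      eps <- 1e-3  # 1 mm
      nx1 <- x1; ny1 <- y1; nx2 <- x2; ny2 <- y2
      nx1[bad1] <- x1[bad1] + eps * dx[bad1] / len[bad1]
      ny1[bad1] <- y1[bad1] + eps * dy[bad1] / len[bad1]
      nx2[bad2] <- x2[bad2] - eps * dx[bad2] / len[bad2]
      ny2[bad2] <- y2[bad2] - eps * dy[bad2] / len[bad2]
      redo <- bad1 | bad2
      out <- integer(n)
      keep <- !redo
      if (any(keep)) {
        out[keep] <- .seg_poly_count(x1[keep], y1[keep], x2[keep], y2[keep],
                                     poly, .depth = 3L)
      }
      out[redo] <- .seg_poly_count(nx1[redo], ny1[redo], nx2[redo], ny2[redo],
                                   poly, .depth = .depth + 1L)
      return(out)
    }
  }

  straddle_riv <- (d3 > 0) != (d4 > 0)
  as.integer(rowSums(straddle_seg & straddle_riv))
}

#' Count proper intersections between a segment and a polyline
#'
#' Counts transversal intersection points between the segment
#' `p1`--`p2` and a river polyline. A segment endpoint lying exactly on
#' the polyline is perturbed by 1 mm toward the other endpoint before
#' counting; collinear overlap contributes no intersections.
#'
#' @param p1,p2 numeric length-2 vectors, `(x, y)` in metres; must differ.
#' @param polyline two-column numeric matrix of vertices.
#' @return integer intersection count.
#' @export
segment_polyline_intersections <- function(p1, p2, polyline) {
  stopifnot(length(p1) == 2, length(p2) == 2)
  if (all(p1 == p2)) stop("segment endpoints coincide; intersection count undefined")
  polyline <- as.matrix(polyline)
  if (nrow(polyline) < 2) stop("polyline needs at least 2 vertices")
  .seg_poly_count(p1[1], p1[2], p2[1], p2[2], polyline)
}

# Batch odd-parity crossing counts for N segments against all rivers.
# p1, p2: N x 2 matrices. Returns integer vector in 0..n_rivers.
.rivers_crossed_batch <- function(p1, p2, rivers) {
  n <- nrow(p1)
  out <- integer(n)
  for (rv in rivers$rivers) {
    cnt <- .seg_poly_count(p1[, 1], p1[, 2], p2[, 1], p2[, 2], rv$polyline)
    out <- out + (cnt %% 2L)
  }
  out
}

#' Number of rivers crossed by a dispersal segment
#'
#' A river counts as crossed only if the segment intersects its polyline
#' an odd number of times, i.e. the endpoints lie on opposite banks. A
#' meander intersected back and forth (even parity) leaves the endpoints
#' on the same bank and counts as not crossed.
#'
#' @param p1,p2 numeric length-2 coordinates in metres; must differ.
#' @param rivers a [river_set()].
#' @return integer in `0..n_rivers`.
#' @export
rivers_crossed <- function(p1, p2, rivers) {
  stopifnot(inherits(rivers, "river_set"))
  if (all(p1 == p2)) stop("segment endpoints coincide; crossing count undefined")
  if (length(rivers$rivers) == 0) return(0L)
  .rivers_crossed_batch(matrix(p1, 1), matrix(p2, 1), rivers)
}

#' Euclidean dispersal distance in kilometres
#'
#' @param p1,p2 coordinates in metres.
#' @return distance in km.
#' @export
dispersal_distance_km <- function(p1, p2) {
  sqrt(sum((p2 - p1)^2)) / 1000
}

#' Dispersal angle relative to the reference line
#'
#' Acute angle, in degrees within `[0, 90]`, between the undirected line
#' through `p1` and `p2` and the undirected reference line whose azimuth
#' (degrees clockwise from north) is `reference_azimuth_deg`.
#'
#' @param p1,p2 coordinates in metres; must differ.
#' @param reference_azimuth_deg reference-line azimuth in degrees.
#' @return angle in degrees, `[0, 90]`.
#' @export
dispersal_angle_deg <- function(p1, p2, reference_azimuth_deg) {
  d <- c(p2[1] - p1[1], p2[2] - p1[2])
  len <- sqrt(sum(d^2))
  if (len == 0) stop("zero-length displacement; angle undefined")
  az <- reference_azimuth_deg * pi / 180
  u <- c(sin(az), cos(az))  # unit vector of the reference line
  cosang <- abs(sum(d * u)) / len
  cosang <- min(max(cosang, -1), 1)
  acos(cosang) * 180 / pi
}

#' Classify a dispersal angle into direction D1 or D2
#'
#' D1 ("orthogonal to rivers") for angles less than or equal to 45
#' degrees from the reference line; D2 ("parallel to rivers") otherwise.
#'
#' @param angle_deg angle in `[0, 90]` (vectorised; `NA` passes through).
#' @return character vector of `"D1"`/`"D2"`.
#' @export
classify_direction <- function(angle_deg) {
  ifelse(is.na(angle_deg), NA_character_, ifelse(angle_deg <= 45, "D1", "D2"))
}

#' Band (region) index of points relative to the river set
#'
#' Region 1 lies south of the first river; region `n_rivers + 1` north of
#' the last. Computed by crossing parity against an anchor far south of
#' the river extent, so it is consistent with [rivers_crossed()] for any
#' simple river spanning the extent.
#'
#' @param points two-column matrix of coordinates (metres).
#' @param rivers a [river_set()].
#' @return integer vector of band indices in `1..(n_rivers + 1)`.
#' @export
assign_bands <- function(points, rivers) {
  points <- rbind(points)
  if (length(rivers$rivers) == 0) return(rep(1L, nrow(points)))
  ylo <- min(vapply(rivers$rivers, function(r) min(r$polyline[, 2]), 0))
  yhi <- max(vapply(rivers$rivers, function(r) max(r$polyline[, 2]), 0))
  anchor_y <- ylo - (yhi - ylo) - 1e4
  p2 <- cbind(points[, 1] + 0.5,  # generic offset avoids vertex alignment
              rep(anchor_y, nrow(points)))
  1L + .rivers_crossed_batch(points, p2, rivers)
}
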