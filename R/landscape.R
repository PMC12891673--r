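#' River sets and synthetic landscapes
#'
#' A `river_set` holds ordered, named river polylines (south to north)
#' plus the azimuth of the reference line used for dispersal angles
#' ("orthogonal to rivers"). Synthetic landscapes mimic a study region
#' divided into parallel bands by a few sub-parallel rivers running the
#' full width of a rectangular extent.
#'
#' @name landscape
NULL

#' Construct a river set
#'
#' @param rivers list of `list(name =, polyline = <k x 2 matrix>)`,
#'   ordered south to north. May be empty.
#' @param reference_azimuth_deg azimuth (degrees clockwise from north) of
#'   the reference line orthogonal to the mean river course. If `NULL`
#'   and rivers are present, computed as the length-weighted mean river
#'   segment azimuth plus 90 degrees (modulo 180).
#' @param extent optional `c(xmin, xmax, ymin, ymax)` in metres.
#' @param validate verify polyline simplicity and pairwise
#'   non-intersection (brute force over segment pairs).
#' @return object of class `river_set`.
#' @export
river_set <- function(rivers = list(), reference_azimuth_deg = NULL,
                      extent = NULL, validate = TRUE) {
  for (rv in rivers) {
    if (is.null(rv$name) || !nzchar(rv$name)) stop("every river needs a name")
    if (!is.matrix(rv$polyline) || ncol(rv$polyline) != 2 || nrow(rv$polyline) < 2)
      stop("river '", rv$name, "': polyline must be a k x 2 matrix, k >= 2")
    if (any(!is.finite(rv$polyline)))
      stop("river '", rv$name, "': non-finite vertex")
  }
  nms <- vapply(rivers, `[[`, "", "name")
  if (anyDuplicated(nms)) stop("river names must be unique")
  obj <- structure(list(rivers = rivers,
                        reference_azimuth_deg = reference_azimuth_deg,
                        extent = extent),
                   class = "river_set")
  if (is.null(reference_azimuth_deg) && length(rivers) > 0)
    obj$reference_azimuth_deg <- mean_course_azimuth(obj) + 90
  if (validate) validate_river_set(obj)
  obj
}

#' @export
print.river_set <- function(x, ...) {
  cat("<river_set> ", length(x$rivers), " river(s); reference azimuth ",
      if (is.null(x$reference_azimuth_deg)) "unset" else
        sprintf("%.1f deg", x$reference_azimuth_deg), "\n", sep = "")
  for (rv in x$rivers)
    cat("  ", rv$name, ": ", nrow(rv$polyline), " vertices\n", sep = "")
  invisible(x)
}

# Length-weighted mean azimuth of river segments, folded to [0, 180).
mean_course_azimuth <- function(rivers) {
  sx <- 0; sy <- 0
  for (rv in rivers$rivers) {
    p <- rv$polyline
    dx <- diff(p[, 1]); dy <- diff(p[, 2])
    len <- sqrt(dx^2 + dy^2)
    # double-angle trick: undirected axes average on the doubled circle
    th <- 2 * atan2(dx, dy)
    sx <- sx + sum(len * sin(th)); sy <- sy + sum(len * cos(th))
  }
  (atan2(sx, sy) / 2 * 180 / pi) %% 180
}

# brute-force simplicity + pairwise non-intersection check
#' Validate a river set's geometry
#'
#' Checks every polyline is simple (no self-intersection) and that
#' distinct rivers do not intersect, by testing all segment pairs.
#'
#' @param rivers a [river_set()].
#' @return invisibly `TRUE`; errors on violation.
#' @export
validate_river_set <- function(rivers) {
  polys <- lapply(rivers$rivers, `[[`, "polyline")
  segs <- function(p) cbind(p[-nrow(p), , drop = FALSE], p[-1, , drop = FALSE])
  for (i in seq_along(polys)) {
    p <- polys[[i]]
    m <- nrow(p) - 1  # segment count
    if (m >= 3) {
      for (a in seq_len(m - 2)) {
        # test segment a against all non-adjacent later segments
        sub <- p[(a + 2):(m + 1), , drop = FALSE]
        cnt <- .seg_poly_count(p[a, 1], p[a, 2], p[a + 1, 1], p[a + 1, 2], sub)
        if (cnt > 0)
          stop("river '", rivers$rivers[[i]]$name, "' is self-intersecting")
      }
    }
  }
  if (length(polys) >= 2) {
    for (i in seq_len(length(polys) - 1)) for (j in (i + 1):length(polys)) {
      s <- segs(polys[[i]])
      cnt <- .seg_poly_count(s[, 1], s[, 2], s[, 3], s[, 4], polys[[j]])
      if (sum(cnt) > 0)
        stop("rivers '", rivers$rivers[[i]]$name, "' and '",
             rivers$rivers[[j]]$name, "' intersect")
    }
  }
  invisible(TRUE)
}

#' Specify a synthetic landscape
#'
#' Rectangular extent crossed west-to-east by `n_rivers` sub-parallel
#' rivers, generated as sinusoidal perturbations of evenly spaced
#' horizontal baselines. With the default spacing the rivers divide the
#' extent into `n_rivers + 1` bands of equal height.
#'
#' @param extent `c(xmin, xmax, ymin, ymax)` metres. Default a
#'   400 x 300 km region.
#' @param n_rivers number of rivers (default 3).
#' @param river_spacing metres between river baselines; default
#'   `height / (n_rivers + 1)`.
#' @param meander_amplitude,meander_wavelength metres; amplitude must
#'   stay below 45% of the spacing so rivers cannot meet.
#' @param reference_azimuth_deg optional override of the reference-line
#'   azimuth (degrees from north).
#' @return object of class `landscape_spec`.
#' @export
landscape_spec <- function(extent = c(0, 400e3, 0, 300e3), n_rivers = 3,
                           river_spacing = NULL,
                           meander_amplitude = 8e3, meander_wavelength = 80e3,
                           reference_azimuth_deg = NULL) {
  if (n_rivers < 0) stop("n_rivers must be >= 0")
  h <- extent[4] - extent[3]
  if (is.null(river_spacing)) river_spacing <- h / (n_rivers + 1)
  if (n_rivers > 0 && river_spacing * (n_rivers + 1) > h + 1e-9)
    stop("river_spacing * (n_rivers + 1) exceeds the extent height")
  if (n_rivers > 1 && meander_amplitude > 0.45 * river_spacing)
    stop("meander_amplitude too large relative to river_spacing")
  structure(list(extent = extent, n_rivers = n_rivers,
                 river_spacing = river_spacing,
                 meander_amplitude = meander_amplitude,
                 meander_wavelength = meander_wavelength,
                 reference_azimuth_deg = reference_azimuth_deg),
            class = "landscape_spec")
}

#' Generate a synthetic river landscape
#'
#' @param spec a [landscape_spec()].
#' @param seed integer seed (random meander phases).
#' @return a [river_set()] with rivers named `"River 1"` (southernmost)
#'   upwards, and the landscape extent attached.
#' @export
generate_landscape <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "landscape_spec"))
  set.seed(seed)
  e <- spec$extent
  n <- spec$n_rivers
  rivers <- list()
  if (n > 0) {
    phases <- stats::runif(n, 0, 2 * pi)
    for (i in seq_len(n)) {
      y0 <- e[3] + spec$river_spacing * i
      if (spec$meander_amplitude > 0) {
        step <- spec$meander_wavelength / 16
        xs <- seq(e[1], e[2], by = step)
        if (xs[length(xs)] < e[2]) xs <- c(xs, e[2])
      } else {
        xs <- c(e[1], e[2])
      }
      ys <- y0 + spec$meander_amplitude *
        sin(2 * pi * xs / spec$meander_wavelength + phases[i])
      rivers[[i]] <- list(name = paste("River", i), polyline = cbind(xs, ys))
    }
  }
  river_set(rivers, reference_azimuth_deg = spec$reference_azimuth_deg,
            extent = e, validate = TRUE)
}
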