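#' File formats
#'
#' Genotype tables travel as CSV with one row per fecal sample: fixed
#' columns `sample_id, x, y, year`, sexing-marker columns `Y1..Y4` and
#' `X1..X3` (0/1 amplification calls), then one column per autosomal
#' locus holding `"A/T"`-style unordered calls (`""` = missing).
#' Coordinates are projected planar metres (x = easting, y = northing);
#' no reprojection happens in the package. Rivers travel as GeoJSON
#' LineString/MultiLineString features with a `name` property, or as a
#' WKT file with one `LINESTRING` per line.
#'
#' @name pipeline_io
NULL

.fixed_cols <- c("sample_id", "x", "y", "year")
.marker_cols <- c(paste0("Y", 1:4), paste0("X", 1:3))

#' Write a sample set to genotype CSV
#'
#' @param samples a `sample_set`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genotype_csv <- function(samples, path) {
  stopifnot(inherits(samples, "sample_set"))
  panel <- samples$panel
  g <- samples$geno
  calls <- matrix("", nrow(g), ncol(g), dimnames = dimnames(g))
  for (j in seq_len(ncol(g))) {
    a1 <- panel$a1[j]; a2 <- panel$a2[j]
    v <- g[, j]
    calls[, j] <- ifelse(is.na(v), "",
                  ifelse(v == 0, paste0(a1, "/", a1),
                  ifelse(v == 1, paste0(a1, "/", a2), paste0(a2, "/", a2))))
  }
  df <- cbind(samples$meta[, c("sample_id", "x", "y", "year")],
              as.data.frame(samples$sex_markers),
              as.data.frame(calls, stringsAsFactors = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a genotype CSV into a sample set
#'
#' Malformed rows (non-numeric coordinates, call syntax errors, alleles
#' outside a locus's biallelic alphabet) are reported with their line
#' numbers. Locus columns are every column after the fixed and marker
#' columns; each locus's two alleles are taken from the panel if given,
#' otherwise inferred from the observed calls (alphabetical order fixes
#' the dosage coding, so write/read round-trips are lossless).
#'
#' @param path CSV file.
#' @param panel optional panel data.frame (`locus`, `a1`, `a2`).
#' @return a `sample_set`.
#' @export
read_genotypes <- function(path, panel = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  miss <- setdiff(c("sample_id", "x", "y"), names(df))
  if (length(miss)) stop("genotype CSV lacks column(s): ", paste(miss, collapse = ", "))
  locus_cols <- setdiff(names(df), c(.fixed_cols, .marker_cols))
  if (length(locus_cols) == 0) stop("no locus columns found")
  if (!is.null(panel)) {
    unknown <- setdiff(locus_cols, panel$locus)
    if (length(unknown))
      stop("unknown locus column(s) not in panel: ", paste(unknown, collapse = ", "))
    locus_cols <- intersect(panel$locus, locus_cols)
  }
  n <- nrow(df)
  line <- seq_len(n) + 1L  # header is line 1
  x <- suppressWarnings(as.numeric(df$x)); y <- suppressWarnings(as.numeric(df$y))
  bad <- which(is.na(x) | is.na(y) | !is.finite(x) | !is.finite(y))
  if (length(bad))
    stop("non-numeric coordinates at line(s) ", paste(line[bad], collapse = ", "))

  calls <- as.matrix(df[, locus_cols, drop = FALSE])
  okfmt <- calls == "" | grepl("^[A-Z]/[A-Z]$", calls)
  if (!all(okfmt)) {
    badrow <- unique(which(!okfmt, arr.ind = TRUE)[, 1])
    stop("bad call syntax at line(s) ", paste(line[badrow], collapse = ", "),
         " (expected \"A/T\" style or empty)")
  }
  if (is.null(panel)) {
    al <- lapply(seq_along(locus_cols), function(j) {
      v <- calls[, j]; v <- v[v != ""]
      sort(unique(unlist(strsplit(v, "/", fixed = TRUE))))
    })
    if (any(vapply(al, length, 0L) > 2)) {
      badl <- locus_cols[vapply(al, length, 0L) > 2]
      stop("more than two alleles observed at locus(es): ",
           paste(badl, collapse = ", "))
    }
    panel <- data.frame(locus = locus_cols,
                        a1 = vapply(al, function(a) if (length(a)) a[1] else "A", ""),
                        a2 = vapply(al, function(a) if (length(a) == 2) a[2] else "?", ""),
                        stringsAsFactors = FALSE)
  }
  g <- matrix(NA_integer_, n, length(locus_cols),
              dimnames = list(df$sample_id, locus_cols))
  for (j in seq_along(locus_cols)) {
    pj <- panel[panel$locus == locus_cols[j], ]
    v <- calls[, j]
    known <- c(paste0(pj$a1, "/", pj$a1), paste0(pj$a1, "/", pj$a2),
               paste0(pj$a2, "/", pj$a2), paste0(pj$a2, "/", pj$a1))
    badal <- which(v != "" & !(v %in% known))
    if (length(badal))
      stop("alleles outside panel alphabet for locus ", locus_cols[j],
           " at line(s) ", paste(line[badal], collapse = ", "))
    g[, j] <- c(0L, 1L, 2L, 1L, NA_integer_)[match(v, c(known, ""))]
  }
  sexm <- matrix(0L, n, length(.marker_cols),
                 dimnames = list(NULL, .marker_cols))
  for (mc in intersect(.marker_cols, names(df)))
    sexm[, mc] <- as.integer(df[[mc]])
  meta <- data.frame(sample_id = df$sample_id,
                     true_individual_id = NA_character_, x = x, y = y,
                     year = if ("year" %in% names(df))
                       suppressWarnings(as.integer(df$year)) else NA_integer_,
                     stringsAsFactors = FALSE)
  structure(list(meta = meta, sex_markers = sexm, geno = g,
                 panel = panel[match(locus_cols, panel$locus), ], seed = NA),
            class = "sample_set")
}

#' Write rivers as GeoJSON LineString features
#'
#' @param rivers a [river_set()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_rivers_geojson <- function(rivers, path) {
  feats <- lapply(rivers$rivers, function(rv) {
    list(type = "Feature",
         properties = list(name = rv$name),
         geometry = list(type = "LineString",
                         coordinates = unname(apply(rv$polyline, 1, as.list,
                                                    simplify = FALSE))))
  })
  gj <- list(type = "FeatureCollection",
             properties = list(reference_azimuth_deg = rivers$reference_azimuth_deg),
             features = feats)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

.merge_multilinestring <- function(parts, name) {
  poly <- parts[[1]]
  for (p in parts[-1]) {
    if (all(abs(poly[nrow(poly), ] - p[1, ]) < 1e-6)) {
      poly <- rbind(poly, p[-1, , drop = FALSE])
    } else if (all(abs(poly[nrow(poly), ] - p[nrow(p), ]) < 1e-6)) {
      poly <- rbind(poly, p[rev(seq_len(nrow(p) - 1)), , drop = FALSE])
    } else {
      stop("MultiLineString parts of river '", name,
           "' do not touch end-to-end; cannot merge")
    }
  }
  poly
}

#' Read rivers from GeoJSON or WKT
#'
#' GeoJSON FeatureCollections of LineString/MultiLineString features
#' (with a `name` property) are read in file order; MultiLineString
#' parts are merged when consecutive parts touch end-to-end, otherwise
#' an error is raised. A WKT file holds one `LINESTRING (x y, ...)` per
#' line, optionally prefixed `name;LINESTRING (...)`. Geometry must be
#' in the same projected CRS as the genotype coordinates.
#'
#' @param path input file (`.geojson`/`.json` or WKT text).
#' @param reference_azimuth_deg optional override of the reference-line
#'   azimuth.
#' @return a [river_set()] (simplicity validated).
#' @export
read_rivers <- function(path, reference_azimuth_deg = NULL) {
  first <- readLines(path, n = 1, warn = FALSE)
  is_json <- grepl("^\\s*\\{", first) ||
    grepl("\\.(geo)?json$", path, ignore.case = TRUE)
  if (is_json) {
    gj <- jsonlite::read_json(path)
    if (is.null(gj$type) || gj$type != "FeatureCollection")
      stop("expected a GeoJSON FeatureCollection")
    rivers <- lapply(gj$features, function(f) {
      nm <- f$properties$name
      if (is.null(nm)) stop("river feature lacks a 'name' property")
      gt <- f$geometry$type
      to_mat <- function(coords)
        do.call(rbind, lapply(coords, function(pt) c(pt[[1]], pt[[2]])))
      poly <- switch(gt,
        LineString = to_mat(f$geometry$coordinates),
        MultiLineString = .merge_multilinestring(
          lapply(f$geometry$coordinates, to_mat), nm),
        stop("unsupported geometry type '", gt, "' for river '", nm, "'"))
      list(name = nm, polyline = poly)
    })
    if (is.null(reference_azimuth_deg) &&
        !is.null(gj$properties$reference_azimuth_deg))
      reference_azimuth_deg <- gj$properties$reference_azimuth_deg
  } else {
    lines <- trimws(readLines(path, warn = FALSE))
    lines <- lines[nzchar(lines)]
    rivers <- lapply(seq_along(lines), function(i) {
      ln <- lines[i]
      nm <- if (grepl(";", ln, fixed = TRUE))
        trimws(sub(";.*$", "", ln)) else paste("River", i)
      wkt <- sub("^[^;]*;", "", ln)
      m <- regmatches(wkt, regexec("^\\s*LINESTRING\\s*\\((.*)\\)\\s*$", wkt,
                                   ignore.case = TRUE))[[1]]
      if (length(m) < 2) stop("line ", i, ": not a WKT LINESTRING")
      pts <- strsplit(trimws(strsplit(m[2], ",")[[1]]), "\\s+")
      poly <- do.call(rbind, lapply(pts, function(p) as.numeric(p[1:2])))
      if (any(is.na(poly))) stop("line ", i, ": unparseable coordinates")
      list(name = nm, polyline = poly)
    })
  }
  river_set(rivers, reference_azimuth_deg = reference_azimuth_deg,
            validate = TRUE)
}

#' Warn when sample and river bounding boxes do not overlap
#'
#' A cheap guard against mixed coordinate reference systems.
#'
#' @param samples a `sample_set`.
#' @param rivers a [river_set()].
#' @return `TRUE` (overlap) or `FALSE` (warned), invisibly.
#' @export
check_crs_overlap <- function(samples, rivers) {
  if (length(rivers$rivers) == 0) return(invisible(TRUE))
  rb <- sapply(rivers$rivers, function(rv) c(range(rv$polyline[, 1]),
                                             range(rv$polyline[, 2])))
  riv <- c(min(rb[1, ]), max(rb[2, ]), min(rb[3, ]), max(rb[4, ]))
  sx <- range(samples$meta$x); sy <- range(samples$meta$y)
  ok <- sx[1] <= riv[2] && sx[2] >= riv[1] && sy[1] <= riv[4] && sy[2] >= riv[3]
  if (!ok)
    warning("sample and river bounding boxes do not overlap; ",
            "check that both use the same projected CRS")
  invisible(ok)
}

#' Write synthetic ground truth as JSON
#'
#' @param truth a `synthetic_truth`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  out <- list(pedigree = truth$pedigree,
              relationships = truth$relationships,
              allele_freqs = truth$allele_freqs,
              coords = if (is.null(truth$coords)) NULL else
                data.frame(individual_id = rownames(truth$coords),
                           x = truth$coords[, 1], y = truth$coords[, 2]),
              crossings = truth$crossings,
              seed = truth$seed)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
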