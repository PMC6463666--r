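# Planar polygon helpers. Polygons are open rings: an n x 2 matrix of vertex
# coordinates in CRS units (metres), implicitly closed. The field layouts the
# simulator produces are axis-aligned rectangles, but everything here accepts
# arbitrary simple polygons except poly_shrink(), which requires convexity.

#' @keywords internal
ring_close <- function(ring) {
  if (!all(ring[1, ] == ring[nrow(ring), ])) ring <- rbind(ring, ring[1, ])
  ring
}

#' Polygon area, centroid and bounding box
#'
#' Shoelace-formula area (always positive) and area-weighted centroid of a
#' simple polygon given as an open ring.
#'
#' @param ring numeric n x 2 matrix of vertices.
#' @return `poly_area()` a scalar (m^2); `poly_centroid()` length-2 vector;
#'   `poly_bbox()` named vector xmin/xmax/ymin/ymax.
#' @export
poly_area <- function(ring) {
  r <- ring_close(ring)
  x <- r[, 1]; y <- r[, 2]
  n <- nrow(r)
  abs(sum(x[-n] * y[-1] - x[-1] * y[-n])) / 2
}

#' @rdname poly_area
#' @export
poly_centroid <- function(ring) {
  r <- ring_close(ring)
  x <- r[, 1]; y <- r[, 2]
  n <- nrow(r)
  cr <- x[-n] * y[-1] - x[-1] * y[-n]
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(colMeans(ring))
  c(sum((x[-n] + x[-1]) * cr) / (6 * a),
    sum((y[-n] + y[-1]) * cr) / (6 * a))
}

#' @rdname poly_area
#' @export
poly_bbox <- function(ring) {
  c(xmin = min(ring[, 1]), xmax = max(ring[, 1]),
    ymin = min(ring[, 2]), ymax = max(ring[, 2]))
}

#' Point-in-polygon test
#'
#' Vectorised even-odd (ray casting) containment test. Points exactly on an
#' edge may land on either side; the pipeline only ever tests pixel centres
#' against polygons whose edges fall between pixel centres, so the ambiguity
#' is immaterial there.
#'
#' @param px,py point coordinates (equal-length vectors).
#' @param ring polygon as an open ring (n x 2 matrix).
#' @return logical vector.
#' @export
points_in_poly <- function(px, py, ring) {
  n <- nrow(ring)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Shrink a convex polygon inward
#'
#' Moves every edge inward by `d` metres and intersects the resulting
#' half-planes (Sutherland–Hodgman clipping of the original ring against each
#' offset edge). Exact for rectangles and any convex plot polygon; an empty
#' intersection returns a 0-row matrix.
#'
#' @param ring convex polygon as an open ring, either orientation.
#' @param d inward offset in metres (>= 0).
#' @return the shrunk open ring (possibly 0 rows).
#' @export
poly_shrink <- function(ring, d) {
  stopifnot(d >= 0)
  if (d == 0) return(ring)
  r <- ring
  # enforce counter-clockwise orientation
  rc <- ring_close(r)
  signed <- sum(rc[-nrow(rc), 1] * rc[-1, 2] - rc[-1, 1] * rc[-nrow(rc), 2]) / 2
  if (signed < 0) r <- r[rev(seq_len(nrow(r))), , drop = FALSE]
  subj <- r
  n <- nrow(r)
  for (i in seq_len(n)) {
    a <- r[i, ]; b <- r[if (i == n) 1L else i + 1L, ]
    e <- b - a
    len <- sqrt(sum(e^2))
    if (len < 1e-12) next
    nrm <- c(-e[2], e[1]) / len           # inward normal for CCW ring
    a2 <- a + nrm * d                     # offset edge passes through a2
    subj <- clip_halfplane(subj, a2, e)
    if (nrow(subj) < 3L) return(subj[0, , drop = FALSE])
  }
  subj
}

# keep the part of `subj` on the left of the directed line through p with
# direction v (Sutherland–Hodgman step)
clip_halfplane <- function(subj, p, v) {
  n <- nrow(subj)
  if (n == 0L) return(subj)
  side <- (subj[, 1] - p[1]) * v[2] - (subj[, 2] - p[2]) * v[1]
  keep <- side <= 1e-12
  out <- matrix(numeric(0), 0, 2)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    a <- subj[i, ]; b <- subj[j, ]
    if (keep[i]) out <- rbind(out, a)
    if (keep[i] != keep[j]) {
      denom <- side[i] - side[j]
      t <- side[i] / denom
      out <- rbind(out, a + t * (b - a))
    }
  }
  # drop duplicate consecutive vertices
  if (nrow(out) > 1L) {
    dup <- c(FALSE, rowSums(abs(diff(out))) < 1e-12)
    out <- out[!dup, , drop = FALSE]
  }
  out
}

#' Read and write polygon layers as GeoJSON
#'
#' Minimal GeoJSON FeatureCollection support for Polygon features (single
#' exterior ring), the exchange format for plot and bare-ground layers.
#' Feature properties become columns of the returned data frame; geometries
#' are returned in a `ring` list-column of open-ring matrices.
#'
#' @param path file path.
#' @param rings list of open-ring matrices.
#' @param properties data frame of per-feature properties (one row per ring).
#' @param crs CRS identifier stored in the (foreign) `crs` member.
#' @return `read_geojson_polygons()` a data frame with a `ring` list-column;
#'   `write_geojson_polygons()` the path, invisibly.
#' @export
write_geojson_polygons <- function(rings, properties, path, crs = "EPSG:32650") {
  stopifnot(length(rings) == nrow(properties))
  feats <- lapply(seq_along(rings), function(i) {
    ring <- ring_close(rings[[i]])
    coords <- lapply(seq_len(nrow(ring)), function(k) c(ring[k, 1], ring[k, 2]))
    list(
      type = "Feature",
      properties = as.list(properties[i, , drop = FALSE]),
      geometry = list(type = "Polygon", coordinates = list(coords))
    )
  })
  fc <- list(type = "FeatureCollection", crs = crs, features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = 10, pretty = FALSE)
  invisible(path)
}

#' @rdname write_geojson_polygons
#' @export
read_geojson_polygons <- function(path) {
  fc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(fc$type) || fc$type != "FeatureCollection")
    stop("not a GeoJSON FeatureCollection: ", path, call. = FALSE)
  feats <- fc$features
  rings <- vector("list", length(feats))
  props <- vector("list", length(feats))
  for (i in seq_along(feats)) {
    g <- feats[[i]]$geometry
    if (g$type != "Polygon")
      stop("only Polygon features are supported (feature ", i, ")", call. = FALSE)
    ring <- do.call(rbind, lapply(g$coordinates[[1]], function(p)
      c(as.numeric(p[[1]]), as.numeric(p[[2]]))))
    # drop the closing vertex
    if (nrow(ring) > 1 && all(ring[1, ] == ring[nrow(ring), ]))
      ring <- ring[-nrow(ring), , drop = FALSE]
    rings[[i]] <- ring
    props[[i]] <- lapply(feats[[i]]$properties, function(x) if (is.null(x)) NA else x)
  }
  keys <- unique(unlist(lapply(props, names)))
  df <- as.data.frame(
    stats::setNames(lapply(keys, function(k) {
      sapply(props, function(p) if (is.null(p[[k]])) NA else p[[k]])
    }), keys),
    stringsAsFactors = FALSE
  )
  df$ring <- rings
  attr(df, "crs") <- if (!is.null(fc$crs)) fc$crs else "unknown"
  df
}

# axis-aligned rectangle ring from bounds
rect_ring <- function(xmin, ymin, xmax, ymax) {
  cbind(c(xmin, xmax, xmax, xmin), c(ymin, ymin, ymax, ymax))
}
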