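# DTM estimation: ground control points sampled inside bare-ground polygons
# on the DSM, TIN-linear interpolation over their Delaunay triangulation,
# and error statistics against a reference terrain.

#' Sample ground control points from bare-ground polygons
#'
#' Per polygon, three control points are emitted: the polygon centroid
#' paired with the median of its pixel elevations (robust against stray
#' vegetation pixels), and the pixel locations of the lowest and highest
#' elevations (the "lowest and highest ground elevation points" of each
#' zone). Polygons with no valid pixel are skipped with a warning.
#'
#' @param dsm an [elev_raster()].
#' @param bare data frame of bare-ground polygons: either bounds columns
#'   (xmin/ymin/xmax/ymax) or a `ring` list-column, plus `polygon_id`.
#' @return data frame (x, y, elev_m, polygon_id, kind) with kind in
#'   `median`, `min`, `max`.
#' @export
sample_ground_elevations <- function(dsm, bare) {
  stopifnot(inherits(dsm, "elev_raster"))
  xs <- raster_x(dsm)
  ys <- raster_y(dsm)
  out <- vector("list", nrow(bare))
  skipped <- character(0)
  for (i in seq_len(nrow(bare))) {
    if (!is.null(bare$ring)) {
      ring <- bare$ring[[i]]
      bb <- poly_bbox(ring)
    } else {
      ring <- rect_ring(bare$xmin[i], bare$ymin[i], bare$xmax[i], bare$ymax[i])
      bb <- c(xmin = bare$xmin[i], xmax = bare$xmax[i],
              ymin = bare$ymin[i], ymax = bare$ymax[i])
    }
    ci <- which(xs >= bb["xmin"] & xs <= bb["xmax"])
    ri <- which(ys >= bb["ymin"] & ys <= bb["ymax"])
    if (!length(ci) || !length(ri)) { skipped <- c(skipped, bare$polygon_id[i]); next }
    gx <- rep(xs[ci], each = length(ri))
    gy <- rep(ys[ri], times = length(ci))
    v <- as.vector(dsm$values[ri, ci, drop = FALSE])
    ins <- points_in_poly(gx, gy, ring) & !is.na(v)
    if (!any(ins)) { skipped <- c(skipped, bare$polygon_id[i]); next }
    gx <- gx[ins]; gy <- gy[ins]; v <- v[ins]
    ctr <- poly_centroid(ring)
    imin <- which.min(v)
    imax <- which.max(v)
    out[[i]] <- data.frame(
      x = c(ctr[1], gx[imin], gx[imax]),
      y = c(ctr[2], gy[imin], gy[imax]),
      elev_m = c(stats::median(v), v[imin], v[imax]),
      polygon_id = bare$polygon_id[i],
      kind = c("median", "min", "max"),
      stringsAsFactors = FALSE
    )
  }
  if (length(skipped))
    warning("skipped bare-ground polygons with no valid pixels: ",
            paste(skipped, collapse = ", "), call. = FALSE)
  out <- do.call(rbind, out)
  if (is.null(out) || nrow(out) == 0L)
    stop("no usable bare-ground polygons; cannot build a DTM", call. = FALSE)
  rownames(out) <- NULL
  out
}

#' Interpolate a DTM from ground control points
#'
#' Linear interpolation over the Delaunay triangulation of the control
#' points (a TIN: the surface of minimal complexity through the data, with
#' no curvature added between points), evaluated at the pixel centres of the
#' template grid. Outside the convex hull of the control points the nearest
#' control point's elevation is used; those pixels are flagged in the
#' quality mask.
#'
#' @param points data frame with columns x, y, elev_m (e.g. from
#'   [sample_ground_elevations()]).
#' @param template an [elev_raster()] defining grid, CRS and nodata.
#' @return list: `dtm` ([elev_raster()]), `quality` ([elev_raster()], 0 =
#'   interpolated, 1 = extrapolated beyond the hull).
#' @export
interpolate_dtm <- function(points, template) {
  stopifnot(all(c("x", "y", "elev_m") %in% names(points)))
  pts <- cbind(points$x, points$y)
  z <- points$elev_m
  dup <- duplicated(round(pts, 9))
  pts <- pts[!dup, , drop = FALSE]
  z <- z[!dup]
  if (nrow(pts) < 3)
    stop("need at least 3 distinct control points", call. = FALSE)
  if (qr(cbind(1, pts))$rank < 3)
    stop("control points are collinear; cannot interpolate a surface",
         call. = FALSE)
  tri <- delaunay_triangulate(pts)
  ip <- tin_interpolate(pts, z, template, tri)
  vals <- nearest_fill(ip$values, pts, z, template)
  vals[is.na(template$values)] <- NA_real_
  qual <- matrix(1, nrow(vals), ncol(vals))
  qual[ip$inside] <- 0
  qual[is.na(template$values)] <- NA_real_
  list(
    dtm = elev_raster(vals, template$xmin, template$ymin, template$cellsize,
                      crs = template$crs, nodata = template$nodata),
    quality = elev_raster(qual, template$xmin, template$ymin,
                          template$cellsize, crs = template$crs,
                          nodata = template$nodata)
  )
}

#' DTM error statistics
#'
#' Mean bias, RMSE and maximum absolute error of a DTM against a reference,
#' over the valid (non-nodata) overlap. The reference may be another raster
#' on the same grid or a data frame of held-out points (x, y, elev_m).
#'
#' @param dtm an [elev_raster()].
#' @param reference an [elev_raster()] on the same grid, or a points data
#'   frame.
#' @return list (bias_m, rmse_m, max_abs_m, n).
#' @export
dtm_error <- function(dtm, reference) {
  if (inherits(reference, "elev_raster")) {
    if (!same_grid(dtm, reference))
      stop("dtm and reference are on different grids", call. = FALSE)
    err <- dtm$values - reference$values
    err <- err[!is.na(err)]
  } else {
    stopifnot(all(c("x", "y", "elev_m") %in% names(reference)))
    xs <- raster_x(dtm)
    ys <- raster_y(dtm)
    ci <- vapply(reference$x, function(x) which.min(abs(xs - x)), 1L)
    ri <- vapply(reference$y, function(y) which.min(abs(ys - y)), 1L)
    ok <- reference$x >= raster_extent(dtm)["xmin"] &
      reference$x <= raster_extent(dtm)["xmax"] &
      reference$y >= raster_extent(dtm)["ymin"] &
      reference$y <= raster_extent(dtm)["ymax"]
    err <- dtm$values[cbind(ri[ok], ci[ok])] - reference$elev_m[ok]
    err <- err[!is.na(err)]
  }
  if (!length(err))
    stop("no valid overlap between dtm and reference", call. = FALSE)
  list(bias_m = mean(err),
       rmse_m = sqrt(mean(err^2)),
       max_abs_m = max(abs(err)),
       n = length(err))
}
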