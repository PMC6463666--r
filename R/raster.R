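#' Elevation raster
#'
#' A minimal single-band georeferenced raster: a numeric matrix of elevations
#' (metres above datum) on a regular square grid in a projected, metre-unit
#' CRS. Row 1 is the northernmost row, matching the on-disk convention of the
#' Esri ASCII grid format used by [write_asc()]/[read_asc()]. The same
#' container plays the DSM, DTM and PHM roles throughout the pipeline.
#'
#' @param values numeric matrix, `nrow` = rows (north to south), `ncol` =
#'   columns (west to east). `NA` entries are nodata.
#' @param xmin,ymin coordinates of the lower-left corner of the grid (CRS
#'   units, metres).
#' @param cellsize pixel edge length in metres (> 0).
#' @param crs CRS identifier string (informative only; no reprojection is
#'   ever performed).
#' @param nodata nodata marker used when the raster is written to disk.
#' @return An object of class `elev_raster`.
#' @export
elev_raster <- function(values, xmin = 0, ymin = 0, cellsize = 0.025,
                        crs = "EPSG:32650", nodata = -9999) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (!is.numeric(cellsize) || length(cellsize) != 1L || cellsize <= 0)
    stop("`cellsize` must be a single positive number", call. = FALSE)
  if (any(is.infinite(values)))
    stop("elevations must be finite or NA", call. = FALSE)
  structure(
    list(values = values, xmin = xmin, ymin = ymin, cellsize = cellsize,
         crs = crs, nodata = nodata),
    class = "elev_raster"
  )
}

#' @export
print.elev_raster <- function(x, ...) {
  v <- x$values
  cat(sprintf("<elev_raster> %d rows x %d cols @ %g m (%s)\n",
              nrow(v), ncol(v), x$cellsize, x$crs))
  cat(sprintf("  extent: x [%g, %g], y [%g, %g]\n",
              x$xmin, x$xmin + ncol(v) * x$cellsize,
              x$ymin, x$ymin + nrow(v) * x$cellsize))
  ok <- !is.na(v)
  if (any(ok))
    cat(sprintf("  values: [%.3f, %.3f] m, %d nodata px\n",
                min(v[ok]), max(v[ok]), sum(!ok)))
  invisible(x)
}

#' @export
dim.elev_raster <- function(x) dim(x$values)

#' Pixel-centre coordinates
#'
#' @param r an [elev_raster()].
#' @return `raster_x()`/`raster_y()` return the x (per column) and y (per
#'   row) pixel-centre coordinates; y decreases with row index (row 1 is the
#'   top of the grid).
#' @keywords internal
raster_x <- function(r) r$xmin + (seq_len(ncol(r$values)) - 0.5) * r$cellsize

#' @rdname raster_x
#' @keywords internal
raster_y <- function(r) {
  n <- nrow(r$values)
  r$ymin + (n - seq_len(n) + 0.5) * r$cellsize
}

#' @keywords internal
raster_extent <- function(r) {
  c(xmin = r$xmin, xmax = r$xmin + ncol(r$values) * r$cellsize,
    ymin = r$ymin, ymax = r$ymin + nrow(r$values) * r$cellsize)
}

same_grid <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(a$xmin, b$xmin, tolerance = 1e-9)) &&
    isTRUE(all.equal(a$ymin, b$ymin, tolerance = 1e-9)) &&
    isTRUE(all.equal(a$cellsize, b$cellsize, tolerance = 1e-12))
}

#' Write / read an elevation raster as an Esri ASCII grid
#'
#' The ASCII grid (`.asc`) format is the plain-text single-band raster
#' standard understood by GDAL and QGIS: a six-line header (ncols, nrows,
#' xllcorner, yllcorner, cellsize, NODATA_value) followed by rows of values,
#' north first. A one-line `.prj`-style sidecar is not written; the CRS
#' string is stored in a comment-free companion `<path>.crs` file so a round
#' trip preserves it.
#'
#' @param r an [elev_raster()].
#' @param path output path (conventionally ending in `.asc`).
#' @param digits decimal digits written per value.
#' @return `write_asc()` returns `path` invisibly; `read_asc()` returns an
#'   [elev_raster()].
#' @export
write_asc <- function(r, path, digits = 4) {
  stopifnot(inherits(r, "elev_raster"))
  v <- r$values
  v[is.na(v)] <- r$nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.6f", r$xmin),
    sprintf("yllcorner %.6f", r$ymin),
    sprintf("cellsize %.6f", r$cellsize),
    sprintf("NODATA_value %g", r$nodata)
  ), con)
  fmt <- paste0("%.", digits, "f")
  for (i in seq_len(nrow(v)))
    writeLines(paste(sprintf(fmt, v[i, ]), collapse = " "), con)
  crs_path <- paste0(path, ".crs")
  writeLines(r$crs, crs_path)
  invisible(path)
}

#' @rdname write_asc
#' @export
read_asc <- function(path) {
  hdr <- readLines(path, n = 6L)
  kv <- strsplit(trimws(hdr), "\\s+")
  key <- tolower(vapply(kv, `[`, "", 1L))
  val <- as.numeric(vapply(kv, `[`, "", 2L))
  names(val) <- key
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% key))
    stop("not an Esri ASCII grid: ", path, call. = FALSE)
  nodata <- if ("nodata_value" %in% key) val[["nodata_value"]] else -9999
  vals <- scan(path, skip = 6L, quiet = TRUE)
  m <- matrix(vals, nrow = val[["nrows"]], ncol = val[["ncols"]], byrow = TRUE)
  m[m == nodata] <- NA_real_
  crs_path <- paste0(path, ".crs")
  crs <- if (file.exists(crs_path)) readLines(crs_path, n = 1L) else "unknown"
  elev_raster(m, xmin = val[["xllcorner"]], ymin = val[["yllcorner"]],
              cellsize = val[["cellsize"]], crs = crs, nodata = nodata)
}
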