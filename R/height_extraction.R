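# Plant height model and per-plot height extraction. The height rule is the
# upper-canopy-boundary sampling scheme: small square windows placed at
# random inside the trimmed plot, the per-window maximum as a canopy-top
# reading, rejection of readings more than a tolerance (default 10 cm) below
# the plot-wide top (they cannot be spike height), and the reported height
# H = (U + L) / 2 from the highest (U) and lowest (L) accepted readings.

#' Extraction parameters
#'
#' @param trim_frac margin trim per side, as a fraction of the shorter plot
#'   side (in `[0, 0.4)`); defends against overlap from neighbouring plots.
#' @param n_windows sampling windows per plot (>= 2); default 10, one per
#'   ground-measured plant in the protocol this mirrors.
#' @param window_m window edge length in metres; default 0.075 m (3 pixels
#'   at 2.5 cm GSD, about one spike).
#' @param tolerance_m rejection tolerance below the plot-wide top (m);
#'   default 0.10.
#' @param seed integer seed for window placement.
#' @return list of class `extraction_params`.
#' @export
extraction_params <- function(trim_frac = 0.10, n_windows = 10L,
                              window_m = 0.075, tolerance_m = 0.10,
                              seed = 1L) {
  stopifnot(trim_frac >= 0, trim_frac < 0.4, n_windows >= 2, tolerance_m > 0,
            window_m > 0)
  structure(list(trim_frac = trim_frac, n_windows = as.integer(n_windows),
                 window_m = window_m, tolerance_m = tolerance_m,
                 seed = as.integer(seed)),
            class = "extraction_params")
}

#' Plant height model
#'
#' PHM = DSM - DTM, elementwise on identical grids. Nodata in either operand
#' propagates. Negative values are retained — they are diagnostic of DTM
#' bias — but counted in the `n_negative` attribute.
#'
#' @param dsm,dtm [elev_raster()]s on the same grid.
#' @return an [elev_raster()] of per-pixel canopy height (m), with
#'   attribute `n_negative`.
#' @export
compute_phm <- function(dsm, dtm) {
  stopifnot(inherits(dsm, "elev_raster"), inherits(dtm, "elev_raster"))
  if (!same_grid(dsm, dtm))
    stop("DSM and DTM grids differ; refusing to resample silently",
         call. = FALSE)
  v <- dsm$values - dtm$values
  phm <- elev_raster(v, dsm$xmin, dsm$ymin, dsm$cellsize, crs = dsm$crs,
                     nodata = dsm$nodata)
  attr(phm, "n_negative") <- sum(v < 0, na.rm = TRUE)
  phm
}

#' Trim a plot polygon
#'
#' Shrinks the polygon inward by `trim_frac` times its shorter side length,
#' discarding the noisy plot margin where neighbouring plants overhang.
#'
#' @param ring convex plot polygon (open ring) or a plot row with bounds.
#' @param trim_frac fraction in `[0, 0.4)`.
#' @param plot_id label used in error messages.
#' @return the trimmed open ring.
#' @export
trim_plot <- function(ring, trim_frac, plot_id = "plot") {
  stopifnot(trim_frac >= 0, trim_frac < 0.4)
  if (trim_frac == 0) return(ring)
  bb <- poly_bbox(ring)
  short <- min(bb["xmax"] - bb["xmin"], bb["ymax"] - bb["ymin"])
  out <- poly_shrink(ring, trim_frac * short)
  if (nrow(out) < 3 || poly_area(out) <= 0)
    stop("trimming left plot ", plot_id, " empty", call. = FALSE)
  out
}

#' Sample canopy-top readings inside a plot
#'
#' Places `n_windows` axis-aligned square windows uniformly at random with
#' centres inside the trimmed polygon, windows clipped to it, non-overlap
#' enforced by rejection sampling with a retry cap. Each reading is the
#' maximum non-nodata PHM value inside its window.
#'
#' @param phm the plant height model raster.
#' @param ring trimmed plot polygon (open ring).
#' @param params an [extraction_params()].
#' @param seed seed for placement (defaults to `params$seed`).
#' @return numeric vector of readings `t_i` (m), with attribute `n_placed`.
#' @export
sample_canopy_top <- function(phm, ring, params, seed = params$seed) {
  set.seed(seed)
  xs <- raster_x(phm)
  ys <- raster_y(phm)
  bb <- poly_bbox(ring)
  half <- params$window_m / 2
  n <- params$n_windows
  centers <- matrix(numeric(0), 0, 2)
  tries <- 0L
  cap <- 200L * n
  while (nrow(centers) < n && tries < cap) {
    tries <- tries + 1L
    cx <- stats::runif(1, bb["xmin"], bb["xmax"])
    cy <- stats::runif(1, bb["ymin"], bb["ymax"])
    if (!points_in_poly(cx, cy, ring)) next
    if (nrow(centers) > 0 &&
        any(abs(centers[, 1] - cx) < params$window_m &
            abs(centers[, 2] - cy) < params$window_m)) next
    centers <- rbind(centers, c(cx, cy))
  }
  if (nrow(centers) < n)
    warning(sprintf("placed %d of %d windows before the retry cap",
                    nrow(centers), n), call. = FALSE)
  if (nrow(centers) < 2)
    stop("fewer than 2 sampling windows could be placed", call. = FALSE)
  tvals <- rep(NA_real_, nrow(centers))
  for (i in seq_len(nrow(centers))) {
    ci <- which(xs >= centers[i, 1] - half & xs <= centers[i, 1] + half)
    ri <- which(ys >= centers[i, 2] - half & ys <= centers[i, 2] + half)
    if (!length(ci) || !length(ri)) next
    gx <- rep(xs[ci], each = length(ri))
    gy <- rep(ys[ri], times = length(ci))
    v <- as.vector(phm$values[ri, ci, drop = FALSE])
    ins <- points_in_poly(gx, gy, ring) & !is.na(v)
    if (any(ins)) tvals[i] <- max(v[ins])
  }
  tvals <- tvals[!is.na(tvals)]
  if (length(tvals) < 2)
    stop("fewer than 2 windows contained valid PHM pixels", call. = FALSE)
  attr(tvals, "n_placed") <- nrow(centers)
  tvals
}

#' Plot height from canopy-top readings
#'
#' Rejects every reading more than `tolerance_m` below the highest reading
#' (such values cannot be spike height), then reports U = highest accepted,
#' L = lowest accepted and H = (U + L) / 2. If only one reading survives,
#' H = U = L and the record is flagged low-confidence.
#'
#' @param tvals canopy-top readings (m), length >= 2.
#' @param tolerance_m rejection tolerance (m).
#' @return one-row data frame (U_m, L_m, H_m, n_samples, n_accepted,
#'   low_confidence).
#' @export
plot_height <- function(tvals, tolerance_m = 0.10) {
  stopifnot(length(tvals) >= 2, tolerance_m > 0)
  top <- max(tvals)
  acc <- tvals[tvals >= top - tolerance_m]
  U <- max(acc)
  L <- min(acc)
  data.frame(U_m = U, L_m = L, H_m = (U + L) / 2,
             n_samples = length(tvals), n_accepted = length(acc),
             low_confidence = length(acc) < 2)
}

#' Extract heights for every plot of a layout
#'
#' Batch driver: trims each plot, samples canopy-top readings on the PHM and
#' applies the height rule. Heights are returned in cm alongside the full
#' diagnostics. Plots failing extraction are reported, not silently
#' dropped; if 20% or more fail the run aborts.
#'
#' @param dsm,dtm [elev_raster()]s of one site (same grid).
#' @param layout a [make_field_layout()] (only plots matching `site` and
#'   intersecting the raster are used).
#' @param params an [extraction_params()].
#' @param site site label; default: the single site present in the rasters'
#'   plots.
#' @param stage stage label stamped on the table.
#' @return list: `heights` (plot_id, genotype_id, site, rep, stage, source =
#'   "uav", value_cm, U_cm, L_cm, n_samples, n_accepted, low_confidence) and
#'   `failed` (plot ids with error messages).
#' @export
extract_heights <- function(dsm, dtm, layout, params = extraction_params(),
                            site = NULL, stage = "mid_grain_fill") {
  phm <- compute_phm(dsm, dtm)
  plots <- layout$plots
  if (!is.null(site)) plots <- plots[plots$site == site, , drop = FALSE]
  if (nrow(plots) == 0L) {
    warning("empty layout; returning an empty height table", call. = FALSE)
    return(list(heights = data.frame(), failed = data.frame()))
  }
  rows <- vector("list", nrow(plots))
  failed <- list()
  for (i in seq_len(nrow(plots))) {
    p <- plots[i, ]
    res <- tryCatch({
      ring <- trim_plot(plot_ring(p), params$trim_frac, p$plot_id)
      # per-plot seed: deterministic, independent across plots
      tv <- sample_canopy_top(phm, ring, params,
                              seed = params$seed + 7L * i)
      rec <- plot_height(tv, params$tolerance_m)
      cbind(data.frame(plot_id = p$plot_id, genotype_id = p$genotype_id,
                       site = p$site, rep = p$rep, stage = stage,
                       source = "uav",
                       value_cm = rec$H_m * 100,
                       U_cm = rec$U_m * 100, L_cm = rec$L_m * 100,
                       stringsAsFactors = FALSE),
            rec[c("n_samples", "n_accepted", "low_confidence")])
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed[[length(failed) + 1L]] <-
        data.frame(plot_id = p$plot_id, error = conditionMessage(res),
                   stringsAsFactors = FALSE)
    } else rows[[i]] <- res
  }
  failed <- if (length(failed)) do.call(rbind, failed) else
    data.frame(plot_id = character(0), error = character(0))
  if (nrow(failed) >= 0.2 * nrow(plots))
    stop(sprintf("%d of %d plots failed extraction; aborting. First errors: %s",
                 nrow(failed), nrow(plots),
                 paste(utils::head(failed$error, 3), collapse = " | ")),
         call. = FALSE)
  heights <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  rownames(heights) <- NULL
  list(heights = heights, failed = failed)
}
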