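test_that("control points reproduce a constant field exactly", {
  r <- flat_raster(100)
  bare <- data.frame(polygon_id = "b1", xmin = 0.1, ymin = 0.1,
                     xmax = 0.6, ymax = 0.6, stringsAsFactors = FALSE)
  pts <- sample_ground_elevations(r, bare)
  expect_equal(nrow(pts), 3L)
  expect_equal(pts$elev_m, rep(100, 3))
  expect_setequal(pts$kind, c("median", "min", "max"))
})

test_that("nodata polygons are skipped with a warning; zero usable is an error", {
  r <- flat_raster(100)
  r$values[1:20, 1:20] <- NA
  bare <- data.frame(polygon_id = c("dead", "live"),
                     xmin = c(0.05, 0.6), ymin = c(0.55, 0.1),
                     xmax = c(0.45, 0.95), ymax = c(0.95, 0.45),
                     stringsAsFactors = FALSE)
  expect_warning(pts <- sample_ground_elevations(r, bare), "dead")
  expect_equal(unique(pts$polygon_id), "live")
  all_dead <- bare[1, , drop = FALSE]
  expect_error(suppressWarnings(sample_ground_elevations(r, all_dead)),
               "no usable")
})

test_that("min/max control points sit at opposite corners of a tilted plane", {
  r <- plane_raster(100, 0.01, 0.02)
  bare <- data.frame(polygon_id = "sq", xmin = 0.5, ymin = 0.5,
                     xmax = 2.0, ymax = 2.0, stringsAsFactors = FALSE)
  pts <- sample_ground_elevations(r, bare)
  pmin <- pts[pts$kind == "min", ]
  pmax <- pts[pts$kind == "max", ]
  # gradient is (+x, +y): lowest at the SW corner, highest at the NE corner
  expect_lt(pmin$x, 0.6); expect_lt(pmin$y, 0.6)
  expect_gt(pmax$x, 1.9); expect_gt(pmax$y, 1.9)
  med <- pts[pts$kind == "median", ]
  expect_equal(med$elev_m, 100 + 0.01 * 1.25 + 0.02 * 1.25,
               tolerance = 0.002)
})

test_that("TIN interpolation is exact on planes and reproduces its data", {
  tmpl <- flat_raster(0, nr = 60, nc = 60, cellsize = 0.05)
  set.seed(42)
  pts <- data.frame(x = stats::runif(25, 0, 3), y = stats::runif(25, 0, 3))
  pts$elev_m <- 5 + 0.3 * pts$x - 0.2 * pts$y
  out <- interpolate_dtm(pts, tmpl)
  xs <- uavheight:::raster_x(tmpl)
  ys <- uavheight:::raster_y(tmpl)
  truth <- outer(ys, xs, function(y, x) 5 + 0.3 * x - 0.2 * y)
  inside <- out$quality$values == 0
  expect_gt(mean(inside), 0.5)
  expect_lt(max(abs((out$dtm$values - truth)[inside])), 1e-6)
  # nearest-point extrapolation outside the hull is bounded by the data range
  expect_true(all(out$dtm$values >= min(pts$elev_m) - 1e-9 &
                    out$dtm$values <= max(pts$elev_m) + 1e-9))
})

test_that("interpolation through a single triangle returns vertex values", {
  tmpl <- flat_raster(0, nr = 20, nc = 20, cellsize = 0.1)
  pts <- data.frame(x = c(0.15, 1.85, 0.95), y = c(0.15, 0.15, 1.85),
                    elev_m = c(1, 2, 3))
  out <- interpolate_dtm(pts, tmpl)
  for (i in 1:3) {
    ci <- which.min(abs(uavheight:::raster_x(tmpl) - pts$x[i]))
    ri <- which.min(abs(uavheight:::raster_y(tmpl) - pts$y[i]))
    expect_equal(out$dtm$values[ri, ci], pts$elev_m[i], tolerance = 1e-6)
  }
})

test_that("a redundant point on an existing face leaves the DTM unchanged", {
  tmpl <- flat_raster(0, nr = 40, nc = 40, cellsize = 0.05)
  set.seed(9)
  pts <- data.frame(x = c(0.1, 1.9, 1.0, 0.2, 1.8),
                    y = c(0.1, 0.2, 1.9, 1.5, 1.4))
  pts$elev_m <- 2 + 0.1 * pts$x + 0.05 * pts$y
  base <- interpolate_dtm(pts, tmpl)
  # a new point with the plane's value at an interior location
  extra <- rbind(pts, data.frame(x = 1.0, y = 0.9,
                                 elev_m = 2 + 0.1 * 1.0 + 0.05 * 0.9))
  with_extra <- interpolate_dtm(extra, tmpl)
  # compare interpolated pixels only: outside the hull the nearest control
  # point may legitimately change when a point is added
  inside <- base$quality$values == 0 & with_extra$quality$values == 0
  expect_lt(max(abs((base$dtm$values - with_extra$dtm$values)[inside])), 1e-6)
})

test_that("degenerate control configurations are refused", {
  tmpl <- flat_raster(0)
  two <- data.frame(x = c(0, 1), y = c(0, 1), elev_m = c(1, 2))
  expect_error(interpolate_dtm(two, tmpl), "3")
  coll <- data.frame(x = c(0, 1, 2, 3), y = c(0, 1, 2, 3),
                     elev_m = c(1, 2, 3, 4))
  expect_error(interpolate_dtm(coll, tmpl), "collinear")
})

test_that("dtm_error matches identity, constant offset and refuses disjoint grids", {
  r <- plane_raster(100, 0.01, -0.01, nr = 30, nc = 30)
  self <- dtm_error(r, r)
  expect_equal(self$bias_m, 0)
  expect_equal(self$rmse_m, 0)
  shifted <- r
  shifted$values <- r$values + 0.04
  err <- dtm_error(shifted, r)
  expect_equal(err$bias_m, 0.04, tolerance = 1e-12)
  expect_equal(err$rmse_m, 0.04, tolerance = 1e-12)
  expect_equal(err$max_abs_m, 0.04, tolerance = 1e-12)
  other <- flat_raster(0, nr = 10, nc = 10)
  expect_error(dtm_error(r, other), "different grids")
})

test_that("estimated DTM recovers synthetic terrain within the survey regime", {
  cfg <- tiny_config(seed = 17)
  f <- simulate_field(cfg, sites = "site1")
  r <- f$rasters$site1
  pts <- sample_ground_elevations(r$dsm, f$layout$bare)
  est <- interpolate_dtm(pts, r$dsm)
  err <- dtm_error(est$dtm, r$dtm)
  expect_lt(err$rmse_m, 0.05)
  expect_lt(abs(err$bias_m), 0.02)
  # terrain stays below the canopy: DTM under the plot-interior DSM maxima
  xs <- uavheight:::raster_x(r$dsm)
  ys <- uavheight:::raster_y(r$dsm)
  plots <- f$layout$plots[f$layout$plots$site == "site1", ]
  below <- vapply(seq_len(nrow(plots)), function(i) {
    p <- plots[i, ]
    ci <- which(xs >= p$xmin & xs < p$xmax)
    ri <- which(ys >= p$ymin & ys < p$ymax)
    max(r$dsm$values[ri, ci]) > max(est$dtm$values[ri, ci])
  }, TRUE)
  expect_true(all(below))
})
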