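# Delaunay triangulation (Bowyer-Watson incremental insertion) and linear
# TIN interpolation onto a raster grid. Point sets here are bare-ground
# control points -- a few hundred at most -- so the O(n^2) insertion with
# cached circumcircles is more than fast enough and keeps the code auditable.

# Deterministic sub-micron jitter breaks the exact cocircularity of control
# points that sit on pixel centres of a regular grid; it perturbs
# interpolated values by < 1e-8 * local gradient, far below sensor noise.
tin_jitter <- function(n, scale) {
  i <- seq_len(n)
  u1 <- ((i * 2654435761) %% 1e6) / 1e6 - 0.5
  u2 <- ((i * 1442695041) %% 1e6) / 1e6 - 0.5
  cbind(u1, u2) * 1e-8 * scale
}

circumcircle <- function(ax, ay, bx, by, cx, cy) {
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  if (abs(d) < 1e-300) return(c(Inf, Inf, Inf))
  a2 <- ax * ax + ay * ay
  b2 <- bx * bx + by * by
  c2 <- cx * cx + cy * cy
  ux <- (a2 * (by - cy) + b2 * (cy - ay) + c2 * (ay - by)) / d
  uy <- (a2 * (cx - bx) + b2 * (ax - cx) + c2 * (bx - ax)) / d
  r2 <- (ax - ux)^2 + (ay - uy)^2
  c(ux, uy, r2)
}

#' Delaunay triangulation of a planar point set
#'
#' Incremental Bowyer-Watson construction. Intended for the control-point
#' sets behind DTM interpolation; exported because it is independently
#' useful and independently testable.
#'
#' @param pts n x 2 matrix of point coordinates (n >= 3, not all collinear).
#' @return integer matrix (m x 3) of 1-based vertex indices per triangle.
#' @export
delaunay_triangulate <- function(pts) {
  n <- nrow(pts)
  if (n < 3) stop("need at least 3 points", call. = FALSE)
  rngx <- range(pts[, 1]); rngy <- range(pts[, 2])
  scale <- max(rngx[2] - rngx[1], rngy[2] - rngy[1], 1e-9)
  # normalise to the unit box and jitter to break degeneracies
  p <- cbind((pts[, 1] - rngx[1]) / scale, (pts[, 2] - rngy[1]) / scale)
  p <- p + tin_jitter(n, 1)
  if (qr(cbind(1, p))$rank < 3)
    stop("control points are collinear; triangulation impossible", call. = FALSE)
  verts <- rbind(p, c(-100, -100), c(300, -100), c(-100, 300))
  s1 <- n + 1L; s2 <- n + 2L; s3 <- n + 3L
  tri <- matrix(c(s1, s2, s3), 1, 3)
  cc <- matrix(circumcircle(verts[s1, 1], verts[s1, 2], verts[s2, 1],
                            verts[s2, 2], verts[s3, 1], verts[s3, 2]), 1, 3)
  for (ip in seq_len(n)) {
    px <- verts[ip, 1]; py <- verts[ip, 2]
    bad <- which((px - cc[, 1])^2 + (py - cc[, 2])^2 <= cc[, 3] * (1 + 1e-12))
    if (length(bad) == 0L) bad <- 1L  # numerical fallback; should not happen
    # boundary = edges of the bad cavity appearing exactly once
    e <- rbind(tri[bad, c(1, 2), drop = FALSE],
               tri[bad, c(2, 3), drop = FALSE],
               tri[bad, c(3, 1), drop = FALSE])
    key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    once <- key %in% names(which(table(key) == 1L))
    bnd <- e[once, , drop = FALSE]
    tri <- tri[-bad, , drop = FALSE]
    cc <- cc[-bad, , drop = FALSE]
    newt <- cbind(bnd, ip)
    newcc <- t(apply(newt, 1, function(tr)
      circumcircle(verts[tr[1], 1], verts[tr[1], 2],
                   verts[tr[2], 1], verts[tr[2], 2],
                   verts[tr[3], 1], verts[tr[3], 2])))
    tri <- rbind(tri, newt)
    cc <- rbind(cc, newcc)
  }
  keep <- tri[, 1] <= n & tri[, 2] <= n & tri[, 3] <= n
  tri <- tri[keep, , drop = FALSE]
  storage.mode(tri) <- "integer"
  tri
}

# Linear interpolation of (pts, z) over its Delaunay triangulation, evaluated
# at the pixel centres of `template`. Returns the value matrix plus a logical
# matrix marking pixels inside the convex hull (direct interpolation);
# remaining pixels are NA and left to the caller's extrapolation rule.
tin_interpolate <- function(pts, z, template, tri = NULL) {
  if (is.null(tri)) tri <- delaunay_triangulate(pts)
  xs <- raster_x(template)
  ys <- raster_y(template)
  out <- matrix(NA_real_, nrow(template$values), ncol(template$values))
  for (k in seq_len(nrow(tri))) {
    v <- tri[k, ]
    x1 <- pts[v[1], 1]; y1 <- pts[v[1], 2]
    x2 <- pts[v[2], 1]; y2 <- pts[v[2], 2]
    x3 <- pts[v[3], 1]; y3 <- pts[v[3], 2]
    det <- (y2 - y3) * (x1 - x3) + (x3 - x2) * (y1 - y3)
    if (abs(det) < 1e-300) next
    ci <- which(xs >= min(x1, x2, x3) - 1e-9 & xs <= max(x1, x2, x3) + 1e-9)
    ri <- which(ys >= min(y1, y2, y3) - 1e-9 & ys <= max(y1, y2, y3) + 1e-9)
    if (!length(ci) || !length(ri)) next
    gx <- rep(xs[ci], each = length(ri))
    gy <- rep(ys[ri], times = length(ci))
    l1 <- ((y2 - y3) * (gx - x3) + (x3 - x2) * (gy - y3)) / det
    l2 <- ((y3 - y1) * (gx - x3) + (x1 - x3) * (gy - y3)) / det
    l3 <- 1 - l1 - l2
    tol <- -1e-9
    ins <- l1 >= tol & l2 >= tol & l3 >= tol
    if (!any(ins)) next
    val <- l1 * z[v[1]] + l2 * z[v[2]] + l3 * z[v[3]]
    sub <- out[ri, ci, drop = FALSE]
    sub[ins] <- val[ins]
    out[ri, ci] <- sub
  }
  list(values = out, inside = !is.na(out))
}

# Nearest-control-point fill for pixels outside the convex hull. Pixels are
# processed in spatially coherent chunks (column-major order); per chunk the
# triangle inequality prunes the candidate points exactly: any point farther
# from the chunk centroid than (nearest centroid distance + chunk diameter)
# cannot be the nearest of any pixel in the chunk.
nearest_fill <- function(out, pts, z, template) {
  miss <- which(is.na(out))
  if (!length(miss)) return(out)
  xs <- raster_x(template)
  ys <- raster_y(template)
  nr <- nrow(out)
  mi <- ((miss - 1L) %% nr) + 1L   # row
  mj <- ((miss - 1L) %/% nr) + 1L  # col
  px <- xs[mj]; py <- ys[mi]
  # group pixels into ~3.5 m square tiles so each group's candidate set
  # stays tiny
  tile <- 3.5
  key <- paste(floor(px / tile), floor(py / tile))
  groups <- split(seq_along(miss), key)
  for (idx in groups) {
    cx <- mean(range(px[idx])); cy <- mean(range(py[idx]))
    diam <- sqrt(diff(range(px[idx]))^2 + diff(range(py[idx]))^2)
    dc <- sqrt((pts[, 1] - cx)^2 + (pts[, 2] - cy)^2)
    cand <- which(dc <= min(dc) + diam + 1e-9)
    d2 <- outer(px[idx], pts[cand, 1], "-")^2 +
      outer(py[idx], pts[cand, 2], "-")^2
    out[miss[idx]] <- z[cand[max.col(-d2, ties.method = "first")]]
  }
  out
}
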