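# Synthetic wheat-field generator: linkage map, doubled-haploid genotypes,
# plot phenotypes with a known genetic architecture, field layout, and
# rendered DSM/DTM raster pairs with exact ground truth. Every downstream
# stage of the pipeline is testable against what this module planted.

#' Haldane map function
#'
#' Recombination fraction between two loci `d` centimorgans apart under the
#' Haldane (no-interference) map function, r = (1 - exp(-2d/100)) / 2.
#'
#' @param d_cm map distance in centimorgans (>= 0).
#' @return recombination fraction in `[0, 0.5)`.
#' @export
haldane_r <- function(d_cm) 0.5 * (1 - exp(-2 * d_cm / 100))

#' Simulation configuration
#'
#' Bundles every knob of the synthetic field. The defaults are the study
#' design this generator emulates: 198 DH lines plus the two parents,
#' 3 replicates at each of 2 sites, 1.3 m x 3 m plots, 2.5 cm ground
#' sampling distance, two major height QTL (chromosomes 4B and 4D) plus a
#' minor locus on 6D over a polygenic background. Heights are in cm,
#' raster quantities in metres.
#'
#' @param seed integer seed governing every random draw downstream.
#' @param n_chromosomes,chrom_length_cm,marker_spacing_cm linkage-map grid.
#' @param chrom_names chromosome labels (length `n_chromosomes`).
#' @param n_lines number of DH lines.
#' @param include_parents add the two parental genotypes (P1 all-0, P2
#'   all-1) to the field, giving the design's 600 plots per site.
#' @param n_sites,n_reps environments and replicates per site.
#' @param mu_cm population mean plant height.
#' @param qtl data frame (chrom, pos_cm, effect_cm): additive effect is the
#'   full difference between the two homozygous classes.
#' @param sigma2_g,sigma2_ge,sigma2_e,sigma2_site polygenic, genotype x
#'   environment, residual-plot and site-effect variances (cm^2).
#' @param gsd ground sampling distance (m / pixel).
#' @param noise_sd i.i.d. sensor noise sd on the DSM (m).
#' @param terrain_amplitude total terrain relief across the field (m).
#' @param spike_fraction fraction of canopy pixels at canopy-top level.
#' @param spike_sd mixed-pixel attenuation scale of canopy-top pixels (m).
#' @param plot_w,plot_l,alley_x,alley_y,margin field geometry (m).
#' @param base_elev datum elevation of the field (m).
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 21L,
                       chrom_length_cm = 150,
                       marker_spacing_cm = 2,
                       chrom_names = as.vector(outer(1:7, c("A", "B", "D"),
                                                     paste0)),
                       n_lines = 198L,
                       include_parents = TRUE,
                       n_sites = 2L,
                       n_reps = 3L,
                       mu_cm = 78,
                       qtl = data.frame(
                         chrom = c("4B", "4D", "6D"),
                         pos_cm = c(54, 60, 70),
                         effect_cm = c(19, 19, 6),
                         stringsAsFactors = FALSE),
                       sigma2_g = 100,
                       sigma2_ge = 25,
                       sigma2_e = 36,
                       sigma2_site = 25,
                       gsd = 0.025,
                       noise_sd = 0.02,
                       terrain_amplitude = 0.5,
                       spike_fraction = 0.35,
                       spike_sd = 0.03,
                       plot_w = 1.3,
                       plot_l = 3.0,
                       alley_x = 0.4,
                       alley_y = 0.6,
                       margin = 1.5,
                       base_elev = 100) {
  stopifnot(sigma2_g >= 0, sigma2_ge >= 0, sigma2_e >= 0, sigma2_site >= 0,
            gsd > 0, spike_fraction > 0, spike_fraction <= 1,
            length(chrom_names) == n_chromosomes)
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

#' Regular linkage map
#'
#' Equally spaced markers on each chromosome; stands in for a real map so
#' the simulator and the interval scan share coordinates.
#'
#' @param n_chromosomes number of chromosomes.
#' @param chrom_length_cm chromosome length (cM).
#' @param marker_spacing_cm marker spacing (cM).
#' @param chrom_names chromosome labels.
#' @return data frame (marker, chrom, pos_cm), the `linkage_map` layout used
#'   everywhere: positions nondecreasing within chromosome, marker ids
#'   unique.
#' @export
sim_linkage_map <- function(n_chromosomes = 5L, chrom_length_cm = 150,
                            marker_spacing_cm = 2,
                            chrom_names = NULL) {
  if (is.null(chrom_names))
    chrom_names <- sprintf("chr%02d", seq_len(n_chromosomes))
  stopifnot(length(chrom_names) == n_chromosomes, marker_spacing_cm > 0)
  pos <- seq(0, chrom_length_cm, by = marker_spacing_cm)
  do.call(rbind, lapply(seq_len(n_chromosomes), function(c) {
    data.frame(
      marker = sprintf("%s_%04.0f", chrom_names[c], pos * 10),
      chrom = chrom_names[c],
      pos_cm = pos,
      stringsAsFactors = FALSE
    )
  }))
}

check_map <- function(map) {
  if (is.null(map) || nrow(map) == 0L)
    stop("linkage map is empty", call. = FALSE)
  stopifnot(all(c("marker", "chrom", "pos_cm") %in% names(map)))
  if (anyDuplicated(map$marker))
    stop("marker ids must be unique", call. = FALSE)
  if (any(map$pos_cm < 0))
    stop("map positions must be nonnegative", call. = FALSE)
  bad <- tapply(map$pos_cm, map$chrom, function(p) any(diff(p) < 0))
  if (any(unlist(bad)))
    stop("map positions must be nondecreasing within chromosome", call. = FALSE)
  invisible(map)
}

#' Simulate a doubled-haploid population
#'
#' One recombinant gamete per line is generated chromosome by chromosome:
#' the first-marker allele is a fair coin, and each adjacent interval
#' recombines independently with the Haldane fraction of its map distance
#' (no interference). Chromosome doubling makes every line fully homozygous,
#' so the returned matrix is the gamete itself, coded 0/1.
#'
#' @param map linkage map (see [sim_linkage_map()]).
#' @param n_lines number of DH lines (>= 2).
#' @param seed integer seed.
#' @return integer matrix `n_lines` x markers, entries in `{0, 1}`, rownames
#'   `DH001`..., colnames matching `map$marker`.
#' @export
simulate_dh_population <- function(map, n_lines, seed = 1L) {
  check_map(map)
  stopifnot(n_lines >= 2)
  set.seed(seed)
  out <- matrix(0L, n_lines, nrow(map),
                dimnames = list(sprintf("DH%03d", seq_len(n_lines)), map$marker))
  col0 <- 0L
  for (ch in unique(map$chrom)) {
    pos <- map$pos_cm[map$chrom == ch]
    m <- length(pos)
    g <- matrix(0L, n_lines, m)
    g[, 1] <- stats::rbinom(n_lines, 1L, 0.5)
    if (m > 1) {
      r <- haldane_r(diff(pos))
      for (j in 2:m) {
        rec <- stats::rbinom(n_lines, 1L, r[j - 1])
        g[, j] <- bitwXor(g[, j - 1], rec)
      }
    }
    out[, col0 + seq_len(m)] <- g
    col0 <- col0 + m
  }
  out
}

#' Add the parental genotypes
#'
#' @param geno DH genotype matrix from [simulate_dh_population()].
#' @return the matrix with rows `P1` (all 0) and `P2` (all 1) appended.
#' @export
add_parents <- function(geno) {
  rbind(geno,
        P1 = rep(0L, ncol(geno)),
        P2 = rep(1L, ncol(geno)))
}

snap_qtl <- function(qtl, map) {
  stopifnot(all(c("chrom", "pos_cm", "effect_cm") %in% names(qtl)))
  if (!all(qtl$chrom %in% map$chrom))
    stop("QTL on a chromosome absent from the map: ",
         paste(setdiff(qtl$chrom, map$chrom), collapse = ", "), call. = FALSE)
  if (any(!is.finite(qtl$effect_cm)))
    stop("QTL effects must be finite", call. = FALSE)
  qtl$marker <- vapply(seq_len(nrow(qtl)), function(i) {
    sub <- map[map$chrom == qtl$chrom[i], ]
    sub$marker[which.min(abs(sub$pos_cm - qtl$pos_cm[i]))]
  }, "")
  qtl
}

#' Simulate plot-level phenotypes
#'
#' Every genotype x site x rep cell receives
#' `mu + QTL effects + polygenic deviate + site effect + GxE deviate +
#' residual` (all cm). QTL act through the genotype at their nearest map
#' marker; the additive effect is the full difference between the two
#' homozygous classes, centred so `mu` stays the population mean. The
#' polygenic deviate is marker-linked (an infinitesimal-model sum of small
#' effects over every marker, rescaled to sample variance `sigma2_g`), so
#' genome-wide prediction retains signal outside the major QTL. Site
#' effects are drawn once per site, GxE deviates i.i.d. per genotype x
#' site, residuals i.i.d. per plot. The table is exactly balanced.
#'
#' @param geno genotype matrix (lines x markers, 0/1).
#' @param map linkage map aligned with `geno` columns.
#' @param qtl data frame (chrom, pos_cm, effect_cm); may have 0 rows.
#' @param config a [sim_config()] (variances, design sizes, `mu_cm`).
#' @param seed integer seed.
#' @param stage stage label stamped on the table.
#' @param stage_factor multiplier on the genetic signal (e.g. < 1 at
#'   booting, before final height is reached).
#' @return list with `phenotypes` (genotype_id, site, rep, stage, source =
#'   "ground", value_cm), `genetic_values` (named, cm, deviations from mu),
#'   and `site_effects`.
#' @export
simulate_phenotypes <- function(geno, map, qtl, config, seed = config$seed,
                                stage = "mid_grain_fill", stage_factor = 1) {
  check_map(map)
  stopifnot(identical(colnames(geno), map$marker))
  set.seed(seed)
  n <- nrow(geno)
  ids <- rownames(geno)
  # polygenic background: many small effects spread over every marker
  # (infinitesimal model), rescaled so its sample variance over the
  # population is exactly sigma2_g; marker-linked, so genomic prediction
  # retains signal when major-QTL regions are excluded
  gv <- rep(0, n)
  if (config$sigma2_g > 0) {
    beta <- stats::rnorm(ncol(geno))
    pg <- as.vector((geno - 0.5) %*% beta)
    s <- stats::sd(pg)
    if (s > 0) gv <- pg * sqrt(config$sigma2_g) / s
  }
  if (nrow(qtl) > 0) {
    qtl <- snap_qtl(qtl, map)
    for (i in seq_len(nrow(qtl)))
      gv <- gv + (geno[, qtl$marker[i]] - 0.5) * qtl$effect_cm[i]
  }
  names(gv) <- ids
  sites <- sprintf("site%d", seq_len(config$n_sites))
  site_eff <- stats::rnorm(config$n_sites, 0, sqrt(config$sigma2_site))
  names(site_eff) <- sites
  ge <- matrix(stats::rnorm(n * config$n_sites, 0, sqrt(config$sigma2_ge)),
               n, config$n_sites, dimnames = list(ids, sites))
  tab <- expand.grid(rep = seq_len(config$n_reps), site = sites,
                     genotype_id = ids, KEEP.OUT.ATTRS = FALSE,
                     stringsAsFactors = FALSE)
  tab <- tab[, c("genotype_id", "site", "rep")]
  eps <- stats::rnorm(nrow(tab), 0, sqrt(config$sigma2_e))
  tab$stage <- stage
  tab$source <- "ground"
  tab$value_cm <- config$mu_cm +
    stage_factor * gv[tab$genotype_id] +
    site_eff[tab$site] +
    stage_factor * ge[cbind(tab$genotype_id, tab$site)] +
    eps
  rownames(tab) <- NULL
  list(phenotypes = tab, genetic_values = gv, site_effects = site_eff)
}

#' Lay out the field
#'
#' Plots are 1.3 m x 3 m rectangles on a regular grid with alleys between
#' columns and rows; each replicate is a contiguous block with its own
#' randomisation of the genotypes (RCBD). Bare-ground polygons are placed in
#' the horizontal alleys on a regular spacing so the terrain is sampled
#' across the whole field. All sites share the same local coordinates (each
#' site is its own field; rasters are per site).
#'
#' @param genotype_ids genotype labels to plant.
#' @param config a [sim_config()].
#' @param seed seed for the per-block randomisation.
#' @return list of class `field_layout`: `plots` (plot_id, genotype_id, rep,
#'   site, xmin/ymin/xmax/ymax), `bare` (polygon_id, bounds), `extent`,
#'   and the plot dimensions.
#' @export
make_field_layout <- function(genotype_ids, config, seed = config$seed) {
  set.seed(seed + 1000L)
  n_geno <- length(genotype_ids)
  n_plots <- n_geno * config$n_reps
  sx <- config$plot_w + config$alley_x
  sy <- config$plot_l + config$alley_y
  n_cols <- max(2L, ceiling(sqrt(n_plots * sy / sx)))
  n_rows <- ceiling(n_plots / n_cols)
  sites <- sprintf("site%d", seq_len(config$n_sites))
  plots <- vector("list", config$n_sites)
  for (s in seq_along(sites)) {
    order_ids <- unlist(lapply(seq_len(config$n_reps),
                               function(r) sample(genotype_ids)))
    reps <- rep(seq_len(config$n_reps), each = n_geno)
    idx <- seq_len(n_plots)
    row <- (idx - 1L) %/% n_cols + 1L
    col <- (idx - 1L) %% n_cols + 1L
    xmin <- config$margin + (col - 1L) * sx
    ymin <- config$margin + (row - 1L) * sy
    plots[[s]] <- data.frame(
      plot_id = sprintf("%s_p%03d", sites[s], idx),
      genotype_id = order_ids,
      rep = reps,
      site = sites[s],
      xmin = xmin, ymin = ymin,
      xmax = xmin + config$plot_w, ymax = ymin + config$plot_l,
      stringsAsFactors = FALSE
    )
  }
  plots <- do.call(rbind, plots)
  # bare-ground patches in the horizontal alleys, every 4th column, plus the
  # outer margins, so control points cover the field edge to edge
  bw <- 0.5; bh <- min(0.35, config$alley_y - 0.1)
  cols_b <- sort(unique(c(seq(1L, n_cols, by = 4L), n_cols)))
  rows_b <- 0:n_rows
  bare <- expand.grid(col = cols_b, row = rows_b, KEEP.OUT.ATTRS = FALSE)
  bx <- config$margin + (bare$col - 1L) * sx + config$plot_w / 2 - bw / 2
  by <- config$margin + bare$row * sy - config$alley_y / 2 - bh / 2
  bare <- data.frame(
    polygon_id = sprintf("bare%03d", seq_len(nrow(bare))),
    xmin = bx, ymin = by, xmax = bx + bw, ymax = by + bh,
    stringsAsFactors = FALSE
  )
  ext <- c(xmin = 0,
           xmax = 2 * config$margin + n_cols * sx - config$alley_x,
           ymin = 0,
           ymax = 2 * config$margin + n_rows * sy - config$alley_y)
  bare$ymin <- pmax(bare$ymin, 0.05)
  bare$ymax <- pmax(bare$ymax, bare$ymin + bh)
  structure(list(plots = plots, bare = bare, extent = ext,
                 plot_w = config$plot_w, plot_l = config$plot_l),
            class = "field_layout")
}

#' @export
print.field_layout <- function(x, ...) {
  cat(sprintf("<field_layout> %d plots (%d sites), %d bare-ground polygons\n",
              nrow(x$plots), length(unique(x$plots$site)), nrow(x$bare)))
  cat(sprintf("  extent: %.1f m x %.1f m\n",
              x$extent["xmax"] - x$extent["xmin"],
              x$extent["ymax"] - x$extent["ymin"]))
  invisible(x)
}

plot_ring <- function(p)
  rect_ring(p$xmin, p$ymin, p$xmax, p$ymax)

# smooth terrain: tilted plane + two low-frequency sinusoids, seed-derived
# orientation and phase, total relief ~ `amplitude` across the field
terrain_fun <- function(config, extent, seed) {
  set.seed(seed + 2000L)
  w <- extent["xmax"] - extent["xmin"]
  h <- extent["ymax"] - extent["ymin"]
  dmax <- max(w, h)
  a <- config$terrain_amplitude
  th <- stats::runif(1, 0, 2 * pi)
  slope <- 0.5 * a / dmax
  sin_a <- c(0.2, 0.15) * a
  sin_th <- stats::runif(2, 0, 2 * pi)
  sin_l <- c(0.9, 0.6) * dmax
  sin_ph <- stats::runif(2, 0, 2 * pi)
  base <- config$base_elev
  function(x, y) {
    z <- base + slope * (cos(th) * x + sin(th) * y)
    for (k in 1:2)
      z <- z + sin_a[k] *
        sin(2 * pi * (cos(sin_th[k]) * x + sin(sin_th[k]) * y) / sin_l[k] +
              sin_ph[k])
    z
  }
}

#' Render the DSM and true DTM of one site
#'
#' The true DTM is a smooth terrain surface (plane + low-frequency
#' sinusoids) sampled at the ground sampling distance. Inside each plot a
#' fraction `spike_fraction` of pixels sit at canopy-top level minus a
#' half-normal mixed-pixel attenuation (scale `spike_sd`; a pixel averages a
#' spike tip with its surroundings, so the photogrammetric surface cannot
#' exceed the true tip), and the remaining pixels sample the lower canopy
#' (leaves and gaps) uniformly between 45% and 90% of plant height. Alleys
#' and bare ground are terrain only. I.i.d. sensor noise is added to every
#' DSM pixel. Both rasters share grid, CRS and nodata convention.
#'
#' @param layout a [make_field_layout()].
#' @param plot_heights named vector of true plant heights in cm, one entry
#'   per plot_id of `site`.
#' @param config a [sim_config()].
#' @param site site label to render.
#' @param seed integer seed (terrain and texture).
#' @param spike_fraction optional override: scalar or named per-plot vector.
#' @return list `dsm`, `dtm` of [elev_raster()] on the same grid.
#' @export
render_field_dsm <- function(layout, plot_heights, config, site = "site1",
                             seed = config$seed, spike_fraction = NULL) {
  if (config$gsd > min(config$plot_w, config$plot_l))
    stop("gsd exceeds the smallest plot dimension; plots would have no pixels",
         call. = FALSE)
  plots <- layout$plots[layout$plots$site == site, , drop = FALSE]
  if (nrow(plots) == 0L) stop("no plots for site ", site, call. = FALSE)
  missing_h <- setdiff(plots$plot_id, names(plot_heights))
  if (length(missing_h))
    stop("no true height for plots: ", paste(utils::head(missing_h, 3),
                                             collapse = ", "), call. = FALSE)
  ext <- layout$extent
  cs <- config$gsd
  nc <- ceiling((ext["xmax"] - ext["xmin"]) / cs)
  nr <- ceiling((ext["ymax"] - ext["ymin"]) / cs)
  tmpl <- elev_raster(matrix(0, nr, nc), xmin = ext[["xmin"]],
                      ymin = ext[["ymin"]], cellsize = cs)
  xs <- raster_x(tmpl)
  ys <- raster_y(tmpl)
  site_idx <- match(site, sort(unique(layout$plots$site)))
  tf <- terrain_fun(config, ext, seed + 10L * site_idx)
  terrain <- outer(ys, xs, function(y, x) tf(x, y))
  set.seed(seed + 3000L + site_idx)
  canvas <- terrain
  sf <- spike_fraction
  for (i in seq_len(nrow(plots))) {
    p <- plots[i, ]
    ci <- which(xs >= p$xmin & xs < p$xmax)
    ri <- which(ys >= p$ymin & ys < p$ymax)
    npx <- length(ci) * length(ri)
    if (npx == 0L) next
    h <- plot_heights[[p$plot_id]] / 100  # cm -> m
    frac <- if (is.null(sf)) config$spike_fraction
            else if (length(sf) == 1L) sf else sf[[p$plot_id]]
    spike <- stats::runif(npx) < frac
    vals <- numeric(npx)
    vals[spike] <- h - abs(stats::rnorm(sum(spike), 0, config$spike_sd))
    vals[!spike] <- h * stats::runif(sum(!spike), 0.45, 0.90)
    canvas[ri, ci] <- terrain[ri, ci] + matrix(vals, length(ri), length(ci))
  }
  dsm_vals <- canvas +
    matrix(stats::rnorm(nr * nc, 0, config$noise_sd), nr, nc)
  list(
    dsm = elev_raster(dsm_vals, ext[["xmin"]], ext[["ymin"]], cs),
    dtm = elev_raster(terrain, ext[["xmin"]], ext[["ymin"]], cs)
  )
}

#' Simulate a complete field trial
#'
#' Driver tying the generator together: map, DH genotypes (plus parents),
#' QTL effects, plot phenotypes for every site, the field layout, and —
#' optionally — rendered DSM/true-DTM raster pairs per site.
#'
#' @param config a [sim_config()].
#' @param render render rasters (set `FALSE` for genetics-only work).
#' @param sites sites to render (default all).
#' @return list with `map`, `geno` (incl. parents if configured), `qtl`,
#'   `phenotypes` (ground source, true plot heights), `genetic_values`,
#'   `layout`, `plot_heights` (named cm vector over all plots) and
#'   `rasters` (per-site list of `dsm`/`dtm`).
#' @export
simulate_field <- function(config = sim_config(), render = TRUE,
                           sites = NULL) {
  map <- sim_linkage_map(config$n_chromosomes, config$chrom_length_cm,
                         config$marker_spacing_cm, config$chrom_names)
  geno <- simulate_dh_population(map, config$n_lines, seed = config$seed)
  if (config$include_parents) geno <- add_parents(geno)
  sim <- simulate_phenotypes(geno, map, config$qtl, config,
                             seed = config$seed + 1L)
  layout <- make_field_layout(rownames(geno), config, seed = config$seed)
  ph <- sim$phenotypes
  key <- paste(ph$genotype_id, ph$site, ph$rep)
  pkey <- paste(layout$plots$genotype_id, layout$plots$site, layout$plots$rep)
  plot_heights <- ph$value_cm[match(pkey, key)]
  names(plot_heights) <- layout$plots$plot_id
  rasters <- NULL
  if (render) {
    if (is.null(sites)) sites <- sort(unique(layout$plots$site))
    rasters <- lapply(sites, function(s)
      render_field_dsm(layout, plot_heights, config, site = s,
                       seed = config$seed))
    names(rasters) <- sites
  }
  list(map = map, geno = geno, qtl = config$qtl, phenotypes = ph,
       genetic_values = sim$genetic_values, site_effects = sim$site_effects,
       layout = layout, plot_heights = plot_heights, rasters = rasters,
       config = config)
}
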