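test_that("Haldane map function matches its closed form and limits", {
  expect_equal(haldane_r(0), 0)
  expect_equal(haldane_r(10), (1 - exp(-0.2)) / 2)
  expect_equal(haldane_r(1e9), 0.5)
})

test_that("DH gametes recombine at the Haldane fraction of the map distance", {
  # zero distance forces co-inheritance
  map0 <- data.frame(marker = c("a", "b"), chrom = "1A", pos_cm = c(5, 5),
                     stringsAsFactors = FALSE)
  g0 <- simulate_dh_population(map0, 1000, seed = 3)
  expect_equal(mean(g0[, 1] != g0[, 2]), 0)
  # 10 cM: observed fraction within 3 binomial SE of (1 - e^-0.2)/2 = 0.0906
  map10 <- data.frame(marker = c("a", "b"), chrom = "1A", pos_cm = c(0, 10),
                      stringsAsFactors = FALSE)
  g10 <- simulate_dh_population(map10, 5000, seed = 7)
  r_hat <- mean(g10[, 1] != g10[, 2])
  r_exp <- haldane_r(10)
  se <- sqrt(r_exp * (1 - r_exp) / 5000)
  expect_lt(abs(r_hat - r_exp), 3 * se)
  # unlinked limit: recombination fraction approaches 1/2
  mapu <- data.frame(marker = c("a", "b"), chrom = "1A", pos_cm = c(0, 1e5),
                     stringsAsFactors = FALSE)
  gu <- simulate_dh_population(mapu, 5000, seed = 9)
  expect_lt(abs(mean(gu[, 1] != gu[, 2]) - 0.5), 3 * sqrt(0.25 / 5000))
  expect_error(simulate_dh_population(data.frame(), 10), "empty")
})

test_that("genotypes are biallelic with ~0.5 allele frequency and Haldane-consistent LD", {
  map <- sim_linkage_map(2, 100, 5, c("1A", "1B"))
  g <- simulate_dh_population(map, 198, seed = 11)
  expect_true(all(g %in% c(0L, 1L)))
  freq <- colMeans(g)
  se <- sqrt(0.25 / 198)
  expect_true(all(abs(freq - 0.5) < 4 * se))
  # adjacent-marker recombinant fractions across the whole map, 3 SE each
  r_exp <- haldane_r(5)
  se_r <- sqrt(r_exp * (1 - r_exp) / 198)
  for (ch in c("1A", "1B")) {
    idx <- which(map$chrom == ch)
    r_hat <- vapply(idx[-length(idx)], function(j)
      mean(g[, j] != g[, j + 1]), 0)
    expect_true(all(abs(r_hat - r_exp) < 3.5 * se_r))
  }
})

test_that("phenotype table is balanced and degenerates to two QTL classes", {
  cfg <- tiny_config(sigma2_g = 0, sigma2_ge = 0, sigma2_e = 0,
                     sigma2_site = 0,
                     qtl = data.frame(chrom = "4B", pos_cm = 50,
                                      effect_cm = 10))
  map <- sim_linkage_map(3, 150, 2, c("4B", "4D", "6D"))
  g <- simulate_dh_population(map, 20, seed = 2)
  sim <- simulate_phenotypes(g, map, cfg$qtl, cfg, seed = 4)
  expect_equal(nrow(sim$phenotypes), 20 * 2 * 3)
  vals <- sort(unique(round(sim$phenotypes$value_cm, 9)))
  expect_length(vals, 2)
  expect_equal(diff(vals), 10)
  # QTL on an absent chromosome is refused
  bad <- data.frame(chrom = "7A", pos_cm = 10, effect_cm = 1)
  expect_error(simulate_phenotypes(g, map, bad, cfg), "absent")
})

test_that("residual variance is recovered when genetic variances are off", {
  cfg <- tiny_config(n_lines = 150L, sigma2_g = 0, sigma2_ge = 0,
                     sigma2_e = 36, qtl = data.frame(chrom = character(0),
                                                     pos_cm = numeric(0),
                                                     effect_cm = numeric(0)))
  map <- sim_linkage_map(3, 150, 2, c("4B", "4D", "6D"))
  g <- simulate_dh_population(map, 150, seed = 5)
  sim <- simulate_phenotypes(g, map, cfg$qtl, cfg, seed = 6)
  ph <- sim$phenotypes
  cellvar <- tapply(ph$value_cm, paste(ph$genotype_id, ph$site),
                    stats::var)
  expect_lt(abs(mean(cellvar) - 36) / 36, 0.15)
})

test_that("default architecture reproduces the trial's population spread", {
  cfg <- sim_config(include_parents = FALSE)
  map <- sim_linkage_map(cfg$n_chromosomes, cfg$chrom_length_cm,
                         cfg$marker_spacing_cm, cfg$chrom_names)
  g <- simulate_dh_population(map, cfg$n_lines, seed = 13)
  sim <- simulate_phenotypes(g, map, cfg$qtl, cfg, seed = 14)
  y <- line_means(sim$phenotypes)
  # configured line-mean variance: QTL + polygene + ge/e + residual/(re)
  target <- sqrt(sum(cfg$qtl$effect_cm^2) / 4 + cfg$sigma2_g +
                   cfg$sigma2_ge / 2 + cfg$sigma2_e / 6)
  expect_lt(abs(stats::sd(y) - target) / target, 0.15)
})

test_that("degenerate texture renders canopy at exactly terrain + height", {
  cfg <- degenerate_config()
  f <- simulate_field(cfg, sites = "site1")
  r <- f$rasters$site1
  p <- f$layout$plots[f$layout$plots$site == "site1", ][3, ]
  xs <- uavheight:::raster_x(r$dsm)
  ys <- uavheight:::raster_y(r$dsm)
  ci <- which(xs >= p$xmin & xs < p$xmax)
  ri <- which(ys >= p$ymin & ys < p$ymax)
  h_m <- f$plot_heights[[p$plot_id]] / 100
  expect_equal(r$dsm$values[ri, ci] - r$dtm$values[ri, ci],
               matrix(h_m, length(ri), length(ci)), tolerance = 1e-12)
})

test_that("bare-ground pixels carry only terrain plus sensor noise", {
  cfg <- tiny_config(seed = 21)
  f <- simulate_field(cfg, sites = "site1")
  r <- f$rasters$site1
  xs <- uavheight:::raster_x(r$dsm)
  ys <- uavheight:::raster_y(r$dsm)
  diffs <- unlist(lapply(seq_len(nrow(f$layout$bare)), function(i) {
    b <- f$layout$bare[i, ]
    ci <- which(xs >= b$xmin & xs <= b$xmax)
    ri <- which(ys >= b$ymin & ys <= b$ymax)
    r$dsm$values[ri, ci] - r$dtm$values[ri, ci]
  }))
  expect_lt(abs(mean(diffs)), 3 * cfg$noise_sd / sqrt(length(diffs)))
  expect_lt(abs(stats::sd(diffs) - cfg$noise_sd) / cfg$noise_sd, 0.1)
})

test_that("canopy pixels reach the true height in nearly every plot", {
  cfg <- tiny_config(seed = 8)
  f <- simulate_field(cfg, sites = "site1")
  r <- f$rasters$site1
  xs <- uavheight:::raster_x(r$dsm)
  ys <- uavheight:::raster_y(r$dsm)
  plots <- f$layout$plots[f$layout$plots$site == "site1", ]
  ok <- vapply(seq_len(nrow(plots)), function(i) {
    p <- plots[i, ]
    ci <- which(xs >= p$xmin & xs < p$xmax)
    ri <- which(ys >= p$ymin & ys < p$ymax)
    mx <- max(r$dsm$values[ri, ci] - r$dtm$values[ri, ci])
    mx >= f$plot_heights[[p$plot_id]] / 100 - 2 * cfg$noise_sd
  }, TRUE)
  expect_gte(mean(ok), 0.99)
})

test_that("rendering is bit-identical under a repeated seed", {
  cfg <- tiny_config(seed = 31)
  a <- simulate_field(cfg, sites = "site1")
  b <- simulate_field(cfg, sites = "site1")
  expect_identical(a$rasters$site1$dsm$values, b$rasters$site1$dsm$values)
  expect_identical(a$rasters$site1$dtm$values, b$rasters$site1$dtm$values)
  expect_identical(a$plot_heights, b$plot_heights)
})

test_that("gsd coarser than the plot is refused", {
  cfg <- tiny_config(gsd = 2)
  map <- sim_linkage_map(3, 150, 2, c("4B", "4D", "6D"))
  g <- simulate_dh_population(map, 20, seed = 2)
  sim <- simulate_phenotypes(g, map, cfg$qtl, cfg, seed = 4)
  lay <- make_field_layout(rownames(g), cfg)
  key <- paste(sim$phenotypes$genotype_id, sim$phenotypes$site,
               sim$phenotypes$rep)
  h <- sim$phenotypes$value_cm[match(paste(lay$plots$genotype_id,
                                           lay$plots$site, lay$plots$rep),
                                     key)]
  names(h) <- lay$plots$plot_id
  expect_error(render_field_dsm(lay, h, cfg, site = "site1"), "gsd")
})

test_that("layout reproduces the trial design: 600 disjoint plots per site", {
  cfg <- sim_config()  # 198 DH + 2 parents, 3 reps
  ids <- c(sprintf("DH%03d", 1:198), "P1", "P2")
  lay <- make_field_layout(ids, cfg)
  for (s in c("site1", "site2")) {
    p <- lay$plots[lay$plots$site == s, ]
    expect_equal(nrow(p), 600L)
    expect_equal(sort(unique(table(p$genotype_id))), 3L)
  }
  # plot rectangles are pairwise disjoint (grid spacing exceeds plot size)
  p1 <- lay$plots[lay$plots$site == "site1", ]
  ov <- outer(seq_len(nrow(p1)), seq_len(nrow(p1)), function(i, j)
    p1$xmin[i] < p1$xmax[j] & p1$xmax[i] > p1$xmin[j] &
      p1$ymin[i] < p1$ymax[j] & p1$ymax[i] > p1$ymin[j])
  expect_equal(sum(ov), nrow(p1))  # only self-overlaps
  # bare-ground polygons never intersect plots
  b <- lay$bare
  hit <- outer(seq_len(nrow(b)), seq_len(nrow(p1)), function(i, j)
    b$xmin[i] < p1$xmax[j] & b$xmax[i] > p1$xmin[j] &
      b$ymin[i] < p1$ymax[j] & b$ymax[i] > p1$ymin[j])
  expect_equal(sum(hit), 0L)
})
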