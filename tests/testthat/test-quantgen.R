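make_geno <- function(n = 120, n_chrom = 3, len = 150, sp = 2, seed = 1,
                      names = c("4B", "4D", "6D")) {
  map <- sim_linkage_map(n_chrom, len, sp, names)
  list(map = map, geno = simulate_dh_population(map, n, seed = seed))
}

test_that("line means are exact under degenerate designs and zero noise", {
  tab <- data.frame(genotype_id = c("a", "b"), value_cm = c(70, 90))
  expect_equal(line_means(tab), c(a = 70, b = 90))
  # linearity: mean of v + delta equals v + mean(delta)
  tab2 <- expand.grid(genotype_id = "a", site = c("s1", "s2"), rep = 1:3,
                      stringsAsFactors = FALSE)
  delta <- c(1, -2, 3, -4, 5, -6)
  tab2$value_cm <- 80 + delta
  expect_equal(unname(line_means(tab2)), 80 + mean(delta))
  # zero-noise simulation: line means equal mu + genetic values exactly
  cfg <- tiny_config(sigma2_ge = 0, sigma2_e = 0, sigma2_site = 0)
  map <- sim_linkage_map(3, 150, 2, c("4B", "4D", "6D"))
  g <- simulate_dh_population(map, 20, seed = 3)
  sim <- simulate_phenotypes(g, map, cfg$qtl, cfg, seed = 5)
  expect_equal(line_means(sim$phenotypes, rownames(g)),
               cfg$mu_cm + sim$genetic_values, tolerance = 1e-12)
  expect_error(line_means(tab, genotypes = c("a", "zz")), "no observations")
})

test_that("a marker collinear with the phenotype is selected first", {
  gm <- make_geno(n = 80, seed = 21)
  y <- as.numeric(gm$geno[, "4D_0500"]) * 10 + 70
  sel <- select_cofactors(gm$geno, y)
  expect_equal(sel[1], "4D_0500")
})

test_that("cofactor selection stays near the null expectation on pure noise", {
  gm <- make_geno(n = 150, n_chrom = 5, sp = 1.5,
                  names = paste0("c", 1:5), seed = 31)
  expect_gte(ncol(gm$geno), 500)
  set.seed(8)
  y <- stats::rnorm(150)
  sel <- select_cofactors(gm$geno, y, p_in = 0.001, p_out = 0.002)
  # expected false entries ~ 0.5 under the null; allow a generous margin
  expect_lte(length(sel), 3)
})

test_that("scan at a marker equals single-marker regression and is affine invariant", {
  gm <- make_geno(n = 100, seed = 41)
  set.seed(9)
  y <- 75 + gm$geno[, "4B_0400"] * 8 + stats::rnorm(100, 0, 5)
  sc <- icim_scan(gm$geno, gm$map, y, character(0), step_cm = 2)
  # at marker positions the expected genotype collapses to the observed one
  at_marker <- sc[sc$chrom == "4B" & sc$pos_cm == 40, ]
  x <- gm$geno[, "4B_0400"]
  rss0 <- sum((y - mean(y))^2)
  rss1 <- sum(stats::resid(stats::lm(y ~ x))^2)
  expect_equal(at_marker$lod, 50 * log10(rss0 / rss1), tolerance = 1e-9)
  expect_equal(at_marker$effect_cm,
               unname(stats::coef(stats::lm(y ~ x))[2]) / 2,
               tolerance = 1e-9)
  # LOD is invariant under affine transformation of the phenotype
  sc2 <- icim_scan(gm$geno, gm$map, 3.2 * y - 100, character(0), step_cm = 2)
  expect_equal(sc2$lod, sc$lod, tolerance = 1e-8)
  expect_true(all(sc$lod >= 0))
  expect_true(all(sc$pve >= 0 & sc$pve <= 100))
})

test_that("a planted QTL is located and two distant QTL give two peaks", {
  gm <- make_geno(n = 198, seed = 51)
  set.seed(10)
  # effects sized to ~30% PVE each, 80 cM apart on 4B
  y <- 70 + gm$geno[, "4B_0300"] * 8 + gm$geno[, "4B_1100"] * 8 +
    stats::rnorm(198, 0, 5)
  cof <- select_cofactors(gm$geno, y)
  sc <- icim_scan(gm$geno, gm$map, y, cof)
  pk <- qtl_peaks(sc, threshold = 2.5, geno = gm$geno, map = gm$map, y = y)
  pk4b <- pk[pk$chrom == "4B", ]
  expect_equal(nrow(pk4b), 2L)
  expect_lt(abs(pk4b$pos_cm[1] - 30), 10)
  expect_lt(abs(pk4b$pos_cm[2] - 110), 10)
  expect_true(all(pk$ci_lo <= pk$pos_cm & pk$ci_hi >= pk$pos_cm))
})

test_that("peak calling returns nothing on flat profiles and breaks ties leftward", {
  flat <- data.frame(chrom = "1A", pos_cm = 0:50, lod = 1.0,
                     effect_cm = 0, pve = 0)
  expect_equal(nrow(qtl_peaks(flat, threshold = 2.5)), 0L)
  tied <- data.frame(chrom = "1A", pos_cm = 0:10,
                     lod = c(0, 1, 2, 4, 4, 2, 1, 0, 0, 0, 0),
                     effect_cm = 0, pve = 0)
  pk <- qtl_peaks(tied, threshold = 2.5)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$pos_cm, 3)
})

test_that("ridge BLUP matches an independent normal-equations solve", {
  gm <- make_geno(n = 20, n_chrom = 1, len = 100, sp = 2, names = "1A",
                  seed = 61)
  geno <- gm$geno[, 1:50]
  set.seed(11)
  y <- stats::rnorm(20, 80, 8)
  fit <- fit_gblup(geno, y, lambda = 10)
  # oracle: primal normal equations on the same centred coding
  X <- 2 * (geno - 0.5)
  X <- sweep(X, 2, colMeans(X))
  g_oracle <- solve(crossprod(X) + 10 * diag(ncol(X)),
                    crossprod(X, y - mean(y)))
  expect_lt(max(abs(fit$effects - as.vector(g_oracle))), 1e-8)
  pred_oracle <- mean(y) + as.vector(X %*% g_oracle)
  expect_lt(max(abs(predict_gblup(fit, geno) - pred_oracle)), 1e-8)
})

test_that("shrinkage limits behave: infinite lambda gives the mean, zero gives OLS", {
  gm <- make_geno(n = 60, n_chrom = 1, len = 40, sp = 2, names = "1A",
                  seed = 71)
  geno <- gm$geno  # 60 lines x 21 markers: n > p
  set.seed(12)
  y <- stats::rnorm(60, 80, 8)
  inf <- fit_gblup(geno, y, lambda = 1e12)
  expect_lt(max(abs(inf$effects)), 1e-6)
  expect_equal(predict_gblup(inf, geno), rep(mean(y), 60), tolerance = 1e-4)
  ols <- fit_gblup(geno, y, lambda = 0)
  X <- 2 * (geno - 0.5)
  X <- sweep(X, 2, colMeans(X))
  lmfit <- stats::lm(y ~ X)
  expect_equal(ols$fitted, unname(stats::fitted(lmfit)), tolerance = 1e-8)
})

test_that("predictions are invariant to marker coding sign flips", {
  gm <- make_geno(n = 50, seed = 81)
  set.seed(13)
  y <- stats::rnorm(50, 80, 8)
  a <- fit_gblup(gm$geno, y, lambda = 5)
  flipped <- 1L - gm$geno
  b <- fit_gblup(flipped, y, lambda = 5)
  expect_equal(predict_gblup(a, gm$geno), predict_gblup(b, flipped),
               tolerance = 1e-9)
})

test_that("cross-validation is deterministic, supports leave-one-out and REML", {
  gm <- make_geno(n = 40, n_chrom = 2, len = 60, sp = 4,
                  names = c("1A", "2A"), seed = 91)
  set.seed(14)
  y <- 75 + rowSums(2 * (gm$geno[, c(3, 20)] - 0.5)) * 4 +
    stats::rnorm(40, 0, 3)
  a <- cross_validate(gm$geno, y, k = 5, repeats = 3, seed = 5)
  b <- cross_validate(gm$geno, y, k = 5, repeats = 3, seed = 5)
  expect_identical(a$predictions, b$predictions)
  expect_true(all(colSums(is.na(a$predictions)) == 0))
  loo <- cross_validate(gm$geno, y, k = 40, repeats = 1, seed = 5,
                        lambda = 20)
  expect_true(is.finite(loo$r))
  expect_true(abs(loo$r) <= 1)
})

test_that("excluding nothing reproduces the full model exactly", {
  gm <- make_geno(n = 40, seed = 95)
  set.seed(15)
  y <- stats::rnorm(40, 80, 5)
  ex <- marker_exclusion_experiment(gm$geno, gm$map, y,
                                    exclude_chroms = character(0),
                                    k = 5, repeats = 3, seed = 6,
                                    lambda = 50)
  expect_equal(ex$r_full, ex$r_excluded, tolerance = 1e-12)
  expect_equal(ex$diff, 0, tolerance = 1e-12)
  expect_error(
    marker_exclusion_experiment(gm$geno, gm$map, y,
                                exclude_chroms = c("4B", "4D", "6D"),
                                k = 5, repeats = 2, seed = 6),
    "fewer than 10")
})
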