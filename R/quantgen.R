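# Quantitative genetics on DH-line means: inclusive composite interval
# mapping in regression (Haley-Knott) form -- stepwise cofactor selection
# followed by an adjusted-phenotype interval scan using expected QTL
# genotypes from flanking markers under Haldane recombination -- plus
# ridge-regression BLUP genomic prediction with REML shrinkage,
# cross-validation and the marker-exclusion experiment.

#' Per-genotype entry means
#'
#' Arithmetic mean over sites and reps, the standard input for QTL scans and
#' genomic prediction in DH trials.
#'
#' @param table long-format phenotype table (genotype_id, value_cm).
#' @param genotypes optional genotype ids to keep, in order (e.g.
#'   `rownames(geno)` to drop parents).
#' @return named numeric vector of means (cm).
#' @export
line_means <- function(table, genotypes = NULL) {
  stopifnot(all(c("genotype_id", "value_cm") %in% names(table)))
  m0 <- tapply(table$value_cm, table$genotype_id, mean)
  m <- stats::setNames(as.vector(m0), dimnames(m0)[[1]])
  if (!is.null(genotypes)) {
    miss <- setdiff(genotypes, names(m))
    if (length(miss))
      stop("genotypes with no observations: ",
           paste(utils::head(miss, 3), collapse = ", "), call. = FALSE)
    m <- m[genotypes]
  }
  m
}

# partial-regression p-values of every candidate column of M given the
# columns already in X (with intercept); returns a vector of p-values
partial_pvals <- function(y, X, M) {
  qx <- qr(X)
  k <- qx$rank
  n <- length(y)
  ry <- qr.resid(qx, y)
  RM <- qr.resid(qx, M)
  sxx <- colSums(RM^2)
  sxy <- as.vector(crossprod(RM, ry))
  syy <- sum(ry^2)
  df <- n - k - 1L
  rss1 <- syy - ifelse(sxx > 1e-10, sxy^2 / sxx, 0)
  # a perfect predictor (rss1 ~ 0 with syy > 0) gets F = Inf, p = 0
  Fstat <- ifelse(sxx > 1e-10 & syy > 1e-12,
                  (syy - rss1) * df / pmax(rss1, 1e-300), 0)
  p <- stats::pf(Fstat, 1, df, lower.tail = FALSE)
  p[sxx <= 1e-10 | syy <= 1e-12] <- 1
  p
}

#' Stepwise cofactor selection
#'
#' Forward-backward stepwise marker regression with entry/exit p-value
#' thresholds — the background-control stage of inclusive composite interval
#' mapping. Deterministic given the data.
#'
#' @param geno lines x markers matrix (0/1).
#' @param y phenotype means aligned with `geno` rows.
#' @param p_in,p_out entry and exit p-value thresholds.
#' @param max_cofactors hard cap (default `n/5`) so the scan model stays
#'   well-conditioned.
#' @return character vector of selected marker names (possibly empty).
#' @export
select_cofactors <- function(geno, y, p_in = 0.001, p_out = 0.002,
                             max_cofactors = floor(nrow(geno) / 5)) {
  stopifnot(nrow(geno) == length(y), p_in <= p_out)
  n <- nrow(geno)
  sel <- character(0)
  repeat {
    changed <- FALSE
    if (length(sel) < max_cofactors) {
      cand <- setdiff(colnames(geno), sel)
      if (length(cand)) {
        X <- cbind(1, geno[, sel, drop = FALSE])
        p <- partial_pvals(y, X, geno[, cand, drop = FALSE])
        best <- which.min(p)
        if (p[best] < p_in) {
          sel <- c(sel, cand[best])
          changed <- TRUE
        }
      }
    }
    # backward sweep: drop the worst marker whose partial p exceeds p_out
    while (length(sel) > 0) {
      pdrop <- vapply(seq_along(sel), function(j) {
        X <- cbind(1, geno[, sel[-j], drop = FALSE])
        partial_pvals(y, X, geno[, sel[j], drop = FALSE])
      }, 0)
      worst <- which.max(pdrop)
      if (pdrop[worst] > p_out) {
        sel <- sel[-worst]
        changed <- TRUE
      } else break
    }
    if (!changed) break
  }
  sel
}

# expected QTL genotype P(Q = 1 | flanking DH genotypes) at position `s` on
# a chromosome with marker positions `pos` and genotype block `G` (0/1);
# Haldane, no interference
expected_genotype <- function(G, pos, s) {
  m <- length(pos)
  if (m == 1L) return(as.numeric(G[, 1]))
  jR <- findInterval(s, pos, rightmost.closed = TRUE) # interval index
  jL <- min(max(jR, 1L), m - 1L)
  jR <- jL + 1L
  rL <- haldane_r(s - pos[jL])
  rR <- haldane_r(pos[jR] - s)
  gL <- G[, jL]
  gR <- G[, jR]
  p11 <- (1 - rL) * (1 - rR)
  p10 <- (1 - rL) * rR
  p01 <- rL * (1 - rR)
  p00 <- rL * rR
  num <- gL * gR * p11 + gL * (1 - gR) * p10 + (1 - gL) * gR * p01 +
    (1 - gL) * (1 - gR) * p00
  den <- (gL == gR) * (p11 + p00) + (gL != gR) * (p10 + p01)
  num / den
}

#' Interval scan with cofactor control (ICIM, regression form)
#'
#' At each grid position the phenotype is adjusted for the selected
#' cofactors — excluding any cofactor within `window_cm` of the position on
#' the same chromosome, so the scanned QTL does not absorb itself — and
#' regressed on the expected QTL genotype computed from the flanking DH
#' marker genotypes under Haldane recombination. `LOD = (n/2) log10(RSS0 /
#' RSS1)`; the additive effect is half the fitted genotype contrast; PVE is
#' the RSS reduction rescaled against the total phenotypic variance of the
#' unadjusted means.
#'
#' @param geno lines x markers matrix (0/1), columns aligned with `map`.
#' @param map linkage map (marker, chrom, pos_cm).
#' @param y phenotype means aligned with `geno` rows.
#' @param cofactors marker names from [select_cofactors()] (may be empty,
#'   giving simple interval mapping).
#' @param step_cm scan step (cM).
#' @param window_cm cofactor exclusion window around the scan position.
#' @return data frame of class `qtl_scan` (chrom, pos_cm, lod, effect_cm,
#'   pve) with the cofactors as an attribute.
#' @export
icim_scan <- function(geno, map, y, cofactors = character(0), step_cm = 1,
                      window_cm = 10) {
  check_map(map)
  stopifnot(identical(colnames(geno), map$marker), nrow(geno) == length(y))
  n <- length(y)
  ss_tot <- sum((y - mean(y))^2)
  cof_pos <- map$pos_cm[match(cofactors, map$marker)]
  cof_chr <- map$chrom[match(cofactors, map$marker)]
  adj_cache <- new.env(parent = emptyenv())
  adjusted <- function(excl) {
    inc <- setdiff(cofactors, excl)
    key <- paste0("k:", paste(inc, collapse = ";"))
    if (!is.null(adj_cache[[key]])) return(adj_cache[[key]])
    ya <- if (length(inc) == 0) y else
      stats::resid(stats::lsfit(geno[, inc, drop = FALSE], y)) + mean(y)
    adj_cache[[key]] <- ya
    ya
  }
  rows <- list()
  for (ch in unique(map$chrom)) {
    sub <- map$chrom == ch
    pos <- map$pos_cm[sub]
    G <- geno[, sub, drop = FALSE]
    span <- max(pos) - min(pos)
    if (step_cm > span && span > 0) {
      warning("step larger than chromosome ", ch,
              "; evaluating at the midpoint only", call. = FALSE)
      grid <- min(pos) + span / 2
    } else grid <- seq(min(pos), max(pos), by = step_cm)
    for (s in grid) {
      excl <- cofactors[cof_chr == ch & abs(cof_pos - s) <= window_cm]
      ya <- adjusted(excl)
      x <- expected_genotype(G, pos, s)
      sxx <- sum((x - mean(x))^2)
      rss0 <- sum((ya - mean(ya))^2)
      if (sxx < 1e-10 || rss0 < 1e-12) {
        lod <- 0; a <- 0; pve <- 0
      } else {
        sxy <- sum((x - mean(x)) * (ya - mean(ya)))
        rss1 <- rss0 - sxy^2 / sxx
        lod <- (n / 2) * log10(rss0 / max(rss1, 1e-300))
        a <- (sxy / sxx) / 2
        pve <- 100 * (rss0 - rss1) / ss_tot
      }
      rows[[length(rows) + 1L]] <-
        data.frame(chrom = ch, pos_cm = s, lod = lod, effect_cm = a,
                   pve = pve, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "cofactors") <- cofactors
  class(out) <- c("qtl_scan", class(out))
  out
}

#' QTL peaks from a scan profile
#'
#' Local maxima above the LOD threshold, with 1-LOD support intervals;
#' peaks whose support intervals overlap on a chromosome are merged into the
#' stronger one (leftmost position on a tie). If `geno`/`y` are supplied,
#' per-peak PVE is recomputed from the joint multi-QTL regression on the
#' peak-nearest markers (each peak's PVE is the RSS increase from dropping
#' its marker from the joint model, over the total sum of squares).
#'
#' @param scan a `qtl_scan`.
#' @param threshold LOD threshold (default 2.5).
#' @param min_sep_cm minimum separation between reported peaks on a
#'   chromosome; closer local maxima (e.g. shoulders of a major QTL at the
#'   cofactor-window boundary) are absorbed into the stronger peak.
#' @param geno,map,y optional, for joint-model PVE.
#' @return data frame (chrom, pos_cm, lod, effect_cm, pve, ci_lo, ci_hi,
#'   marker).
#' @export
qtl_peaks <- function(scan, threshold = 2.5, min_sep_cm = 20, geno = NULL,
                      map = NULL, y = NULL) {
  peaks <- list()
  for (ch in unique(scan$chrom)) {
    pr <- scan[scan$chrom == ch, ]
    pr <- pr[order(pr$pos_cm), ]
    lod <- pr$lod
    n <- nrow(pr)
    if (n == 0) next
    # strict rise on the left, non-strict on the right: the leftmost point
    # of a tied plateau is the reported peak
    is_max <- vapply(seq_len(n), function(i) {
      lod[i] >= threshold &&
        lod[i] > (if (i > 1) lod[i - 1] else -Inf) &&
        lod[i] >= (if (i < n) lod[i + 1] else -Inf)
    }, TRUE)
    idx <- which(is_max)
    if (!length(idx)) next
    cand <- lapply(idx, function(i) {
      lo <- i; while (lo > 1 && lod[lo - 1] > lod[i] - 1) lo <- lo - 1
      hi <- i; while (hi < n && lod[hi + 1] > lod[i] - 1) hi <- hi + 1
      data.frame(chrom = ch, pos_cm = pr$pos_cm[i], lod = lod[i],
                 effect_cm = pr$effect_cm[i], pve = pr$pve[i],
                 ci_lo = pr$pos_cm[lo], ci_hi = pr$pos_cm[hi],
                 stringsAsFactors = FALSE)
    })
    cand <- do.call(rbind, cand)
    # merge overlapping support intervals, keeping the strongest peak
    # (leftmost on ties)
    cand <- cand[order(-cand$lod, cand$pos_cm), ]
    kept <- cand[0, ]
    for (i in seq_len(nrow(cand))) {
      ov <- nrow(kept) > 0 &&
        any(cand$ci_lo[i] <= kept$ci_hi & cand$ci_hi[i] >= kept$ci_lo |
              abs(cand$pos_cm[i] - kept$pos_cm) < min_sep_cm)
      if (!ov) kept <- rbind(kept, cand[i, ])
    }
    peaks[[ch]] <- kept
  }
  out <- if (length(peaks)) do.call(rbind, peaks) else
    data.frame(chrom = character(0), pos_cm = numeric(0), lod = numeric(0),
               effect_cm = numeric(0), pve = numeric(0), ci_lo = numeric(0),
               ci_hi = numeric(0))
  rownames(out) <- NULL
  if (nrow(out) == 0) return(out)
  out <- out[order(out$chrom, out$pos_cm), ]
  if (!is.null(geno) && !is.null(map) && !is.null(y)) {
    out$marker <- vapply(seq_len(nrow(out)), function(i) {
      sub <- map[map$chrom == out$chrom[i], ]
      sub$marker[which.min(abs(sub$pos_cm - out$pos_cm[i]))]
    }, "")
    M <- geno[, out$marker, drop = FALSE]
    ss_tot <- sum((y - mean(y))^2)
    rss_full <- sum(stats::resid(stats::lsfit(M, y))^2)
    out$pve <- vapply(seq_len(nrow(out)), function(i) {
      Mi <- M[, -i, drop = FALSE]
      rss_i <- if (ncol(Mi) == 0) ss_tot else
        sum(stats::resid(stats::lsfit(Mi, y))^2)
      100 * (rss_i - rss_full) / ss_tot
    }, 0)
  }
  rownames(out) <- NULL
  out
}

# centred marker design: {0,1} -> {-1,+1}, then column-centred; keeps the
# centring vector so new lines are coded identically
marker_design <- function(geno, centers = NULL) {
  X <- 2 * (as.matrix(geno) - 0.5)
  if (is.null(centers)) centers <- colMeans(X)
  list(X = sweep(X, 2, centers), centers = centers)
}

# restricted log-likelihood of the intercept + ridge model at shrinkage
# lambda, via the eigendecomposition of K = XX'
reml_ll <- function(loglam, d, z, w) {
  lam <- exp(loglam)
  dv <- d + lam
  sw <- sum(w^2 / dv)
  mu <- sum(w * z / dv) / sw
  R <- sum((z - w * mu)^2 / dv)
  n1 <- length(d) - 1
  -0.5 * (n1 * log(R / n1) + sum(log(dv)) + log(sw) + n1)
}

#' Ridge-regression BLUP (GBLUP) of marker effects
#'
#' Fits `y = mu + X g + e` with `g ~ N(0, sg2 I)`: the ridge solution
#' `g = X' (XX' + lambda I)^-1 (y - mu)` with `lambda = se2 / sg2`.
#' By default lambda is estimated by maximising the restricted likelihood
#' over a log-lambda grid followed by local refinement; a fixed lambda can
#' be supplied instead. Markers are coded {0,1} -> {-1,+1} and
#' column-centred. If the REML search fails to bracket a finite optimum the
#' fit falls back to `lambda = p` (number of markers) with a warning.
#'
#' @param geno lines x markers matrix (0/1).
#' @param y phenotype means aligned with rows.
#' @param lambda fixed shrinkage, or `NULL` for REML.
#' @return list of class `gblup_fit`: mu, effects, lambda, sigma2_g,
#'   sigma2_e (NA for fixed lambda), fitted, centers.
#' @export
fit_gblup <- function(geno, y, lambda = NULL) {
  stopifnot(nrow(geno) >= 2, nrow(geno) == length(y))
  md <- marker_design(geno)
  X <- md$X
  n <- nrow(X)
  K <- tcrossprod(X)
  sigma2_g <- sigma2_e <- NA_real_
  if (is.null(lambda)) {
    eg <- eigen(K, symmetric = TRUE)
    d <- pmax(eg$values, 0)
    z <- as.vector(crossprod(eg$vectors, y))
    w <- as.vector(crossprod(eg$vectors, rep(1, n)))
    grid <- seq(-8, 10, by = 0.25)
    ll <- vapply(grid, reml_ll, 0, d = d, z = z, w = w)
    if (all(!is.finite(ll))) {
      warning("REML failed to bracket an optimum; falling back to lambda = p",
              call. = FALSE)
      lambda <- ncol(X)
    } else {
      i <- which.max(ll)
      lo <- grid[max(1, i - 1)]
      hi <- grid[min(length(grid), i + 1)]
      opt <- stats::optimize(reml_ll, c(lo, hi), d = d, z = z, w = w,
                             maximum = TRUE)
      lambda <- exp(opt$maximum)
      dv <- d + lambda
      sw <- sum(w^2 / dv)
      mu <- sum(w * z / dv) / sw
      sigma2_g <- sum((z - w * mu)^2 / dv) / (n - 1)
      sigma2_e <- lambda * sigma2_g
    }
  }
  mu <- mean(y)  # the GLS intercept: X is column-centred, so K %*% 1 = 0
  if (lambda == 0) {
    # K is singular at lambda = 0 (centred X); use the primal least-squares
    # solution, which the ridge limit equals when X has full column rank
    effects <- as.vector(qr.coef(qr(X), y - mu))
    effects[is.na(effects)] <- 0
  } else {
    # dual (Woodbury) form of the ridge solution: X'(K + lambda I)^-1 ytilde
    alpha <- solve(K + lambda * diag(n), y - mu)
    effects <- as.vector(crossprod(X, alpha))
  }
  names(effects) <- colnames(geno)
  fitted <- mu + as.vector(X %*% effects)
  structure(list(mu = mu, effects = effects, lambda = lambda,
                 sigma2_g = sigma2_g, sigma2_e = sigma2_e, fitted = fitted,
                 centers = md$centers),
            class = "gblup_fit")
}

#' @rdname fit_gblup
#' @param fit a `gblup_fit`.
#' @param newgeno genotypes of lines to predict (0/1, same markers).
#' @return `predict_gblup()`: numeric vector of predictions.
#' @export
predict_gblup <- function(fit, newgeno) {
  Xn <- marker_design(newgeno, centers = fit$centers)$X
  fit$mu + as.vector(Xn %*% fit$effects)
}

#' Cross-validated genomic prediction accuracy
#'
#' Random k-fold partitions per repeat; the model (including REML shrinkage)
#' is refit on the training folds only. Accuracy per repeat is the mean of
#' the per-fold correlations between observed and predicted values (the
#' fold-wise convention: a correlation pooled across folds is pulled towards
#' -sqrt(k/n) under a null phenotype by the anti-correlation between a test
#' fold and its training mean, so it is not centred on zero when there is no
#' signal). For folds with fewer than 3 lines (e.g. leave-one-out) the
#' correlation is pooled within the repeat instead. The reported accuracy is
#' the average over repeats; deterministic given the seed.
#'
#' @param geno lines x markers matrix (0/1).
#' @param y phenotype means.
#' @param k folds (2..n; `k = n` is leave-one-out).
#' @param repeats number of repeated partitions.
#' @param seed integer seed.
#' @param lambda fixed shrinkage or `NULL` for per-fit REML.
#' @param folds optional precomputed list (one integer fold vector per
#'   repeat), e.g. to pair two experiments on identical partitions.
#' @return list of class `cv_result`: r (mean), r_repeats, predictions
#'   (n x repeats), k, repeats, seed, folds.
#' @export
cross_validate <- function(geno, y, k = 5, repeats = 20, seed = 1L,
                           lambda = NULL, folds = NULL) {
  n <- nrow(geno)
  stopifnot(k >= 2, k <= n, n == length(y))
  if (is.null(folds)) {
    set.seed(seed)
    folds <- lapply(seq_len(repeats), function(i)
      sample(rep(seq_len(k), length.out = n)))
  }
  repeats <- length(folds)
  preds <- matrix(NA_real_, n, repeats)
  r_rep <- numeric(repeats)
  for (rp in seq_len(repeats)) {
    fd <- folds[[rp]]
    r_fold <- c()
    for (f in unique(fd)) {
      test <- fd == f
      fit <- fit_gblup(geno[!test, , drop = FALSE], y[!test], lambda = lambda)
      preds[test, rp] <- predict_gblup(fit, geno[test, , drop = FALSE])
      if (sum(test) >= 3)
        r_fold <- c(r_fold, suppressWarnings(stats::cor(y[test],
                                                        preds[test, rp])))
    }
    r_rep[rp] <- if (length(r_fold)) mean(r_fold, na.rm = TRUE) else
      suppressWarnings(stats::cor(y, preds[, rp]))
  }
  structure(list(r = mean(r_rep, na.rm = TRUE), r_repeats = r_rep,
                 predictions = preds, k = k, repeats = repeats, seed = seed,
                 folds = folds),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> r = %.3f (mean of %d repeats, %d-fold)\n",
              x$r, x$repeats, x$k))
  invisible(x)
}

#' Marker-exclusion experiment
#'
#' Two cross-validations on identical fold partitions: all markers versus
#' markers outside the excluded regions (QTL support intervals plus a flank,
#' or whole chromosomes). Reports both accuracies and the per-repeat paired
#' differences, quantifying how much of the predictive signal the excluded
#' QTL regions carry.
#'
#' @param geno lines x markers (0/1), columns aligned with `map`.
#' @param map linkage map.
#' @param y phenotype means.
#' @param exclude_chroms chromosomes to drop entirely, and/or
#' @param exclude_regions data frame (chrom, ci_lo, ci_hi) of intervals to
#'   drop with `flank_cm` margin (e.g. `qtl_peaks()` output).
#' @param flank_cm flank added around each region (default 10).
#' @param k,repeats,seed,lambda as in [cross_validate()].
#' @return list of class `exclusion_result`: r_full, r_excluded, diff
#'   (mean paired difference), diff_repeats, n_markers_full,
#'   n_markers_excluded.
#' @export
marker_exclusion_experiment <- function(geno, map, y, exclude_chroms = NULL,
                                        exclude_regions = NULL,
                                        flank_cm = 10, k = 5, repeats = 20,
                                        seed = 1L, lambda = NULL) {
  stopifnot(identical(colnames(geno), map$marker))
  drop <- rep(FALSE, nrow(map))
  if (!is.null(exclude_chroms)) drop <- drop | map$chrom %in% exclude_chroms
  if (!is.null(exclude_regions) && nrow(exclude_regions) > 0) {
    for (i in seq_len(nrow(exclude_regions)))
      drop <- drop | (map$chrom == exclude_regions$chrom[i] &
                        map$pos_cm >= exclude_regions$ci_lo[i] - flank_cm &
                        map$pos_cm <= exclude_regions$ci_hi[i] + flank_cm)
  }
  keep <- !drop
  if (sum(keep) < 10)
    stop("exclusion leaves fewer than 10 markers", call. = FALSE)
  set.seed(seed)
  n <- nrow(geno)
  folds <- lapply(seq_len(repeats), function(i)
    sample(rep(seq_len(k), length.out = n)))
  cv_full <- cross_validate(geno, y, k = k, seed = seed, lambda = lambda,
                            folds = folds)
  cv_excl <- cross_validate(geno[, keep, drop = FALSE], y, k = k,
                            seed = seed, lambda = lambda, folds = folds)
  structure(list(r_full = cv_full$r, r_excluded = cv_excl$r,
                 diff = mean(cv_full$r_repeats - cv_excl$r_repeats),
                 diff_repeats = cv_full$r_repeats - cv_excl$r_repeats,
                 n_markers_full = ncol(geno),
                 n_markers_excluded = sum(keep)),
            class = "exclusion_result")
}

#' @export
print.exclusion_result <- function(x, ...) {
  cat(sprintf(
    "<exclusion_result> r_full = %.3f (%d markers), r_excluded = %.3f (%d markers), paired diff = %.3f\n",
    x$r_full, x$n_markers_full, x$r_excluded, x$n_markers_excluded, x$diff))
  invisible(x)
}
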