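# Validation of UAV heights against ground measurements, variance-component
# estimation by expected mean squares for the balanced genotype x
# environment design, and broad-sense heritability.

#' Validate UAV heights against ground measurements
#'
#' Ordinary least squares of ground on UAV height over pairs matched by
#' (genotype, site, rep), plus RMSE and mean bias of the UAV values.
#' `RMSE = sqrt(mean((ground - uav)^2))`, `bias = mean(ground - uav)` (a
#' positive bias means the UAV under-estimates).
#'
#' @param uav,ground either two numeric vectors already paired, or two
#'   phenotype tables (long format with genotype_id, site, rep, value_cm)
#'   to be merged on (genotype_id, site, rep).
#' @return list of class `validation_report`: slope, intercept, r2, rmse_cm,
#'   bias_cm, n.
#' @export
regress_validate <- function(uav, ground) {
  if (is.data.frame(uav)) {
    m <- merge(uav[, c("genotype_id", "site", "rep", "value_cm")],
               ground[, c("genotype_id", "site", "rep", "value_cm")],
               by = c("genotype_id", "site", "rep"),
               suffixes = c("_uav", "_ground"))
    u <- m$value_cm_uav
    g <- m$value_cm_ground
  } else {
    stopifnot(length(uav) == length(ground))
    u <- uav
    g <- ground
  }
  if (length(u) < 3) stop("need at least 3 pairs", call. = FALSE)
  if (stats::var(u) == 0)
    stop("UAV values have zero variance; regression undefined", call. = FALSE)
  fit <- stats::lm(g ~ u)
  err <- g - u
  structure(list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r2 = summary(fit)$r.squared,
    rmse_cm = sqrt(mean(err^2)),
    bias_cm = mean(err),
    n = length(u)
  ), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf(
    "<validation_report> n=%d  ground = %.3f + %.3f * uav\n  R2 = %.4f, RMSE = %.2f cm, bias (ground - uav) = %.2f cm\n",
    x$n, x$intercept, x$slope, x$r2, x$rmse_cm, x$bias_cm))
  invisible(x)
}

#' Error split by canopy elevation
#'
#' Splits the paired records at the median ground height and reports the
#' mean absolute UAV error per group — tall canopies are harder to measure,
#' and this quantifies by how much.
#'
#' @param uav,ground paired numeric vectors (cm).
#' @param split threshold; default the median ground height.
#' @return list (mean_abs_err_tall_cm, mean_abs_err_short_cm, split_cm,
#'   n_tall, n_short).
#' @export
bias_by_elevation <- function(uav, ground, split = stats::median(ground)) {
  stopifnot(length(uav) == length(ground))
  tall <- ground > split
  if (sum(tall) < 2 || sum(!tall) < 2)
    stop("need at least 2 records per elevation group", call. = FALSE)
  err <- abs(uav - ground)
  list(mean_abs_err_tall_cm = mean(err[tall]),
       mean_abs_err_short_cm = mean(err[!tall]),
       split_cm = split, n_tall = sum(tall), n_short = sum(!tall))
}

#' Variance components for a balanced genotype x environment trial
#'
#' Two-way ANOVA (genotype, environment, their interaction, residual) on a
#' balanced table, with variance components by equating observed to
#' expected mean squares:
#' `se2 = MSE`, `sge2 = (MS_GE - MSE) / r`, `sg2 = (MS_G - MS_GE) / (r e)`.
#' F ratios use the interaction mean square as denominator for the genotype
#' and environment effects and the residual for the interaction. Negative
#' component solutions are truncated to 0 and flagged.
#'
#' @param table long-format phenotype table with genotype_id, site, rep,
#'   value_cm; filter to one stage and one source before calling (the
#'   function refuses mixed tables).
#' @return list of class `varcomp`: sigma2_g, sigma2_ge, sigma2_e, r, e,
#'   F_G, F_E, F_GE, p_G, p_E, p_GE, truncated, mean_squares.
#' @export
anova_variance_components <- function(table) {
  need <- c("genotype_id", "site", "rep", "value_cm")
  stopifnot(all(need %in% names(table)))
  for (col in c("stage", "source"))
    if (col %in% names(table) && length(unique(table[[col]])) > 1)
      stop("table mixes several ", col,
           " values; filter to one before estimating components",
           call. = FALSE)
  e <- length(unique(table$site))
  if (e < 2)
    stop("single environment: genotype x environment variance is ",
         "inestimable; need at least 2 sites", call. = FALSE)
  counts <- table(table$genotype_id, table$site)
  if (length(unique(as.vector(counts))) != 1L)
    stop("unbalanced table: every genotype x site cell must have the same ",
         "number of replicates; analyse a balanced subset", call. = FALSE)
  r <- unique(as.vector(counts))
  dat <- data.frame(g = factor(table$genotype_id), s = factor(table$site),
                    y = table$value_cm)
  aovt <- stats::anova(stats::lm(y ~ g + s + g:s, data = dat))
  ms <- aovt[["Mean Sq"]]
  names(ms) <- rownames(aovt)
  ms_g <- ms[["g"]]; ms_e <- ms[["s"]]; ms_ge <- ms[["g:s"]]
  mse <- ms[["Residuals"]]
  df <- aovt[["Df"]]
  names(df) <- rownames(aovt)
  sigma2_e <- mse
  sigma2_ge <- (ms_ge - mse) / r
  sigma2_g <- (ms_g - ms_ge) / (r * e)
  truncated <- c(sigma2_g = sigma2_g < 0, sigma2_ge = sigma2_ge < 0)
  sigma2_g <- max(0, sigma2_g)
  sigma2_ge <- max(0, sigma2_ge)
  structure(list(
    sigma2_g = sigma2_g, sigma2_ge = sigma2_ge, sigma2_e = sigma2_e,
    r = r, e = e,
    F_G = ms_g / ms_ge, F_E = ms_e / ms_ge, F_GE = ms_ge / mse,
    p_G = stats::pf(ms_g / ms_ge, df[["g"]], df[["g:s"]], lower.tail = FALSE),
    p_E = stats::pf(ms_e / ms_ge, df[["s"]], df[["g:s"]], lower.tail = FALSE),
    p_GE = stats::pf(ms_ge / mse, df[["g:s"]], df[["Residuals"]],
                     lower.tail = FALSE),
    truncated = truncated, mean_squares = ms
  ), class = "varcomp")
}

#' @export
print.varcomp <- function(x, ...) {
  cat(sprintf(
    "<varcomp> sg2 = %.2f, sge2 = %.2f, se2 = %.2f (r = %d reps, e = %d envs)\n",
    x$sigma2_g, x$sigma2_ge, x$sigma2_e, x$r, x$e))
  cat(sprintf("  F_G = %.2f (p = %.3g), F_E = %.2f (p = %.3g), F_GE = %.2f (p = %.3g)\n",
              x$F_G, x$p_G, x$F_E, x$p_E, x$F_GE, x$p_GE))
  cat(sprintf("  h2 = %.3f\n", heritability(x)))
  invisible(x)
}

#' Broad-sense heritability across environments
#'
#' Default convention, as published for this design:
#' `h2 = sg2 / (sg2 + sge2 / r + se2 / (r e))`,
#' with r replicates per environment and e environments. The textbook
#' entry-mean convention divides the interaction variance by the number of
#' environments instead (`sge2 / e + se2 / (r e)`); it is available via
#' `convention = "standard"` so both are auditable. The result is clipped
#' to `[0, 1]`.
#'
#' @param vc a `varcomp` (or any list with sigma2_g, sigma2_ge, sigma2_e,
#'   r, e).
#' @param convention `"as_published"` (default) or `"standard"`.
#' @return h2 in `[0, 1]`.
#' @export
heritability <- function(vc, convention = c("as_published", "standard")) {
  convention <- match.arg(convention)
  sg <- vc$sigma2_g; sge <- vc$sigma2_ge; se <- vc$sigma2_e
  stopifnot(sg >= 0, sge >= 0, se >= 0, vc$r >= 1, vc$e >= 1)
  if (sg + sge + se == 0)
    stop("all variance components are zero; heritability undefined",
         call. = FALSE)
  denom <- if (convention == "as_published")
    sg + sge / vc$r + se / (vc$r * vc$e)
  else
    sg + sge / vc$e + se / (vc$r * vc$e)
  min(1, max(0, sg / denom))
}
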