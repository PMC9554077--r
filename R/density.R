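# MagDensity and the task-based reproducibility statistics: fat-fraction
# maps, the MagDensity breast-density percentage, paired test-retest delta
# statistics, MSE, absolute-agreement single-measure ICC with its F-based
# confidence interval, and the significance simulation for a small true
# density change.

#' Fat-fraction map from a fat/water volume pair
#'
#' `FF = 100 * fat / (fat + water)` per voxel, the relative percentage of
#' signal attributable to fat. Voxels with `fat + water <= eps` carry no
#' signal and are flagged undefined (`NA`), not imputed.
#'
#' @param fw A [fat_water_volume].
#' @param eps Signal floor below which a voxel is undefined.
#' @return An object of class `fat_fraction_map` with fields `ff`
#'   (3D array, percent, `NA` where undefined) and `spacing`.
#' @export
fat_fraction <- function(fw, eps = 1e-8) {
  stopifnot(inherits(fw, "fat_water_volume"))
  tot <- fw$fat + fw$water
  ff <- 100 * fw$fat / tot
  ff[tot <= eps] <- NA_real_
  structure(list(ff = array(ff, dim(fw$fat)), spacing = fw$spacing),
            class = "fat_fraction_map")
}

#' MagDensity: MR-based breast density within a mask
#'
#' The fibroglandular proportion of the segmented breast:
#' `MagDensity = 100 - mean(FF)` over the defined voxels inside the mask.
#' Undefined fat-fraction voxels inside the mask are excluded from the mean
#' and reported in the voxel accounting.
#'
#' @param ff A [fat_fraction_map].
#' @param mask A non-empty [segmentation_mask] on the same grid.
#' @return An object of class `density_result`: `magdensity` (percent),
#'   `n_voxels` (defined voxels used), `n_undefined` (excluded), and
#'   `mask_volume` in mm^3.
#' @export
magdensity <- function(ff, mask) {
  stopifnot(inherits(ff, "fat_fraction_map"),
            inherits(mask, "segmentation_mask"))
  if (!identical(dim(ff$ff), dim(mask$data)))
    stop("fat-fraction map and mask grids differ")
  inside <- mask$data > 0
  if (!any(inside)) stop("empty mask")
  vals <- ff$ff[inside]
  n_undef <- sum(is.na(vals))
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0) stop("mask entirely undefined in the fat-fraction map")
  structure(list(magdensity = 100 - mean(vals),
                 n_voxels = length(vals),
                 n_undefined = n_undef,
                 mask_volume = sum(inside) * prod(mask$spacing)),
            class = "density_result")
}

#' Paired test-retest measurements
#'
#' @param subject Subject identifiers.
#' @param test,retest Paired measurements (same units, typically MagDensity
#'   percent), finite, at least one pair.
#' @return An object of class `paired_measures`.
#' @export
paired_measures <- function(subject, test, retest) {
  if (length(test) != length(retest) || length(subject) != length(test))
    stop("subject, test, retest must have equal lengths")
  if (length(test) < 1) stop("at least one pair required")
  if (!all(is.finite(test)) || !all(is.finite(retest)))
    stop("measurements must be finite")
  structure(list(subject = as.character(subject),
                 test = as.numeric(test), retest = as.numeric(retest)),
            class = "paired_measures")
}

#' Test-retest delta statistics
#'
#' `Delta = retest - test` per subject; returns the mean signed difference,
#' the mean absolute difference, and the maximum absolute difference.
#'
#' @param p A [paired_measures].
#' @return Named list: `mean_delta`, `mean_abs_delta`, `max_abs_delta`.
#' @export
delta_stats <- function(p) {
  stopifnot(inherits(p, "paired_measures"))
  d <- p$retest - p$test
  list(mean_delta = mean(d), mean_abs_delta = mean(abs(d)),
       max_abs_delta = max(abs(d)))
}

#' Mean squared error of paired measurements
#'
#' @param p A [paired_measures].
#' @return Mean over subjects of `(retest - test)^2`.
#' @export
mse_paired <- function(p) {
  stopifnot(inherits(p, "paired_measures"))
  mean((p$retest - p$test)^2)
}

#' Absolute-agreement single-measure intraclass correlation, ICC(A,1)
#'
#' Two-way model without replication: with row (subject) mean square `MSR`,
#' column (measurement) mean square `MSC`, and error mean square `MSE`,
#' `ICC(A,1) = (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))`. The 95%
#' confidence interval is the McGraw-Wong F-based interval for absolute
#' agreement, single measures.
#'
#' @param p A [paired_measures] with at least 3 subjects (k = 2 measurements).
#' @param alpha Two-sided confidence level is `1 - alpha`.
#' @return An object of class `icc_result`: `icc`, `ci_low`, `ci_high`,
#'   mean squares `msr`, `msc`, `mse`, and counts `n`, `k`.
#' @export
icc_a1 <- function(p, alpha = 0.05) {
  stopifnot(inherits(p, "paired_measures"))
  X <- cbind(p$test, p$retest)
  n <- nrow(X); k <- ncol(X)
  if (n < 3) stop("at least 3 subjects required")
  grand <- mean(X)
  row_means <- rowMeans(X)
  col_means <- colMeans(X)
  ss_total <- sum((X - grand)^2)
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  if (ss_total <= 0) stop("zero total variance: ICC undefined")
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  if (mse <= 1e-14 * msr && msc <= 1e-14 * msr) {
    # perfect agreement: the interval degenerates
    return(structure(list(icc = 1, ci_low = 1, ci_high = 1,
                          msr = msr, msc = msc, mse = mse, n = n, k = k),
                     class = "icc_result"))
  }
  a <- (k * icc) / (n * (1 - icc))
  b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- qf(1 - alpha / 2, n - 1, v)
  f_u <- qf(1 - alpha / 2, v, n - 1)
  ci_low <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  ci_high <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  structure(list(icc = icc, ci_low = ci_low, ci_high = ci_high,
                 msr = msr, msc = msc, mse = mse, n = n, k = k),
            class = "icc_result")
}

#' Significance simulation for a small true density change
#'
#' Illustrates how test-retest reliability translates into detectability of a
#' small true change: the analytic branch computes the two-sample t-test
#' p-value for a mean difference of `true_change` between two groups of
#' `n_per_group` with common standard deviation `sd`; the Monte-Carlo branch
#' draws `reps` replicated experiments and reports the fraction significant
#' at `alpha = 0.05` (the power).
#'
#' @param n_per_group Subjects per group.
#' @param true_change True mean difference (percent MagDensity).
#' @param sd Test-retest standard deviation (percent).
#' @param reps Monte-Carlo replicates.
#' @param seed RNG seed for the Monte-Carlo branch.
#' @param sided `"two"` (default) or `"one"`.
#' @return List with `p_analytic` and `power_mc`.
#' @export
power_simulation <- function(n_per_group = 10L, true_change = 1,
                             sd = 1.42, reps = 1000L, seed = 1L,
                             sided = c("two", "one")) {
  sided <- match.arg(sided)
  stopifnot(n_per_group > 0, sd >= 0, reps >= 1)
  df <- 2 * n_per_group - 2
  if (sd == 0) {
    p_analytic <- 0
  } else {
    tstat <- true_change / (sd * sqrt(2 / n_per_group))
    p_analytic <- if (sided == "two") 2 * pt(-abs(tstat), df) else
      pt(-tstat, df)
  }
  alt <- if (sided == "two") "two.sided" else "greater"
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  hits <- 0L
  for (r in seq_len(reps)) {
    g1 <- rnorm(n_per_group, mean = true_change, sd = max(sd, 1e-12))
    g2 <- rnorm(n_per_group, mean = 0, sd = max(sd, 1e-12))
    pv <- t.test(g1, g2, alternative = alt, var.equal = TRUE)$p.value
    if (pv < 0.05) hits <- hits + 1L
  }
  list(p_analytic = p_analytic, power_mc = hits / reps)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
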