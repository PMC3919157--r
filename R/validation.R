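# Statistical validation framework: QQ normality coefficient, permutation
# null calibration, false-positive mapping, and F-distribution comparison.

#' QQ normality coefficient of a residual sample
#'
#' Sorts the residuals and correlates them with standard-normal quantiles
#' at the Blom plotting positions: `q_j = sqrt(2) * erfinv(2 (j - 3/8) /
#' (J + 1/4) - 1)` for the j-th of J values (equivalently
#' `qnorm((j - 3/8) / (J + 1/4))`). An `r` near 1 indicates Gaussian
#' residuals; heavy tails pull it down.
#'
#' @param residuals numeric vector, J >= 3, finite.
#' @return A `qq_result`: `r` (Pearson correlation), `J`, `quantiles`.
#' @export
qq_coefficient <- function(residuals) {
  residuals <- as.numeric(residuals)
  if (length(residuals) < 3 || any(!is.finite(residuals)))
    stop("qq_coefficient: need >= 3 finite residuals")
  J <- length(residuals)
  if (stats::sd(residuals) == 0)
    stop("qq_coefficient: correlation undefined for constant residuals")
  j <- seq_len(J)
  q <- stats::qnorm((j - 3 / 8) / (J + 1 / 4))
  r <- stats::cor(sort(residuals), q)
  structure(list(r = r, J = J, quantiles = q), class = "qq_result")
}

#' Reference distribution of the QQ coefficient under Gaussianity
#'
#' Repeatedly draws Gaussian samples of size `J` and records the QQ
#' coefficient, giving the null reference against which observed
#' coefficients are judged. In convergence mode, batches of draws are
#' added until the relative population of every histogram bin changes by
#' less than `bin_tol` between batches.
#'
#' @param J sample size per draw.
#' @param reps number of draws (fixed mode), or batch size (convergence
#'   mode).
#' @param seed RNG seed.
#' @param converge use the histogram-stability stopping rule.
#' @param bin_tol relative bin-population change tolerance (default 0.001).
#' @param breaks histogram bin count for the convergence criterion.
#' @param max_reps hard cap on total draws in convergence mode.
#' @return numeric vector of r values (with attribute `reps_used`).
#' @export
reference_qq_distribution <- function(J, reps = 1000, seed = 1,
                                      converge = FALSE, bin_tol = 0.001,
                                      breaks = 50, max_reps = 2e5) {
  stopifnot(reps >= 1, J >= 3)
  set.seed(seed)
  draw <- function(n) vapply(seq_len(n), function(i)
    qq_coefficient(stats::rnorm(J))$r, 0)
  if (!converge) {
    out <- draw(reps)
    attr(out, "reps_used") <- reps
    return(out)
  }
  out <- draw(reps)
  edges <- seq(0, 1, length.out = breaks + 1)
  repeat {
    h_old <- tabulate(findInterval(out, edges, all.inside = TRUE), breaks)
    p_old <- h_old / sum(h_old)
    out <- c(out, draw(reps))
    h_new <- tabulate(findInterval(out, edges, all.inside = TRUE), breaks)
    p_new <- h_new / sum(h_new)
    nz <- p_old > 0 | p_new > 0
    rel <- abs(p_new[nz] - p_old[nz]) / pmax(p_old[nz], 1 / length(out))
    if (max(rel) < bin_tol || length(out) >= max_reps) break
  }
  attr(out, "reps_used") <- length(out)
  out
}

#' Expected false-positive count for repeated tests
#'
#' @param n_tests number of independent analyses.
#' @param alpha per-analysis significance level in (0, 1).
#' @return list: `exact` (`n_tests * alpha`) and `rounded` (nearest
#'   integer).
#' @export
expected_false_positives <- function(n_tests, alpha) {
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1)
    stop("expected_false_positives: alpha must be in (0, 1)")
  ex <- n_tests * alpha
  list(exact = ex, rounded = round(ex))
}

#' Permutation null calibration of a voxelwise analysis
#'
#' Repeats the two-group GLM analysis with randomly permuted balanced group
#' labels (the TIV covariate stays attached to its subject), computes the
#' F-contrast `[-1 1 0]` map for each relabelling, thresholds it by the
#' requested rule, and accumulates per-permutation suprathreshold voxel and
#' cluster counts plus a voxelwise false-positive count map.
#'
#' Permutations are sampled uniformly with replacement over balanced
#' relabelings; the identity labelling is not excluded. For the `fwe-rft`
#' rule the height threshold depends only on the design's degrees of
#' freedom and the residual smoothness, which are invariant under
#' relabelling, so it is estimated once from the first permutation's fit
#' and reused.
#'
#' @param images list of [volume3d]s (or n x V matrix with `geometry`),
#'   one per subject; all subjects exchangeable under the null.
#' @param tiv numeric TIV per subject, or `NULL` to omit the covariate
#'   (contrast shrinks to `[-1 1]`).
#' @param n_group1,n_group2 balanced group sizes (default: split in half).
#' @param n_perms number of random relabelings.
#' @param rule list: `method` ("fwe-rft" or "uncorrected") and `alpha`.
#' @param seed RNG seed; the summary is reproducible bit-for-bit.
#' @param mask optional analysis mask (logical array).
#' @param geometry geometry when `images` is a matrix.
#' @param connectivity cluster connectivity for per-permutation cluster
#'   counts.
#' @return A `null_permutation_summary`: `voxel_counts`, `cluster_counts`
#'   (per permutation), `count_map` (full-grid exceedance counts),
#'   `threshold`, `n_perms`, `rule`, `seed`, `mask`, `df`,
#'   `max_stats` (per-permutation maximum F).
#' @export
permutation_null <- function(images, tiv = NULL, n_group1 = NULL,
                             n_group2 = NULL, n_perms = 100,
                             rule = list(method = "fwe-rft", alpha = 0.05),
                             seed = 1, mask = NULL, geometry = NULL,
                             connectivity = 26) {
  if (is.list(images)) {
    n <- length(images)
  } else {
    n <- nrow(images)
    stopifnot(!is.null(geometry))
  }
  if (is.null(n_group1)) n_group1 <- n %/% 2
  if (is.null(n_group2)) n_group2 <- n - n_group1
  stopifnot(n_group1 + n_group2 == n, n_group1 >= 2, n_group2 >= 2)
  if (n_perms >= choose(n, n_group1))
    warning("permutation_null: n_perms exceeds the number of distinct ",
            "labelings; sampling with replacement")
  # materialise the data matrix once
  if (is.list(images)) {
    geometry <- images[[1]]
    Y <- do.call(rbind, lapply(images, function(v) as.numeric(v$data)))
  } else {
    Y <- as.matrix(images)
  }
  set.seed(seed)
  labels1 <- replicate(n_perms, sample.int(n, n_group1), simplify = FALSE)
  contrast <- if (is.null(tiv)) c(-1, 1) else c(-1, 1, 0)
  make_fit <- function(pick) {
    g <- rep("g2", n)
    g[pick] <- "g1"
    des <- build_design(factor(g, levels = c("g1", "g2")), tiv = tiv,
                        interaction = FALSE)
    fit_glm(Y, des, mask = mask, geometry = geometry)
  }
  fit1 <- make_fit(labels1[[1]])
  if (is.null(mask)) mask <- fit1$mask
  df <- c(1, fit1$error_df)
  sm1 <- contrast_map(fit1, contrast, kind = "F")
  if (rule$method == "fwe-rft") {
    smo <- estimate_smoothness(fit1)
    thr <- fwe_threshold(sm1, smo, alpha = rule$alpha, method = "rft")
  } else if (rule$method == "uncorrected") {
    thr <- stats::qf(1 - rule$alpha, df[1], df[2])
    smo <- NULL
  } else stop("permutation_null: unknown rule method '", rule$method, "'")
  vox_counts <- integer(n_perms)
  clu_counts <- integer(n_perms)
  max_stats <- numeric(n_perms)
  count_map <- array(0L, dim(mask))
  vidx <- which(mask)
  for (p in seq_len(n_perms)) {
    fit <- if (p == 1) fit1 else make_fit(labels1[[p]])
    sm <- if (p == 1) sm1 else contrast_map(fit, contrast, kind = "F")
    supra <- sm$stat > thr
    vox_counts[p] <- sum(supra)
    max_stats[p] <- max(sm$stat)
    if (vox_counts[p] > 0) {
      count_map[vidx[supra]] <- count_map[vidx[supra]] + 1L
      clu_counts[p] <- nrow(cluster_table(sm, thr, connectivity))
    }
  }
  structure(list(voxel_counts = vox_counts, cluster_counts = clu_counts,
                 count_map = count_map, threshold = thr, n_perms = n_perms,
                 rule = rule, seed = seed, mask = mask, df = df,
                 max_stats = max_stats, smoothness = smo,
                 geometry = geometry),
            class = "null_permutation_summary")
}

#' @export
print.null_permutation_summary <- function(x, ...) {
  cat(sprintf("<null_permutation_summary> %d permutations, %s alpha %.3g\n",
              x$n_perms, x$rule$method, x$rule$alpha))
  cat(sprintf("  threshold %.4g; %d permutation(s) with >= 1 voxel (%.2f%%)\n",
              x$threshold, sum(x$voxel_counts > 0),
              100 * mean(x$voxel_counts > 0)))
  invisible(x)
}

#' End-to-end familywise-error calibration study on null phantoms
#'
#' Convenience harness for the null-calibration experiment: generates an
#' exchangeable null cohort of smoothed grey-matter maps (each subject a
#' jittered copy of one truth geometry plus voxel noise, smoothed with the
#' standard kernel), then runs [permutation_null] with the two-group
#' F-contrast design including the TIV covariate and the requested
#' thresholding rule. The fraction of permutations with any suprathreshold
#' voxel estimates the realised familywise error of the rule.
#'
#' @param n_subjects cohort size (split into two balanced pseudo-groups).
#' @param grid grid dimensions (scalar or length 3).
#' @param voxel_size_mm voxel size in mm.
#' @param n_perms number of random relabelings.
#' @param alpha nominal level of the rule.
#' @param rule_method "fwe-rft" or "uncorrected".
#' @param fwhm_um smoothing kernel applied to the GM maps.
#' @param noise_sd voxelwise noise added to the GM maps before smoothing.
#' @param seed RNG seed for cohort and permutations.
#' @return the [permutation_null] summary, with an added
#'   `fwe_rate_percent` field (percentage of permutations with >= 1
#'   suprathreshold voxel).
#' @export
null_calibration_study <- function(n_subjects = 40, grid = 48,
                                   voxel_size_mm = 0.1, n_perms = 512,
                                   alpha = 0.05,
                                   rule_method = "fwe-rft",
                                   fwhm_um = 400, noise_sd = 0.02,
                                   seed = 1) {
  if (length(grid) == 1) grid <- rep(grid, 3)
  sp <- phantom_spec(dim = grid, voxel_size = rep(voxel_size_mm, 3),
                     seed = seed)
  co <- null_cohort(sp, n_subjects)
  set.seed(seed + 1L)
  images <- lapply(co$subjects, function(s) {
    g <- s$gm_truth
    g$data <- g$data + array(stats::rnorm(length(g$data), 0, noise_sd),
                             dim(g$data))
    smooth_volume(g, fwhm = fwhm_um)
  })
  mgm <- Reduce(`+`, lapply(images, function(v) v$data)) / length(images)
  mask <- mgm > 0.05
  summ <- permutation_null(images, tiv = co$manifest$tiv_truth,
                           n_perms = n_perms,
                           rule = list(method = rule_method, alpha = alpha),
                           seed = seed + 2L, mask = mask)
  summ$fwe_rate_percent <- 100 * mean(summ$voxel_counts > 0)
  summ
}

#' Spatial uniformity of false positives across the brain
#'
#' Tests whether the per-voxel exceedance counts accumulated over
#' permutations are homogeneous across in-mask voxels, i.e. consistent
#' with every voxel sharing one Binomial(n_perms, alpha) law, via a
#' chi-square goodness-of-fit on the histogram of counts (tail bins pooled
#' to expected counts >= 5).
#'
#' @param summary a [permutation_null] result, or a list with `count_map`,
#'   `mask`, `n_perms`, `rule`.
#' @param alpha per-voxel rate tested against; defaults to the summary's
#'   rule alpha.
#' @param spacing_vox optional integer: subsample the mask on a regular
#'   lattice with this spacing (in voxels) before testing, so that the
#'   pooled voxels are approximately independent. Smooth statistic maps
#'   correlate neighbouring voxels, which would otherwise overdisperse the
#'   histogram relative to the binomial reference; a spacing of about
#'   twice the smoothness FWHM restores approximate independence.
#' @return list: `count_map`, `statistic`, `df`, `p_value`,
#'   `expected_rate`, `observed_rate`, `n_voxels_tested`.
#' @export
fp_spatial_uniformity <- function(summary, alpha = NULL, spacing_vox = 1L) {
  if (summary$n_perms < 30)
    stop("fp_spatial_uniformity: need >= 30 permutations")
  if (is.null(alpha)) alpha <- summary$rule$alpha
  mask <- summary$mask
  if (spacing_vox > 1L) {
    dm <- dim(mask)
    lat <- array(FALSE, dm)
    lat[seq(1, dm[1], by = spacing_vox),
        seq(1, dm[2], by = spacing_vox),
        seq(1, dm[3], by = spacing_vox)] <- TRUE
    mask <- mask & lat
  }
  counts <- summary$count_map[mask]
  if (length(counts) == 0) stop("fp_spatial_uniformity: empty mask")
  n <- summary$n_perms
  # estimate the common rate from the data so the test is about
  # homogeneity, not about the absolute level
  phat <- mean(counts) / n
  kmax <- stats::qbinom(1 - 1e-6, n, phat)
  pk <- stats::dbinom(0:kmax, n, phat)
  obs <- tabulate(pmin(counts, kmax) + 1L, nbins = kmax + 1L)
  expd <- pk * length(counts)
  # counts beyond the binomial's effective support are kept in a separate
  # overflow cell so a single impossible voxel still explodes the
  # statistic rather than being pooled away
  over_obs <- sum(counts > kmax)
  over_exp <- length(counts) * stats::pbinom(kmax, n, phat,
                                             lower.tail = FALSE)
  obs[kmax + 1L] <- obs[kmax + 1L] - over_obs
  # pool main bins from the upper tail until every expected count >= 5
  while (length(expd) > 2 && expd[length(expd)] < 5) {
    L <- length(expd)
    expd[L - 1] <- expd[L - 1] + expd[L]
    obs[L - 1] <- obs[L - 1] + obs[L]
    expd <- expd[-L]; obs <- obs[-L]
  }
  stat <- sum((obs - expd)^2 / pmax(expd, 1e-12)) +
    (over_obs - over_exp)^2 / max(over_exp, 1e-8)
  df <- length(expd) - 2  # one fitted rate parameter
  pv <- stats::pchisq(stat, df = max(df, 1), lower.tail = FALSE)
  list(count_map = summary$count_map, statistic = stat, df = max(df, 1),
       p_value = pv, expected_rate = alpha, observed_rate = phat,
       n_voxels_tested = length(counts))
}

#' Maximum-intensity projections of a count map
#'
#' Collapses a 3-D count map along each axis, giving the coronal, sagittal
#' and horizontal views used to display where false positives concentrate.
#'
#' @param count_map 3-D array (e.g. `summary$count_map`).
#' @return list of three matrices: `sagittal` (max over x), `coronal`
#'   (max over y), `horizontal` (max over z).
#' @export
mip_views <- function(count_map) {
  stopifnot(length(dim(count_map)) == 3)
  list(sagittal = apply(count_map, c(2, 3), max),
       coronal = apply(count_map, c(1, 3), max),
       horizontal = apply(count_map, c(1, 2), max))
}

#' Empirical versus theoretical F distribution
#'
#' Compares pooled null F statistics with the theoretical F(df_num,
#' df_err) law: empirical and theoretical CDFs tabulated on a grid, plus
#' the Kolmogorov-Smirnov distance evaluated at the sample points.
#'
#' @param f_values numeric vector of F statistics.
#' @param df_num,df_err degrees of freedom.
#' @param grid evaluation grid for the CDF table (default 200 points over
#'   the sample range).
#' @return list: `table` (data frame grid / empirical / theoretical),
#'   `ks_distance`.
#' @export
compare_f_distribution <- function(f_values, df_num, df_err, grid = NULL) {
  f_values <- as.numeric(f_values)
  if (any(!is.finite(f_values))) stop("compare_f_distribution: non-finite F")
  if (!is.finite(df_num) || !is.finite(df_err) || df_num <= 0 || df_err <= 0)
    stop("compare_f_distribution: invalid degrees of freedom")
  if (is.null(grid))
    grid <- seq(0, max(f_values), length.out = 200)
  emp <- stats::ecdf(f_values)
  tab <- data.frame(f = grid, empirical = emp(grid),
                    theoretical = stats::pf(grid, df_num, df_err))
  xs <- sort(f_values)
  n <- length(xs)
  Ft <- stats::pf(xs, df_num, df_err)
  ks <- max(pmax(abs(seq_len(n) / n - Ft), abs((seq_len(n) - 1) / n - Ft)))
  list(table = tab, ks_distance = ks)
}
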