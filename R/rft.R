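# Random-field-theory machinery: residual-based smoothness estimation,
# resel counts of an arbitrary mask, Euler-characteristic densities for t
# and F fields, and the FWE height threshold.

#' Residual-based smoothness estimate of a fitted GLM
#'
#' Estimates the FWHM of the component Gaussian field along each axis from
#' the spatial derivatives of the normalised residual fields: for a
#' unit-variance field, `Var(dZ/dx) = 4 log 2 / FWHM^2`. Resel counts of
#' the analysis mask are computed from the discrete Euler-characteristic
#' decomposition of the mask (points, edges, faces, cubes).
#'
#' @param fit a [fit_glm] result with at least 3 residual maps.
#' @return A `smoothness_estimate`: `fwhm_mm` (per axis), `fwhm_vox`,
#'   `resels` (length 4: 0-D..3-D resel counts), `mask_volume_vox`.
#' @export
estimate_smoothness <- function(fit) {
  stopifnot(inherits(fit, "glm_fit"))
  n <- nrow(fit$residuals)
  if (n < 3) stop("estimate_smoothness: need at least 3 residual maps")
  dm <- dim(fit$mask)
  h <- fit$geometry$voxel_size
  # normalise residuals to unit sum-of-squares per voxel
  ss <- sqrt(colSums(fit$residuals^2))
  U <- sweep(fit$residuals, 2, pmax(ss, 1e-300), `/`)
  mask <- fit$mask
  lam <- numeric(3)
  for (a in 1:3) {
    full <- array(NA_real_, dm)
    acc <- 0; cnt <- 0
    ixm <- lapply(dm, seq_len); ixp <- ixm
    ixm[[a]] <- 1:(dm[a] - 1); ixp[[a]] <- 2:dm[a]
    mpair <- do.call(`[`, c(list(mask), ixm)) & do.call(`[`, c(list(mask), ixp))
    for (s in seq_len(n)) {
      full[fit$voxel_index] <- U[s, ]
      d <- (do.call(`[`, c(list(full), ixp)) -
              do.call(`[`, c(list(full), ixm)))
      acc <- acc + sum(d[mpair]^2)
    }
    cnt <- sum(mpair)
    # summed over scans of unit-SS residuals, so acc/cnt estimates
    # 2(1 - rho) of the component field without further scaling
    lam[a] <- acc / cnt
  }
  # For unit-SS residuals, sum over scans of squared neighbour differences
  # estimates 2(1 - rho) = Var(dZ) of the unit-variance component field.
  fwhm_vox <- sqrt(4 * log(2) / pmax(lam, 1e-12))
  fwhm_mm <- fwhm_vox * h
  resels <- resel_counts(fit$mask, fwhm_vox)
  structure(list(fwhm_mm = fwhm_mm, fwhm_vox = fwhm_vox, resels = resels,
                 mask_volume_vox = sum(fit$mask)),
            class = "smoothness_estimate")
}

#' Resel counts of a mask at a given smoothness
#'
#' Discrete Lipschitz-Killing estimate from counts of in-mask points,
#' edges, faces and cubes; `fwhm_vox` is the field FWHM in voxel units per
#' axis.
#'
#' @param mask logical 3-D array.
#' @param fwhm_vox FWHM per axis in voxels.
#' @return numeric length 4: resel counts of dimension 0..3.
#' @export
resel_counts <- function(mask, fwhm_vox) {
  mask <- as.array(mask)
  dm <- dim(mask)
  r <- 1 / fwhm_vox
  # counts of k-dimensional grid elements fully inside the mask
  count <- function(axes) {
    m <- mask
    for (a in axes) {
      d <- dim(m)
      ixa <- lapply(d, seq_len); ixa[[a]] <- 1:(d[a] - 1)
      ixb <- lapply(d, seq_len); ixb[[a]] <- 2:d[a]
      m <- do.call(`[`, c(list(m), ixa)) & do.call(`[`, c(list(m), ixb))
    }
    sum(m)
  }
  P <- count(integer(0))
  Ex <- count(1); Ey <- count(2); Ez <- count(3)
  Fxy <- count(c(1, 2)); Fxz <- count(c(1, 3)); Fyz <- count(c(2, 3))
  C <- count(c(1, 2, 3))
  R0 <- P - (Ex + Ey + Ez) + (Fxy + Fxz + Fyz) - C
  R1 <- (Ex - Fxy - Fxz + C) * r[1] + (Ey - Fxy - Fyz + C) * r[2] +
    (Ez - Fxz - Fyz + C) * r[3]
  R2 <- (Fxy - C) * r[1] * r[2] + (Fxz - C) * r[1] * r[3] +
    (Fyz - C) * r[2] * r[3]
  R3 <- C * r[1] * r[2] * r[3]
  c(R0, R1, R2, R3)
}

#' Euler-characteristic densities of t and F random fields
#'
#' Densities of dimension 0..3 at height `u` for a t field with `df[2]`
#' degrees of freedom or an F field with `df = c(k, v)`.
#'
#' @param u height (vector ok).
#' @param df numeric length 2: numerator and error df (numerator 1 for t).
#' @param kind "t" or "F".
#' @return matrix length(u) x 4 of EC densities.
#' @export
ec_density <- function(u, df, kind = c("t", "F")) {
  kind <- match.arg(kind)
  a4 <- 4 * log(2)
  out <- matrix(0, length(u), 4)
  if (kind == "t") {
    v <- df[2]
    cpow <- (1 + u^2 / v)^((1 - v) / 2)
    b <- exp(lgamma((v + 1) / 2) - lgamma(v / 2))
    out[, 1] <- stats::pt(u, v, lower.tail = FALSE)
    out[, 2] <- sqrt(a4) / (2 * pi) * cpow
    out[, 3] <- a4 / (2 * pi)^(3 / 2) * b * cpow * u / sqrt(v / 2)
    out[, 4] <- a4^(3 / 2) / (2 * pi)^2 * cpow * ((v - 1) * u^2 / v - 1)
  } else {
    k <- df[1]; v <- df[2]
    a <- a4 / (2 * pi)
    b <- lgamma(v / 2) + lgamma(k / 2)
    x <- k * u / v
    out[, 1] <- stats::pf(u, k, v, lower.tail = FALSE)
    out[, 2] <- sqrt(a) * exp(lgamma((v + k - 1) / 2) - b) * sqrt(2) *
      x^((k - 1) / 2) * (1 + x)^(-(v + k - 2) / 2)
    out[, 3] <- a * exp(lgamma((v + k - 2) / 2) - b) *
      x^((k - 2) / 2) * (1 + x)^(-(v + k - 2) / 2) * ((v - 1) * x - (k - 1))
    out[, 4] <- a^(3 / 2) * exp(lgamma((v + k - 3) / 2) - b) / sqrt(2) *
      x^((k - 3) / 2) * (1 + x)^(-(v + k - 2) / 2) *
      ((v - 1) * (v - 2) * x^2 - (2 * v * k - v - k - 1) * x +
         (k - 1) * (k - 2))
  }
  out
}

# Expected Euler characteristic of the excursion set at height u.
expected_ec <- function(u, resels, df, kind) {
  rowSums(ec_density(u, df, kind) *
            matrix(resels, length(u), 4, byrow = TRUE))
}

#' Family-wise error height threshold
#'
#' Either the random-field-theory threshold (smallest height whose expected
#' Euler characteristic of the excursion set equals `alpha`) or the
#' `(1 - alpha)` quantile of a supplied permutation null distribution of
#' maxima.
#'
#' @param stat a `stat_map` (used for its kind and df), or a list with
#'   `kind` and `df`.
#' @param smoothness a [estimate_smoothness] result (rft method).
#' @param alpha FWE rate in (0, 1).
#' @param method "rft" or "permutation".
#' @param null_maxima numeric vector of null maximum statistics
#'   (permutation method).
#' @return scalar height threshold.
#' @export
fwe_threshold <- function(stat, smoothness = NULL, alpha = 0.05,
                          method = c("rft", "permutation"),
                          null_maxima = NULL) {
  method <- match.arg(method)
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1)
    stop("fwe_threshold: alpha must be in (0, 1)")
  if (method == "permutation") {
    if (is.null(null_maxima) || length(null_maxima) < 10)
      stop("fwe_threshold: supply >= 10 null maxima for the permutation ",
         "method")
    return(as.numeric(stats::quantile(null_maxima, 1 - alpha, type = 1)))
  }
  stopifnot(!is.null(smoothness))
  kind <- stat$kind
  df <- stat$df
  resels <- smoothness$resels
  lo <- if (kind == "t") stats::qt(1 - alpha, df[2])
        else stats::qf(1 - alpha, df[1], df[2])
  f <- function(u) expected_ec(u, resels, df, kind) - alpha
  hi <- lo + 1
  while (f(hi) > 0 && hi < lo + 1e4) hi <- hi * 2
  if (f(lo) <= 0) return(lo)
  stats::uniroot(f, c(lo, hi), tol = 1e-8)$root
}
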