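#' Two-group design matrix with optional TIV covariate and interaction
#'
#' Columns are the two group indicators, followed by either a single
#' mean-centred total-intracranial-volume column or, with
#' `interaction = TRUE`, one TIV column per group (each mean-centred within
#' its group), allowing the TIV slope to differ by genotype.
#'
#' @param groups factor or character vector of group labels (exactly two
#'   levels, at least two scans per group).
#' @param tiv optional numeric TIV per scan (mm^3).
#' @param interaction allow the TIV slope to interact with group.
#' @return A `design_matrix`: numeric matrix `X` with labelled columns,
#'   plus `groups` and `error_df = nrow - ncol`.
#' @export
build_design <- function(groups, tiv = NULL, interaction = FALSE) {
  groups <- factor(groups)
  if (nlevels(groups) != 2)
    stop("build_design: exactly two groups required")
  if (min(table(groups)) < 2)
    stop("build_design: at least 2 scans per group required")
  n <- length(groups)
  g1 <- as.numeric(groups == levels(groups)[1])
  g2 <- as.numeric(groups == levels(groups)[2])
  X <- cbind(g1, g2)
  colnames(X) <- levels(groups)
  if (!is.null(tiv)) {
    tiv <- as.numeric(tiv)
    if (length(tiv) != n) stop("build_design: tiv length mismatch")
    if (interaction) {
      t1 <- ifelse(g1 == 1, tiv - mean(tiv[g1 == 1]), 0)
      t2 <- ifelse(g2 == 1, tiv - mean(tiv[g2 == 1]), 0)
      X <- cbind(X, t1, t2)
      colnames(X)[3:4] <- paste0("tiv:", levels(groups))
    } else {
      X <- cbind(X, tiv - mean(tiv))
      colnames(X)[3] <- "tiv"
    }
  }
  if (qr(X)$rank < ncol(X))
    stop("build_design: design is rank deficient (constant covariate?)")
  structure(list(X = X, groups = groups, error_df = n - ncol(X)),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("<design_matrix> %d scans x %d columns (%s); error df %d\n",
              nrow(x$X), ncol(x$X), paste(colnames(x$X), collapse = ", "),
              x$error_df))
  invisible(x)
}

#' Voxelwise ordinary least squares fit
#'
#' Fits the design at every in-mask voxel of an image stack by OLS and
#' retains the residuals (needed downstream for smoothness estimation and
#' residual-normality checks).
#'
#' @param images list of [volume3d]s sharing one geometry, or an
#'   `n_scans x n_voxels` matrix (then `geometry` must be supplied).
#' @param design a [build_design] result.
#' @param mask logical array of voxels to analyse, or `NULL` to analyse
#'   voxels whose cohort mean exceeds 5% of the mean image's range.
#' @param geometry a [volume3d] providing geometry when `images` is a
#'   matrix.
#' @return A `glm_fit`: `beta` (p x V), `residuals` (n x V), `sigma2`
#'   (length V), `error_df`, `mask`, `design`, `geometry`.
#' @export
fit_glm <- function(images, design, mask = NULL, geometry = NULL) {
  stopifnot(inherits(design, "design_matrix"))
  X <- design$X
  if (is.list(images)) {
    ref <- images[[1]]
    for (v in images)
      if (!same_geometry(ref, v))
        stop("fit_glm: images do not share geometry")
    Y <- do.call(rbind, lapply(images, function(v) as.numeric(v$data)))
    geometry <- ref
  } else {
    Y <- as.matrix(images)
    if (is.null(geometry))
      stop("fit_glm: supply `geometry` when passing a matrix")
  }
  if (nrow(Y) != nrow(X))
    stop("fit_glm: number of images (", nrow(Y),
         ") does not match design rows (", nrow(X), ")")
  if (nrow(X) <= ncol(X))
    stop("fit_glm: fewer images than design columns")
  dm <- dim(geometry$data)
  if (is.null(mask)) {
    mu <- colMeans(Y)
    mask <- array(mu > min(mu) + 0.05 * (max(mu) - min(mu)), dm)
  }
  vidx <- which(as.logical(mask))
  Ym <- Y[, vidx, drop = FALSE]
  XtXi <- solve(crossprod(X))
  pinv <- XtXi %*% t(X)
  beta <- pinv %*% Ym
  res <- Ym - X %*% beta
  df <- design$error_df
  sigma2 <- colSums(res^2) / df
  if (any(sigma2 < .Machine$double.eps * 100))
    message("fit_glm: zero residual variance at ",
            sum(sigma2 < .Machine$double.eps * 100), " voxel(s)")
  structure(list(beta = beta, residuals = res, sigma2 = sigma2,
                 error_df = df, mask = array(as.logical(mask), dm),
                 voxel_index = vidx, design = design, XtXi = XtXi,
                 geometry = geometry),
            class = "glm_fit")
}

#' Voxelwise t or F statistic map for a contrast
#'
#' Standard GLM contrast statistics: for a single contrast vector the t
#' statistic `c'b / sqrt(s2 c'(X'X)^-1 c)`; for `kind = "F"` (vector or
#' matrix contrast) the usual extra-sum-of-squares F. For a 1-row contrast
#' the F map is exactly the squared t map.
#'
#' @param fit a [fit_glm] result.
#' @param contrast numeric vector (length p) or q x p matrix.
#' @param kind `"t"` or `"F"`.
#' @param tail for t maps, `"one"` or `"two"`; p-values in the returned
#'   object use this tail convention (one-tailed in the stated direction).
#' @return A `stat_map`: `values` (full-grid array, NA outside mask),
#'   `stat` vector over in-mask voxels, `kind`, `df` (numerator, error),
#'   `mask`, `p` (uncorrected in-mask p-values), `geometry`.
#' @export
contrast_map <- function(fit, contrast, kind = c("t", "F"),
                         tail = c("one", "two")) {
  stopifnot(inherits(fit, "glm_fit"))
  kind <- match.arg(kind)
  tail <- match.arg(tail)
  C <- if (is.matrix(contrast)) contrast else matrix(contrast, nrow = 1)
  p <- nrow(fit$beta)
  if (ncol(C) != p)
    stop("contrast_map: contrast length ", ncol(C),
         " does not match design columns ", p)
  M <- C %*% fit$XtXi %*% t(C)
  if (rcond(M) < 1e-12)
    stop("contrast_map: contrast is not estimable under this design")
  cb <- C %*% fit$beta
  if (kind == "t") {
    if (nrow(C) != 1) stop("contrast_map: t requires a single contrast row")
    se <- sqrt(fit$sigma2 * as.numeric(M))
    stat <- as.numeric(cb) / se
    df <- c(1, fit$error_df)
    pv <- if (tail == "one") stats::pt(stat, df[2], lower.tail = FALSE)
          else 2 * stats::pt(abs(stat), df[2], lower.tail = FALSE)
  } else {
    q <- nrow(C)
    Mi <- solve(M)
    quad <- colSums((Mi %*% cb) * cb)
    stat <- quad / (q * fit$sigma2)
    df <- c(q, fit$error_df)
    pv <- stats::pf(stat, df[1], df[2], lower.tail = FALSE)
  }
  vals <- array(NA_real_, dim(fit$mask))
  vals[fit$voxel_index] <- stat
  structure(list(values = vals, stat = stat, kind = kind, df = df,
                 tail = tail, p = pv, mask = fit$mask,
                 geometry = fit$geometry),
            class = "stat_map")
}

#' Benjamini-Hochberg FDR threshold over in-mask voxels
#'
#' Step-up procedure on the uncorrected voxelwise p-values: the threshold
#' is the largest order statistic `p(k) <= k q / m`. Assumes positive
#' regression dependence (no log-factor correction), the convention of
#' voxelwise FDR in morphometry.
#'
#' @param stat a `stat_map` (its `p` field is used) or a numeric vector of
#'   p-values.
#' @param q FDR level (default 0.05).
#' @return list: `p_threshold` (0 if nothing survives), `survivors`
#'   (logical over in-mask voxels), `mask` (full-grid logical array, when a
#'   `stat_map` was supplied), `n_suprathreshold`.
#' @export
fdr_threshold <- function(stat, q = 0.05) {
  if (inherits(stat, "stat_map")) {
    pv <- stat$p
  } else {
    pv <- as.numeric(stat)
  }
  if (length(pv) == 0) stop("fdr_threshold: empty mask")
  m <- length(pv)
  ps <- sort(pv)
  ok <- ps <= seq_len(m) * q / m
  thr <- if (any(ok)) ps[max(which(ok))] else 0
  surv <- pv <= thr & thr > 0
  out <- list(p_threshold = thr, survivors = surv,
              n_suprathreshold = sum(surv))
  if (inherits(stat, "stat_map")) {
    mk <- array(FALSE, dim(stat$mask))
    mk[which(stat$mask)] <- surv
    out$mask <- mk
  }
  out
}

#' Connected-component cluster table of a suprathreshold map
#'
#' Labels the suprathreshold voxels into connected components (26- or
#' 6-neighbour connectivity) and reports each cluster's extent, peak
#' statistic, and the peak's stereotaxic (bregma-relative) coordinates.
#'
#' @param stat a `stat_map`.
#' @param threshold statistic height threshold.
#' @param connectivity 26 (default) or 6.
#' @return data frame with columns `extent_vox`, `peak_stat`, `x_mm`,
#'   `y_mm`, `z_mm`, ordered by decreasing extent; zero rows if nothing
#'   survives.
#' @export
cluster_table <- function(stat, threshold, connectivity = 26) {
  stopifnot(inherits(stat, "stat_map"), is.finite(threshold))
  if (!connectivity %in% c(6, 26))
    stop("cluster_table: connectivity must be 6 or 26")
  dm <- dim(stat$values)
  supra <- which(!is.na(stat$values) & stat$values > threshold)
  empty <- data.frame(extent_vox = integer(0), peak_stat = numeric(0),
                      x_mm = numeric(0), y_mm = numeric(0),
                      z_mm = numeric(0))
  if (length(supra) == 0) return(empty)
  # neighbour offsets in linear index space, guarded by coordinate checks
  if (connectivity == 6) {
    offs <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
                  c(0, 0, -1), c(0, 0, 1))
  } else {
    offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  }
  coord <- arrayInd(supra, dm)
  inset <- array(0L, dm)
  inset[supra] <- seq_along(supra)
  labels <- integer(length(supra))
  cur <- 0L
  for (s in seq_along(supra)) {
    if (labels[s] > 0L) next
    cur <- cur + 1L
    frontier <- s
    labels[s] <- cur
    while (length(frontier) > 0) {
      cc <- coord[frontier, , drop = FALSE]
      nxt <- integer(0)
      for (o in seq_len(nrow(offs))) {
        nb <- sweep(cc, 2, offs[o, ], `+`)
        ok <- nb[, 1] >= 1 & nb[, 1] <= dm[1] &
          nb[, 2] >= 1 & nb[, 2] <= dm[2] &
          nb[, 3] >= 1 & nb[, 3] <= dm[3]
        if (!any(ok)) next
        lin <- nb[ok, 1] + dm[1] * (nb[ok, 2] - 1) +
          dm[1] * dm[2] * (nb[ok, 3] - 1)
        id <- inset[lin]
        id <- id[id > 0L]
        id <- id[labels[id] == 0L]
        if (length(id)) {
          labels[id] <- cur
          nxt <- c(nxt, id)
        }
      }
      frontier <- unique(nxt)
    }
  }
  rows <- lapply(seq_len(cur), function(cl) {
    idx <- supra[labels == cl]
    vals <- stat$values[idx]
    pk <- idx[which.max(vals)]
    ijk <- arrayInd(pk, dm) - 1L
    w <- voxel_to_world(stat$geometry, as.numeric(ijk))
    data.frame(extent_vox = length(idx), peak_stat = max(vals),
               x_mm = w[1], y_mm = w[2], z_mm = w[3])
  })
  out <- do.call(rbind, rows)
  out[order(-out$extent_vox), , drop = FALSE]
}

#' Write a cluster table as TSV
#' @param tab a [cluster_table] result.
#' @param path output path.
#' @export
write_cluster_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
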