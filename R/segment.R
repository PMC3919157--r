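#' Tissue probability maps
#'
#' Bundle of template-space prior probability images for grey matter, white
#' matter and CSF; the remainder at each voxel is the implicit "everything
#' else" class.
#'
#' @param gm,wm,csf [volume3d] objects with values in `[0, 1]` sharing one
#'   geometry.
#' @return A `tissue_probability_maps` object.
#' @export
tissue_probability_maps <- function(gm, wm, csf) {
  stopifnot(inherits(gm, "volume3d"), inherits(wm, "volume3d"),
            inherits(csf, "volume3d"))
  if (!same_geometry(gm, wm) || !same_geometry(gm, csf))
    stop("tissue_probability_maps: maps must share geometry")
  s <- gm$data + wm$data + csf$data
  if (max(s) > 1 + 1e-6)
    stop("tissue_probability_maps: gm+wm+csf exceeds 1 at some voxels")
  structure(list(gm = gm, wm = wm, csf = csf),
            class = "tissue_probability_maps")
}

# --- bias field basis --------------------------------------------------

bias_bases <- function(dm, voxel_size, cutoff_mm) {
  K <- mapply(dct_orders_for_cutoff, dm, voxel_size,
              MoreArgs = list(cutoff_mm = cutoff_mm))
  list(Bx = dct_basis(dm[1], K[1]), By = dct_basis(dm[2], K[2]),
       Bz = dct_basis(dm[3], K[3]), K = K)
}

#' Fit a smooth multiplicative bias field to a volume
#'
#' Projects the log-intensity of the volume onto a separable low-frequency
#' cosine basis whose highest retained frequency has spatial period at
#' least `cutoff_mm` along each axis. The field is parameterised as
#' `exp(sum of coefficients x basis)`, so the reconstruction is strictly
#' positive. Intended both as a standalone smooth-field fit and as the
#' bias model inside [segment_unified].
#'
#' @param volume a [volume3d] with positive intensities where `mask` is
#'   true.
#' @param cutoff_mm smallest spatial period retained, in mm; must exceed
#'   twice the largest voxel dimension.
#' @param mask optional logical array selecting voxels to fit (default:
#'   voxels above 5% of the intensity range).
#' @return A `bias_field` object: coefficient array `coef` (Kx x Ky x Kz),
#'   the basis sizes, the cutoff, and the reference geometry.
#' @export
fit_bias_basis <- function(volume, cutoff_mm, mask = NULL) {
  stopifnot(inherits(volume, "volume3d"))
  dm <- dim(volume$data)
  minc <- 2 * max(volume$voxel_size)
  if (cutoff_mm <= minc)
    stop("fit_bias_basis: cutoff_mm must exceed twice the largest voxel ",
         "dimension (minimum ", signif(minc, 4), " mm)")
  bb <- bias_bases(dm, volume$voxel_size, cutoff_mm)
  x <- volume$data
  if (is.null(mask)) {
    thr <- min(x) + 0.05 * (max(x) - min(x))
    mask <- x > thr
  }
  idx <- which(mask)
  lg <- log(pmax(x[idx], .Machine$double.eps))
  lg <- lg - mean(lg)
  Mb <- bias_design_matrix(bb, idx, dm)
  coef <- solve_bias_wls(Mb, rep(1, length(idx)), lg, bb$K)
  structure(list(coef = coef, K = bb$K, cutoff_mm = cutoff_mm,
                 dim = dm, voxel_size = volume$voxel_size),
            class = "bias_field")
}

#' Evaluate a fitted bias field on its grid
#'
#' @param bias a `bias_field` from [fit_bias_basis] or [segment_unified].
#' @param log_scale return the log-field instead of the exponentiated field.
#' @return 3-D array of the strictly positive multiplicative field (or its
#'   logarithm).
#' @export
evaluate_bias <- function(bias, log_scale = FALSE) {
  stopifnot(inherits(bias, "bias_field"))
  bb <- bias_bases(bias$dim, bias$voxel_size, bias$cutoff_mm)
  f <- sep_tensor(bias$coef, bb$Bx, bb$By, bb$Bz)
  if (log_scale) f else exp(f)
}

# Explicit basis design matrix rows for the given linear voxel indices;
# column order matches the linearisation of a Kx x Ky x Kz coefficient
# array (first index fastest).
bias_design_matrix <- function(bb, idx, dm) {
  ar <- arrayInd(idx, dm)
  M <- matrix(0, length(idx), prod(bb$K))
  col <- 0L
  for (mz in seq_len(bb$K[3]))
    for (my in seq_len(bb$K[2]))
      for (mx in seq_len(bb$K[1])) {
        col <- col + 1L
        M[, col] <- bb$Bx[ar[, 1], mx] * bb$By[ar[, 2], my] *
          bb$Bz[ar[, 3], mz]
      }
  M
}

# Exact weighted least-squares fit of a field sampled at voxels idx onto
# the separable basis: solve (B'WB) c = B'W r with a light ridge.
solve_bias_wls <- function(Mb, w, r, K) {
  sw <- sqrt(pmax(w, 0))
  A <- crossprod(Mb * sw)
  rhs <- crossprod(Mb, w * r)
  ridge <- 1e-8 * mean(diag(A))
  cf <- tryCatch(solve(A + diag(ridge, ncol(Mb)), rhs),
                 error = function(e) matrix(0, ncol(Mb), 1))
  array(as.numeric(cf), K)
}

# --- unified segmentation ---------------------------------------------

#' Joint bias correction and mixture-of-Gaussians tissue segmentation
#'
#' Models the (bias-corrected) intensity at each voxel as a mixture of
#' `gaussians_per_class` Gaussians per tissue class (GM, WM, CSF and
#' "everything else"), with class membership priors taken from the tissue
#' probability maps. Alternates posterior (E) steps, mixture-parameter (M)
#' steps and a guarded update of the smooth multiplicative bias field on a
#' low-frequency cosine basis; the penalised negative log-likelihood is
#' non-increasing by construction (bias updates are accepted only when
#' they improve it).
#'
#' @param volume a [volume3d], affine-aligned with the maps' space.
#' @param tpms a [tissue_probability_maps].
#' @param gaussians_per_class Gaussians per tissue class (default 2).
#' @param cutoff_mm bias-field spatial cutoff in mm (default 12, the
#'   midpoint of the 10-15 mm working range for mouse-scale coils).
#' @param tpm_blend mixing weight of a uniform prior blended into the
#'   tissue probability maps (default 0.25). A pure template prior can
#'   veto tissue that is genuinely present in a subject but absent from
#'   the template -- exactly the situation created by pathology such as
#'   ex vacuo CSF in an atrophied structure -- so the blend keeps the
#'   posterior responsive to intensity evidence everywhere.
#' @param max_iter,tol stopping rule: relative objective change below
#'   `tol` or `max_iter` iterations.
#' @param bias_correct set `FALSE` to skip bias estimation.
#' @return A `segmentation_result`: `posteriors` (list of gm/wm/csf/other
#'   [volume3d]), `bias_field` ([volume3d], multiplicative, positive),
#'   `bias` (coefficients), `mixture` (per-component data frame),
#'   `objective_trace`.
#' @export
segment_unified <- function(volume, tpms, gaussians_per_class = 2,
                            cutoff_mm = 12, max_iter = 30, tol = 1e-5,
                            bias_correct = TRUE, tpm_blend = 0.25) {
  stopifnot(inherits(volume, "volume3d"),
            inherits(tpms, "tissue_probability_maps"))
  if (!same_geometry(volume, tpms$gm))
    stop("segment_unified: volume must share the maps' geometry")
  y <- as.numeric(volume$data)
  if (any(!is.finite(y)))
    stop("segment_unified: non-finite intensities in input")
  dm <- dim(volume$data)
  n <- length(y)
  K <- gaussians_per_class
  tpm_floor <- 1e-4
  P <- cbind(gm = as.numeric(tpms$gm$data), wm = as.numeric(tpms$wm$data),
             csf = as.numeric(tpms$csf$data))
  P <- pmax(P, tpm_floor)
  other <- pmax(1 - rowSums(P), tpm_floor)
  P <- cbind(P, other = other)
  P <- P / rowSums(P)
  P_raw <- P  # template prior before blending, used for certainty masks
  if (tpm_blend > 0) {
    # blend only where the template expects head tissue: pathology can
    # only re-label tissue inside the head, and leaving the air prior
    # intact keeps background out of the tissue posteriors
    inhead <- (P_raw[, "gm"] + P_raw[, "wm"] + P_raw[, "csf"]) > 0.05
    P[inhead, ] <- (1 - tpm_blend) * P[inhead, ] + tpm_blend / 4
  }
  classes <- colnames(P)
  nc <- 4L
  # head mask for the bias fit: voxels likely to be tissue
  head <- (P[, "gm"] + P[, "wm"] + P[, "csf"]) > 0.5
  if (!any(head)) head <- rep(TRUE, n)

  # initial mixture from TPM-weighted moments
  comp <- data.frame(class = rep(classes, each = K),
                     weight = rep(1 / K, nc * K),
                     mean = 0, var = 1)
  anchored <- rep(FALSE, nc * K)
  for (t in seq_len(nc)) {
    w <- P[, t]
    m <- sum(w * y) / sum(w)
    v <- sum(w * (y - m)^2) / sum(w)
    v <- max(v, (1e-3 * stats::sd(y))^2, .Machine$double.eps)
    idx <- which(comp$class == classes[t])
    # split component means slightly so K>1 components can separate
    off <- if (K > 1) seq(-0.5, 0.5, length.out = K) else 0
    comp$mean[idx] <- m + off * sqrt(v)
    comp$var[idx] <- v
    if (classes[t] == "other" && K > 1) {
      # dedicated partial-volume component for the head/air boundary:
      # anchored midway between background and head intensity with a
      # variance spanning the gap. It is excluded from the M-step so it
      # cannot collapse onto pure air, which would leave boundary
      # partial-volume voxels to be swallowed by a tissue class.
      mhead <- sum(head * y) / max(sum(head), 1)
      comp$mean[idx[K]] <- (m + mhead) / 2
      comp$var[idx[K]] <- ((mhead - m) / 4)^2
      comp$weight[idx] <- c(rep(0.7 / (K - 1), K - 1), 0.3)
      anchored[idx[K]] <- TRUE
    }
  }

  bb <- if (bias_correct) bias_bases(dm, volume$voxel_size, cutoff_mm) else NULL
  if (bias_correct && cutoff_mm <= 2 * max(volume$voxel_size))
    stop("segment_unified: cutoff_mm must exceed twice the largest voxel ",
         "dimension")
  bcoef <- if (bias_correct) array(0, bb$K) else NULL
  logb <- rep(0, n)
  if (bias_correct) {
    hidx <- which(head)
    Mb_seg <- bias_design_matrix(bb, hidx, dm)
    pcert <- apply(P_raw, 1, max)
  }

  loglik_terms <- function(logb) {
    c_int <- y * exp(-logb)
    L <- matrix(0, n, nc * K)
    for (g in seq_len(nc * K)) {
      t <- match(comp$class[g], classes)
      L[, g] <- P[, t] * comp$weight[g] *
        stats::dnorm(c_int, comp$mean[g], sqrt(comp$var[g]))
    }
    list(L = L, logdens = log(pmax(rowSums(L), 1e-300)) - logb)
  }

  trace <- numeric(0)
  frozen <- rep(FALSE, nc)
  obj_of <- function(lt) -sum(lt$logdens)
  lt <- loglik_terms(logb)  # kept in sync with (mixture, logb) below
  for (it in seq_len(max_iter)) {
    G <- lt$L / pmax(rowSums(lt$L), 1e-300)  # responsibilities, n x (nc*K)
    c_int <- y * exp(-logb)
    # M-step
    for (t in seq_len(nc)) {
      idx <- which(comp$class == classes[t])
      mass <- colSums(G[, idx, drop = FALSE])
      if (sum(mass) < 1e-8) {
        if (!frozen[t]) {
          warning("segment_unified: class '", classes[t],
                  "' has zero posterior mass; freezing its Gaussians")
          frozen[t] <- TRUE
        }
        next
      }
      anch <- anchored[idx]
      if (any(anch)) {
        # anchored components keep their mixing share; free components
        # split the remainder by posterior mass
        free_share <- 1 - sum(comp$weight[idx][anch])
        mfree <- mass[!anch]
        if (sum(mfree) > 1e-12)
          comp$weight[idx][!anch] <- free_share * mfree / sum(mfree)
      } else {
        comp$weight[idx] <- mass / sum(mass)
      }
      for (g in idx) {
        sg <- sum(G[, g])
        if (sg < 1e-8 || anchored[g]) next
        m <- sum(G[, g] * c_int) / sg
        v <- sum(G[, g] * (c_int - m)^2) / sg
        comp$mean[g] <- m
        comp$var[g] <- max(v, 1e-10)
      }
    }
    # guarded bias update: regress the log-ratio of the data to a
    # class-level prediction onto the basis. The prediction mixes the
    # *class-average* means by the class posteriors: class membership is
    # driven largely by the spatial priors, and the class means are
    # global scalars, so the prediction cannot chase the smooth field
    # itself and shrink it toward zero (which a component-posterior mean
    # does). The fit is restricted to prior-certain voxels and 3-MAD
    # trimmed against partial-volume outliers.
    if (bias_correct) {
      clmean <- vapply(classes, function(cl) {
        idx <- which(comp$class == cl)
        sum(comp$weight[idx] * comp$mean[idx])
      }, 0)
      clprec <- vapply(classes, function(cl) {
        idx <- which(comp$class == cl)
        sum(comp$weight[idx] * comp$mean[idx]^2 / comp$var[idx])
      }, 0)
      postc <- vapply(seq_len(nc), function(t)
        rowSums(G[, comp$class == classes[t], drop = FALSE]), numeric(n))
      pred <- as.numeric(postc %*% clmean)
      prec <- as.numeric(postc %*% clprec)
      ratio <- log(pmax(y[hidx], 1e-12)) - log(pmax(pred[hidx], 1e-12))
      wgt <- prec[hidx] * as.numeric(pcert[hidx] > 0.99)
      if (sum(wgt > 0) < 10 * prod(bb$K))
        wgt <- prec[hidx]  # certainty trim too aggressive for these TPMs
      rz <- ratio - logb[hidx]
      madv <- stats::mad(rz[wgt > 0])
      if (is.finite(madv) && madv > 0)
        wgt <- wgt * as.numeric(abs(rz - stats::median(rz[wgt > 0])) <
                                  3 * madv)
      step <- solve_bias_wls(Mb_seg, wgt, ratio, bb$K)
      lt <- loglik_terms(logb)  # mixture changed in the M-step
      obj_cur <- obj_of(lt)
      alpha <- 1
      for (ls in 1:10) {
        cand <- bcoef + alpha * (step - bcoef)
        # gain applied over the head only: air voxels neither steer nor
        # receive the coil non-uniformity model
        logb_cand <- as.numeric(sep_tensor(cand, bb$Bx, bb$By, bb$Bz)) * head
        lt_cand <- loglik_terms(logb_cand)
        if (obj_of(lt_cand) < obj_cur) {
          bcoef <- cand; logb <- logb_cand; lt <- lt_cand
          break
        }
        alpha <- alpha / 2
      }
    } else {
      lt <- loglik_terms(logb)
    }
    obj <- obj_of(lt)
    trace <- c(trace, obj)
    if (it > 1 &&
        abs(trace[it - 1] - obj) < tol * abs(trace[it - 1]))
      break
  }

  G <- lt$L / pmax(rowSums(lt$L), 1e-300)
  post <- lapply(seq_len(nc), function(t) {
    idx <- which(comp$class == classes[t])
    arr <- array(rowSums(G[, idx, drop = FALSE]), dm)
    volume3d(arr, vox2world = volume$vox2world, units = "probability")
  })
  names(post) <- classes
  bf <- volume3d(array(exp(logb), dm), vox2world = volume$vox2world,
                 units = "multiplicative")
  res <- structure(list(posteriors = post, bias_field = bf,
                        bias = if (bias_correct)
                          structure(list(coef = bcoef, K = bb$K,
                                         cutoff_mm = cutoff_mm, dim = dm,
                                         voxel_size = volume$voxel_size),
                                    class = "bias_field") else NULL,
                        mixture = comp, objective_trace = trace),
                   class = "segmentation_result")
  res
}

#' Total intracranial volume from a segmentation
#'
#' Sum of the GM, WM and CSF posteriors times the voxel volume.
#'
#' @param seg a `segmentation_result`.
#' @param voxel_volume mm^3 per voxel; defaults to the posterior maps'
#'   voxel volume.
#' @return TIV in mm^3.
#' @export
total_intracranial_volume <- function(seg, voxel_volume = NULL) {
  stopifnot(inherits(seg, "segmentation_result"))
  if (is.null(voxel_volume))
    voxel_volume <- prod(seg$posteriors$gm$voxel_size)
  s <- sum(seg$posteriors$gm$data) + sum(seg$posteriors$wm$data) +
    sum(seg$posteriors$csf$data)
  s * voxel_volume
}
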