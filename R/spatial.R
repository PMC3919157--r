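#' Small-deformation warp field on a separable cosine basis
#'
#' Displacement (in mm, one coefficient array per axis) expanded on an
#' orthonormal separable DCT basis over the reference grid. The default
#' basis size of 8 x 8 x 6 coefficients per axis gives roughly a thousand
#' scalar parameters in total, the classic size for small-deformation
#' normalisation.
#'
#' @param coef list of three coefficient arrays (x, y, z displacement),
#'   each `n_basis[1] x n_basis[2] x n_basis[3]`.
#' @param reference a [volume3d] providing the grid the warp lives on.
#' @param reg_weight bending-energy weight used during estimation
#'   (per mm^4), recorded for provenance.
#' @return A `warp_field` object.
#' @export
warp_field <- function(coef, reference, reg_weight = NA_real_) {
  stopifnot(is.list(coef), length(coef) == 3,
            inherits(reference, "volume3d"))
  nb <- dim(coef[[1]])
  for (a in 2:3) stopifnot(all(dim(coef[[a]]) == nb))
  structure(list(coef = coef, n_basis = nb,
                 reference = reference, reg_weight = reg_weight),
            class = "warp_field")
}

warp_bases <- function(warp, deriv_axis = 0L) {
  dm <- dim(warp$reference$data)
  h <- warp$reference$voxel_size
  nb <- warp$n_basis
  mk <- function(axis) {
    if (axis == deriv_axis) dct_basis_deriv(dm[axis], nb[axis], h[axis])
    else dct_basis(dm[axis], nb[axis])
  }
  list(Bx = mk(1L), By = mk(2L), Bz = mk(3L))
}

#' Evaluate a warp's displacement on its reference grid
#'
#' @param warp a [warp_field].
#' @return list of three 3-D arrays: displacement in mm along x, y, z.
#' @export
evaluate_warp <- function(warp) {
  stopifnot(inherits(warp, "warp_field"))
  bb <- warp_bases(warp)
  lapply(warp$coef, function(cf) sep_tensor(cf, bb$Bx, bb$By, bb$Bz))
}

#' Jacobian determinant map of a warp
#'
#' Determinant of the local deformation gradient `I + du/dx` of the mapping
#' `x -> x + u(x)` (world mm), evaluated analytically from the basis
#' derivatives. Values below 1 are contractions; negative values indicate
#' folding and are returned as-is with a message.
#'
#' @param warp a [warp_field].
#' @return A [volume3d] in the warp's reference geometry.
#' @export
jacobian_determinant <- function(warp) {
  stopifnot(inherits(warp, "warp_field"))
  dm <- dim(warp$reference$data)
  Ju <- vector("list", 9)
  for (b in 1:3) {
    bb <- warp_bases(warp, deriv_axis = b)
    for (a in 1:3)
      Ju[[(a - 1) * 3 + b]] <- sep_tensor(warp$coef[[a]], bb$Bx, bb$By, bb$Bz)
  }
  # det(I + J), J[a,b] = du_a/dx_b
  j11 <- 1 + Ju[[1]]; j12 <- Ju[[2]]; j13 <- Ju[[3]]
  j21 <- Ju[[4]]; j22 <- 1 + Ju[[5]]; j23 <- Ju[[6]]
  j31 <- Ju[[7]]; j32 <- Ju[[8]]; j33 <- 1 + Ju[[9]]
  det <- j11 * (j22 * j33 - j23 * j32) -
    j12 * (j21 * j33 - j23 * j31) +
    j13 * (j21 * j32 - j22 * j31)
  nneg <- sum(det <= 0)
  if (nneg > 0)
    message("jacobian_determinant: ", nneg,
            " voxel(s) with non-positive determinant (folding)")
  volume3d(det, vox2world = warp$reference$vox2world, units = "jacobian")
}

#' Resample a volume through a warp, optionally with Jacobian modulation
#'
#' Pull-back trilinear resampling of `vol` at the warped positions
#' `x + u(x)` of the reference grid (edge-clamped). With `modulate = TRUE`
#' the result is multiplied by the warp's Jacobian determinant so that the
#' total tissue quantity is conserved — the "optimised VBM" modulation
#' step.
#'
#' @param vol a [volume3d] in the warp's source space.
#' @param warp a [warp_field].
#' @param modulate multiply by the Jacobian determinant.
#' @return A [volume3d] in the reference geometry.
#' @export
apply_warp <- function(vol, warp, modulate = FALSE) {
  stopifnot(inherits(vol, "volume3d"), inherits(warp, "warp_field"))
  u <- evaluate_warp(warp)
  g <- world_grid(warp$reference)
  xyz <- cbind(g[, 1] + as.numeric(u[[1]]),
               g[, 2] + as.numeric(u[[2]]),
               g[, 3] + as.numeric(u[[3]]))
  vals <- sample_world(vol, xyz)
  out <- array(vals, dim(warp$reference$data))
  if (modulate) {
    jd <- jacobian_determinant(warp)
    out <- out * jd$data
    volume3d(out, vox2world = warp$reference$vox2world, units = vol$units)
  } else {
    volume3d(out, vox2world = warp$reference$vox2world, units = vol$units)
  }
}

# Local mean/variance normalisation used as the registration contrast
# model: subtract a coarse Gaussian local mean and divide by the local SD.
# The default scale is a quarter of the smallest field-of-view extent, so
# only slow contrast/bias trends are removed, not anatomical structure.
local_normalise <- function(vol, scale_mm = NULL) {
  if (is.null(scale_mm))
    scale_mm <- max(8 * max(vol$voxel_size),
                    0.25 * min(dim(vol$data) * vol$voxel_size))
  mu <- smooth_volume(vol, fwhm = scale_mm * 2.355 * 1000)
  d <- vol$data - mu$data
  v <- smooth_volume(volume3d(d^2, vox2world = vol$vox2world),
                     fwhm = scale_mm * 2.355 * 1000)
  sd0 <- sqrt(mean(d^2))
  volume3d(d / (sqrt(pmax(v$data, 0)) + 0.1 * sd0 + 1e-12),
           vox2world = vol$vox2world)
}

# Bending-energy (squared-Laplacian) penalty spectrum: for DCT order m
# along an axis of n voxels of size h mm, the angular frequency is
# pi*m/(n*h) per mm; the penalty per coefficient is (wx^2+wy^2+wz^2)^2.
bending_spectrum <- function(dm, h, nb) {
  wx <- (pi * (seq_len(nb[1]) - 1) / (dm[1] * h[1]))^2
  wy <- (pi * (seq_len(nb[2]) - 1) / (dm[2] * h[2]))^2
  wz <- (pi * (seq_len(nb[3]) - 1) / (dm[3] * h[3]))^2
  (outer(outer(wx, wy, `+`), wz, `+`))^2
}

#' Non-linear registration on a low-frequency cosine basis
#'
#' Estimates a small-deformation warp taking template-grid coordinates into
#' the source, by minimising the sum of squared differences between the
#' locally mean/variance-normalised images plus a bending-energy penalty
#' on the displacement (computed in millimetre units, so behaviour is
#' invariant to voxel-size relabelling). Gradient-based (L-BFGS-B) with the
#' analytic gradient of the data term through the trilinear resampling.
#'
#' @param source a [volume3d], already affine-aligned to the template.
#' @param template a [volume3d] defining the reference grid.
#' @param n_basis integer 3-vector of DCT orders per axis (default
#'   `c(8, 8, 6)`, i.e. 1,152 parameters over three axes).
#' @param reg_weight bending-energy weight per mm^4.
#' @param iterations L-BFGS iteration cap per smoothing stage.
#' @param normalise apply local mean/variance normalisation first.
#' @param smooth_fwhm_vox coarse-to-fine presmoothing schedule: Gaussian
#'   FWHM in voxels applied to both images at each stage (warm-started),
#'   widening the capture range beyond the image structure scale.
#' @return A [warp_field] with attributes `objective` and `trace` (data
#'   term at the final stage's smoothing, per accepted stage).
#' @export
register_nonlinear <- function(source, template, n_basis = c(8, 8, 6),
                               reg_weight = 0.05, iterations = 40,
                               normalise = TRUE,
                               smooth_fwhm_vox = c(6, 2)) {
  stopifnot(inherits(source, "volume3d"), inherits(template, "volume3d"))
  dm <- dim(template$data)
  h <- template$voxel_size
  if (normalise) {
    src_n <- local_normalise(source)
    tpl_n <- local_normalise(template)
  } else {
    src_n <- source; tpl_n <- template
  }
  if (stats::sd(src_n$data) == 0 || stats::sd(tpl_n$data) == 0)
    stop("register_nonlinear: degenerate (constant) image")
  nb <- pmin(as.integer(n_basis), dm)
  wf0 <- warp_field(list(array(0, nb), array(0, nb), array(0, nb)),
                    template, reg_weight)
  bb <- warp_bases(wf0)
  g <- world_grid(template)
  pen <- bending_spectrum(dm, h, nb)
  npar <- prod(nb)
  sM <- solve(src_n$vox2world)
  nvox <- prod(dm)
  unpack <- function(p) list(array(p[1:npar], nb),
                             array(p[npar + 1:npar], nb),
                             array(p[2 * npar + 1:npar], nb))
  hs <- src_n$voxel_size
  make_funs <- function(src_arr, tdat) {
    grad_src <- lapply(1:3, function(a) {
      d <- dim(src_arr)
      gr <- array(0, d)
      ixc <- lapply(d, seq_len); ixp <- ixc; ixm <- ixc
      ixc[[a]] <- 2:(d[a] - 1); ixp[[a]] <- 3:d[a]; ixm[[a]] <- 1:(d[a] - 2)
      val <- (do.call(`[`, c(list(src_arr), ixp)) -
                do.call(`[`, c(list(src_arr), ixm))) / (2 * hs[a])
      do.call(`[<-`, c(list(gr), ixc, list(val)))
    })
    sample_at <- function(p) {
      cf <- unpack(p)
      u <- lapply(cf, function(c1)
        as.numeric(sep_tensor(c1, bb$Bx, bb$By, bb$Bz)))
      xyz <- cbind(g[, 1] + u[[1]], g[, 2] + u[[2]], g[, 3] + u[[3]])
      ijk <- cbind(xyz, 1) %*% t(sM)
      list(cf = cf, ijk = ijk,
           w = interp_trilinear(src_arr, ijk[, 1], ijk[, 2], ijk[, 3]))
    }
    objfun <- function(p) {
      s <- sample_at(p)
      sum((s$w - tdat)^2) / nvox +
        reg_weight * sum(vapply(s$cf, function(c1) sum(c1^2 * pen), 0)) / nvox
    }
    gradfun <- function(p) {
      s <- sample_at(p)
      r <- s$w - tdat
      out <- numeric(3 * npar)
      for (a in 1:3) {
        ga <- interp_trilinear(grad_src[[a]], s$ijk[, 1], s$ijk[, 2],
                               s$ijk[, 3])
        gc <- sep_tensor(array(2 * r * ga / nvox, dm),
                         t(bb$Bx), t(bb$By), t(bb$Bz)) +
          2 * reg_weight * pen * s$cf[[a]] / nvox
        out[(a - 1) * npar + 1:npar] <- gc
      }
      out
    }
    list(obj = objfun, grad = gradfun)
  }
  p <- numeric(3 * npar)
  trace <- numeric(0)
  for (fw in smooth_fwhm_vox) {
    if (fw > 0) {
      src_s <- smooth_volume(src_n, fw * mean(hs) * 1000)$data
      tpl_s <- smooth_volume(tpl_n, fw * mean(h) * 1000)$data
    } else {
      src_s <- src_n$data; tpl_s <- tpl_n$data
    }
    funs <- make_funs(src_s, as.numeric(tpl_s))
    if (length(trace) == 0) trace <- funs$obj(p)
    opt <- stats::optim(p, funs$obj, funs$grad, method = "L-BFGS-B",
                        control = list(maxit = iterations, factr = 1e6))
    p <- opt$par
    trace <- c(trace, opt$value)
  }
  wf <- warp_field(unpack(p), template, reg_weight)
  attr(wf, "objective") <- trace[length(trace)]
  attr(wf, "trace") <- trace
  wf
}

#' Gaussian smoothing in world units
#'
#' Separable Gaussian with `sigma = fwhm / (2 sqrt(2 log 2))` along each
#' axis, specified in micrometres of world space. Boundary handling
#' renormalises each source voxel's outgoing kernel mass so the total sum
#' of intensities is conserved exactly.
#'
#' @param vol a [volume3d].
#' @param fwhm full width at half maximum in micrometres (e.g. 400 for the
#'   default mouse in vivo kernel).
#' @return A smoothed [volume3d].
#' @export
smooth_volume <- function(vol, fwhm) {
  stopifnot(inherits(vol, "volume3d"))
  if (length(fwhm) != 1 || !is.finite(fwhm) || fwhm < 0)
    stop("smooth_volume: fwhm must be a single non-negative number (um)")
  if (fwhm == 0) return(vol)
  sigma_mm <- (fwhm / 1000) / (2 * sqrt(2 * log(2)))
  out <- vol$data
  dm <- dim(out)
  for (a in 1:3) {
    s_vox <- sigma_mm / vol$voxel_size[a]
    if (s_vox < 1e-6) next
    n <- dm[a]
    d <- abs(outer(seq_len(n), seq_len(n), `-`))
    K <- exp(-d^2 / (2 * s_vox^2))
    K <- sweep(K, 2, colSums(K), `/`)  # conserve each voxel's mass
    perm <- switch(a, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
    x <- aperm(out, perm)
    dmx <- dim(x)
    x <- K %*% matrix(x, dmx[1], dmx[2] * dmx[3])
    x <- array(x, dmx)
    out <- aperm(x, order(perm))
  }
  volume3d(out, vox2world = vol$vox2world, units = vol$units)
}

#' Iterative cohort mean template
#'
#' Builds a minimum-deformation style average: each round registers every
#' volume to the current mean non-linearly, averages the warped images, and
#' subtracts the cohort-mean displacement so the template stays at the
#' cohort's average shape rather than drifting toward any one subject.
#'
#' @param volumes list of at least two affine-aligned [volume3d]s.
#' @param rounds registration/averaging rounds (default 2).
#' @param ... passed on to [register_nonlinear].
#' @return The final mean [volume3d].
#' @export
build_template <- function(volumes, rounds = 2, ...) {
  if (!is.list(volumes) || length(volumes) < 2)
    stop("build_template: need at least 2 volumes")
  for (v in volumes) stopifnot(inherits(v, "volume3d"))
  ref <- volumes[[1]]
  tmpl <- volume3d(Reduce(`+`, lapply(volumes, function(v) v$data)) /
                     length(volumes), vox2world = ref$vox2world)
  for (r in seq_len(rounds)) {
    warps <- lapply(volumes, function(v)
      register_nonlinear(v, tmpl, ...))
    # recentre: subtract the mean displacement coefficients
    mean_cf <- lapply(1:3, function(a)
      Reduce(`+`, lapply(warps, function(w) w$coef[[a]])) / length(warps))
    warps <- lapply(warps, function(w) {
      w$coef <- lapply(1:3, function(a) w$coef[[a]] - mean_cf[[a]])
      w
    })
    imgs <- mapply(function(v, w) apply_warp(v, w)$data,
                   volumes, warps, SIMPLIFY = FALSE)
    tmpl <- volume3d(Reduce(`+`, imgs) / length(imgs),
                     vox2world = ref$vox2world)
  }
  tmpl
}

#' Mean gradient magnitude of a volume (sharpness index)
#'
#' Average Euclidean norm of the central-difference intensity gradient in
#' per-mm units; used to compare template sharpness across registration
#' strategies.
#'
#' @param vol a [volume3d].
#' @return scalar sharpness.
#' @export
sharpness <- function(vol) {
  stopifnot(inherits(vol, "volume3d"))
  d <- dim(vol$data)
  arr <- vol$data
  gsq <- array(0, d - 2)
  for (a in 1:3) {
    ix_p <- ix_m <- ix_c <- list(2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1))
    ix_p[[a]] <- ix_p[[a]] + 1
    ix_m[[a]] <- ix_m[[a]] - 1
    gp <- do.call(`[`, c(list(arr), ix_p))
    gm <- do.call(`[`, c(list(arr), ix_m))
    gsq <- gsq + ((gp - gm) / (2 * vol$voxel_size[a]))^2
  }
  mean(sqrt(gsq))
}

#' Serialise a warp as a displacement-field NIfTI plus JSON coefficients
#'
#' Writes three scalar NIfTI volumes (x/y/z displacement in mm) and a JSON
#' file of the basis coefficients.
#'
#' @param warp a [warp_field].
#' @param prefix output path prefix; files are written as
#'   `<prefix>_disp_x.nii.gz` etc. and `<prefix>_coef.json`.
#' @export
write_warp <- function(warp, prefix) {
  stopifnot(inherits(warp, "warp_field"))
  u <- evaluate_warp(warp)
  ax <- c("x", "y", "z")
  for (a in 1:3)
    write_volume(volume3d(u[[a]], vox2world = warp$reference$vox2world,
                          units = "mm"),
                 paste0(prefix, "_disp_", ax[a], ".nii.gz"))
  jsonlite::write_json(list(n_basis = warp$n_basis,
                            reg_weight = warp$reg_weight,
                            coef = lapply(warp$coef, as.numeric)),
                       paste0(prefix, "_coef.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}
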