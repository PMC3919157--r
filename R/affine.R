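#' 12-parameter affine transform in rigid-invariant decomposed form
#'
#' Parameters follow the classic T * R * Z * W ordering: translation (mm),
#' rotation (radians, principal branch), then a stretch factor built from
#' zoom (scale) and shear values. The scale/shear block is invariant to any
#' rigid motion composed on the left, which is what makes it suitable for a
#' population prior: it is obtained from the Cholesky factor of M'M, so the
#' determinant of the transform equals `sx*sy*sz`.
#'
#' @param translation (tx, ty, tz) in mm.
#' @param rotation (rx, ry, rz) in radians.
#' @param scale (sx, sy, sz), strictly positive, dimensionless.
#' @param shear (hxy, hxz, hyz), dimensionless.
#' @return An `affine_params` object.
#' @export
affine_params <- function(translation = c(0, 0, 0), rotation = c(0, 0, 0),
                          scale = c(1, 1, 1), shear = c(0, 0, 0)) {
  stopifnot(length(translation) == 3, length(rotation) == 3,
            length(scale) == 3, length(shear) == 3)
  if (any(scale <= 0))
    stop("affine_params: scales must be strictly positive")
  structure(list(translation = as.numeric(translation),
                 rotation = as.numeric(rotation),
                 scale = as.numeric(scale),
                 shear = as.numeric(shear)),
            class = "affine_params")
}

#' @export
print.affine_params <- function(x, ...) {
  cat("<affine_params>\n")
  cat(sprintf("  translation (mm): %s\n", paste(signif(x$translation, 5), collapse = ", ")))
  cat(sprintf("  rotation   (rad): %s\n", paste(signif(x$rotation, 5), collapse = ", ")))
  cat(sprintf("  scale           : %s\n", paste(signif(x$scale, 5), collapse = ", ")))
  cat(sprintf("  shear           : %s\n", paste(signif(x$shear, 5), collapse = ", ")))
  invisible(x)
}

rot_x <- function(a) matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
rot_y <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
rot_z <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)

#' Compose an affine 4x4 matrix from decomposed parameters
#'
#' Fixed composition order: Translation . Rotation . Stretch, with the
#' stretch `diag(scale) %*% upper-unit-triangular(shear)`.
#'
#' @param params an [affine_params].
#' @return 4x4 numeric matrix; determinant of the linear block equals the
#'   product of the scales.
#' @export
compose_affine <- function(params) {
  stopifnot(inherits(params, "affine_params"))
  if (any(params$scale <= 0))
    stop("compose_affine: scales must be strictly positive")
  R <- rot_x(params$rotation[1]) %*% rot_y(params$rotation[2]) %*%
    rot_z(params$rotation[3])
  h <- params$shear
  W <- matrix(c(1, 0, 0, h[1], 1, 0, h[2], h[3], 1), 3, 3)
  A <- R %*% (diag(params$scale) %*% W)
  M <- diag(4)
  M[1:3, 1:3] <- A
  M[1:3, 4] <- params$translation
  M
}

#' Decompose a 4x4 affine matrix into rigid-invariant parameters
#'
#' Recovers translation, rotation (principal branch), and the rigid-motion
#' invariant scale/shear block from the Cholesky factor of M'M. Pure
#' rotations are absorbed entirely by the orthogonal factor, leaving unit
#' scales and zero shears.
#'
#' @param M 4x4 affine matrix whose 3x3 block has positive determinant.
#' @return An [affine_params] such that `compose_affine()` reproduces `M`.
#' @export
polar_decompose <- function(M) {
  M <- as.matrix(M)
  stopifnot(all(dim(M) == c(4, 4)))
  A <- M[1:3, 1:3]
  dA <- det(A)
  if (dA <= 0)
    stop("polar_decompose: matrix determinant is not positive ",
         "(reflections are not representable)")
  C <- chol(crossprod(A))
  sc <- diag(C)
  sh <- c(C[1, 2] / C[1, 1], C[1, 3] / C[1, 1], C[2, 3] / C[2, 2])
  R <- A %*% solve(C)
  # re-orthogonalise against accumulated round-off
  sv <- svd(R)
  R <- sv$u %*% t(sv$v)
  ry <- asin(max(-1, min(1, R[1, 3])))
  if (abs(cos(ry)) > 1e-9) {
    rz <- atan2(-R[1, 2], R[1, 1])
    rx <- atan2(-R[2, 3], R[3, 3])
  } else {
    rz <- atan2(R[2, 1], R[2, 2])
    rx <- 0
  }
  affine_params(translation = M[1:3, 4], rotation = c(rx, ry, rz),
                scale = sc, shear = sh)
}

#' Gaussian prior over affine scale and shear parameters
#'
#' @param mean 6-vector: (sx, sy, sz, hxy, hxz, hyz).
#' @param covariance symmetric positive semi-definite 6x6 matrix.
#' @return An `affine_prior` object.
#' @export
affine_prior <- function(mean, covariance) {
  mean <- as.numeric(mean)
  covariance <- as.matrix(covariance)
  stopifnot(length(mean) == 6, all(dim(covariance) == c(6, 6)))
  if (max(abs(covariance - t(covariance))) > 1e-8)
    stop("affine_prior: covariance must be symmetric")
  ev <- eigen(covariance, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10)
    stop("affine_prior: covariance must be positive semi-definite")
  structure(list(mean = mean, covariance = covariance),
            class = "affine_prior")
}

#' Shipped mouse-brain affine prior
#'
#' Population means and standard deviations of the rigid-invariant affine
#' parameters of mouse brains registered to a Paxinos-aligned template:
#' scales 1.00 (SD 0.01), 1.00 (SD 0.02), 1.00 (SD 0.02) along x, y, z and
#' shears 0.00 (SD 0.02), 0.01 (SD 0.04), 0.02 (SD 0.01) for the xy, xz,
#' yz components. Only marginal SDs are available, so the covariance is
#' diagonal.
#'
#' @return An [affine_prior].
#' @export
default_affine_prior <- function() {
  affine_prior(mean = c(1, 1, 1, 0, 0.01, 0.02),
               covariance = diag(c(0.01, 0.02, 0.02, 0.02, 0.04, 0.01)^2))
}

#' Quadratic prior penalty on scale/shear parameters
#'
#' One half of the Mahalanobis distance between the transform's rigid-
#' invariant (scale, shear) vector and the prior mean. Zero iff the vector
#' equals the mean; unchanged by composing any rigid motion with the
#' transform.
#'
#' @param params an [affine_params].
#' @param prior an [affine_prior].
#' @return non-negative scalar.
#' @export
prior_penalty <- function(params, prior) {
  stopifnot(inherits(params, "affine_params"), inherits(prior, "affine_prior"))
  v <- c(params$scale, params$shear) - prior$mean
  Ci <- tryCatch(solve(prior$covariance),
                 error = function(e) NULL)
  if (is.null(Ci))
    Ci <- tryCatch(solve(prior$covariance + diag(1e-8, 6)),
                   error = function(e)
                     stop("prior_penalty: covariance is singular even after ",
                          "diagonal regularisation"))
  as.numeric(0.5 * t(v) %*% Ci %*% v)
}

# --- registration cost -------------------------------------------------

# Negative normalised mutual information on a 64-bin joint histogram.
# Returns +Inf when the overlap is empty.
neg_nmi <- function(a, b, nbins = 64L) {
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 100) return(Inf)
  ra <- range(a); rb <- range(b)
  if (diff(ra) == 0 || diff(rb) == 0) return(Inf)
  ia <- pmin(nbins - 1L, floor((a - ra[1]) / diff(ra) * nbins)) + 1L
  ib <- pmin(nbins - 1L, floor((b - rb[1]) / diff(rb) * nbins)) + 1L
  jh <- tabulate(ia + nbins * (ib - 1L), nbins = nbins * nbins)
  jh <- jh / sum(jh)
  pa <- rowSums(matrix(jh, nbins, nbins))
  pb <- colSums(matrix(jh, nbins, nbins))
  Ha <- -sum(pa[pa > 0] * log(pa[pa > 0]))
  Hb <- -sum(pb[pb > 0] * log(pb[pb > 0]))
  Hab <- -sum(jh[jh > 0] * log(jh[jh > 0]))
  -(Ha + Hb) / Hab
}

params_to_vec <- function(p) c(p$translation, p$rotation, p$scale, p$shear)
vec_to_params <- function(v)
  affine_params(v[1:3], v[4:6], pmax(v[7:9], 1e-3), v[10:12])

centre_of_mass <- function(vol) {
  w <- vol$data - min(vol$data)
  s <- sum(w)
  if (s <= 0) return(c(0, 0, 0))
  g <- world_grid(vol)
  c(sum(g[, 1] * w), sum(g[, 2] * w), sum(g[, 3] * w)) / s
}

downsample2 <- function(vol) {
  d <- dim(vol$data)
  ii <- seq(1, d[1], by = 2); jj <- seq(1, d[2], by = 2); kk <- seq(1, d[3], by = 2)
  M <- vol$vox2world %*% diag(c(2, 2, 2, 1))
  volume3d(vol$data[ii, jj, kk, drop = FALSE], vox2world = M, units = vol$units)
}

#' Prior-penalised affine registration to a template
#'
#' Estimates the 12-parameter affine mapping template world coordinates to
#' source world coordinates, by minimising the negative normalised mutual
#' information of the resampled overlap (scaled by the number of
#' overlapping voxels) plus the quadratic prior penalty on the scale/shear
#' block. Optimisation is derivative-free (Nelder-Mead) in three stages —
#' rigid at coarse resolution, full affine at coarse, then full resolution —
#' starting from a centre-of-mass alignment unless `init` is supplied.
#'
#' @param source a [volume3d] to be aligned.
#' @param template a [volume3d] defining the target space.
#' @param prior an [affine_prior], or `NULL` for no penalty.
#' @param init optional starting [affine_params] or 4x4 matrix.
#' @param maxit Nelder-Mead iteration cap per stage.
#' @param tol relative convergence tolerance on the objective.
#' @return An [affine_params] with attributes `matrix` (the composed 4x4),
#'   `objective` (final cost), `trace` (best objective after each stage)
#'   and `evaluations` (number of cost evaluations).
#' @export
register_affine <- function(source, template, prior = default_affine_prior(),
                            init = NULL, maxit = 300, tol = 1e-4) {
  stopifnot(inherits(source, "volume3d"), inherits(template, "volume3d"))
  if (is.null(init)) {
    shift <- centre_of_mass(source) - centre_of_mass(template)
    p0 <- affine_params(translation = shift)
  } else if (inherits(init, "affine_params")) {
    p0 <- init
  } else {
    p0 <- polar_decompose(as.matrix(init))
  }
  n_eval <- 0L
  make_cost <- function(src, tpl, free) {
    g <- world_grid(tpl)
    tdat <- as.numeric(tpl$data)
    base <- params_to_vec(p0)
    function(v) {
      n_eval <<- n_eval + 1L
      full <- base
      full[free] <- v
      p <- vec_to_params(full)
      M <- compose_affine(p)
      xyz <- cbind(g, 1) %*% t(M)
      ijk <- xyz %*% t(solve(src$vox2world))
      d <- dim(src$data)
      inb <- ijk[, 1] >= 0 & ijk[, 1] <= d[1] - 1 &
        ijk[, 2] >= 0 & ijk[, 2] <= d[2] - 1 &
        ijk[, 3] >= 0 & ijk[, 3] <= d[3] - 1
      if (sum(inb) < 100)
        return(1e10)
      vals <- interp_trilinear(src$data, ijk[inb, 1], ijk[inb, 2], ijk[inb, 3])
      cost <- sum(inb) * (1 + neg_nmi(vals, tdat[inb]))
      if (!is.null(prior)) cost <- cost + prior_penalty(p, prior)
      cost
    }
  }
  src_c <- downsample2(source); tpl_c <- downsample2(template)
  stages <- list(list(src = src_c, tpl = tpl_c, free = 1:6),
                 list(src = src_c, tpl = tpl_c, free = 1:12),
                 list(src = source, tpl = template, free = 1:12),
                 list(src = source, tpl = template, free = 1:12))
  scales <- c(rep(0.1, 3), rep(0.03, 3), rep(0.02, 3), rep(0.02, 3))
  trace <- numeric(0)
  cur <- params_to_vec(p0)
  f0 <- make_cost(source, template, 1:12)(cur)
  n_eval <- 0L
  for (si in seq_along(stages)) {
    st <- stages[[si]]
    cost <- make_cost(st$src, st$tpl, st$free)
    # restart stages shrink the simplex around the incumbent
    psc <- scales[st$free] * if (si == length(stages)) 0.2 else 1
    opt <- stats::optim(cur[st$free], cost, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = tol * 1e-2,
                                       parscale = psc))
    cur[st$free] <- opt$par
    trace <- c(trace, opt$value)
  }
  final <- trace[length(trace)]
  if (is.finite(f0) && final > f0 - abs(f0) * 1e-6)
    warning("register_affine: failed to improve on the initialisation; ",
            "returning best-found parameters")
  if (!is.finite(final) || final >= 1e10)
    stop("register_affine: source and template do not overlap")
  out <- vec_to_params(cur)
  attr(out, "matrix") <- compose_affine(out)
  attr(out, "objective") <- final
  attr(out, "trace") <- trace
  attr(out, "evaluations") <- n_eval
  out
}

#' Write an affine transform as plain text with a JSON parameter sidecar
#'
#' @param params an [affine_params].
#' @param path output path for the 4x4 matrix (one row per line); the
#'   decomposed parameters go to `paste0(path, ".json")`.
#' @export
write_affine <- function(params, path) {
  M <- compose_affine(params)
  utils::write.table(M, path, row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(unclass(params), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an affine transform written by [write_affine]
#' @param path path to the matrix file.
#' @return An [affine_params].
#' @export
read_affine <- function(path) {
  M <- as.matrix(utils::read.table(path))
  dimnames(M) <- NULL
  polar_decompose(M)
}
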