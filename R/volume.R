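#' Three-dimensional scalar volume in stereotaxic space
#'
#' `volume3d` is the core image container of the package: a 3-D numeric
#' array together with its voxel size (mm) and a 4x4 voxel-to-world affine
#' mapping 0-based voxel indices into bregma-origin Paxinos millimetre
#' coordinates (+x left-to-right lateral, +y posterior-to-anterior,
#' +z inferior-to-superior).
#'
#' @param data 3-D numeric array.
#' @param voxel_size length-3 positive numeric, voxel edge lengths in mm.
#'   Ignored (derived from `vox2world`) when `vox2world` is supplied.
#' @param vox2world 4x4 matrix mapping 0-based voxel indices `(i,j,k,1)` to
#'   world mm. Defaults to a pure scaling by `voxel_size` with the origin at
#'   voxel (0,0,0).
#' @param units free-text intensity unit label.
#'
#' @return An object of class `volume3d` with fields `data`, `voxel_size`,
#'   `vox2world`, `units`.
#' @export
volume3d <- function(data, voxel_size = c(1, 1, 1), vox2world = NULL,
                     units = "arbitrary") {
  data <- as.array(data)
  if (length(dim(data)) != 3L)
    stop("volume3d: `data` must be a 3-D array, got ", length(dim(data)),
         " dimension(s)")
  storage.mode(data) <- "double"
  if (is.null(vox2world)) {
    voxel_size <- as.numeric(voxel_size)
    if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
        any(voxel_size <= 0))
      stop("volume3d: voxel_size must be 3 strictly positive numbers")
    vox2world <- diag(c(voxel_size, 1))
  } else {
    vox2world <- as.matrix(vox2world)
    if (!all(dim(vox2world) == c(4L, 4L)))
      stop("volume3d: vox2world must be 4x4")
    A <- vox2world[1:3, 1:3]
    if (!all(is.finite(vox2world)) || abs(det(A)) < .Machine$double.eps * 10)
      stop("volume3d: vox2world has a (near-)zero determinant 3x3 block")
    voxel_size <- sqrt(colSums(A^2))
  }
  structure(list(data = data, voxel_size = voxel_size,
                 vox2world = vox2world, units = units),
            class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume3d> %d x %d x %d voxels, %.4g x %.4g x %.4g mm (%s)\n",
              d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2],
              x$voxel_size[3], x$units))
  org <- x$vox2world[1:3, 4]
  cat(sprintf("  voxel (0,0,0) at world (%.3f, %.3f, %.3f) mm\n",
              org[1], org[2], org[3]))
  invisible(x)
}

#' @export
dim.volume3d <- function(x) dim(x$data)

#' Read a NIfTI-1 volume
#'
#' Reads a single-file 3-D NIfTI-1 volume into a [volume3d], taking the
#' voxel-to-world matrix from the sform (falling back to whatever xform
#' RNifti resolves). World coordinates are interpreted as bregma-origin
#' Paxinos mm.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return A [volume3d].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("read_volume: file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("read_volume: expected a 3-D volume, file has ", length(d),
         " dimensions (", paste(d, collapse = "x"), ")")
  xf <- RNifti::xform(img, useQuaternionFirst = FALSE)
  xf <- matrix(as.numeric(xf), 4, 4)
  A <- xf[1:3, 1:3]
  if (abs(det(A)) < .Machine$double.eps * 10)
    stop("read_volume: header voxel-to-world matrix is singular ",
         "(zero-determinant 3x3 block)")
  volume3d(array(as.numeric(img), dim = d), vox2world = xf)
}

#' Write a volume as NIfTI-1
#'
#' Stores the voxel-to-world matrix in the sform with code 2 ("aligned");
#' the qform mirrors the sform. Data are stored as 32-bit float.
#'
#' @param vol a [volume3d].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "volume3d"))
  img <- RNifti::asNifti(
    vol$data,
    reference = list(pixdim = c(1, vol$voxel_size, rep(1, 4))),
    datatype = "float")
  img <- RNifti::`sform<-`(img, structure(vol$vox2world, code = 2L))
  img <- RNifti::`qform<-`(img, structure(vol$vox2world, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Map 0-based voxel indices to stereotaxic world coordinates
#'
#' @param vol a [volume3d].
#' @param ijk numeric vector of 3 (or n x 3 matrix of) 0-based voxel
#'   indices; fractional indices are allowed.
#' @return numeric vector of 3 (or n x 3 matrix): world mm relative to
#'   bregma.
#' @export
voxel_to_world <- function(vol, ijk) {
  stopifnot(inherits(vol, "volume3d"))
  ijk <- if (is.matrix(ijk)) ijk else matrix(ijk, nrow = 1)
  d <- dim(vol$data)
  if (any(ijk < -0.5) || any(sweep(ijk, 2, d - 0.5, ">")))
    stop("voxel_to_world: voxel index out of bounds for grid ",
         paste(d, collapse = "x"))
  out <- cbind(ijk, 1) %*% t(vol$vox2world)
  out <- out[, 1:3, drop = FALSE]
  if (nrow(out) == 1L) drop(out) else out
}

#' Map stereotaxic world coordinates to 0-based voxel indices
#'
#' Inverse of [voxel_to_world]; returns fractional indices.
#'
#' @param vol a [volume3d].
#' @param xyz numeric vector of 3 (or n x 3 matrix of) world mm.
#' @return 0-based (fractional) voxel indices.
#' @export
world_to_voxel <- function(vol, xyz) {
  stopifnot(inherits(vol, "volume3d"))
  xyz <- if (is.matrix(xyz)) xyz else matrix(xyz, nrow = 1)
  out <- cbind(xyz, 1) %*% t(solve(vol$vox2world))
  out <- out[, 1:3, drop = FALSE]
  if (nrow(out) == 1L) drop(out) else out
}

#' Voxel volume in cubic millimetres
#' @param vol a [volume3d].
#' @return scalar mm^3 per voxel.
#' @export
voxel_volume <- function(vol) prod(vol$voxel_size)

# Shared geometry check used by stages that stack multiple volumes.
same_geometry <- function(a, b, tol = 1e-6) {
  all(dim(a$data) == dim(b$data)) &&
    max(abs(a$vox2world - b$vox2world)) < tol
}
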