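# Internal numerical helpers shared across modules: trilinear sampling,
# separable cosine (DCT-II) bases and tensor-mode products.

# Trilinear interpolation of a 3-D array at 0-based fractional voxel
# coordinates, with edge clamping. i, j, k are equal-length vectors.
interp_trilinear <- function(arr, i, j, k) {
  d <- dim(arr)
  i <- pmin(pmax(i, 0), d[1] - 1)
  j <- pmin(pmax(j, 0), d[2] - 1)
  k <- pmin(pmax(k, 0), d[3] - 1)
  i0 <- floor(i); j0 <- floor(j); k0 <- floor(k)
  i0 <- pmin(i0, d[1] - 2); j0 <- pmin(j0, d[2] - 2); k0 <- pmin(k0, d[3] - 2)
  i0 <- pmax(i0, 0); j0 <- pmax(j0, 0); k0 <- pmax(k0, 0)
  fi <- i - i0; fj <- j - j0; fk <- k - k0
  base <- 1 + i0 + d[1] * (j0 + d[2] * k0)
  sx <- 1; sy <- d[1]; sz <- d[1] * d[2]
  v000 <- arr[base]
  v100 <- arr[base + sx]
  v010 <- arr[base + sy]
  v110 <- arr[base + sx + sy]
  v001 <- arr[base + sz]
  v101 <- arr[base + sx + sz]
  v011 <- arr[base + sy + sz]
  v111 <- arr[base + sx + sy + sz]
  w000 <- (1 - fi) * (1 - fj) * (1 - fk)
  w100 <- fi * (1 - fj) * (1 - fk)
  w010 <- (1 - fi) * fj * (1 - fk)
  w110 <- fi * fj * (1 - fk)
  w001 <- (1 - fi) * (1 - fj) * fk
  w101 <- fi * (1 - fj) * fk
  w011 <- (1 - fi) * fj * fk
  w111 <- fi * fj * fk
  v000 * w000 + v100 * w100 + v010 * w010 + v110 * w110 +
    v001 * w001 + v101 * w101 + v011 * w011 + v111 * w111
}

# Sample a volume's data at world-mm positions (n x 3), trilinear with
# edge clamping. Returns a vector of n intensities.
sample_world <- function(vol, xyz) {
  ijk <- cbind(xyz, 1) %*% t(solve(vol$vox2world))
  interp_trilinear(vol$data, ijk[, 1], ijk[, 2], ijk[, 3])
}

# 0-based voxel index grid of a volume as an n x 3 matrix (column-major,
# i fastest), plus the matching world coordinates.
voxel_grid <- function(dm) {
  cbind(rep.int(seq_len(dm[1]) - 1, dm[2] * dm[3]),
        rep.int(rep(seq_len(dm[2]) - 1, each = dm[1]), dm[3]),
        rep(seq_len(dm[3]) - 1, each = dm[1] * dm[2]))
}

world_grid <- function(vol) {
  g <- voxel_grid(dim(vol$data))
  out <- cbind(g, 1) %*% t(vol$vox2world)
  out[, 1:3, drop = FALSE]
}

# Orthonormal DCT-II basis matrix: n samples x K orders. Order m (0-based)
# is cos(pi*m*(x+0.5)/n), so its spatial period along an axis of physical
# length L = n*h is 2L/m.
dct_basis <- function(n, K) {
  x <- seq_len(n) - 0.5
  B <- matrix(0, n, K)
  for (m in seq_len(K)) {
    B[, m] <- cos(pi * (m - 1) * x / n)
  }
  B[, 1] <- B[, 1] / sqrt(n)
  if (K > 1) B[, -1] <- B[, -1] * sqrt(2 / n)
  B
}

# Spatial derivative of the orthonormal DCT basis with respect to
# millimetres (h = voxel size along the axis).
dct_basis_deriv <- function(n, K, h) {
  x <- seq_len(n) - 0.5
  B <- matrix(0, n, K)
  for (m in seq_len(K)) {
    w <- pi * (m - 1) / n
    B[, m] <- -w * sin(w * x) / h
  }
  if (K > 1) B[, -1] <- B[, -1] * sqrt(2 / n)
  B[, 1] <- 0
  B
}

# Apply matrices along each mode of a 3-D array: out = A x1 Mx x2 My x3 Mz.
# Mx is (a x n1) etc. Used both to evaluate separable basis expansions
# (coefficients -> field) and, with transposed bases, to project
# (field -> coefficients).
sep_tensor <- function(arr, Mx, My, Mz) {
  d <- dim(arr)
  # mode 1
  out <- Mx %*% matrix(arr, d[1], d[2] * d[3])
  d1 <- nrow(Mx)
  out <- array(out, c(d1, d[2], d[3]))
  # mode 2
  out <- aperm(out, c(2, 1, 3))
  out <- My %*% matrix(out, d[2], d1 * d[3])
  d2 <- nrow(My)
  out <- array(out, c(d2, d1, d[3]))
  out <- aperm(out, c(2, 1, 3))
  # mode 3
  out <- aperm(out, c(3, 1, 2))
  out <- Mz %*% matrix(out, d[3], d1 * d2)
  d3 <- nrow(Mz)
  out <- array(out, c(d3, d1, d2))
  aperm(out, c(2, 3, 1))
}

# Number of DCT orders along one axis such that the highest retained
# frequency has spatial period >= cutoff_mm. Axis length L = n*h mm;
# order m has period 2L/m, so m_max = floor(2L/cutoff) and the count
# includes the DC term.
dct_orders_for_cutoff <- function(n, h, cutoff_mm) {
  L <- n * h
  max(1L, as.integer(floor(2 * L / cutoff_mm)) + 1L)
}
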