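# Synthetic mouse-brain cohort generator. Geometry is stylised
# (ellipsoidal brain, WM core, ventricle lobes, striatum-like and
# cortex-like labelled regions) rather than anatomically faithful: the
# pipeline's acceptance surface is statistical, not anatomical.

#' Specification of a synthetic mouse-brain phantom cohort
#'
#' Defaults emulate an in vivo mouse T2-weighted-like acquisition at
#' 100 um isotropic voxels: bright CSF, intermediate GM, darker WM.
#' Inter-subject variability combines a random global affine (scale/shear
#' SDs set to the mouse population values that also drive the shipped
#' registration prior) with a smooth random warp; intensities carry a
#' smooth multiplicative bias field and additive Gaussian noise.
#'
#' @param dim grid dimensions (default 64 x 80 x 48).
#' @param voxel_size voxel edge lengths in mm (default 0.1 isotropic).
#' @param intensity_means named class means (gm, wm, csf, other) in
#'   arbitrary units.
#' @param noise_sd additive Gaussian noise SD (same units).
#' @param bias_amplitude SD of the log bias field (0 disables bias).
#' @param bias_cutoff_mm spatial cutoff of the generated bias field.
#' @param jitter_translation_sd mm, per-axis subject translation SD.
#' @param jitter_rotation_sd radians, per-axis rotation SD.
#' @param jitter_scale_sd per-axis scale SD (default the population values
#'   0.01, 0.02, 0.02).
#' @param jitter_shear_sd per-component shear SD (default 0.02, 0.04,
#'   0.01).
#' @param warp_sd_mm per-axis RMS displacement of the random smooth warp
#'   in mm. Together with `warp_basis` the default gives local volume
#'   fluctuations of a few percent, matching regional morphometric
#'   variability of inbred strains.
#' @param warp_basis DCT orders per axis of the random warp.
#' @param atrophy list of `(region, fraction)` pairs applied to disease
#'   subjects, e.g. `list(striatum = 0.15)`; fractions in `[0, 1)`.
#' @param seed RNG seed; the spec plus the seed fully determine a cohort.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(dim = c(64, 80, 48), voxel_size = c(0.1, 0.1, 0.1),
                         intensity_means = c(gm = 0.60, wm = 0.45,
                                             csf = 1.00, other = 0.08),
                         noise_sd = 0.03, bias_amplitude = 0.05,
                         bias_cutoff_mm = 12,
                         jitter_translation_sd = 0.05,
                         jitter_rotation_sd = 0.01,
                         jitter_scale_sd = c(0.01, 0.02, 0.02),
                         jitter_shear_sd = c(0.02, 0.04, 0.01),
                         warp_sd_mm = 0.03, warp_basis = c(4, 4, 4),
                         atrophy = list(), seed = 1) {
  af <- unlist(atrophy)
  if (length(af) && (any(af < 0) || any(af >= 1)))
    stop("phantom_spec: atrophy fractions must be in [0, 1)")
  if (length(af) && !all(names(af) %in% c("striatum", "cortex")))
    stop("phantom_spec: atrophy regions must be 'striatum' or 'cortex'")
  structure(list(dim = as.integer(dim), voxel_size = as.numeric(voxel_size),
                 intensity_means = intensity_means, noise_sd = noise_sd,
                 bias_amplitude = bias_amplitude,
                 bias_cutoff_mm = bias_cutoff_mm,
                 jitter_translation_sd = jitter_translation_sd,
                 jitter_rotation_sd = jitter_rotation_sd,
                 jitter_scale_sd = jitter_scale_sd,
                 jitter_shear_sd = jitter_shear_sd,
                 warp_sd_mm = warp_sd_mm, warp_basis = as.integer(warp_basis),
                 atrophy = atrophy, seed = seed),
            class = "phantom_spec")
}

# Soft (partial-volume) ellipsoid indicator: ~1 inside, ~0 outside, with a
# transition shell about one voxel wide. centre/semiaxes in mm; g is an
# n x 3 matrix of world coordinates.
soft_ellipsoid <- function(g, centre, semiaxes, edge_mm) {
  q <- sqrt(((g[, 1] - centre[1]) / semiaxes[1])^2 +
              ((g[, 2] - centre[2]) / semiaxes[2])^2 +
              ((g[, 3] - centre[3]) / semiaxes[3])^2)
  s_eff <- exp(mean(log(semiaxes)))
  pmin(1, pmax(0, (1 - q) * s_eff / edge_mm + 0.5))
}

# Progenitor tissue geometry: probability maps, region weights, and the
# Paxinos-style world matrix (bregma at the grid centre).
phantom_progenitor <- function(spec) {
  dm <- spec$dim; h <- spec$voxel_size
  M <- diag(c(h, 1))
  M[1:3, 4] <- -h * (dm - 1) / 2  # bregma at the grid centre
  ref <- volume3d(array(0, dm), vox2world = M)
  g <- world_grid(ref)
  fov <- dm * h
  edge <- 1.5 * max(h)
  br_ax <- 0.42 * fov
  brain <- soft_ellipsoid(g, c(0, 0, 0), br_ax, edge)
  wm <- soft_ellipsoid(g, c(0, -0.05 * fov[2], 0), 0.52 * br_ax, edge)
  vent <- pmax(
    soft_ellipsoid(g, c(-0.18 * br_ax[1], 0.05 * fov[2], 0.1 * br_ax[3]),
                   c(0.13, 0.30, 0.13) * br_ax, edge),
    soft_ellipsoid(g, c(0.18 * br_ax[1], 0.05 * fov[2], 0.1 * br_ax[3]),
                   c(0.13, 0.30, 0.13) * br_ax, edge))
  stri <- pmax(
    soft_ellipsoid(g, c(-0.45 * br_ax[1], 0.25 * br_ax[2], 0),
                   c(0.28, 0.30, 0.32) * br_ax, edge),
    soft_ellipsoid(g, c(0.45 * br_ax[1], 0.25 * br_ax[2], 0),
                   c(0.28, 0.30, 0.32) * br_ax, edge))
  csf <- brain * vent
  wm_p <- brain * (1 - vent) * wm
  gm <- brain * (1 - vent) * (1 - wm)
  qn <- sqrt(((g[, 1]) / br_ax[1])^2 + ((g[, 2]) / br_ax[2])^2 +
               ((g[, 3]) / br_ax[3])^2)
  cortex <- gm * as.numeric(qn > 0.72)
  striatum <- gm * stri * (1 - as.numeric(qn > 0.72))
  mk <- function(v, unit = "probability")
    volume3d(array(v, dm), vox2world = M, units = unit)
  list(gm = mk(gm), wm = mk(wm_p), csf = mk(csf),
       regions = list(striatum = mk(striatum, "weight"),
                      cortex = mk(cortex, "weight")),
       reference = ref)
}

# Implant regional GM atrophy as calibrated tissue rarefaction: the GM
# partial volume inside the region is reduced along a smooth profile
# (strongest in the region core, fading at its boundary), scaled by
# bisection so the regional GM volume drops by exactly the requested
# fraction; the removed partial volume becomes CSF. A pure boundary
# erosion of the same calibrated volume concentrates the change in a rim
# thinner than one voxel at the grid scales used here, which vanishes
# into partial-volume noise after smoothing; distributed rarefaction
# carries the identical volumetric effect while remaining resolvable.
implant_atrophy <- function(prog, region, fraction) {
  w <- prog$regions[[region]]$data
  gm <- prog$gm$data
  reg_gm <- gm * w
  target_removed <- fraction * sum(reg_gm)
  ind <- volume3d(array(as.numeric(reg_gm > 0.25), dim(gm)),
                  vox2world = prog$gm$vox2world)
  profile <- smooth_volume(ind,
                           fwhm = 4 * max(prog$gm$voxel_size) * 1000)$data
  profile <- profile / max(profile)
  # removal fraction field a*profile, a calibrated so the *measured*
  # regional GM (weighted by the region map) drops by `fraction`
  lo <- 0; hi <- 1 / max(profile)
  for (i in 1:60) {
    a <- (lo + hi) / 2
    rem <- sum(gm * pmin(a * profile, 1) * w * w)
    if (rem < target_removed) lo <- a else hi <- a
  }
  removed <- gm * pmin(((lo + hi) / 2) * profile, 1) * w
  prog$gm$data <- gm - removed
  prog$csf$data <- prog$csf$data + removed
  prog$atrophy_mask <- volume3d(
    array(as.numeric(removed > 0.5 * fraction * pmax(gm, 1e-6)), dim(gm)) *
      (reg_gm > 0.25),
    vox2world = prog$gm$vox2world, units = "mask")
  prog$atrophy_removed <- sum(removed)
  prog
}

# One subject: random affine + smooth warp pull-back of the progenitor
# maps, then class intensities, bias and noise. RNG state is advanced by
# the caller's seeding discipline.
phantom_subject <- function(spec, prog, subject_id, group) {
  dm <- spec$dim
  ref <- prog$reference
  g <- world_grid(ref)
  p <- affine_params(
    translation = stats::rnorm(3, 0, spec$jitter_translation_sd),
    rotation = stats::rnorm(3, 0, spec$jitter_rotation_sd),
    scale = pmax(stats::rnorm(3, 1, spec$jitter_scale_sd), 0.5),
    shear = stats::rnorm(3, 0, spec$jitter_shear_sd))
  A <- compose_affine(p)
  nb <- pmin(spec$warp_basis, dm)
  npar <- prod(nb)
  cf <- lapply(1:3, function(a) {
    c1 <- array(stats::rnorm(npar), nb)
    c1[1, 1, 1] <- 0
    c1
  })
  tot <- sum(vapply(cf, function(c1) sum(c1^2), 0))
  scl <- if (tot > 0)
    spec$warp_sd_mm * sqrt(3 * prod(dm) / tot) else 0
  cf <- lapply(cf, function(c1) c1 * scl)
  wf <- warp_field(cf, ref)
  u <- evaluate_warp(wf)
  xyz <- cbind(g, 1) %*% t(A)
  xyz <- xyz[, 1:3, drop = FALSE] +
    cbind(as.numeric(u[[1]]), as.numeric(u[[2]]), as.numeric(u[[3]]))
  gm <- array(sample_world(prog$gm, xyz), dm)
  wm <- array(sample_world(prog$wm, xyz), dm)
  csf <- array(sample_world(prog$csf, xyz), dm)
  other <- pmax(0, 1 - gm - wm - csf)
  mu <- spec$intensity_means
  img <- mu[["gm"]] * gm + mu[["wm"]] * wm + mu[["csf"]] * csf +
    mu[["other"]] * other
  if (spec$bias_amplitude > 0) {
    bb <- bias_bases(dm, spec$voxel_size, spec$bias_cutoff_mm)
    bc <- array(stats::rnorm(prod(bb$K)), bb$K)
    bc[1, 1, 1] <- 0
    fld <- sep_tensor(bc, bb$Bx, bb$By, bb$Bz)
    if (stats::sd(fld) > 0)
      fld <- fld * spec$bias_amplitude / stats::sd(fld)
    bias <- exp(fld)
  } else bias <- array(1, dm)
  img <- img * bias + array(stats::rnorm(prod(dm), 0, spec$noise_sd), dm)
  lab <- array(0L, dm)
  stack <- cbind(as.numeric(other), as.numeric(gm), as.numeric(wm),
                 as.numeric(csf))
  lab <- array(max.col(stack, ties.method = "first") - 1L, dm)
  reg_vol <- vapply(prog$regions, function(r) {
    prodmap <- volume3d(r$data * prog$gm$data, vox2world = r$vox2world)
    sum(sample_world(prodmap, xyz)) * prod(spec$voxel_size)
  }, 0)
  list(id = subject_id, group = group,
       volume = volume3d(img, vox2world = ref$vox2world, units = "signal"),
       labels = volume3d(lab, vox2world = ref$vox2world, units = "class"),
       gm_truth = volume3d(gm, vox2world = ref$vox2world,
                           units = "probability"),
       wm_truth = volume3d(wm, vox2world = ref$vox2world,
                           units = "probability"),
       csf_truth = volume3d(csf, vox2world = ref$vox2world,
                            units = "probability"),
       bias_truth = volume3d(bias, vox2world = ref$vox2world,
                             units = "multiplicative"),
       tiv_truth = sum(gm + wm + csf) * prod(spec$voxel_size),
       regional_gm_truth = reg_vol,
       affine_truth = p)
}

#' Generate a two-group synthetic mouse-brain cohort with known truth
#'
#' Control subjects are jittered copies of one progenitor geometry;
#' disease subjects additionally carry the spec's implanted regional GM
#' atrophy (eroded into the region and replaced by CSF, calibrated to the
#' requested volume fraction). Every subject records its true tissue maps,
#' label map, TIV, regional GM volumes and applied transform.
#'
#' @param spec a [phantom_spec].
#' @param n_control,n_disease group sizes (>= 1).
#' @return A `phantom_cohort`: `subjects` (list), `manifest` (data frame:
#'   subject, group, tiv_truth), `spec`, `progenitor` (control geometry,
#'   with `tpms` usable as segmentation priors), `atrophy_truth` (mask
#'   [volume3d] or NULL).
#' @export
make_phantom_cohort <- function(spec, n_control, n_disease) {
  stopifnot(inherits(spec, "phantom_spec"), n_control >= 1, n_disease >= 1)
  set.seed(spec$seed)
  prog <- phantom_progenitor(spec)
  prog_dis <- prog
  for (rg in names(spec$atrophy))
    prog_dis <- implant_atrophy(prog_dis, rg, spec$atrophy[[rg]])
  subjects <- vector("list", n_control + n_disease)
  for (i in seq_len(n_control))
    subjects[[i]] <- phantom_subject(spec, prog, i, "control")
  for (i in seq_len(n_disease))
    subjects[[n_control + i]] <- phantom_subject(spec, prog_dis,
                                                 n_control + i, "disease")
  manifest <- data.frame(
    subject = vapply(subjects, function(s) as.integer(s$id), 0L),
    group = vapply(subjects, function(s) s$group, ""),
    tiv_truth = vapply(subjects, function(s) s$tiv_truth, 0))
  structure(list(subjects = subjects, manifest = manifest, spec = spec,
                 progenitor = prog,
                 tpms = tissue_probability_maps(prog$gm, prog$wm, prog$csf),
                 atrophy_truth = prog_dis$atrophy_mask),
            class = "phantom_cohort")
}

#' Generate a single-group exchangeable null cohort
#'
#' As [make_phantom_cohort] with no atrophy and no group structure: all
#' subjects are jittered, biased, noisy copies of the same truth geometry,
#' so any balanced relabelling satisfies the null hypothesis exactly.
#'
#' @param spec a [phantom_spec] (its `atrophy` field is ignored).
#' @param n number of subjects (>= 2).
#' @return A `phantom_cohort` with `group = NA` for every subject.
#' @export
null_cohort <- function(spec, n) {
  stopifnot(inherits(spec, "phantom_spec"), n >= 2)
  spec$atrophy <- list()
  set.seed(spec$seed)
  prog <- phantom_progenitor(spec)
  subjects <- lapply(seq_len(n), function(i)
    phantom_subject(spec, prog, i, NA_character_))
  manifest <- data.frame(
    subject = vapply(subjects, function(s) as.integer(s$id), 0L),
    group = NA_character_,
    tiv_truth = vapply(subjects, function(s) s$tiv_truth, 0))
  structure(list(subjects = subjects, manifest = manifest, spec = spec,
                 progenitor = prog,
                 tpms = tissue_probability_maps(prog$gm, prog$wm, prog$csf),
                 atrophy_truth = NULL),
            class = "phantom_cohort")
}

#' Write a phantom cohort to disk
#'
#' Writes each subject's intensity volume and label map as NIfTI, a TSV
#' manifest (subject, group, tiv_truth, file) and a JSON echo of the spec.
#'
#' @param cohort a `phantom_cohort`.
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "phantom_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(length(cohort$subjects))
  for (i in seq_along(cohort$subjects)) {
    s <- cohort$subjects[[i]]
    files[i] <- file.path(dir, sprintf("sub-%03d.nii.gz", s$id))
    write_volume(s$volume, files[i])
    write_volume(s$labels, file.path(dir, sprintf("sub-%03d_labels.nii.gz",
                                                  s$id)))
  }
  man <- cbind(cohort$manifest, file = files)
  mpath <- file.path(dir, "manifest.tsv")
  utils::write.table(man, mpath, sep = "\t", row.names = FALSE, quote = FALSE)
  sp <- cohort$spec
  sp$intensity_means <- as.list(sp$intensity_means)
  jsonlite::write_json(unclass(sp), file.path(dir, "spec.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(mpath)
}
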