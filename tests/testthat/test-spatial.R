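test_that("jacobian determinant matches analytic and finite-difference oracles", {
  ref <- volume3d(array(0, c(24, 24, 20)), voxel_size = rep(0.1, 3))
  # identity warp
  w0 <- warp_field(lapply(1:3, function(a) array(0, c(2, 2, 2))), ref)
  expect_equal(range(jacobian_determinant(w0)$data), c(1, 1))

  # random smooth warp vs central differences
  wf <- random_warp(ref, rms_mm = 0.03, seed = 13)
  jd <- jacobian_determinant(wf)$data
  u <- evaluate_warp(wf)
  h <- 0.1
  fd_grad <- function(arr, a) {
    # fourth-order central differences keep the oracle's truncation error
    # well below the comparison tolerance
    d <- dim(arr); gr <- array(0, d)
    ix <- lapply(d, seq_len)
    ixc <- ix; ixc[[a]] <- 3:(d[a] - 2)
    sl <- function(off) {
      ixo <- ix; ixo[[a]] <- (3:(d[a] - 2)) + off
      do.call(`[`, c(list(arr), ixo))
    }
    val <- (-sl(2) + 8 * sl(1) - 8 * sl(-1) + sl(-2)) / (12 * h)
    do.call(`[<-`, c(list(gr), ixc, list(val)))
  }
  J <- lapply(1:3, function(a) lapply(1:3, function(b) fd_grad(u[[a]], b)))
  det_fd <- (1 + J[[1]][[1]]) * ((1 + J[[2]][[2]]) * (1 + J[[3]][[3]]) -
                                   J[[2]][[3]] * J[[3]][[2]]) -
    J[[1]][[2]] * (J[[2]][[1]] * (1 + J[[3]][[3]]) -
                     J[[2]][[3]] * J[[3]][[1]]) +
    J[[1]][[3]] * (J[[2]][[1]] * J[[3]][[2]] -
                     (1 + J[[2]][[2]]) * J[[3]][[1]])
  core <- 4:21
  rel <- abs(jd[core, core, 4:17] - det_fd[core, core, 4:17]) /
    abs(det_fd[core, core, 4:17])
  expect_lt(max(rel), 1e-3)
})

test_that("apply_warp is exact for the identity and conserves under modulation", {
  ref <- volume3d(array(0, c(24, 24, 20)), voxel_size = rep(0.1, 3))
  img <- tiny_volume(c(24, 24, 20), rep(0.1, 3), seed = 2)
  w0 <- warp_field(lapply(1:3, function(a) array(0, c(2, 2, 2))), ref)
  out <- apply_warp(img, w0)
  expect_lt(max(abs(out$data - img$data)), 1e-6)

  # compactly supported blob so edge clamping cannot leak mass
  sp <- phantom_spec(dim = c(32, 36, 26), seed = 5, noise_sd = 0,
                     bias_amplitude = 0, warp_sd_mm = 0,
                     jitter_translation_sd = 0, jitter_rotation_sd = 0,
                     jitter_scale_sd = c(0, 0, 0),
                     jitter_shear_sd = c(0, 0, 0))
  gm <- null_cohort(sp, 2)$subjects[[1]]$gm_truth
  for (sd in 1:4) {
    wf <- random_warp(gm, rms_mm = 0.06, seed = sd)
    mod <- apply_warp(gm, wf, modulate = TRUE)
    expect_true(all(mod$data > -1e-9))
    expect_lt(abs(sum(mod$data) - sum(gm$data)) / sum(gm$data), 0.01)
  }
})

test_that("implanted regional volume loss survives modulation to template space", {
  sp <- phantom_spec(dim = c(40, 48, 32), seed = 41,
                     atrophy = list(striatum = 0.15),
                     jitter_translation_sd = 0.01, jitter_rotation_sd = 0.002,
                     jitter_scale_sd = rep(0.005, 3),
                     jitter_shear_sd = rep(0.005, 3))
  co <- make_phantom_cohort(sp, 4, 4)
  w <- co$progenitor$regions$striatum$data
  ratio <- vapply(co$subjects, function(s) {
    wf <- random_warp(s$gm_truth, rms_mm = 0.02, seed = s$id)
    mod <- apply_warp(s$gm_truth, wf, modulate = TRUE)
    sum(mod$data * w)
  }, 0)
  expect_equal(mean(ratio[5:8]) / mean(ratio[1:4]), 0.85, tolerance = 0.03)
})

test_that("smoothing is a calibrated, conservative, linear Gaussian", {
  dm <- c(41, 41, 41)
  a <- array(0, dm); a[21, 21, 21] <- 1
  v <- volume3d(a, voxel_size = rep(0.1, 3))
  expect_identical(smooth_volume(v, 0)$data, v$data)
  s <- smooth_volume(v, 400)
  expect_lt(abs(sum(s$data) - 1), 1e-6)
  # measured FWHM of the impulse response
  prof <- s$data[, 21, 21]
  half <- max(prof) / 2
  ix <- which(prof >= half)
  lo <- approx(prof[c(min(ix) - 1, min(ix))], c(min(ix) - 1, min(ix)),
               xout = half)$y
  hi <- approx(prof[c(max(ix), max(ix) + 1)], c(max(ix), max(ix) + 1),
               xout = half)$y
  expect_equal((hi - lo) * 100, 400, tolerance = 0.05 * 400)

  # linearity and conservation on arbitrary input
  set.seed(8)
  x <- tiny_volume(dm, rep(0.1, 3), seed = 8)
  y <- tiny_volume(dm, rep(0.1, 3), seed = 9)
  sxy <- smooth_volume(volume3d(x$data + y$data, vox2world = x$vox2world), 300)
  expect_lt(max(abs(sxy$data - smooth_volume(x, 300)$data -
                      smooth_volume(y, 300)$data)), 1e-9)
  expect_lt(abs(sum(smooth_volume(x, 300)$data) - sum(x$data)) /
              abs(sum(x$data)), 1e-6)

  # Gaussian semigroup: twice at f equals once at f*sqrt(2) (within 1%).
  # Checked away from the boundary: the mass-conserving edge
  # renormalisation deliberately departs from the infinite-domain
  # Gaussian inside the kernel support of the faces.
  s2 <- smooth_volume(smooth_volume(x, 600), 600)
  s1 <- smooth_volume(x, 600 * sqrt(2))
  core <- 13:29
  expect_lt(sqrt(mean((s2$data - s1$data)[core, core, core]^2)) /
              sd(s1$data[core, core, core]), 0.01)
  expect_error(smooth_volume(x, -1), "non-negative")
})

test_that("non-linear registration recovers a known synthetic warp", {
  tpl <- clean_phantom_image(dm = c(40, 48, 32), seed = 31)
  nb <- c(5, 5, 5); nvox <- prod(dim(tpl$data))
  wtrue <- random_warp(tpl, nb = nb, rms_mm = 0.12, seed = 9)
  u <- evaluate_warp(wtrue)
  expect_lt(max(sqrt(u[[1]]^2 + u[[2]]^2 + u[[3]]^2)), 0.45)
  src <- apply_warp(tpl, wtrue)

  # self-registration stays put
  wid <- register_nonlinear(tpl, tpl, n_basis = c(6, 6, 6), iterations = 15)
  expect_lt(max(abs(unlist(evaluate_warp(wid)))), 0.05)

  wrec <- register_nonlinear(src, tpl, n_basis = c(6, 6, 6),
                             reg_weight = 0.01, iterations = 60)
  tr <- attr(wrec, "trace")
  urec <- evaluate_warp(wrec)
  brain <- tpl$data > 0.2
  rmse <- sqrt(mean(((urec[[1]] + u[[1]])^2 + (urec[[2]] + u[[2]])^2 +
                       (urec[[3]] + u[[3]])^2)[brain]))
  expect_lt(rmse, 0.1)
})

test_that("template building averages shape and sharpens the mean", {
  # identical inputs reproduce the input
  img <- clean_phantom_image(dm = c(24, 28, 20), seed = 3)
  tpl <- build_template(list(img, img), rounds = 1, n_basis = c(4, 4, 4),
                        iterations = 10)
  expect_lt(max(abs(tpl$data - img$data)), 1e-6)

  # two oppositely deformed copies: template closer to the progenitor
  prog <- clean_phantom_image(dm = c(32, 36, 26), seed = 6)
  wf <- random_warp(prog, rms_mm = 0.08, seed = 10)
  plus <- apply_warp(prog, wf)
  minus_wf <- wf; minus_wf$coef <- lapply(wf$coef, function(c1) -c1)
  minus <- apply_warp(prog, minus_wf)
  tpl2 <- build_template(list(plus, minus), rounds = 1,
                         n_basis = c(5, 5, 5), reg_weight = 0.01,
                         iterations = 30)
  rms <- function(a, b) sqrt(mean((a$data - b$data)^2))
  expect_lt(rms(tpl2, prog), min(rms(plus, prog), rms(minus, prog)))
  expect_error(build_template(list(img)), "at least 2")
})

test_that("non-linear registration sharpens the cohort mean image", {
  # a cohort with clearly visible anatomical variability: the comparison
  # asks whether registration recovers correspondence the affine stage
  # left behind, which requires misalignment larger than the sub-voxel
  # blur introduced by resampling itself
  sp <- phantom_spec(dim = c(32, 36, 26), seed = 51, noise_sd = 0.01,
                     bias_amplitude = 0, warp_sd_mm = 0.15,
                     warp_basis = c(4, 4, 4),
                     jitter_translation_sd = 0.05)
  co <- null_cohort(sp, 8)
  tpl <- volume3d(Reduce(`+`, lapply(co$subjects,
                                     function(s) s$volume$data)) / 8,
                  vox2world = co$subjects[[1]]$volume$vox2world)
  warped <- lapply(co$subjects, function(s) {
    wf <- register_nonlinear(s$volume, tpl, n_basis = c(6, 6, 5),
                             reg_weight = 0.005, iterations = 40)
    apply_warp(s$volume, wf)$data
  })
  mean_aff <- tpl
  mean_nl <- volume3d(Reduce(`+`, warped) / 8, vox2world = tpl$vox2world)
  expect_gt(sharpness(mean_nl), sharpness(mean_aff))
})

test_that("warps serialise as displacement NIfTI plus JSON coefficients", {
  ref <- volume3d(array(0, c(16, 16, 12)), voxel_size = rep(0.2, 3))
  wf <- random_warp(ref, rms_mm = 0.05, seed = 4)
  pre <- tempfile()
  write_warp(wf, pre)
  expect_true(file.exists(paste0(pre, "_disp_x.nii.gz")))
  expect_true(file.exists(paste0(pre, "_coef.json")))
  u <- evaluate_warp(wf)
  back <- read_volume(paste0(pre, "_disp_x.nii.gz"))
  expect_lt(max(abs(back$data - u[[1]])), 1e-5)
})
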