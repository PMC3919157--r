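test_that("bias basis size honours the spatial cutoff", {
  # 25.6 mm field of view at 0.1 mm voxels, 10 mm cutoff: at most
  # ceiling(2 * 25.6 / 10) + 1 = 7 basis orders per axis
  expect_lte(mousevbm:::dct_orders_for_cutoff(256, 0.1, 10),
             ceiling(2 * 25.6 / 10) + 1)
  # period of the highest retained order is >= the cutoff
  K <- mousevbm:::dct_orders_for_cutoff(256, 0.1, 10)
  expect_gte(2 * 25.6 / (K - 1), 10)
  expect_error(fit_bias_basis(tiny_volume(vs = rep(0.4, 3)), 0.5),
               "minimum")
})

test_that("fit_bias_basis is flat for a uniform image and recovers a known field", {
  dm <- c(24, 24, 16)
  u <- volume3d(array(1, dm), voxel_size = rep(0.4, 3))
  bf <- fit_bias_basis(u, 10, mask = array(TRUE, dm))
  fld <- evaluate_bias(bf, log_scale = TRUE)
  expect_lt(max(abs(fld)), 1e-6)

  bb <- mousevbm:::bias_bases(dm, rep(0.4, 3), 10)
  set.seed(4)
  bc <- array(rnorm(prod(bb$K), 0, 0.1), bb$K); bc[1, 1, 1] <- 0
  truth <- mousevbm:::sep_tensor(bc, bb$Bx, bb$By, bb$Bz)
  img <- volume3d(array(0.7 * exp(truth), dm), voxel_size = rep(0.4, 3))
  rec <- evaluate_bias(fit_bias_basis(img, 10, mask = array(TRUE, dm)),
                       log_scale = TRUE)
  expect_gt(cor(as.numeric(rec), as.numeric(truth)), 0.95)
  # exponentiated parameterisation keeps the field positive
  expect_true(all(evaluate_bias(fit_bias_basis(img, 10)) > 0))
})

# Hard-label fixture: a piecewise-constant three-intensity brain with
# exact one-hot probability maps -- the fully separable case.
hard_phantom <- function(dm = c(32, 36, 26), noise_sd = 0, seed = 31) {
  sp <- phantom_spec(dim = dm, seed = seed, noise_sd = 0,
                     bias_amplitude = 0, warp_sd_mm = 0,
                     jitter_translation_sd = 0, jitter_rotation_sd = 0,
                     jitter_scale_sd = c(0, 0, 0),
                     jitter_shear_sd = c(0, 0, 0))
  co <- null_cohort(sp, 2)
  lab <- co$subjects[[1]]$labels
  mu <- sp$intensity_means
  img <- array(mu[["other"]], dm)
  img[lab$data == 1] <- mu[["gm"]]
  img[lab$data == 2] <- mu[["wm"]]
  img[lab$data == 3] <- mu[["csf"]]
  set.seed(seed)
  img <- img + array(rnorm(prod(dm), 0, noise_sd), dm)
  onehot <- function(k) volume3d(array(as.numeric(lab$data == k), dm),
                                 vox2world = lab$vox2world)
  list(volume = volume3d(img, vox2world = lab$vox2world),
       labels = lab,
       tpms = tissue_probability_maps(onehot(1), onehot(2), onehot(3)),
       mu = mu)
}

test_that("the separable three-intensity phantom is segmented near-perfectly", {
  hp <- hard_phantom(noise_sd = 0.002)
  seg <- segment_unified(hp$volume, hp$tpms, bias_correct = FALSE,
                         max_iter = 15, tpm_blend = 0)
  est <- array(max.col(cbind(as.numeric(seg$posteriors$other$data),
                             as.numeric(seg$posteriors$gm$data),
                             as.numeric(seg$posteriors$wm$data),
                             as.numeric(seg$posteriors$csf$data))) - 1L,
               dim(hp$labels$data))
  brain <- hp$labels$data > 0
  expect_gt(mean(est[brain] == hp$labels$data[brain]), 0.999)
  # posteriors sum to one everywhere
  tot <- seg$posteriors$gm$data + seg$posteriors$wm$data +
    seg$posteriors$csf$data + seg$posteriors$other$data
  expect_lt(max(abs(tot - 1)), 1e-6)
  # objective is monotone non-increasing
  tr <- seg$objective_trace
  expect_true(all(diff(tr) <= 1e-8 * abs(tr[-length(tr)])))
})

test_that("single-Gaussian classes recover the generating means", {
  hp <- hard_phantom(noise_sd = 0.01, seed = 33)
  seg <- segment_unified(hp$volume, hp$tpms,
                         gaussians_per_class = 1, bias_correct = FALSE,
                         max_iter = 20, tpm_blend = 0)
  mix <- seg$mixture
  for (cl in c("gm", "wm", "csf")) {
    expect_lt(abs(mix$mean[mix$class == cl] - hp$mu[[cl]]) / hp$mu[[cl]],
              0.02)
  }
})

test_that("bias field and tissue maps are recovered on a noisy biased phantom", {
  co <- bias_scale_cohort(seed = 12)
  s <- co$subjects[[1]]
  seg <- segment_unified(s$volume, co$tpms)
  head <- (s$gm_truth$data + s$wm_truth$data + s$csf_truth$data) > 0.5
  expect_gt(cor(log(seg$bias_field$data[head]),
                log(s$bias_truth$data[head])), 0.95)
  truth_gm <- s$labels$data == 1
  est_gm <- seg$posteriors$gm$data > 0.5
  expect_gte(dice_coef(truth_gm, est_gm), 0.90)
  expect_true(all(seg$bias_field$data > 0))
})

test_that("bias estimate is invariant to global intensity rescaling", {
  co <- bias_scale_cohort(seed = 12)
  s <- co$subjects[[1]]
  seg1 <- segment_unified(s$volume, co$tpms, max_iter = 12)
  v10 <- volume3d(s$volume$data * 10, vox2world = s$volume$vox2world)
  seg10 <- segment_unified(v10, co$tpms, max_iter = 12)
  expect_gt(cor(as.numeric(seg1$bias_field$data),
                as.numeric(seg10$bias_field$data)), 0.99)
})

test_that("total intracranial volume sums tissue posteriors", {
  dm <- c(10, 10, 10)
  mk <- function(x) volume3d(array(x, dm), voxel_size = rep(0.1, 3))
  post <- list(gm = mk(1), wm = mk(0), csf = mk(0), other = mk(0))
  seg <- structure(list(posteriors = post), class = "segmentation_result")
  expect_equal(total_intracranial_volume(seg), 1000 * 0.001)
  post0 <- list(gm = mk(0), wm = mk(0), csf = mk(0), other = mk(1))
  seg0 <- structure(list(posteriors = post0), class = "segmentation_result")
  expect_equal(total_intracranial_volume(seg0), 0)
})

test_that("segmentation TIV tracks the generated intracranial truth", {
  # subjects in register with the maps' space, as the segmentation
  # contract requires (residual post-alignment jitter only)
  sp <- phantom_spec(dim = c(48, 56, 40), seed = 21,
                     jitter_translation_sd = 0.01,
                     jitter_rotation_sd = 0.002,
                     jitter_scale_sd = rep(0.005, 3),
                     jitter_shear_sd = rep(0.005, 3))
  co <- null_cohort(sp, 4)
  errs <- vapply(co$subjects, function(s) {
    seg <- segment_unified(s$volume, co$tpms, max_iter = 20)
    abs(total_intracranial_volume(seg) / s$tiv_truth - 1)
  }, 0)
  expect_lt(mean(errs), 0.03)
})

test_that("invalid segmentation inputs are refused", {
  co <- bias_scale_cohort(seed = 12)
  v <- co$subjects[[1]]$volume
  v$data[1] <- NA
  expect_error(segment_unified(v, co$tpms), "non-finite")
  gm <- co$tpms$gm
  expect_error(tissue_probability_maps(gm, gm, gm), "exceeds")
})
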