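# Shared fixture builders. Everything is generated in code at test time;
# seeds are fixed so failures are reproducible.

tiny_volume <- function(dm = c(12, 10, 8), vs = c(0.1, 0.1, 0.1), seed = 1) {
  set.seed(seed)
  volume3d(array(rnorm(prod(dm)), dm), voxel_size = vs)
}

# Clean progenitor-image phantom (no noise/bias/jitter) for registration
# fixtures.
clean_phantom_image <- function(dm = c(40, 48, 32), seed = 1) {
  sp <- phantom_spec(dim = dm, seed = seed, noise_sd = 0, bias_amplitude = 0,
                     warp_sd_mm = 0, jitter_translation_sd = 0,
                     jitter_rotation_sd = 0, jitter_scale_sd = c(0, 0, 0),
                     jitter_shear_sd = c(0, 0, 0))
  null_cohort(sp, 2)$subjects[[1]]$volume
}

# Coarse-voxel phantom at a field of view where the 12 mm bias cutoff
# retains several basis orders (the scale real mouse coils operate at).
bias_scale_cohort <- function(n = 2, seed = 12) {
  sp <- phantom_spec(dim = c(48, 56, 32), voxel_size = rep(0.4, 3),
                     seed = seed, noise_sd = 0.046, bias_amplitude = 0.1)
  null_cohort(sp, n)
}

random_warp <- function(ref, nb = c(4, 4, 4), rms_mm = 0.05, seed = 1) {
  set.seed(seed)
  cf <- lapply(1:3, function(a) {
    c1 <- array(rnorm(prod(nb)), nb)
    c1[1, 1, 1] <- 0
    c1
  })
  tot2 <- sum(vapply(cf, function(c1) sum(c1^2), 0))
  scl <- rms_mm * sqrt(prod(dim(ref$data)) / tot2)
  warp_field(lapply(cf, function(c1) c1 * scl), ref)
}

dice_coef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))
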