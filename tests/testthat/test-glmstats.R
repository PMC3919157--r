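test_that("design matrices reproduce the study degrees of freedom", {
  # 12 scans, TIV allowed to interact with genotype: 4 columns, 8 error df
  g12 <- rep(c("wt", "r62"), each = 6)
  set.seed(1)
  d12 <- build_design(g12, tiv = rnorm(12, 400, 20), interaction = TRUE)
  expect_equal(ncol(d12$X), 4L)
  expect_equal(d12$error_df, 8L)

  # 42 + 42 validation design: 3 columns, 81 error df, contrast [-1 1 0]
  g84 <- rep(c("a", "b"), each = 42)
  d84 <- build_design(g84, tiv = rnorm(84, 400, 20), interaction = FALSE)
  expect_equal(ncol(d84$X), 3L)
  expect_equal(d84$error_df, 81L)

  # groups only
  d2 <- build_design(rep(c("a", "b"), each = 4))
  expect_equal(ncol(d2$X), 2L)

  expect_error(build_design(g12, tiv = rep(400, 12)), "rank deficient")
  expect_error(build_design(c("a", "a", "b")), "2 scans per group")
})

test_that("GLM t equals the pooled two-sample t and respects row exchange", {
  set.seed(23)
  n1 <- 7; n2 <- 5; V <- 50
  Y <- matrix(rnorm((n1 + n2) * V), n1 + n2, V)
  g <- rep(c("a", "b"), c(n1, n2))
  des <- build_design(g)
  geom <- volume3d(array(0, c(5, 5, 2)), voxel_size = rep(1, 3))
  fit <- fit_glm(Y, des, mask = array(TRUE, c(5, 5, 2)), geometry = geom)
  sm <- contrast_map(fit, c(1, -1), kind = "t", tail = "two")
  # textbook pooled-variance two-sample t per voxel
  for (v in seq_len(V)) {
    a <- Y[1:n1, v]; b <- Y[n1 + 1:n2, v]
    sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
    tt <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
    expect_equal(sm$stat[v], tt, tolerance = 1e-9)
  }
  # permuted rows of images and design together give the identical fit
  perm <- sample(n1 + n2)
  desp <- build_design(g[perm])
  fitp <- fit_glm(Y[perm, ], desp, mask = array(TRUE, c(5, 5, 2)),
                  geometry = geom)
  expect_equal(contrast_map(fitp, c(1, -1), kind = "t", tail = "two")$stat,
               sm$stat, tolerance = 1e-12)
})

test_that("noiseless data are fitted exactly and flagged", {
  set.seed(4)
  X <- build_design(rep(c("a", "b"), each = 4), tiv = rnorm(8))
  beta <- matrix(rnorm(3 * 20), 3, 20)
  Y <- X$X %*% beta
  geom <- volume3d(array(0, c(5, 2, 2)), voxel_size = rep(1, 3))
  expect_message(
    fit <- fit_glm(Y, X, mask = array(TRUE, c(5, 2, 2)), geometry = geom),
    "zero residual variance")
  expect_lt(max(abs(fit$beta - beta)), 1e-9)
  expect_lt(max(fit$sigma2), 1e-16)
})

test_that("F maps square t maps and match the null F moments", {
  set.seed(31)
  n <- 30; V <- 4000
  Y <- matrix(rnorm(n * V), n, V)
  des <- build_design(rep(c("a", "b"), each = n / 2), tiv = rnorm(n))
  geom <- volume3d(array(0, c(20, 20, 10)), voxel_size = rep(1, 3))
  fit <- fit_glm(Y, des, mask = array(TRUE, c(20, 20, 10)), geometry = geom)
  tmap <- contrast_map(fit, c(-1, 1, 0), kind = "t", tail = "two")
  fmap <- contrast_map(fit, c(-1, 1, 0), kind = "F")
  expect_equal(fmap$stat, tmap$stat^2, tolerance = 1e-9)
  expect_true(all(fmap$stat >= 0))
  # E[F] = v/(v-2) under the null
  v <- fit$error_df
  expect_equal(mean(fmap$stat), v / (v - 2), tolerance = 0.1)
  expect_error(contrast_map(fit, c(1, 1)), "length")
})

test_that("uncorrected null p-values are uniform over pooled voxels", {
  set.seed(42)
  n <- 16; V <- 1e5 / 4
  geom <- volume3d(array(0, c(50, 50, 10)), voxel_size = rep(1, 3))
  pv <- unlist(lapply(1:4, function(b) {
    Y <- matrix(rnorm(n * V), n, V)
    des <- build_design(rep(c("a", "b"), each = n / 2))
    fit <- fit_glm(Y, des, mask = array(TRUE, c(50, 50, 10)),
                   geometry = geom)
    contrast_map(fit, c(-1, 1), kind = "t", tail = "two")$p
  }))
  expect_gt(ks.test(pv, "punif")$p.value, 0.01)
})

test_that("BH step-up reproduces the hand calculation and controls FDR", {
  r <- fdr_threshold(c(0.01, 0.02, 0.04, 0.20), q = 0.05)
  expect_equal(r$p_threshold, 0.02)
  expect_equal(r$n_suprathreshold, 2L)
  expect_equal(fdr_threshold(rep(1, 10), q = 0.05)$n_suprathreshold, 0L)

  # empirical FDP under null + signal mixture
  set.seed(77)
  q <- 0.1
  fdp <- replicate(500, {
    p0 <- runif(400)                  # true nulls
    p1 <- pbeta(runif(100), 1, 30)    # signals
    r <- fdr_threshold(c(p0, p1), q = q)
    if (r$n_suprathreshold == 0) 0
    else sum(r$survivors[1:400]) / r$n_suprathreshold
  })
  mc_sd <- sd(fdp) / sqrt(length(fdp))
  expect_lte(mean(fdp), q + 2 * mc_sd)
})

test_that("under a complete null, analyses with any FDR survivor are rare", {
  set.seed(13)
  q <- 0.05
  any_surv <- replicate(400, {
    fdr_threshold(runif(500), q = q)$n_suprathreshold > 0
  })
  mc_sd <- sqrt(q * (1 - q) / length(any_surv))
  expect_lte(mean(any_surv), q + 3 * mc_sd)
})

test_that("residual smoothness estimation recovers the generating FWHM", {
  set.seed(2)
  dm <- c(36, 36, 36); n <- 16
  des <- build_design(rep(c("a", "b"), each = n / 2))
  imgs <- lapply(1:n, function(i)
    smooth_volume(volume3d(array(rnorm(prod(dm)), dm),
                           voxel_size = rep(0.1, 3)), 400))
  fit <- fit_glm(imgs, des, mask = array(TRUE, dm))
  sm <- estimate_smoothness(fit)
  expect_true(all(abs(sm$fwhm_mm - 0.4) / 0.4 < 0.1))

  # unsmoothed white noise: the discrete estimator's analytic value is
  # sqrt(4 log 2 / 2) = 1.18 voxels, within 20% of the voxel size
  imgs2 <- lapply(1:n, function(i)
    volume3d(array(rnorm(prod(dm)), dm), voxel_size = rep(0.1, 3)))
  fit2 <- fit_glm(imgs2, des, mask = array(TRUE, dm))
  sm2 <- estimate_smoothness(fit2)
  expect_true(all(abs(sm2$fwhm_vox - 1) < 0.2 * 1 + 0.2))
  expect_true(all(abs(sm2$fwhm_vox - sqrt(4 * log(2) / 2)) < 0.05))
})

test_that("resel counts scale with mask volume at fixed smoothness", {
  m1 <- array(FALSE, c(30, 30, 30)); m1[1:10, , ] <- TRUE
  m2 <- array(FALSE, c(30, 30, 30)); m2[1:20, , ] <- TRUE
  r1 <- resel_counts(m1, rep(2, 3))
  r2 <- resel_counts(m2, rep(2, 3))
  expect_equal(r2[4] / r1[4], (19 * 29 * 29) / (9 * 29 * 29),
               tolerance = 1e-9)
})

test_that("RFT threshold behaviour: limits, t/F consistency, calibration", {
  stat_t <- list(kind = "t", df = c(1, 20))
  mk_sm <- function(resels) structure(list(resels = resels),
                                      class = "smoothness_estimate")
  # threshold approaches the uncorrected quantile as resels -> 0 (monotone)
  u_small <- fwe_threshold(stat_t, mk_sm(c(1, 0.01, 0.01, 0.01)),
                           alpha = 0.05)
  u_big <- fwe_threshold(stat_t, mk_sm(c(1, 5, 50, 300)), alpha = 0.05)
  expect_gt(u_big, u_small)
  expect_gte(u_small, qt(0.95, 20))
  expect_lt(u_small, qt(0.95, 20) + 0.6)

  # 1-df F field threshold is the square of the two-tailed t threshold
  stat_f <- list(kind = "F", df = c(1, 20))
  uf <- fwe_threshold(stat_f, mk_sm(c(1, 5, 20, 60)), alpha = 0.05)
  # EC densities of F(1, v) at u relate to the t field at sqrt(u) (both tails)
  ec_f <- expected_ec_sum <- mousevbm::ec_density(uf, c(1, 20), "F")
  ec_t <- mousevbm::ec_density(sqrt(uf), c(1, 20), "t")
  expect_equal(ec_f[2:4], 2 * ec_t[2:4], tolerance = 1e-6)

  # permutation threshold is the exact empirical quantile
  set.seed(6)
  nm <- rnorm(200)
  thr <- fwe_threshold(stat_t, alpha = 0.05, method = "permutation",
                       null_maxima = nm)
  expect_equal(sum(nm > thr), floor(0.05 * 200))
  expect_error(fwe_threshold(stat_t, mk_sm(c(1, 1, 1, 1)), alpha = 1.2),
               "alpha")
})

test_that("RFT familywise error is controlled on simulated smooth t-fields", {
  set.seed(99)
  dm <- c(24, 24, 24); n <- 22  # 20 error df in a two-group design
  des <- build_design(rep(c("a", "b"), each = n / 2))
  mask <- array(TRUE, dm)
  nrep <- 60
  hits <- logical(nrep)
  for (r in seq_len(nrep)) {
    imgs <- matrix(0, n, prod(dm))
    for (i in 1:n)
      imgs[i, ] <- as.numeric(smooth_volume(
        volume3d(array(rnorm(prod(dm)), dm), voxel_size = rep(0.1, 3)),
        300)$data)
    geom <- volume3d(array(0, dm), voxel_size = rep(0.1, 3))
    fit <- fit_glm(imgs, des, mask = mask, geometry = geom)
    sm <- contrast_map(fit, c(-1, 1), kind = "t", tail = "two")
    smo <- estimate_smoothness(fit)
    thr <- fwe_threshold(sm, smo, alpha = 0.05)
    hits[r] <- max(abs(sm$stat)) > thr  # two-tailed field: test |t|
  }
  # achieved rate at nominal 0.05 stays below 0.07 plus Monte-Carlo slack
  expect_lte(mean(hits), 0.07 + 2 * sqrt(0.05 * 0.95 / nrep))
})

test_that("cluster tables follow connectivity semantics and report bregma mm", {
  dm <- c(20, 20, 10)
  vals <- array(NA_real_, dm)
  mask <- array(TRUE, dm)
  vals[mask] <- 0
  vals[3:5, 3:5, 3] <- 5        # 9-voxel slab
  vals[10, 10, 5] <- 7          # singleton
  geom <- volume3d(array(0, dm), voxel_size = rep(0.1, 3))
  stat <- structure(list(values = vals, kind = "t", df = c(1, 8),
                         mask = mask, geometry = geom), class = "stat_map")
  tab <- cluster_table(stat, 1)
  expect_equal(nrow(tab), 2L)
  expect_equal(sort(tab$extent_vox), c(1L, 9L))
  expect_equal(tab$peak_stat[tab$extent_vox == 1], 7)
  # peak coordinates are the voxel's world position
  expect_equal(tab$x_mm[tab$extent_vox == 1],
               unname(voxel_to_world(geom, c(9, 9, 4))[1]))

  # corner-touching blobs: one cluster under 26, two under 6
  vals2 <- array(0, dm)
  vals2[5, 5, 5] <- 3
  vals2[6, 6, 6] <- 3
  stat2 <- structure(list(values = vals2, kind = "t", df = c(1, 8),
                          mask = mask, geometry = geom), class = "stat_map")
  expect_equal(nrow(cluster_table(stat2, 1, connectivity = 26)), 1L)
  expect_equal(nrow(cluster_table(stat2, 1, connectivity = 6)), 2L)
  # empty table allowed
  expect_equal(nrow(cluster_table(stat2, 10)), 0L)
})
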