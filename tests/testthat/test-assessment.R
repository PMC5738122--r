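mk_rep <- function(spec, seed) {
  spec$seed <- seed
  sim <- simulate_protocol(spec)
  list(single = sim$single, dual = sim$dual, sim = sim)
}

test_that("ensemble: 8 realizations, duplicate repetitions give sigma = 0", {
  spec <- small_phantom(10)
  rep_a <- mk_rep(spec, 1L)
  ens <- build_ensemble(rep_a, rep_a)
  expect_s3_class(ens, "protocol_ensemble")
  expect_length(ens$bundles, 8L)
  expect_identical(dim(ens$combos), c(8L, 3L))
  expect_identical(unique(rowSums(ens$combos)), c(0, 1, 2, 3)[
    order(unique(rowSums(ens$combos)))])

  rep <- repro_stats(ens, rep_a$sim$support)
  expect_true(all(rep$summary$normalized_median_sigma == 0))
  expect_true(all(rep$maps$r1$sigma[rep_a$sim$support] == 0))
})

test_that("geometry mismatch is rejected", {
  rep_a <- mk_rep(small_phantom(10), 1L)
  rep_b <- mk_rep(small_phantom(12), 2L)
  expect_error(build_ensemble(rep_a, rep_b), "geometry")
})

test_that("two-realization closed form: sd of {a, a+2} is sqrt(2)", {
  spec <- small_phantom(8)
  sim <- simulate_protocol(spec)
  b1 <- fit_resume(sim$single, sim$dual)
  b2 <- b1
  for (mp in c("r1", "r2star", "pd")) b2[[mp]] <- b1[[mp]] + 2
  rep <- repro_stats(list(b1, b2), sim$support)
  sup <- sim$support
  expect_equal(rep$maps$r1$sigma[sup],
               rep(sqrt(2), sum(sup)), tolerance = 1e-12)
  # normalized median: sqrt(2) / range * 100; affine invariance
  rg <- diff(quantile(rep$maps$r1$mu[sup], c(0.001, 0.999), names = FALSE))
  expect_equal(rep$summary$normalized_median_sigma[1], 100 * sqrt(2) / rg,
               tolerance = 1e-9)
})

test_that("iid ensemble: median sigma matches the chi distribution", {
  set.seed(30)
  dm <- c(16, 16, 16)
  base <- array(runif(prod(dm), 1, 2), dm)
  sigma0 <- 0.1
  mkb <- function() {
    m <- base + array(rnorm(prod(dm), 0, sigma0), dm)
    qmap_bundle(m, m, m, array(0L, dm))
  }
  ens <- replicate(8, mkb(), simplify = FALSE)
  rep <- repro_stats(ens, array(TRUE, dm))
  # median of the n = 8 sample sd: sigma0 * sqrt(qchisq(.5, 7)/7)
  expected <- sigma0 * sqrt(qchisq(0.5, 7) / 7)
  expect_lt(abs(rep$summary$median_sigma[1] / expected - 1), 0.1)
  # permutation invariance
  rep2 <- repro_stats(ens[sample(8)], array(TRUE, dm))
  expect_equal(rep2$summary, rep$summary)
})

test_that("noisy-phantom ensemble sigma agrees with the noise model", {
  # 2^3 Cartesian ensemble from 2 repetitions: the voxelwise sample
  # variance estimates 4/7 of the true single-shot variance (three
  # independent inputs, two draws each). Compare rms sigma_j in white
  # matter against that deflation of the delta-method prediction.
  r1 <- 1.08; r2s <- 21.1; pdv <- 0.718
  sigma <- wm_sigma_snr100()
  spec <- small_phantom(16, noise_sigma = sigma)
  rep_a <- mk_rep(spec, 101L)
  rep_b <- mk_rep(spec, 202L)
  ens <- build_ensemble(rep_a, rep_b)
  rep <- repro_stats(ens, rep_a$sim$labels == 1L)
  wm <- rep_a$sim$labels == 1L
  rms_sigma <- sqrt(mean(rep$maps$r1$sigma[wm]^2, na.rm = TRUE))
  pred <- predict_r1_sd(r1, r2s, pdv, sigma) * sqrt(4 / 7)
  expect_lt(abs(rms_sigma / pred - 1), 0.30)
})

test_that("accuracy maps: exact zero, constant offset, triangle inequality", {
  spec <- small_phantom(10)
  sim <- simulate_protocol(spec)
  b <- fit_resume(sim$single, sim$dual)
  sup <- sim$support

  acc0 <- accuracy_map(b, b, sup)
  expect_true(all(acc0$summary$normalized_median_delta == 0))

  b_off <- b
  for (mp in c("r1", "r2star", "pd")) b_off[[mp]] <- b[[mp]] + 0.05
  acc <- accuracy_map(b_off, b, sup)
  rg <- diff(quantile(b$r1[sup], c(0.001, 0.999), names = FALSE,
                      na.rm = TRUE))
  expect_equal(acc$summary$normalized_median_delta[1], 100 * 0.05 / rg,
               tolerance = 1e-9)

  # voxelwise triangle inequality across three bundles
  set.seed(31)
  b2 <- b; b3 <- b
  dmv <- dim(b$r1)
  b2$r1 <- b$r1 + array(rnorm(prod(dmv), 0, 0.02), dmv)
  b3$r1 <- b$r1 + array(rnorm(prod(dmv), 0, 0.02), dmv)
  d12 <- accuracy_map(b2, b, sup, maps = "r1")$delta$r1
  d13 <- accuracy_map(b3, b, sup, maps = "r1")$delta$r1
  d23 <- accuracy_map(b2, b3, sup, maps = "r1")$delta$r1
  ok <- is.finite(d12) & is.finite(d13) & is.finite(d23)
  expect_true(all(d23[ok] <= d12[ok] + d13[ok] + 1e-12))

  # affine rescaling of map and reference together leaves the summary
  b4 <- b; ref4 <- b
  b4$r1 <- 3 * b2$r1 + 1
  ref4$r1 <- 3 * b$r1 + 1
  a1 <- accuracy_map(b2, b, sup, maps = "r1")$summary
  a2 <- accuracy_map(b4, ref4, sup, maps = "r1")$summary
  expect_equal(a1$normalized_median_delta, a2$normalized_median_delta,
               tolerance = 1e-9)
})

test_that("end-to-end accuracy at SNR 100 with denoising: delta(R1) < 3%", {
  # layered phantom (flat regions larger than the patch, as in real
  # tissue) at SNR 100 on the strongest acquired image; the pipeline
  # denoises before mapping
  spec <- slab_phantom(24, noise_sigma = wm_sigma_snr100(), seed = 57L)
  sim <- simulate_protocol(spec)
  b <- fit_resume(sim$single, sim$dual, denoise = TRUE,
                  noise = spec$noise_sigma,
                  mnlm = mnlm_params(rho = 1.5, max_radius = 6))
  truth <- qmap_bundle(sim$truth$r1, sim$truth$r2star, sim$truth$pd,
                       array(0L, dim(sim$truth$r1)))
  acc <- accuracy_map(b, truth, sim$support)
  expect_lt(acc$summary$normalized_median_delta[1], 3)
  # denoising must beat the raw reconstruction
  braw <- fit_resume(sim$single, sim$dual)
  accr <- accuracy_map(braw, truth, sim$support, maps = "r1")
  expect_lt(acc$summary$normalized_median_delta[1],
            accr$summary$normalized_median_delta[1])
})

test_that("ROI statistics and CSF normalization", {
  spec <- small_phantom(16)
  sim <- simulate_protocol(spec)
  b <- fit_resume(sim$single, sim$dual)
  rois <- sim$labels

  tab <- roi_stats(b$r1, rois)
  expect_identical(tab$label, c(1L, 2L, 3L))
  # white matter label 1: R1 = 1.08 recovered exactly (noiseless)
  expect_equal(tab$mean[tab$label == 1L], 1.08, tolerance = 1e-9)
  expect_equal(tab$sd[tab$label == 1L], 0, tolerance = 1e-9)

  # single-voxel ROI: mean = value, sd = 0
  one <- array(0L, dim(rois)); one[8, 8, 8] <- 7L
  t1v <- roi_stats(b$r1, one)
  expect_equal(t1v$mean, b$r1[8, 8, 8])
  expect_identical(t1v$sd, 0)
  expect_identical(t1v$n, 1L)

  # PD normalized to the CSF region (label 3) maps CSF to exactly 1
  tpd <- roi_stats(b$pd, rois, normalize_to = 3L)
  expect_equal(tpd$mean[tpd$label == 3L], 1, tolerance = 1e-12)
  expect_equal(tpd$mean[tpd$label == 1L], 0.718, tolerance = 1e-6)
})
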