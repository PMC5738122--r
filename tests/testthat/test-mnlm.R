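test_that("channel quality: constants, homogeneity, brute-force sum", {
  dm <- c(6, 6, 6)
  # X = const, sigma = const -> Q = X^2 / sigma^2
  img <- multichannel_image(array(4, dm))
  expect_equal(channel_quality(img, 2), 4, tolerance = 1e-12)

  # doubling a channel quadruples its quality factor
  set.seed(5)
  a <- array(rnorm(prod(dm), 10), dm)
  q1 <- channel_quality(multichannel_image(a), 1.5)
  q2 <- channel_quality(multichannel_image(2 * a), 1.5)
  expect_equal(q2 / q1, 4, tolerance = 1e-12)

  # random image and spatially varying sigma vs a direct sum
  sg <- array(runif(prod(dm), 0.5, 2), dm)
  mask <- array(runif(prod(dm)) > 0.3, dm)
  img <- multichannel_image(a, mask = mask)
  q <- channel_quality(img, list(sg))
  expect_equal(q, sum(a[mask]^2) / sum(sg[mask]^2), tolerance = 1e-14)
  img$mask[] <- FALSE
  expect_error(channel_quality(img, 1), "empty")
})

test_that("patch distance: zero at self, symmetric, delta-window limit", {
  dm <- c(9, 9, 9)
  set.seed(6)
  ch <- list(array(rnorm(prod(dm), 5), dm), array(rnorm(prod(dm), 2), dm))
  img <- multichannel_image(ch)
  sg <- list(array(runif(prod(dm), 0.5, 1.5), dm),
             array(runif(prod(dm), 0.5, 1.5), dm))
  x <- c(4, 5, 6); y <- c(7, 3, 5)
  expect_equal(patch_distance(img, sg, x, x, rho = 1.5), 0)
  expect_equal(patch_distance(img, sg, x, y, rho = 1.5),
               patch_distance(img, sg, y, x, rho = 1.5),
               tolerance = 1e-12)

  # rho below the voxel size degenerates to the single-voxel distance
  d <- patch_distance(img, sg, x, y, rho = 0.2)
  ref <- sum(vapply(1:2, function(m) {
    (ch[[m]][x[1], x[2], x[3]] - ch[[m]][y[1], y[2], y[3]])^2 /
      (sg[[m]][x[1], x[2], x[3]]^2 + sg[[m]][y[1], y[2], y[3]]^2)
  }, numeric(1)))
  expect_equal(d, ref, tolerance = 1e-12)
})

test_that("patch distance matches a direct triple-loop sum", {
  dm <- c(9, 9, 9)
  set.seed(7)
  a <- array(rnorm(prod(dm), 3), dm)
  img <- multichannel_image(a, voxel_size = c(1, 1, 2))
  sig <- 0.8
  rho <- 1.6
  x <- c(5, 5, 5); y <- c(4, 6, 4)
  # direct sum with per-axis normalized Gaussian weights (interior points,
  # no padding involved)
  ext <- floor(2 * rho / c(1, 1, 2))
  w1 <- lapply(1:3, function(d) {
    t <- (-ext[d]:ext[d]) * c(1, 1, 2)[d]
    w <- exp(-t^2 / (2 * rho^2)); w / sum(w)
  })
  ref <- 0
  for (i in -ext[1]:ext[1]) for (j in -ext[2]:ext[2])
    for (k in -ext[3]:ext[3]) {
      w <- w1[[1]][i + ext[1] + 1] * w1[[2]][j + ext[2] + 1] *
        w1[[3]][k + ext[3] + 1]
      ref <- ref + w * (a[x[1] + i, x[2] + j, x[3] + k] -
                          a[y[1] + i, y[2] + j, y[3] + k])^2
    }
  ref <- ref / (2 * sig^2)
  expect_equal(patch_distance(img, sig, x, y, rho = rho), ref,
               tolerance = 1e-12)
})

test_that("search radius: uniform weights give the analytic ball", {
  dm <- c(17, 17, 17)
  w <- array(1, dm)
  ctr <- c(9, 9, 9)
  for (kappa in c(30, 60)) {
    r <- search_radius(w, ctr, kappa, max_radius = 8)
    expect_true(r$reached)
    # n voxels * unit volume >= kappa, and the radius is the continuum
    # value up to discretization
    expect_gte(r$n, kappa)
    expect_equal(r$radius, (3 * kappa / (4 * pi))^(1 / 3), tolerance = 0.35)
  }
  # doubling kappa scales the radius by ~2^(1/3)
  r1 <- search_radius(w, ctr, 40, max_radius = 8)
  r2 <- search_radius(w, ctr, 80, max_radius = 8)
  expect_equal(r2$radius / r1$radius, 2^(1 / 3), tolerance = 0.2)
})

test_that("search radius equals incremental brute-force growth", {
  dm <- c(11, 11, 11)
  set.seed(8)
  w <- array(rexp(prod(dm), rate = 2), dm)   # adversarial weight field
  ctr <- c(6, 6, 6)
  kappa <- 15
  got <- search_radius(w, ctr, kappa, max_radius = 5)
  # brute force: sort all offsets by distance, walk shells
  off <- as.matrix(expand.grid(-5:5, -5:5, -5:5))
  d <- sqrt(rowSums(off^2))
  keep <- d <= 5 + 1e-9
  off <- off[keep, ]; d <- d[keep]
  o <- order(d); off <- off[o, ]; d <- d[o]
  acc <- 0; r_ref <- NA
  for (dist in unique(d)) {
    rows <- which(abs(d - dist) < 1e-9)
    for (i in rows)
      acc <- acc + w[ctr[1] + off[i, 1], ctr[2] + off[i, 2],
                     ctr[3] + off[i, 3]]
    if (acc >= kappa) { r_ref <- dist; break }
  }
  expect_equal(got$radius, r_ref)
  expect_true(got$reached)
  # unreachable budget hits the cap and says so
  cap <- search_radius(array(1e-9, dm), ctr, kappa, max_radius = 3)
  expect_false(cap$reached)
})

test_that("compiled denoiser agrees with the R reference loop on 8^3", {
  dm <- c(8, 8, 8)
  set.seed(9)
  base <- array(5, dm); base[5:8, , ] <- 9
  ch <- list(base + array(rnorm(prod(dm), 0, 0.5), dm),
             2 * base + array(rnorm(prod(dm), 0, 0.8), dm))
  img <- multichannel_image(ch, voxel_size = c(1, 1, 1.3))
  par <- toy_mnlm_params()
  fast <- mnlm_denoise(img, noise = list(0.5, 0.8), params = par,
                       method = "fast")
  ref <- mnlm_denoise(img, noise = list(0.5, 0.8), params = par,
                      method = "reference")
  for (m in 1:2)
    expect_lt(max(abs(fast$channels[[m]] - ref$channels[[m]]) /
                    pmax(abs(ref$channels[[m]]), 1e-12)), 1e-10)
  expect_equal(attr(fast, "radius"), attr(ref, "radius"))
  expect_identical(attr(fast, "capped") == TRUE,
                   attr(ref, "capped") == TRUE)
})

test_that("constant image is an exact fixed point", {
  dm <- c(10, 10, 10)
  img <- multichannel_image(array(3.25, dm))
  out <- mnlm_denoise(img, noise = 1, params = toy_mnlm_params())
  expect_equal(out$channels[[1]], array(3.25, dm), tolerance = 1e-14)
})

test_that("output is a convex combination over each search ball", {
  dm <- c(10, 10, 10)
  set.seed(10)
  ch <- list(array(rnorm(prod(dm), 10, 3), dm),
             array(rnorm(prod(dm), -4, 2), dm))
  img <- multichannel_image(ch)
  out <- mnlm_denoise(img, noise = 1, params = toy_mnlm_params())
  for (m in 1:2) {
    # global bound is implied by the per-ball bound
    expect_gte(min(out$channels[[m]]), min(ch[[m]]))
    expect_lte(max(out$channels[[m]]), max(ch[[m]]))
  }
})

test_that("filter-strength limits: huge = ball mean, tiny = identity", {
  dm <- c(8, 8, 8)
  set.seed(11)
  a <- array(rnorm(prod(dm), 5, 1), dm)
  img <- multichannel_image(a)

  tiny <- mnlm_denoise(img, noise = 1,
                       params = mnlm_params(kappa = 8, rho = 0.8,
                                            sigma_filter = 1e-3,
                                            max_radius = 2.1))
  expect_equal(tiny$channels[[1]], a, tolerance = 1e-6)

  big <- mnlm_denoise(img, noise = 1,
                      params = mnlm_params(kappa = 8, rho = 0.8,
                                           sigma_filter = 1e3,
                                           max_radius = 2.1))
  # with all weights ~1 the ball is the smallest shell set with >= 8
  # voxels: compare against the (effectively) unweighted ball mean
  ref <- mnlm_denoise(img, noise = 1,
                      params = mnlm_params(kappa = 8, rho = 0.8,
                                           sigma_filter = 1e9,
                                           max_radius = 2.1))
  expect_equal(big$channels[[1]], ref$channels[[1]], tolerance = 1e-4)
})

test_that("channel permutation symmetry", {
  dm <- c(8, 8, 8)
  set.seed(12)
  ch <- list(array(rnorm(prod(dm), 5), dm), array(rnorm(prod(dm), 9), dm))
  par <- toy_mnlm_params()
  out12 <- mnlm_denoise(multichannel_image(ch), noise = list(1, 2),
                        params = par)
  out21 <- mnlm_denoise(multichannel_image(ch[2:1]), noise = list(2, 1),
                        params = par)
  expect_equal(out12$channels[[1]], out21$channels[[2]], tolerance = 1e-13)
  expect_equal(out12$channels[[2]], out21$channels[[1]], tolerance = 1e-13)
})

test_that("a pure-noise channel barely disturbs the others", {
  dm <- c(10, 10, 10)
  set.seed(13)
  base <- array(8, dm); base[, 6:10, ] <- 14
  good <- base + array(rnorm(prod(dm), 0, 0.4), dm)
  junk <- array(rnorm(prod(dm), 0, 1), dm)  # zero-mean: tiny Q
  par <- toy_mnlm_params()
  alone <- mnlm_denoise(multichannel_image(list(good)),
                        noise = list(0.4), params = par)
  with_junk <- mnlm_denoise(multichannel_image(list(good, junk)),
                            noise = list(0.4, 1), params = par)
  relchange <- abs(with_junk$channels[[1]] - alone$channels[[1]]) /
    pmax(abs(alone$channels[[1]]), 1e-12)
  expect_lt(mean(relchange), 0.01)
  expect_lt(quantile(relchange, 0.99), 0.05)
})

test_that("two-region noisy phantom: 3x noise reduction, small bias", {
  dm <- c(16, 16, 16)
  truth <- array(10, dm); truth[9:16, , ] <- 20
  sigma <- 1
  set.seed(14)
  noisy <- truth + array(rnorm(prod(dm), 0, sigma), dm)
  out <- mnlm_denoise(multichannel_image(noisy), noise = sigma,
                      params = mnlm_params(kappa = 60, rho = 2,
                                           max_radius = 5))
  res <- out$channels[[1]] - truth
  left <- array(FALSE, dm); left[1:8, , ] <- TRUE
  right <- !left
  for (reg in list(left, right)) {
    expect_gte(sigma / sd(res[reg]), 3)
    expect_lt(abs(mean(res[reg])), 0.5 * sigma)
  }
})

test_that("non-finite voxels are excluded and flagged", {
  dm <- c(8, 8, 8)
  set.seed(15)
  a <- array(rnorm(prod(dm), 5, 0.5), dm)
  a[4, 4, 4] <- NA
  out <- mnlm_denoise(multichannel_image(a), noise = 0.5,
                      params = toy_mnlm_params())
  # neighbors of the broken voxel stay finite
  expect_true(is.finite(out$channels[[1]][5, 4, 4]))
  expect_true(is.finite(out$channels[[1]][3, 4, 4]))
})

test_that("local noise estimator recovers a flat sigma within 25%", {
  dm <- c(20, 20, 20)
  set.seed(16)
  a <- array(100 + rnorm(prod(dm), 0, 2), dm)
  nm <- estimate_noise_map(multichannel_image(a))
  expect_lt(abs(median(nm[[1]]) / 2 - 1), 0.25)
})
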