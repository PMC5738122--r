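th <- function(deg) deg * pi / 180

# forward model for the TE=0 ratio (independent of the solver path)
q_fwd <- function(e, t1, t2) {
  k <- sin(t1) / sin(t2)
  k * (1 - e^2 * cos(t2)) * (1 - e) / ((1 - e^2) * (1 - e * cos(t1)))
}

test_that("plus-branch root inverts the forward ratio at the protocol", {
  q <- q_fwd(0.9, th(2), th(20))
  sol <- solve_e10(array(q, c(1, 1, 1)), th(2), th(20))
  expect_equal(sol$e10[1], 0.9, tolerance = 1e-12)
  expect_identical(sol$branch[1], 1L)
  expect_true(sol$valid[1])
})

test_that("branch selection recovers the generating root over a sweep", {
  # E in 0.4..0.99, theta2 in 5..60 deg, theta1 = 0.4 theta2: the selected
  # branch must always return the generating value, never the spurious root
  es <- seq(0.4, 0.99, by = 0.01)
  t2s <- th(seq(5, 60, by = 5))
  for (t2 in t2s) {
    t1 <- 0.4 * t2
    q <- vapply(es, q_fwd, numeric(1), t1 = t1, t2 = t2)
    sol <- solve_e10(q, t1, t2)
    expect_true(all(sol$valid))
    expect_lt(max(abs(sol$e10 - es)), 1e-10)
  }
})

test_that("fully-relaxed boundary q = k is masked invalid", {
  t1 <- th(2); t2 <- th(20)
  k <- sin(t1) / sin(t2)
  sol <- solve_e10(array(k, c(1, 1, 1)), t1, t2)
  expect_false(sol$valid[1])
  expect_identical(sol$code[1], 4L)
})

test_that("degenerate quadratic falls back to the linear root", {
  # C = q cos(t1) - k cos(t2) vanishes at q = k cos(t2)/cos(t1); a root
  # in (0, 1) then requires theta1/theta2 near 1 (ambiguous regime, so
  # the 0.47 warning is expected)
  t1 <- th(60); t2 <- th(70)
  k <- sin(t1) / sin(t2)
  q <- k * cos(t2) / cos(t1)
  sol <- suppressWarnings(solve_e10(array(q, c(1, 1, 1)), t1, t2))
  # linear root E = (k - q)/R must satisfy the original relation
  e <- sol$e10[1]
  expect_identical(sol$branch[1], 3L)
  expect_equal(e, (k - q) / (q * (1 - cos(t1))), tolerance = 1e-12)
  expect_lt(abs(q - q_fwd(e, t1, t2)), 1e-12)
})

test_that("ambiguity warning fires and scale invariance holds", {
  q <- q_fwd(0.9, th(15), th(20))
  expect_warning(solve_e10(array(q, c(1, 1, 1)), th(15), th(20)),
                 "0.47")
  # scaling S1 and S2 together leaves q, hence E and R1, unchanged
  set.seed(4)
  e <- runif(20, 0.5, 0.99)
  q <- vapply(e, q_fwd, numeric(1), t1 = th(2), t2 = th(20))
  s_a <- solve_e10(q, th(2), th(20))
  s_b <- solve_e10(q * 1.0, th(2), th(20))  # q is already a pure ratio
  expect_identical(s_a$e10, s_b$e10)
})

test_that("recovery factor converts to R1 and supports the closed forms", {
  dm <- c(2, 1, 1)
  sol <- structure(list(
    e10 = array(c(exp(-1), exp(-0.014)), dm),
    branch = array(1L, dm), valid = array(TRUE, dm),
    code = array(0L, dm)), class = "r1_solution")
  out <- r1_map(sol, 0.014)
  expect_equal(out$r1[1, 1, 1], 1 / 0.014, tolerance = 1e-12)
  expect_equal(out$r1[2, 1, 1], 1, tolerance = 1e-12)

  sol$e10[1, 1, 1] <- 1.2  # out of range -> invalid
  out <- r1_map(sol, 0.014)
  expect_false(out$valid[1, 1, 1])
  expect_true(is.na(out$r1[1, 1, 1]))
})

test_that("PD inversion matches its closed forms", {
  dm <- c(1, 1, 1)
  sol <- structure(list(e10 = array(0, dm), branch = array(1L, dm),
                        valid = array(TRUE, dm), code = array(0L, dm)),
                   class = "r1_solution")
  # E = 0: PD = S2 / sin(theta2)
  out <- pd_map(array(2, dm), sol, th(20))
  expect_equal(out$pd[1], 2 / sin(th(20)), tolerance = 1e-12)

  # forward-generated S2 at pd = 1, E = 0.9 returns exactly 1
  e <- 0.9
  s2 <- sin(th(20)) * (1 - e^2) / (1 - e^2 * cos(th(20)))
  sol$e10[1] <- e
  out <- pd_map(array(s2, dm), sol, th(20))
  expect_equal(out$pd[1], 1, tolerance = 1e-12)

  # degenerate denominator at E -> 1
  sol$e10[1] <- 1
  out <- pd_map(array(s2, dm), sol, th(20))
  expect_false(out$valid[1])
})

test_that("noiseless phantom round-trip is exact to 1e-9", {
  spec <- small_phantom(16)
  sim <- simulate_protocol(spec)
  b <- fit_resume(sim$single, sim$dual)
  sup <- sim$support
  expect_true(all(b$mask[sup] == 0L))
  expect_lt(max_rel_err(b$r1, sim$truth$r1, sup), 1e-9)
  expect_lt(max_rel_err(b$r2star, sim$truth$r2star, sup), 1e-9)
  expect_lt(max_rel_err(b$pd, sim$truth$pd, sup), 1e-9)
  # white-matter value from the brain-like phantom is recovered
  wm <- sim$labels == 1L
  expect_lt(max_rel_err(b$r1, array(1.08, dim(b$r1)), wm), 1e-9)
})

test_that("general-TR mode solves non-doubled repetition times", {
  # dual TR = 1.6 x single TR: quadratic no longer applies
  sq1 <- sequence_params(14, 7.63, 2, 190, units = "ms",
                         angle_units = "deg")
  sq2 <- sequence_params(22.4, c(7.63, 18), 20, 190, units = "ms",
                         angle_units = "deg")
  spec <- small_phantom(10)
  sim <- suppressWarnings(simulate_protocol(spec, sq1, sq2))
  b <- fit_resume(sim$single, sim$dual, general_tr = TRUE)
  expect_lt(max_rel_err(b$r1, sim$truth$r1, sim$support), 1e-7)
  expect_warning(fit_resume(sim$single, sim$dual), "doubling")
})

test_that("branch boundary locus stays above the 0.47 ratio", {
  t2 <- seq(1e-3, pi - 1e-3, length.out = 5000)
  r <- branch_boundary_ratio(t2, e10 = exp(-1))
  expect_true(all(r > 0.47))
  expect_lt(min(r), 0.48)  # the bound is tight near theta2 -> pi
})

test_that("B1 correction: exact with the true map, biased without", {
  b1c <- list(x = 0.05, xx = -0.10, yy = -0.06)  # smooth ~10% dip
  spec <- small_phantom(16, b1_coef = b1c)
  sim <- simulate_protocol(spec)
  sup <- sim$support

  with_map <- fit_resume(sim$single, sim$dual, b1 = sim$b1)
  expect_lt(max_rel_err(with_map$r1, sim$truth$r1, sup), 1e-9)

  without <- fit_resume(sim$single, sim$dual)
  rel_bias <- abs(without$r1 - sim$truth$r1) / sim$truth$r1
  expect_gt(max(rel_bias[sup], na.rm = TRUE), 0.01)

  # identity correction leaves everything untouched
  flat <- array(1, dim(sim$b1))
  same <- fit_resume(sim$single, sim$dual, b1 = flat)
  base <- fit_resume(sim$single, sim$dual)
  expect_equal(same$r1, base$r1, tolerance = 1e-12)
  sq <- sim$single$params
  expect_message(apply_b1_correction(sq, NULL), "nominal")
  expect_identical(apply_b1_correction(sq, NULL), sq$flip_angle)
  expect_equal(apply_b1_correction(sq, flat), array(sq$flip_angle,
                                                    dim(flat)))
})
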