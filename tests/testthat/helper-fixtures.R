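# Shared fixtures: tiny phantoms and tolerance helpers. Everything is
# generated in code; no binary fixtures.

max_rel_err <- function(est, truth, mask = NULL) {
  if (!is.null(mask)) { est <- est[mask]; truth <- truth[mask] }
  max(abs(est - truth) / pmax(abs(truth), .Machine$double.xmin),
      na.rm = TRUE)
}

# small three-region phantom (defaults mirror the full-size one)
small_phantom <- function(n = 16, noise_sigma = 0, seed = 1L, ...) {
  default_phantom_spec(n, noise_sigma = noise_sigma, seed = seed, ...)
}

# uniform one-region phantom: handy for noise statistics
uniform_phantom <- function(n = 16, t1 = 1 / 1.08, t2star = 1 / 21.1,
                            pd = 0.718, noise_sigma = 0, seed = 1L) {
  phantom_spec(rep(n, 3L), regions = list(
    list(shape = "box", center = rep((n + 1) / 2, 3),
         radius = rep(n / 2, 3), t1 = t1, t2star = t2star, pd = pd)),
    noise_sigma = noise_sigma, seed = seed)
}

# MNLM parameters small enough for the pure-R reference loop
toy_mnlm_params <- function() {
  mnlm_params(kappa = 8, rho = 0.8, sigma_filter = 1, max_radius = 2.1)
}

# layered phantom: three full-width slabs (WM / GM / CSF values) whose
# flat interiors exceed the denoiser patch, as in real tissue
slab_phantom <- function(n = 24, noise_sigma = 0, seed = 1L) {
  zs <- round(seq(0, n, length.out = 4)) + 0.5
  slab <- function(z0, z1, t1, t2s, pd)
    list(shape = "box", center = c((n + 1) / 2, (n + 1) / 2, (z0 + z1) / 2),
         radius = c(n / 2, n / 2, (z1 - z0) / 2),
         t1 = t1, t2star = t2s, pd = pd)
  phantom_spec(rep(n, 3L), regions = list(
    slab(zs[1], zs[2], 1 / 1.08, 1 / 21.1, 0.718),
    slab(zs[2], zs[3], 1 / 0.624, 1 / 15.1, 0.852),
    slab(zs[3], zs[4], 4.0, 1.0, 1.0)),
    noise_sigma = noise_sigma, seed = seed)
}

# noise sigma giving SNR 100 on the strongest acquired image (white
# matter, dual-echo sequence, first echo)
wm_sigma_snr100 <- function() {
  sqs <- default_sequences()
  e <- exp(-sqs$single$tr * 1.08)
  s1acq <- 0.718 * sin(sqs$dual$flip_angle) * (1 - e^2) /
    (1 - e^2 * cos(sqs$dual$flip_angle)) * exp(-sqs$dual$te[1] * 21.1)
  s1acq / 100
}
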