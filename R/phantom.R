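#' Digital phantom specification
#'
#' Describes a piecewise-constant tissue phantom on a regular grid:
#' axis-aligned boxes/ellipsoids with known (T1, T2*, PD), optional smooth
#' multiplicative coil-sensitivity and transmit (B1+) fields modelled as
#' low-order polynomials normalized to mean 1 over the phantom support, and
#' additive Gaussian noise on the magnitude channels. Later regions paint
#' over earlier ones, so the ground truth is exactly known per voxel (no
#' partial-volume modelling).
#'
#' @param dim Integer grid shape, length 3.
#' @param voxel_size Voxel edge lengths in mm, length 3.
#' @param regions List of regions. Each region is a list with elements
#'   `shape` ("ellipsoid" or "box"), `center` (voxel coordinates, 1-based),
#'   `radius` (semi-axes / half-widths in voxels), and tissue values `t1`,
#'   `t2star` (seconds, positive) and `pd` (arbitrary units, non-negative).
#' @param coil_coef,b1_coef Optional named numeric vectors of polynomial
#'   coefficients over normalized coordinates in `[-1, 1]`; names among
#'   `x, y, z, xx, yy, zz, xy, xz, yz`. The resulting field `1 + p(x,y,z)`
#'   is rescaled to mean 1 over the support and must stay positive.
#' @param noise_sigma Standard deviation of the additive Gaussian noise on
#'   each magnitude channel: a scalar or a 3D array (spatially varying).
#' @param seed Master random seed for the noise streams.
#'
#' @return An object of class `phantom_spec`.
#' @seealso [default_phantom_spec()], [simulate_protocol()]
#' @export
phantom_spec <- function(dim, voxel_size = c(1, 1, 1), regions,
                         coil_coef = NULL, b1_coef = NULL,
                         noise_sigma = 0, seed = 1L) {
  dim <- as.integer(dim)
  if (length(dim) != 3L || any(dim < 1L))
    stop("'dim' must be three positive integers", call. = FALSE)
  if (!is.list(regions) || length(regions) == 0L)
    stop("'regions' must be a non-empty list", call. = FALSE)
  for (i in seq_along(regions)) {
    r <- regions[[i]]
    need <- c("shape", "center", "radius", "t1", "t2star", "pd")
    if (!all(need %in% names(r)))
      stop(sprintf("region %d is missing fields: %s", i,
                   paste(setdiff(need, names(r)), collapse = ", ")),
           call. = FALSE)
    if (!r$shape %in% c("ellipsoid", "box"))
      stop(sprintf("region %d: unknown shape '%s'", i, r$shape),
           call. = FALSE)
    if (r$t1 <= 0 || r$t2star <= 0 || r$pd < 0)
      stop(sprintf("region %d: need t1 > 0, t2star > 0, pd >= 0", i),
           call. = FALSE)
    if (any(r$center - r$radius < 0.5) || any(r$center + r$radius > dim + 0.5))
      stop(sprintf("region %d extends outside the grid", i), call. = FALSE)
  }
  if (is.array(noise_sigma) && !identical(dim(noise_sigma), dim))
    stop("'noise_sigma' array must match 'dim'", call. = FALSE)
  if (any(noise_sigma < 0))
    stop("'noise_sigma' must be non-negative", call. = FALSE)
  structure(
    list(dim = dim, voxel_size = as.numeric(voxel_size), regions = regions,
         coil_coef = coil_coef, b1_coef = b1_coef,
         noise_sigma = noise_sigma, seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

#' Three-compartment brain-like phantom
#'
#' A default phantom with white-matter-, grey-matter- and CSF-like
#' compartments. Relaxometry values follow typical 3 T brain tissue:
#' WM R1 = 1.08 1/s, R2* = 21.1 1/s, PD = 0.718; cortical GM R1 = 0.624 1/s,
#' R2* = 15.1 1/s, PD = 0.852; CSF R1 = 0.25 1/s, R2* = 1 1/s, PD = 1.
#'
#' @param n Grid edge length (cubic grid).
#' @param voxel_size Voxel size in mm.
#' @param noise_sigma Noise standard deviation (see [phantom_spec()]).
#' @param seed Master seed.
#' @param coil_coef,b1_coef Optional field coefficients (see [phantom_spec()]).
#' @return A `phantom_spec`.
#' @export
default_phantom_spec <- function(n = 64, voxel_size = c(1, 1, 1),
                                 noise_sigma = 0, seed = 1L,
                                 coil_coef = NULL, b1_coef = NULL) {
  c0 <- (n + 1) / 2
  regions <- list(
    list(shape = "ellipsoid", center = rep(c0, 3),
         radius = c(0.42, 0.42, 0.40) * n, label = "wm",
         t1 = 1 / 1.08, t2star = 1 / 21.1, pd = 0.718),
    list(shape = "ellipsoid", center = c(c0 - 0.12 * n, c0, c0),
         radius = c(0.16, 0.22, 0.20) * n, label = "gm",
         t1 = 1 / 0.624, t2star = 1 / 15.1, pd = 0.852),
    list(shape = "ellipsoid", center = c(c0 + 0.18 * n, c0, c0),
         radius = c(0.10, 0.12, 0.12) * n, label = "csf",
         t1 = 4.0, t2star = 1.0, pd = 1.0)
  )
  phantom_spec(rep(n, 3L), voxel_size, regions, coil_coef = coil_coef,
               b1_coef = b1_coef, noise_sigma = noise_sigma, seed = seed)
}

# Region membership mask; center/radius in 1-based voxel coordinates.
.region_mask <- function(dm, region) {
  x <- (seq_len(dm[1]) - region$center[1]) / region$radius[1]
  y <- (seq_len(dm[2]) - region$center[2]) / region$radius[2]
  z <- (seq_len(dm[3]) - region$center[3]) / region$radius[3]
  X <- array(x, dm)
  Y <- array(rep(y, each = dm[1]), dm)
  Z <- array(rep(z, each = dm[1] * dm[2]), dm)
  if (region$shape == "ellipsoid") {
    X^2 + Y^2 + Z^2 <= 1
  } else {
    abs(X) <= 1 & abs(Y) <= 1 & abs(Z) <= 1
  }
}

# Low-order polynomial field 1 + p(u, v, w) on [-1,1]^3, rescaled to mean 1
# over `support`; must remain positive.
.poly_field <- function(dm, coef, support) {
  f <- array(1, dm)
  if (!is.null(coef) && length(coef) > 0L) {
    u <- seq(-1, 1, length.out = dm[1])
    v <- seq(-1, 1, length.out = dm[2])
    w <- seq(-1, 1, length.out = dm[3])
    U <- array(u, dm)
    V <- array(rep(v, each = dm[1]), dm)
    W <- array(rep(w, each = dm[1] * dm[2]), dm)
    mono <- list(x = U, y = V, z = W, xx = U^2, yy = V^2, zz = W^2,
                 xy = U * V, xz = U * W, yz = V * W)
    bad <- setdiff(names(coef), names(mono))
    if (length(bad))
      stop("unknown polynomial terms: ", paste(bad, collapse = ", "),
           call. = FALSE)
    for (nm in names(coef)) f <- f + coef[[nm]] * mono[[nm]]
    f <- f / mean(f[support])
    if (any(f <= 0))
      stop("polynomial field is not positive everywhere", call. = FALSE)
  }
  f
}

#' Build ground-truth tissue maps from a phantom specification
#'
#' Paints the regions onto the grid (later regions overwrite earlier ones)
#' and folds the coil-sensitivity magnitude into the PD map. Background
#' voxels (outside every region) have zero PD and zero rates.
#'
#' @param spec A [phantom_spec] object.
#' @return A list: `tissue` ([tissue_maps], with coil field folded into
#'   `pd`), `support` (logical array, inside-phantom voxels), `coil` and
#'   `b1` (multiplicative field arrays), `labels` (integer array of region
#'   indices, 0 = background).
#' @export
build_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  dm <- spec$dim
  r1 <- array(0, dm); r2s <- array(0, dm); pd <- array(0, dm)
  labels <- array(0L, dm)
  for (i in seq_along(spec$regions)) {
    rg <- spec$regions[[i]]
    m <- .region_mask(dm, rg)
    r1[m] <- 1 / rg$t1
    r2s[m] <- 1 / rg$t2star
    pd[m] <- rg$pd
    labels[m] <- i
  }
  support <- labels > 0L
  coil <- .poly_field(dm, spec$coil_coef, support)
  b1 <- .poly_field(dm, spec$b1_coef, support)
  tissue <- tissue_maps(r1, r2s, pd * coil, voxel_size = spec$voxel_size)
  list(tissue = tissue, support = support, coil = coil, b1 = b1,
       labels = labels)
}

#' Add Gaussian noise to an echo volume set
#'
#' Additive zero-mean Gaussian noise on each magnitude channel with
#' voxelwise standard deviation; negative post-noise magnitudes are clipped
#' to zero and counted in the `"clipped"` attribute. Phase channels, when
#' present, receive independent Gaussian noise with standard deviation
#' `sigma / magnitude` (the inverse-SNR small-angle model), capped at pi.
#' The Gaussian (rather than Rician) magnitude model is appropriate at the
#' high SNR of 3 T protocols.
#'
#' @param volumes An [echo_volume_set].
#' @param noise Noise standard deviation: scalar, 3D array, or list of 3D
#'   arrays (one per echo).
#' @param seed Integer seed; one stream per echo is derived deterministically.
#' @return A new `echo_volume_set`; attribute `clipped` holds a logical
#'   array per echo marking zero-clipped voxels.
#' @export
add_noise <- function(volumes, noise, seed = 1L) {
  stopifnot(inherits(volumes, "echo_volume_set"))
  ne <- length(volumes$magnitude)
  dm <- dim(volumes$magnitude[[1]])
  if (!is.list(noise)) noise <- rep(list(noise), ne)
  if (length(noise) != ne)
    stop("'noise' list must have one entry per echo", call. = FALSE)
  sig <- lapply(noise, function(s) {
    if (is.array(s) && !identical(dim(s), dm))
      stop("noise grid shape differs from the volumes", call. = FALSE)
    if (any(s < 0)) stop("noise sigma must be non-negative", call. = FALSE)
    array(s, dm)
  })
  out <- volumes
  clipped <- vector("list", ne)
  for (i in seq_len(ne)) {
    set.seed((as.integer(seed) + 7919L * (i - 1L)) %% .Machine$integer.max)
    m <- volumes$magnitude[[i]] + array(rnorm(prod(dm)), dm) * sig[[i]]
    clipped[[i]] <- m < 0
    m[m < 0] <- 0
    out$magnitude[[i]] <- m
    if (!is.null(volumes$phase)) {
      snr_inv <- sig[[i]] / pmax(volumes$magnitude[[i]],
                                 .Machine$double.eps)
      p <- volumes$phase[[i]] +
        array(rnorm(prod(dm)), dm) * pmin(snr_inv, pi)
      out$phase[[i]] <- (p + pi) %% (2 * pi) - pi
    }
  }
  attr(out, "clipped") <- clipped
  out
}

#' Simulate the two-sequence acquisition of a phantom
#'
#' Generates the single-echo and multi-echo GRE magnitude (and phase)
#' volumes predicted by the forward signal model for a phantom, with the
#' coil field folded into PD, the B1+ field scaling the nominal flip
#' angles, and optional additive Gaussian noise. With a fixed seed the
#' output is bit-reproducible.
#'
#' @param spec A [phantom_spec].
#' @param seq_single,seq_dual [sequence_params] of the two acquisitions;
#'   default: [default_sequences()]. `seq_single` must have exactly one
#'   echo; a dual repetition time different from twice the single one
#'   triggers a warning (the closed-form R1 solution assumes the doubling).
#' @param phase Logical: also simulate phase volumes?
#' @return A list: `single` and `dual` ([echo_volume_set]s), `truth`
#'   ([tissue_maps] including the coil field in `pd`), `support`, `coil`,
#'   `b1`, `labels` as in [build_phantom()].
#' @export
simulate_protocol <- function(spec, seq_single = NULL, seq_dual = NULL,
                              phase = FALSE) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (is.null(seq_single) || is.null(seq_dual)) {
    dft <- default_sequences()
    if (is.null(seq_single)) seq_single <- dft$single
    if (is.null(seq_dual)) seq_dual <- dft$dual
  }
  if (length(seq_single$te) != 1L)
    stop("'seq_single' must have exactly one echo", call. = FALSE)
  if (abs(seq_dual$tr - 2 * seq_single$tr) > 1e-12 * seq_single$tr)
    warning("dual-sequence TR is not twice the single-sequence TR; ",
            "the closed-form R1 solution assumes the doubling",
            call. = FALSE)
  ph <- build_phantom(spec)
  mk <- function(sq) {
    sig <- lapply(seq_along(sq$te), function(i)
      gre_signal(ph$tissue, sq, i, b1 = ph$b1))
    echo_volume_set(lapply(sig, Mod), sq,
                    phase = if (phase) lapply(sig, Arg) else NULL,
                    voxel_size = spec$voxel_size)
  }
  single <- mk(seq_single)
  dual <- mk(seq_dual)
  if (any(spec$noise_sigma > 0)) {
    single <- add_noise(single, spec$noise_sigma, seed = spec$seed)
    dual <- add_noise(dual, spec$noise_sigma,
                      seed = (spec$seed + 500009L) %% .Machine$integer.max)
  }
  list(single = single, dual = dual, truth = ph$tissue,
       support = ph$support, coil = ph$coil, b1 = ph$b1,
       labels = ph$labels)
}
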