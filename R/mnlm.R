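#' Multichannel image container
#'
#' A set of co-registered 3D channels (for example the three acquired GRE
#' magnitudes plus a precomputed susceptibility map) processed jointly by
#' the multispectral non-local-means denoiser.
#'
#' @param channels List of 3D arrays sharing one shape (a single array is
#'   accepted).
#' @param voxel_size Voxel edge lengths in mm, length 3.
#' @param mask Optional logical support array; voxels outside it are passed
#'   through unchanged. Default: all voxels.
#' @return An object of class `mc_image`.
#' @export
multichannel_image <- function(channels, voxel_size = c(1, 1, 1),
                               mask = NULL) {
  if (!is.list(channels)) channels <- list(channels)
  if (length(channels) < 1L)
    stop("at least one channel is required", call. = FALSE)
  dm <- dim(channels[[1]])
  if (is.null(dm) || length(dm) != 3L)
    stop("channels must be 3D arrays", call. = FALSE)
  for (ch in channels)
    if (!identical(dim(ch), dm))
      stop("all channels must share one grid shape", call. = FALSE)
  if (is.null(mask)) mask <- array(TRUE, dm)
  if (!identical(dim(mask), dm))
    stop("'mask' must match the channel shape", call. = FALSE)
  structure(list(channels = channels, voxel_size = as.numeric(voxel_size),
                 mask = mask),
            class = "mc_image")
}

#' Per-channel noise standard-deviation maps
#'
#' @param sigma Scalar, 3D array, or list (one per channel) of voxelwise
#'   noise standard deviations; recycled across channels when needed.
#' @param dim Grid shape the maps must match.
#' @param n_channels Number of channels.
#' @param floor Positive floor applied to every voxel (zero-noise voxels
#'   would make the patch distance singular). Default `1e-12`.
#' @return An object of class `noise_map`: list of 3D sigma arrays.
#' @export
noise_map <- function(sigma, dim, n_channels = NULL, floor = 1e-12) {
  if (inherits(sigma, "noise_map")) return(sigma)
  if (!is.list(sigma)) {
    if (is.null(n_channels))
      stop("'n_channels' needed when 'sigma' is not a list", call. = FALSE)
    sigma <- rep(list(sigma), n_channels)
  }
  sig <- lapply(sigma, function(s) {
    if (any(s < 0, na.rm = TRUE))
      stop("noise sigma must be non-negative", call. = FALSE)
    s <- array(s, dim)
    pmax(s, floor)
  })
  structure(sig, class = "noise_map")
}

#' Denoiser parameters
#'
#' The three tuning constants of the multispectral non-local-means filter,
#' with the field defaults tied to the voxel volume `dV` (in mm^3):
#' search-ball weight budget `kappa = 100 * dV` (mm^3), patch similarity
#' radius `rho = 5 * dV^(1/3)` (mm), and dimensionless filter strength
#' `sigma_filter = 1`. `NULL` values are resolved against the image voxel
#' size at call time.
#'
#' @param kappa Search-ball weight budget in mm^3 (weight sum times voxel
#'   volume); the ball at each voxel grows shell by shell until it is met.
#' @param rho Gaussian patch-window radius in mm.
#' @param sigma_filter Filter strength (dimensionless, > 0).
#' @param max_radius Cap on the search radius in mm; default
#'   `3 * (3 kappa / (4 pi))^(1/3)` (three times the uniform-weight ball
#'   radius). Voxels that cannot reach `kappa` within the cap are flagged.
#' @param patch_trunc Per-axis truncation of the Gaussian window, in units
#'   of `rho` (default 2).
#' @return An object of class `mnlm_params`.
#' @export
mnlm_params <- function(kappa = NULL, rho = NULL, sigma_filter = 1,
                        max_radius = NULL, patch_trunc = 2) {
  if (!is.null(kappa) && kappa <= 0) stop("'kappa' must be positive",
                                          call. = FALSE)
  if (!is.null(rho) && rho <= 0) stop("'rho' must be positive",
                                      call. = FALSE)
  if (sigma_filter <= 0) stop("'sigma_filter' must be positive",
                              call. = FALSE)
  structure(list(kappa = kappa, rho = rho, sigma_filter = sigma_filter,
                 max_radius = max_radius, patch_trunc = patch_trunc),
            class = "mnlm_params")
}

# Resolve NULL defaults against a voxel size.
.resolve_mnlm_params <- function(params, voxel_size) {
  if (is.null(params)) params <- mnlm_params()
  dv <- prod(voxel_size)
  if (is.null(params$kappa)) params$kappa <- 100 * dv
  if (is.null(params$rho)) params$rho <- 5 * dv^(1 / 3)
  if (is.null(params$max_radius))
    params$max_radius <- 3 * (3 * params$kappa / (4 * pi))^(1 / 3)
  params
}

# Separable Gaussian patch window: per-axis truncation at trunc*rho, each
# 1D kernel normalized to unit sum, 3D weights are the outer product (so
# the full window is normalized too, and exactly separable).
.mnlm_patch_kernel <- function(voxel_size, rho, trunc = 2) {
  ext <- pmax(0L, as.integer(floor(trunc * rho / voxel_size)))
  k1d <- lapply(1:3, function(d) {
    t <- (-ext[d]:ext[d]) * voxel_size[d]
    w <- exp(-t^2 / (2 * rho^2))
    w / sum(w)
  })
  off <- as.matrix(expand.grid(dx = -ext[1]:ext[1], dy = -ext[2]:ext[2],
                               dz = -ext[3]:ext[3]))
  w <- k1d[[1]][off[, 1] + ext[1] + 1L] *
    k1d[[2]][off[, 2] + ext[2] + 1L] *
    k1d[[3]][off[, 3] + ext[3] + 1L]
  list(k1d = k1d, ext = ext, offsets = off, w = w)
}

# Search-ball offsets within max_radius (mm), sorted by distance (ties
# broken lexicographically); shells are groups of equal distance.
.mnlm_search_offsets <- function(voxel_size, max_radius) {
  ext <- pmax(0L, as.integer(floor(max_radius / voxel_size)))
  off <- as.matrix(expand.grid(dx = -ext[1]:ext[1], dy = -ext[2]:ext[2],
                               dz = -ext[3]:ext[3]))
  d <- sqrt((off[, 1] * voxel_size[1])^2 + (off[, 2] * voxel_size[2])^2 +
              (off[, 3] * voxel_size[3])^2)
  keep <- d <= max_radius + 1e-9
  off <- off[keep, , drop = FALSE]
  d <- d[keep]
  o <- order(d, off[, 1], off[, 2], off[, 3])
  off <- off[o, , drop = FALSE]
  d <- d[o]
  shell <- cumsum(c(TRUE, diff(d) > 1e-9)) - 1L
  list(offsets = off, dist = d, shell = as.integer(shell), ext = ext)
}

# Reflective padding (edge duplicated), valid for any pad width via
# period-2n folding.
.reflect_index <- function(i, n) {
  j <- ((i - 1L) %% (2L * n))
  j[j < 0L] <- j[j < 0L] + 2L * n
  ifelse(j < n, j + 1L, 2L * n - j)
}

.reflect_pad <- function(arr, pad) {
  dm <- dim(arr)
  ix <- .reflect_index(seq(1L - pad[1], dm[1] + pad[1]), dm[1])
  iy <- .reflect_index(seq(1L - pad[2], dm[2] + pad[2]), dm[2])
  iz <- .reflect_index(seq(1L - pad[3], dm[3] + pad[3]), dm[3])
  arr[ix, iy, iz, drop = FALSE]
}

#' Per-channel quality factor
#'
#' Ratio of the channel's signal energy to its noise energy over the
#' support mask: `Q_m = sum(X_m^2) / sum(sigma_m^2)`. The quality factors
#' weight the filter strength per channel (relative to their sum), so that
#' low-SNR channels are smoothed more aggressively and contribute less to
#' the shared patch distance.
#'
#' @param img A [multichannel_image].
#' @param noise A [noise_map] (or anything [noise_map()] accepts).
#' @return Numeric vector of `Q_m`, one per channel.
#' @export
channel_quality <- function(img, noise) {
  stopifnot(inherits(img, "mc_image"))
  noise <- noise_map(noise, dim(img$channels[[1]]),
                     n_channels = length(img$channels))
  if (!any(img$mask)) stop("empty support mask", call. = FALSE)
  vapply(seq_along(img$channels), function(m) {
    sum(img$channels[[m]][img$mask]^2) / sum(noise[[m]][img$mask]^2)
  }, numeric(1))
}

#' Gaussian-windowed patch distance between two voxels
#'
#' The squared patch dissimilarity of Eq-style non-local means: a
#' Gaussian-weighted sum of squared channel differences over a window
#' around the two voxels, normalized voxelwise by `sigma_m^2(x) +
#' sigma_m^2(y)` and summed over channels. Windows extending beyond the
#' volume use reflective padding. The distance is symmetric and vanishes
#' at `y = x`.
#'
#' @param img A [multichannel_image].
#' @param noise A [noise_map] (or input to [noise_map()]).
#' @param x,y Voxel coordinates (1-based integer triples).
#' @param rho Patch radius in mm; default: the field default for the image
#'   voxel size.
#' @param patch_trunc Window truncation in units of `rho`.
#' @return A single non-negative number.
#' @export
patch_distance <- function(img, noise, x, y, rho = NULL, patch_trunc = 2) {
  stopifnot(inherits(img, "mc_image"))
  dm <- dim(img$channels[[1]])
  noise <- noise_map(noise, dm, n_channels = length(img$channels))
  if (is.null(rho)) rho <- 5 * prod(img$voxel_size)^(1 / 3)
  ker <- .mnlm_patch_kernel(img$voxel_size, rho, patch_trunc)
  x <- as.integer(x); y <- as.integer(y)
  ix <- lapply(1:3, function(d)
    .reflect_index(x[d] + (-ker$ext[d]:ker$ext[d]), dm[d]))
  iy <- lapply(1:3, function(d)
    .reflect_index(y[d] + (-ker$ext[d]:ker$ext[d]), dm[d]))
  w3 <- array(ker$w, 2L * ker$ext + 1L)
  d2 <- 0
  for (m in seq_along(img$channels)) {
    px <- img$channels[[m]][ix[[1]], ix[[2]], ix[[3]], drop = FALSE]
    py <- img$channels[[m]][iy[[1]], iy[[2]], iy[[3]], drop = FALSE]
    s2 <- noise[[m]][x[1], x[2], x[3]]^2 + noise[[m]][y[1], y[2], y[3]]^2
    d2 <- d2 + sum(w3 * (px - py)^2) / s2
  }
  d2
}

#' Adaptive search radius from a weight field
#'
#' Grows the search ball around a voxel shell by shell (shells are groups
#' of equal voxel-center distance) until the accumulated weight times the
#' voxel volume reaches the budget `kappa`, or the cap is hit.
#'
#' @param w 3D array of non-negative weights.
#' @param center Voxel coordinate (1-based triple).
#' @param kappa Weight budget in mm^3.
#' @param voxel_size Voxel edge lengths in mm.
#' @param max_radius Radius cap in mm.
#' @return List: `radius` (mm, distance of the last shell included), `n`
#'   (voxels in the ball), `wsum` (accumulated weight), `reached`
#'   (logical: was `kappa` attained within the cap?).
#' @export
search_radius <- function(w, center, kappa, voxel_size = c(1, 1, 1),
                          max_radius = NULL) {
  stopifnot(kappa > 0)
  dm <- dim(w)
  if (is.null(max_radius))
    max_radius <- 3 * (3 * kappa / (4 * pi))^(1 / 3)
  so <- .mnlm_search_offsets(voxel_size, max_radius)
  dv <- prod(voxel_size)
  wsum <- 0; n <- 0L; radius <- 0
  for (s in unique(so$shell)) {
    idx <- which(so$shell == s)
    for (i in idx) {
      px <- .reflect_index(center[1] + so$offsets[i, 1], dm[1])
      py <- .reflect_index(center[2] + so$offsets[i, 2], dm[2])
      pz <- .reflect_index(center[3] + so$offsets[i, 3], dm[3])
      wsum <- wsum + w[px, py, pz]
      n <- n + 1L
    }
    radius <- so$dist[idx[1]]
    if (wsum * dv >= kappa)
      return(list(radius = radius, n = n, wsum = wsum, reached = TRUE))
  }
  list(radius = radius, n = n, wsum = wsum, reached = FALSE)
}

#' Multispectral non-local-means denoising
#'
#' Patch-similarity-weighted averaging across co-registered channels. For
#' each voxel and channel, the output is a convex combination of channel
#' values inside an adaptive search ball,
#' `Y_m(x) = sum_y W_m(x,y) X_m(y) / sum_y W_m(x,y)`, with weights
#' `W_m(x,y) = exp(-d2(x,y) / sigma_filter^2 * Q_m / sum_l Q_l)` built from
#' the shared multichannel patch distance `d2` (see [patch_distance()]) and
#' the channel quality factors (see [channel_quality()]). The ball at each
#' voxel and channel grows shell by shell until the accumulated weight
#' times the voxel volume reaches `kappa` (see [search_radius()]), capped
#' at `max_radius`. The self-weight `W_m(x,x) = 1` is always included, so
#' every output voxel lies in the range of the input values inside its
#' ball. Neighbors with a non-finite patch distance are excluded.
#'
#' `method = "fast"` runs the compiled offset-major path (separable
#' Gaussian convolutions per search offset, early termination once every
#' voxel has met its budget); `method = "reference"` runs a plain R
#' voxel-by-voxel loop with identical discretization. Both produce the
#' same result to floating-point reordering (about 1e-13 relative) and the
#' reference is only practical on toy volumes.
#'
#' @param img A [multichannel_image] (or a bare 3D array / list of them).
#' @param noise A [noise_map], or anything [noise_map()] accepts; `NULL`
#'   estimates it with [estimate_noise_map()].
#' @param params An [mnlm_params]; `NULL` uses the field defaults.
#' @param method `"fast"` (compiled) or `"reference"` (R loop oracle).
#' @param voxel_size Used only when `img` is not a [multichannel_image].
#' @return A [multichannel_image] with denoised channels; attributes
#'   `radius` (matrix, per-voxel per-channel final ball radius in mm),
#'   `capped` (logical matrix: budget not reached within the cap) and
#'   `quality` (the channel quality factors used).
#' @export
mnlm_denoise <- function(img, noise = NULL, params = NULL,
                         method = c("fast", "reference"),
                         voxel_size = c(1, 1, 1)) {
  method <- match.arg(method)
  if (!inherits(img, "mc_image"))
    img <- multichannel_image(img, voxel_size = voxel_size)
  dm <- dim(img$channels[[1]])
  M <- length(img$channels)
  if (is.null(noise)) noise <- estimate_noise_map(img)
  noise <- noise_map(noise, dm, n_channels = M)
  params <- .resolve_mnlm_params(params, img$voxel_size)

  orig_channels <- img$channels
  # non-finite voxels are excluded as neighbors (and as centers); their
  # entries are zeroed so patch distances around them stay computable
  ffin <- Reduce(`&`, lapply(img$channels, is.finite))
  if (!all(ffin)) {
    img$channels <- lapply(img$channels, function(a) {
      a[!ffin] <- 0; a
    })
    img$mask <- img$mask & ffin
  }
  Q <- channel_quality(img, noise)
  qn <- Q / sum(Q)
  ker <- .mnlm_patch_kernel(img$voxel_size, params$rho, params$patch_trunc)
  so <- .mnlm_search_offsets(img$voxel_size, params$max_radius)
  pad <- ker$ext + so$ext
  Xp <- lapply(img$channels, .reflect_pad, pad = pad)
  Sp <- lapply(noise, .reflect_pad, pad = pad)
  finite <- .reflect_pad(array(ffin, dm), pad)
  dv <- prod(img$voxel_size)
  target <- params$kappa / dv
  sc2 <- params$sigma_filter^2

  if (method == "fast") {
    res <- mnlm_core(Xp, Sp, as.numeric(qn), sc2, target,
                     so$offsets, so$dist, so$shell,
                     ker$k1d, as.integer(ker$ext),
                     as.integer(dm), as.integer(pad),
                     as.logical(img$mask), finite)
  } else {
    res <- .mnlm_reference(Xp, Sp, qn, sc2, target, so, ker, dm, pad,
                           img$mask, finite)
  }
  out <- img
  for (m in seq_len(M)) {
    ch <- orig_channels[[m]]
    ch[img$mask] <- res$out[img$mask, m]
    out$channels[[m]] <- ch
  }
  attr(out, "radius") <- res$radius
  attr(out, "capped") <- res$capped
  attr(out, "quality") <- Q
  out
}

# Reference voxel-by-voxel implementation (the oracle for the compiled
# path). Same padded arrays, offsets, shells and kernel as the fast path.
.mnlm_reference <- function(Xp, Sp, qn, sc2, target, so, ker, dm, pad,
                            mask, finite) {
  M <- length(Xp)
  nv <- prod(dm)
  out <- matrix(NA_real_, nv, M)
  radius <- matrix(0, nv, M)
  capped <- matrix(FALSE, nv, M)
  np <- dim(Xp[[1]])
  koff <- ker$offsets
  kw <- ker$w
  nshell <- max(so$shell)
  shidx <- split(seq_along(so$shell), so$shell)
  vi <- 0L
  for (z in seq_len(dm[3])) for (y in seq_len(dm[2])) for (x in seq_len(dm[1])) {
    vi <- vi + 1L
    if (!mask[x, y, z]) next
    cx <- c(x, y, z) + pad
    num <- numeric(M); den <- numeric(M)
    stopped <- logical(M)
    sig_x <- vapply(seq_len(M), function(m)
      Sp[[m]][cx[1], cx[2], cx[3]]^2, numeric(1))
    for (s in seq_along(shidx)) {
      for (i in shidx[[s]]) {
        cy <- cx + so$offsets[i, ]
        if (!finite[cy[1], cy[2], cy[3]]) next
        d2 <- 0
        for (m in seq_len(M)) {
          ps <- 0
          for (kk in seq_along(kw)) {
            tx <- koff[kk, ]
            ps <- ps + kw[kk] *
              (Xp[[m]][cx[1] + tx[1], cx[2] + tx[2], cx[3] + tx[3]] -
                 Xp[[m]][cy[1] + tx[1], cy[2] + tx[2], cy[3] + tx[3]])^2
          }
          d2 <- d2 + ps / (sig_x[m] + Sp[[m]][cy[1], cy[2], cy[3]]^2)
        }
        if (!is.finite(d2)) next
        for (m in seq_len(M)) {
          if (stopped[m]) next
          w <- exp(-d2 * qn[m] / sc2)
          num[m] <- num[m] + w * Xp[[m]][cy[1], cy[2], cy[3]]
          den[m] <- den[m] + w
        }
      }
      newly <- !stopped & den >= target
      radius[vi, newly] <- so$dist[shidx[[s]][1]]
      stopped <- stopped | newly
      if (all(stopped)) break
    }
    capped[vi, ] <- !stopped
    radius[vi, !stopped] <- so$dist[length(so$dist)]
    out[vi, ] <- num / den
  }
  list(out = out, radius = radius, capped = capped)
}

#' Local robust noise estimation
#'
#' A simple spatially varying noise estimator used when no noise map is
#' supplied: the high-frequency residual (voxel value minus its 3x3x3 box
#' mean) is summarized per non-overlapping block by the median absolute
#' deviation with the Gaussian-consistent 1.4826 scaling, corrected for
#' the variance removed by the box mean (factor sqrt(26/27)), then
#' expanded blockwise-constant to the full grid. Structure crossing a
#' block inflates the estimate there; the median keeps the estimator
#' usable away from edges. Users with a calibrated noise model should
#' supply their own [noise_map].
#'
#' @param img A [multichannel_image] or 3D array.
#' @param block Block edge length in voxels (default 5).
#' @return A [noise_map] with one sigma array per channel.
#' @export
estimate_noise_map <- function(img, block = 5L) {
  if (!inherits(img, "mc_image")) img <- multichannel_image(img)
  dm <- dim(img$channels[[1]])
  sig <- lapply(img$channels, function(X) {
    Xp <- .reflect_pad(X, c(1L, 1L, 1L))
    acc <- array(0, dm)
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1)
      acc <- acc + Xp[seq_len(dm[1]) + 1L + dx,
                      seq_len(dm[2]) + 1L + dy,
                      seq_len(dm[3]) + 1L + dz]
    r <- X - acc / 27
    bx <- ceiling(seq_len(dm[1]) / block)
    by <- ceiling(seq_len(dm[2]) / block)
    bz <- ceiling(seq_len(dm[3]) / block)
    idx <- array(paste(bx[slice.index(r, 1)], by[slice.index(r, 2)],
                       bz[slice.index(r, 3)], sep = "-"), dm)
    med <- tapply(r, idx, function(v) stats::mad(v, constant = 1.4826))
    s <- array(med[idx], dm) / sqrt(26 / 27)
    s[!is.finite(s)] <- 0
    s
  })
  noise_map(sig, dm, n_channels = length(sig))
}
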