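#' Voxelwise weighted-least-squares R2* fit
#'
#' Fits the log-linear multi-echo decay `log s_i = k0 - TE_i * R2*` by
#' weighted least squares with weights `w_i = 1 / (BW_i * s_i^2)` (the
#' inverse variance of `log s_i` under additive noise whose power scales
#' with the receiver bandwidth). For two echoes with equal bandwidth the
#' estimate reduces algebraically to `R2* = log(s1/s2) / (TE2 - TE1)`.
#'
#' Voxels with fewer than two positive echo magnitudes are masked invalid
#' rather than raising an error; non-positive echoes are dropped from the
#' fit voxelwise.
#'
#' @param echoes An [echo_volume_set] with at least two echoes.
#' @return An object of class `r2star_fit`: list with 3D arrays `r2star`
#'   (1/s), `k0` (log signal intercept at TE = 0) and logical `valid`.
#'   Invalid voxels carry `NA`.
#' @export
fit_r2star_wls <- function(echoes) {
  stopifnot(inherits(echoes, "echo_volume_set"))
  te <- echoes$params$te
  bw <- echoes$params$bandwidth
  ne <- length(te)
  if (ne < 2L)
    stop("R2* fitting requires at least two echoes", call. = FALSE)
  dm <- dim(echoes$magnitude[[1]])
  nv <- prod(dm)
  S <- matrix(unlist(echoes$magnitude, use.names = FALSE), nv, ne)
  ok <- is.finite(S) & S > 0
  L <- matrix(NA_real_, nv, ne)
  L[ok] <- log(S[ok])
  W <- matrix(0, nv, ne)
  W[ok] <- 1 / (rep(bw, each = nv)[ok] * S[ok]^2)

  wsum <- rowSums(W)
  valid <- rowSums(ok) >= 2L & wsum > 0
  TEm <- matrix(te, nv, ne, byrow = TRUE)
  tbar <- rowSums(W * TEm) / wsum
  Lw <- W * L
  Lw[!ok] <- 0
  lbar <- rowSums(Lw) / wsum
  dt <- TEm - tbar
  dL <- L - lbar
  dL[!ok] <- 0
  sxx <- rowSums(W * dt^2)
  sxy <- rowSums(W * dt * dL)
  valid <- valid & sxx > 0
  r2s <- -sxy / sxx
  k0 <- lbar + r2s * tbar
  r2s[!valid] <- NA_real_
  k0[!valid] <- NA_real_
  structure(
    list(r2star = array(r2s, dm), k0 = array(k0, dm),
         valid = array(valid, dm)),
    class = "r2star_fit"
  )
}

#' Extrapolate signal magnitudes to TE = 0
#'
#' Combines the single-echo magnitude with the multi-echo R2* fit to
#' estimate the transverse-decay-free magnitudes of both sequences:
#' `S1 = s0 * exp(TE0 * R2*)` for the single-echo acquisition and
#' `S2 = exp(k0)` for the multi-echo one. These feed the closed-form
#' variable-flip-angle R1 solution via their ratio.
#'
#' @param echoes_single [echo_volume_set] of the single-echo sequence.
#' @param r2fit An `r2star_fit` from the multi-echo sequence.
#' @return List with 3D arrays `s1`, `s2` (both non-negative, `NA` where
#'   invalid) and logical `valid`.
#' @export
extrapolate_te0 <- function(echoes_single, r2fit) {
  stopifnot(inherits(echoes_single, "echo_volume_set"),
            inherits(r2fit, "r2star_fit"))
  if (length(echoes_single$magnitude) != 1L)
    stop("'echoes_single' must be a single-echo set", call. = FALSE)
  s0 <- echoes_single$magnitude[[1]]
  if (!identical(dim(s0), dim(r2fit$r2star)))
    stop("grid shape of 'echoes_single' differs from the R2* fit",
         call. = FALSE)
  te0 <- echoes_single$params$te[1]
  s1 <- s0 * exp(te0 * r2fit$r2star)
  s2 <- exp(r2fit$k0)
  valid <- r2fit$valid & is.finite(s1) & is.finite(s2) & s1 > 0 & s2 > 0
  s1[!valid] <- NA_real_
  s2[!valid] <- NA_real_
  list(s1 = s1, s2 = s2, valid = valid)
}
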