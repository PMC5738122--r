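#' Quantitative map bundle
#'
#' Output container of the reconstruction: R1, R2* and proton-density maps
#' plus a per-voxel validity mask with per-stage failure codes and a
#' provenance record.
#'
#' Mask codes: 0 valid; 1 R2* fit failed (fewer than two positive echoes);
#' 2 non-positive extrapolated TE = 0 magnitude; 3 negative discriminant in
#' the R1 quadratic; 4 recovery factor outside (0, 1) (including the
#' fully-relaxed boundary); 5 ambiguous branch; 6 degenerate proton-density
#' denominator.
#'
#' @param r1,r2star,pd 3D maps (1/s, 1/s, arbitrary units).
#' @param mask Integer 3D array of failure codes (0 = valid).
#' @param voxel_size Voxel edge lengths in mm.
#' @param provenance Named list recording inputs, parameters, seed and
#'   software version.
#' @return An object of class `qmap_bundle`.
#' @export
qmap_bundle <- function(r1, r2star, pd, mask, voxel_size = c(1, 1, 1),
                        provenance = list()) {
  dm <- dim(r1)
  for (nm in c("r2star", "pd", "mask")) {
    if (!identical(dim(get(nm)), dm))
      stop(sprintf("grid shape of '%s' differs from 'r1'", nm),
           call. = FALSE)
  }
  structure(list(r1 = r1, r2star = r2star, pd = pd, mask = mask,
                 voxel_size = as.numeric(voxel_size),
                 provenance = provenance),
            class = "qmap_bundle")
}

#' @export
print.qmap_bundle <- function(x, ...) {
  nv <- length(x$mask)
  cat(sprintf("Quantitative map bundle: grid %s, %d/%d voxels valid\n",
              paste(dim(x$r1), collapse = "x"), sum(x$mask == 0L), nv))
  codes <- table(x$mask[x$mask != 0L])
  if (length(codes))
    cat("  failure codes:",
        paste(sprintf("%s:%d", names(codes), codes), collapse = " "), "\n")
  invisible(x)
}

#' Reconstruct R1, R2* and PD maps from the two-sequence protocol
#'
#' The end-to-end analytic reconstruction: optional multispectral
#' non-local-means denoising of the acquired magnitudes (plus an optional
#' susceptibility channel), weighted-least-squares R2* from the multi-echo
#' set, TE = 0 extrapolation of both sequences, the closed-form
#' recovery-factor solution with branch selection, and the proton-density
#' inversion. An externally measured transmit map (`b1`) scales the nominal
#' flip angles voxelwise; a receive map divides the PD map.
#'
#' @param single [echo_volume_set] of the single-echo sequence.
#' @param dual [echo_volume_set] of the multi-echo sequence at doubled TR.
#' @param b1 Optional 3D transmit-field factor array (1 = nominal).
#' @param receive Optional 3D receive-field array dividing the PD map.
#' @param denoise Logical: run the MNLM denoiser first?
#' @param noise `NULL`, or anything [noise_map()] accepts, for the
#'   denoiser; `NULL` estimates the noise with [estimate_noise_map()].
#' @param mnlm An [mnlm_params] or `NULL` for the field defaults.
#' @param qsm Optional 3D susceptibility array used as an extra denoising
#'   channel only (it is never reconstructed here).
#' @param general_tr Logical: if the dual TR is not twice the single TR,
#'   solve the recovery factor numerically instead of warning and using
#'   the closed form.
#' @param provenance Named list merged into the output provenance.
#' @return A [qmap_bundle].
#' @export
fit_resume <- function(single, dual, b1 = NULL, receive = NULL,
                       denoise = FALSE, noise = NULL, mnlm = NULL,
                       qsm = NULL, general_tr = FALSE,
                       provenance = list()) {
  stopifnot(inherits(single, "echo_volume_set"),
            inherits(dual, "echo_volume_set"))
  if (length(single$magnitude) != 1L)
    stop("'single' must have exactly one echo", call. = FALSE)
  if (length(dual$magnitude) < 2L)
    stop("'dual' must have at least two echoes", call. = FALSE)
  dm <- dim(single$magnitude[[1]])
  if (!identical(dm, dim(dual$magnitude[[1]])))
    stop("grid shapes of the two sequences differ", call. = FALSE)
  tr0 <- single$params$tr
  ratio <- dual$params$tr / tr0
  if (abs(ratio - 2) > 1e-9 && !general_tr)
    warning(sprintf(
      "dual TR is %.4g x the single TR (expected 2): the closed-form ",
      ratio), "solution assumes the doubling; set general_tr = TRUE ",
      "for the numerical solution", call. = FALSE)

  if (denoise) {
    channels <- c(single$magnitude, dual$magnitude)
    if (!is.null(qsm)) channels <- c(channels, list(qsm))
    img <- multichannel_image(channels, voxel_size = single$voxel_size)
    den <- mnlm_denoise(img, noise = noise, mnlm)
    single$magnitude[[1]] <- den$channels[[1]]
    for (i in seq_along(dual$magnitude))
      dual$magnitude[[i]] <- den$channels[[1L + i]]
  }

  code <- array(0L, dm)
  r2fit <- fit_r2star_wls(dual)
  code[!r2fit$valid] <- 1L
  ext <- extrapolate_te0(single, r2fit)
  code[r2fit$valid & !ext$valid] <- 2L

  th1 <- if (is.null(b1)) single$params$flip_angle
         else apply_b1_correction(single$params, b1)
  th2 <- if (is.null(b1)) dual$params$flip_angle
         else apply_b1_correction(dual$params, b1)

  q <- ext$s1 / ext$s2
  sol <- solve_e10(q, th1, th2,
                   tr_ratio = if (general_tr) ratio else 2)
  sol <- r1_map(sol, tr0)
  code[ext$valid & sol$code != 0L] <- sol$code[ext$valid & sol$code != 0L]

  pd <- pd_map(ext$s2, sol, th2)
  code[sol$valid & !pd$valid] <- 6L
  pdv <- pd$pd
  if (!is.null(receive)) {
    if (!identical(dim(receive), dm))
      stop("grid shape of 'receive' differs from the data", call. = FALSE)
    pdv <- pdv / receive
  }

  r2s <- r2fit$r2star
  r1 <- sol$r1
  bad <- code != 0L
  r2s[!r2fit$valid] <- NA_real_
  r1[bad] <- NA_real_
  pdv[bad] <- NA_real_

  prov <- utils::modifyList(list(
    software = "resumeqmri",
    version = as.character(utils::packageVersion("resumeqmri")),
    tr0_s = tr0, tr_dual_s = dual$params$tr,
    te_single_s = single$params$te, te_dual_s = dual$params$te,
    flip_single_rad = single$params$flip_angle,
    flip_dual_rad = dual$params$flip_angle,
    denoise = denoise, b1_corrected = !is.null(b1),
    general_tr = general_tr
  ), provenance)
  qmap_bundle(r1, r2s, pdv, code, voxel_size = single$voxel_size,
              provenance = prov)
}
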