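#' Forward spoiled gradient-echo signal
#'
#' Evaluates the steady-state complex signal of an ideally spoiled GRE
#' sequence voxelwise:
#' \deqn{S = PD \cdot \sin\theta \frac{1 - E_1}{1 - E_1\cos\theta}
#'       \exp[-T_E (R_2^* + i \gamma \Delta B) + i \phi_0],}
#' with \eqn{E_1 = \exp(-T_R R_1)} and \eqn{PD = |K| M_0} (coil sensitivity
#' magnitude folded into the proton-density map, coil phase into `phi0`).
#'
#' @param tissue A [tissue_maps] object.
#' @param seq A [sequence_params] object.
#' @param echo_index Which echo of `seq` to evaluate (1-based).
#' @param b1 Optional 3D array (or scalar) of transmit-field factors; the
#'   effective flip angle is `seq$flip_angle * b1`. Default 1 (nominal).
#'
#' @return A complex 3D array of the same shape as the tissue grids.
#' @export
gre_signal <- function(tissue, seq, echo_index = 1L, b1 = NULL) {
  stopifnot(inherits(tissue, "tissue_maps"), inherits(seq, "sequence_params"))
  if (echo_index < 1L || echo_index > length(seq$te))
    stop("'echo_index' out of range for the sequence echo times",
         call. = FALSE)
  dm <- dim(tissue$r1)
  theta <- seq$flip_angle
  if (!is.null(b1)) {
    if (length(b1) != 1L && !identical(dim(b1), dm))
      stop("grid shape of 'b1' differs from tissue maps", call. = FALSE)
    theta <- theta * b1
  }
  te <- seq$te[echo_index]
  e1 <- exp(-seq$tr * tissue$r1)
  amp <- tissue$pd * sin(theta) * (1 - e1) / (1 - e1 * cos(theta))
  out <- amp * exp(complex(
    real = -te * tissue$r2star,
    imaginary = -te * tissue$gyro * tissue$delta_b + tissue$phi0))
  array(out, dm)
}
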