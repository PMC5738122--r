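#' Apply a transmit-field (B1+) correction to the nominal flip angle
#'
#' Multiplies the nominal flip angle of a sequence by an externally
#' measured transmit-field map, producing the voxelwise effective flip
#' angles used by [solve_e10()] and [pd_map()]. With `b1 = NULL` the
#' correction is the identity and a notice is emitted. Receive-field
#' (B1-) inhomogeneity cancels in the signal ratio and only biases the
#' proton-density scale; [fit_resume()] accepts a separate receive map to
#' divide it out.
#'
#' @param seq A [sequence_params] object.
#' @param b1 3D array of positive multiplicative transmit factors (1 =
#'   nominal), or `NULL`.
#' @return Effective flip angle: the scalar nominal angle if `b1` is
#'   `NULL`, otherwise a 3D array in radians.
#' @export
apply_b1_correction <- function(seq, b1 = NULL) {
  stopifnot(inherits(seq, "sequence_params"))
  if (is.null(b1)) {
    message("no B1+ map supplied: using the nominal flip angle")
    return(seq$flip_angle)
  }
  if (any(!is.finite(b1)) || any(b1 <= 0))
    stop("'b1' must be positive and finite everywhere", call. = FALSE)
  seq$flip_angle * b1
}
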