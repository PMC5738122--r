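#' Spoiled gradient-echo sequence parameters
#'
#' Container for the timing and excitation metadata of one spoiled
#' gradient-echo (GRE) acquisition. All values are stored in SI units
#' (seconds, radians, Hz per pixel); millisecond and degree inputs are
#' converted at construction so that downstream code never mixes units.
#'
#' @param tr Repetition time. Seconds unless `units = "ms"`.
#' @param te Echo times, strictly increasing, all positive and smaller than
#'   `tr`. Seconds unless `units = "ms"`.
#' @param flip_angle Excitation flip angle, in `(0, pi)`. Radians unless
#'   `angle_units = "deg"`.
#' @param bandwidth Receiver bandwidth per echo in Hz/pixel; recycled to the
#'   number of echoes if scalar.
#' @param flow_compensated Logical metadata flag; does not affect any
#'   computation.
#' @param units Time units of `tr` and `te`: `"s"` (default) or `"ms"`.
#' @param angle_units `"rad"` (default) or `"deg"`.
#'
#' @return An object of class `sequence_params`: a list with elements
#'   `tr` (s), `te` (s), `flip_angle` (rad), `bandwidth` (Hz/pixel),
#'   `flow_compensated`.
#' @examples
#' # the reference dual-echo protocol: TR 28 ms, TE 7.63/22.14 ms, 20 deg
#' sequence_params(28, c(7.63, 22.14), 20, 190, units = "ms",
#'                 angle_units = "deg")
#' @export
sequence_params <- function(tr, te, flip_angle, bandwidth = 190,
                            flow_compensated = FALSE,
                            units = c("s", "ms"),
                            angle_units = c("rad", "deg")) {
  units <- match.arg(units)
  angle_units <- match.arg(angle_units)
  if (units == "ms") {
    tr <- tr / 1000
    te <- te / 1000
  }
  if (angle_units == "deg") flip_angle <- flip_angle * pi / 180
  te <- as.numeric(te)
  bandwidth <- rep_len(as.numeric(bandwidth), length(te))
  if (!is.numeric(tr) || length(tr) != 1L || tr <= 0)
    stop("'tr' must be a single positive time", call. = FALSE)
  if (length(te) < 1L || any(te <= 0) || any(te >= tr))
    stop("'te' must be positive and smaller than 'tr'", call. = FALSE)
  if (is.unsorted(te, strictly = TRUE))
    stop("'te' must be strictly increasing", call. = FALSE)
  if (length(flip_angle) != 1L || flip_angle <= 0 || flip_angle >= pi)
    stop("'flip_angle' must lie in (0, pi) radians", call. = FALSE)
  if (any(bandwidth <= 0))
    stop("'bandwidth' must be positive", call. = FALSE)
  structure(
    list(tr = tr, te = te, flip_angle = flip_angle, bandwidth = bandwidth,
         flow_compensated = isTRUE(flow_compensated)),
    class = "sequence_params"
  )
}

#' @export
print.sequence_params <- function(x, ...) {
  cat(sprintf(
    "Spoiled GRE: TR %.4g ms, TE {%s} ms, flip %.4g deg, BW {%s} Hz/px\n",
    x$tr * 1000, paste(signif(x$te * 1000, 5), collapse = ", "),
    x$flip_angle * 180 / pi, paste(signif(x$bandwidth, 5), collapse = ", ")))
  invisible(x)
}

#' Default single-echo / dual-echo acquisition pair
#'
#' The reference 3 T protocol: a single-echo GRE (TR 14 ms, TE 7.63 ms,
#' flip 2 degrees) plus a dual-echo GRE at doubled repetition time
#' (TR 28 ms, TE 7.63 and 22.14 ms, flip 20 degrees), both at
#' 190 Hz/pixel receiver bandwidth.
#'
#' @return A list with elements `single` and `dual`, both `sequence_params`.
#' @export
default_sequences <- function() {
  list(
    single = sequence_params(14, 7.63, 2, 190, flow_compensated = TRUE,
                             units = "ms", angle_units = "deg"),
    dual = sequence_params(28, c(7.63, 22.14), 20, c(190, 190),
                           flow_compensated = TRUE,
                           units = "ms", angle_units = "deg")
  )
}

#' Voxelwise tissue parameter maps
#'
#' Ground-truth or estimated physical parameters on a common 3D grid. The
#' `pd` map is the product of coil sensitivity magnitude and equilibrium
#' magnetization (|K| M0); the coil phase is folded into `phi0`.
#'
#' @param r1 3D array of longitudinal relaxation rates, 1/s, non-negative.
#' @param r2star 3D array of effective transverse rates, 1/s, non-negative.
#' @param pd 3D array of |K| M0, arbitrary units, non-negative.
#' @param delta_b 3D array of local field offsets in Tesla (default 0).
#' @param phi0 3D array of RF-induced phase in radians (default 0).
#' @param gyro Gyromagnetic ratio in rad/s/T (default: proton).
#' @param voxel_size Voxel edge lengths in mm, length 3.
#'
#' @return An object of class `tissue_maps`.
#' @export
tissue_maps <- function(r1, r2star, pd, delta_b = NULL, phi0 = NULL,
                        gyro = 2.6752218744e8, voxel_size = c(1, 1, 1)) {
  dm <- dim(r1)
  if (is.null(dm) || length(dm) != 3L)
    stop("'r1' must be a 3D array", call. = FALSE)
  if (is.null(delta_b)) delta_b <- array(0, dm)
  if (is.null(phi0)) phi0 <- array(0, dm)
  for (nm in c("r2star", "pd", "delta_b", "phi0")) {
    v <- get(nm)
    if (!identical(dim(v), dm))
      stop(sprintf("grid shape of '%s' differs from 'r1'", nm), call. = FALSE)
  }
  if (any(r1 < 0, na.rm = TRUE) || any(r2star < 0, na.rm = TRUE) ||
      any(pd < 0, na.rm = TRUE))
    stop("'r1', 'r2star' and 'pd' must be non-negative", call. = FALSE)
  structure(
    list(r1 = r1, r2star = r2star, pd = pd, delta_b = delta_b, phi0 = phi0,
         gyro = gyro, voxel_size = as.numeric(voxel_size)),
    class = "tissue_maps"
  )
}

#' Acquired (or simulated) echo volumes of one sequence
#'
#' @param magnitude List of 3D arrays, one per echo, non-negative.
#' @param params The `sequence_params` the volumes were acquired with.
#' @param phase Optional list of 3D phase arrays in (-pi, pi].
#' @param voxel_size Voxel edge lengths in mm.
#'
#' @return An object of class `echo_volume_set`.
#' @export
echo_volume_set <- function(magnitude, params, phase = NULL,
                            voxel_size = c(1, 1, 1)) {
  if (!inherits(params, "sequence_params"))
    stop("'params' must be a sequence_params object", call. = FALSE)
  if (!is.list(magnitude)) magnitude <- list(magnitude)
  if (length(magnitude) != length(params$te))
    stop("number of magnitude volumes must equal number of echo times",
         call. = FALSE)
  dm <- dim(magnitude[[1]])
  if (is.null(dm) || length(dm) != 3L)
    stop("magnitude volumes must be 3D arrays", call. = FALSE)
  for (m in magnitude)
    if (!identical(dim(m), dm))
      stop("all magnitude volumes must share one grid shape", call. = FALSE)
  if (!is.null(phase)) {
    if (!is.list(phase)) phase <- list(phase)
    if (length(phase) != length(magnitude))
      stop("'phase', when present, must have one volume per echo",
           call. = FALSE)
    for (p in phase)
      if (!identical(dim(p), dm))
        stop("phase volumes must share the magnitude grid shape",
             call. = FALSE)
  }
  structure(
    list(magnitude = magnitude, phase = phase, params = params,
         voxel_size = as.numeric(voxel_size)),
    class = "echo_volume_set"
  )
}

#' @export
print.echo_volume_set <- function(x, ...) {
  dm <- dim(x$magnitude[[1]])
  cat(sprintf("Echo volume set: %d echo(es), grid %s, %s phase\n",
              length(x$magnitude), paste(dm, collapse = "x"),
              if (is.null(x$phase)) "no" else "with"))
  print(x$params)
  invisible(x)
}
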