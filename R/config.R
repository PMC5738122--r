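# JSON sidecar and run-configuration handling. Times are accepted in
# milliseconds and angles in degrees in the sidecars (the scanner
# convention) and converted to SI at parse time; everything internal is
# seconds and radians.

.affine_equal <- function(a, b, tol = 1e-4) {
  if (is.null(a) || is.null(b)) return(TRUE)
  max(abs(a - b)) <= tol
}

#' Read an acquisition protocol sidecar
#'
#' The sidecar is a JSON file describing the acquired sequences and their
#' echo volume files:
#' \preformatted{
#' {"sequences": [
#'   {"role": "single", "tr_ms": 14, "te_ms": [7.63], "flip_deg": 2,
#'    "bandwidth_hz": [190], "magnitude_files": ["single_e1.nii.gz"]},
#'   {"role": "dual", "tr_ms": 28, "te_ms": [7.63, 22.14], "flip_deg": 20,
#'    "bandwidth_hz": [190, 190],
#'    "magnitude_files": ["dual_e1.nii.gz", "dual_e2.nii.gz"]}]}
#' }
#' File paths are resolved relative to the sidecar location. Echoes given
#' out of order are reordered ascending with a notice; NIfTI affines must
#' agree across echoes to 1e-4; a missing file or an echo time at or beyond
#' the repetition time is an error naming the offending field.
#'
#' @param path Path to the sidecar JSON.
#' @return Named list (by role) of [echo_volume_set]s.
#' @export
read_protocol <- function(path) {
  if (!file.exists(path)) stop("no such sidecar: ", path, call. = FALSE)
  js <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  if (is.null(js$sequences) || !length(js$sequences))
    stop("sidecar has no 'sequences' entry: ", path, call. = FALSE)
  base <- dirname(normalizePath(path))
  out <- list()
  for (sq in js$sequences) {
    for (f in c("role", "tr_ms", "te_ms", "flip_deg", "magnitude_files"))
      if (is.null(sq[[f]]))
        stop("sidecar sequence is missing field '", f, "'", call. = FALSE)
    te <- as.numeric(sq$te_ms)
    files <- as.character(sq$magnitude_files)
    if (length(files) != length(te))
      stop("field 'magnitude_files' must have one file per echo time",
           call. = FALSE)
    if (any(te >= sq$tr_ms))
      stop("field 'te_ms' has echoes at or beyond 'tr_ms'", call. = FALSE)
    if (is.unsorted(te, strictly = TRUE)) {
      o <- order(te)
      te <- te[o]; files <- files[o]
      message("sidecar '", sq$role,
              "': echoes were out of order and have been sorted by TE")
    }
    bw <- if (is.null(sq$bandwidth_hz)) 190 else as.numeric(sq$bandwidth_hz)
    params <- sequence_params(sq$tr_ms, te, sq$flip_deg, bw,
                              flow_compensated =
                                isTRUE(sq$flow_compensated),
                              units = "ms", angle_units = "deg")
    vols <- list(); aff <- NULL; vs <- NULL
    for (i in seq_along(files)) {
      fp <- file.path(base, files[i])
      if (!file.exists(fp))
        stop("missing echo file (field 'magnitude_files'): ", fp,
             call. = FALSE)
      v <- read_nifti(fp)
      if (is.null(vs)) {
        vs <- attr(v, "voxel_size"); aff <- attr(v, "affine")
      } else if (!.affine_equal(aff, attr(v, "affine"))) {
        stop("NIfTI affines disagree across echoes of sequence '",
             sq$role, "'", call. = FALSE)
      }
      vols[[i]] <- v
    }
    out[[sq$role]] <- echo_volume_set(vols, params, voxel_size = vs)
  }
  out
}

# md5 digest of an R object via its canonical JSON serialization.
.param_hash <- function(x) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(x, tf, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tf))
}

#' Write a quantitative map bundle to disk
#'
#' Writes `r1.nii.gz`, `r2star.nii.gz`, `pd.nii.gz` and `mask.nii.gz`
#' (units in the header description field) plus a `provenance.json`
#' sidecar naming every input digest, the parameter hash, software
#' version and seed.
#'
#' @param bundle A [qmap_bundle].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "qmap_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vs <- bundle$voxel_size
  na0 <- function(x) { x[!is.finite(x)] <- 0; x }
  write_nifti(na0(bundle$r1), file.path(dir, "r1.nii.gz"), vs,
              "R1 map [1/s]; invalid voxels 0, see mask")
  write_nifti(na0(bundle$r2star), file.path(dir, "r2star.nii.gz"), vs,
              "R2* map [1/s]; invalid voxels 0, see mask")
  write_nifti(na0(bundle$pd), file.path(dir, "pd.nii.gz"), vs,
              "PD map [a.u.]; invalid voxels 0, see mask")
  write_nifti(bundle$mask, file.path(dir, "mask.nii.gz"), vs,
              "validity mask [0 ok; stage failure codes 1-6]")
  jsonlite::write_json(bundle$provenance,
                       file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a quantitative map bundle from disk
#'
#' @param dir Directory written by [write_bundle()].
#' @return A [qmap_bundle]; voxels with non-zero mask code carry `NA`.
#' @export
read_bundle <- function(dir) {
  r1 <- read_nifti(file.path(dir, "r1.nii.gz"))
  r2s <- read_nifti(file.path(dir, "r2star.nii.gz"))
  pd <- read_nifti(file.path(dir, "pd.nii.gz"))
  mask <- read_nifti(file.path(dir, "mask.nii.gz"))
  bad <- mask != 0
  r1[bad] <- NA_real_; r2s[bad] <- NA_real_; pd[bad] <- NA_real_
  prov_path <- file.path(dir, "provenance.json")
  prov <- if (file.exists(prov_path))
    jsonlite::fromJSON(prov_path, simplifyVector = TRUE) else list()
  vs <- attr(r1, "voxel_size")
  qmap_bundle(unclass_array(r1), unclass_array(r2s), unclass_array(pd),
              array(as.integer(mask), dim(mask)),
              voxel_size = vs, provenance = prov)
}

# strip reader attributes so bundles compare cleanly
unclass_array <- function(x) {
  attributes(x) <- list(dim = dim(x))
  x
}

#' Run the full reconstruction from a configuration
#'
#' Orchestrates the end-to-end pipeline from files on disk: reads the
#' protocol sidecar, optional transmit/receive/susceptibility volumes,
#' denoises when requested, reconstructs the maps and writes them with
#' full provenance (input digests, parameter hash, version, seed).
#' Identical configuration and inputs give identical outputs.
#'
#' @param config Path to a JSON run configuration, or an equivalent named
#'   list. Fields: `protocol` (sidecar path), optional `b1_file`,
#'   `receive_file`, `qsm_file`, `denoise` (logical), `mnlm` (list with
#'   any of `kappa`, `rho`, `sigma_filter`, `max_radius`), `noise_sigma`
#'   (scalar, for the denoiser), `output_dir`, `seed`. Relative paths are
#'   resolved against the configuration file location.
#' @return The [qmap_bundle], invisibly; maps are written to `output_dir`
#'   when it is set.
#' @export
run_resume <- function(config) {
  base <- "."
  if (is.character(config)) {
    base <- dirname(normalizePath(config))
    config <- jsonlite::fromJSON(config, simplifyVector = TRUE)
  }
  if (is.null(config$protocol))
    stop("configuration needs a 'protocol' sidecar path", call. = FALSE)
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (grepl("^(/|~)", p) || file.exists(p)) p else file.path(base, p)
  }
  proto_path <- resolve(config$protocol)
  seqs <- read_protocol(proto_path)
  if (is.null(seqs$single) || is.null(seqs$dual))
    stop("protocol must declare sequences with roles 'single' and 'dual'",
         call. = FALSE)
  inputs <- c(protocol = proto_path)
  grab <- function(field) {
    p <- resolve(config[[field]])
    if (is.null(p)) return(NULL)
    inputs[[field]] <<- p
    unclass_array(read_nifti(p))
  }
  b1 <- grab("b1_file")
  receive <- grab("receive_file")
  qsm <- grab("qsm_file")
  mn <- if (is.null(config$mnlm)) NULL else
    do.call(mnlm_params, config$mnlm)
  noise <- config$noise_sigma
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)

  prov <- list(
    inputs = as.list(vapply(inputs, function(p) unname(tools::md5sum(p)),
                            character(1))),
    parameter_hash = .param_hash(config[setdiff(names(config),
                                                "output_dir")]),
    seed = seed
  )
  bundle <- fit_resume(seqs$single, seqs$dual, b1 = b1, receive = receive,
                       denoise = isTRUE(config$denoise), noise = noise,
                       mnlm = mn, qsm = qsm,
                       general_tr = isTRUE(config$general_tr),
                       provenance = prov)
  if (!is.null(config$output_dir))
    write_bundle(bundle, resolve(config$output_dir))
  invisible(bundle)
}

#' Parse a phantom specification from JSON
#'
#' @param path JSON file with fields mirroring [phantom_spec()] (`dim`,
#'   `voxel_size`, `regions`, optional `coil_coef`, `b1_coef`,
#'   `noise_sigma`, `seed`).
#' @return A [phantom_spec].
#' @export
phantom_spec_from_json <- function(path) {
  js <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  for (f in c("dim", "regions"))
    if (is.null(js[[f]]))
      stop("phantom spec is missing field '", f, "'", call. = FALSE)
  phantom_spec(js$dim,
               voxel_size = if (is.null(js$voxel_size)) c(1, 1, 1)
                            else js$voxel_size,
               regions = js$regions,
               coil_coef = js$coil_coef, b1_coef = js$b1_coef,
               noise_sigma = if (is.null(js$noise_sigma)) 0
                             else js$noise_sigma,
               seed = if (is.null(js$seed)) 1L else js$seed)
}

#' Write a simulated acquisition to disk
#'
#' Writes the echo volumes of both simulated sequences, the ground-truth
#' parameter maps and a protocol sidecar compatible with
#' [read_protocol()] / [run_resume()].
#'
#' @param sim Output of [simulate_protocol()].
#' @param dir Output directory.
#' @return The sidecar path, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vs <- sim$single$voxel_size
  seq_entry <- function(evs, role, prefix) {
    files <- sprintf("%s_e%d.nii.gz", prefix, seq_along(evs$magnitude))
    for (i in seq_along(files))
      write_nifti(evs$magnitude[[i]], file.path(dir, files[i]), vs,
                  sprintf("%s GRE magnitude, echo %d [a.u.]", role, i))
    p <- evs$params
    list(role = role, tr_ms = p$tr * 1000, te_ms = p$te * 1000,
         flip_deg = p$flip_angle * 180 / pi, bandwidth_hz = p$bandwidth,
         flow_compensated = p$flow_compensated,
         magnitude_files = files)
  }
  sidecar <- list(sequences = list(
    seq_entry(sim$single, "single", "single"),
    seq_entry(sim$dual, "dual", "dual")))
  write_nifti(sim$truth$r1, file.path(dir, "truth_r1.nii.gz"), vs,
              "ground-truth R1 [1/s]")
  write_nifti(sim$truth$r2star, file.path(dir, "truth_r2star.nii.gz"), vs,
              "ground-truth R2* [1/s]")
  write_nifti(sim$truth$pd, file.path(dir, "truth_pd.nii.gz"), vs,
              "ground-truth |K|M0 [a.u.]")
  write_nifti(sim$b1, file.path(dir, "truth_b1.nii.gz"), vs,
              "ground-truth B1+ factor")
  write_nifti(sim$support * 1, file.path(dir, "support.nii.gz"), vs,
              "phantom support mask")
  sc <- file.path(dir, "protocol.json")
  jsonlite::write_json(sidecar, sc, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(sc)
}
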