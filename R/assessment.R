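#' Cartesian-product ensemble of protocol realizations
#'
#' With every sequence of the protocol acquired twice, the three magnitude
#' inputs (single echo `s0`, dual echoes `s1`, `s2`) can each be drawn from
#' either repetition, giving `2^3 = 8` complete relaxometry realizations.
#' Each combination is reconstructed with [fit_resume()]; the spread across
#' realizations measures reproducibility (uncorrelated image noise, scanner
#' amplification drift, temperature fluctuations, ...).
#'
#' Combinations are ordered by binary counting with repetition A coded 0:
#' combination `k` (0..7) takes `s0` from B iff bit 0 of `k` is set, `s1`
#' iff bit 1, `s2` iff bit 2.
#'
#' @param rep_a,rep_b Two protocol repetitions: lists with elements
#'   `single` and `dual` ([echo_volume_set]s sharing geometry and
#'   sequence parameters).
#' @param ... Passed to [fit_resume()] (for example `b1`).
#' @return An object of class `protocol_ensemble`: list with `bundles`
#'   (8 [qmap_bundle]s) and `combos` (8 x 3 matrix of repetition indices,
#'   0 = A, 1 = B, columns `s0`, `s1`, `s2`).
#' @export
build_ensemble <- function(rep_a, rep_b, ...) {
  for (r in list(rep_a, rep_b))
    if (!all(c("single", "dual") %in% names(r)))
      stop("each repetition needs elements 'single' and 'dual'",
           call. = FALSE)
  dma <- dim(rep_a$single$magnitude[[1]])
  for (evs in list(rep_a$dual, rep_b$single, rep_b$dual)) {
    dmb <- dim(evs$magnitude[[1]])
    if (!identical(dma, dmb))
      stop(sprintf("geometry mismatch: %s vs %s",
                   paste(dma, collapse = "x"),
                   paste(dmb, collapse = "x")), call. = FALSE)
  }
  if (length(rep_a$dual$magnitude) < 2L)
    stop("dual sequence must have at least two echoes", call. = FALSE)
  combos <- cbind(s0 = bitwAnd(0:7, 1L) > 0L,
                  s1 = bitwAnd(0:7, 2L) > 0L,
                  s2 = bitwAnd(0:7, 4L) > 0L)
  bundles <- vector("list", 8L)
  for (k in 1:8) {
    single <- rep_a$single
    single$magnitude[[1]] <-
      (if (combos[k, "s0"]) rep_b else rep_a)$single$magnitude[[1]]
    dual <- rep_a$dual
    dual$magnitude[[1]] <-
      (if (combos[k, "s1"]) rep_b else rep_a)$dual$magnitude[[1]]
    dual$magnitude[[2]] <-
      (if (combos[k, "s2"]) rep_b else rep_a)$dual$magnitude[[2]]
    bundles[[k]] <- fit_resume(single, dual, ...)
  }
  structure(list(bundles = bundles, combos = combos * 1L),
            class = "protocol_ensemble")
}

# Range of map values within a mask; optionally trimmed of the extreme
# 0.1 percentiles to resist single-voxel outliers.
.mask_range <- function(v, clip = TRUE) {
  v <- v[is.finite(v)]
  if (!length(v)) return(NA_real_)
  if (clip && length(v) >= 10L) {
    qs <- stats::quantile(v, c(0.001, 0.999), names = FALSE, type = 7)
    diff(qs)
  } else {
    diff(range(v))
  }
}

#' Voxelwise reproducibility statistics of an ensemble
#'
#' Computes voxelwise mean and standard deviation maps across the ensemble
#' realizations and summarizes each map by the median standard deviation
#' within the mask, normalized to the range of the corresponding mean map
#' (in percent). The range is reported both with the extreme 0.1
#' percentiles discarded (robust variant, the headline number) and
#' unclipped. The sample standard deviation uses the n-1 convention.
#'
#' @param ens A `protocol_ensemble`, or a plain list of [qmap_bundle]s.
#' @param mask Logical 3D array (for example a brain mask); must be
#'   non-empty.
#' @param maps Which maps to summarize.
#' @return An object of class `repro_report`: per map, `mu` and `sigma`
#'   arrays plus a `summary` data frame with columns `map`,
#'   `normalized_median_sigma` (percent, clipped range),
#'   `normalized_median_sigma_unclipped`, `median_sigma`, `range_mu`,
#'   `range_mu_unclipped`, `n_realizations`.
#' @export
repro_stats <- function(ens, mask, maps = c("r1", "r2star", "pd")) {
  bundles <- if (inherits(ens, "protocol_ensemble")) ens$bundles else ens
  n <- length(bundles)
  if (n < 2L) stop("need at least two realizations", call. = FALSE)
  if (!any(mask)) stop("empty mask", call. = FALSE)
  dm <- dim(bundles[[1]]$r1)
  out <- list()
  rows <- list()
  for (mp in maps) {
    V <- vapply(bundles, function(b) as.numeric(b[[mp]]),
                numeric(prod(dm)))
    mu <- rowMeans(V)
    sg <- sqrt(pmax(0, rowSums((V - mu)^2) / (n - 1)))
    mu <- array(mu, dm); sg <- array(sg, dm)
    med <- stats::median(sg[mask], na.rm = TRUE)
    rg <- .mask_range(mu[mask], clip = TRUE)
    rgu <- .mask_range(mu[mask], clip = FALSE)
    rows[[mp]] <- data.frame(
      map = mp,
      normalized_median_sigma = 100 * med / rg,
      normalized_median_sigma_unclipped = 100 * med / rgu,
      median_sigma = med, range_mu = rg, range_mu_unclipped = rgu,
      n_realizations = n)
    out[[mp]] <- list(mu = mu, sigma = sg)
  }
  structure(list(maps = out, summary = do.call(rbind, c(rows,
                 make.row.names = FALSE))),
            class = "repro_report")
}

#' @export
print.repro_report <- function(x, ...) {
  cat("Reproducibility report (median sigma / range of mu, percent):\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Voxelwise accuracy against a reference reconstruction
#'
#' Difference-magnitude maps `delta = |map - reference|` voxelwise, with
#' the median within the mask normalized to the range of the reference map
#' (clipped and unclipped variants, in percent). Grids must be
#' co-registered; no resampling is performed.
#'
#' @param bundle,reference [qmap_bundle]s on the same grid.
#' @param mask Logical 3D array.
#' @param maps Which maps to compare.
#' @return An object of class `accuracy_report`: per map a `delta` array,
#'   plus a `summary` data frame with `normalized_median_delta` (percent)
#'   and companions as in [repro_stats()].
#' @export
accuracy_map <- function(bundle, reference, mask,
                         maps = c("r1", "r2star", "pd")) {
  dm <- dim(bundle$r1)
  if (!identical(dm, dim(reference$r1)))
    stop("bundle and reference grids differ", call. = FALSE)
  if (!identical(dm, dim(mask)))
    stop("mask grid differs from the maps", call. = FALSE)
  if (!any(mask)) stop("empty mask", call. = FALSE)
  out <- list(); rows <- list()
  for (mp in maps) {
    delta <- abs(bundle[[mp]] - reference[[mp]])
    med <- stats::median(delta[mask], na.rm = TRUE)
    rg <- .mask_range(reference[[mp]][mask], clip = TRUE)
    rgu <- .mask_range(reference[[mp]][mask], clip = FALSE)
    rows[[mp]] <- data.frame(
      map = mp,
      normalized_median_delta = 100 * med / rg,
      normalized_median_delta_unclipped = 100 * med / rgu,
      median_delta = med, range_reference = rg,
      range_reference_unclipped = rgu)
    out[[mp]] <- delta
  }
  structure(list(delta = out, summary = do.call(rbind, c(rows,
                 make.row.names = FALSE))),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat("Accuracy report (median |difference| / reference range, percent):\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Region-of-interest statistics
#'
#' Mean and standard deviation of a map within each labelled region.
#' Empty regions are omitted with a notice. When `normalize_to` names a
#' label (for proton density, typically the CSF region), the map is first
#' divided by the mean over that region, so the reference region maps to
#' exactly 1.
#'
#' @param map 3D array.
#' @param rois Integer (or factor-like) 3D label array, 0 = background.
#' @param normalize_to Optional label used as normalization reference.
#' @return A data frame with columns `label`, `n`, `mean`, `sd`.
#' @export
roi_stats <- function(map, rois, normalize_to = NULL) {
  if (!identical(dim(map), dim(rois)))
    stop("map and ROI grids differ", call. = FALSE)
  labels <- sort(unique(rois[rois != 0]))
  if (!is.null(normalize_to)) {
    ref <- map[rois == normalize_to]
    ref <- ref[is.finite(ref)]
    if (!length(ref))
      stop("normalization region is empty", call. = FALSE)
    map <- map / mean(ref)
  }
  rows <- lapply(labels, function(lb) {
    v <- map[rois == lb]
    v <- v[is.finite(v)]
    if (!length(v)) {
      message("ROI ", lb, " is empty after masking; omitted")
      return(NULL)
    }
    data.frame(label = lb, n = length(v), mean = mean(v),
               sd = if (length(v) > 1L) stats::sd(v) else 0)
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}
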