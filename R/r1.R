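#' Plus-branch selection condition for the closed-form R1 solution
#'
#' The quadratic relating the TE = 0 signal ratio of the two acquisitions to
#' the recovery factor `E = exp(-TR0 * R1)` has two roots. The physical root
#' is the "plus" one exactly when
#' \deqn{\cos\theta_1 \ge \frac{1 + \cos\theta_2 \, E (2 + E)}
#'                              {1 + E (2 + \cos\theta_2 \, E)}.}
#' `branch_threshold()` returns the right-hand side; `plus_branch_ok()`
#' evaluates the inequality. For `E > exp(-1)` (repetition time shorter than
#' T1) the sufficient condition `theta1 < 0.47 * theta2` guarantees the plus
#' branch for every `theta2` in `(0, pi)`.
#'
#' @param e10 Recovery factor(s) `E` in `(0, 1)`.
#' @param theta2 Flip angle(s) of the double-TR sequence, radians.
#' @param theta1 Flip angle(s) of the single-TR sequence, radians.
#' @return `branch_threshold`: the threshold on `cos(theta1)`;
#'   `plus_branch_ok`: logical.
#' @export
branch_threshold <- function(e10, theta2) {
  (1 + cos(theta2) * e10 * (2 + e10)) / (1 + e10 * (2 + cos(theta2) * e10))
}

#' @rdname branch_threshold
#' @export
plus_branch_ok <- function(e10, theta1, theta2) {
  cos(theta1) >= branch_threshold(e10, theta2)
}

#' Flip-angle ratio along the branch-selection boundary
#'
#' For a given recovery factor `E`, solves the equality case of the
#' plus-branch condition for `theta1` and returns the ratio
#' `theta1 / theta2`. The infimum of this ratio over `theta2 in (0, pi)` at
#' `E = exp(-1)` is the bound (about 0.474, i.e. above 0.47) behind the
#' `theta1 < 0.47 * theta2` sufficient rule.
#'
#' @param theta2 Vector of flip angles in `(0, pi)`, radians.
#' @param e10 Recovery factor, default `exp(-1)`.
#' @return Vector of boundary ratios `theta1 / theta2`.
#' @export
branch_boundary_ratio <- function(theta2, e10 = exp(-1)) {
  g <- branch_threshold(e10, theta2)
  acos(pmin(1, pmax(-1, g))) / theta2
}

# Forward model for the TE=0 ratio: q(E) at flip angles th1, th2, with the
# dual sequence at TR ratio `g` (recovery factor E^g; g = 2 by default).
.q_forward <- function(e10, theta1, theta2, g = 2) {
  k <- sin(theta1) / sin(theta2)
  eg <- e10^g
  k * (1 - eg * cos(theta2)) * (1 - e10) /
    ((1 - eg) * (1 - e10 * cos(theta1)))
}

#' Closed-form recovery-factor solution from the TE = 0 signal ratio
#'
#' Solves voxelwise for `E = exp(-TR0 * R1)` given the ratio
#' `q = S1 / S2` of the extrapolated TE = 0 magnitudes of the single-TR and
#' double-TR acquisitions. With the doubled repetition time the relation is
#' a quadratic `C E^2 - R E - (q - k) = 0` with `k = sin(theta1)/sin(theta2)`,
#' `R = q (1 - cos(theta1))`, `C = q cos(theta1) - k cos(theta2)`; the
#' branch is selected by the plus-branch condition (see
#' [branch_threshold()]).
#'
#' Branch handling: when `theta1 < 0.47 * theta2` everywhere, the plus
#' branch is taken unconditionally (valid whenever TR0 < T1). Otherwise
#' both roots are computed; a root is self-consistent when it lies in
#' `(0, 1)` and the plus-branch condition evaluated at that root agrees
#' with the branch it came from. A unique self-consistent root is kept;
#' none or two leave the voxel masked as ambiguous. Voxels with negative
#' discriminant, a root outside `(0, 1)`, or `q = k` (the fully-relaxed
#' boundary `E = 0`) are masked invalid. Near-vanishing quadratic
#' coefficient (`|C| < tol * |R|`) falls back to the linear root
#' `E = (k - q) / R`; the smaller quadratic root is always computed by the
#' numerically stable conjugate form.
#'
#' @param q 3D array (or vector) of TE = 0 magnitude ratios `S1 / S2`.
#' @param theta1,theta2 Flip angles in radians; scalars or arrays matching
#'   `q` (voxelwise effective flip angles after B1 correction).
#' @param tol_c Relative tolerance triggering the linear fallback.
#' @param tr_ratio Repetition-time ratio of the two sequences. Values other
#'   than 2 switch to a per-voxel numerical root finder (general-TR mode).
#' @return An object of class `r1_solution`: list with `e10` (array, `NA`
#'   where invalid), `branch` (integer codes: 1 plus, 2 minus, 3 linear
#'   fallback, 0 invalid), `valid` (logical) and `code` (failure codes:
#'   0 ok, 3 negative discriminant, 4 root outside (0,1) or boundary,
#'   5 ambiguous branch).
#' @export
solve_e10 <- function(q, theta1, theta2, tol_c = 1e-12, tr_ratio = 2) {
  dm <- dim(q)
  if (any(theta1 <= 0) || any(theta1 >= pi) ||
      any(theta2 <= 0) || any(theta2 >= pi))
    stop("flip angles must lie in (0, pi)", call. = FALSE)
  if (any(theta1 >= 0.47 * theta2))
    warning("theta1 >= 0.47 * theta2 at some voxels: branch selection may ",
            "be ambiguous; roots are disambiguated self-consistently",
            call. = FALSE)
  if (abs(tr_ratio - 2) > 1e-9)
    return(.solve_e10_general(q, theta1, theta2, tr_ratio))

  n <- length(q)
  q <- as.numeric(q)
  th1 <- rep_len(as.numeric(theta1), n)
  th2 <- rep_len(as.numeric(theta2), n)
  k <- sin(th1) / sin(th2)
  a <- 1 - cos(th1)
  R <- q * a
  C <- q * cos(th1) - k * cos(th2)
  code <- integer(n)
  e <- rep(NA_real_, n)
  branch <- integer(n)

  finite <- is.finite(q) & q > 0
  boundary <- finite & abs(q - k) <= 1e-13 * pmax(abs(k), abs(q))
  code[!finite] <- 4L
  code[boundary] <- 4L

  lin <- finite & !boundary & abs(C) < tol_c * pmax(abs(R), tol_c)
  if (any(lin)) {
    el <- (k[lin] - q[lin]) / R[lin]
    okl <- is.finite(el) & el > 0 & el < 1
    e[lin][okl] <- el[okl]
    branch[lin][okl] <- 3L
    code[lin][!okl] <- 4L
  }

  quad <- finite & !boundary & !lin
  if (any(quad)) {
    disc <- R^2 + 4 * C * (q - k)
    neg <- quad & disc < 0
    code[neg] <- 3L
    qq <- quad & disc >= 0
    if (any(qq)) {
      s <- sqrt(disc[qq])
      # R >= 0 for q > 0, so R + s never cancels
      eplus <- (R[qq] + s) / (2 * C[qq])
      eminus <- 2 * (k[qq] - q[qq]) / (R[qq] + s)
      inp <- is.finite(eplus) & eplus > 0 & eplus < 1
      inm <- is.finite(eminus) & eminus > 0 & eminus < 1
      suff <- th1[qq] < 0.47 * th2[qq]
      # self-consistency of each root against the branch condition
      consp <- inp & plus_branch_ok(eplus, th1[qq], th2[qq])
      consm <- inm & !plus_branch_ok(eminus, th1[qq], th2[qq])
      pick <- ifelse(suff, ifelse(inp, 1L, 0L),
              ifelse(consp & !consm, 1L,
              ifelse(consm & !consp, 2L,
              ifelse(consp & consm, -1L,
              ifelse(inp & !inm, 1L, ifelse(inm & !inp, 2L, 0L))))))
      ei <- rep(NA_real_, sum(qq))
      ei[pick == 1L] <- eplus[pick == 1L]
      ei[pick == 2L] <- eminus[pick == 2L]
      e[qq] <- ei
      branch[qq] <- pmax(pick, 0L)
      codei <- integer(sum(qq))
      codei[pick == 0L] <- 4L
      codei[pick == -1L] <- 5L
      branch[qq][pick == -1L] <- 0L
      code[qq] <- codei
    }
  }
  valid <- code == 0L & !is.na(e)
  e[!valid] <- NA_real_
  shape <- function(x) if (is.null(dm)) x else array(x, dm)
  structure(
    list(e10 = shape(e), branch = shape(branch), valid = shape(valid),
         code = shape(code)),
    class = "r1_solution"
  )
}

# General TR-ratio mode: per-voxel root finding of q - q_forward(E) = 0 on
# (0, 1). Used when the dual sequence TR is not exactly twice the single
# one; slower, documented as a generalization beyond the closed form.
.solve_e10_general <- function(q, theta1, theta2, g) {
  dm <- dim(q)
  n <- length(q)
  q <- as.numeric(q)
  th1 <- rep_len(as.numeric(theta1), n)
  th2 <- rep_len(as.numeric(theta2), n)
  e <- rep(NA_real_, n)
  code <- integer(n)
  lo <- 1e-12; hi <- 1 - 1e-12
  for (i in seq_len(n)) {
    if (!is.finite(q[i]) || q[i] <= 0) { code[i] <- 4L; next }
    f <- function(E) q[i] - .q_forward(E, th1[i], th2[i], g)
    flo <- f(lo); fhi <- f(hi)
    if (!is.finite(flo) || !is.finite(fhi) || flo * fhi > 0) {
      code[i] <- 4L; next
    }
    e[i] <- stats::uniroot(f, c(lo, hi), tol = 1e-14)$root
  }
  valid <- code == 0L & !is.na(e)
  shape <- function(x) if (is.null(dm)) x else array(x, dm)
  structure(
    list(e10 = shape(e), branch = shape(ifelse(valid, 1L, 0L)),
         valid = shape(valid), code = shape(code)),
    class = "r1_solution"
  )
}

#' Longitudinal relaxation rate from the recovery factor
#'
#' Converts the recovery-factor solution to `R1 = -log(E) / TR0`. Voxels
#' with `E` outside the open interval `(0, 1)` are invalid.
#'
#' @param sol An `r1_solution` from [solve_e10()].
#' @param tr0 Repetition time of the single-echo sequence, seconds.
#' @return The `r1_solution` with an added 3D array `r1` (1/s, `NA` where
#'   invalid).
#' @export
r1_map <- function(sol, tr0) {
  stopifnot(inherits(sol, "r1_solution"), tr0 > 0)
  ok <- sol$valid & is.finite(sol$e10) & sol$e10 > 0 & sol$e10 < 1
  r1 <- -log(sol$e10) / tr0
  r1[!ok] <- NA_real_
  sol$r1 <- r1
  sol$valid <- ok
  sol
}

#' Proton-density map
#'
#' Inverts the double-TR steady-state amplitude for `PD = |K| M0`:
#' `PD = S2 * (1 - E^2 cos(theta2)) / (sin(theta2) * (1 - E^2))` with
#' `E = exp(-TR0 * R1)`. As `E -> 1` the denominator vanishes and the voxel
#' is masked invalid.
#'
#' @param s2 3D array of TE = 0 magnitudes of the double-TR sequence.
#' @param sol An `r1_solution`.
#' @param theta2 Flip angle of the double-TR sequence (radians); scalar or
#'   voxelwise array (after B1 correction).
#' @param tol Degeneracy tolerance on `1 - E^2`.
#' @return List with 3D arrays `pd` (`NA` where invalid) and logical
#'   `valid`.
#' @export
pd_map <- function(s2, sol, theta2, tol = 1e-12) {
  stopifnot(inherits(sol, "r1_solution"))
  e <- sol$e10
  den <- sin(theta2) * (1 - e^2)
  ok <- sol$valid & is.finite(s2) & is.finite(den) & abs(1 - e^2) > tol
  pd <- s2 * (1 - e^2 * cos(theta2)) / den
  pd[!ok] <- NA_real_
  list(pd = pd, valid = ok)
}
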