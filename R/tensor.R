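#' Nuclear quadrupole coupling tensor in the inertial axis system
#'
#' Traceless symmetric coupling tensor of one quadrupolar nucleus (here 14N,
#' spin 1) expressed in the principal inertial axes a, b, c.  For a nucleus
#' lying in the ab plane the out-of-plane couplings chi_ac and chi_bc vanish
#' by symmetry and only chi_ab survives off the diagonal.
#'
#' @param chi_aa,chi_bb Diagonal couplings in MHz.
#' @param chi_cc Diagonal coupling in MHz; defaults to `-(chi_aa + chi_bb)`
#'   (the Laplace relation).  If supplied it must satisfy the relation to
#'   within 1e-6 MHz.
#' @param chi_ab In-plane off-diagonal coupling in MHz.
#' @param nucleus Label, e.g. `"Na"` (amino) or `"Nr"` (ring).
#' @param spin Nuclear spin (only 1 is supported by the hyperfine code).
#' @return An object of class `quadrupole_tensor`.
#' @export
#' @examples
#' quadrupole_tensor(-3.2504, 1.3684, chi_ab = 1.43, nucleus = "Nr")
quadrupole_tensor <- function(chi_aa, chi_bb, chi_cc = -(chi_aa + chi_bb),
                              chi_ab = 0, nucleus = "N", spin = 1) {
  if (abs(chi_aa + chi_bb + chi_cc) > 1e-6) {
    stop("quadrupole tensor violates the Laplace relation chi_aa+chi_bb+chi_cc = 0")
  }
  structure(list(chi_aa = chi_aa, chi_bb = chi_bb, chi_cc = chi_cc,
                 chi_ab = chi_ab, nucleus = nucleus, spin = spin),
            class = "quadrupole_tensor")
}

#' @export
print.quadrupole_tensor <- function(x, ...) {
  cat(sprintf(
    "Quadrupole tensor [%s, I=%g]: chi_aa=%.4f chi_bb=%.4f chi_cc=%.4f chi_ab=%.4f MHz\n",
    x$nucleus, x$spin, x$chi_aa, x$chi_bb, x$chi_cc, x$chi_ab))
  invisible(x)
}

#' Tensor from the direct hyperfine parameters of fit
#'
#' Line-list fits determine the combinations `(3/2) chi_aa` and
#' `(chi_bb - chi_cc)/4` directly; the full diagonal is recovered from them
#' with the Laplace relation `chi_aa + chi_bb + chi_cc = 0`.
#'
#' @param three_halves_chi_aa The fitted `(3/2) chi_aa` in MHz.
#' @param quarter_bb_minus_cc The fitted `(chi_bb - chi_cc)/4` in MHz.
#' @param chi_ab Optional off-diagonal coupling in MHz.
#' @inheritParams quadrupole_tensor
#' @return A `quadrupole_tensor`.
#' @export
#' @examples
#' # amino nitrogen of 2-aminopyridine: chi_cc comes out at -4.203 MHz
#' tensor_from_fit_params(3.5854, 1.50413, nucleus = "Na")$chi_cc
tensor_from_fit_params <- function(three_halves_chi_aa, quarter_bb_minus_cc,
                                   chi_ab = 0, nucleus = "N", spin = 1) {
  chi_aa <- (2 / 3) * three_halves_chi_aa
  dd <- 4 * quarter_bb_minus_cc          # chi_bb - chi_cc
  chi_bb <- (-chi_aa + dd) / 2
  chi_cc <- (-chi_aa - dd) / 2
  quadrupole_tensor(chi_aa, chi_bb, chi_cc, chi_ab, nucleus, spin)
}

#' Direct fit parameters from a tensor
#'
#' Inverse of [tensor_from_fit_params()]; the round trip is lossless.
#'
#' @param t A `quadrupole_tensor`.
#' @return A list with `three_halves_chi_aa`, `quarter_bb_minus_cc`,
#'   `chi_ab`.
#' @export
fit_params_from_tensor <- function(t) {
  stopifnot(inherits(t, "quadrupole_tensor"))
  list(three_halves_chi_aa = 1.5 * t$chi_aa,
       quarter_bb_minus_cc = (t$chi_bb - t$chi_cc) / 4,
       chi_ab = t$chi_ab)
}

#' Rotate a planar quadrupole tensor about the c axis
#'
#' Similarity transform of the ab block by an in-plane axis rotation.  The
#' sign convention is that positive `theta` rotates the a axis towards b:
#' `chi'_aa = chi_aa cos^2(t) + chi_bb sin^2(t) + 2 chi_ab sin(t) cos(t)`.
#' Trace and eigenvalues are preserved.  This reproduces, for example, the
#' effect of the ~2 degree inertial-axis rotation caused by single
#' deuteration on a ring site.
#'
#' @param t A `quadrupole_tensor` with `chi_ac = chi_bc = 0`.
#' @param theta Rotation angle in degrees.
#' @return The rotated `quadrupole_tensor`.
#' @export
rotate_tensor <- function(t, theta) {
  stopifnot(inherits(t, "quadrupole_tensor"))
  th <- theta * pi / 180
  c2 <- cos(th)^2; s2 <- sin(th)^2; sc <- sin(th) * cos(th)
  aa <- t$chi_aa * c2 + t$chi_bb * s2 + 2 * t$chi_ab * sc
  bb <- t$chi_aa * s2 + t$chi_bb * c2 - 2 * t$chi_ab * sc
  ab <- (t$chi_bb - t$chi_aa) * sc + t$chi_ab * (c2 - s2)
  quadrupole_tensor(aa, bb, t$chi_cc, ab, t$nucleus, t$spin)
}

#' Uniformly scale a quadrupole tensor
#'
#' Multiplies every component by a positive factor, e.g. the empirical
#' factor that maps computed electric-field gradients onto experimental
#' couplings.  Tracelessness is preserved.
#'
#' @param t A `quadrupole_tensor`.
#' @param factor Positive dimensionless scale factor.
#' @return The scaled `quadrupole_tensor`.
#' @export
scale_tensor <- function(t, factor) {
  stopifnot(inherits(t, "quadrupole_tensor"))
  if (!is.finite(factor) || factor <= 0) stop("scale factor must be positive")
  quadrupole_tensor(t$chi_aa * factor, t$chi_bb * factor, t$chi_cc * factor,
                    t$chi_ab * factor, t$nucleus, t$spin)
}

#' Diagonalise a planar quadrupole tensor to its principal quadrupolar axes
#'
#' Diagonalises the 2x2 ab block; the third principal value is chi_cc.  The
#' principal z axis is assigned to the largest-magnitude eigenvalue and
#' `theta_za` is the angle between that axis and the inertial a axis,
#' reported as a magnitude in [0, 90] degrees (the signed value is kept in
#' the `theta_za_signed` field).  For a nitrogen in the molecular plane the
#' z axis tracks the bond direction (ring N: the CNC bisector; amino N: the
#' C-N bond), so `theta_za` carries structural information.
#'
#' @param t A `quadrupole_tensor` with `chi_ac = chi_bc = 0`.
#' @return An object of class `principal_tensor` with fields `chi_zz`,
#'   `chi_xx`, `chi_yy` (MHz), `theta_za`, `theta_za_signed` (degrees) and
#'   a logical `degenerate` flag set when the ab block is proportional to
#'   the identity (angle undefined, reported as 0).
#' @export
#' @examples
#' diagonalize_tensor(quadrupole_tensor(-3.2504, 1.3684, chi_ab = 1.43))
diagonalize_tensor <- function(t) {
  stopifnot(inherits(t, "quadrupole_tensor"))
  degenerate <- abs(t$chi_aa - t$chi_bb) < 1e-12 && abs(t$chi_ab) < 1e-12
  blk <- matrix(c(t$chi_aa, t$chi_ab, t$chi_ab, t$chi_bb), 2, 2)
  eig <- eigen(blk, symmetric = TRUE)
  vals <- eig$values            # decreasing
  cand <- c(vals, t$chi_cc)
  iz <- which.max(abs(cand))
  chi_zz <- cand[iz]
  if (iz == 3) {
    # out-of-plane coupling dominates: z is the c axis
    theta_signed <- 90
    others <- vals
  } else {
    v <- eig$vectors[, iz]
    theta_signed <- atan2(v[2], v[1]) * 180 / pi
    if (theta_signed > 90) theta_signed <- theta_signed - 180
    if (theta_signed < -90) theta_signed <- theta_signed + 180
    others <- c(vals[-iz], t$chi_cc)
  }
  if (degenerate) theta_signed <- 0
  # convention: x the in-plane (or remaining) value with larger magnitude
  others <- others[order(-abs(others))]
  structure(list(chi_zz = chi_zz, chi_xx = others[2], chi_yy = others[1],
                 theta_za = abs(theta_signed), theta_za_signed = theta_signed,
                 degenerate = degenerate),
            class = "principal_tensor")
}

#' @export
print.principal_tensor <- function(x, ...) {
  cat(sprintf(
    "Principal tensor: chi_zz=%.4f chi_yy=%.4f chi_xx=%.4f MHz, theta_za=%.2f deg%s\n",
    x$chi_zz, x$chi_yy, x$chi_xx, x$theta_za,
    if (x$degenerate) " (degenerate ab block)" else ""))
  invisible(x)
}

#' Correct the diagonalisation angle to the structural bond angle
#'
#' The angle `theta_za` obtained from tensor diagonalisation differs from
#' the structural bond-axis angle by a small, reliably computable amount.
#' Given the computed pair (`theta_za_calc`, `theta_str_calc`) the
#' experimental angle is corrected additively:
#' `theta_str = theta_za_exp + (theta_str_calc - theta_za_calc)`.
#'
#' @param theta_za_exp Experimental diagonalisation angle (degrees).
#' @param theta_za_calc Computed diagonalisation angle (degrees).
#' @param theta_str_calc Computed structural angle (degrees).
#' @return The corrected structural angle in degrees.
#' @export
theta_str_correction <- function(theta_za_exp, theta_za_calc, theta_str_calc) {
  theta_za_exp + (theta_str_calc - theta_za_calc)
}
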