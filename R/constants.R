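#' Conversion constant between rotational constants and moments of inertia
#'
#' The product of a rotational constant (MHz) and the corresponding principal
#' moment of inertia (u A^2): I_g = kappa / X for X in (A, B, C).  The default
#' value 505379.07 MHz u A^2 reproduces published inertial defects of
#' quasi-planar aromatics to about 1e-4 u A^2; it can be overridden in
#' [moments_from_constants()] for sensitivity studies.
#'
#' @format A length-1 numeric, MHz u A^2.
#' @export
inertia_conversion <- 505379.07

#' Rotational constants of one vibronic state
#'
#' @param A,B,C Rotational constants in MHz, with `A >= B >= C > 0`.
#' @param state_label Label of the vibronic state (e.g. `"0+"`, `"0-"`,
#'   `"ground"`).  The two inversion sublevels of an amine-inverting molecule
#'   are treated as independent states with their own constants.
#' @return An object of class `rotational_constants`.
#' @export
#' @examples
#' rotational_constants(5780.37487, 2733.50446, 1857.675172, "0+")
rotational_constants <- function(A, B, C, state_label = "ground") {
  if (!all(is.finite(c(A, B, C))) || any(c(A, B, C) <= 0)) {
    stop("rotational constants must be positive and finite")
  }
  if (!(A >= B && B >= C)) {
    stop("rotational constants must satisfy A >= B >= C")
  }
  structure(list(A = A, B = B, C = C, state_label = state_label),
            class = "rotational_constants")
}

#' @export
print.rotational_constants <- function(x, ...) {
  cat(sprintf("Rotational constants [%s]: A = %.6f  B = %.6f  C = %.6f MHz\n",
              x$state_label, x$A, x$B, x$C))
  invisible(x)
}

#' Centrifugal distortion constants (Watson A-reduction, representation Ir)
#'
#' Quartic constants are given in kHz and the sextic `HK` in Hz, mirroring
#' the conventional table presentation; conversion to MHz happens inside the
#' Hamiltonian builder.  Only the A-reduction in representation Ir is
#' supported; other choices are rejected rather than silently approximated.
#'
#' @param DJ,DJK,DK Quartic constants Delta_J, Delta_JK, Delta_K in kHz.
#' @param dJ,dK Quartic constants delta_J, delta_K in kHz.
#' @param HK Sextic constant H_K in Hz.
#' @param reduction Must be `"A"`.
#' @param representation Must be `"Ir"`.
#' @return An object of class `distortion_set`.
#' @export
distortion_set <- function(DJ = 0, DJK = 0, DK = 0, dJ = 0, dK = 0, HK = 0,
                           reduction = "A", representation = "Ir") {
  if (!identical(reduction, "A")) {
    stop("only the Watson A-reduction is supported")
  }
  if (!identical(representation, "Ir")) {
    stop("only representation Ir (a -> z) is supported")
  }
  vals <- c(DJ = DJ, DJK = DJK, DK = DK, dJ = dJ, dK = dK, HK = HK)
  if (!all(is.finite(vals))) stop("distortion constants must be finite")
  structure(list(DJ = DJ, DJK = DJK, DK = DK, dJ = dJ, dK = dK, HK = HK,
                 reduction = "A", representation = "Ir"),
            class = "distortion_set")
}

#' Principal moments of inertia from rotational constants
#'
#' @param rc A [rotational_constants()] object.
#' @param conversion_constant Conversion constant in MHz u A^2
#'   (default [inertia_conversion]).
#' @return An object of class `moments_of_inertia` with fields `Ia`, `Ib`,
#'   `Ic` (u A^2) and `conversion_constant`.
#' @export
#' @examples
#' m <- moments_from_constants(
#'   rotational_constants(5780.37487, 2733.50446, 1857.675172, "0+"))
#' inertial_defect(m)
moments_from_constants <- function(rc, conversion_constant = inertia_conversion) {
  stopifnot(inherits(rc, "rotational_constants"))
  moments_of_inertia(conversion_constant / rc$A,
                     conversion_constant / rc$B,
                     conversion_constant / rc$C,
                     conversion_constant = conversion_constant)
}

#' Construct a set of principal moments of inertia
#'
#' @param Ia,Ib,Ic Principal moments in u A^2, `Ia <= Ib <= Ic`.
#' @param conversion_constant Conversion constant in MHz u A^2.
#' @return An object of class `moments_of_inertia`.
#' @export
moments_of_inertia <- function(Ia, Ib, Ic,
                               conversion_constant = inertia_conversion) {
  if (Ia > -1e-9 && Ia < 0) Ia <- 0   # numerical noise for linear bodies
  if (Ia < 0 || any(c(Ib, Ic) <= 0)) {
    stop("moments of inertia must be positive (Ia may be zero for a linear body)")
  }
  if (!(Ia <= Ib && Ib <= Ic)) stop("moments must satisfy Ia <= Ib <= Ic")
  structure(list(Ia = Ia, Ib = Ib, Ic = Ic,
                 conversion_constant = conversion_constant),
            class = "moments_of_inertia")
}

#' Inertial defect
#'
#' `Delta_i = Ic - Ia - Ib`; identically zero for a rigid planar body and
#' slightly negative for quasi-planar molecules with low-frequency
#' out-of-plane motion.
#'
#' @param m A `moments_of_inertia` object.
#' @return The inertial defect in u A^2.
#' @export
inertial_defect <- function(m) {
  stopifnot(inherits(m, "moments_of_inertia"))
  m$Ic - m$Ia - m$Ib
}

#' Planar moments
#'
#' `Pa = (-Ia + Ib + Ic)/2` and cyclic permutations.  `Pc` equals minus one
#' half of the inertial defect and measures the mass distribution out of the
#' ab plane.
#'
#' @param m A `moments_of_inertia` object.
#' @return An object of class `planar_moments` with fields `Pa`, `Pb`, `Pc`
#'   (u A^2).
#' @export
planar_moments <- function(m) {
  stopifnot(inherits(m, "moments_of_inertia"))
  structure(list(Pa = (-m$Ia + m$Ib + m$Ic) / 2,
                 Pb = (m$Ia - m$Ib + m$Ic) / 2,
                 Pc = (m$Ia + m$Ib - m$Ic) / 2),
            class = "planar_moments")
}

#' @export
print.planar_moments <- function(x, ...) {
  cat(sprintf("Planar moments: Pa = %.4f  Pb = %.4f  Pc = %.4f uA^2\n",
              x$Pa, x$Pb, x$Pc))
  invisible(x)
}
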