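---
title: "Models and methods in rotspec"
author: "rotspec authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in rotspec}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rotspec)
```

# Scope

rotspec models the rotational spectroscopy of near-planar asymmetric-top
molecules carrying one or two quadrupolar (spin-1) nitrogen nuclei, and the
determination of hydrogen-bonded cluster geometry from isotopologue
rotational constants.  The worked system shipped with the package is
2-aminopyridine (AMP) and its 1:1 water cluster (AMW): the monomer is
characterised by millimetre-wave and jet-cooled cavity FTMW spectroscopy,
the cluster by FTMW alone, and the cluster structure follows from the nine
ground-state moments of inertia of the parent and two ring-deuterated
species.  All reference constants used in examples and tests are packaged
as plain-text tables under `inst/extdata/`.

# Rotational Hamiltonian

Energy levels come from the Watson A-reduced effective rotational
Hamiltonian in representation Ir (quantisation axis z = a):

$$H = A J_a^2 + B J_b^2 + C J_c^2
  - \Delta_J \mathbf{J}^4 - \Delta_{JK}\mathbf{J}^2 J_a^2 - \Delta_K J_a^4
  - 2\delta_J \mathbf{J}^2 (J_b^2 - J_c^2)
  - \delta_K [J_a^2(J_b^2-J_c^2) + (J_b^2-J_c^2)J_a^2]
  + H_K J_a^6.$$

The matrix is built per J in a signed-k symmetric-top basis, symmetrised
into the four Wang blocks, and each block is diagonalised separately.
(Ka, Kc) labels are assigned by sorting each J block in energy and walking
the standard asymmetric-top ladder; exact degeneracies (high-Ka doublets)
are broken deterministically by Wang-block parity, which matters only for
labelling, never for the physics.  The test suite cross-checks the
Wang-block route against a dense diagonalisation built independently from
angular-momentum operator products, requiring agreement below 1 Hz up to
J = 10.

Units are MHz throughout the core; quartic constants enter in kHz and the
sextic H_K in Hz only at the I/O boundary, mirroring how such constants
are tabulated.  Other reductions (S) or representations are rejected
outright rather than approximated.  The two inversion sublevels 0+ and 0-
of an amine-inverting molecule are treated as independent states with
their own constants; no inversion coupling term is included, which is
adequate because the sublevels are far enough apart that their rotational
manifolds do not interact measurably.

Moments of inertia follow from the conversion constant
505379.07 MHz uA^2 (the package default, adjustable per call); the
inertial defect is Delta_i = Ic - Ia - Ib and planar moments are the usual
half-sums, with Pc = -Delta_i/2.

# Nuclear quadrupole hyperfine structure

The coupling scheme is I_tot = I(N1) + I(N2), F = J + I_tot, with both
spins fixed at 1 (14N).  Hyperfine structure is treated first order within
each rotational level: the electric-field-gradient tensor of each nucleus,
expressed by its coupling constants chi_gg' (MHz) in the inertial frame,
is projected onto the level through a single reduced matrix element
computed from the level eigenvector, and the resulting interaction is
diagonalised in the coupled |J,(I1 I2)I_tot,F> basis using Wigner 6-j
recoupling.  The treatment neglects mixing of different rotational levels,
a relative error of order |chi|/B ~ 1e-3 for these systems; a practical
consequence is that the off-diagonal coupling chi_ab does not shift
first-order energies (it connects levels, not sublevels) and is carried as
a fixed parameter taken from scaled quantum-chemistry values where needed.

Because eigenvectors within an F block can mix I_tot strongly, sublevels
are labelled by a unique greedy assignment of I_tot labels (each label
used once per F block, paired by descending overlap).  This keeps
synthetic-data generation and line-list fitting consistent under parameter
changes; near a 50/50 mixing either label is defensible and the assignment
is simply deterministic.

Component intensities use coupled-basis line-strength factors for a
dipole operator acting on the rotational space only, diagonal in I_tot,
with interference over the I_tot mixing amplitudes; intensities are
normalised to sum to one within each rotational transition.  Two sum rules
guard the implementation in the tests: the number of F sublevels of a
J >= 2 level is nine, and the intensity-weighted mean hyperfine offset of
any transition vanishes (first-order centre of gravity).  The energies are
cross-checked against an independent brute-force diagonalisation in the
uncoupled product basis |J m>|I1 m1>|I2 m2> and, for a single nucleus,
against the closed-form Casimir expression.

Tensor utilities (rotation in the ab plane, uniform scaling,
diagonalisation) implement the standard conventions: positive rotation
angles rotate a towards b; the principal z axis is the largest-magnitude
eigenvalue (for both nitrogens here chi_zz is the most negative value);
theta_za is reported as a magnitude in [0, 90] degrees with the signed
value retained.  The structural angle correction adds the computed
difference (theta_str - theta_za) to the experimental theta_za,
compensating the small, reliably calculable offset between the principal
quadrupolar axis and the bond axis.

# Spectrum prediction and type-II bands

Forward prediction enumerates |dJ| <= 1 transitions in a frequency
window.  Line strengths come from eigenvector-based dipole matrix
elements, so a-type (dKa even, dKc odd), b-type (odd, odd) and c-type
(odd, even) selection rules emerge from the angular-momentum algebra;
intensities weight the line strength by frequency and the Boltzmann
population of the lower level at the model temperature (1 K for jet
spectra, 300 K for the room-temperature millimetre-wave region).

High-J R-branch transitions of near-planar tops pile into type-II bands
whose spacing approaches 2C.  The band detector builds an
intensity-weighted Gaussian kernel density (default bandwidth 120 MHz,
grid 10 MHz), finds local maxima above a quarter of the tallest peak,
suppresses satellite maxima closer than five bandwidths (keeping the
taller), refines each centre as the local intensity-weighted mean, and
returns the mean spacing.  For the AMP lower inversion sublevel predicted
over 256-276 GHz with J up to 130, the detected spacing agrees with 2C =
3715.35 MHz to a few MHz.  The defaults were chosen for GHz-scale band
spacings; for models on a different frequency scale the bandwidth and
grid should be scaled along (the tests do exactly this for a synthetic
C = 1000 MHz rotor).

# Global line-list fitting

`fit_constants()` minimises the weighted sum of squared residuals
(obs - calc)/u over a line list by Levenberg-Marquardt (via
minpack.lm), with 1/u^2 weighting combining subsets of very different
accuracy (2 kHz FTMW, 50 kHz MMW) into one global fit.  The deviation of
fit is reported per source tag as a plain rms in kHz, the presentation
used in spectroscopic tables.  Hyperfine-resolved lines are matched to
first-order components through their (F, I_tot) labels; blended lines
(shared blend id) are matched to the intensity-weighted centroid of their
components.  Fixed-parameter strategies — deuterated species inheriting
parent distortion constants — are expressed by the `free` mask.

Standard errors come from the unscaled covariance (J^T J)^{-1} of the
weighted problem, i.e. the stated uncertainties are taken at face value.
This choice makes the errors scale linearly with uniformly inflated
uncertainties and lets Monte-Carlo recovery tests use the pull
(deviation/SE) directly; it differs from the reduced-chi-square scaling
some fitting programs apply.  Rank deficiency is detected by QR and
reported with the names of the unconstrained parameters; the iteration
cap (default 100) aborts only when the residual norm is still changing.

# Cluster geometry and the r0 fit

The monomer fixtures are synthetic: `amp_reference_geometry()` builds a
2-aminopyridine-like planar ring from idealised bond lengths and angles
with a mildly pyramidal NH2 (tilt 23 degrees, chosen so the out-of-plane
amino hydrogens reproduce a realistic positive Pc), and
`water_reference_geometry()` uses the standard effective ground-state
water parameters r(OH) = 0.9572 A, HOH = 104.52 degrees.  The AMP
fixture's rotational constants land within about 1% of experiment; before
structure work it is corrected onto experiment by per-axis planar-moment
scaling (`scale_geometry_to_planar_moments()`), after which it reproduces
the experimental constants to better than 0.05 MHz.  An axis whose planar
moment is essentially zero (strictly planar input) cannot be scaled to a
positive target; its factor is pinned at 1 and flagged.

The cluster is assembled from three intermolecular parameters — the
heavy-atom bond length d(O...Nr), the in-plane angle A(O...Nr-C2) and the
free-hydrogen dihedral D(HOH...Nr) about the O...Nr axis (IUPAC sign
convention; only magnitudes are physically compared) — with two frozen
assumptions: the bonded O-H lies in the aromatic plane and deviates from
the O...Nr axis by a configurable nonlinearity angle, default 0.  The
binding side is the amino side of the ring, where the cyclic double
hydrogen bond (O-H...Nr and Na-H...O) forms.  Assembly followed by
measurement round-trips the parameters to 1e-9.

`r0_fit()` adjusts the three parameters against observed isotopologue
moments of inertia (unweighted by default, with an optional weight
vector) by Levenberg-Marquardt, holding both monomers rigid.  Here the
covariance is scaled by s^2 = SSR/(n - p), the convention of structure-fit
programs, so the quoted errors reflect the actual moment residuals; the
Monte-Carlo calibration test verifies that the scatter of fitted distances
over 50 noise realisations matches the mean reported standard error.
With the packaged experimental moments the fitted d(O...Nr) falls within
0.01 A of the published 2.8489 A; angle-like parameters are more
sensitive to the approximate monomer fixtures, and the overall sigma_fit
(about 0.07 uA^2) is correspondingly larger than the published 0.0247
uA^2, which was obtained with the authors' own scaled monomer geometry.
Kraitchman substitution analysis is intentionally out of scope: the
available isotopic data do not support it.

# Synthetic data and what the tests do (and do not) show

The generators mirror the statistical structure the analysis assumes:
Gaussian frequency noise at the stated per-subset accuracies (2 kHz FTMW,
50 kHz MMW) with the noise sigma stamped as the line uncertainty, and
Gaussian moment noise (default 0.025 uA^2) for the structure stage.
Every stochastic operation takes an explicit seed and restores the
caller's RNG state: generators are pure functions of (inputs, seed).

Calibration tests run the full generate-analyse loop: zero-noise line
lists refit to the generating constants to below 1 Hz; at 2 kHz noise,
50-seed recovery of A, B, C stays within three standard errors with bias
below one; r0 recovery is exact at zero noise and correctly calibrated at
the nominal moment noise.  Problem sizes were picked to exercise the
physics while keeping the default test run around a minute and a half:
J <= 10 for the rotor oracle, J <= 3 for the hyperfine oracle, 50-seed
Monte-Carlo batches with ~60-line fits, and a single high-J (J <= 130)
band prediction.

What passing does not show: the generators draw independent Gaussian
errors, while real measurement errors correlate through blended,
Doppler-doubled or baseline-distorted line shapes; the hyperfine model
omits spin-rotation and deuterium quadrupole coupling (real deuterated
species fit with visibly larger deviations for exactly this reason); and
the synthetic monomer geometry stands in for an unpublished scaled
quantum-chemistry geometry, so cluster-structure comparisons are
tolerance-based, never exact.

# Numerical choices

Wigner 3-j/6-j symbols use the Racah closed forms with log-factorials;
the few-term sums for the ranks needed here (k <= 2) are numerically
benign even at J ~ 130.  Dipole Clebsch-Gordan coefficients on hot paths
use the closed-form j2 = 1 table, verified against the Racah route in the
tests.  Eigen-decompositions use LAPACK symmetric routines.  The LM
convergence tolerances (ftol 1e-10, ptol 1e-8) balance finite-difference
Jacobian noise against parameter precision; finite-difference steps are
relative (1e-6) with an absolute floor.  Degenerate inputs are defined,
not accidental: a degenerate ab tensor block reports theta_za = 0 with a
flag, a single-atom geometry is an error, a band window with fewer than
two detected bands is an error, and a linear body may carry Ia = 0.
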