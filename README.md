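# rotspec

High-resolution rotational spectroscopy of near-planar asymmetric-top
molecules with one or two quadrupolar (¹⁴N, I = 1) nuclei, and effective
(r₀) structure determination of their hydrogen-bonded clusters — as an R
package with a fully synthetic, offline-testable data path.

rotspec is written for molecular spectroscopists and structural modellers
who work with jet-cooled Fourier-transform microwave (FTMW) and
room-temperature millimetre-wave (MMW) spectra: assign and fit line lists,
predict spectra, analyse nuclear quadrupole coupling tensors, and fit
cluster geometries to isotopologue moments of inertia.  The worked system
shipped with the package is 2-aminopyridine (AMP) and its 1:1 water cluster
(AMW), a biomimetic pairing in which water bridges the H₂N–C=N ring segment
with two hydrogen bonds (O–H···N and N–H···O).

## What is implemented

* **Rotor core** — Watson A-reduced asymmetric-rotor Hamiltonian
  (representation Iʳ, quartic constants Δ_J, Δ_JK, Δ_K, δ_J, δ_K and
  sextic H_K), solved per Wang symmetry block with (Ka, Kc) assignment;
  moments of inertia, inertial defect Δᵢ = I_c − I_a − I_b, planar moments.
* **Hyperfine** — first-order nuclear quadrupole coupling of two I = 1
  nuclei in the I_tot = I(N₁) + I(N₂), F = J + I_tot coupling scheme
  (Wigner 6-j recoupling), component intensities, and the tensor calculus
  used in structural analysis: the (3/2)χ_aa, (χ_bb−χ_cc)/4
  fit-parameterisation, Laplace-relation χ_cc derivation, in-plane
  rotation, uniform scaling, diagonalisation to the principal quadrupolar
  axes (χ_zz, θ_za) and the θ_str bond-angle correction.
* **Spectra** — forward prediction with a/b/c-type selection rules from
  eigenvector dipole matrix elements, Boltzmann intensities, hyperfine
  substructure on request, high-J type-II band detection (spacing ≈ 2C),
  and weighted global least-squares fitting of mixed-accuracy line lists
  (Levenberg–Marquardt, per-subset σ_fit, parameter masks for
  fixed-constant strategies).
* **Structure** — principal moments from Cartesian geometries, isotopic
  substitution, per-axis planar-moment scaling of a monomer geometry onto
  experimental constants, rigid assembly of an aromatic–water cluster from
  three intermolecular parameters (d(O···N_r), A(O···N_r–C2),
  D(HOH···N_r)), and the three-parameter r₀ least-squares fit to nine
  isotopologue moments.
* **Synthetic data** — seeded generators for line lists (Gaussian noise at
  2 kHz FTMW / 50 kHz MMW accuracy) and cluster moment sets (0.025 uÅ²),
  plus toy and reference geometries, so every stage is testable with no
  downloads.
* **Workbench** — a `run_pipeline()` config runner with table-style text
  reports and JSON results, and a thin CLI (`inst/cli/rotspec.R`) with
  verbs `predict`, `bands`, `tensor`, `fit`, `simulate`, `structure-fit`,
  `report`.

Reference spectroscopic constants for AMP (both inversion sublevels 0⁺/0⁻
and the ring-deuterated d-5/d-6 species) and AMW are shipped as YAML under
`inst/extdata/` and loaded with `read_constants(rotspec_example("amp.yaml"))`.

## A worked example

```r
library(rotspec)

# ring-nitrogen coupling tensor of AMP from the direct parameters of fit
amp <- read_constants(rotspec_example("amp.yaml"))
amp$tensors$Nr
#> Quadrupole tensor [Nr, I=1]: chi_aa=-0.0526 chi_bb=-2.2902 chi_cc=2.3428 chi_ab=2.9200 MHz

# diagonalise the AMW ring-nitrogen tensor to its principal axes
diagonalize_tensor(read_constants(rotspec_example("amw.yaml"))$tensors$Nr)
#> Principal tensor: chi_zz=-3.6573 chi_yy=1.8820 chi_xx=1.7753 MHz, theta_za=15.88 deg

# inertial defect of the lower inversion sublevel of AMP
mmw <- read_constants(rotspec_example("amp_mmw.yaml"))$states
inertial_defect(moments_from_constants(mmw[["0+"]]$rc))
#> [1] -0.2641477

# rigid-rotor levels: the J = 1 triplet at B+C, A+C, A+B
rotor_states(amp$states$ground$rc, amp$states$ground$dist, J_max = 1)$levels
#>   J Ka Kc   energy
#> 1 0  0  0    0.000
#> 2 1  0  1 4591.179
#> 3 1  1  1 7638.049
#> 4 1  1  0 8513.876
```

The χ_cc values (−4.203 MHz for the amino nitrogen, +2.343 MHz for the
ring nitrogen in the monomer) follow from the traceless condition and are
the complexation-sensitive observables: on cluster formation the ring
nitrogen's χ_cc drops by nearly 20 % (to 1.882 MHz) while the amino
nitrogen's barely moves — direct evidence that water binds at the ring
nitrogen.  The diagonalisation angle θ_za = 15.9°, corrected by the
computed (θ_str − θ_za) offset, gives a structural angle of 17.5° between
the CNC bisector and the a axis.  The end-to-end structure stage
(`demo_config("amw-structure")`) fits d(O···N_r) ≈ 2.85 Å against the nine
packaged experimental moments.

## Limitations

First-order hyperfine treatment (no rotational-level mixing, so χ_ab is
carried but does not shift energies); no spin–rotation or deuterium
quadrupole coupling; no inversion-tunnelling Hamiltonian (0⁺/0⁻ are
independent states); S-reduction not supported; the packaged monomer
geometries are synthetic stand-ins corrected onto experiment by
planar-moment scaling, so structure-fit comparisons are tolerance-based.
See the methods vignette (`vignettes/rotspec-methods.Rmd`) for the full
model description and design rationale.
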