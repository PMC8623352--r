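#' Noise specification for synthetic data
#'
#' Frequency noise per measurement subset and moment-of-inertia noise, with
#' an explicit seed.  Defaults mirror typical experimental accuracies:
#' 2 kHz for cavity FTMW lines, 50 kHz for room-temperature MMW lines, and
#' 0.025 u A^2 for ground-state moments entering a structure fit.
#'
#' @param freq_sigma Named numeric of frequency standard deviations in MHz,
#'   one per source tag.
#' @param moment_sigma Moment-of-inertia noise in u A^2.
#' @param seed Integer seed; identical seeds give identical synthetic data.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(freq_sigma = c(FTMW = 2e-3, MMW = 50e-3),
                       moment_sigma = 0.025, seed = 1L) {
  freq_sigma <- unlist(freq_sigma)
  if (any(freq_sigma < 0) || moment_sigma < 0) stop("noise sigmas must be >= 0")
  structure(list(freq_sigma = freq_sigma, moment_sigma = moment_sigma,
                 seed = as.integer(seed)),
            class = "noise_spec")
}

## Run `expr` under a local RNG stream seeded by `seed`, restoring the
## caller's RNG state afterwards (generators are pure functions of seed).
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Simulate a measured line list from known constants
#'
#' Predicts transitions from a [spectrum_model()], selects them by J range
#' and transition type, adds Gaussian frequency noise at the per-source
#' sigma and stamps each line with that sigma as its uncertainty.  The
#' output feeds [fit_constants()] directly, closing the generate-fit loop
#' used for calibration.
#'
#' @param model A [spectrum_model()].
#' @param J_range Length-2 integer vector, inclusive range of the lower
#'   level J.
#' @param noise A [noise_spec()].
#' @param source Source tag selecting the noise sigma (must name an entry
#'   of `noise$freq_sigma`).
#' @param types Transition types to keep, subset of `c("a","b","c")`.
#' @param Ka_max Optional cap on the lower-level Ka.
#' @param f_range Frequency window in MHz (default wide open).
#' @param n_max Optionally subsample to at most this many lines (strongest
#'   first), keeping the list compact.
#' @param hyperfine If `TRUE`, lines are hyperfine components with F/Itot
#'   labels (requires tensors in the model).
#' @return A data.frame of measured lines with columns as expected by
#'   [fit_constants()], plus `true_frequency` for calibration studies.
#' @export
simulate_linelist <- function(model, J_range, noise = noise_spec(),
                              source = "FTMW", types = c("a", "b"),
                              Ka_max = Inf, f_range = c(1, 1e7),
                              n_max = Inf, hyperfine = FALSE) {
  stopifnot(inherits(model, "spectrum_model"), inherits(noise, "noise_spec"))
  if (!(source %in% names(noise$freq_sigma))) {
    stop("source tag has no noise sigma: ", source)
  }
  tr <- predict_spectrum(model, f_range[1], f_range[2],
                         J_max = max(J_range) + 1, hyperfine = hyperfine)
  tr <- tr[tr$J_lo >= J_range[1] & tr$J_lo <= max(J_range) &
             tr$type %in% types & tr$Ka_lo <= Ka_max, ]
  if (nrow(tr) == 0) stop("selection produced an empty prediction")
  if (nrow(tr) > n_max) {
    tr <- tr[order(-tr$intensity), ][seq_len(n_max), ]
    tr <- tr[order(tr$frequency), ]
  }
  sigma <- noise$freq_sigma[[source]]
  eps <- with_seed(noise$seed, stats::rnorm(nrow(tr), 0, sigma))
  out <- data.frame(
    J_up = tr$J_up, Ka_up = tr$Ka_up, Kc_up = tr$Kc_up,
    J_lo = tr$J_lo, Ka_lo = tr$Ka_lo, Kc_lo = tr$Kc_lo,
    frequency = tr$frequency + eps,
    uncertainty = rep(max(sigma, 1e-12), nrow(tr)),
    source = source, blend = NA_integer_,
    true_frequency = tr$frequency)
  if (hyperfine) {
    out$F_up <- tr$F_up; out$Itot_up <- tr$Itot_up
    out$F_lo <- tr$F_lo; out$Itot_lo <- tr$Itot_lo
  }
  rownames(out) <- NULL
  out
}

#' Simulate noisy isotopologue moments of a cluster
#'
#' Assembles the cluster at known parameters, substitutes isotopes,
#' computes principal moments and adds Gaussian noise at
#' `noise$moment_sigma` — the synthetic analogue of the experimental
#' moment table entering [r0_fit()].
#'
#' @inheritParams r0_fit
#' @param p True [cluster_params()].
#' @param noise A [noise_spec()].
#' @return Data.frame with columns `Ia`, `Ib`, `Ic` (one row per
#'   isotopologue, u A^2).
#' @export
simulate_cluster_moments <- function(host, water, p, isotopologues,
                                     noise = noise_spec()) {
  cl <- assemble_cluster(host, water, p)
  mm <- t(vapply(isotopologues, function(s) {
    gi <- if (is.null(s)) cl else make_isotopologue(cl, s)
    m <- principal_moments(gi)$moments
    c(Ia = m$Ia, Ib = m$Ib, Ic = m$Ic)
  }, numeric(3)))
  eps <- with_seed(noise$seed,
                   stats::rnorm(length(mm), 0, noise$moment_sigma))
  out <- as.data.frame(mm + matrix(eps, nrow(mm), 3))
  names(out) <- c("Ia", "Ib", "Ic")
  out
}

#' Toy planar ring molecule with closed-form moments
#'
#' Regular n-gon of unit-mass-style atoms in the xy plane — a fixture whose
#' principal moments have a closed form (ring of point masses:
#' `Ia = Ib = n m R^2 / 2`, `Ic = n m R^2`), used as an oracle for the
#' rigid-body machinery.
#'
#' @param n_ring_atoms Number of ring atoms (>= 3).
#' @param bond_length Side length of the polygon in Angstrom.
#' @param mass Mass per atom in u.
#' @return A [geometry()].
#' @export
toy_planar_molecule <- function(n_ring_atoms, bond_length = 1, mass = 1) {
  if (n_ring_atoms < 3) stop("a ring needs at least 3 atoms")
  R <- bond_length / (2 * sin(pi / n_ring_atoms))
  th <- 2 * pi * (seq_len(n_ring_atoms) - 1) / n_ring_atoms
  geometry(rep("C", n_ring_atoms), R * cos(th), R * sin(th),
           rep(0, n_ring_atoms), mass = rep(mass, n_ring_atoms),
           label = paste0("X", seq_len(n_ring_atoms)))
}

#' Synthetic 2-aminopyridine-like monomer geometry
#'
#' A stand-in planar aromatic geometry built from idealised bond lengths
#' and angles (pyridine-like ring, exocyclic NH2 with a modest pyramidal
#' tilt), constructed in code because no reference Cartesian geometry is
#' shipped.  Its rotational constants land within ~1% of the experimental
#' 2-aminopyridine values; before quantitative structure work it should be
#' corrected onto experiment with [scale_geometry_to_planar_moments()].
#' Atom labels follow ring numbering: `Nr` (ring N), `C2`..`C6`, ring
#' hydrogens `H3`..`H6`, amino group `Na`, `Ha1`, `Ha2`.
#'
#' @param pyramidal_tilt Out-of-plane tilt of the NH2 plane in degrees
#'   (both amino hydrogens on the same side, as in the inversion-averaged
#'   effective structure).
#' @return A [geometry()] in the principal-axis frame.
#' @export
amp_reference_geometry <- function(pyramidal_tilt = 23) {
  bonds <- c(1.345, 1.409, 1.379, 1.398, 1.375, 1.342)  # Nr-C2 ... C6-Nr
  interior <- c(Nr = 117.6, C2 = 122.6, C3 = 118.5, C4 = 119.3,
                C5 = 118.0, C6 = 124.0)
  nm <- names(interior)
  pos <- matrix(0, 6, 2, dimnames = list(nm, NULL))
  heading <- 0
  for (i in 1:5) {
    pos[i + 1, ] <- pos[i, ] + bonds[i] * c(cos(heading), sin(heading))
    heading <- heading + pi - interior[[nm[i + 1]]] * pi / 180
  }
  cen <- colMeans(pos)
  exo <- function(at) unit3(c(pos[at, ] - cen, 0))[1:2]
  lab <- nm; el <- c("N", "C", "C", "C", "C", "C")
  xy <- pos
  add <- function(label, element, p2) {
    lab <<- c(lab, label); el <<- c(el, element)
    xy <<- rbind(xy, p2)
  }
  for (ch in list(c("C3", 1.082), c("C4", 1.081), c("C5", 1.082),
                  c("C6", 1.085))) {
    at <- ch[1]
    add(sub("C", "H", at), "H", pos[at, ] + as.numeric(ch[2]) * exo(at))
  }
  add("Na", "N", pos["C2", ] + 1.358 * exo("C2"))
  z <- numeric(nrow(xy))
  # amino hydrogens: N-H 1.008 A, HNH 113 deg, common out-of-plane tilt
  ex <- c(exo("C2"), 0); ez <- c(0, 0, 1)
  ey <- pracma_cross(ez, ex)
  tilt <- pyramidal_tilt * pi / 180
  na3 <- c(xy[nrow(xy), ], 0)
  for (s in c(1, -1)) {
    d <- cos(113 * pi / 360) * ex + sin(113 * pi / 360) * s * ey
    d <- cos(tilt) * d + sin(tilt) * ez
    h <- na3 + 1.008 * unit3(d)
    lab <- c(lab, if (s > 0) "Ha1" else "Ha2"); el <- c(el, "H")
    xy <- rbind(xy, h[1:2]); z <- c(z, h[3])
  }
  g <- geometry(el, xy[, 1], xy[, 2], z, label = lab)
  principal_moments(g)$geometry
}

#' Effective ground-state water geometry
#'
#' Rigid water monomer with the standard effective structural parameters
#' r(OH) = 0.9572 A and HOH angle 104.52 deg, labels `O`, `H1`, `H2`.
#'
#' @return A [geometry()].
#' @export
water_reference_geometry <- function() {
  r <- 0.9572; half <- 104.52 / 2 * pi / 180
  geometry(c("O", "H", "H"),
           x = c(0, r * cos(half), r * cos(half)),
           y = c(0, r * sin(half), -r * sin(half)),
           z = c(0, 0, 0),
           label = c("O", "H1", "H2"))
}
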