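#' Intermolecular parameters of the hydrogen-bonded aromatic-water cluster
#'
#' The relative orientation of a rigid water molecule against a rigid
#' planar aromatic partner, reduced to three fitted parameters: the
#' heavy-atom hydrogen-bond distance d(O...Nr), the in-plane angle
#' A(O...Nr-C2), and the dihedral D(Hf-O-Nr-C2) of the free water hydrogen
#' about the O...Nr axis.  The remaining degrees of freedom are frozen by
#' two recorded assumptions: the O-H...Nr hydrogen bond lies in the
#' aromatic plane and deviates from the O...Nr axis by a fixed
#' `nonlinearity` angle (default 0).
#'
#' @param d_O_Nr Heavy-atom hydrogen bond length O...Nr in Angstrom (> 0).
#' @param angle_O_Nr_C2 Angle O...Nr-C2 in degrees, in (0, 180).
#' @param dihedral_HOH_Nr Dihedral of the free water hydrogen,
#'   D(Hf-O-Nr-C2), IUPAC sign convention, degrees.
#' @param nonlinearity In-plane deviation of the bonded O-H from the O...Nr
#'   axis, degrees (assumption frozen from quantum chemistry; not fitted).
#' @param in_plane Logical; the O-H...Nr bond is kept in the aromatic
#'   plane (the only supported mode, recorded for provenance).
#' @return An object of class `cluster_params`.
#' @export
cluster_params <- function(d_O_Nr, angle_O_Nr_C2, dihedral_HOH_Nr,
                           nonlinearity = 0, in_plane = TRUE) {
  if (!is.finite(d_O_Nr) || d_O_Nr <= 0) stop("d_O_Nr must be positive")
  if (angle_O_Nr_C2 <= 0 || angle_O_Nr_C2 >= 180) {
    stop("angle_O_Nr_C2 must lie in (0, 180) degrees")
  }
  if (!in_plane) stop("only the in-plane hydrogen-bond mode is supported")
  structure(list(d_O_Nr = d_O_Nr, angle_O_Nr_C2 = angle_O_Nr_C2,
                 dihedral_HOH_Nr = dihedral_HOH_Nr,
                 nonlinearity = nonlinearity, in_plane = in_plane),
            class = "cluster_params")
}

#' @export
print.cluster_params <- function(x, ...) {
  cat(sprintf(
    "d(O...Nr) = %.4f A   A(O...Nr-C2) = %.2f deg   D(HOH...Nr) = %.1f deg\n",
    x$d_O_Nr, x$angle_O_Nr_C2, x$dihedral_HOH_Nr))
  invisible(x)
}

unit3 <- function(v) v / sqrt(sum(v^2))

## IUPAC torsion angle p1-p2-p3-p4 in degrees (right-hand rule about b2).
torsion_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- pracma_cross(b1, b2); n2 <- pracma_cross(b2, b3)
  x <- sum(n1 * n2)
  y <- sum(pracma_cross(n1, n2) * unit3(b2))
  atan2(y, x) * 180 / pi
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

bond_angle <- function(p1, p2, p3) {
  u <- unit3(p1 - p2); v <- unit3(p3 - p2)
  acos(max(-1, min(1, sum(u * v)))) * 180 / pi
}

#' Assemble the aromatic-water cluster from three intermolecular parameters
#'
#' Places a rigid water molecule against the rigid aromatic monomer: the
#' oxygen at distance `d_O_Nr` from the ring nitrogen Nr, at in-plane angle
#' `angle_O_Nr_C2` from the Nr-C2 direction (on the amino side of the ring,
#' where the cyclic double hydrogen bond forms), the bonded hydrogen
#' pointing along O -> Nr (deviating by the frozen `nonlinearity` angle in
#' the aromatic plane), and the free hydrogen set by the dihedral
#' D(Hf-O-Nr-C2).
#'
#' @param host A [geometry()] of the aromatic monomer whose atom labels
#'   include `"Nr"` (ring nitrogen), `"C2"` (carbon bonded to Nr carrying
#'   the amino group) and `"Na"` (amino nitrogen, used to pick the binding
#'   side).  Ring heavy atoms must be planar to within ~0.05 A.
#' @param water A [geometry()] with labels `"O"`, `"H1"`, `"H2"` supplying
#'   the rigid internal water geometry (bond length and angle).
#' @param p A [cluster_params()].
#' @return A [geometry()] of the cluster in the host's input frame; the
#'   water atoms carry labels `"Ow"`, `"Hb"` (bonded) and `"Hf"` (free).
#' @export
assemble_cluster <- function(host, water, p) {
  stopifnot(inherits(host, "geometry"), inherits(water, "geometry"),
            inherits(p, "cluster_params"))
  need <- c("Nr", "C2", "Na")
  if (!all(need %in% host$label)) {
    stop("host geometry must label atoms Nr, C2 and Na")
  }
  X <- geom_coords(host)
  rownames(X) <- host$label
  nr <- X["Nr", ]; c2 <- X["C2", ]; na_ <- X["Na", ]
  ring <- X[host$label %in% c("Nr", "C2", "C3", "C4", "C5", "C6"), , drop = FALSE]
  # plane of the ring (normal = smallest principal direction of the spread)
  cen <- colMeans(ring)
  sv <- svd(sweep(ring, 2, cen))
  zhat <- sv$v[, 3]
  if (max(abs(sweep(ring, 2, cen) %*% zhat)) > 0.05) {
    stop("host ring atoms are not planar within tolerance")
  }
  u <- unit3(c2 - nr)
  w <- unit3(pracma_cross(zhat, u))
  if (sum(w * (na_ - nr)) < 0) w <- -w      # binding side = amino side
  al <- p$angle_O_Nr_C2 * pi / 180
  O <- nr + p$d_O_Nr * (cos(al) * u + sin(al) * w)

  # rigid internal water geometry
  Wx <- geom_coords(water)
  rownames(Wx) <- water$label
  r_oh1 <- sqrt(sum((Wx["H1", ] - Wx["O", ])^2))
  r_oh2 <- sqrt(sum((Wx["H2", ] - Wx["O", ])^2))
  hoh <- bond_angle(Wx["H1", ], Wx["O", ], Wx["H2", ]) * pi / 180

  # bonded H: along O -> Nr, rotated by the nonlinearity angle in-plane
  axis <- unit3(nr - O)
  delta <- p$nonlinearity * pi / 180
  inpl <- unit3(pracma_cross(zhat, axis))
  if (sum(inpl * w) < 0) inpl <- -inpl      # tilt towards the amino side
  e_hb <- cos(delta) * axis + sin(delta) * inpl
  Hb <- O + r_oh1 * e_hb

  # free H: polar angle beta from the O...Nr axis and azimuth D about it,
  # measured from the C2 half-plane; beta solves the rigid HOH constraint
  bref <- unit3((c2 - nr) - sum((c2 - nr) * axis) * axis)
  n2 <- pracma_cross(bref, axis)   # sign such that the measured IUPAC torsion equals D
  Drad <- p$dihedral_HOH_Nr * pi / 180
  phi_hb <- atan2(sum((e_hb - sum(e_hb * axis) * axis) * n2),
                  sum((e_hb - sum(e_hb * axis) * axis) * bref))
  if (abs(delta) < 1e-12) phi_hb <- 0
  # cos(HOH) = cos(beta) cos(delta) + sin(beta) sin(delta) cos(D - phi_hb)
  aa <- cos(delta)
  bb <- sin(delta) * cos(Drad - phi_hb)
  cc <- cos(hoh)
  # aa cos(beta) + bb sin(beta) = cc  ->  beta = atan2(bb, aa) +- acos(...)
  rr <- sqrt(aa^2 + bb^2)
  beta <- atan2(bb, aa) + acos(max(-1, min(1, cc / rr)))
  e_hf <- cos(beta) * axis + sin(beta) * (cos(Drad) * bref + sin(Drad) * n2)
  Hf <- O + r_oh2 * e_hf

  wat <- geometry(c("O", "H", "H"),
                  c(O[1], Hb[1], Hf[1]),
                  c(O[2], Hb[2], Hf[2]),
                  c(O[3], Hb[3], Hf[3]),
                  mass = c(water$mass[water$label == "O"],
                           water$mass[water$label == "H1"],
                           water$mass[water$label == "H2"]),
                  label = c("Ow", "Hb", "Hf"))
  out <- rbind(host, wat)
  class(out) <- c("geometry", "data.frame")
  attr(out, "frame") <- "arbitrary"
  attr(out, "params") <- p
  out
}

#' Measure the intermolecular parameters from an assembled cluster
#'
#' Inverse of [assemble_cluster()]: reads d(O...Nr), A(O...Nr-C2) and
#' D(Hf-O-Nr-C2) back off the Cartesian geometry.
#'
#' @param cluster A cluster [geometry()] with labels `Nr`, `C2`, `Ow`,
#'   `Hf`.
#' @return A [cluster_params()] (nonlinearity copied from the assembly
#'   record when present).
#' @export
measure_cluster_params <- function(cluster) {
  X <- geom_coords(cluster)
  rownames(X) <- cluster$label
  d <- sqrt(sum((X["Ow", ] - X["Nr", ])^2))
  ang <- bond_angle(X["Ow", ], X["Nr", ], X["C2", ])
  dih <- torsion_angle(X["Hf", ], X["Ow", ], X["Nr", ], X["C2", ])
  p_old <- attr(cluster, "params")
  cluster_params(d, ang, dih,
                 nonlinearity = if (!is.null(p_old)) p_old$nonlinearity else 0)
}

#' Least-squares effective (r0) structure fit to isotopologue moments
#'
#' Fits the three intermolecular parameters of [cluster_params()] to the
#' observed principal moments of inertia of several isotopologues (three
#' moments each), keeping both monomer geometries rigid.  A
#' Levenberg-Marquardt (damped Gauss-Newton) minimiser is used; standard
#' errors come from the s^2-scaled covariance at convergence, so they
#' reflect the scatter of the moment residuals.
#'
#' @param host,water Rigid monomer geometries as in [assemble_cluster()].
#' @param p0 Starting [cluster_params()].
#' @param observed Data.frame with one row per isotopologue and columns
#'   `Ia`, `Ib`, `Ic` (u A^2); row order matches `isotopologues`.
#' @param isotopologues List (one entry per observed row) of substitution
#'   lists for [make_isotopologue()] applied to the assembled cluster;
#'   `NULL` entries mean the parent species.
#' @param weights Optional per-moment weights (length 3 x rows); default
#'   unweighted, matching common structure-fit practice.
#' @return An object of class `structure_fit_result`: fitted `params`,
#'   `se` (named standard errors), `sigma_fit` (rms of the moment
#'   residuals, u A^2), `residuals` (per isotopologue and moment),
#'   `niter`.
#' @export
r0_fit <- function(host, water, p0, observed, isotopologues,
                   weights = NULL) {
  stopifnot(inherits(p0, "cluster_params"), is.data.frame(observed))
  nspec <- nrow(observed)
  if (length(isotopologues) != nspec) {
    stop("need one isotopologue spec per observed row")
  }
  if (3 * nspec < 3) stop("need at least one isotopologue (three moments)")
  obs <- as.vector(t(as.matrix(observed[, c("Ia", "Ib", "Ic")])))
  if (is.null(weights)) weights <- rep(1, length(obs))

  model_moments <- function(par) {
    p <- cluster_params(par[1], par[2], par[3],
                        nonlinearity = p0$nonlinearity)
    cl <- assemble_cluster(host, water, p)
    unlist(lapply(isotopologues, function(s) {
      gi <- if (is.null(s)) cl else make_isotopologue(cl, s)
      m <- principal_moments(gi)$moments
      c(m$Ia, m$Ib, m$Ic)
    }))
  }
  resid_fun <- function(par) (model_moments(par) - obs) * sqrt(weights)
  par0 <- c(p0$d_O_Nr, p0$angle_O_Nr_C2, p0$dihedral_HOH_Nr)
  fit <- minpack.lm::nls.lm(par = par0, fn = resid_fun,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 100, ftol = 1e-12, ptol = 1e-12))
  par <- unlist(fit$par)
  r <- model_moments(par) - obs
  Jm <- fd_jacobian(resid_fun, par)
  qrJ <- qr(Jm)
  if (qrJ$rank < 3) {
    nm <- c("d_O_Nr", "angle_O_Nr_C2", "dihedral_HOH_Nr")
    stop("rank-deficient structure fit; undetermined: ",
         paste(nm[qrJ$pivot[(qrJ$rank + 1):3]], collapse = ", "))
  }
  dof <- max(1, length(obs) - 3)
  s2 <- sum((r * sqrt(weights))^2) / dof
  cov <- chol2inv(qr.R(qrJ)[, order(qrJ$pivot), drop = FALSE]) * s2
  se <- setNames(sqrt(diag(cov)),
                 c("d_O_Nr", "angle_O_Nr_C2", "dihedral_HOH_Nr"))
  calc <- model_moments(par)
  resid <- data.frame(
    species = rep(seq_len(nspec), each = 3),
    moment = rep(c("Ia", "Ib", "Ic"), nspec),
    obs = obs, calc = calc, omc = obs - calc)
  structure(list(
    params = cluster_params(par[1], par[2], par[3],
                            nonlinearity = p0$nonlinearity),
    se = se, sigma_fit = sqrt(mean(r^2)), residuals = resid,
    niter = fit$niter),
    class = "structure_fit_result")
}

#' @export
print.structure_fit_result <- function(x, ...) {
  cat("Effective (r0) structure fit\n")
  cat(sprintf("  d(O...Nr)      = %.4f (%.4f) A\n",
              x$params$d_O_Nr, x$se["d_O_Nr"]))
  cat(sprintf("  A(O...Nr-C2)   = %.2f (%.2f) deg\n",
              x$params$angle_O_Nr_C2, x$se["angle_O_Nr_C2"]))
  cat(sprintf("  D(HOH...Nr)    = %.1f (%.1f) deg\n",
              x$params$dihedral_HOH_Nr, x$se["dihedral_HOH_Nr"]))
  cat(sprintf("  sigma_fit      = %.4f uA^2 over %d moments\n",
              x$sigma_fit, nrow(x$residuals)))
  invisible(x)
}
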