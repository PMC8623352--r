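#' Atomic masses of the isotopes used in this package
#'
#' Monoisotopic masses in unified atomic mass units (u) for the most common
#' isotopes plus deuterium (CODATA/AME-style values at the precision needed
#' for microwave-spectroscopy work).
#'
#' @format Named numeric vector; names are element/isotope symbols
#'   (`"H"`, `"D"`, `"C"`, `"N"`, `"O"`).
#' @export
atomic_masses <- c(H = 1.00782503207, D = 2.01410177812, C = 12.0,
                   N = 14.0030740048, O = 15.9949146196)

#' Molecular geometry
#'
#' A light container for an atom list: element symbols, isotope masses and
#' Cartesian coordinates in Angstrom.  Atom labels (e.g. `"Nr"`, `"C2"`)
#' let downstream code address structurally meaningful sites.
#'
#' @param element Character vector of element symbols.
#' @param x,y,z Numeric coordinate vectors (Angstrom).
#' @param mass Optional isotope masses in u; defaults to
#'   [atomic_masses]`[element]`.
#' @param label Optional unique atom labels; defaults to
#'   `element` + position index.
#' @param frame Frame tag: `"arbitrary"` or `"principal"`.
#' @return An object of class `geometry` (a data.frame with attributes).
#' @export
geometry <- function(element, x, y, z, mass = NULL, label = NULL,
                     frame = "arbitrary") {
  n <- length(element)
  stopifnot(length(x) == n, length(y) == n, length(z) == n)
  if (is.null(mass)) mass <- unname(atomic_masses[element])
  if (any(!is.finite(mass)) || any(mass <= 0)) {
    stop("all atoms need positive masses (unknown element symbol?)")
  }
  if (is.null(label)) label <- paste0(element, seq_len(n))
  if (anyDuplicated(label)) stop("atom labels must be unique")
  g <- data.frame(label = label, element = element, mass = mass,
                  x = x, y = y, z = z, stringsAsFactors = FALSE)
  class(g) <- c("geometry", "data.frame")
  attr(g, "frame") <- frame
  g
}

geom_coords <- function(g) as.matrix(g[, c("x", "y", "z")])

#' @export
print.geometry <- function(x, ...) {
  cat(sprintf("Geometry: %d atoms, frame = %s\n", nrow(x), attr(x, "frame")))
  print.data.frame(x, digits = 6)
  invisible(x)
}

#' Principal moments of inertia and principal-axis frame of a geometry
#'
#' Shifts to the centre of mass, diagonalises the inertia tensor and
#' returns the moments ordered `Ia <= Ib <= Ic` together with the geometry
#' rotated into the principal frame (axes a, b, c mapped to x, y, z; the
#' rotation is chosen right-handed).
#'
#' @param g A [geometry()] with at least two atoms.
#' @return A list with `moments` (a [moments_of_inertia()] object),
#'   `geometry` (the rotated geometry, frame `"principal"`) and `axes`
#'   (3x3 rotation matrix whose columns are the principal axes in the
#'   input frame).
#' @export
principal_moments <- function(g) {
  stopifnot(inherits(g, "geometry"))
  if (nrow(g) < 2) stop("moments of inertia are undefined for a single atom")
  X <- geom_coords(g)
  m <- g$mass
  com <- colSums(X * m) / sum(m)
  X <- sweep(X, 2, com)
  I <- matrix(0, 3, 3)
  for (i in seq_len(nrow(X))) {
    r <- X[i, ]
    I <- I + m[i] * (sum(r^2) * diag(3) - tcrossprod(r))
  }
  eig <- eigen(I, symmetric = TRUE)
  ord <- order(eig$values)
  V <- eig$vectors[, ord]
  if (det(V) < 0) V[, 3] <- -V[, 3]
  Xp <- X %*% V
  gp <- g
  gp$x <- Xp[, 1]; gp$y <- Xp[, 2]; gp$z <- Xp[, 3]
  attr(gp, "frame") <- "principal"
  mom <- eig$values[ord]
  # strictly enforce the ordering invariant against numerical ties
  mom <- sort(mom)
  list(moments = moments_of_inertia(mom[1], mom[2], mom[3]),
       geometry = gp, axes = V)
}

#' Substitute isotope masses
#'
#' Replaces the masses of selected atoms (coordinates untouched: isotopic
#' substitution in the rigid equilibrium frame), e.g. single ring
#' deuteration d-5 / d-6.
#'
#' @param g A [geometry()].
#' @param substitutions Data.frame with columns `label` (or `index`) and
#'   `mass`, or a list of `list(label =, mass =)` entries.  An empty list
#'   returns the geometry unchanged.
#' @return The substituted [geometry()].
#' @export
#' @examples
#' w <- water_reference_geometry()
#' make_isotopologue(w, list(list(label = "H1", mass = atomic_masses[["D"]])))
make_isotopologue <- function(g, substitutions) {
  stopifnot(inherits(g, "geometry"))
  if (length(substitutions) == 0) return(g)
  if (is.data.frame(substitutions)) {
    substitutions <- lapply(seq_len(nrow(substitutions)),
                            function(i) as.list(substitutions[i, ]))
  }
  for (s in substitutions) {
    idx <- if (!is.null(s$label)) match(s$label, g$label) else s$index
    if (is.na(idx) || is.null(idx) || idx < 1 || idx > nrow(g)) {
      stop("isotopologue substitution refers to a missing atom")
    }
    if (!is.finite(s$mass) || s$mass <= 0) stop("isotope mass must be positive")
    g$mass[idx] <- s$mass
    if (g$element[idx] == "H" && abs(s$mass - atomic_masses[["D"]]) < 0.1) {
      g$element[idx] <- "D"
    }
  }
  g
}

#' Planar moments of a geometry
#'
#' Mass-weighted sums of squared principal-axis coordinates,
#' `P_g = sum_i m_i g_i^2`; computed in the principal frame.
#'
#' @param g A [geometry()].
#' @return A `planar_moments` object.
#' @export
geometry_planar_moments <- function(g) {
  gp <- if (identical(attr(g, "frame"), "principal")) g
        else principal_moments(g)$geometry
  m <- gp$mass
  structure(list(Pa = sum(m * gp$x^2), Pb = sum(m * gp$y^2),
                 Pc = sum(m * gp$z^2)),
            class = "planar_moments")
}

#' Scale a geometry axis-by-axis to match target planar moments
#'
#' Multiplies the coordinates along each principal axis by an individual
#' factor `f_g = sqrt(P_target / P_current)` so that the scaled geometry
#' reproduces the observed planar moments (and hence the observed
#' rotational constants).  This is the standard way of correcting a
#' computed equilibrium geometry onto the experimental ground state before
#' using it as a rigid fragment in a cluster structure fit.
#'
#' If an axis has (near-)zero planar moment (a planar molecule and the c
#' axis) or the target is non-positive, that axis cannot be scaled to the
#' target; its factor is fixed at 1 and the axis is reported in the
#' `unscaled_axes` attribute.
#'
#' @param g A [geometry()] in the principal frame (see
#'   [principal_moments()]).
#' @param target A `planar_moments` object (u A^2).
#' @return The scaled geometry with attributes `scale_factors` (named
#'   numeric, axes a, b, c) and `unscaled_axes`.
#' @export
scale_geometry_to_planar_moments <- function(g, target) {
  stopifnot(inherits(g, "geometry"), inherits(target, "planar_moments"))
  if (!identical(attr(g, "frame"), "principal")) {
    stop("geometry must be in the principal-axis frame")
  }
  cur <- geometry_planar_moments(g)
  axes <- c("a", "b", "c")
  curv <- c(cur$Pa, cur$Pb, cur$Pc)
  tgtv <- c(target$Pa, target$Pb, target$Pc)
  fac <- rep(1, 3)
  unscaled <- character(0)
  for (i in 1:3) {
    if (curv[i] < 1e-8 || tgtv[i] <= 0) {
      unscaled <- c(unscaled, axes[i])
    } else {
      fac[i] <- sqrt(tgtv[i] / curv[i])
    }
  }
  g$x <- g$x * fac[1]; g$y <- g$y * fac[2]; g$z <- g$z * fac[3]
  attr(g, "scale_factors") <- setNames(fac, axes)
  attr(g, "unscaled_axes") <- unscaled
  g
}

#' Read / write XYZ geometry files
#'
#' Standard XYZ format (count line, comment line, then `element x y z`
#' rows) with an optional fifth column holding the isotope mass in u.
#'
#' @param path File path.
#' @return `read_xyz()` returns a [geometry()].
#' @export
read_xyz <- function(path) {
  ln <- readLines(path)
  n <- as.integer(trimws(ln[1]))
  rows <- strsplit(trimws(ln[3:(2 + n)]), "\\s+")
  el <- vapply(rows, `[[`, character(1), 1)
  xyz <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3)))
  mass <- vapply(rows, function(r) {
    if (length(r) >= 5) as.numeric(r[5]) else NA_real_
  }, numeric(1))
  if (all(is.na(mass))) mass <- NULL else {
    mass[is.na(mass)] <- unname(atomic_masses[el[is.na(mass)]])
  }
  geometry(el, xyz[, 1], xyz[, 2], xyz[, 3], mass = mass)
}

#' @param g A [geometry()] to write.
#' @param comment Comment line for the file.
#' @rdname read_xyz
#' @export
write_xyz <- function(g, path, comment = "") {
  stopifnot(inherits(g, "geometry"))
  lines <- c(as.character(nrow(g)), comment,
             sprintf("%-2s %14.8f %14.8f %14.8f %14.8f",
                     g$element, g$x, g$y, g$z, g$mass))
  writeLines(lines, path)
  invisible(path)
}
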