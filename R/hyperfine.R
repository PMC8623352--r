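#' Hyperfine sublevels of one rotational level (two coupled spin-1 nuclei)
#'
#' First-order nuclear quadrupole analysis within a single rotational level:
#' the interaction of each nucleus is projected onto the level (no mixing of
#' different rotational states, valid because couplings of a few MHz are
#' small against GHz-scale rotational spacings) and the resulting operator
#' is diagonalised in the coupled basis `|J, (I1 I2) Itot, F>` with
#' Itot = I(N1) + I(N2) and F = J + Itot.  Recoupling uses Wigner 6-j
#' algebra; the spins must both be 1 (14N).
#'
#' Within a level only the diagonal couplings chi_aa, chi_bb, chi_cc
#' contribute at first order; chi_ab connects different rotational states
#' and enters only through level mixing, which this treatment neglects.
#'
#' @param states A [rotor_states()] object.
#' @param J,Ka,Kc Quantum labels of the rotational level.
#' @param tensors List of one or two [quadrupole_tensor()] objects, coupling
#'   order fixed as `I(N1) + I(N2)` matching the list order.  A single
#'   tensor is padded with a zero tensor for the second nucleus.
#' @return A data.frame with columns `F`, `Itot` (label of the dominant
#'   coupled-spin component), `shift` (MHz), plus an attribute
#'   `"eigenvectors"`: a list (one entry per F) of matrices whose columns
#'   are sublevel eigenvectors over the Itot basis given in attribute
#'   `"Itot_basis"`.
#' @export
#' @examples
#' rc <- rotational_constants(5780.375, 2733.504, 1857.675)
#' st <- rotor_states(rc, J_max = 1)
#' na <- tensor_from_fit_params(3.5854, 1.50413, nucleus = "Na")
#' nr <- tensor_from_fit_params(-0.0789, -1.15823, nucleus = "Nr")
#' hyperfine_levels(st, 1, 0, 1, list(na, nr))
hyperfine_levels <- function(states, J, Ka, Kc, tensors) {
  tensors <- normalize_tensor_pair(tensors)
  I1 <- tensors[[1]]$spin; I2 <- tensors[[2]]$spin
  if (I1 != 1 || I2 != 1) {
    stop("hyperfine_levels: only two spin-1 nuclei are supported")
  }
  vec <- level_vector(states, J, Ka, Kc)
  RR <- vapply(tensors, function(t) rot_reduced_element(vec, J, t), numeric(1))
  RS <- spin_reduced_element(1)
  pref <- 1 / (6 * 1 * (2 * 1 - 1))          # 1/(6 I (2I-1)) for I = 1
  Fs <- seq(max(0, J - 2), J + 2)
  out_F <- integer(0); out_I <- integer(0); out_E <- numeric(0)
  eigvecs <- list(); bases <- list()
  for (f in Fs) {
    Is <- (0:2)[abs(J - 0:2) <= f & f <= J + 0:2]
    nI <- length(Is)
    if (nI == 0) next
    H <- matrix(0, nI, nI)
    for (ai in seq_len(nI)) {
      for (bi in seq_len(nI)) {
        Ip <- Is[ai]; Ii <- Is[bi]
        sc <- wigner6j(2, J, J, f, Ii, Ip)
        nuc <- sqrt((2 * Ii + 1) * (2 * Ip + 1)) * wigner6j(1, Ip, 1, Ii, 1, 2)
        ph2 <- (-1)^(f + J)
        ph1 <- (-1)^(f + Ii + Ip + J)
        H[ai, bi] <- pref * sc * nuc * RS *
          (ph1 * RR[1] + ph2 * RR[2])
      }
    }
    eig <- eigen(H, symmetric = TRUE)
    ord <- order(eig$values)
    V <- eig$vectors[, ord, drop = FALSE]
    # unique Itot labels: greedily pair sublevels with basis states by
    # descending overlap, so every label in an F block is distinct even
    # under strong Itot mixing
    lab <- integer(nI)
    Wt <- V^2
    for (step in seq_len(nI)) {
      ij <- arrayInd(which.max(Wt), dim(Wt))
      lab[ij[2]] <- Is[ij[1]]
      Wt[ij[1], ] <- -1
      Wt[, ij[2]] <- -1
    }
    out_F <- c(out_F, rep(f, nI))
    out_I <- c(out_I, lab)
    out_E <- c(out_E, eig$values[ord])
    eigvecs[[as.character(f)]] <- V
    bases[[as.character(f)]] <- Is
  }
  res <- data.frame(F = out_F, Itot = out_I, shift = out_E)
  attr(res, "eigenvectors") <- eigvecs
  attr(res, "Itot_basis") <- bases
  attr(res, "J") <- J
  res
}

## Pad/validate the tensor argument into a list of exactly two tensors.
normalize_tensor_pair <- function(tensors) {
  if (inherits(tensors, "quadrupole_tensor")) tensors <- list(tensors)
  stopifnot(is.list(tensors), length(tensors) %in% c(1, 2))
  for (t in tensors) stopifnot(inherits(t, "quadrupole_tensor"))
  if (length(tensors) == 1) {
    tensors[[2]] <- quadrupole_tensor(0, 0, 0, 0, "zero", tensors[[1]]$spin)
  }
  tensors
}

## Spherical components (q = -2..2) of a planar coupling tensor in the Ir
## frame (z = a, x = b, y = c); all real for chi_ac = chi_bc = 0.
tensor_spherical <- function(t) {
  c(`-2` = (t$chi_bb - t$chi_cc) / 2,
    `-1` = t$chi_ab,
    `0`  = sqrt(3 / 2) * t$chi_aa,
    `1`  = -t$chi_ab,
    `2`  = (t$chi_bb - t$chi_cc) / 2)
}

## Reduced matrix element <J||T2(eQV)||J> of the lab-frame coupling tensor
## within one rotational level with signed-k eigenvector `vec`.
rot_reduced_element <- function(vec, J, tensor) {
  if (J == 0) return(0)
  T2 <- tensor_spherical(tensor)
  ks <- -J:J
  W <- 0
  for (q in -2:2) {
    kp <- ks - q                       # <J kp 2 q | J k>
    ok <- abs(kp) <= J
    if (!any(ok)) next
    cg <- vapply(which(ok), function(i) {
      clebsch_gordan(J, kp[i], 2, q, J, ks[i])
    }, numeric(1))
    W <- W + T2[[as.character(q)]] * sum(vec[ok] * vec[match(kp[ok], ks)] * cg)
  }
  W * clebsch_gordan(J, J, 2, 0, J, J) / wigner3j(J, 2, J, -J, 0, J)
}

## Reduced matrix element <I||T2(spin)||I> of the spin quadrupole tensor
## operator (3/2)(Ia Ib + Ib Ia) - delta_ab I^2 mapped to spherical form.
spin_reduced_element <- function(I) {
  sqrt(3 / 2) * I * (2 * I - 1) / wigner3j(I, 2, I, -I, 0, I)
}

#' Hyperfine splitting pattern of one rotational transition
#'
#' Combines [hyperfine_levels()] of the upper and lower rotational level
#' into the list of allowed hyperfine components (Delta F = 0, +-1, F = 0
#' to F' = 0 forbidden), with relative intensities from coupled-basis
#' line-strength factors (6-j recoupling of the rotation-only dipole
#' operator, diagonal in Itot) normalised to sum to 1 within the
#' rotational transition.
#'
#' @param states A [rotor_states()] object covering both levels.
#' @param upper,lower Length-3 integer vectors `c(J, Ka, Kc)`.
#' @param tensors List of one or two [quadrupole_tensor()] objects (same
#'   coupling order for both levels).
#' @param collapse_tol Components whose offsets agree within this tolerance
#'   (MHz) are merged into one line with summed intensity, as an
#'   experimentalist would count them; set to 0 to keep every (F', F) pair.
#' @return A data.frame with columns `F_up`, `Itot_up`, `F_lo`, `Itot_lo`,
#'   `offset` (MHz, component frequency minus unsplit rotational frequency)
#'   and `rel_intensity` (sums to 1).
#' @export
hyperfine_pattern <- function(states, upper, lower, tensors,
                              collapse_tol = 1e-9) {
  tensors <- normalize_tensor_pair(tensors)
  Ju <- upper[1]; Jl <- lower[1]
  if (abs(Ju - Jl) > 1) stop("electric dipole transitions require |dJ| <= 1")
  hu <- hyperfine_levels(states, Ju, upper[2], upper[3], tensors)
  hl <- hyperfine_levels(states, Jl, lower[2], lower[3], tensors)
  vu <- attr(hu, "eigenvectors"); bu <- attr(hu, "Itot_basis")
  vl <- attr(hl, "eigenvectors"); bl <- attr(hl, "Itot_basis")
  rows <- list()
  for (iu in seq_len(nrow(hu))) {
    Fu <- hu$F[iu]
    # column index of this sublevel within its F block
    cu <- sum(hu$F[seq_len(iu)] == Fu)
    au <- vu[[as.character(Fu)]][, cu]
    Iu_basis <- bu[[as.character(Fu)]]
    for (il in seq_len(nrow(hl))) {
      Fl <- hl$F[il]
      if (abs(Fu - Fl) > 1 || (Fu == 0 && Fl == 0)) next
      cl <- sum(hl$F[seq_len(il)] == Fl)
      al <- vl[[as.character(Fl)]][, cl]
      Il_basis <- bl[[as.character(Fl)]]
      amp <- 0
      for (I in intersect(Iu_basis, Il_basis)) {
        ai <- au[match(I, Iu_basis)]
        bi <- al[match(I, Il_basis)]
        amp <- amp + ai * bi * (-1)^(Ju + I + Fl + 1) *
          sqrt((2 * Fu + 1) * (2 * Fl + 1)) *
          wigner6j(Ju, Fu, I, Fl, Jl, 1)
      }
      s <- amp^2
      if (s > 1e-14) {
        rows[[length(rows) + 1]] <- data.frame(
          F_up = Fu, Itot_up = hu$Itot[iu],
          F_lo = Fl, Itot_lo = hl$Itot[il],
          offset = hu$shift[iu] - hl$shift[il],
          rel_intensity = s)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$rel_intensity <- out$rel_intensity / sum(out$rel_intensity)
  out <- out[order(out$offset), ]
  rownames(out) <- NULL
  if (collapse_tol > 0 && nrow(out) > 1) {
    grp <- cumsum(c(TRUE, diff(out$offset) > collapse_tol))
    merged <- lapply(split(out, grp), function(d) {
      lead <- d[which.max(d$rel_intensity), ]
      lead$offset <- sum(d$offset * d$rel_intensity) / sum(d$rel_intensity)
      lead$rel_intensity <- sum(d$rel_intensity)
      lead
    })
    out <- do.call(rbind, merged)
    rownames(out) <- NULL
  }
  out
}
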