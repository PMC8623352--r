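#' Asymmetric-rotor energy levels and wavefunctions
#'
#' Diagonalises the Watson A-reduced rotational Hamiltonian (representation
#' Ir, quantisation axis z = a) in a signed-K symmetric-top basis for every
#' J up to `J_max`.  The Hamiltonian is built per Wang symmetry block
#' (E+/E-/O+/O-), each block is diagonalised separately, and (Ka, Kc) labels
#' are assigned by ascending energy onto the standard asymmetric-top ladder.
#'
#' The operator form is
#' `H = A Jz^2 + B Jx^2 + C Jy^2 - DJ J^4 - DJK J^2 Jz^2 - DK Jz^4
#'  - 2 dJ J^2 (Jx^2 - Jy^2) - dK [Jz^2 (Jx^2 - Jy^2) + (Jx^2 - Jy^2) Jz^2]
#'  + HK Jz^6`
#' with (x, y, z) = (b, c, a).
#'
#' @param rc A [rotational_constants()] object (MHz).
#' @param dist A [distortion_set()] (quartics kHz, sextic Hz); defaults to a
#'   rigid rotor.
#' @param J_max Highest rotational quantum number J (>= 0).
#' @return An object of class `rotor_states`: a list with `levels` (a
#'   data.frame with columns `J`, `Ka`, `Kc`, `energy` in MHz relative to
#'   the 0_00 level) and `vectors` (per-J matrices of eigenvectors in the
#'   signed-k basis, rows ordered k = -J..J, columns matching the rows of
#'   `levels` for that J).
#' @export
#' @examples
#' rc <- rotational_constants(5780.37487, 2733.50446, 1857.675172, "0+")
#' st <- rotor_states(rc, J_max = 2)
#' subset(st$levels, J == 1)
rotor_states <- function(rc, dist = distortion_set(), J_max) {
  stopifnot(inherits(rc, "rotational_constants"),
            inherits(dist, "distortion_set"))
  if (length(J_max) != 1 || J_max < 0 || J_max != round(J_max)) {
    stop("J_max must be a non-negative integer")
  }
  cons <- list(A = rc$A, B = rc$B, C = rc$C,
               DJ = dist$DJ * 1e-3, DJK = dist$DJK * 1e-3, DK = dist$DK * 1e-3,
               dJ = dist$dJ * 1e-3, dK = dist$dK * 1e-3, HK = dist$HK * 1e-6)
  lev <- vector("list", J_max + 1)
  vecs <- vector("list", J_max + 1)
  for (J in 0:J_max) {
    sol <- solve_one_J(J, cons)
    lev[[J + 1]] <- sol$levels
    vecs[[J + 1]] <- sol$vectors
  }
  levels <- do.call(rbind, lev)
  rownames(levels) <- NULL
  structure(list(levels = levels, vectors = vecs, rc = rc, dist = dist),
            class = "rotor_states")
}

#' Rotational energy levels
#'
#' Convenience wrapper around [rotor_states()] returning only the level
#' table.
#'
#' @inheritParams rotor_states
#' @return A data.frame with columns `J`, `Ka`, `Kc`, `energy` (MHz,
#'   relative to 0_00).
#' @export
energy_levels <- function(rc, dist = distortion_set(), J_max) {
  rotor_states(rc, dist, J_max)$levels
}

## Diagonal element <k|H|k> at given J (MHz).
watson_h0 <- function(J, k, cons) {
  jj <- J * (J + 1)
  0.5 * (cons$B + cons$C) * (jj - k^2) + cons$A * k^2 -
    cons$DJ * jj^2 - cons$DJK * jj * k^2 - cons$DK * k^4 + cons$HK * k^6
}

## Off-diagonal element <k+2|H|k> at given J (MHz).
watson_h2 <- function(J, k, cons) {
  jj <- J * (J + 1)
  coef <- 0.25 * (cons$B - cons$C) - cons$dJ * jj -
    0.5 * cons$dK * (k^2 + (k + 2)^2)
  coef * sqrt((jj - k * (k + 1)) * (jj - (k + 1) * (k + 2)))
}

## Build and diagonalise the four Wang blocks for one J; returns levels and
## eigenvectors mapped back to the signed-k basis (rows k = -J..J).
solve_one_J <- function(J, cons) {
  n <- 2 * J + 1
  if (J == 0) {
    levels <- data.frame(J = 0L, Ka = 0L, Kc = 0L, energy = watson_h0(0, 0, cons))
    return(list(levels = levels, vectors = matrix(1, 1, 1)))
  }
  blocks <- list(
    Ep = seq(0, J, by = 2),
    Em = if (J >= 2) seq(2, J, by = 2) else integer(0),
    Op = seq(1, J, by = 2),
    Om = seq(1, J, by = 2)
  )
  energies <- numeric(0)
  parities <- character(0)
  veclist <- list()
  for (bn in names(blocks)) {
    ks <- blocks[[bn]]
    if (length(ks) == 0) next
    m <- length(ks)
    H <- matrix(0, m, m)
    sgn <- if (bn %in% c("Ep", "Op")) 1 else -1
    for (i in seq_len(m)) {
      k <- ks[i]
      H[i, i] <- watson_h0(J, k, cons)
      if (k == 1) H[i, i] <- H[i, i] + sgn * watson_h2(J, -1, cons)
      if (i < m) {
        v <- watson_h2(J, k, cons)
        if (k == 0) v <- sqrt(2) * v
        H[i, i + 1] <- v
        H[i + 1, i] <- v
      }
    }
    eig <- eigen(H, symmetric = TRUE)
    for (col in seq_len(m)) {
      w <- eig$vectors[, m - col + 1]  # eigen() sorts decreasing; reverse
      full <- numeric(n)               # signed basis index: k + J + 1
      for (i in seq_len(m)) {
        k <- ks[i]
        if (k == 0) {
          full[J + 1] <- w[i]
        } else {
          full[k + J + 1] <- w[i] / sqrt(2)
          full[-k + J + 1] <- sgn * w[i] / sqrt(2)
        }
      }
      veclist[[length(veclist) + 1]] <- full
      energies <- c(energies, eig$values[m - col + 1])
      parities <- c(parities, bn)
    }
  }
  ord <- order(energies, parities)  # parity as deterministic tie-break
  energies <- energies[ord]
  veclist <- veclist[ord]
  idx <- seq_len(n) - 1
  levels <- data.frame(J = as.integer(J),
                       Ka = as.integer(floor((idx + 1) / 2)),
                       Kc = as.integer(J - floor(idx / 2)),
                       energy = energies)
  list(levels = levels, vectors = do.call(cbind, veclist))
}

#' Retrieve the signed-k eigenvector of one rotational level
#'
#' @param states A `rotor_states` object.
#' @param J,Ka,Kc Quantum labels of the level.
#' @return Numeric vector of length 2J+1 (basis k = -J..J).
#' @export
level_vector <- function(states, J, Ka, Kc) {
  stopifnot(inherits(states, "rotor_states"))
  lv <- states$levels
  sel <- which(lv$J == J & lv$Ka == Ka & lv$Kc == Kc)
  if (length(sel) != 1) stop(sprintf("level %d_%d,%d not found", J, Ka, Kc))
  within_J <- sel - match(J, lv$J) + 1
  states$vectors[[J + 1]][, within_J]
}

#' Energy of one rotational level
#'
#' @inheritParams level_vector
#' @return Energy in MHz relative to 0_00.
#' @export
level_energy <- function(states, J, Ka, Kc) {
  lv <- states$levels
  sel <- which(lv$J == J & lv$Ka == Ka & lv$Kc == Kc)
  if (length(sel) != 1) stop(sprintf("level %d_%d,%d not found", J, Ka, Kc))
  lv$energy[sel]
}
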