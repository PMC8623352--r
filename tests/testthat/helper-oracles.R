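## Independent oracles used across the test suite.  These deliberately take
## a different computational route from the package: dense matrix algebra
## from angular-momentum operators instead of Wang blocks and closed-form
## matrix elements, and an uncoupled product basis instead of 6-j
## recoupling.

## Angular momentum matrices in the |j, m> basis, m = j..-j (molecule-fixed
## ladder convention; eigenvalues are convention independent).
ao_spin_ops <- function(I) {
  n <- round(2 * I + 1)
  ms <- seq(I, -I)
  Jz <- diag(ms, nrow = n)
  Jp <- matrix(0, n, n)
  for (m in ms) {
    if (m + 1 <= I) Jp[match(m + 1, ms), match(m, ms)] <- sqrt(I * (I + 1) - m * (m + 1))
  }
  Jm <- t(Jp)
  list(x = (Jp + Jm) / 2, y = (Jp - Jm) / (2i), z = Jz * (1 + 0i),
       ms = ms)
}

## Dense Watson A-reduction Hamiltonian from operator products; returns the
## sorted eigenvalues for one J (MHz).
oracle_rotor_levels <- function(rc, dist, J) {
  op <- ao_spin_ops(J)
  n <- 2 * J + 1
  J2 <- diag(n) * J * (J + 1)
  Jz2 <- op$z %*% op$z
  Jx2 <- op$x %*% op$x
  Jy2 <- op$y %*% op$y
  Jxy <- Jx2 - Jy2
  H <- rc$A * Jz2 + rc$B * Jx2 + rc$C * Jy2 -
    (dist$DJ * 1e-3) * J2 %*% J2 -
    (dist$DJK * 1e-3) * J2 %*% Jz2 -
    (dist$DK * 1e-3) * Jz2 %*% Jz2 -
    2 * (dist$dJ * 1e-3) * J2 %*% Jxy -
    (dist$dK * 1e-3) * (Jz2 %*% Jxy + Jxy %*% Jz2) +
    (dist$HK * 1e-6) * Jz2 %*% Jz2 %*% Jz2
  sort(Re(eigen(H, only.values = TRUE)$values))
}

## Spherical spin quadrupole tensor operators T2_q for spin I from the
## Cartesian form (3/2)(Ia Ib + Ib Ia) - delta_ab I^2.
oracle_spin_T2 <- function(I) {
  op <- ao_spin_ops(I)
  Iden <- diag(round(2 * I + 1)) * I * (I + 1)
  S <- list()
  for (a in c("x", "y", "z")) {
    for (b in c("x", "y", "z")) {
      S[[paste0(a, b)]] <- 1.5 * (op[[a]] %*% op[[b]] + op[[b]] %*% op[[a]]) -
        (if (a == b) Iden else 0)
    }
  }
  list(`-2` = 0.5 * (S$xx - S$yy - 2i * S$xy),
       `-1` = S$xz - 1i * S$yz,
       `0`  = (2 * S$zz - S$xx - S$yy) / sqrt(6),
       `1`  = -(S$xz + 1i * S$yz),
       `2`  = 0.5 * (S$xx - S$yy + 2i * S$xy))
}

## First-order quadupole eigenshifts of one rotational level for two spin-1
## nuclei, from brute-force diagonalisation in the uncoupled product basis
## |J m> |I1 m1> |I2 m2>.  Returns sorted shifts with multiplicities.
oracle_hyperfine_shifts <- function(states, J, Ka, Kc, tensors) {
  v <- level_vector(states, J, Ka, Kc)
  ms <- seq(J, -J)
  W_of <- function(t) {
    T2 <- c(`-2` = (t$chi_bb - t$chi_cc) / 2, `-1` = t$chi_ab,
            `0` = sqrt(1.5) * t$chi_aa, `1` = -t$chi_ab,
            `2` = (t$chi_bb - t$chi_cc) / 2)
    ks <- -J:J
    W <- 0
    for (q in -2:2) {
      for (i in seq_along(ks)) {
        kp <- ks[i] - q
        if (abs(kp) <= J) {
          W <- W + T2[[as.character(q)]] * v[i] * v[kp + J + 1] *
            clebsch_gordan(J, kp, 2, q, J, ks[i])
        }
      }
    }
    W
  }
  rot_q <- function(q, W) {
    M <- matrix(0 + 0i, 2 * J + 1, 2 * J + 1)
    for (a in seq_along(ms)) {
      for (b in seq_along(ms)) {
        M[a, b] <- clebsch_gordan(J, ms[b], 2, q, J, ms[a]) * W
      }
    }
    M
  }
  T2s <- oracle_spin_T2(1)
  id3 <- diag(3)
  n <- (2 * J + 1) * 9
  H <- matrix(0 + 0i, n, n)
  Ws <- vapply(tensors, W_of, numeric(1))
  for (i in seq_along(tensors)) {
    for (q in -2:2) {
      sp <- T2s[[as.character(-q)]]
      Sp <- if (i == 1) kronecker(sp, id3) else kronecker(id3, sp)
      H <- H + (1 / 6) * (-1)^q * kronecker(rot_q(q, Ws[i]), Sp)
    }
  }
  sort(Re(eigen(H, symmetric = TRUE, only.values = TRUE)$values))
}

## Casimir/Bragg closed-form first-order quadrupole shifts of one
## asymmetric-rotor level for a single I = 1 nucleus: E(F) for F = |J-1|..J+1.
oracle_casimir_shifts <- function(states, J, Ka, Kc, tensor, I = 1) {
  v <- level_vector(states, J, Ka, Kc)
  ks <- -J:J
  op <- ao_spin_ops(J)
  Ja2 <- sum(v^2 * ks^2)
  Jb2 <- Re(t(v) %*% (op$x %*% op$x) %*% v)[1]
  Jc2 <- Re(t(v) %*% (op$y %*% op$y) %*% v)[1]
  chiJ <- tensor$chi_aa * Ja2 + tensor$chi_bb * Jb2 + tensor$chi_cc * Jc2
  Fs <- seq(abs(J - I), J + I)
  vapply(Fs, function(F) {
    C <- F * (F + 1) - I * (I + 1) - J * (J + 1)
    Y <- (0.75 * C * (C + 1) - I * (I + 1) * J * (J + 1)) /
      (2 * I * (2 * I - 1) * (2 * J - 1) * (2 * J + 3))
    2 * Y / (J * (J + 1)) * chiJ
  }, numeric(1)) |> setNames(Fs)
}

## Reference constants used throughout: AMP parent global-fit values and
## the AMW cluster values, read from the packaged tables.
amp_constants <- function() read_constants(rotspec_example("amp.yaml"))
amw_constants <- function() read_constants(rotspec_example("amw.yaml"))

amp_host_scaled <- function() {
  cons <- amp_constants()
  scale_geometry_to_planar_moments(
    amp_reference_geometry(),
    planar_moments(moments_from_constants(cons$states$ground$rc)))
}

amw_iso_specs <- function() {
  D <- atomic_masses[["D"]]
  list(NULL,
       list(list(label = "H5", mass = D)),
       list(list(label = "H6", mass = D)))
}
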