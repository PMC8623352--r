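rc_amp <- rotational_constants(5780.37487, 2733.50446, 1857.675172, "0+")
dist_amp <- distortion_set(0.137392, 0.202586, 0.93717, 0.0458083, 0.365545,
                           0.000643)

test_that("moments of inertia follow from the conversion identity", {
  iso <- rotational_constants(505379.07, 505379.07, 505379.07)
  m <- moments_from_constants(iso)
  expect_equal(c(m$Ia, m$Ib, m$Ic), c(1, 1, 1))
  m2 <- moments_from_constants(rc_amp)
  expect_equal(m2$Ia, 505379.07 / 5780.37487, tolerance = 1e-12)
  expect_true(m2$Ia <= m2$Ib && m2$Ib <= m2$Ic)
  expect_error(rotational_constants(-1, -2, -3), "positive")
  expect_error(rotational_constants(1000, 2000, 500), "A >= B >= C")
  # cluster constants reproduce the tabulated experimental moments to the
  # precision the published table is internally consistent to (~0.003 uA^2)
  amw <- moments_from_constants(rotational_constants(3722.8201, 1384.23544,
                                                     1011.15836))
  expect_lt(abs(amw$Ia - 135.7523), 0.003)
  expect_lt(abs(amw$Ib - 365.0978), 0.003)
  expect_lt(abs(amw$Ic - 499.8001), 0.003)
})

test_that("inertial defect and planar moments have their defining relations", {
  m <- moments_of_inertia(2, 3, 5)        # Ic = Ia + Ib: rigid planar body
  expect_equal(inertial_defect(m), 0)
  expect_equal(planar_moments(m)$Pc, 0)
  sphere <- moments_of_inertia(1, 1, 1)
  p <- planar_moments(sphere)
  expect_equal(c(p$Pa, p$Pb, p$Pc), c(0.5, 0.5, 0.5))
  # defect of the quasi-planar aromatic: Pc = -defect/2
  mA <- moments_from_constants(rc_amp)
  expect_equal(planar_moments(mA)$Pc, -inertial_defect(mA) / 2,
               tolerance = 1e-12)
  expect_equal(planar_moments(mA)$Pc, 0.1321, tolerance = 1e-3)
  # increasing C at fixed A, B decreases Ic and therefore the defect
  rc_up <- rotational_constants(rc_amp$A, rc_amp$B, rc_amp$C + 5)
  expect_lt(inertial_defect(moments_from_constants(rc_up)),
            inertial_defect(mA))
})

test_that("rigid-rotor J = 1 energies take their closed form", {
  st <- rotor_states(rc_amp, J_max = 1)
  expect_equal(nrow(st$levels), 4)
  expect_equal(level_energy(st, 0, 0, 0), 0)
  expect_equal(level_energy(st, 1, 0, 1), rc_amp$B + rc_amp$C,
               tolerance = 1e-12)
  expect_equal(level_energy(st, 1, 1, 1), rc_amp$A + rc_amp$C,
               tolerance = 1e-12)
  expect_equal(level_energy(st, 1, 1, 0), rc_amp$A + rc_amp$B,
               tolerance = 1e-12)
})

test_that("every J block carries exactly 2J+1 levels with valid labels", {
  st <- rotor_states(rc_amp, dist_amp, J_max = 8)
  for (J in 0:8) {
    blk <- st$levels[st$levels$J == J, ]
    expect_equal(nrow(blk), 2 * J + 1)
    expect_true(all(blk$Ka + blk$Kc %in% c(J, J + 1)))
    expect_true(all(blk$Ka >= 0 & blk$Ka <= J & blk$Kc >= 0 & blk$Kc <= J))
    expect_false(is.unsorted(blk$energy))
  }
  expect_error(rotor_states(rc_amp, J_max = -1), "non-negative")
})

test_that("spherical-top limit collapses each J to B J(J+1)", {
  iso <- rotational_constants(1000, 1000, 1000)
  st <- rotor_states(iso, J_max = 4)
  for (J in 0:4) {
    e <- st$levels$energy[st$levels$J == J]
    expect_equal(e, rep(1000 * J * (J + 1), 2 * J + 1), tolerance = 1e-12)
  }
})

test_that("Wang-block energies match dense operator diagonalisation", {
  st <- rotor_states(rc_amp, dist_amp, J_max = 10)
  worst <- 0
  for (J in 0:10) {
    mine <- sort(st$levels$energy[st$levels$J == J])
    orac <- oracle_rotor_levels(rc_amp, dist_amp, J)
    worst <- max(worst, max(abs(mine - orac)))
  }
  expect_lt(worst, 1e-6)   # 1 Hz in MHz units
})

test_that("eigenvectors are orthonormal within each J block", {
  st <- rotor_states(rc_amp, dist_amp, J_max = 5)
  for (J in 2:5) {
    V <- st$vectors[[J + 1]]
    expect_equal(crossprod(V), diag(2 * J + 1), tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})

test_that("only the A-reduction in representation Ir is accepted", {
  expect_error(distortion_set(reduction = "S"), "A-reduction")
  expect_error(distortion_set(representation = "IIIl"), "Ir")
})
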