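cons <- amp_constants()
rc <- cons$states$ground$rc
dd <- cons$states$ground$dist

test_that("dipole selection rules emerge from the matrix elements", {
  m_none <- spectrum_model(rc, dd, mu = c(0, 0, 0))
  expect_warning(tr0 <- predict_spectrum(m_none, 4000, 30000, J_max = 2),
                 "dipole")
  expect_equal(nrow(tr0), 0)

  m_b <- spectrum_model(rc, dd, mu = c(0, 0.86, 0))
  trb <- predict_spectrum(m_b, 1000, 40000, J_max = 3)
  expect_true(all(trb$type == "b"))
  expect_true(all(abs(trb$Ka_up - trb$Ka_lo) %% 2 == 1))
  expect_true(all(abs(trb$Kc_up - trb$Kc_lo) %% 2 == 1))

  m_a <- spectrum_model(rc, dd, mu = c(0.166, 0, 0))
  tra <- predict_spectrum(m_a, 1000, 40000, J_max = 3)
  expect_true(all(tra$type == "a"))
  expect_true(all(abs(tra$Ka_up - tra$Ka_lo) %% 2 == 0))
})

test_that("low-J line strengths and intensity ratios match hand computation", {
  st <- rotor_states(rc, dd, 2)
  expect_equal(line_strength(st, c(1, 0, 1), c(0, 0, 0), c(1, 0, 0)), 1,
               tolerance = 1e-9)
  expect_equal(line_strength(st, c(1, 1, 1), c(0, 0, 0), c(0, 1, 0)), 1,
               tolerance = 1e-9)
  expect_equal(line_strength(st, c(1, 0, 1), c(0, 0, 0), c(0, 1, 0)), 0)

  # two lines out of 0_00: intensity ratio = (mu line strength x nu) ratio,
  # Boltzmann factors identical
  m <- spectrum_model(rc, dd, mu = c(0.166, 0.86, 0), temperature = 1)
  tr <- predict_spectrum(m, 1000, 40000, J_max = 2)
  l1 <- tr[tr$J_up == 1 & tr$Ka_up == 0 & tr$J_lo == 0, ]
  l2 <- tr[tr$J_up == 1 & tr$Ka_up == 1 & tr$Kc_up == 1 & tr$J_lo == 0, ]
  expect_equal(l1$intensity / l2$intensity,
               (0.166^2 * l1$frequency) / (0.86^2 * l2$frequency),
               tolerance = 1e-9)
})

test_that("hyperfine substructure can be attached to predictions", {
  m <- spectrum_model(rc, dd, mu = c(0.166, 0.86, 0),
                      tensors = unname(cons$tensors))
  tr <- predict_spectrum(m, 4000, 15000, J_max = 2, hyperfine = TRUE)
  expect_true(all(c("F_up", "F_lo", "offset", "rel_intensity") %in% names(tr)))
  one <- tr[tr$J_up == 1 & tr$J_lo == 0 & tr$Ka_up == 0, ]
  expect_gt(nrow(one), 3)
  expect_equal(sum(one$rel_intensity), 1, tolerance = 1e-9)
})

test_that("type-II band spacing of a synthetic prolate model equals 2C", {
  # every term of the Hamiltonian is linear in its constant, so scaling the
  # whole constant set by s scales the spectrum, and the band spacing stays
  # locked to 2C: a synthetic near-planar rotor with C = 1000 MHz must give
  # 2000 MHz
  base <- read_constants(rotspec_example("amp_mmw.yaml"))$states[["0+"]]
  s <- 1000 / base$rc$C
  rcs <- rotational_constants(base$rc$A * s, base$rc$B * s, 1000)
  dds <- distortion_set(base$dist$DJ * s, base$dist$DJK * s, base$dist$DK * s,
                        base$dist$dJ * s, base$dist$dK * s, base$dist$HK * s)
  m <- spectrum_model(rcs, dds, mu = c(1, 0, 0), temperature = 300 * s)
  tr <- predict_spectrum(m, 256000 * s, 276000 * s, J_max = 130, max_dKa = 0,
                         strengths = TRUE)
  sp <- type2_band_spacing(tr, bw = 120 * s, grid_step = 10 * s)
  expect_equal(as.numeric(sp), 2000, tolerance = 0.005)
  # fewer than two bands is a detected degenerate input
  expect_error(type2_band_spacing(tr[tr$frequency < (256000 + 2500) * s, ],
                                  bw = 120 * s, grid_step = 10 * s),
               "fewer than two")
})

test_that("cat-style export writes one row per component", {
  m <- spectrum_model(rc, dd, mu = c(0.166, 0.86, 0))
  tr <- predict_spectrum(m, 4000, 25000, J_max = 2)
  f <- tempfile(fileext = ".cat")
  write_cat(tr, f)
  expect_equal(length(readLines(f)), nrow(tr))
})
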