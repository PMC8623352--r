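cons <- amp_constants()
st3 <- rotor_states(cons$states$ground$rc, cons$states$ground$dist, J_max = 3)
na <- cons$tensors$Na
nr <- cons$tensors$Nr

test_that("single-nucleus shifts reproduce the closed-form Casimir pattern", {
  for (lv in list(c(1, 0, 1), c(1, 1, 0), c(2, 0, 2), c(3, 1, 3))) {
    hl <- hyperfine_levels(st3, lv[1], lv[2], lv[3], list(na))
    cas <- oracle_casimir_shifts(st3, lv[1], lv[2], lv[3], na)
    # with the second spin silent, each single-nucleus F1 level recurs in the
    # two-spin ladder; the distinct shift values must match the Casimir set
    expect_equal(sort(unique(round(hl$shift, 9))),
                 sort(unique(round(unname(cas), 9))), tolerance = 1e-7)
  }
})

test_that("two-nucleus shifts match the uncoupled product-basis oracle", {
  for (lv in list(c(1, 0, 1), c(1, 1, 1), c(2, 1, 2), c(2, 2, 0),
                  c(3, 0, 3), c(3, 2, 1))) {
    hl <- hyperfine_levels(st3, lv[1], lv[2], lv[3], list(na, nr))
    mine <- sort(rep(hl$shift, 2 * hl$F + 1))
    orac <- oracle_hyperfine_shifts(st3, lv[1], lv[2], lv[3], list(na, nr))
    expect_equal(length(mine), (2 * lv[1] + 1) * 9)
    expect_equal(mine, orac, tolerance = 1e-9)
  }
})

test_that("levels with J >= 2 split into 9 F sublevels", {
  hl <- hyperfine_levels(st3, 2, 1, 2, list(na, nr))
  expect_equal(nrow(hl), 9)
  expect_equal(sort(unique(hl$F)), 0:4)
  hl3 <- hyperfine_levels(st3, 3, 2, 1, list(na, nr))
  expect_equal(nrow(hl3), 9)
})

test_that("hyperfine components obey selection rules, sum rules and the
           intensity-weighted centre of gravity", {
  for (tra in list(list(c(1, 0, 1), c(0, 0, 0)),
                   list(c(2, 1, 2), c(1, 1, 1)),
                   list(c(3, 1, 3), c(2, 1, 2)))) {
    pat <- hyperfine_pattern(st3, tra[[1]], tra[[2]], list(na, nr),
                             collapse_tol = 0)
    expect_true(all(abs(pat$F_up - pat$F_lo) <= 1))
    expect_false(any(pat$F_up == 0 & pat$F_lo == 0))
    expect_equal(sum(pat$rel_intensity), 1, tolerance = 1e-12)
    expect_lt(abs(sum(pat$rel_intensity * pat$offset)), 1e-6)
  }
})

test_that("zero tensors give a single unshifted component", {
  z <- quadrupole_tensor(0, 0, 0)
  pat <- hyperfine_pattern(st3, c(1, 0, 1), c(0, 0, 0), list(z, z))
  expect_equal(nrow(pat), 1)
  expect_equal(pat$offset, 0)
  expect_equal(pat$rel_intensity, 1)
})

test_that("single-nucleus R-branch intensities follow the 2F+1 pattern", {
  pat <- hyperfine_pattern(st3, c(1, 0, 1), c(0, 0, 0), list(na))
  expect_equal(nrow(pat), 3)
  # out of 0_00 the three F1-ladder components carry weights (2F1+1)/9
  expect_equal(sort(pat$rel_intensity), c(1, 3, 5) / 9, tolerance = 1e-9)
})

test_that("unsupported spins are rejected", {
  bad <- quadrupole_tensor(1, -0.5, spin = 3 / 2)
  expect_error(hyperfine_levels(st3, 1, 0, 1, list(bad)), "spin-1")
})
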