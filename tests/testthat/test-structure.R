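test_that("closed-form rigid-body moments are reproduced", {
  g2 <- geometry(c("H", "H"), c(-0.5, 0.5), c(0, 0), c(0, 0),
                 mass = c(1, 1), label = c("Ha", "Hb"))
  pm <- principal_moments(g2)
  expect_equal(pm$moments$Ia, 0, tolerance = 1e-12)
  expect_equal(pm$moments$Ib, 0.5, tolerance = 1e-12)
  expect_equal(pm$moments$Ic, 0.5, tolerance = 1e-12)
  expect_error(principal_moments(geometry("C", 0, 0, 0)), "single atom")
})

test_that("ring fixtures have closed-form moments and zero inertial defect", {
  tri <- toy_planar_molecule(3, bond_length = 1, mass = 1)
  R <- 1 / (2 * sin(pi / 3))
  pm <- principal_moments(tri)
  expect_equal(pm$moments$Ic, 3 * R^2, tolerance = 1e-12)
  expect_equal(pm$moments$Ia + pm$moments$Ib, pm$moments$Ic, tolerance = 1e-12)
  expect_equal(inertial_defect(pm$moments), 0, tolerance = 1e-10)
  # scaling the ring scales the moments by s^2
  hex1 <- principal_moments(toy_planar_molecule(6, 1))$moments
  hex2 <- principal_moments(toy_planar_molecule(6, 1.3))$moments
  expect_equal(hex2$Ic / hex1$Ic, 1.3^2, tolerance = 1e-10)
  expect_error(toy_planar_molecule(2), "3")
})

test_that("moments are invariant under rigid rotation of the frame", {
  g <- amp_reference_geometry()
  m0 <- principal_moments(g)$moments
  th <- 0.83; ph <- -1.2
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  Rx <- matrix(c(1, 0, 0, 0, cos(ph), sin(ph), 0, -sin(ph), cos(ph)), 3, 3)
  X <- as.matrix(g[, c("x", "y", "z")]) %*% Rz %*% Rx
  g2 <- geometry(g$element, X[, 1] + 0.7, X[, 2] - 1.1, X[, 3] + 0.2,
                 mass = g$mass, label = g$label)
  m1 <- principal_moments(g2)$moments
  expect_equal(c(m1$Ia, m1$Ib, m1$Ic), c(m0$Ia, m0$Ib, m0$Ic),
               tolerance = 1e-9)
})

test_that("isotopic substitution changes masses only and raises moments", {
  g <- amp_reference_geometry()
  expect_identical(make_isotopologue(g, list()), g)
  m0 <- principal_moments(g)$moments
  d5 <- make_isotopologue(g, list(list(label = "H5",
                                       mass = atomic_masses[["D"]])))
  expect_equal(d5$mass[d5$label == "H5"], atomic_masses[["D"]])
  expect_equal(as.matrix(d5[, c("x", "y", "z")]),
               as.matrix(g[, c("x", "y", "z")]), ignore_attr = TRUE)
  m5 <- principal_moments(d5)$moments
  expect_true(m5$Ia > m0$Ia && m5$Ib > m0$Ib && m5$Ic > m0$Ic)
  expect_error(make_isotopologue(g, list(list(label = "Xx", mass = 2))),
               "missing atom")
  # H -> D in a diatomic: moment scales as the reduced mass
  mh <- atomic_masses[["H"]]; md <- atomic_masses[["D"]]; mo <- atomic_masses[["O"]]
  oh <- geometry(c("O", "H"), c(0, 0.97), c(0, 0), c(0, 0), label = c("O", "H1"))
  od <- make_isotopologue(oh, list(list(label = "H1", mass = md)))
  r <- principal_moments(od)$moments$Ic / principal_moments(oh)$moments$Ic
  expect_equal(r, (md * mo / (md + mo)) / (mh * mo / (mh + mo)),
               tolerance = 1e-12)
})

test_that("planar-moment scaling round-trips imposed factors", {
  g <- amp_reference_geometry()
  p0 <- geometry_planar_moments(g)
  s0 <- scale_geometry_to_planar_moments(g, p0)
  expect_equal(unname(attr(s0, "scale_factors")), c(1, 1, 1), tolerance = 1e-9)

  fac <- c(1.01, 0.99, 1.00)
  gp <- g
  gp$x <- gp$x * fac[1]; gp$y <- gp$y * fac[2]; gp$z <- gp$z * fac[3]
  tgt <- geometry_planar_moments(gp)
  s1 <- scale_geometry_to_planar_moments(g, tgt)
  expect_equal(unname(attr(s1, "scale_factors")), fac, tolerance = 1e-9)
})

test_that("scaling a strictly planar geometry to positive Pc is flagged", {
  ring <- principal_moments(toy_planar_molecule(6))$geometry
  tgt <- structure(list(Pa = 2, Pb = 2, Pc = 0.1), class = "planar_moments")
  s <- scale_geometry_to_planar_moments(ring, tgt)
  expect_equal(attr(s, "unscaled_axes"), "c")
  expect_equal(unname(attr(s, "scale_factors")[3]), 1)
})

test_that("scaled monomer reproduces the experimental rotational constants", {
  host <- amp_host_scaled()
  m <- principal_moments(host)$moments
  rc <- amp_constants()$states$ground$rc
  expect_equal(inertia_conversion / m$Ia, rc$A, tolerance = 0.05 / rc$A)
  expect_equal(inertia_conversion / m$Ib, rc$B, tolerance = 0.05 / rc$B)
  expect_equal(inertia_conversion / m$Ic, rc$C, tolerance = 0.05 / rc$C)
})

test_that("cluster assembly round-trips its three defining parameters", {
  host <- amp_host_scaled()
  w <- water_reference_geometry()
  for (pars in list(c(2.8272, 101.75, 134.3), c(3.1, 95, -140),
                    c(2.9, 110, 60))) {
    p <- cluster_params(pars[1], pars[2], pars[3])
    cl <- assemble_cluster(host, w, p)
    q <- measure_cluster_params(cl)
    expect_equal(q$d_O_Nr, pars[1], tolerance = 1e-9)
    expect_equal(q$angle_O_Nr_C2, pars[2], tolerance = 1e-9)
    expect_equal(q$dihedral_HOH_Nr, pars[3], tolerance = 1e-9)
  }
  # the water internal geometry is carried over rigidly
  cl <- assemble_cluster(host, w, cluster_params(2.85, 102, 140))
  X <- as.matrix(cl[, c("x", "y", "z")])
  rownames(X) <- cl$label
  expect_equal(sqrt(sum((X["Hb", ] - X["Ow", ])^2)), 0.9572, tolerance = 1e-9)
  expect_error(assemble_cluster(host, w, cluster_params(2.8, 190, 140)),
               "angle")
})

test_that("cluster assembled at computed parameters predicts the cluster
           rotational constants to ~1 percent", {
  host <- amp_host_scaled()
  w <- water_reference_geometry()
  cl <- assemble_cluster(host, w, cluster_params(2.8272, 101.75, 134.3))
  m <- principal_moments(cl)$moments
  rc <- amw_constants()$states$ground$rc
  expect_equal(inertia_conversion / m$Ia, rc$A, tolerance = 0.015)
  expect_equal(inertia_conversion / m$Ib, rc$B, tolerance = 0.015)
  expect_equal(inertia_conversion / m$Ic, rc$C, tolerance = 0.015)
})

test_that("r0 fit recovers generating parameters exactly at zero noise", {
  host <- amp_host_scaled()
  w <- water_reference_geometry()
  iso <- amw_iso_specs()
  p_true <- cluster_params(2.85, 102.0, 140.0)
  mom <- simulate_cluster_moments(host, w, p_true, iso,
                                  noise_spec(moment_sigma = 0, seed = 1))
  sf <- r0_fit(host, w, cluster_params(2.95, 99, 150), mom, iso)
  expect_equal(sf$params$d_O_Nr, 2.85, tolerance = 1e-8)
  expect_equal(sf$params$angle_O_Nr_C2, 102.0, tolerance = 1e-7)
  expect_equal(sf$params$dihedral_HOH_Nr, 140.0, tolerance = 1e-6)
  expect_lt(sf$sigma_fit, 1e-10)
  # sigma_fit is invariant under relabelling of the isotopologue rows
  mom2 <- mom[c(2, 3, 1), ]
  sf2 <- r0_fit(host, w, cluster_params(2.95, 99, 150), mom2,
                amw_iso_specs()[c(2, 3, 1)])
  expect_equal(sf2$sigma_fit, sf$sigma_fit, tolerance = 1e-12)
})
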