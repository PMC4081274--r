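# Hydrogen-bond correction: parameters, damping factors, term
# enumeration, energies and the analytic gradient.

test_that("parameter loading, overrides and validation work", {
  p <- hplus_params()
  expect_s3_class(p, "hplus_params")
  p2 <- hplus_params(c_n = -0.2)
  expect_equal(p2$c_n, -0.2)
  expect_equal(p2$c_o, p$c_o)
  expect_error(hplus_params(c_n = 0.1), "<= 0")
  expect_error(hplus_params(cutoff = 5), "cutoff")
  f <- tempfile()
  on.exit(unlink(f))
  writeLines("c_n -0.1", f)
  expect_error(hplus_params(f), "missing H\\+ parameter")
})

test_that("angular fitness is 1 at ideal geometry and clamps at 90 deg", {
  expect_equal(f_geom(0), 1)
  expect_equal(f_geom(60), cos(pi / 3)^2, tolerance = 1e-12)
  expect_equal(f_geom(91), 0)
  expect_equal(f_geom(0, phi_a = 120), 0)  # one dead factor kills the term
  # product structure
  expect_equal(f_geom(30, 40, 50, 60, 70),
               prod(cos(c(30, 40, 50, 60, 70) * pi / 180)^2),
               tolerance = 1e-12)
})

test_that("damping factors are monotone with correct limits", {
  p <- hplus_params()
  r <- seq(0.8, 2.0, by = 0.05)
  expect_true(all(diff(f_bond(r, p)) < 0))
  expect_equal(f_bond(0.95, p), 1, tolerance = 1e-5)
  expect_equal(f_bond(2.0, p), 0, tolerance = 1e-8)
  expect_true(all(f_damp(seq(1, 9, by = 0.25), p) >= 0))
  fc <- f_damp(3.0, p, components = TRUE)
  expect_equal(fc$value, fc$short * fc$long)
})

test_that("term enumeration finds the expected hydrogen-bond topology", {
  tm <- enumerate_hbond_terms(make_water_dimer())
  expect_s3_class(tm, "hbond_terms")
  # one O...O heteroatom pair, four hydrogens bonded to either oxygen
  expect_equal(length(tm), 4L)
  # cyclic formamide dimer: both strong N-H...O contacts present
  b <- hplus_energy(make_formamide_chain(2))$breakdown
  strong <- b[b$energy < -1, ]
  expect_equal(nrow(strong), 2L)
  # the two cyclic contacts are symmetry-equivalent
  expect_equal(strong$energy[1], strong$energy[2], tolerance = 1e-8)
})

test_that("terms beyond the enumeration cutoff are dropped", {
  far <- make_water_dimer(r_oo = 12)
  expect_equal(length(enumerate_hbond_terms(far)), 0L)
  expect_equal(hplus_energy(far)$energy, 0)
})

test_that("hydrogen-bond energies of the fixtures are reproducible", {
  expect_equal(hplus_energy(make_water_dimer())$energy,
               -0.735142209885, tolerance = 1e-8)
  expect_equal(hplus_energy(make_ammonia_dimer())$energy,
               -6.379161213884, tolerance = 1e-8)
  expect_equal(hplus_energy(make_formamide_chain(2))$energy,
               -17.106264974534, tolerance = 1e-8)
})

test_that("energy scales linearly in the strength parameters", {
  m <- make_formamide_chain(3)
  e1 <- hplus_energy(m)$energy
  e2 <- hplus_energy(m, hplus_params(c_n = -0.220, c_o = -0.240))$energy
  expect_equal(e2, 2 * e1, tolerance = 1e-10)
})

test_that("donor assignment follows the nearer heteroatom", {
  tm <- enumerate_hbond_terms(make_water_dimer())
  b <- hplus_energy(make_water_dimer())$breakdown
  act <- b[abs(b$energy) > 1e-12, ]
  expect_equal(nrow(act), 1L)
  expect_equal(act$a, 1L)     # donor oxygen
  expect_equal(act$h, 2L)     # bridging hydrogen
  expect_equal(act$b, 4L)     # acceptor oxygen
  expect_equal(act$donor, 1L)
})

test_that("energy is invariant under rigid rotation and translation", {
  for (m in list(make_water_dimer(), make_formamide_chain(3))) {
    e1 <- hplus_energy(m)$energy
    e2 <- hplus_energy(rigid_move(m))$energy
    expect_equal(e1, e2, tolerance = 1e-10)
  }
})

test_that("analytic gradient matches finite differences on fixtures", {
  for (m in list(make_water_dimer(), make_ammonia_dimer(),
                 make_amide_water())) {
    ga <- hplus_gradient(m)
    gn <- numerical_gradient(function(mm) hplus_energy(mm)$energy, m)
    expect_lt(max(abs(ga - gn)), 1e-6)
    expect_lt(max(abs(colSums(ga))), 1e-8)
    expect_equal(attr(ga, "fd_fallback_terms"), integer(0))
  }
})

test_that("exactly tied substituents still give a deterministic energy", {
  # exact-tie study variants of the fixtures (documented pathology: the
  # substituent assignment is then fixed by the lowest-index rule)
  tied <- list(make_water_dimer(acceptor_twist = 0),
               make_amide_water(tilt = 0),
               make_ammonia_dimer(donor_asym = 0))
  for (m in tied) {
    e1 <- hplus_energy(m)$energy
    e2 <- hplus_energy(m)$energy
    expect_identical(e1, e2)
    expect_true(is.finite(e1) && e1 <= 0)
  }
})

test_that("sp2 versus sp3 acceptor environments get different targets", {
  tbl <- target_angle_table()
  m <- make_amide_water()
  adj <- perceive_bonds(m)
  # formamide N (atom 3) is planar via conjugation with the C=O
  tn <- assign_target_angles(m, adj, 3L, tbl)
  expect_equal(tn$phi_target, 120, tolerance = 1e-8)
  # water O (atom 7) is a plain sp3 acceptor
  to <- assign_target_angles(m, adj, 7L, tbl)
  expect_equal(to$phi_target, 109.47, tolerance = 1e-8)
})
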