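# Dispersion term: parameters, reference data, coordination numbers, C6
# interpolation, two-body/three-body energies and the analytic gradient.
# Frozen numeric values come from an independent reimplementation of the
# same equations over the same packaged synthetic tables (scratch
# cross-check, numpy), agreeing to ~5e-10 kcal/mol.

test_that("dispersion parameter defaults and validation", {
  p <- d3_params()
  expect_equal(p$s6, 1.000)
  expect_equal(p$s8, 1.009)
  expect_equal(p$sr6, 1.560)
  expect_equal(p$alpha, 14.000)
  expect_equal(p$alpha8, 16.000)
  expect_error(d3_params(s6 = -1))
})

test_that("reference data tables are complete for H-Ne", {
  d <- d3_reference_data()
  expect_setequal(names(d$rcov), supported_elements())
  expect_true(all(d$rcov > 0))
  expect_true(all(d$q > 0))
  # single-reference noble gases, two-point grids elsewhere
  expect_equal(nrow(d$refs$He), 1L)
  expect_equal(nrow(d$refs$C), 2L)
  expect_equal(d$k1, 16)
  expect_equal(d$k3, -4)
})

test_that("coordination numbers count covalent neighbours", {
  cn <- coordination_numbers(make_water_dimer())
  expect_equal(cn[1], 1.990280670865, tolerance = 1e-8)
  expect_gt(cn[1], 1.9)          # donor oxygen: ~2 bonded hydrogens
  expect_lt(cn[2], 1.2)          # hydrogen: ~1 bond
  cn <- coordination_numbers(make_ammonia_dimer())
  expect_equal(cn[1], 2.991496328853, tolerance = 1e-8)
})

test_that("C6 interpolation is symmetric and hits its anchors", {
  d <- d3_reference_data()
  expect_equal(c6_effective("N", "O", 2.1, 1.3, d),
               c6_effective("O", "N", 1.3, 2.1, d), tolerance = 1e-12)
  # far below any reference CN the free-atom limit dominates
  expect_equal(c6_effective("C", "C", -10, -10, d), d$refs$C$c6[1],
               tolerance = 1e-6)
  # single-reference elements are CN-independent
  expect_equal(c6_effective("He", "He", 0, 0, d),
               c6_effective("He", "He", 3, 3, d), tolerance = 1e-12)
})

test_that("two-body energies match the independent cross-check", {
  frozen <- c(water_dimer = -15.133796392268167,
              ammonia_dimer = -20.035183753107887,
              amide_water = -23.45478201494024,
              formamide_chain2 = -40.00371980831898,
              formamide_chain3 = -53.483681513444985)
  fx <- default_fixtures()
  for (nm in names(frozen))
    expect_equal(d3_two_body(fx[[nm]])$energy, frozen[[nm]],
                 tolerance = 1e-6)
})

test_that("three-body energies match the independent cross-check", {
  frozen <- c(water_dimer = -0.04947671438658194,
              ammonia_dimer = -0.04278441676747179,
              amide_water = 0.16163365586527292,
              formamide_chain2 = 0.08953419131918654,
              formamide_chain3 = 0.7157024039052633)
  fx <- default_fixtures()
  for (nm in names(frozen))
    expect_equal(d3_three_body(fx[[nm]])$energy, frozen[[nm]],
                 tolerance = 1e-6)
})

test_that("two-body energy is pairwise additive over the breakdown", {
  tb <- d3_two_body(make_water_dimer())
  expect_equal(sum(tb$pairs$energy), tb$energy, tolerance = 1e-12)
  expect_equal(nrow(tb$pairs), 15L)      # 6 choose 2
  expect_true(all(tb$pairs$energy < 0))
  expect_true(all(tb$pairs$c6 > 0 & tb$pairs$c8 > 0))
})

test_that("analytic two-body gradient matches finite differences", {
  for (m in list(make_water_dimer(), make_amide_water())) {
    ga <- d3_two_body_gradient(m)
    gn <- numerical_gradient(function(mm) d3_two_body(mm)$energy, m)
    expect_lt(max(abs(ga - gn)), 1e-6)
    expect_lt(max(abs(colSums(ga))), 1e-8)
  }
})

test_that("dispersion energy is invariant under rigid motion", {
  m <- make_formamide_chain(2)
  expect_equal(d3_two_body(rigid_move(m))$energy, d3_two_body(m)$energy,
               tolerance = 1e-10)
})

test_that("elements missing from a custom table are rejected by name", {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(c("symbol rcov q c6_free c6_valence cn_valence",
               "H 0.32 2.0 7.59 2.43 1"), f)
  d <- d3_reference_data(elements_file = f)
  m <- molecule(c("O", "H"), rbind(c(0, 0, 0), c(0.96, 0, 0)))
  expect_error(d3_two_body(m, data = d), "O")
})

test_that("zero-damping switches off the singularity at short range", {
  d <- d3_reference_data()
  m <- function(r) molecule(c("Ne", "Ne"), rbind(c(0, 0, 0), c(r, 0, 0)))
  e <- vapply(c(0.3, 0.6, 1.0, 2.0), function(r) d3_two_body(m(r))$energy,
              numeric(1))
  # damped energies stay finite and small at absurdly short range
  expect_true(all(is.finite(e)))
  expect_lt(abs(e[1]), abs(e[4]))
})
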