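# Geometry core: molecule container, XYZ I/O, bond perception, internal
# coordinates and their analytic derivatives.

test_that("molecule() validates its inputs", {
  m <- molecule(c("O", "H"), rbind(c(0, 0, 0), c(0.96, 0, 0)))
  expect_s3_class(m, "molecule")
  expect_equal(natoms(m), 2L)
  expect_error(molecule("O", matrix(0, 2, 3)), "length\\(symbols\\)")
  expect_error(molecule("Xx", matrix(0, 1, 3)), "element")
  expect_error(molecule("O", matrix(NA_real_, 1, 3)), "finite")
})

test_that("XYZ round trip preserves coordinates and comment", {
  m <- make_water_dimer()
  f <- tempfile(fileext = ".xyz")
  on.exit(unlink(f))
  write_xyz(m, f)
  m2 <- read_xyz(f)
  expect_equal(m2$symbols, m$symbols)
  expect_equal(m2$coords, m$coords, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(m2$comment, m$comment)
})

test_that("read_xyz reports the offending line on malformed input", {
  f <- tempfile(fileext = ".xyz")
  on.exit(unlink(f))
  writeLines(c("2", "bad", "O 0 0 0", "H zero 0 0"), f)
  expect_error(read_xyz(f), "line 4")
})

test_that("bond perception finds the covalent skeleton of water", {
  m <- split_mol(make_water_dimer(), 1:3)
  adj <- perceive_bonds(m)
  expect_equal(sort(adj$neighbors[[1]]), c(2L, 3L))
  expect_equal(adj$neighbors[[2]], 1L)
  expect_equal(nrow(adj$bonds), 2L)
})

test_that("no spurious intermolecular bonds in the dimers", {
  adj <- perceive_bonds(make_water_dimer())
  expect_equal(nrow(adj$bonds), 4L)      # 2 O-H bonds per monomer
  adj <- perceive_bonds(make_ammonia_dimer())
  expect_equal(nrow(adj$bonds), 6L)
})

test_that("internal coordinates reproduce constructed values", {
  m <- split_mol(make_water_dimer(r_oo = 2.91, donor_tilt = 0), 1:3)
  expect_equal(internal_coordinate(m, "distance", c(1, 2))$value, 0.9572,
               tolerance = 1e-10)
  expect_equal(internal_coordinate(m, "angle", c(2, 1, 3))$value, 104.52,
               tolerance = 1e-8)
})

test_that("dihedral of a planar cis/trans arrangement is 0/180", {
  coords <- rbind(c(1, 1, 0), c(0, 0, 0), c(2, 0, 0), c(3, 1, 0))
  m <- molecule(c("C", "C", "C", "C"), coords)
  expect_equal(abs(internal_coordinate(m, "dihedral", 1:4)$value), 0,
               tolerance = 1e-10)
  coords[4, ] <- c(3, -1, 0)
  m <- molecule(c("C", "C", "C", "C"), coords)
  expect_equal(abs(internal_coordinate(m, "dihedral", 1:4)$value), 180,
               tolerance = 1e-10)
})

test_that("internal coordinate derivatives match finite differences", {
  set.seed(11)
  for (trial in 1:5) {
    m <- molecule(c("C", "N", "O", "H"), matrix(rnorm(12, sd = 1.5), 4, 3))
    for (spec in list(list("distance", c(1, 3)),
                      list("angle", c(1, 2, 3)),
                      list("dihedral", 1:4))) {
      ic <- internal_coordinate(m, spec[[1]], spec[[2]])
      fd <- matrix(0, 4, 3)
      for (a in 1:4) for (x in 1:3) {
        mp <- m; mp$coords[a, x] <- mp$coords[a, x] + 1e-6
        mm <- m; mm$coords[a, x] <- mm$coords[a, x] - 1e-6
        dv <- internal_coordinate(mp, spec[[1]], spec[[2]])$value -
          internal_coordinate(mm, spec[[1]], spec[[2]])$value
        if (spec[[1]] == "dihedral")       # unwrap across the branch cut
          dv <- ((dv + 180) %% 360) - 180
        fd[a, x] <- dv / 2e-6
      }
      expect_lt(max(abs(ic$grad - fd)), 1e-5)
      # derivative rows sum to zero (translational invariance)
      expect_lt(max(abs(colSums(ic$grad))), 1e-10)
    }
  }
})

test_that("degenerate geometries signal the dedicated condition class", {
  lin <- molecule(c("C", "C", "C"),
                  rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)))
  expect_error(internal_coordinate(lin, "angle", 1:3),
               class = "d3hplus_degenerate_geometry")
  lin4 <- molecule(c("C", "C", "C", "C"),
                   rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)))
  expect_error(internal_coordinate(lin4, "dihedral", 1:4),
               class = "d3hplus_degenerate_geometry")
})

test_that("transform_molecule preserves internal coordinates", {
  m <- split_mol(make_water_dimer(), 1:3)
  th <- 0.6
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
                3L, 3L, byrow = TRUE)
  m2 <- transform_molecule(m, rotation = rot, translation = c(1, -2, 0.5))
  d1 <- internal_coordinate(m, "distance", c(1, 2))$value
  d2 <- internal_coordinate(m2, "distance", c(1, 2))$value
  expect_equal(d1, d2, tolerance = 1e-12)
  a1 <- internal_coordinate(m, "angle", c(2, 1, 3))$value
  a2 <- internal_coordinate(m2, "angle", c(2, 1, 3))$value
  expect_equal(a1, a2, tolerance = 1e-10)
})
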