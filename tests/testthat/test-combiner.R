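# Energy combiner: base backends, component composition and the combined
# gradient.

test_that("total energy is the sum of its reported components", {
  m <- make_water_dimer()
  br <- total_energy(m, include = c("d3", "hplus"))
  expect_s3_class(br, "energy_breakdown")
  expect_equal(br$total, br$d3_two_body + br$hplus, tolerance = 1e-12)
  expect_equal(br$d3_two_body, d3_two_body(m)$energy, tolerance = 1e-12)
  expect_equal(br$hplus, hplus_energy(m)$energy, tolerance = 1e-12)
  expect_true(is.na(br$d3_three_body))
  br3 <- total_energy(m, include = c("d3", "hplus"), three_body = TRUE)
  expect_equal(br3$total,
               br3$d3_two_body + br3$d3_three_body + br3$hplus,
               tolerance = 1e-12)
})

test_that("component selection switches terms off", {
  m <- make_water_dimer()
  expect_equal(total_energy(m, include = "hplus")$total,
               hplus_energy(m)$energy, tolerance = 1e-12)
  expect_equal(total_energy(m, include = "d3")$total,
               d3_two_body(m)$energy, tolerance = 1e-12)
})

test_that("function backend feeds the base energy through", {
  m <- make_water_dimer()
  be <- base_function(function(mol) -42.5, name = "constant")
  br <- total_energy(m, be)
  expect_equal(br$base, -42.5)
  expect_equal(br$total, -42.5 + br$d3_two_body + br$hplus,
               tolerance = 1e-12)
})

test_that("table backend resolves energies by id and errors on misses", {
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  write.csv(data.frame(id = c("a1", "a2"), energy = c(-1.5, -2.5)), f,
            row.names = FALSE)
  be <- base_table(f)
  m <- make_water_dimer()
  expect_equal(total_energy(m, be, id = "a2")$base, -2.5)
  expect_error(total_energy(m, be, id = "zzz"), "zzz")
})

test_that("hartree-unit backends are converted to kcal/mol", {
  m <- make_water_dimer()
  be <- base_function(function(mol) -1, unit = "hartree",
                      name = "hartree backend")
  expect_equal(total_energy(m, be)$base, -627.509474, tolerance = 1e-9)
})

test_that("combined gradient matches the combined energy", {
  m <- make_amide_water()
  ga <- total_gradient(m, include = c("d3", "hplus"))
  gn <- numerical_gradient(function(mm)
    total_energy(mm, include = c("d3", "hplus"))$total, m)
  expect_lt(max(abs(ga - gn)), 1e-6)
})

test_that("a base backend without gradient capability errors clearly", {
  m <- make_water_dimer()
  be <- base_function(function(mol) 0, name = "energy only")
  expect_error(total_gradient(m, be, include = c("base", "d3", "hplus")),
               "gradient")
})

test_that("the breakdown print method reports every component", {
  m <- make_water_dimer()
  out <- capture.output(print(total_energy(m, include = c("d3", "hplus"))))
  expect_true(any(grepl("total", out)))
  expect_true(any(grepl("h-bond", out, fixed = TRUE)))
})
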