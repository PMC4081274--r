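# Shared helpers for the test suite.

# extract a subset of atoms as a new molecule (monomer of a complex)
split_mol <- function(mol, idx) {
  molecule(mol$symbols[idx], mol$coords[idx, , drop = FALSE])
}

# the standard fixture set used by the gradient and property tests:
# every generator at its default study conditions
default_fixtures <- function() {
  list(water_dimer = make_water_dimer(),
       amide_water = make_amide_water(),
       ammonia_dimer = make_ammonia_dimer(),
       formamide_chain2 = make_formamide_chain(2),
       formamide_chain3 = make_formamide_chain(3),
       formamide_chain4 = make_formamide_chain(4),
       formamide_chain5 = make_formamide_chain(5),
       formamide_chain6 = make_formamide_chain(6))
}

# monomer index ranges of the two-fragment fixtures
fixture_fragments <- function() {
  list(water_dimer = list(a = 1:3, b = 4:6),
       amide_water = list(a = 1:6, b = 7:9),
       ammonia_dimer = list(a = 1:4, b = 5:8),
       formamide_chain2 = list(a = 1:6, b = 7:12))
}

# benchmark records with references planted as base + hydrogen-bond
# interaction at the packaged default strength parameters
planted_records <- function() {
  fx <- default_fixtures()[names(fixture_fragments())]
  fr <- fixture_fragments()
  ev_d3 <- function(m) d3_two_body(m)$energy
  ev_hp <- function(m) hplus_energy(m)$energy
  lapply(names(fx), function(nm) {
    d <- fx[[nm]]
    a <- split_mol(d, fr[[nm]]$a)
    b <- split_mol(d, fr[[nm]]$b)
    base <- interaction_energy(d, a, b, ev_d3)
    ref <- base + interaction_energy(d, a, b, ev_hp)
    benchmark_record(nm, d, a, b, base, ref)
  })
}

# rigid rotation (z axis, radians) plus translation of a molecule
rigid_move <- function(mol, angle = 0.7, shift = c(3, -1, 2)) {
  rot <- matrix(c(cos(angle), -sin(angle), 0,
                  sin(angle), cos(angle), 0,
                  0, 0, 1), 3L, 3L, byrow = TRUE)
  mol$coords <- mol$coords %*% t(rot) +
    matrix(shift, natoms(mol), 3L, byrow = TRUE)
  mol
}
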