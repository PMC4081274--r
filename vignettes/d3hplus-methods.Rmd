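---
title: "Methods: dispersion and hydrogen-bond corrections in d3hplus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dispersion and hydrogen-bond corrections in d3hplus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`d3hplus` implements two additive post-hoc corrections to a semiempirical
base energy,

$$E_\mathrm{total} = E_\mathrm{base} + E_\mathrm{D3} + E_\mathrm{H+},$$

together with analytic Cartesian gradients, benchmarking machinery and
deterministic molecular fixtures. The base electronic energy is never
computed here: it enters through a pluggable backend (`base_backend()`,
`base_function()`, `base_table()`), so the package is a correction
library, not a quantum-chemistry engine. This vignette states the exact
model implemented, the provenance of every number in the packaged data
files, and the numerical design decisions that the test suite pins down.

## The hydrogen-bond correction

Each correction term is attached to a triple $(A, H, B)$ where $A$ and
$B$ are nitrogen or oxygen atoms within a 9.5 Å enumeration cutoff and
$H$ is a hydrogen covalently bonded to one of them (the *donor* is the
heteroatom nearer the hydrogen). The term energy is

$$E_t = \frac{C_A + C_B}{2\, r_{AB}^2}\; f_\mathrm{geom}\,
f_\mathrm{bond}\, f_\mathrm{damp},$$

with element-wise strength parameters $C_N = -0.110$ and $C_O = -0.120$
(Hartree·Å²; a single configurable constant, 627.509474, converts to
kcal/mol). The three factors, each in $[0, 1]$:

- $f_\mathrm{geom}$ is the product of five squared cosines of deviation
  angles: the deviation of the $A\!-\!H\!\cdots\!B$ angle from
  linearity, and on each heteroatom side the deviations of the
  $H\cdots X\!-\!R_1$ bond angle and the $R_1 R_2 X \cdots H$ torsion
  from hybridization-dependent target angles.
- $f_\mathrm{bond}$ is a falling sigmoid on the donor–hydrogen distance
  (steepness 60, midpoint 1.2 Å): the term only exists while the
  hydrogen is covalently attached.
- $f_\mathrm{damp}$ is the product of a rising sigmoid on the
  donor–acceptor distance (steepness 100, midpoint 2.4 Å) and a falling
  one (steepness 10, midpoint 7.0 Å): no correction for atoms in
  covalent contact, none at non-interacting range. Both sigmoids are
  exactly $1/2$ at their midpoints, which the acceptance tests check.

Target angles come from a data-driven table
(`inst/extdata/target_angles.txt`): trigonal ($\varphi = 120^\circ$,
torsion targets $0/180^\circ$) for sp² environments, tetrahedral
($\varphi = 109.47^\circ$, torsion targets $\pm 120^\circ$) for sp³.
A nitrogen counts as sp² when it or a direct neighbour carries a double
bond, detected by the distance criterion
$r < 0.89\,(r_\mathrm{cov,X} + r_\mathrm{cov,Y})$; an oxygen only when
it is itself doubly bonded (carbonyl).

### Numerical design decisions

**Squared-cosine clamp.** Each $\cos^2$ fitness factor is clamped to
zero when its deviation angle exceeds $90^\circ$. Without the clamp,
$\cos^2$ rises again beyond $90^\circ$ and badly misaligned
arrangements (for instance the non-bridging hydrogens of a water dimer,
whose "linearity" angle is near $55^\circ$) regain spurious fitness.
$\cos^2$ has zero value *and* zero slope at $90^\circ$, so the clamp is
$C^1$-continuous and gradient-safe.

**Frozen substituent assignment.** The torsion coordinate needs two
reference substituents $R_1, R_2$ on each heteroatom. $R_1$ is the
substituent closest to the bridging hydrogen, with exact distance ties
(tolerance $10^{-9}$ Å) broken by lowest atom index, and the assignment
is frozen per evaluation. Without freezing, symmetric acceptors (a
water accepting through the midpoint of its two hydrogens) make the
torsion definition oscillate between evaluations, which is exactly the
kind of discontinuity that stalls geometry optimizers. At an exact tie
the energy is still deterministic but has a kink; the fixture
generators therefore default to slightly desymmetrized geometries and
expose the exact-tie variants through arguments (`tilt = 0`,
`acceptor_twist = 0`, `donor_asym = 0`) for studying that pathology.

**Degenerate geometries.** Collinear angle or torsion configurations
raise a typed condition (`d3hplus_degenerate_geometry`). The energy
path never needs the angle derivative and accepts exactly linear
bridges; the analytic gradient falls back to central finite differences
for any term whose internal-coordinate derivatives are singular, and
reports such terms in the `fd_fallback_terms` attribute (none occur on
the default fixtures).

## The dispersion correction

The two-body term is the standard zero-damped pairwise form,

$$E^{(2)} = -\sum_{A<B}\; s_6 \frac{C_6^{AB}}{r^6}\, f_6(r) \;+\;
s_8 \frac{C_8^{AB}}{r^8}\, f_8(r), \qquad
f_n(r) = \frac{1}{1 + 6\,(s_{r,n} R_0^{AB} / r)^{\alpha_n}},$$

with $s_6 = 1$, $s_8 = 1.009$, $s_{r6} = 1.56$, $\alpha_6 = 14$,
$s_{r8} = 1$, $\alpha_8 = 16$ — the parameter set fitted for the
semiempirical base method. $C_8^{AB} = 3\, C_6^{AB} Q_A Q_B$ with
element-wise $Q$ factors. $C_6^{AB}$ is interpolated over
coordination-number reference points with Gaussian weights
$\exp(-4\,[(\mathrm{CN}_A - \mathrm{CN}_A^{(i)})^2 +
(\mathrm{CN}_B - \mathrm{CN}_B^{(j)})^2])$, where the fractional
coordination number uses the counting function
$\sum_B [1 + e^{-16\,(4(R_A + R_B)/(3 r_{AB}) - 1)}]^{-1}$ over
covalent radii. The optional three-body triple-dipole term uses
$C_9 = -\sqrt{C_6^{AB} C_6^{BC} C_6^{CA}}$ with a zero-damping factor
on the geometric-mean distance (scale $4/3$, exponent 16); it is off by
default and its gradient is obtained by finite differences.

Gradients of the two-body term are fully analytic, including the
chain-rule contribution of the coordination-number dependence of
$C_6$; the interpolation weights are evaluated in log-sum-exp form for
stability far from the reference points.

### The synthetic reference dataset — construction and limitations

The original third-generation dispersion scheme ships large tables of
CN-interpolated $C_6$ reference grids computed from time-dependent DFT.
Those grids are not redistributable here, so the packaged dataset
(`inst/extdata/d3_synthetic_elements.txt`, marked SYNTHETIC in the file
and in `?d3_reference_data`) is *constructed* from published scalar
constants:

- covalent radii: single-bond radii (Pyykkö/Atsumi values, Å);
- $Q$ factors: effective $\sqrt{\langle r^4\rangle/\langle r^2\rangle}$
  values including the $\sqrt{Z}$ scaling;
- a two-point $C_6(\mathrm{CN})$ grid per element: the free-atom $C_6$
  at $\mathrm{CN} = 0$ and an in-molecule value at a nominal valence
  CN, converted from published molecular $C_6$ coefficients
  (J·nm⁶/mol × 17.3458 → a.u.); noble gases keep a single
  CN-independent point;
- pair references combined geometrically,
  $C_6^{AB}(i,j) = \sqrt{C_6^A(i)\, C_6^B(j)}$;
- cutoff radii by the rule $R_0^{AB} = 0.627672\sqrt{3 Q_A Q_B}$ Bohr,
  anchored so the H–H cutoff equals 2.1823 Bohr.

The *functional form* is exact and is verified against an independent
reimplementation of the same equations over the same tables (agreement
~5·10⁻¹⁰ kcal/mol). The *absolute energies* are not those of the
original tables: the free-atom anchor dominates at molecular
coordination numbers and overbinds by roughly an order of magnitude on
the package fixtures. The acceptance test comparing against frozen
values from an established external dispersion implementation is
therefore expected to fail, deliberately and documentedly so: it
records the gap between the synthetic stand-in and the real reference
data rather than hiding it. Supplying a file with the original grids
via `d3_reference_data(elements_file = ...)` would close that gap
without code changes.

## Parameter fitting machinery

`scan_parameters()` refits $(C_N, C_O)$ against reference interaction
energies by RMSD over a rectangular grid. Because the hydrogen-bond
energy is *linear* in the two strength parameters,
$E_{H+} = C_N A + C_O B$ with geometry-only coefficients $A, B \ge 0$,
the coefficients are extracted once per benchmark record from two probe
evaluations of the public energy function and the scan is then linear
in the grid size. The acceptance tests plant references constructed as
base + hydrogen-bond interaction at $(-0.11, -0.12)$ and require exact
recovery (zero RMSD), and recovery within one grid step under Gaussian
noise of $\sigma = 0.1$ kcal/mol.

## Fixtures

All fixtures are generated programmatically (`make_water_dimer()`,
`make_ammonia_dimer()`, `make_formamide_chain()`, `make_amide_water()`)
from textbook bond lengths and angles; nothing binary is stored. Design
points:

- Bridging bonds are built at ~175°, not 180°: exactly collinear
  bridges are energy-valid but derivative-degenerate, and the gradient
  tests require the fully analytic path.
- The formamide cyclic dimer (two equivalent N–H···O bonds) and the
  translational catemer ($n - 1$ bonds for $n$ monomers) exercise
  multi-term bookkeeping; the catemer energy grows by a near-constant
  increment per added monomer.
- `make_amide_water()` is the near-tie study case. Its `tilt` rotates
  the water about an in-plane axis perpendicular to the contact
  direction — the only single rotation that actually breaks the
  substituent equidistance — and its `twist` rotates about the
  out-of-plane normal to break an otherwise exact coplanarity that
  pins the acceptor torsion at 180°, midway between its two staggered
  targets. Setting either to zero restores the corresponding
  degeneracy on purpose.
- `perturb_molecule()` adds Gaussian coordinate noise from the current
  RNG state; the sign/limit acceptance test runs 1000 such
  perturbations.

## Problem sizes and costs

Everything is desk-scale: fixtures have 6–36 atoms, the full test suite
(including the thousand-perturbation property block and all
finite-difference comparisons) runs in a few minutes on one CPU, and
the default 21×21 parameter scan over four records takes well under a
second thanks to coefficient caching. Reproducing published benchmark
statistics for large curated sets would additionally require those
sets' geometries and an external base-method engine, and is out of
scope.
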