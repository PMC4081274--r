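# Programmatic fixture geometries. Bond lengths and angles are textbook
# values (O-H 0.9572, N-H 1.012, C=O 1.22 Angstrom, tetrahedral/trigonal
# angles): the fixtures exercise the correction functions, they are not
# spectroscopic geometries. All generators are deterministic.

# rotation matrix about a (unit) axis by an angle in degrees
.rot_axis <- function(axis, angle_deg) {
  a <- axis / sqrt(sum(axis^2))
  th <- angle_deg * .deg2rad
  c <- cos(th); s <- sin(th); C <- 1 - c
  matrix(c(a[1] * a[1] * C + c, a[1] * a[2] * C - a[3] * s, a[1] * a[3] * C + a[2] * s,
           a[2] * a[1] * C + a[3] * s, a[2] * a[2] * C + c, a[2] * a[3] * C - a[1] * s,
           a[3] * a[1] * C - a[2] * s, a[3] * a[2] * C + a[1] * s, a[3] * a[3] * C + c),
         3L, 3L, byrow = TRUE)
}

#' Water dimer fixture
#'
#' Canonical near-linear O-H...O dimer with a tetrahedral-type (sp3)
#' acceptor. The donor molecule lies in the xy-plane with the bridging
#' O-H along the O...O axis (optionally tilted); the acceptor is tilted
#' back and, by default, twisted slightly about its bisector so that its
#' two hydrogens are inequivalent with respect to the bridging hydrogen
#' (a twist of 0 produces the exactly symmetric, substituent-tied case).
#'
#' @param r_oo Donor-acceptor oxygen distance, Angstrom (> 1.5).
#' @param donor_tilt Tilt of the donor O-H off the O...O axis, degrees.
#' @param acceptor_twist Twist of the acceptor about its bisector,
#'   degrees.
#' @return A [molecule()] with atoms O, H (bridging), H, O, H, H.
#' @export
make_water_dimer <- function(r_oo = 2.91, donor_tilt = 5,
                             acceptor_twist = 8) {
  if (!is.finite(r_oo) || r_oo <= 1.5)
    stop("r_oo must exceed 1.5 Angstrom")
  roh <- 0.9572; hoh <- 104.52
  t <- donor_tilt * .deg2rad
  o_d <- c(0, 0, 0)
  h_b <- roh * c(cos(t), sin(t), 0)
  h_d <- roh * c(cos(t + hoh * .deg2rad), sin(t + hoh * .deg2rad), 0)
  o_a <- c(r_oo, 0, 0)
  beta <- 125 * .deg2rad            # acceptor bisector tilt off the axis
  bis <- c(cos(beta), 0, sin(beta))
  perp0 <- c(0, 1, 0)
  perp <- .rot_axis(bis, acceptor_twist) %*% perp0
  half <- hoh / 2 * .deg2rad
  h_a1 <- o_a + roh * (cos(half) * bis + sin(half) * as.numeric(perp))
  h_a2 <- o_a + roh * (cos(half) * bis - sin(half) * as.numeric(perp))
  molecule(c("O", "H", "H", "O", "H", "H"),
           rbind(o_d, h_b, h_d, o_a, h_a1, h_a2),
           comment = sprintf("water dimer r_OO=%.3f tilt=%.1f twist=%.1f",
                             r_oo, donor_tilt, acceptor_twist))
}

#' Ammonia dimer fixture
#'
#' Near-linear N-H...N dimer. With `donor_asym = 0` the two non-bridging
#' donor hydrogens are exactly equidistant from the bridging hydrogen,
#' reproducing the highly symmetric configuration in which the torsion
#' substituent assignment is tie-broken by atom index; the default breaks
#' the tie slightly.
#'
#' @param r_nn Nitrogen-nitrogen distance, Angstrom.
#' @param donor_asym Polar-angle asymmetry (degrees) applied to the two
#'   non-bridging donor hydrogens.
#' @return A [molecule()] with atoms N, H (bridging), H, H, N, H, H, H.
#' @export
make_ammonia_dimer <- function(r_nn = 3.25, donor_asym = 3) {
  rnh <- 1.012
  dirp <- function(polar, az) {
    p <- polar * .deg2rad; a <- az * .deg2rad
    c(cos(p), sin(p) * cos(a), sin(p) * sin(a))
  }
  n_d <- c(0, 0, 0)
  h_b <- rnh * c(cos(5 * .deg2rad), sin(5 * .deg2rad), 0)  # 175 deg bond
  h_d1 <- rnh * dirp(109.5 - donor_asym, 90)
  h_d2 <- rnh * dirp(109.5 + donor_asym, 210)
  n_a <- c(r_nn, 0, 0)
  # acceptor umbrella opens away from the donor (lone pair toward it)
  h_a <- lapply(c(17, 137, 257), function(az) n_a + rnh * dirp(68, az))
  molecule(c("N", "H", "H", "H", "N", "H", "H", "H"),
           rbind(n_d, h_b, h_d1, h_d2, n_a, h_a[[1]], h_a[[2]], h_a[[3]]),
           comment = sprintf("ammonia dimer r_NN=%.3f asym=%.1f",
                             r_nn, donor_asym))
}

# planar formamide monomer in the xy-plane; returns coords plus named
# atom indices (C, O, N, H_C, H_syn, H_anti)
.formamide <- function() {
  c_at <- c(0, 0, 0)
  o_at <- c(1.22, 0, 0)
  n_at <- 1.352 * c(cos(123 * .deg2rad), sin(123 * .deg2rad), 0)
  h_c <- 1.10 * c(cos(-120 * .deg2rad), sin(-120 * .deg2rad), 0)
  d_nc <- (c_at - n_at); d_nc <- d_nc / sqrt(sum(d_nc^2))
  rot <- function(v, ang) as.numeric(.rot_axis(c(0, 0, 1), ang) %*% v)
  h1 <- n_at + 1.01 * rot(d_nc, 120)
  h2 <- n_at + 1.01 * rot(d_nc, -120)
  # syn = the N-H nearer the carbonyl oxygen
  if (sum((h1 - o_at)^2) < sum((h2 - o_at)^2)) {
    h_syn <- h1; h_anti <- h2
  } else {
    h_syn <- h2; h_anti <- h1
  }
  list(symbols = c("C", "O", "N", "H", "H", "H"),
       coords = rbind(c_at, o_at, n_at, h_c, h_syn, h_anti),
       idx = list(C = 1L, O = 2L, N = 3L, H_C = 4L, H_syn = 5L,
                  H_anti = 6L))
}

#' Formamide chain fixtures
#'
#' Hydrogen-bonded formamide assemblies. `n = 1` is the planar monomer;
#' `n = 2` is the doubly hydrogen-bonded cyclic dimer (two equivalent
#' N-H...O=C bonds); `n >= 3` is a translational catemer in which each
#' molecule donates its anti N-H to the carbonyl oxygen of the previous
#' one (n - 1 strong hydrogen bonds), the motif behind cooperative
#' hydrogen-bond chains.
#'
#' @param n Number of monomers (1 to 6).
#' @param r_ho Hydrogen...oxygen contact distance, Angstrom.
#' @return A [molecule()] with 6 n atoms.
#' @export
make_formamide_chain <- function(n, r_ho = 1.90) {
  if (!n %in% 1:6) stop("n must be in 1..6")
  fm <- .formamide()
  if (n == 1L)
    return(molecule(fm$symbols, fm$coords, comment = "formamide monomer"))
  if (n == 2L) {
    # cyclic dimer: second molecule is the inversion image placed so both
    # syn N-H...O contacts sit at r_ho
    h <- fm$coords[fm$idx$H_syn, ]
    nn <- fm$coords[fm$idx$N, ]
    d <- (h - nn); d <- d / sqrt(sum(d^2))
    d <- as.numeric(.rot_axis(c(0, 0, 1), 5) %*% d)  # ~175 deg N-H...O
    t <- fm$coords[fm$idx$O, ] + h + r_ho * d
    coords2 <- matrix(t, nrow(fm$coords), 3L, byrow = TRUE) - fm$coords
    return(molecule(c(fm$symbols, fm$symbols), rbind(fm$coords, coords2),
                    comment = "formamide cyclic dimer"))
  }
  h <- fm$coords[fm$idx$H_anti, ]
  nn <- fm$coords[fm$idx$N, ]
  d <- (h - nn); d <- d / sqrt(sum(d^2))
  d <- as.numeric(.rot_axis(c(0, 0, 1), 5) %*% d)  # ~175 deg N-H...O
  tvec <- fm$coords[fm$idx$O, ] - h - r_ho * d
  coords <- do.call(rbind, lapply(seq_len(n) - 1L, function(k)
    fm$coords + matrix(k * tvec, nrow(fm$coords), 3L, byrow = TRUE)))
  molecule(rep(fm$symbols, n), coords,
           comment = sprintf("formamide catemer n=%d", n))
}

#' Amide-water fixture (near-tied torsion substituents)
#'
#' Formamide donating its N-H to a water oxygen whose two hydrogens are
#' (nearly) equidistant from the amide proton. With `tilt = 0` the two
#' water hydrogens are exactly equidistant, so the torsion substituent
#' choice on the acceptor side is decided purely by the index tie-break -
#' the configuration whose oscillating torsion definition stalls
#' optimizers of this family of corrections. The default small tilt makes
#' the assignment geometrically unambiguous.
#'
#' @param r_ho Amide H ... water O distance, Angstrom.
#' @param tilt Water tilt (degrees) breaking the equidistance.
#' @param twist Rotation of the water about the out-of-plane axis through
#'   its oxygen (degrees). A non-zero twist swings the water hydrogens
#'   out of the plane spanned by the contact direction and the amide
#'   normal, so the acceptor torsion is not pinned at exactly 180
#'   degrees, midway between its two staggered target values.
#' @return A [molecule()]; atoms 1-6 formamide, 7-9 water (O, H, H).
#' @export
make_amide_water <- function(r_ho = 1.95, tilt = 4, twist = 12) {
  fm <- .formamide()
  h <- fm$coords[fm$idx$H_anti, ]
  nn <- fm$coords[fm$idx$N, ]
  d <- (h - nn); d <- d / sqrt(sum(d^2))
  d <- as.numeric(.rot_axis(c(0, 0, 1), 5) %*% d)  # ~175 deg N-H...O
  o_w <- h + r_ho * d
  # water plane perpendicular to the N-H...O axis: both H equidistant
  m <- c(0, 0, 1)                       # out-of-plane unit vector
  half <- 104.52 / 2 * .deg2rad
  roh <- 0.9572
  h_w1 <- o_w + roh * (cos(half) * d + sin(half) * m)
  h_w2 <- o_w + roh * (cos(half) * d - sin(half) * m)
  water <- rbind(o_w, h_w1, h_w2)
  if (tilt != 0) {
    # tilt about the in-plane axis perpendicular to the contact direction:
    # this tips one water hydrogen toward the amide proton and the other
    # away, which is what actually breaks the substituent equidistance
    # (a rotation about z or about d itself would leave both hydrogens
    # exactly equidistant from the in-plane amide proton)
    ax <- c(d[2] * m[3] - d[3] * m[2],
            d[3] * m[1] - d[1] * m[3],
            d[1] * m[2] - d[2] * m[1])
    rot <- .rot_axis(ax, tilt)
    water <- sweep(water, 2L, o_w) %*% t(rot) +
      matrix(o_w, 3L, 3L, byrow = TRUE)
  }
  if (twist != 0) {
    # a rotation about the contact axis itself would be a no-op for the
    # acceptor torsion (the amide proton lies on that axis); rotating
    # about the out-of-plane normal is what de-planarizes the torsion
    rot <- .rot_axis(m, twist)
    water <- sweep(water, 2L, o_w) %*% t(rot) +
      matrix(o_w, 3L, 3L, byrow = TRUE)
  }
  molecule(c(fm$symbols, "O", "H", "H"), rbind(fm$coords, water),
           comment = sprintf("amide-water r_HO=%.2f tilt=%.1f twist=%.1f",
                             r_ho, tilt, twist))
}

#' Randomly perturb a fixture geometry
#'
#' Adds independent Gaussian displacements to every coordinate, using the
#' current RNG state (set a seed for reproducibility). Used by the
#' property tests that assert sign and bound invariants over randomized
#' geometries.
#'
#' @param mol A [molecule()].
#' @param sigma Displacement standard deviation, Angstrom.
#' @return The perturbed [molecule()].
#' @export
perturb_molecule <- function(mol, sigma = 0.02) {
  stopifnot(inherits(mol, "molecule"), sigma >= 0)
  mol$coords <- mol$coords + matrix(stats::rnorm(3L * natoms(mol), 0, sigma),
                                    natoms(mol), 3L)
  mol
}
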