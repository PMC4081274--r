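# Hydrogen-bond correction E(H+): per-term energy
#   E_t = (C_A + C_B) / (2 r_AB^2) * f_geom * f_bond * f_damp
# summed over all (A, H, B) triples with A, B in {N, O} and H covalently
# bonded to one of them. Strength parameters C_N, C_O carry units of
# Hartree * Angstrom^2; the conversion to kcal/mol is a single
# configurable constant in the parameter set.

#' Hydrogen-bond correction parameters
#'
#' Default parameter set for the hydrogen-bond correction. The strength
#' parameters (`c_n = -0.110`, `c_o = -0.120`, Hartree Angstrom^2) are the
#' grid-scan optimum packaged as defaults; the damping constants are fixed
#' by the functional form: the covalent-bond damping sigmoid has steepness
#' 60 and midpoint 1.2 Angstrom on the donor-hydrogen distance, and the
#' donor-acceptor damping is the product of a rising sigmoid (steepness
#' 100, midpoint 2.4 Angstrom) and a falling one (steepness 10, midpoint
#' 7.0 Angstrom).
#'
#' @param file Optional key-value parameter file overriding the packaged
#'   defaults (lines of `name value`).
#' @param ... Named overrides applied after reading the file, e.g.
#'   `c_n = -0.2`.
#' @return Object of class `"hplus_params"`.
#' @export
hplus_params <- function(file = NULL, ...) {
  if (is.null(file)) {
    file <- system.file("extdata", "hplus_params.txt", package = "d3hplus",
                        mustWork = TRUE)
  }
  tab <- utils::read.table(file, header = FALSE,
                           col.names = c("key", "value"),
                           stringsAsFactors = FALSE)
  p <- as.list(stats::setNames(tab$value, tab$key))
  over <- list(...)
  p[names(over)] <- over
  required <- c("c_n", "c_o", "bond_steepness", "bond_midpoint",
                "damp_short_steepness", "damp_short_midpoint",
                "damp_long_steepness", "damp_long_midpoint",
                "cutoff", "unit_conversion")
  missing <- setdiff(required, names(p))
  if (length(missing))
    stop("missing H+ parameter(s): ", paste(missing, collapse = ", "))
  p <- lapply(p, as.numeric)
  if (p$c_n > 0 || p$c_o > 0)
    stop("strength parameters c_n, c_o must be <= 0 (attractive)")
  if (!(p$bond_midpoint < p$damp_short_midpoint &&
        p$damp_short_midpoint < p$damp_long_midpoint))
    stop("damping midpoints must be ordered bond < short < long")
  if (p$cutoff <= p$damp_long_midpoint)
    stop("enumeration cutoff must lie beyond the long-range midpoint")
  structure(p, class = "hplus_params")
}

#' Angular fitness factor of the hydrogen-bond correction
#'
#' Product of squared cosines of the five angular deviation coordinates of
#' a hydrogen bond: the linearity deviation at the hydrogen and the
#' bond-angle and torsion deviations from their target values on the donor
#' and acceptor sides. All arguments in degrees; the result lies in
#' \[0, 1\] and equals 1 for an ideal geometry.
#'
#' @param theta_dev,phi_a,psi_a,phi_b,psi_b Deviation angles in degrees
#'   (vectorized).
#' @return Numeric in \[0, 1\].
#' @export
f_geom <- function(theta_dev, phi_a = 0, psi_a = 0, phi_b = 0, psi_b = 0) {
  .cos2c(theta_dev * .deg2rad) * .cos2c(phi_a * .deg2rad) *
    .cos2c(psi_a * .deg2rad) * .cos2c(phi_b * .deg2rad) *
    .cos2c(psi_b * .deg2rad)
}

# squared-cosine fitness of a deviation angle (radians), clamped to zero
# beyond 90 degrees so badly misaligned arrangements cannot regain
# fitness; cos^2 has zero value and slope at 90 degrees, so the clamp is
# C1-continuous. Returns value and derivative with respect to the
# *measured* coordinate (dev = target - measured).
.cos2c <- function(dev) ifelse(abs(dev) > pi / 2, 0, cos(dev)^2)
.cos2c_d <- function(dev) ifelse(abs(dev) > pi / 2, 0, sin(2 * dev))

#' Covalent-bond damping factor of the hydrogen-bond correction
#'
#' Monotonically decreasing sigmoid complement on the donor-hydrogen
#' distance: 1 at covalent bond lengths, 1/2 at the midpoint (1.2
#' Angstrom by default), 0 for a detached hydrogen.
#'
#' @param r_xh Donor-hydrogen distance(s), Angstrom; the shorter of the
#'   two hydrogen-heteroatom distances of the bond.
#' @param params An [hplus_params()] object.
#' @return Numeric in (0, 1).
#' @export
f_bond <- function(r_xh, params = hplus_params()) {
  stats::plogis(-params$bond_steepness * (r_xh / params$bond_midpoint - 1))
}

#' Donor-acceptor distance damping factor
#'
#' Product of a rising sigmoid (short-range cut-on, midpoint 2.4 Angstrom,
#' steepness 100) and a falling sigmoid complement (long-range cut-off,
#' midpoint 7.0 Angstrom, steepness 10) on the donor-acceptor distance.
#'
#' @param r_ab Donor-acceptor distance(s), Angstrom.
#' @param params An [hplus_params()] object.
#' @param components If `TRUE`, return a data frame with the `short` and
#'   `long` factors alongside the product.
#' @return Numeric in (0, 1), or a data frame when `components = TRUE`.
#' @export
f_damp <- function(r_ab, params = hplus_params(), components = FALSE) {
  short <- stats::plogis(params$damp_short_steepness *
                           (r_ab / params$damp_short_midpoint - 1))
  long <- stats::plogis(-params$damp_long_steepness *
                          (r_ab / params$damp_long_midpoint - 1))
  if (components)
    data.frame(short = short, long = long, value = short * long)
  else short * long
}

# value + d/dr of f_bond
.f_bond_d <- function(r, params) {
  f <- f_bond(r, params)
  list(value = f,
       deriv = -(params$bond_steepness / params$bond_midpoint) * f * (1 - f))
}

# value + d/dr of f_damp
.f_damp_d <- function(r, params) {
  s1 <- stats::plogis(params$damp_short_steepness *
                        (r / params$damp_short_midpoint - 1))
  s2 <- stats::plogis(params$damp_long_steepness *
                        (r / params$damp_long_midpoint - 1))
  v <- s1 * (1 - s2)
  d <- (params$damp_short_steepness / params$damp_short_midpoint) *
    s1 * (1 - s1) * (1 - s2) -
    (params$damp_long_steepness / params$damp_long_midpoint) *
    s1 * s2 * (1 - s2)
  list(value = v, deriv = d)
}

#' Target-angle table for hydrogen-bond environments
#'
#' Pure-data table mapping a heteroatom environment (element plus
#' hybridization class) to its ideal bond angle and the candidate ideal
#' torsion angles. The packaged defaults use textbook values: tetrahedral
#' environments get 109.47 degrees with staggered torsion targets (+-120),
#' planar (double-bond bearing or conjugated) environments get 120 degrees
#' with in-plane torsion targets (0/180). The candidate torsion target
#' nearest to the observed torsion is selected at evaluation time.
#'
#' @param file Optional alternative table (columns `element`, `hybrid`,
#'   `phi_target`, `psi_targets`; torsion candidates separated by `;`).
#' @return Data frame with one row per (element, hybridization) entry and
#'   a list column `psi_targets`.
#' @export
target_angle_table <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "target_angles.txt", package = "d3hplus",
                        mustWork = TRUE)
  }
  tab <- utils::read.table(file, header = TRUE, stringsAsFactors = FALSE)
  tab$psi_targets <- lapply(strsplit(tab$psi_targets, ";"), as.numeric)
  tab$phi_target <- as.numeric(tab$phi_target)
  if (anyDuplicated(tab[c("element", "hybrid")]))
    stop("duplicate (element, hybrid) entry in target-angle table")
  tab
}

# is the x-y bond a double bond? Distance criterion: r < 0.89 * sum of
# covalent radii separates typical double from single bonds for the
# first-row pairs encountered here (e.g. C=O 1.22 vs C-O 1.43 against a
# threshold of 1.26 Angstrom).
.is_double_bond <- function(mol, x, y, radii) {
  r <- sqrt(sum((mol$coords[x, ] - mol$coords[y, ])^2))
  r < 0.89 * (radii[[mol$symbols[x]]] + radii[[mol$symbols[y]]])
}

#' Classify a heteroatom environment and assign its target angles
#'
#' Determines the hybridization class of an N or O atom involved in a
#' hydrogen bond and returns its target angles from the
#' [target_angle_table()]. Oxygen is planar (`"sp2"`) when it bears a
#' double bond (carbonyl), tetrahedral (`"sp3"`) otherwise. Nitrogen is
#' planar when it bears a double bond or is conjugated to one through a
#' neighbor (amide); a saturated NR3 group is tetrahedral.
#'
#' @param mol A [molecule()].
#' @param adj Adjacency from [perceive_bonds()].
#' @param x Index of the N or O atom to classify.
#' @param table Target-angle table, defaults to [target_angle_table()].
#' @param radii Covalent radii used for the double-bond distance test.
#' @return List with `element`, `hybrid`, `phi_target` (degrees) and
#'   `psi_targets` (numeric vector of candidate torsion targets,
#'   degrees). Unclassifiable atoms raise an error naming the atom.
#' @export
assign_target_angles <- function(mol, adj, x, table = target_angle_table(),
                                 radii = covalent_radii()) {
  el <- mol$symbols[x]
  if (!el %in% c("N", "O"))
    stop("atom ", x, " (", el, ") is not a hydrogen-bond heteroatom (N/O)")
  nb <- adj$neighbors[[x]]
  own_double <- any(vapply(nb, function(y) .is_double_bond(mol, x, y, radii),
                           logical(1)))
  conj_double <- any(vapply(nb, function(y) {
    yy <- setdiff(adj$neighbors[[y]], x)
    any(vapply(yy, function(z) .is_double_bond(mol, y, z, radii), logical(1)))
  }, logical(1)))
  hybrid <- if (el == "O") {
    if (own_double) "sp2" else "sp3"
  } else {
    if (own_double || conj_double) "sp2" else "sp3"
  }
  row <- table[table$element == el & table$hybrid == hybrid, ]
  if (nrow(row) != 1L)
    stop("no target-angle entry for atom ", x, " (", el, ", ", hybrid, ")")
  list(element = el, hybrid = hybrid, phi_target = row$phi_target[[1L]],
       psi_targets = row$psi_targets[[1L]])
}

# order candidate indices by (distance to reference atom, then index),
# treating distances within `tol` as tied so that near-degenerate
# geometries get a deterministic, index-based assignment
.order_by_distance <- function(coords, cands, ref, tol = 1e-9) {
  d <- sqrt(rowSums((coords[cands, , drop = FALSE] -
                       matrix(coords[ref, ], length(cands), 3L,
                              byrow = TRUE))^2))
  ord <- order(d, cands)
  # stable pass: swap neighbors whose distances tie within tol but whose
  # indices are out of order
  if (length(ord) > 1L) {
    repeat {
      swapped <- FALSE
      for (k in seq_len(length(ord) - 1L)) {
        a <- ord[k]; b <- ord[k + 1L]
        if (abs(d[a] - d[b]) < tol && cands[a] > cands[b]) {
          ord[k] <- b; ord[k + 1L] <- a; swapped <- TRUE
        }
      }
      if (!swapped) break
    }
  }
  cands[ord]
}

# circular angular difference a - b mapped to (-180, 180]
.ang_diff <- function(a, b) {
  d <- (a - b) %% 360
  d[d > 180] <- d[d > 180] - 360
  d
}

# build the frozen side description for heteroatom x of a term:
# substituent atoms R1/R2, the four-point torsion definition, and targets
.hbond_side <- function(mol, adj, x, h, table, radii) {
  cands <- setdiff(adj$neighbors[[x]], h)
  side <- list(x = x, r1 = NA_integer_, r2 = NA_integer_,
               psi_points = NULL, phi_target = NA_real_,
               psi_target = NA_real_, hybrid = NA_character_)
  if (!length(cands)) return(side)
  tgt <- assign_target_angles(mol, adj, x, table, radii)
  side$hybrid <- tgt$hybrid
  ord <- .order_by_distance(mol$coords, cands, h)
  side$r1 <- ord[1L]
  side$phi_target <- tgt$phi_target
  if (length(ord) >= 2L) {
    side$r2 <- ord[2L]
    side$psi_points <- c(side$r1, side$r2, x, h)
  } else {
    # single substituent (e.g. carbonyl oxygen): borrow the torsion
    # reference from the substituent's own neighbors, giving the proper
    # torsion R2'-R1-X...H
    r2cands <- setdiff(adj$neighbors[[side$r1]], x)
    if (length(r2cands)) {
      side$r2 <- .order_by_distance(mol$coords, r2cands, h)[1L]
      side$psi_points <- c(side$r2, side$r1, x, h)
    }
  }
  if (!is.null(side$psi_points)) {
    psi_now <- tryCatch(
      .ic_dihedral(mol$coords, side$psi_points[1L], side$psi_points[2L],
                   side$psi_points[3L], side$psi_points[4L])$value * .rad2deg,
      d3hplus_degenerate_geometry = function(e) NA_real_)
    if (is.na(psi_now)) {
      side$psi_points <- NULL
      side$r2 <- NA_integer_
    } else {
      dev <- abs(.ang_diff(tgt$psi_targets, psi_now))
      side$psi_target <- tgt$psi_targets[which.min(dev)]
    }
  }
  side
}

#' Enumerate hydrogen-bond terms of a molecule
#'
#' Finds every (A, H, B) triple with A and B nitrogen or oxygen atoms
#' within the enumeration cutoff and a hydrogen covalently bonded to one
#' of them. Each triple is one correction term; a heteroatom pair bridged
#' by two hydrogens contributes two terms. The donor is the heteroatom
#' nearer the hydrogen. Substituent choices (R1 = substituent closest to
#' the hydrogen, R2 the next) and target angles are frozen into the term,
#' with exact distance ties broken by lowest atom index.
#'
#' @param mol A [molecule()].
#' @param adj Adjacency from [perceive_bonds()] (computed if `NULL`).
#' @param params An [hplus_params()] object (supplies the cutoff).
#' @param table Target-angle table.
#' @return Object of class `"hbond_terms"`: list of frozen term
#'   descriptions ordered by (A, B, H) atom indices.
#' @export
enumerate_hbond_terms <- function(mol, adj = NULL, params = hplus_params(),
                                  table = target_angle_table()) {
  stopifnot(inherits(mol, "molecule"))
  if (is.null(adj)) adj <- perceive_bonds(mol)
  radii <- covalent_radii()
  het <- which(mol$symbols %in% c("N", "O"))
  hyd <- which(mol$symbols == "H")
  terms <- list()
  if (length(het) >= 2L && length(hyd) >= 1L) {
    dm <- distance_matrix(mol)
    for (ia in seq_along(het)) {
      for (ib in seq_along(het)) {
        if (ib <= ia) next
        a <- het[ia]; b <- het[ib]
        if (dm[a, b] > params$cutoff) next
        hs <- sort(intersect(hyd, union(adj$neighbors[[a]],
                                        adj$neighbors[[b]])))
        for (h in hs) {
          r_ah <- dm[a, h]; r_bh <- dm[b, h]
          donor <- if (r_bh < r_ah - 1e-9) "b"
                   else if (r_ah < r_bh - 1e-9) "a"
                   else if (h %in% adj$neighbors[[a]]) "a" else "b"
          xmin <- if (donor == "a") a else b
          term <- list(
            a = a, b = b, h = h,
            el_a = mol$symbols[a], el_b = mol$symbols[b],
            donor = donor, xmin = xmin,
            side_a = .hbond_side(mol, adj, a, h, table, radii),
            side_b = .hbond_side(mol, adj, b, h, table, radii))
          terms[[length(terms) + 1L]] <- term
        }
      }
    }
  }
  structure(terms, class = "hbond_terms")
}

# evaluate one frozen term at the given coordinates; returns the full
# factor decomposition (energies in kcal/mol, angles in degrees)
.term_eval <- function(coords, term, params) {
  r_ab <- .ic_distance(coords, term$a, term$b)$value
  r_xh <- .ic_distance(coords, term$xmin, term$h)$value
  theta <- .ic_angle(coords, term$a, term$h, term$b, grad = FALSE)$value *
    .rad2deg
  c_of <- c(N = params$c_n, O = params$c_o)
  pref <- params$unit_conversion *
    (c_of[[term$el_a]] + c_of[[term$el_b]]) / (2 * r_ab^2)
  side_vals <- lapply(list(a = term$side_a, b = term$side_b), function(s) {
    out <- list(phi = NA_real_, phi_dev = 0, psi = NA_real_, psi_dev = 0)
    if (!is.na(s$r1)) {
      out$phi <- .ic_angle(coords, term$h, s$x, s$r1, grad = FALSE)$value *
        .rad2deg
      out$phi_dev <- s$phi_target - out$phi
    }
    if (!is.null(s$psi_points)) {
      p <- s$psi_points
      out$psi <- .ic_dihedral(coords, p[1], p[2], p[3], p[4])$value * .rad2deg
      out$psi_dev <- .ang_diff(s$psi_target, out$psi)
    }
    out
  })
  theta_dev <- 180 - theta
  fg <- f_geom(theta_dev,
               side_vals$a$phi_dev, side_vals$a$psi_dev,
               side_vals$b$phi_dev, side_vals$b$psi_dev)
  fb <- f_bond(r_xh, params)
  fd <- f_damp(r_ab, params)
  list(energy = pref * fg * fb * fd,
       r_ab = r_ab, r_xh = r_xh, theta = theta, theta_dev = theta_dev,
       phi_a = side_vals$a$phi, phi_dev_a = side_vals$a$phi_dev,
       psi_a = side_vals$a$psi, psi_dev_a = side_vals$a$psi_dev,
       phi_b = side_vals$b$phi, phi_dev_b = side_vals$b$phi_dev,
       psi_b = side_vals$b$psi, psi_dev_b = side_vals$b$psi_dev,
       f_geom = fg, f_bond = fb, f_damp = fd, prefactor = pref)
}

#' Hydrogen-bond correction energy
#'
#' Total hydrogen-bond correction energy of a molecule with a per-term
#' breakdown. The energy is always non-positive and vanishes for
#' molecules without N/O heteroatoms or beyond the damping range.
#'
#' @param mol A [molecule()].
#' @param params An [hplus_params()] object.
#' @param adj Optional precomputed adjacency.
#' @param terms Optional precomputed [enumerate_hbond_terms()] result
#'   (assignments are then reused as frozen).
#' @return List with `energy` (kcal/mol) and `breakdown` (data frame, one
#'   row per term: indices, donor flag, distances, the five angular
#'   coordinates with their deviations, the three damping/fitness factors
#'   and the term energy).
#' @export
hplus_energy <- function(mol, params = hplus_params(), adj = NULL,
                         terms = NULL) {
  if (is.null(terms)) terms <- enumerate_hbond_terms(mol, adj, params)
  if (!length(terms))
    return(list(energy = 0,
                breakdown = data.frame()))
  rows <- lapply(terms, function(tm) {
    ev <- .term_eval(mol$coords, tm, params)
    data.frame(a = tm$a, h = tm$h, b = tm$b, el_a = tm$el_a, el_b = tm$el_b,
               donor = if (tm$donor == "a") tm$a else tm$b,
               r_ab = ev$r_ab, r_xh = ev$r_xh,
               theta = ev$theta, phi_a = ev$phi_a, psi_a = ev$psi_a,
               phi_b = ev$phi_b, psi_b = ev$psi_b,
               phi_dev_a = ev$phi_dev_a, psi_dev_a = ev$psi_dev_a,
               phi_dev_b = ev$phi_dev_b, psi_dev_b = ev$psi_dev_b,
               f_geom = ev$f_geom, f_bond = ev$f_bond, f_damp = ev$f_damp,
               energy = ev$energy)
  })
  breakdown <- do.call(rbind, rows)
  list(energy = sum(breakdown$energy), breakdown = breakdown)
}

# analytic gradient of a single frozen term; falls back to central finite
# differences on the frozen term energy if an internal coordinate is
# degenerate
.term_gradient <- function(coords, term, params, fd_step = 1e-5) {
  n <- nrow(coords)
  res <- tryCatch({
    d_ab <- .ic_distance(coords, term$a, term$b)
    d_xh <- .ic_distance(coords, term$xmin, term$h)
    a_th <- .ic_angle(coords, term$a, term$h, term$b)
    c_of <- c(N = params$c_n, O = params$c_o)
    cbar <- params$unit_conversion *
      (c_of[[term$el_a]] + c_of[[term$el_b]]) / 2
    fd <- .f_damp_d(d_ab$value, params)
    fb <- .f_bond_d(d_xh$value, params)
    # radial part P(r_ab) = cbar / r^2 * f_damp
    P <- cbar / d_ab$value^2 * fd$value
    dP <- cbar * (-2 / d_ab$value^3 * fd$value + fd$deriv / d_ab$value^2)
    # angular factors: clamped cos^2 of each deviation (radians); every
    # deviation has the form (target - measured), so the derivative with
    # respect to the measured coordinate is sin(2 dev) throughout
    dev_th <- pi - a_th$value
    vals <- .cos2c(dev_th)
    dvals <- .cos2c_d(dev_th)
    grads <- list(a_th$grad)
    for (s in list(term$side_a, term$side_b)) {
      if (!is.na(s$r1)) {
        a_phi <- .ic_angle(coords, term$h, s$x, s$r1)
        dev <- s$phi_target * .deg2rad - a_phi$value
        vals <- c(vals, .cos2c(dev))
        dvals <- c(dvals, .cos2c_d(dev))
        grads <- c(grads, list(a_phi$grad))
      }
      if (!is.null(s$psi_points)) {
        p <- s$psi_points
        t_psi <- .ic_dihedral(coords, p[1], p[2], p[3], p[4])
        dev <- .ang_diff(s$psi_target, t_psi$value * .rad2deg) * .deg2rad
        vals <- c(vals, .cos2c(dev))
        dvals <- c(dvals, .cos2c_d(dev))
        grads <- c(grads, list(t_psi$grad))
      }
    }
    G <- prod(vals)
    g <- dP * fb$value * G * d_ab$grad +
      P * fb$deriv * G * d_xh$grad
    for (k in seq_along(vals)) {
      others <- prod(vals[-k])
      g <- g + P * fb$value * others * dvals[k] * grads[[k]]
    }
    g
  }, d3hplus_degenerate_geometry = function(e) NULL)
  if (is.null(res)) {
    # finite-difference fallback for degenerate internal coordinates
    g <- matrix(0, n, 3L)
    efun <- function(cc) .term_eval(cc, term, params)$energy
    for (a in seq_len(n)) for (x in 1:3) {
      cp <- coords; cp[a, x] <- cp[a, x] + fd_step
      cm <- coords; cm[a, x] <- cm[a, x] - fd_step
      g[a, x] <- (efun(cp) - efun(cm)) / (2 * fd_step)
    }
    attr(g, "fd_fallback") <- TRUE
    res <- g
  }
  res
}

#' Analytic Cartesian gradient of the hydrogen-bond correction
#'
#' Assembles dE/dx by the chain rule over the internal coordinates of each
#' term (donor-acceptor distance, donor-hydrogen distance, linearity
#' angle, two bond angles and two torsions), using the analytic Wilson
#' rows of [internal_coordinate()]. Substituent and target-angle
#' assignments are frozen for the whole evaluation; terms with degenerate
#' internal coordinates fall back to finite differences.
#'
#' @param mol A [molecule()].
#' @param params An [hplus_params()] object.
#' @param adj Optional precomputed adjacency.
#' @param terms Optional precomputed frozen terms.
#' @return natoms x 3 matrix, kcal/mol/Angstrom. Attribute
#'   `"fd_fallback_terms"` lists indices of terms that required the
#'   finite-difference fallback (normally none).
#' @export
hplus_gradient <- function(mol, params = hplus_params(), adj = NULL,
                           terms = NULL) {
  if (is.null(terms)) terms <- enumerate_hbond_terms(mol, adj, params)
  g <- matrix(0, natoms(mol), 3L)
  fb <- integer(0)
  for (k in seq_along(terms)) {
    gt <- .term_gradient(mol$coords, terms[[k]], params)
    if (isTRUE(attr(gt, "fd_fallback"))) fb <- c(fb, k)
    g <- g + gt
  }
  attr(g, "fd_fallback_terms") <- fb
  g
}
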