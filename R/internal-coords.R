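# Internal coordinates (distance, bond angle, proper dihedral) with
# analytic Cartesian derivatives. The angle/dihedral derivatives are the
# standard Wilson B-matrix rows; every derivative row set sums to zero
# over atoms (translational invariance), which the test suite asserts on
# random geometries.

.deg2rad <- pi / 180
.rad2deg <- 180 / pi

.degenerate <- function(msg, indices) {
  cond <- structure(class = c("d3hplus_degenerate_geometry", "error",
                              "condition"),
                    list(message = paste0(msg, " (atoms ",
                                          paste(indices, collapse = ","), ")"),
                         call = NULL, indices = indices))
  stop(cond)
}

# distance between atoms i, j: value in Angstrom, grad n x 3
.ic_distance <- function(coords, i, j) {
  d <- coords[i, ] - coords[j, ]
  r <- sqrt(sum(d * d))
  g <- matrix(0, nrow(coords), 3L)
  if (r < 1e-12) .degenerate("coincident atoms in distance", c(i, j))
  g[i, ] <- d / r
  g[j, ] <- -d / r
  list(value = r, grad = g)
}

# angle i-j-k with vertex at j: value in radians. The value is defined
# for collinear arrangements; only the derivative is singular there, so
# the degeneracy check is skipped when grad = FALSE.
.ic_angle <- function(coords, i, j, k, grad = TRUE) {
  u <- coords[i, ] - coords[j, ]
  v <- coords[k, ] - coords[j, ]
  nu <- sqrt(sum(u * u)); nv <- sqrt(sum(v * v))
  if (nu < 1e-12 || nv < 1e-12)
    .degenerate("coincident atoms in angle", c(i, j, k))
  uh <- u / nu; vh <- v / nv
  ct <- sum(uh * vh)
  ct <- max(-1, min(1, ct))
  st <- sqrt(max(0, 1 - ct * ct))
  if (!grad) return(list(value = acos(ct), grad = NULL))
  if (st < 1e-10) .degenerate("collinear atoms in angle", c(i, j, k))
  theta <- acos(ct)
  g <- matrix(0, nrow(coords), 3L)
  g[i, ] <- (ct * uh - vh) / (nu * st)
  g[k, ] <- (ct * vh - uh) / (nv * st)
  g[j, ] <- -(g[i, ] + g[k, ])
  list(value = theta, grad = g)
}

# proper dihedral i-j-k-l about the j-k axis, IUPAC sign convention,
# range (-pi, pi]; Blondel-Karplus derivative formulas
.ic_dihedral <- function(coords, i, j, k, l) {
  b1 <- coords[j, ] - coords[i, ]
  b2 <- coords[k, ] - coords[j, ]
  b3 <- coords[l, ] - coords[k, ]
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  n1sq <- sum(n1 * n1); n2sq <- sum(n2 * n2)
  nb2 <- sqrt(sum(b2 * b2))
  if (nb2 < 1e-12) .degenerate("coincident axis atoms in dihedral",
                               c(i, j, k, l))
  if (n1sq < 1e-16 || n2sq < 1e-16)
    .degenerate("collinear atoms in dihedral", c(i, j, k, l))
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1])
  x <- sum(n1 * n2)
  y <- sum(m1 * n2) / nb2
  phi <- atan2(y, x)
  g <- matrix(0, nrow(coords), 3L)
  gi <- nb2 / n1sq * n1
  gl <- -nb2 / n2sq * n2
  f1 <- -sum(b1 * b2) / (nb2 * nb2)
  f3 <- -sum(b3 * b2) / (nb2 * nb2)
  g[i, ] <- gi
  g[l, ] <- gl
  g[j, ] <- (f1 - 1) * gi - f3 * gl
  g[k, ] <- (f3 - 1) * gl - f1 * gi
  list(value = phi, grad = g)
}

#' Evaluate an internal coordinate and its Cartesian derivative
#'
#' Computes a distance, bond angle or proper dihedral together with its
#' analytic derivative with respect to all Cartesian coordinates. Angles
#' and dihedrals are returned in degrees (derivatives in degrees per
#' Angstrom); distances in Angstrom (derivative unitless). Dihedrals
#' follow the IUPAC right-handed convention with range (-180, 180].
#'
#' @param mol A [molecule()].
#' @param kind One of `"distance"`, `"angle"`, `"dihedral"`.
#' @param indices Integer vector of 2, 3 or 4 distinct atom indices.
#' @return List with `value` and `grad` (natoms x 3 matrix). Degenerate
#'   geometries (collinear triplets for angles/dihedrals) signal a
#'   condition of class `"d3hplus_degenerate_geometry"` carrying the
#'   offending indices.
#' @export
internal_coordinate <- function(mol,
                                kind = c("distance", "angle", "dihedral"),
                                indices) {
  stopifnot(inherits(mol, "molecule"))
  kind <- match.arg(kind)
  indices <- as.integer(indices)
  need <- c(distance = 2L, angle = 3L, dihedral = 4L)[[kind]]
  if (length(indices) != need)
    stop(kind, " needs ", need, " atom indices")
  if (anyDuplicated(indices) || any(indices < 1L | indices > natoms(mol)))
    stop("indices must be distinct and within 1..", natoms(mol))
  res <- switch(kind,
    distance = .ic_distance(mol$coords, indices[1], indices[2]),
    angle = .ic_angle(mol$coords, indices[1], indices[2], indices[3]),
    dihedral = .ic_dihedral(mol$coords, indices[1], indices[2],
                            indices[3], indices[4]))
  if (kind != "distance") {
    res$value <- res$value * .rad2deg
    res$grad <- res$grad * .rad2deg
  }
  res
}

#' Central finite-difference gradient of an energy function
#'
#' The finite-difference oracle used throughout the package: to validate
#' every analytic gradient, and as the production gradient of the
#' three-body dispersion term.
#'
#' @param energy_fn Function taking a [molecule()] and returning a single
#'   finite energy (kcal/mol).
#' @param mol A [molecule()].
#' @param step Displacement step in Angstrom (default 1e-5, central
#'   differences).
#' @return natoms x 3 matrix of dE/dx in kcal/mol/Angstrom.
#' @export
numerical_gradient <- function(energy_fn, mol, step = 1e-5) {
  stopifnot(inherits(mol, "molecule"), step > 0)
  n <- natoms(mol)
  g <- matrix(0, n, 3L)
  for (a in seq_len(n)) {
    for (x in 1:3) {
      mp <- mol; mp$coords[a, x] <- mp$coords[a, x] + step
      mm <- mol; mm$coords[a, x] <- mm$coords[a, x] - step
      g[a, x] <- (energy_fn(mp) - energy_fn(mm)) / (2 * step)
    }
  }
  g
}
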