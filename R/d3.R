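# Third-generation pairwise dispersion correction, zero damping, orders 6
# and 8: E = -sum_{A<B} [ s6 C6/r^6 f6 + s8 C8/r^8 f8 ] with
# f_n = 1 / (1 + 6 (r / (s_rn R0_AB))^(-alpha_n)), C8 = 3 C6 sqrt(QA QB),
# and C6 interpolated over coordination-number reference points with
# Gaussian weights exp(-4 d^2). Internal units are atomic (Bohr/Hartree);
# the API takes Angstrom and reports kcal/mol.

.bohr <- 0.52917721067
.hartree_kcal <- 627.509474

#' Dispersion correction parameters
#'
#' Default zero-damping dispersion parameters fitted for the semiempirical
#' base method: `s6 = 1.000` (fixed), `s8 = 1.009`, `sr6 = 1.560`,
#' `alpha = 14.000`. The remaining zero-damping constants follow the
#' standard convention: `sr8 = 1.0`, `alpha8 = alpha + 2`, and the
#' three-body damping uses `sr9 = 4/3` with exponent 16.
#'
#' @param s6,s8 Order-6 and order-8 scale factors.
#' @param sr6 Scaling of the pair cutoff radii in the order-6 damping.
#' @param alpha Sharpness of the order-6 zero-damping function.
#' @param sr8,alpha8 Order-8 damping constants.
#' @param sr9,alpha9 Three-body damping constants.
#' @return Object of class `"d3_params"`.
#' @export
d3_params <- function(s6 = 1.000, s8 = 1.009, sr6 = 1.560, alpha = 14.000,
                      sr8 = 1.0, alpha8 = alpha + 2, sr9 = 4 / 3,
                      alpha9 = 16) {
  stopifnot(s6 >= 0, s8 >= 0, sr6 > 0, alpha > 0, sr8 > 0, alpha8 > 0)
  structure(list(s6 = s6, s8 = s8, sr6 = sr6, alpha = alpha, sr8 = sr8,
                 alpha8 = alpha8, sr9 = sr9, alpha9 = alpha9),
            class = "d3_params")
}

#' Dispersion reference data (synthetic tables, elements H-Ne)
#'
#' Loads the element-wise reference tables used by the dispersion term:
#' covalent radii for the coordination-number counting function, the
#' effective sqrt of the r^4/r^2 expectation-value ratio entering the C8
#' recursion, and the coordination-number/C6 reference points for the C6
#' interpolation, plus the cutoff-radius rule constant. The packaged
#' dataset is synthetic: it is constructed from published scalar constants
#' and documented combination rules rather than the original reference
#' grids (see the methods vignette), and is complete for elements H-Ne.
#'
#' @param elements_file,constants_file Optional alternative table paths.
#' @return Object of class `"d3_data"` with fields `rcov` (Angstrom,
#'   named), `q` (named), `refs` (named list of data frames with columns
#'   `cn`, `c6`), `k1`, `k3` and `r0_scale`.
#' @export
d3_reference_data <- function(elements_file = NULL, constants_file = NULL) {
  if (is.null(elements_file))
    elements_file <- system.file("extdata", "d3_synthetic_elements.txt",
                                 package = "d3hplus", mustWork = TRUE)
  if (is.null(constants_file))
    constants_file <- system.file("extdata", "d3_synthetic_constants.txt",
                                  package = "d3hplus", mustWork = TRUE)
  el <- utils::read.table(elements_file, header = TRUE,
                          stringsAsFactors = FALSE)
  ct <- utils::read.table(constants_file, header = FALSE,
                          col.names = c("key", "value"),
                          stringsAsFactors = FALSE)
  const <- as.list(stats::setNames(ct$value, ct$key))
  refs <- lapply(seq_len(nrow(el)), function(i) {
    cn <- c(0, el$cn_valence[i])
    c6 <- c(el$c6_free[i], el$c6_valence[i])
    keep <- !is.na(cn) & !is.na(c6)
    data.frame(cn = cn[keep], c6 = c6[keep])
  })
  names(refs) <- el$symbol
  stopifnot(all(el$rcov > 0), all(el$q > 0),
            all(vapply(refs, function(r) all(r$c6 > 0), logical(1))))
  structure(list(rcov = stats::setNames(el$rcov, el$symbol),
                 q = stats::setNames(el$q, el$symbol),
                 refs = refs,
                 k1 = const$k1, k3 = const$k3, r0_scale = const$r0_scale),
            class = "d3_data")
}

# pair cutoff radius in Bohr
.d3_r0 <- function(el_a, el_b, data) {
  data$r0_scale * sqrt(3 * data$q[[el_a]] * data$q[[el_b]])
}

.d3_check_elements <- function(mol, data) {
  bad <- setdiff(unique(mol$symbols), names(data$rcov))
  if (length(bad))
    stop("no dispersion reference data for element(s): ",
         paste(bad, collapse = ", "))
}

#' Fractional coordination numbers
#'
#' Counting-function coordination number of every atom:
#' `CN_A = sum_B 1 / (1 + exp(-k1 (4 (Rcov_A + Rcov_B) / (3 r_AB) - 1)))`
#' with `k1 = 16`.
#'
#' @param mol A [molecule()].
#' @param data A [d3_reference_data()] object.
#' @return Numeric vector of per-atom coordination numbers (unitless).
#' @export
coordination_numbers <- function(mol, data = d3_reference_data()) {
  stopifnot(inherits(mol, "molecule"))
  .d3_check_elements(mol, data)
  n <- natoms(mol)
  cn <- numeric(n)
  if (n < 2L) return(cn)
  dm <- distance_matrix(mol)
  rc <- data$rcov[mol$symbols]
  for (a in seq_len(n)) {
    b <- setdiff(seq_len(n), a)
    cn[a] <- sum(stats::plogis(data$k1 *
                                 (4 * (rc[a] + rc[b]) / (3 * dm[a, b]) - 1)))
  }
  cn
}

# C6 interpolation with derivatives w.r.t. both coordination numbers.
# Pair reference values combine the element references geometrically:
# c6_ref(i, j) = sqrt(c6_A(i) * c6_B(j)) (part of the synthetic dataset).
.c6_interp <- function(el_a, el_b, cn_a, cn_b, data) {
  ra <- data$refs[[el_a]]; rb <- data$refs[[el_b]]
  if (is.null(ra) || is.null(rb) || !nrow(ra) || !nrow(rb))
    stop("empty C6 reference grid for pair ", el_a, "-", el_b)
  grid <- expand.grid(i = seq_len(nrow(ra)), j = seq_len(nrow(rb)))
  c6ref <- sqrt(ra$c6[grid$i] * rb$c6[grid$j])
  da <- cn_a - ra$cn[grid$i]
  db <- cn_b - rb$cn[grid$j]
  ex <- data$k3 * (da^2 + db^2)
  ex <- ex - max(ex)                    # log-sum-exp stabilisation
  w <- exp(ex)
  W <- sum(w); Z <- sum(w * c6ref)
  c6 <- Z / W
  dw_da <- w * (2 * data$k3 * da)
  dw_db <- w * (2 * data$k3 * db)
  list(c6 = c6,
       dcn_a = (sum(dw_da * c6ref) - c6 * sum(dw_da)) / W,
       dcn_b = (sum(dw_db * c6ref) - c6 * sum(dw_db)) / W)
}

#' Effective C6 coefficient of an element pair
#'
#' Gaussian-weighted interpolation of the pair C6 coefficient over the
#' coordination-number reference points (weight exponent -4). Reduces to
#' the single reference value when only one point exists and is symmetric
#' in its arguments.
#'
#' @param el_a,el_b Element symbols.
#' @param cn_a,cn_b Fractional coordination numbers of the two atoms.
#' @param data A [d3_reference_data()] object.
#' @return Effective C6 in atomic units (Hartree Bohr^6).
#' @export
c6_effective <- function(el_a, el_b, cn_a, cn_b, data = d3_reference_data()) {
  .c6_interp(el_a, el_b, cn_a, cn_b, data)$c6
}

# zero-damping function and its r-derivative (r, r0 in Bohr)
.f_zero <- function(r, r0, sr, alpha) {
  u <- 6 * (sr * r0 / r)^alpha
  f <- 1 / (1 + u)
  list(value = f, deriv = alpha * u * f * f / r)
}

#' Two-body dispersion energy
#'
#' Pairwise additive dispersion energy with zero damping and dispersion
#' orders 6 and 8. Always non-positive; decays as r^-6.
#'
#' @param mol A [molecule()].
#' @param params A [d3_params()] object.
#' @param data A [d3_reference_data()] object.
#' @return List with `energy` (kcal/mol), `pairs` (per-pair breakdown:
#'   indices, distance in Angstrom, effective C6 and C8 in atomic units,
#'   damping factors, order-6/order-8 and total pair energies in
#'   kcal/mol) and `cn` (per-atom coordination numbers).
#' @export
d3_two_body <- function(mol, params = d3_params(),
                        data = d3_reference_data()) {
  stopifnot(inherits(mol, "molecule"))
  .d3_check_elements(mol, data)
  n <- natoms(mol)
  cn <- coordination_numbers(mol, data)
  if (n < 2L)
    return(list(energy = 0, pairs = data.frame(), cn = cn))
  rows <- vector("list", n * (n - 1L) / 2L)
  k <- 0L
  for (a in seq_len(n - 1L)) for (b in (a + 1L):n) {
    ea <- mol$symbols[a]; eb <- mol$symbols[b]
    r <- sqrt(sum((mol$coords[a, ] - mol$coords[b, ])^2)) / .bohr
    c6 <- .c6_interp(ea, eb, cn[a], cn[b], data)$c6
    c8 <- 3 * c6 * data$q[[ea]] * data$q[[eb]]
    r0 <- .d3_r0(ea, eb, data)
    f6 <- .f_zero(r, r0, params$sr6, params$alpha)$value
    f8 <- .f_zero(r, r0, params$sr8, params$alpha8)$value
    e6 <- -params$s6 * c6 / r^6 * f6 * .hartree_kcal
    e8 <- -params$s8 * c8 / r^8 * f8 * .hartree_kcal
    k <- k + 1L
    rows[[k]] <- data.frame(a = a, b = b, r = r * .bohr, c6 = c6, c8 = c8,
                            f6 = f6, f8 = f8, e6 = e6, e8 = e8,
                            energy = e6 + e8)
  }
  pairs <- do.call(rbind, rows)
  list(energy = sum(pairs$energy), pairs = pairs, cn = cn)
}

#' Analytic gradient of the two-body dispersion energy
#'
#' Cartesian gradient of [d3_two_body()], including the chain-rule terms
#' from the coordination-number dependence of the interpolated C6
#' coefficients. Net force is zero to numerical precision.
#'
#' @inheritParams d3_two_body
#' @return natoms x 3 matrix, kcal/mol/Angstrom.
#' @export
d3_two_body_gradient <- function(mol, params = d3_params(),
                                 data = d3_reference_data()) {
  stopifnot(inherits(mol, "molecule"))
  .d3_check_elements(mol, data)
  n <- natoms(mol)
  g <- matrix(0, n, 3L)
  if (n < 2L) return(g)
  xyz <- mol$coords / .bohr
  rc <- data$rcov[mol$symbols] / .bohr
  cn <- numeric(n)
  # pair distances and unit vectors
  rmat <- matrix(0, n, n)
  for (a in seq_len(n - 1L)) for (b in (a + 1L):n) {
    r <- sqrt(sum((xyz[a, ] - xyz[b, ])^2))
    rmat[a, b] <- r; rmat[b, a] <- r
  }
  for (a in seq_len(n))
    cn[a] <- sum(stats::plogis(data$k1 *
                                 (4 * (rc[a] + rc[-a]) / (3 * rmat[a, -a]) - 1)))
  # dCN_A/dx: stored as a list of n x 3 matrices (small molecules)
  cngrad <- lapply(seq_len(n), function(a) matrix(0, n, 3L))
  for (a in seq_len(n - 1L)) for (b in (a + 1L):n) {
    r <- rmat[a, b]
    s <- stats::plogis(data$k1 * (4 * (rc[a] + rc[b]) / (3 * r) - 1))
    dgdr <- s * (1 - s) * data$k1 * (-4 * (rc[a] + rc[b]) / (3 * r * r))
    u <- (xyz[a, ] - xyz[b, ]) / r
    cngrad[[a]][a, ] <- cngrad[[a]][a, ] + dgdr * u
    cngrad[[a]][b, ] <- cngrad[[a]][b, ] - dgdr * u
    cngrad[[b]][a, ] <- cngrad[[b]][a, ] + dgdr * u
    cngrad[[b]][b, ] <- cngrad[[b]][b, ] - dgdr * u
  }
  for (a in seq_len(n - 1L)) for (b in (a + 1L):n) {
    ea <- mol$symbols[a]; eb <- mol$symbols[b]
    r <- rmat[a, b]
    ci <- .c6_interp(ea, eb, cn[a], cn[b], data)
    qq <- data$q[[ea]] * data$q[[eb]]
    r0 <- .d3_r0(ea, eb, data)
    f6 <- .f_zero(r, r0, params$sr6, params$alpha)
    f8 <- .f_zero(r, r0, params$sr8, params$alpha8)
    # E_pair = c6 * w(r), w = -(s6 f6 / r^6 + 3 s8 qq f8 / r^8)
    w <- -(params$s6 * f6$value / r^6 + 3 * params$s8 * qq * f8$value / r^8)
    dw <- -(params$s6 * (f6$deriv / r^6 - 6 * f6$value / r^7) +
              3 * params$s8 * qq * (f8$deriv / r^8 - 8 * f8$value / r^9))
    u <- (xyz[a, ] - xyz[b, ]) / r
    gr <- ci$c6 * dw
    g[a, ] <- g[a, ] + gr * u
    g[b, ] <- g[b, ] - gr * u
    g <- g + w * (ci$dcn_a * cngrad[[a]] + ci$dcn_b * cngrad[[b]])
  }
  g * (.hartree_kcal / .bohr)
}

#' Three-body triple-dipole dispersion energy
#'
#' Axilrod-Teller-Muto triple sum with `C9 = -sqrt(C6_AB C6_BC C6_CA)`
#' and a zero-damping factor on the geometric-mean distance (scale 4/3,
#' exponent 16). Disabled by default in the combined energy; its gradient
#' is obtained with [numerical_gradient()].
#'
#' @inheritParams d3_two_body
#' @return List with `energy` (kcal/mol) and `triples` (per-triple
#'   breakdown).
#' @export
d3_three_body <- function(mol, params = d3_params(),
                          data = d3_reference_data()) {
  stopifnot(inherits(mol, "molecule"))
  .d3_check_elements(mol, data)
  n <- natoms(mol)
  if (n < 3L) return(list(energy = 0, triples = data.frame()))
  cn <- coordination_numbers(mol, data)
  xyz <- mol$coords / .bohr
  rows <- list()
  for (a in seq_len(n - 2L)) for (b in (a + 1L):(n - 1L)) for (cc in (b + 1L):n) {
    ea <- mol$symbols[a]; eb <- mol$symbols[b]; ec <- mol$symbols[cc]
    rab <- sqrt(sum((xyz[a, ] - xyz[b, ])^2))
    rbc <- sqrt(sum((xyz[b, ] - xyz[cc, ])^2))
    rca <- sqrt(sum((xyz[cc, ] - xyz[a, ])^2))
    c6ab <- .c6_interp(ea, eb, cn[a], cn[b], data)$c6
    c6bc <- .c6_interp(eb, ec, cn[b], cn[cc], data)$c6
    c6ca <- .c6_interp(ec, ea, cn[cc], cn[a], data)$c6
    c9 <- -sqrt(c6ab * c6bc * c6ca)
    cosa <- (rab^2 + rca^2 - rbc^2) / (2 * rab * rca)
    cosb <- (rab^2 + rbc^2 - rca^2) / (2 * rab * rbc)
    cosc <- (rbc^2 + rca^2 - rab^2) / (2 * rbc * rca)
    rbar <- (rab * rbc * rca)^(1 / 3)
    r0 <- (.d3_r0(ea, eb, data) * .d3_r0(eb, ec, data) *
             .d3_r0(ec, ea, data))^(1 / 3)
    fd <- .f_zero(rbar, r0, params$sr9, params$alpha9)$value
    e <- c9 * (3 * cosa * cosb * cosc + 1) / (rab * rbc * rca)^3 * fd *
      .hartree_kcal
    rows[[length(rows) + 1L]] <-
      data.frame(a = a, b = b, c = cc, c9 = c9, energy = e)
  }
  triples <- do.call(rbind, rows)
  list(energy = sum(triples$energy), triples = triples)
}
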