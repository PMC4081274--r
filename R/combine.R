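# Corrected total energy: E(total) = E(base) + E(D3) + E(H+), with the
# base electronic energy supplied by a pluggable backend. The base method
# itself (an SCF) is never computed here.

#' Construct a base-energy backend
#'
#' A backend adapter supplying the base electronic energy (and optionally
#' its gradient) for a molecule. Backends declare their native energy
#' unit; everything is normalized to kcal/mol at this seam.
#'
#' @param energy Function `(mol, id)` returning the base energy in `unit`.
#' @param gradient Optional function `(mol, id)` returning a natoms x 3
#'   gradient matrix in `unit`/Angstrom.
#' @param unit `"kcal"` or `"hartree"`.
#' @param name Backend label used in messages.
#' @return Object of class `"base_backend"`.
#' @export
base_backend <- function(energy, gradient = NULL, unit = c("kcal", "hartree"),
                         name = "custom") {
  unit <- match.arg(unit)
  conv <- if (unit == "hartree") .hartree_kcal else 1
  structure(list(energy = energy, gradient = gradient, conv = conv,
                 name = name,
                 capabilities = c(energy = TRUE,
                                  gradient = !is.null(gradient))),
            class = "base_backend")
}

#' Zero base backend
#'
#' Backend returning zero energy and gradient; the corrected total is then
#' the bare correction sum. Useful for testing and for correction-only
#' analyses.
#' @return A [base_backend()].
#' @export
base_zero <- function() {
  base_backend(energy = function(mol, id = NULL) 0,
               gradient = function(mol, id = NULL)
                 matrix(0, natoms(mol), 3L),
               name = "zero")
}

#' Wrap an R function as a base backend
#'
#' @param energy Function `(mol)` returning the base energy.
#' @param gradient Optional function `(mol)` returning the gradient.
#' @inheritParams base_backend
#' @return A [base_backend()].
#' @export
base_function <- function(energy, gradient = NULL, unit = "kcal",
                          name = "function") {
  efn <- function(mol, id = NULL) energy(mol)
  gfn <- if (is.null(gradient)) NULL else function(mol, id = NULL) gradient(mol)
  base_backend(efn, gfn, unit = unit, name = name)
}

#' Lookup backend over a table of precomputed base energies
#'
#' Reads a CSV (or takes a data frame) of `(id, energy)` rows, typically
#' precomputed base-method energies for a benchmark set, and serves them
#' by structure id. No gradients are available from a table backend.
#'
#' @param x CSV path or data frame with columns `id` and `energy`.
#' @inheritParams base_backend
#' @return A [base_backend()].
#' @export
base_table <- function(x, unit = "kcal") {
  tab <- if (is.character(x)) utils::read.csv(x, stringsAsFactors = FALSE)
         else as.data.frame(x)
  if (!all(c("id", "energy") %in% names(tab)))
    stop("base-energy table needs columns 'id' and 'energy'")
  if (anyDuplicated(tab$id))
    stop("duplicate structure id(s) in base-energy table")
  lookup <- stats::setNames(as.numeric(tab$energy), as.character(tab$id))
  base_backend(energy = function(mol, id = NULL) {
    if (is.null(id)) stop("table backend requires a structure id")
    if (!as.character(id) %in% names(lookup))
      stop("no base energy stored for id '", id, "'")
    lookup[[as.character(id)]]
  }, unit = unit, name = "table")
}

#' Corrected total energy with component breakdown
#'
#' Composes the corrected total energy as the sum of the base energy, the
#' two-body (and optionally three-body) dispersion correction, and the
#' hydrogen-bond correction. Components can be toggled; a disabled
#' component contributes exactly zero.
#'
#' @param mol A [molecule()].
#' @param backend A [base_backend()] (default [base_zero()]).
#' @param hplus An [hplus_params()] object.
#' @param d3 A [d3_params()] object.
#' @param data A [d3_reference_data()] object.
#' @param include Character subset of `c("base", "d3", "hplus")`.
#' @param three_body Include the three-body dispersion term (default
#'   `FALSE`).
#' @param id Structure id forwarded to the backend (table backends).
#' @return Object of class `"energy_breakdown"`: list with `base`,
#'   `d3_two_body`, `d3_three_body`, `hplus` and `total`, all kcal/mol
#'   (disabled components are 0; the three-body slot is `NA` when not
#'   requested).
#' @export
total_energy <- function(mol, backend = base_zero(), hplus = hplus_params(),
                         d3 = d3_params(), data = d3_reference_data(),
                         include = c("base", "d3", "hplus"),
                         three_body = FALSE, id = NULL) {
  stopifnot(inherits(mol, "molecule"), inherits(backend, "base_backend"))
  include <- match.arg(include, c("base", "d3", "hplus"), several.ok = TRUE)
  e_base <- if ("base" %in% include)
    backend$energy(mol, id) * backend$conv else 0
  if (!is.finite(e_base)) stop("backend '", backend$name,
                               "' returned a non-finite base energy")
  e_d3 <- if ("d3" %in% include) d3_two_body(mol, d3, data)$energy else 0
  e_d3_3 <- if ("d3" %in% include && three_body)
    d3_three_body(mol, d3, data)$energy else NA_real_
  e_hp <- if ("hplus" %in% include) hplus_energy(mol, hplus)$energy else 0
  total <- e_base + e_d3 + e_hp + if (is.na(e_d3_3)) 0 else e_d3_3
  structure(list(base = e_base, d3_two_body = e_d3, d3_three_body = e_d3_3,
                 hplus = e_hp, total = total),
            class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat("energy breakdown (kcal/mol)\n")
  cat(sprintf("  base        : %14.8f\n", x$base))
  cat(sprintf("  d3 two-body : %14.8f\n", x$d3_two_body))
  if (!is.na(x$d3_three_body))
    cat(sprintf("  d3 three-body: %13.8f\n", x$d3_three_body))
  cat(sprintf("  h-bond      : %14.8f\n", x$hplus))
  cat(sprintf("  total       : %14.8f\n", x$total))
  invisible(x)
}

#' Gradient of the corrected total energy
#'
#' Vector sum of the component gradients: analytic for the hydrogen-bond
#' and two-body dispersion terms, finite-difference for the three-body
#' term, backend-supplied for the base. Requesting the base component
#' from a backend without gradient capability is an explicit error.
#'
#' @inheritParams total_energy
#' @param fd_step Step for the three-body finite-difference gradient.
#' @return natoms x 3 matrix, kcal/mol/Angstrom.
#' @export
total_gradient <- function(mol, backend = base_zero(),
                           hplus = hplus_params(), d3 = d3_params(),
                           data = d3_reference_data(),
                           include = c("base", "d3", "hplus"),
                           three_body = FALSE, id = NULL, fd_step = 1e-5) {
  stopifnot(inherits(mol, "molecule"), inherits(backend, "base_backend"))
  include <- match.arg(include, c("base", "d3", "hplus"), several.ok = TRUE)
  g <- matrix(0, natoms(mol), 3L)
  if ("base" %in% include) {
    if (!isTRUE(backend$capabilities[["gradient"]]))
      stop("backend '", backend$name, "' does not provide gradients; ",
           "drop \"base\" from 'include' for correction-only gradients")
    g <- g + backend$gradient(mol, id) * backend$conv
  }
  if ("d3" %in% include) {
    g <- g + d3_two_body_gradient(mol, d3, data)
    if (three_body)
      g <- g + numerical_gradient(function(m)
        d3_three_body(m, d3, data)$energy, mol, step = fd_step)
  }
  if ("hplus" %in% include) g <- g + hplus_gradient(mol, hplus)
  g
}
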