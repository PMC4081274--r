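#' Supported elements and their data
#'
#' The correction terms implemented in this package are defined for the
#' elements hydrogen through neon only. Element symbols are matched
#' case-sensitively ("H", "He", ..., "Ne").
#'
#' @return Character vector of supported element symbols, in order of
#'   atomic number.
#' @export
supported_elements <- function() {
  c("H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne")
}

#' Covalent radii used for bond perception
#'
#' Single-bond covalent radii (Cordero et al. consensus values, Angstrom)
#' for the supported elements, used by [perceive_bonds()]. The table is
#' read from a plain-text data file shipped with the package so that an
#' alternative radius set can be substituted without code changes.
#'
#' @param file Optional path to an alternative two-column table
#'   (columns `symbol`, `radius`). Defaults to the packaged table.
#' @return Named numeric vector of radii in Angstrom.
#' @export
covalent_radii <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "covalent_radii.txt", package = "d3hplus",
                        mustWork = TRUE)
  }
  tab <- utils::read.table(file, header = TRUE, stringsAsFactors = FALSE)
  stats::setNames(tab$radius, tab$symbol)
}

#' Construct a molecule
#'
#' A molecule is a minimal container: element symbols plus Cartesian
#' coordinates in Angstrom. It is the geometric substrate for every
#' energy term in the package.
#'
#' @param symbols Character vector of element symbols (H through Ne).
#' @param coords Numeric matrix, one row per atom, three columns (x, y, z)
#'   in Angstrom.
#' @param comment Free-text comment carried through XYZ round-trips.
#' @return An object of class `"molecule"` with fields `symbols`,
#'   `coords` and `comment`.
#' @export
molecule <- function(symbols, coords, comment = "") {
  symbols <- as.character(symbols)
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (length(symbols) < 1L)
    stop("a molecule needs at least one atom")
  if (nrow(coords) != length(symbols) || ncol(coords) != 3L)
    stop("'coords' must be a length(symbols) x 3 matrix")
  if (!all(is.finite(coords)))
    stop("all coordinates must be finite")
  unknown <- setdiff(unique(symbols), supported_elements())
  if (length(unknown))
    stop("unsupported element symbol(s): ", paste(unknown, collapse = ", "),
         " (supported: H through Ne)")
  dimnames(coords) <- NULL
  structure(list(symbols = symbols, coords = coords,
                 comment = as.character(comment)[1L]),
            class = "molecule")
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("molecule: %d atoms (%s)\n", natoms(x),
              paste(x$symbols, collapse = " ")))
  if (nzchar(x$comment)) cat(" comment:", x$comment, "\n")
  invisible(x)
}

#' Number of atoms in a molecule
#' @param mol A [molecule()].
#' @return Integer atom count.
#' @export
natoms <- function(mol) length(mol$symbols)

#' Read a molecule from an XYZ file
#'
#' Standard XYZ layout: an atom-count line, a free-text comment line, then
#' one `symbol x y z` line per atom with coordinates in Angstrom.
#'
#' @param path Path to the XYZ file.
#' @return A [molecule()].
#' @export
read_xyz <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 1L) stop("empty XYZ file: ", path)
  n <- suppressWarnings(as.integer(trimws(lines[1L])))
  if (is.na(n) || n < 1L)
    stop("line 1: malformed atom count '", trimws(lines[1L]), "'")
  if (length(lines) < n + 2L)
    stop("header declares ", n, " atoms but only ",
         max(0L, length(lines) - 2L), " atom lines present")
  comment <- if (length(lines) >= 2L) lines[2L] else ""
  symbols <- character(n)
  coords <- matrix(NA_real_, n, 3L)
  for (i in seq_len(n)) {
    ln <- i + 2L
    parts <- strsplit(trimws(lines[ln]), "[[:space:]]+")[[1L]]
    if (length(parts) < 4L)
      stop("line ", ln, ": expected 'symbol x y z', got '", lines[ln], "'")
    symbols[i] <- parts[1L]
    xyz <- suppressWarnings(as.numeric(parts[2:4]))
    if (anyNA(xyz))
      stop("line ", ln, ": non-numeric coordinate in '", lines[ln], "'")
    coords[i, ] <- xyz
  }
  if (!all(symbols %in% supported_elements())) {
    bad <- which(!(symbols %in% supported_elements()))[1L]
    stop("line ", bad + 2L, ": unknown element symbol '", symbols[bad], "'")
  }
  molecule(symbols, coords, comment)
}

#' Write a molecule to an XYZ file
#'
#' @param mol A [molecule()].
#' @param path Output path.
#' @param digits Number of decimal places for coordinates (default 10,
#'   so that read/write round trips are lossless well below 1e-6 Angstrom).
#' @return `path`, invisibly.
#' @export
write_xyz <- function(mol, path, digits = 10L) {
  stopifnot(inherits(mol, "molecule"))
  fmt <- sprintf("%%-3s %%18.%df %%18.%df %%18.%df", digits, digits, digits)
  lines <- c(as.character(natoms(mol)),
             gsub("[\r\n]", " ", mol$comment),
             sprintf(fmt, mol$symbols,
                     mol$coords[, 1L], mol$coords[, 2L], mol$coords[, 3L]))
  writeLines(lines, path)
  invisible(path)
}

#' Perceive covalent bonds from interatomic distances
#'
#' Atoms i and j are considered bonded when their distance is below
#' `scale` times the sum of their covalent radii. The result is a
#' symmetric adjacency structure (per-atom neighbor index lists). Isolated
#' atoms are allowed.
#'
#' @param mol A [molecule()].
#' @param scale Radius-sum scale factor (default 1.15).
#' @param radii Named radius vector, defaults to [covalent_radii()].
#' @return An object of class `"adjacency"`: a list with `neighbors`
#'   (list of integer vectors, one per atom) and `bonds` (two-column
#'   matrix of bonded index pairs, i < j).
#' @export
perceive_bonds <- function(mol, scale = 1.15, radii = covalent_radii()) {
  stopifnot(inherits(mol, "molecule"), scale > 0)
  n <- natoms(mol)
  r <- radii[mol$symbols]
  if (anyNA(r))
    stop("no covalent radius for element(s): ",
         paste(unique(mol$symbols[is.na(r)]), collapse = ", "))
  nb <- vector("list", n)
  for (i in seq_len(n)) nb[[i]] <- integer(0)
  bonds <- matrix(integer(0), 0L, 2L)
  if (n >= 2L) {
    d <- as.matrix(stats::dist(mol$coords))
    cut <- scale * outer(r, r, "+")
    hit <- which(d < cut & upper.tri(d), arr.ind = TRUE)
    if (nrow(hit)) {
      bonds <- cbind(as.integer(hit[, 1L]), as.integer(hit[, 2L]))
      bonds <- bonds[order(bonds[, 1L], bonds[, 2L]), , drop = FALSE]
      for (k in seq_len(nrow(bonds))) {
        i <- bonds[k, 1L]; j <- bonds[k, 2L]
        nb[[i]] <- c(nb[[i]], j)
        nb[[j]] <- c(nb[[j]], i)
      }
      nb <- lapply(nb, sort)
    }
  }
  structure(list(neighbors = nb, bonds = bonds), class = "adjacency")
}

#' Interatomic distance matrix of a molecule
#' @param mol A [molecule()].
#' @return Symmetric matrix of pairwise distances in Angstrom.
#' @export
distance_matrix <- function(mol) as.matrix(stats::dist(mol$coords))

#' Apply a rigid-body transformation to a molecule
#'
#' Utility for invariance testing: rotates the coordinates by `rotation`
#' (3x3 orthogonal matrix) and then translates by `translation`.
#'
#' @param mol A [molecule()].
#' @param rotation 3x3 rotation matrix (default identity).
#' @param translation Length-3 shift in Angstrom (default none).
#' @return The transformed [molecule()].
#' @export
transform_molecule <- function(mol, rotation = diag(3), translation = c(0, 0, 0)) {
  stopifnot(inherits(mol, "molecule"))
  mol$coords <- mol$coords %*% t(rotation) +
    matrix(translation, natoms(mol), 3L, byrow = TRUE)
  mol
}
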