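#' Construct a molecule
#'
#' A light container for a molecular geometry: element symbols, atomic
#' masses (amu) and Cartesian coordinates in angstrom. Masses default to the
#' most-abundant-isotope masses for the given symbols but can be overridden,
#' e.g. for isotopologues.
#'
#' @param symbols character vector of element symbols
#' @param coords N x 3 numeric matrix of Cartesian coordinates (angstrom)
#' @param masses optional numeric vector of masses in amu
#' @return object of class \code{"molecule"} with fields \code{symbols},
#'   \code{masses}, \code{coords}
#' @export
molecule <- function(symbols, coords, masses = NULL) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop("coords must be an N x 3 matrix")
  n <- nrow(coords)
  if (n < 2L) stop("a molecule needs at least 2 atoms")
  if (length(symbols) != n) stop("length(symbols) must match nrow(coords)")
  if (!all(is.finite(coords))) stop("coords must be finite")
  if (is.null(masses)) masses <- atomic_mass(symbols)
  masses <- as.numeric(masses)
  if (length(masses) != n || any(!is.finite(masses)) || any(masses <= 0)) {
    stop("masses must be positive, finite, one per atom")
  }
  dimnames(coords) <- list(NULL, c("x", "y", "z"))
  structure(list(symbols = as.character(symbols),
                 masses = masses, coords = coords),
            class = "molecule")
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("molecule: %d atoms (%s)\n", length(x$symbols),
              paste(x$symbols, collapse = " ")))
  invisible(x)
}

#' Number of atoms
#' @param mol a \code{molecule}
#' @return integer atom count
#' @export
n_atoms <- function(mol) length(mol$symbols)

#' Vibrational degrees of freedom (3N-6, or 3N-5 if linear)
#'
#' @param mol a \code{molecule}
#' @param linear logical; if \code{NULL} linearity is detected geometrically
#'   (all interatomic direction cosines parallel within 1e-8)
#' @return integer count of vibrational modes
#' @export
n_vib <- function(mol, linear = NULL) {
  if (is.null(linear)) linear <- is_linear_geometry(mol$coords)
  3L * n_atoms(mol) - if (linear) 5L else 6L
}

is_linear_geometry <- function(coords, tol = 1e-8) {
  if (nrow(coords) == 2L) return(TRUE)
  v0 <- coords[2, ] - coords[1, ]
  v0 <- v0 / sqrt(sum(v0^2))
  for (a in 3:nrow(coords)) {
    v <- coords[a, ] - coords[1, ]
    v <- v / sqrt(sum(v^2))
    if (sum(crossprod3(v0, v)^2) > tol) return(FALSE)
  }
  TRUE
}

#' Read an XYZ geometry file
#'
#' Standard XYZ format: atom count, comment line, then one
#' \code{element x y z} line per atom with coordinates in angstrom.
#'
#' @param path file path
#' @return a \code{molecule} (the comment line is kept as attribute
#'   \code{"comment"})
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) | seq_along(lines) == 2L]
  n <- as.integer(trimws(lines[1]))
  if (is.na(n)) stop("malformed XYZ: first line must be the atom count")
  comment <- if (length(lines) >= 2L) lines[2] else ""
  body <- lines[3:(2 + n)]
  toks <- strsplit(trimws(body), "\\s+")
  sym <- vapply(toks, `[[`, "", 1L)
  xyz <- t(vapply(toks, function(t) as.numeric(t[2:4]), numeric(3)))
  mol <- molecule(sym, xyz)
  attr(mol, "comment") <- comment
  mol
}

#' Write an XYZ geometry file
#'
#' @param mol a \code{molecule}
#' @param path file path
#' @param comment comment line content
#' @return \code{path}, invisibly
#' @export
write_xyz <- function(mol, path, comment = "") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(n_atoms(mol)), con)
  writeLines(comment, con)
  writeLines(sprintf("%-3s %18.12f %18.12f %18.12f", mol$symbols,
                     mol$coords[, 1], mol$coords[, 2], mol$coords[, 3]), con)
  invisible(path)
}

# Cartesian geometry as a flat length-3N vector (x1 y1 z1 x2 ...)
flatten_coords <- function(coords) as.numeric(t(coords))
unflatten_coords <- function(x) matrix(x, ncol = 3L, byrow = TRUE)
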