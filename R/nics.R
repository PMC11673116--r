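# Natural internal coordinates: linear combinations of primitives, the
# Wilson B matrix, and the kinetic-energy G matrix.

#' Construct a set of natural internal coordinates
#'
#' A NIC is a linear combination of primitive internal coordinates. Rows of
#' the coefficient matrix are normalized to unit Euclidean norm on
#' construction so that displacement step sizes in "NIC units" are
#' well-defined; the raw coefficients are retained in \code{raw_coeffs}.
#'
#' For \code{linear_bend} primitives without an explicit reference vector, a
#' reference perpendicular is frozen from \code{geometry} (if supplied) so
#' the coordinate definition does not drift when the geometry is displaced.
#'
#' @param primitives list of \code{\link{prim_coord}} objects
#' @param coeffs n_NIC x n_primitive coefficient matrix (a single NIC may be
#'   given as a vector)
#' @param names optional descriptive name per NIC
#' @param irreps optional irreducible-representation label per NIC
#' @param geometry optional N x 3 Cartesian matrix used to freeze
#'   linear-bend reference vectors
#' @return object of class \code{"nic_set"}
#' @export
nic_set <- function(primitives, coeffs, names = NULL, irreps = NULL,
                    geometry = NULL) {
  if (inherits(primitives, "prim_coord")) primitives <- list(primitives)
  coeffs <- rbind(coeffs)
  dimnames(coeffs) <- NULL
  if (ncol(coeffs) != length(primitives)) {
    stop("coeffs must have one column per primitive")
  }
  nrm <- sqrt(rowSums(coeffs^2))
  if (any(nrm == 0)) stop("zero coefficient row in NIC set")
  if (!is.null(geometry)) {
    primitives <- lapply(primitives, function(p) {
      if (p$kind == "linear_bend" && is.null(p$ref)) {
        p$ref <- linear_bend_ref(p, geometry)
      }
      p
    })
  }
  structure(list(primitives = primitives,
                 coeffs = coeffs / nrm,
                 raw_coeffs = coeffs,
                 names = names %||% paste0("S", seq_len(nrow(coeffs))),
                 irreps = irreps),
            class = "nic_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.nic_set <- function(x, ...) {
  cat(sprintf("nic_set: %d coordinates over %d primitives\n",
              nrow(x$coeffs), length(x$primitives)))
  invisible(x)
}

#' Number of NICs in a set
#' @param nics a \code{nic_set}
#' @return integer
#' @export
n_nics <- function(nics) nrow(nics$coeffs)

#' Evaluate all NICs at a geometry
#'
#' @param nics a \code{\link{nic_set}}
#' @param coords N x 3 Cartesian matrix (angstrom)
#' @return numeric vector of NIC values (angstrom / rad, unit-norm rows)
#' @export
evaluate_nics <- function(nics, coords) {
  prim_vals <- vapply(nics$primitives, evaluate_primitive, numeric(1),
                      coords = coords)
  drop(nics$coeffs %*% prim_vals)
}

#' Build the Wilson B matrix
#'
#' Row i of B is the coefficient-weighted stack of primitive B rows:
#' B[i, ] = sum_p c_ip * d(primitive_p)/d(x). Rows that cancel exactly
#' (norm below \code{zero_tol} times the largest row norm) raise an error,
#' since they indicate a self-annihilating combination.
#'
#' @param nics a \code{\link{nic_set}}
#' @param coords N x 3 Cartesian matrix
#' @param zero_tol relative row-norm threshold for flagging cancelled rows
#' @return n_NIC x 3N matrix
#' @export
build_b_matrix <- function(nics, coords, zero_tol = 1e-10) {
  prim_rows <- t(vapply(nics$primitives, primitive_b_row,
                        numeric(3L * nrow(coords)), coords = coords))
  B <- nics$coeffs %*% prim_rows
  rn <- sqrt(rowSums(B^2))
  if (any(rn < zero_tol * max(rn, 1))) {
    stop("NIC combination cancels to a zero B row: ",
         paste(nics$names[rn < zero_tol * max(rn)], collapse = ", "))
  }
  B
}

#' Build the Wilson G matrix
#'
#' G = B u B^T with u the diagonal matrix of reciprocal atomic masses.
#'
#' @param B n_NIC x 3N B matrix
#' @param masses atomic masses in amu (length N)
#' @return symmetric n_NIC x n_NIC matrix (amu^-1 units)
#' @export
build_g_matrix <- function(B, masses) {
  if (ncol(B) != 3L * length(masses)) stop("B and masses are inconsistent")
  u <- rep(1 / masses, each = 3L)
  G <- B %*% (u * t(B))
  (G + t(G)) / 2
}

#' Numerical-rank report for a candidate coordinate set
#'
#' Reports the rank of B (singular values above \code{tol} times the largest)
#' and whether it matches the expected count, diagnosing redundant or
#' incomplete NIC sets.
#'
#' @param B B matrix
#' @param n_expected expected rank (vibrational degrees of freedom)
#' @param tol relative singular-value threshold
#' @return list with \code{rank}, \code{n_expected}, \code{ok},
#'   \code{singular_values}
#' @export
check_nonredundancy <- function(B, n_expected, tol = 1e-8) {
  sv <- svd(B, nu = 0, nv = 0)$d
  rank <- sum(sv > tol * max(sv))
  list(rank = rank, n_expected = as.integer(n_expected),
       ok = rank == n_expected, singular_values = sv)
}

#' Read a NIC definition file
#'
#' The format is block-structured text; \code{#} starts a comment. Each
#' coordinate is a \code{[coordinate]} block with optional \code{name =} and
#' \code{irrep =} lines followed by primitive lines
#' \preformatted{kind  i j [k l]  coefficient}
#' with 1-based atom indices. Identical primitives appearing in several
#' blocks are pooled, so the set shares one primitive list.
#'
#' @param path file path
#' @param geometry optional N x 3 matrix to freeze linear-bend references
#' @return a \code{\link{nic_set}}
#' @export
read_nic_file <- function(path, geometry = NULL) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  blocks <- list(); cur <- NULL
  flush <- function() if (!is.null(cur)) blocks[[length(blocks) + 1L]] <<- cur
  for (ln in lines) {
    if (ln == "[coordinate]") {
      flush()
      cur <- list(name = NULL, irrep = NULL, terms = list())
    } else if (grepl("^name\\s*=", ln)) {
      cur$name <- trimws(sub("^name\\s*=", "", ln))
    } else if (grepl("^irrep\\s*=", ln)) {
      cur$irrep <- trimws(sub("^irrep\\s*=", "", ln))
    } else {
      tok <- strsplit(ln, "\\s+")[[1]]
      kind <- tok[1]
      nat <- .prim_arity[[kind]]
      if (is.null(nat)) stop("unknown primitive kind in NIC file: ", kind)
      if (length(tok) != nat + 2L) {
        stop("malformed NIC line (need ", nat, " indices + coefficient): ", ln)
      }
      cur$terms[[length(cur$terms) + 1L]] <-
        list(kind = kind, atoms = as.integer(tok[2:(nat + 1L)]),
             coef = as.numeric(tok[nat + 2L]))
    }
  }
  flush()
  if (!length(blocks)) stop("no [coordinate] blocks in ", path)

  key <- function(t) paste(t$kind, paste(t$atoms, collapse = ","))
  all_terms <- unlist(lapply(blocks, `[[`, "terms"), recursive = FALSE)
  keys <- unique(vapply(all_terms, key, ""))
  prim_of <- setNames(seq_along(keys), keys)
  prims <- lapply(all_terms[!duplicated(vapply(all_terms, key, ""))],
                  function(t) prim_coord(t$kind, t$atoms))
  coeffs <- matrix(0, length(blocks), length(prims))
  for (b in seq_along(blocks)) {
    for (t in blocks[[b]]$terms) {
      coeffs[b, prim_of[[key(t)]]] <- coeffs[b, prim_of[[key(t)]]] + t$coef
    }
  }
  nms <- vapply(blocks, function(b) b$name %||% "", "")
  nms[!nzchar(nms)] <- paste0("S", which(!nzchar(nms)))
  irr <- vapply(blocks, function(b) b$irrep %||% NA_character_, "")
  if (all(is.na(irr))) irr <- NULL
  nic_set(prims, coeffs, names = nms, irreps = irr, geometry = geometry)
}

#' Write a NIC definition file
#'
#' Emits the raw (un-normalized) coefficients; \code{\link{read_nic_file}}
#' re-normalizes on load.
#'
#' @param nics a \code{\link{nic_set}}
#' @param path file path
#' @return \code{path}, invisibly
#' @export
write_nic_file <- function(nics, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(n_nics(nics))) {
    writeLines("[coordinate]", con)
    writeLines(paste("name =", nics$names[i]), con)
    if (!is.null(nics$irreps) && !is.na(nics$irreps[i])) {
      writeLines(paste("irrep =", nics$irreps[i]), con)
    }
    nz <- which(nics$raw_coeffs[i, ] != 0)
    for (p in nz) {
      pc <- nics$primitives[[p]]
      writeLines(sprintf("%s  %s  %.12g", pc$kind,
                         paste(pc$atoms, collapse = " "),
                         nics$raw_coeffs[i, p]), con)
    }
    writeLines("", con)
  }
  invisible(path)
}
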