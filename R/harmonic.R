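# Wilson GF eigenproblem, Hessian basis transformations, and frequency
# conversion.

#' Construct a force-constant matrix with basis/level metadata
#'
#' @param matrix symmetric force-constant matrix. Units in the internal
#'   basis: aJ A^-2 (stretch-stretch), aJ rad^-2 (bend-bend) and
#'   aJ A^-1 rad^-1 (mixed); in the Cartesian basis aJ A^-2, mass-unweighted.
#' @param basis one of \code{"cartesian"}, \code{"internal"}, \code{"qb"}
#'   (Level-B normal-mode basis)
#' @param level optional level tag (\code{"A"}, \code{"B"}, \code{"C"}, ...)
#' @param geometry_id optional identifier of the reference geometry
#' @return object of class \code{"force_field"}
#' @export
force_field <- function(matrix, basis = c("internal", "cartesian", "qb"),
                        level = NA_character_, geometry_id = NA_character_) {
  basis <- match.arg(basis)
  m <- as.matrix(matrix)
  if (nrow(m) != ncol(m)) stop("force-constant matrix must be square")
  present <- is.finite(m)
  rel <- max(abs(m[present]), 1e-300)
  asym <- abs(m - t(m))
  if (any(asym[present & t(present)] > 1e-12 * rel)) {
    stop("force-constant matrix is not symmetric")
  }
  structure(list(matrix = m, basis = basis, level = level,
                 geometry_id = geometry_id),
            class = "force_field")
}

#' @export
print.force_field <- function(x, ...) {
  cat(sprintf("force_field: %dx%d, basis=%s, level=%s\n",
              nrow(x$matrix), ncol(x$matrix), x$basis, x$level))
  invisible(x)
}

as_ff_matrix <- function(F) if (inherits(F, "force_field")) F$matrix else F

#' Normal modes container
#'
#' Columns of \code{L} are the mode eigenvectors in internal-coordinate
#' amplitudes per unit normal coordinate (S = L Q); \code{lambda} the GF
#' eigenvalues and \code{freq} harmonic wavenumbers in cm^-1 (negative
#' values encode imaginary frequencies).
#'
#' @param L eigenvector matrix
#' @param lambda eigenvalues (aJ A^-2 amu^-1 equivalent)
#' @param freq frequencies, cm^-1
#' @param irreps optional per-mode irrep labels
#' @return object of class \code{"normal_modes"}
#' @export
normal_modes <- function(L, lambda, freq, irreps = NULL) {
  structure(list(L = L, lambda = lambda, freq = freq, irreps = irreps),
            class = "normal_modes")
}

#' @export
print.normal_modes <- function(x, ...) {
  cat("normal_modes:", length(x$freq), "modes\n")
  tab <- data.frame(freq_cm1 = round(x$freq, 2))
  if (!is.null(x$irreps)) tab$irrep <- x$irreps
  print(utils::head(tab, 12))
  if (length(x$freq) > 12) cat("...\n")
  invisible(x)
}

# canonical eigenvector sign: largest-magnitude component positive, ties
# broken by the first nonzero component
fix_eigvec_signs <- function(L) {
  for (j in seq_len(ncol(L))) {
    nz <- which(abs(L[, j]) > 1e-12)
    if (!length(nz)) next
    lead <- nz[which.max(abs(L[nz, j]))]
    if (L[lead, j] < 0) L[, j] <- -L[, j]
  }
  L
}

#' Solve the Wilson GF eigenproblem
#'
#' Computes nonorthogonal eigenvectors L and eigenvalues lambda with
#' GF L = L diag(lambda), using the symmetric square root W of G: L = W C
#' where C are the orthonormal eigenvectors of W F W. This normalization
#' gives L^T F L = diag(lambda) and L^-1 G L^-T = I. Frequencies are
#' omega_i = kappa sqrt(lambda_i) cm^-1 with kappa from
#' \code{\link{freq_conversion_factor}}; negative lambda is reported as a
#' negative (imaginary) frequency.
#'
#' Modes are ordered by descending frequency; when per-coordinate irrep
#' labels are available the ordering is within irrep blocks (grouped in
#' first-appearance order of the labels).
#'
#' @param F internal-basis \code{\link{force_field}} (or plain symmetric
#'   matrix)
#' @param G Wilson G matrix (symmetric positive definite)
#' @param irreps optional per-coordinate irrep labels, used to label and
#'   block-order the modes
#' @return a \code{\link{normal_modes}}
#' @export
solve_gf <- function(F, G, irreps = NULL) {
  Fm <- as_ff_matrix(F)
  if (inherits(F, "force_field") && F$basis == "cartesian") {
    stop("solve_gf expects an internal-basis force field")
  }
  if (max(abs(Fm - t(Fm))) > 1e-10 * max(abs(Fm), 1)) {
    stop("asymmetric force-constant matrix")
  }
  eg <- eigen((G + t(G)) / 2, symmetric = TRUE)
  if (min(eg$values) <= 1e-12 * max(eg$values)) {
    stop("G matrix is not positive definite (redundant coordinate set?)")
  }
  W <- eg$vectors %*% (sqrt(eg$values) * t(eg$vectors))  # G^(1/2)
  M <- W %*% Fm %*% W
  em <- eigen((M + t(M)) / 2, symmetric = TRUE)
  lambda <- em$values
  L <- fix_eigvec_signs(W %*% em$vectors)
  freq <- freq_conversion_factor() * sign(lambda) * sqrt(abs(lambda))
  ord <- order(-freq)
  mode_irr <- NULL
  if (!is.null(irreps)) {
    mode_irr <- vapply(seq_along(lambda), function(j) {
      irreps[which.max(abs(L[, j]))]
    }, "")
    blk <- match(mode_irr, unique(irreps))
    ord <- order(blk, -freq)
  }
  normal_modes(L[, ord, drop = FALSE], lambda[ord], freq[ord],
               irreps = mode_irr[ord])
}

#' Harmonic frequencies from a mass-weighted Cartesian Hessian
#'
#' The textbook route used as the independent reference for the GF method:
#' eigenvalues of M^-1/2 F_x M^-1/2 converted to cm^-1, with the 6 (5 for
#' linear molecules) near-zero rigid-body roots removed.
#'
#' @param F_x Cartesian \code{\link{force_field}} or 3N x 3N matrix (aJ A^-2)
#' @param mol a \code{\link{molecule}}
#' @param n_drop number of rigid-body modes to drop (default from geometry)
#' @return vibrational frequencies in cm^-1, descending
#' @export
cartesian_frequencies <- function(F_x, mol, n_drop = NULL) {
  Fm <- as_ff_matrix(F_x)
  if (is.null(n_drop)) n_drop <- 3L * n_atoms(mol) - n_vib(mol)
  invsq <- rep(1 / sqrt(mol$masses), each = 3L)
  H <- (invsq * Fm) * rep(invsq, each = length(invsq))
  ev <- eigen((H + t(H)) / 2, symmetric = TRUE, only.values = TRUE)$values
  ev <- ev[order(abs(ev))][-seq_len(n_drop)]  # drop the 6/5 smallest |roots|
  freq <- freq_conversion_factor() * sign(ev) * sqrt(abs(ev))
  sort(freq, decreasing = TRUE)
}

#' Transform a Cartesian Hessian to the internal-coordinate basis
#'
#' F_S = A F_x A^T with A = G^-1 B u the generalized inverse transform.
#' Valid at stationary points, where the gradient term of the curvilinear
#' transformation vanishes; if a Cartesian gradient is supplied and its norm
#' exceeds \code{grad_tol} (aJ/A) a warning is issued.
#'
#' @param F_x Cartesian \code{\link{force_field}} or matrix (aJ A^-2)
#' @param B Wilson B matrix
#' @param G Wilson G matrix
#' @param masses atomic masses (amu)
#' @param gradient optional Cartesian gradient for a stationarity check
#' @param grad_tol stationarity warning threshold
#' @return internal-basis \code{\link{force_field}}
#' @export
cartesian_hessian_to_internal <- function(F_x, B, G, masses, gradient = NULL,
                                          grad_tol = 1e-6) {
  Fm <- as_ff_matrix(F_x)
  if (!is.null(gradient) && sqrt(sum(gradient^2)) > grad_tol) {
    warning("geometry does not look stationary (|gradient| = ",
            format(sqrt(sum(gradient^2)), digits = 3),
            " aJ/A); the gradient term is neglected")
  }
  u <- rep(1 / masses, each = 3L)
  A <- solve(G, B) * rep(u, each = nrow(B))   # G^-1 B u
  FS <- A %*% Fm %*% t(A)
  lv <- if (inherits(F_x, "force_field")) F_x$level else NA_character_
  force_field((FS + t(FS)) / 2, basis = "internal", level = lv)
}

#' Project an internal-basis Hessian back to Cartesians
#'
#' F_x = B^T F_S B (stationary-point congruence), the inverse of
#' \code{\link{cartesian_hessian_to_internal}} on the row space of B.
#'
#' @param F_S internal \code{\link{force_field}} or matrix
#' @param B Wilson B matrix
#' @return Cartesian \code{\link{force_field}}
#' @export
internal_hessian_to_cartesian <- function(F_S, B) {
  Fm <- as_ff_matrix(F_S)
  Fx <- crossprod(B, Fm %*% B)
  lv <- if (inherits(F_S, "force_field")) F_S$level else NA_character_
  force_field((Fx + t(Fx)) / 2, basis = "cartesian", level = lv)
}

#' Transform an internal-basis Hessian into the Level-B normal-mode basis
#'
#' F_Q = L_B^T F_S L_B (congruence under S = L_B Q_B). Applied to the
#' Level-B field itself this returns diag(lambda_B) exactly.
#'
#' @param F_S internal \code{\link{force_field}} or matrix
#' @param modes Level-B \code{\link{normal_modes}}
#' @return \code{\link{force_field}} with basis \code{"qb"}
#' @export
internal_to_qb <- function(F_S, modes) {
  Fm <- as_ff_matrix(F_S)
  if (nrow(Fm) != nrow(modes$L)) stop("dimension mismatch")
  FQ <- crossprod(modes$L, Fm %*% modes$L)
  lv <- if (inherits(F_S, "force_field")) F_S$level else NA_character_
  force_field((FQ + t(FQ)) / 2, basis = "qb", level = lv)
}

#' Transform a normal-mode-basis Hessian back to internals
#'
#' The CMA ansatz F_S = (L_B^-1)^T F_Q L_B^-1, the exact inverse of
#' \code{\link{internal_to_qb}}.
#'
#' @param F_Q \code{\link{force_field}} in the qb basis, or matrix
#' @param modes Level-B \code{\link{normal_modes}}
#' @return internal-basis \code{\link{force_field}}
#' @export
qb_to_internal <- function(F_Q, modes) {
  Fm <- as_ff_matrix(F_Q)
  if (nrow(Fm) != ncol(modes$L)) stop("dimension mismatch")
  kap <- kappa(modes$L, exact = FALSE)
  if (kap > 1e10) {
    warning("ill-conditioned L (condition number ", format(kap, digits = 3),
            ")")
  }
  Linv <- solve(modes$L)
  FS <- crossprod(Linv, Fm %*% Linv)
  lv <- if (inherits(F_Q, "force_field")) F_Q$level else NA_character_
  force_field((FS + t(FS)) / 2, basis = "internal", level = lv)
}

#' Harmonic zero-point vibrational energy
#'
#' ZPVE = (1/2) sum(omega) over the real frequencies; imaginary (negative)
#' entries are excluded with a warning.
#'
#' @param freq frequencies in cm^-1
#' @return ZPVE in cm^-1
#' @export
zpve <- function(freq) {
  if (any(freq < 0)) {
    warning(sum(freq < 0), " imaginary frequencies excluded from ZPVE")
    freq <- freq[freq >= 0]
  }
  if (!length(freq)) return(0)
  sum(freq) / 2
}

#' Read a plain-text Hessian file
#'
#' The header line declares basis, units and dimension, e.g.
#' \code{# basis=internal units=aJ,angstrom,rad dim=27 level=A}; the body is
#' the full symmetric matrix, whitespace-separated.
#'
#' @param path file path
#' @return a \code{\link{force_field}}
#' @export
read_hessian <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1]
  if (!startsWith(hdr, "#")) stop("Hessian file must start with a '#' header")
  get_field <- function(key) {
    m <- regmatches(hdr, regexpr(paste0(key, "=[^ ]+"), hdr))
    if (!length(m)) return(NA_character_)
    sub(paste0(key, "="), "", m)
  }
  dim <- as.integer(get_field("dim"))
  vals <- scan(text = paste(lines[-1], collapse = "\n"), quiet = TRUE)
  if (length(vals) != dim * dim) stop("Hessian body does not match dim=", dim)
  force_field(matrix(vals, dim, dim, byrow = TRUE),
              basis = get_field("basis"), level = get_field("level"))
}

#' Write a plain-text Hessian file
#'
#' @param F a \code{\link{force_field}}
#' @param path file path
#' @return \code{path}, invisibly
#' @export
write_hessian <- function(F, path) {
  stopifnot(inherits(F, "force_field"))
  units <- if (F$basis == "cartesian") "aJ,angstrom" else "aJ,angstrom,rad"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# basis=%s units=%s dim=%d level=%s",
                     F$basis, units, nrow(F$matrix), F$level), con)
  apply(F$matrix, 1L, function(r) {
    writeLines(paste(sprintf("%.15g", r), collapse = " "), con)
  })
  invisible(path)
}
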