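# The Concordant Mode Approach: xi diagnostic, off-diagonal selection,
# CMA field assembly, frequencies, residuals and the eta cost metric.

#' Dimensionless xi diagnostic from a Level-C force field
#'
#' The Level-C field expressed in the Level-B normal-mode basis is cast into
#' a dimensionless, symmetric, nonnegative matrix whose large entries flag
#' the mode couplings most sensitive to an increase in the level of theory.
#' Two normalizations are available:
#' \describe{
#'   \item{\code{"diag"} (default)}{xi_ij = |F^C_ij| / sqrt(|F^C_ii F^C_jj|),
#'     the off-diagonal magnitude relative to the geometric mean of the
#'     associated diagonal force constants.}
#'   \item{\code{"lambdaB"}}{xi_ij = |F^C_ij| / sqrt(lambda_Bi lambda_Bj),
#'     normalizing by the Level-B eigenvalues instead (requires
#'     \code{lambda_B}).}
#' }
#' The normalization used is recorded in the result's provenance.
#'
#' @param F_C_qb Level-C \code{\link{force_field}} in the qb basis (or matrix)
#' @param normalization \code{"diag"} or \code{"lambdaB"}
#' @param lambda_B Level-B eigenvalues, needed for \code{"lambdaB"}
#' @return object of class \code{"xi_matrix"}: the matrix plus a
#'   \code{provenance} attribute
#' @export
xi_matrix <- function(F_C_qb, normalization = c("diag", "lambdaB"),
                      lambda_B = NULL) {
  normalization <- match.arg(normalization)
  Fm <- as_ff_matrix(F_C_qb)
  d <- switch(normalization,
    diag = abs(diag(Fm)),
    lambdaB = {
      if (is.null(lambda_B)) stop("lambdaB normalization needs lambda_B")
      abs(lambda_B)
    })
  if (any(d == 0)) stop("zero diagonal element: xi normalization undefined")
  xi <- abs(Fm) / sqrt(tcrossprod(d))
  diag(xi) <- 0
  lv <- if (inherits(F_C_qb, "force_field")) F_C_qb$level else NA_character_
  structure(xi, class = c("xi_matrix", "matrix"),
            provenance = list(level = lv, normalization = normalization))
}

#' @export
print.xi_matrix <- function(x, ...) {
  pr <- attr(x, "provenance")
  cat(sprintf("xi_matrix %dx%d (normalization=%s, level=%s), max xi = %.4g\n",
              nrow(x), ncol(x), pr$normalization, pr$level, max(x)))
  invisible(x)
}

#' Select off-diagonal elements above a xi cutoff
#'
#' Returns the index pairs (i < j) with xi_ij strictly greater than the
#' cutoff. \code{cutoff = Inf} yields the empty set (CMA-0). Selections are
#' nested: a larger cutoff always selects a subset of a smaller one.
#'
#' @param xi a \code{\link{xi_matrix}} (or symmetric nonnegative matrix)
#' @param cutoff positive threshold (may be \code{Inf})
#' @return integer matrix with columns \code{i}, \code{j}; zero rows if none
#' @export
select_offdiagonals <- function(xi, cutoff) {
  if (!is.finite(cutoff) && cutoff > 0) {
    return(matrix(integer(), 0L, 2L, dimnames = list(NULL, c("i", "j"))))
  }
  if (cutoff <= 0) stop("cutoff must be positive (use 'Inf' for CMA-0)")
  idx <- which(upper.tri(xi) & xi > cutoff, arr.ind = TRUE)
  sel <- cbind(i = as.integer(idx[, 1]), j = as.integer(idx[, 2]))
  sel[order(sel[, 1], sel[, 2]), , drop = FALSE]
}

#' The eta cost metric
#'
#' eta = 100 * (number of included off-diagonal elements) / (vibrational
#' degrees of freedom): very nearly the percentage increase in cost of a
#' CMA-2 run over diagonal-only CMA-0.
#'
#' @param selection index-pair matrix (or anything with \code{nrow}), or a
#'   plain count
#' @param dof vibrational degrees of freedom
#' @return eta in percent (full precision; round for display)
#' @export
eta <- function(selection, dof) {
  if (dof <= 0) stop("dof must be positive")
  n <- if (is.matrix(selection)) nrow(selection) else as.numeric(selection)
  100 * n / dof
}

#' Assemble a (possibly sparse) CMA force-constant matrix
#'
#' Builds F_CMA from a complete diagonal plus the supplied off-diagonal
#' values; all unselected off-diagonals are exactly zero.
#'
#' @param diagonal numeric vector of diagonal force constants (complete)
#' @param pairs index-pair matrix (i, j), i != j, or \code{NULL}
#' @param values numeric vector of off-diagonal values matching \code{pairs}
#' @param level level tag for the result
#' @return \code{\link{force_field}} in the qb basis
#' @export
assemble_cma_field <- function(diagonal, pairs = NULL, values = NULL,
                               level = "A") {
  if (anyNA(diagonal)) stop("diagonal force constants must be complete")
  n <- length(diagonal)
  F <- diag(diagonal, n)
  if (!is.null(pairs) && nrow(rbind(pairs))) {
    pairs <- canonical_pairs(pairs, n)
    if (length(values) != nrow(pairs)) {
      stop("one value per selected pair required")
    }
    for (r in seq_len(nrow(pairs))) {
      F[pairs[r, 1], pairs[r, 2]] <- F[pairs[r, 2], pairs[r, 1]] <- values[r]
    }
  }
  force_field(F, basis = "qb", level = level)
}

#' Frequencies from a CMA force field
#'
#' Transforms F_CMA back to the internal basis through the Level-B modes and
#' solves the GF eigenproblem there.
#'
#' @param F_CMA qb-basis \code{\link{force_field}}
#' @param modes_B Level-B \code{\link{normal_modes}}
#' @param G Wilson G matrix
#' @param irreps optional per-coordinate irrep labels
#' @return \code{\link{normal_modes}} at the CMA-composed level
#' @export
cma_frequencies <- function(F_CMA, modes_B, G, irreps = NULL) {
  F_A <- qb_to_internal(F_CMA, modes_B)
  solve_gf(F_A, G, irreps = irreps)
}

#' Match two sets of normal modes and compute residuals
#'
#' Pairs reference and CMA modes by maximal absolute overlap of their
#' eigenvectors in a common metric (greedy assignment on |L_ref^-1 L_cma|,
#' restricted to within-irrep blocks when both sets carry labels), falling
#' back to frequency ordering on ambiguous overlaps. Residuals follow the
#' convention epsilon = omega_cma - omega_ref.
#'
#' @param modes_ref reference \code{\link{normal_modes}}
#' @param modes_cma CMA \code{\link{normal_modes}}
#' @return list with \code{permutation} (index into cma modes per reference
#'   mode) and \code{residuals} (cm^-1)
#' @export
match_modes <- function(modes_ref, modes_cma) {
  n <- length(modes_ref$freq)
  if (length(modes_cma$freq) != n) stop("mode sets differ in dimension")
  ov <- abs(solve(modes_ref$L, modes_cma$L))
  if (!is.null(modes_ref$irreps) && !is.null(modes_cma$irreps)) {
    ov[outer(modes_ref$irreps, modes_cma$irreps, `!=`)] <- -1
  }
  perm <- integer(n)
  taken <- rep(FALSE, n)
  # greedy: repeatedly take the largest remaining overlap
  o <- ov
  for (step in seq_len(n)) {
    k <- arrayInd(which.max(o), dim(o))
    r <- k[1]; c <- k[2]
    second <- suppressWarnings(max(o[r, -c]))
    if (is.finite(second) && abs(o[r, c] - second) < 1e-6) {
      warning("ambiguous mode overlap for reference mode ", r,
              "; falling back to frequency order within the tie")
    }
    perm[r] <- c
    o[r, ] <- -Inf
    o[, c] <- -Inf
  }
  list(permutation = perm,
       residuals = modes_cma$freq[perm] - modes_ref$freq)
}

#' Run a CMA protocol on a pair (or triple) of force fields
#'
#' End-to-end driver for CMA-0 / CMA-1 / CMA-2 given internal-basis force
#' fields. Level B defines the normal-mode basis; Level A is the target whose
#' frequencies are reproduced; for CMA-2, Level C feeds the xi diagnostic.
#' Reference frequencies are the direct GF frequencies of Level A.
#'
#' @param F_A,F_B internal-basis \code{\link{force_field}}s (or matrices)
#' @param G Wilson G matrix
#' @param protocol \code{"cma0"}, \code{"cma1"} or \code{"cma2"}
#' @param F_C Level-C internal field (required for \code{"cma2"})
#' @param pairs hand-picked off-diagonal index pairs (for \code{"cma1"})
#' @param cutoff xi cutoff (for \code{"cma2"}; \code{Inf} reduces to CMA-0)
#' @param xi_normalization passed to \code{\link{xi_matrix}}
#' @param irreps optional per-coordinate irrep labels; when supplied,
#'   symmetry is enforced on all qb-basis fields before selection
#' @param dof vibrational degrees of freedom for eta (defaults to the matrix
#'   dimension)
#' @return object of class \code{"cma_result"}: selection, xi matrix, CMA
#'   frequencies, reference frequencies, residuals, eta, ZPVE residual
#' @export
cma_run <- function(F_A, F_B, G, protocol = c("cma0", "cma1", "cma2"),
                    F_C = NULL, pairs = NULL, cutoff = Inf,
                    xi_normalization = "diag", irreps = NULL, dof = NULL) {
  protocol <- match.arg(protocol)
  FA <- as_ff_matrix(F_A); FB <- as_ff_matrix(F_B)
  n <- nrow(FA)
  if (is.null(dof)) dof <- n
  modes_B <- solve_gf(FB, G, irreps = irreps)
  modes_ref <- solve_gf(FA, G, irreps = irreps)
  F_CMA_full <- internal_to_qb(FA, modes_B)
  qb_irreps <- if (is.null(irreps)) NULL else modes_B$irreps
  if (!is.null(qb_irreps)) {
    F_CMA_full <- enforce_symmetry(F_CMA_full, qb_irreps)
  }
  xi <- NULL
  sel <- switch(protocol,
    cma0 = matrix(integer(), 0L, 2L),
    cma1 = canonical_pairs(pairs, n),
    cma2 = {
      if (is.null(F_C)) stop("cma2 requires a Level C force field")
      FCq <- internal_to_qb(as_ff_matrix(F_C), modes_B)
      if (!is.null(qb_irreps)) FCq <- enforce_symmetry(FCq, qb_irreps)
      xi <- xi_matrix(force_field(FCq$matrix, "qb", level = "C"),
                      normalization = xi_normalization,
                      lambda_B = modes_B$lambda)
      select_offdiagonals(xi, cutoff)
    })
  Fm <- F_CMA_full$matrix
  vals <- if (nrow(sel)) Fm[cbind(sel[, 1], sel[, 2])] else NULL
  F_CMA <- assemble_cma_field(diag(Fm), sel, vals, level = "A")
  modes_cma <- cma_frequencies(F_CMA, modes_B, G, irreps = irreps)
  mm <- match_modes(modes_ref, modes_cma)
  structure(list(protocol = protocol,
                 selection = sel,
                 xi = xi,
                 F_CMA = F_CMA,
                 freq_ref = modes_ref$freq,
                 freq_cma = modes_cma$freq[mm$permutation],
                 residuals = mm$residuals,
                 permutation = mm$permutation,
                 eta = eta(sel, dof),
                 zpve_residual = zpve(modes_cma$freq[mm$permutation]) -
                   zpve(modes_ref$freq),
                 irreps = modes_ref$irreps,
                 cutoff = if (protocol == "cma2") cutoff else NA_real_),
            class = "cma_result")
}

#' @export
print.cma_result <- function(x, ...) {
  cat(sprintf("CMA result (%s): %d modes, %d off-diagonals (eta = %.1f%%)\n",
              x$protocol, length(x$freq_ref), nrow(x$selection), x$eta))
  cat(sprintf("  max |residual| = %.4g cm^-1, MAE = %.4g cm^-1, ZPVE residual = %.4g cm^-1\n",
              max(abs(x$residuals)), mean(abs(x$residuals)),
              x$zpve_residual))
  invisible(x)
}
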