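# Total energy distributions and benchmark residual statistics.

#' Total energy distribution (TED) of normal modes
#'
#' Decomposes the classical vibrational energy of each mode k over the
#' internal coordinates: TED_ik = 100 * L_ik (F_S L)_ik / lambda_k. Signs are
#' retained (they encode the relative phases of the eigenvector components)
#' and each mode's signed percentages sum to 100. Modes with lambda below
#' \code{zero_tol} are skipped with a warning.
#'
#' @param modes a \code{\link{normal_modes}}
#' @param F_S the internal-basis \code{\link{force_field}} that generated them
#' @param zero_tol eigenvalues below this (relative to the largest) are
#'   treated as zero
#' @return matrix (n_coordinate x n_mode) of signed percentages; class
#'   \code{"ted_table"}
#' @export
ted <- function(modes, F_S, zero_tol = 1e-10) {
  Fm <- as_ff_matrix(F_S)
  FL <- Fm %*% modes$L
  out <- matrix(NA_real_, nrow(modes$L), ncol(modes$L))
  small <- abs(modes$lambda) < zero_tol * max(abs(modes$lambda))
  if (any(small)) {
    warning(sum(small), " zero-eigenvalue mode(s) skipped in TED")
  }
  for (k in which(!small)) {
    out[, k] <- 100 * modes$L[, k] * FL[, k] / modes$lambda[k]
  }
  rownames(out) <- paste0("S", seq_len(nrow(out)))
  colnames(out) <- paste0("mode", seq_len(ncol(out)))
  structure(out, class = c("ted_table", "matrix"))
}

#' Format the leading TED contributions of one mode
#'
#' Mirrors the usual report style: contributions of magnitude at least
#' \code{threshold} percent, largest first, signed.
#'
#' @param ted_tab a \code{\link{ted}} table
#' @param mode mode index (column)
#' @param threshold display threshold in percent
#' @return character string such as \code{"S1(65) - S12(32)"}
#' @export
format_ted <- function(ted_tab, mode, threshold = 5) {
  v <- ted_tab[, mode]
  keep <- which(abs(v) >= threshold)
  keep <- keep[order(-abs(v[keep]))]
  if (!length(keep)) return("")
  parts <- sprintf("%s(%d)", rownames(ted_tab)[keep], round(abs(v[keep])))
  signs <- ifelse(v[keep] < 0, " - ", " + ")
  signs[1] <- if (v[keep[1]] < 0) "-" else ""
  paste0(signs, parts, collapse = "")
}

#' Benchmark residual summary statistics
#'
#' Computes, over frequency residuals grouped by molecule: the mean absolute
#' error (MAE), signed mean, sample standard deviation (n-1 denominator),
#' the average per-molecule maximum absolute residual (eps_max), and the
#' global maximum absolute residual (eps_MAX); plus MAE / mean / sd of the
#' ZPVE residuals when supplied.
#'
#' @param residuals list of numeric vectors, one per molecule (a single
#'   vector is treated as one molecule)
#' @param zpve_residuals optional numeric vector, one per molecule
#' @return list of class \code{"cma_stats"}
#' @export
summary_stats <- function(residuals, zpve_residuals = NULL) {
  if (!is.list(residuals)) residuals <- list(residuals)
  all <- unlist(residuals)
  if (!length(all)) stop("no residuals supplied")
  out <- list(
    mae = mean(abs(all)),
    mean = mean(all),
    sd = if (length(all) > 1) stats::sd(all) else 0,
    eps_max = mean(vapply(residuals, function(r) max(abs(r)), 0)),
    eps_MAX = max(abs(all)),
    n = length(all))
  if (!is.null(zpve_residuals)) {
    out$mae_zpve <- mean(abs(zpve_residuals))
    out$mean_zpve <- mean(zpve_residuals)
    out$sd_zpve <- if (length(zpve_residuals) > 1) {
      stats::sd(zpve_residuals)
    } else {
      0
    }
  }
  structure(out, class = "cma_stats")
}

#' @export
print.cma_stats <- function(x, ...) {
  cat(sprintf("residual stats (n=%d): MAE %.4g, mean %.4g, sd %.4g, eps_max %.4g, eps_MAX %.4g cm^-1\n",
              x$n, x$mae, x$mean, x$sd, x$eps_max, x$eps_MAX))
  invisible(x)
}

#' CMA-2 convergence curve over a xi-cutoff sweep
#'
#' For each cutoff, runs CMA-2 on each molecule of the ensemble and
#' aggregates residual statistics, eta, and the fraction of nonzero
#' off-diagonals included. Input is a list of systems, each a list with
#' \code{F_A}, \code{F_B}, \code{F_C} (internal basis) and \code{G}
#' (optionally \code{irreps}, \code{dof}).
#'
#' @param systems list of systems as described above
#' @param cutoffs numeric vector of xi cutoffs (may include \code{Inf})
#' @param xi_normalization passed to \code{\link{xi_matrix}}
#' @return data.frame with one row per cutoff: \code{cutoff}, \code{eta}
#'   (mean over molecules), \code{pct_offdiag} (percent of all off-diagonal
#'   elements included), \code{mae}, \code{eps_max}, \code{eps_MAX}
#' @export
convergence_curve <- function(systems, cutoffs, xi_normalization = "diag") {
  rows <- lapply(cutoffs, function(ct) {
    runs <- lapply(systems, function(sys) {
      cma_run(sys$F_A, sys$F_B, sys$G, "cma2", F_C = sys$F_C,
              cutoff = ct, xi_normalization = xi_normalization,
              irreps = sys$irreps, dof = sys$dof)
    })
    st <- summary_stats(lapply(runs, `[[`, "residuals"))
    n_off <- vapply(runs, function(r) nrow(r$selection), 0)
    n_tot <- vapply(runs, function(r) {
      d <- length(r$freq_ref); d * (d - 1) / 2
    }, 0)
    data.frame(cutoff = ct,
               eta = mean(vapply(runs, `[[`, 0, "eta")),
               pct_offdiag = 100 * sum(n_off) / sum(n_tot),
               mae = st$mae, eps_max = st$eps_max, eps_MAX = st$eps_MAX)
  })
  do.call(rbind, rows)
}
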