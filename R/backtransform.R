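# Iterative back-transformation of internal / normal-mode displacements to
# Cartesian geometries.

# wrap angular residuals into (-pi, pi] so torsions near the branch cut do
# not derail the iteration
wrap_residual <- function(resid, angularish) {
  r <- resid
  r[angularish] <- ((r[angularish] + pi) %% (2 * pi)) - pi
  r
}

nic_has_torsion <- function(nics) {
  vapply(seq_len(n_nics(nics)), function(i) {
    nz <- which(nics$coeffs[i, ] != 0)
    any(vapply(nics$primitives[nz], function(p) p$kind == "torsion", TRUE))
  }, TRUE)
}

#' Map an internal-coordinate displacement to Cartesian coordinates
#'
#' Solves S(x) = S(x0) + dS by iterating the linearized relation
#' dx = u B^T G^-1 (S_target - S(x)), refreshing B and G at every step so
#' curvilinear coordinates are followed exactly. With \code{modes} supplied,
#' \code{dQ} is a displacement along the (nonorthogonal) normal modes and the
#' internal target is L dQ; otherwise \code{dQ} is taken directly as dS in
#' NIC units.
#'
#' @param mol a \code{\link{molecule}}
#' @param dQ displacement vector (normal-mode units if \code{modes} given,
#'   otherwise NIC units)
#' @param nics a complete nonredundant \code{\link{nic_set}}
#' @param modes optional \code{\link{normal_modes}} whose L converts dQ to dS
#' @param tol convergence threshold on max |S - S_target|
#' @param max_iter iteration cap
#' @return N x 3 displaced Cartesian matrix
#' @export
back_transform <- function(mol, dQ, nics, modes = NULL, tol = 1e-12,
                           max_iter = 50L) {
  dS <- if (is.null(modes)) dQ else drop(modes$L %*% dQ)
  if (length(dS) != n_nics(nics)) stop("displacement has wrong length")
  x <- mol$coords
  target <- evaluate_nics(nics, x) + dS
  angular <- nic_has_torsion(nics)
  u <- rep(1 / mol$masses, each = 3L)
  for (it in seq_len(max_iter)) {
    resid <- wrap_residual(target - evaluate_nics(nics, x), angular)
    if (max(abs(resid)) < tol) return(x)
    B <- build_b_matrix(nics, x)
    G <- build_g_matrix(B, mol$masses)
    dx <- u * drop(crossprod(B, solve(G, resid)))
    x <- x + unflatten_coords(dx)
  }
  resid <- max(abs(wrap_residual(target - evaluate_nics(nics, x), angular)))
  stop(sprintf(
    "back-transformation did not converge in %d iterations (residual %.3e)",
    max_iter, resid))
}
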