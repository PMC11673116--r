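# Synthetic molecules, NIC sets, analytic quadratic potentials, and
# correlated Level A/B/C force-field triples. Everything here is seeded and
# bit-reproducible; no global RNG state leaks out.

with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# typical diagonal force constants by primitive kind (aJ A^-2 / aJ rad^-2)
.diag_ranges <- list(bond = c(3, 9), angle = c(0.4, 1.2),
                     torsion = c(0.05, 0.4), out_of_plane = c(0.2, 0.7),
                     linear_bend = c(0.3, 0.9))

dominant_kind <- function(nics, i) {
  nz <- which(abs(nics$coeffs[i, ]) > 0)
  kinds <- vapply(nics$primitives[nz], `[[`, "", "kind")
  kinds[which.max(abs(nics$coeffs[i, nz]))]
}

# random SPD force field in NIC space with chemically plausible diagonals
# and sparse couplings in the xi operating range (~0.005-0.2 relative)
random_nic_field <- function(nics, sparsity = 0.4) {
  n <- n_nics(nics)
  d <- vapply(seq_len(n), function(i) {
    rg <- .diag_ranges[[dominant_kind(nics, i)]]
    stats::runif(1, rg[1], rg[2])
  }, 0)
  F <- diag(d, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (stats::runif(1) < sparsity) {
      m <- exp(stats::runif(1, log(0.005), log(0.2)))
      F[i, j] <- F[j, i] <- sample(c(-1, 1), 1) * m * sqrt(d[i] * d[j])
    }
  }
  # guarantee positive definiteness by damping couplings if needed
  for (k in 1:30) {
    if (min(eigen(F, symmetric = TRUE, only.values = TRUE)$values) > 1e-6) {
      break
    }
    F <- diag(d, n) + 0.5 * (F - diag(d, n))
  }
  F
}

ring_stretch_combos <- function(n6) {
  # hexagon symmetry combinations over 6 sequential quantities
  rbind(c(1, 1, 1, 1, 1, 1),
        c(1, -1, 1, -1, 1, -1),
        c(2, -1, -1, 2, -1, -1),
        c(2, 1, -1, -2, -1, 1),
        c(1, 1, 0, -1, -1, 0),
        c(1, -1, 0, 1, -1, 0))
}

#' Generate a small test molecule with a complete NIC set and potential
#'
#' Produces a seeded toy system: the molecule, a complete nonredundant NIC
#' set, and a positive-definite analytic quadratic potential in NIC space
#' (the \code{F} field, internal basis, level "A"). Kinds:
#' \describe{
#'   \item{bent_triatomic}{water-like; 2 bonds + 1 angle.}
#'   \item{linear_triatomic}{nitrous-oxide-like; 2 bonds + a degenerate
#'     linear-bend pair with frozen perpendicular references (3N-5 = 4).}
#'   \item{planar_ring}{six-membered carbon ring; hexagon-symmetry stretch,
#'     angle and torsion combinations (12 coordinates).}
#'   \item{chain}{4-atom zigzag chain; bonds, angles, one torsion.}
#' }
#'
#' @param kind one of the above
#' @param seed integer seed; the same seed reproduces the system exactly
#' @return list with \code{mol}, \code{nics}, \code{F}
#'   (\code{\link{force_field}}), \code{S0} (reference NIC values),
#'   \code{G} (Wilson G at the reference geometry)
#' @export
make_toy_molecule <- function(kind = c("bent_triatomic", "linear_triatomic",
                                       "planar_ring", "chain"),
                              seed = 1L) {
  kind <- match.arg(kind)
  with_local_seed(seed, {
    sys <- switch(kind,
      bent_triatomic = {
        r1 <- stats::runif(1, 0.92, 1.05)
        r2 <- stats::runif(1, 0.92, 1.05)
        th <- stats::runif(1, 95, 115) * pi / 180
        coords <- rbind(c(0, 0, 0),
                        c(r1, 0, 0),
                        r2 * c(cos(th), sin(th), 0))
        mol <- molecule(c("O", "H", "H"), coords)
        prims <- list(prim_coord("bond", c(1, 2)),
                      prim_coord("bond", c(1, 3)),
                      prim_coord("angle", c(2, 1, 3)))
        nics <- nic_set(prims, diag(3),
                        names = c("r1", "r2", "bend"),
                        irreps = NULL)
        list(mol = mol, nics = nics)
      },
      linear_triatomic = {
        r1 <- stats::runif(1, 1.05, 1.20)
        r2 <- stats::runif(1, 1.10, 1.25)
        coords <- rbind(c(0, 0, 0), c(0, 0, r1), c(0, 0, r1 + r2))
        mol <- molecule(c("N", "N", "O"), coords)
        prims <- list(prim_coord("bond", c(1, 2)),
                      prim_coord("bond", c(2, 3)),
                      prim_coord("linear_bend", c(1, 2, 3),
                                 ref = c(1, 0, 0)),
                      prim_coord("linear_bend", c(1, 2, 3),
                                 ref = c(0, 1, 0)))
        nics <- nic_set(prims, diag(4),
                        names = c("r1", "r2", "bend_x", "bend_y"))
        list(mol = mol, nics = nics)
      },
      planar_ring = {
        r <- stats::runif(1, 1.35, 1.45)
        ang <- (0:5) * pi / 3
        coords <- cbind(r * cos(ang), r * sin(ang), 0)
        mol <- molecule(rep("C", 6), coords)
        nb <- function(i, k) ((i - 1 + k) %% 6) + 1
        bonds <- lapply(1:6, function(i) prim_coord("bond", c(i, nb(i, 1))))
        angles <- lapply(1:6, function(i) {
          prim_coord("angle", c(nb(i, -1), i, nb(i, 1)))
        })
        tors <- lapply(1:6, function(i) {
          prim_coord("torsion", c(i, nb(i, 1), nb(i, 2), nb(i, 3)))
        })
        cb <- ring_stretch_combos()
        ca <- rbind(c(1, -1, 1, -1, 1, -1),
                    c(2, -1, -1, 2, -1, -1),
                    c(0, 1, -1, 0, 1, -1))
        ct <- rbind(c(1, -1, 1, -1, 1, -1),
                    c(0, -1, 1, 0, -1, 1),
                    c(2, -1, -1, 2, -1, -1))
        z6 <- matrix(0, 6, 6); z3 <- matrix(0, 3, 6)
        coeffs <- rbind(cbind(cb, z6, z6),
                        cbind(z3, ca, z3[, 1:6]),
                        cbind(z3, z3[, 1:6], ct))
        nics <- nic_set(c(bonds, angles, tors), coeffs,
                        names = c(paste0("str", 1:6), paste0("bend", 1:3),
                                  paste0("oop", 1:3)))
        list(mol = mol, nics = nics)
      },
      chain = {
        r <- stats::runif(3, 1.45, 1.55)
        th <- stats::runif(2, 105, 115) * pi / 180
        tau <- stats::runif(1, 40, 80) * pi / 180
        coords <- matrix(0, 4, 3)
        coords[2, ] <- c(r[1], 0, 0)
        coords[3, ] <- coords[2, ] + r[2] * c(-cos(th[1]), sin(th[1]), 0)
        # place atom 4 with bond r[3], angle th[2], dihedral tau
        b2 <- coords[3, ] - coords[2, ]; b2 <- b2 / sqrt(sum(b2^2))
        b1 <- coords[2, ] - coords[1, ]; b1 <- b1 / sqrt(sum(b1^2))
        nrm <- crossprod3(b1, b2); nrm <- nrm / sqrt(sum(nrm^2))
        m <- crossprod3(nrm, b2)
        d <- -b2 * cos(th[2]) + sin(th[2]) * (m * cos(tau) + nrm * sin(tau))
        coords[4, ] <- coords[3, ] + r[3] * d
        mol <- molecule(rep("C", 4), coords)
        prims <- list(prim_coord("bond", c(1, 2)),
                      prim_coord("bond", c(2, 3)),
                      prim_coord("bond", c(3, 4)),
                      prim_coord("angle", c(1, 2, 3)),
                      prim_coord("angle", c(2, 3, 4)),
                      prim_coord("torsion", c(1, 2, 3, 4)))
        nics <- nic_set(prims, diag(6),
                        names = c("r12", "r23", "r34", "a123", "a234",
                                  "t1234"))
        list(mol = mol, nics = nics)
      })
    B <- build_b_matrix(sys$nics, sys$mol$coords)
    rank <- check_nonredundancy(B, n_vib(sys$mol))
    if (!rank$ok) {
      stop("internal error: generated NIC set is not complete (rank ",
           rank$rank, " != ", rank$n_expected, ")")
    }
    sys$F <- force_field(random_nic_field(sys$nics), basis = "internal",
                         level = "A")
    sys$S0 <- evaluate_nics(sys$nics, sys$mol$coords)
    sys$G <- build_g_matrix(B, sys$mol$masses)
    sys$kind <- kind
    sys$seed <- seed
    sys
  })
}

sparse_coupling <- function(d, sparsity) {
  n <- length(d)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (stats::runif(1) < sparsity) {
      m <- exp(stats::runif(1, log(0.005), log(0.2)))
      D[i, j] <- D[j, i] <- sample(c(-1, 1), 1) * m * sqrt(d[i] * d[j])
    }
  }
  D
}

#' Generate a correlated Level A/B/C force-field triple
#'
#' Emulates the statistical structure the CMA-2 diagnostic exploits:
#' Level B differs from Level A by a sparse symmetric coupling perturbation
#' Delta (F_B = F_A + alpha * Delta), and Level C differs from B such that
#' its couplings track the A-B difference -- the "photographic negative"
#' premise: F_C = F_B + beta * (rho * (-Delta) + (1 - rho) * Noise), with
#' Noise an independent draw from the same sparse generator. At rho = 1 the
#' xi ranking computed from F_C reproduces the ranking of the A-B coupling
#' differences exactly; rho < 1 degrades the diagnostic's fidelity.
#'
#' Perturbation magnitudes are scaled by sqrt(F_ii F_jj) so that the
#' resulting xi values land in the 0.005-0.2 operating range. If F_B loses
#' positive definiteness, alpha is halved (with a message) until it is
#' restored.
#'
#' @param F_A symmetric positive-definite Level-A matrix (or
#'   \code{\link{force_field}})
#' @param alpha scale of the A-B coupling difference
#' @param beta scale of the C-B difference
#' @param rho correlation fidelity in [0, 1]
#' @param sparsity probability that a given off-diagonal pair is perturbed
#' @param seed integer seed
#' @return list of class \code{"level_triple"} with internal-basis
#'   \code{force_field}s \code{F_A}, \code{F_B}, \code{F_C}, the
#'   perturbation \code{Delta}, and the generating parameters
#' @export
make_level_triple <- function(F_A, alpha = 1, beta = 1, rho = 0.9,
                              sparsity = 0.4, seed = 1L) {
  if (rho < 0 || rho > 1) stop("rho must lie in [0, 1]")
  FA <- as_ff_matrix(F_A)
  if (min(eigen(FA, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
    stop("F_A must be positive definite")
  }
  with_local_seed(seed, {
    d <- abs(diag(FA))
    Delta <- sparse_coupling(d, sparsity)
    Noise <- sparse_coupling(d, sparsity)
    a <- alpha
    repeat {
      FB <- FA + a * Delta
      if (min(eigen(FB, symmetric = TRUE,
                    only.values = TRUE)$values) > 1e-8) {
        break
      }
      a <- a / 2
      message("level triple: damping alpha to ", a,
              " to keep F_B positive definite")
      if (a < 1e-6) stop("could not keep F_B positive definite")
    }
    FC <- FB + beta * (rho * (-a * Delta) + (1 - rho) * Noise)
    structure(list(
      F_A = force_field(FA, "internal", level = "A"),
      F_B = force_field(FB, "internal", level = "B"),
      F_C = force_field(FC, "internal", level = "C"),
      Delta = a * Delta,
      params = list(alpha = a, beta = beta, rho = rho,
                    sparsity = sparsity, seed = seed)),
      class = "level_triple")
  })
}

#' Analytic model energy for the finite-difference backend
#'
#' Evaluates E = 1/2 (S - S0)^T F (S - S0) through the true curvilinear NIC
#' values of the supplied geometry, fulfilling the label -> energy contract
#' of \code{\link{assemble_force_constants}} without an external engine.
#'
#' @param geometry N x 3 Cartesian matrix
#' @param system a \code{\link{make_toy_molecule}} result (or any list with
#'   \code{nics}, \code{F}, \code{S0})
#' @return energy in aJ
#' @export
model_energy <- function(geometry, system) {
  dS <- evaluate_nics(system$nics, geometry) - system$S0
  0.5 * drop(dS %*% as_ff_matrix(system$F) %*% dS)
}

#' Energies for every job of a displacement plan from the model potential
#'
#' @param plan a \code{\link{plan_displacements}} result
#' @param system a \code{\link{make_toy_molecule}} result
#' @return named numeric vector of energies (aJ), one per plan label
#' @export
model_energies <- function(plan, system) {
  vapply(plan$jobs, function(j) model_energy(j$geometry, system), 0)
}

#' Generate an ensemble of synthetic CMA systems
#'
#' Convenience generator for benchmark-style studies: \code{n} toy molecules
#' (cycling through the available kinds), each with a Level A/B/C triple
#' built by \code{\link{make_level_triple}}. The layout matches what
#' \code{\link{convergence_curve}} consumes.
#'
#' @param n number of systems
#' @param seed master seed; system s uses sub-seeds derived from it
#' @param rho diagnostic fidelity passed to \code{\link{make_level_triple}}
#' @param alpha,beta,sparsity passed to \code{\link{make_level_triple}}
#' @param kinds molecule kinds to cycle through
#' @return list of systems, each with \code{F_A}, \code{F_B}, \code{F_C},
#'   \code{G}, \code{mol}, \code{nics}, \code{dof}
#' @export
make_cma_ensemble <- function(n, seed = 1L, rho = 0.9, alpha = 1, beta = 1,
                              sparsity = 0.4,
                              kinds = c("bent_triatomic", "linear_triatomic",
                                        "planar_ring", "chain")) {
  lapply(seq_len(n), function(s) {
    kind <- kinds[((s - 1L) %% length(kinds)) + 1L]
    sub <- (seed * 1000L + s) %% .Machine$integer.max
    toy <- make_toy_molecule(kind, seed = sub)
    tri <- make_level_triple(toy$F, alpha = alpha, beta = beta, rho = rho,
                             sparsity = sparsity, seed = sub + 1L)
    list(F_A = tri$F_A, F_B = tri$F_B, F_C = tri$F_C, G = toy$G,
         mol = toy$mol, nics = toy$nics, S0 = toy$S0,
         dof = n_vib(toy$mol), kind = kind)
  })
}

#' Write a synthetic fixture bundle to a directory
#'
#' Emits geometry (XYZ), NIC definitions, the three level Hessians and a
#' JSON manifest, so a full CMA run can be reproduced from files alone.
#'
#' @param system one element of \code{\link{make_cma_ensemble}}
#' @param dir output directory (created if needed)
#' @return \code{dir}, invisibly
#' @export
write_fixture_bundle <- function(system, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_xyz(system$mol, file.path(dir, "geometry.xyz"),
            comment = paste("synthetic", system$kind))
  write_nic_file(system$nics, file.path(dir, "coords.nic"))
  write_hessian(system$F_A, file.path(dir, "hessian_A.dat"))
  write_hessian(system$F_B, file.path(dir, "hessian_B.dat"))
  write_hessian(system$F_C, file.path(dir, "hessian_C.dat"))
  jsonlite::write_json(
    list(kind = system$kind, dof = system$dof,
         files = list(geometry = "geometry.xyz", nics = "coords.nic",
                      F_A = "hessian_A.dat", F_B = "hessian_B.dat",
                      F_C = "hessian_C.dat")),
    file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}
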