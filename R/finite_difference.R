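# Displacement planning and finite-difference assembly of quadratic force
# constants, with fourth-order-accurate stencils.

# 1-D central second-derivative stencils (multiples of h, weights / h^2)
.diag_stencils <- list(
  `2` = list(mult = c(-1L, 0L, 1L), w = c(1, -2, 1)),
  `4` = list(mult = c(-2L, -1L, 0L, 1L, 2L),
             w = c(-1, 16, -30, 16, -1) / 12)
)
# 1-D central first-derivative stencils used in tensor products for the
# mixed derivatives (exact for polynomials up to degree order+1)
.grad_stencils <- list(
  `2` = list(mult = c(-1L, 1L), w = c(-1, 1) / 2),
  `4` = list(mult = c(-2L, -1L, 1L, 2L), w = c(1, -8, 8, -1) / 12)
)

fd_label <- function(idx, mult) {
  paste0("d", paste(sprintf("%d:%+d", idx, mult), collapse = "_"))
}

#' Plan the displaced geometries for a set of force-constant elements
#'
#' Diagonal elements (i,i) use the 1-D central second-derivative stencil
#' (5-point for \code{order = 4}, 3-point for \code{order = 2}); off-diagonal
#' (i,j) use the tensor product of two first-derivative stencils over the
#' (+-1, +-2) multiples. Displacements are realized through
#' \code{\link{back_transform}}, so the curvilinear coordinates are followed
#' exactly. Geometries are deduplicated by label and the undisplaced
#' reference appears exactly once (label \code{"ref"}).
#'
#' If \code{modes} is supplied the displaced directions are Level-B normal
#' modes (for computing F_CMA elements); otherwise they are the NICs
#' themselves (for computing a Level-B field), with \code{step} in the
#' corresponding units.
#'
#' @param nics a \code{\link{nic_set}}
#' @param mol a \code{\link{molecule}}
#' @param elements two-column matrix or list of index pairs (i, j), i <= j
#' @param step displacement size (NIC or normal-mode units)
#' @param order stencil order, 2 or 4
#' @param modes optional \code{\link{normal_modes}} for qb-basis displacements
#' @return object of class \code{"displacement_plan"}: list with
#'   \code{jobs} (label -> list(geometry, displacement)), \code{step},
#'   \code{order}, \code{elements}, \code{basis}, \code{dim}
#' @export
plan_displacements <- function(nics, mol, elements, step = 0.01, order = 4L,
                               modes = NULL) {
  order <- as.integer(order)
  if (!order %in% c(2L, 4L)) stop("order must be 2 or 4")
  if (step <= 0) stop("step must be positive")
  dim <- if (is.null(modes)) n_nics(nics) else ncol(modes$L)
  elements <- canonical_pairs(elements, dim, allow_diag = TRUE)
  # stable ordering: by (i, j), then multiples
  if (nrow(elements)) {
    elements <- elements[order(elements[, 1], elements[, 2]), , drop = FALSE]
  }
  jobs <- list()
  add_job <- function(idx, mult) {
    keep <- mult != 0L
    lbl <- if (!any(keep)) "ref" else fd_label(idx[keep], mult[keep])
    if (!is.null(jobs[[lbl]])) return(lbl)
    dQ <- numeric(dim)
    dQ[idx] <- dQ[idx] + step * mult
    geo <- tryCatch(
      # near-machine-precision convergence so stencil sums are not limited
      # by the geometry solve
      back_transform(mol, dQ, nics, modes = modes, tol = 1e-13),
      error = function(e) stop("displacement job ", lbl, " failed: ",
                               conditionMessage(e), call. = FALSE))
    jobs[[lbl]] <<- list(geometry = geo, displacement = dQ)
    lbl
  }
  add_job(1L, 0L)  # the reference geometry, exactly once
  for (r in seq_len(nrow(elements))) {
    i <- elements[r, 1]; j <- elements[r, 2]
    if (i == j) {
      st <- .diag_stencils[[as.character(order)]]
      for (m in st$mult) add_job(i, m)
    } else {
      st <- .grad_stencils[[as.character(order)]]
      for (mi in st$mult) for (mj in st$mult) add_job(c(i, j), c(mi, mj))
    }
  }
  structure(list(jobs = jobs, step = step, order = order,
                 elements = elements,
                 basis = if (is.null(modes)) "internal" else "qb",
                 dim = dim),
            class = "displacement_plan")
}

#' @export
print.displacement_plan <- function(x, ...) {
  cat(sprintf("displacement_plan: %d geometries, %d elements, step %g, order %d (%s basis)\n",
              length(x$jobs), nrow(x$elements), x$step, x$order, x$basis))
  invisible(x)
}

canonical_pairs <- function(elements, dim, allow_diag = FALSE) {
  if (is.list(elements) && !is.data.frame(elements)) {
    elements <- do.call(rbind, elements)
  }
  if (is.null(elements) || length(elements) == 0L) {
    return(matrix(integer(), 0L, 2L))
  }
  elements <- matrix(as.integer(elements), ncol = 2L)
  elements <- cbind(pmin(elements[, 1], elements[, 2]),
                    pmax(elements[, 1], elements[, 2]))
  if (any(elements[, 1] < 1L) || any(elements[, 2] > dim)) {
    stop("element indices out of range")
  }
  if (!allow_diag && any(elements[, 1] == elements[, 2])) {
    stop("diagonal pairs not allowed here")
  }
  unique(elements)
}

#' Assemble force constants from finite-difference energies
#'
#' Applies the stencil weights of the plan to the supplied energies. The
#' returned field is partial: elements that were not requested are
#' \code{NA} (absent), not zero. The result is exact for potentials that are
#' polynomial of degree <= order + 1 in the displaced coordinates.
#'
#' @param plan a \code{\link{plan_displacements}} result
#' @param energies named numeric vector or list mapping every plan label to
#'   an energy in aJ
#' @return partial \code{\link{force_field}} in the plan's basis, with
#'   \code{NA} marking absent elements
#' @export
assemble_force_constants <- function(plan, energies) {
  energies <- unlist(energies)
  missing <- setdiff(names(plan$jobs), names(energies))
  if (length(missing)) {
    stop("missing energies for labels: ", paste(missing, collapse = ", "))
  }
  h <- plan$step
  dim <- plan$dim
  F <- matrix(NA_real_, dim, dim)
  ord <- as.character(plan$order)
  for (r in seq_len(nrow(plan$elements))) {
    i <- plan$elements[r, 1]; j <- plan$elements[r, 2]
    if (i == j) {
      st <- .diag_stencils[[ord]]
      lbl <- vapply(st$mult, function(m) {
        if (m == 0L) "ref" else fd_label(i, m)
      }, "")
      F[i, i] <- sum(st$w * energies[lbl]) / h^2
    } else {
      st <- .grad_stencils[[ord]]
      acc <- 0
      for (ai in seq_along(st$mult)) for (aj in seq_along(st$mult)) {
        lbl <- fd_label(c(i, j), c(st$mult[ai], st$mult[aj]))
        acc <- acc + st$w[ai] * st$w[aj] * energies[[lbl]]
      }
      F[i, j] <- F[j, i] <- acc / h^2
    }
  }
  structure(force_field_partial(F, basis = plan$basis), class = "force_field")
}

# a force_field whose matrix may contain NA (absent) entries
force_field_partial <- function(m, basis, level = NA_character_) {
  list(matrix = m, basis = basis, level = level, geometry_id = NA_character_)
}

#' Zero force constants that couple different irreducible representations
#'
#' Symmetry enforcement: elements F[i, j] whose coordinates (or modes) carry
#' different irrep labels are set to exactly zero; within-irrep elements are
#' untouched. With missing labels the matrix is returned unchanged with a
#' warning.
#'
#' @param F a \code{\link{force_field}} or matrix
#' @param irreps character vector of irrep labels, one per index
#' @return same type as \code{F}
#' @export
enforce_symmetry <- function(F, irreps) {
  Fm <- as_ff_matrix(F)
  if (is.null(irreps) || length(irreps) != nrow(Fm) || anyNA(irreps)) {
    warning("incomplete irrep labels; symmetry not enforced")
    return(F)
  }
  mask <- outer(irreps, irreps, `!=`)
  Fm[mask] <- 0
  if (inherits(F, "force_field")) {
    F$matrix <- Fm
    F
  } else {
    Fm
  }
}

#' Export a displacement plan as JSON
#'
#' Geometries are embedded as XYZ blocks so energies can be computed
#' out-of-band and re-imported with \code{\link{read_plan_json}}.
#'
#' @param plan a displacement plan
#' @param mol the \code{\link{molecule}} (for element symbols)
#' @param path output file
#' @return \code{path}, invisibly
#' @export
write_plan_json <- function(plan, mol, path) {
  xyz_block <- function(geo) {
    paste(c(as.character(n_atoms(mol)), "",
            sprintf("%-3s %18.12f %18.12f %18.12f", mol$symbols,
                    geo[, 1], geo[, 2], geo[, 3])), collapse = "\n")
  }
  obj <- list(
    step = plan$step, order = plan$order, basis = plan$basis,
    dim = plan$dim,
    elements = plan$elements,
    jobs = lapply(plan$jobs, function(j) {
      list(displacement = j$displacement, xyz = xyz_block(j$geometry))
    }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Re-import a displacement plan from JSON
#'
#' @param path file written by \code{\link{write_plan_json}}
#' @return a \code{displacement_plan}
#' @export
read_plan_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  parse_xyz <- function(txt) {
    ln <- strsplit(txt, "\n")[[1]]
    n <- as.integer(ln[1])
    toks <- strsplit(trimws(ln[3:(2 + n)]), "\\s+")
    t(vapply(toks, function(t) as.numeric(t[2:4]), numeric(3)))
  }
  jobs <- lapply(obj$jobs, function(j) {
    list(geometry = parse_xyz(j$xyz),
         displacement = as.numeric(j$displacement))
  })
  structure(list(jobs = jobs, step = obj$step, order = as.integer(obj$order),
                 elements = matrix(as.integer(obj$elements), ncol = 2L),
                 basis = obj$basis, dim = as.integer(obj$dim)),
            class = "displacement_plan")
}
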