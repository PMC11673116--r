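# Primitive internal coordinates: values and analytic first derivatives
# (Wilson s-vectors / B-matrix rows).

crossprod3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

skew3 <- function(v) {
  matrix(c(0, -v[3], v[2],
           v[3], 0, -v[1],
           -v[2], v[1], 0), 3, 3, byrow = TRUE)
}

# unit vector from a to b plus the Jacobian d(e)/d(r_b) = (I - e e^T)/r;
# the Jacobian w.r.t. r_a is its negative
unit_vec <- function(ra, rb) {
  d <- rb - ra
  r <- sqrt(sum(d^2))
  if (r < 1e-12) stop("coincident atoms in internal coordinate")
  e <- d / r
  list(e = e, r = r, J = (diag(3) - tcrossprod(e)) / r)
}

.prim_arity <- c(bond = 2L, angle = 3L, torsion = 4L,
                 out_of_plane = 4L, linear_bend = 3L)

#' Define a primitive internal coordinate
#'
#' Supported kinds: \code{bond} r(i,j); \code{angle} theta(i,j,k) with j the
#' apex; \code{torsion} tau(i,j,k,l), the dihedral between the i-j-k and
#' j-k-l planes (IUPAC right-handed sign, range (-pi, pi]); \code{out_of_plane}
#' gamma(i,j,k,l), the signed angle of the i-j bond out of the k-j-l plane,
#' positive on the side of (j->k) x (j->l); \code{linear_bend}, the bending of
#' a near-linear i-j-k chain measured in the plane perpendicular to a
#' reference unit vector \code{ref} (two components with perpendicular
#' references span the degenerate pair).
#'
#' Atom indices are 1-based. Bond values are in angstrom, all angular kinds
#' in radians.
#'
#' @param kind one of \code{"bond"}, \code{"angle"}, \code{"torsion"},
#'   \code{"out_of_plane"}, \code{"linear_bend"}
#' @param atoms integer vector of 1-based atom indices (arity 2/3/4/4/3)
#' @param ref reference unit vector for \code{linear_bend} (ignored otherwise);
#'   if \code{NULL} it is chosen automatically at evaluation from the i-k axis
#' @return object of class \code{"prim_coord"}
#' @export
prim_coord <- function(kind, atoms, ref = NULL) {
  kind <- match.arg(kind, names(.prim_arity))
  atoms <- as.integer(atoms)
  if (length(atoms) != .prim_arity[[kind]]) {
    stop(sprintf("%s requires %d atom indices", kind, .prim_arity[[kind]]))
  }
  if (anyDuplicated(atoms)) stop("atom indices must be distinct")
  if (any(atoms < 1L)) stop("atom indices are 1-based")
  structure(list(kind = kind, atoms = atoms, ref = ref), class = "prim_coord")
}

#' @export
print.prim_coord <- function(x, ...) {
  cat(sprintf("%s(%s)\n", x$kind, paste(x$atoms, collapse = ",")))
  invisible(x)
}

#' @export
format.prim_coord <- function(x, ...) {
  sprintf("%s(%s)", x$kind, paste(x$atoms, collapse = ","))
}

prim_units <- function(coord) if (coord$kind == "bond") "angstrom" else "rad"

# auto reference perpendicular for a linear bend: the coordinate axis is
# e(i->k); take the Cartesian axis least parallel to it and orthogonalize
linear_bend_ref <- function(coord, coords) {
  if (!is.null(coord$ref)) {
    d <- coord$ref / sqrt(sum(coord$ref^2))
    return(d)
  }
  i <- coord$atoms[1]; k <- coord$atoms[3]
  ax <- coords[k, ] - coords[i, ]
  ax <- ax / sqrt(sum(ax^2))
  cand <- diag(3)[, which.min(abs(ax))]
  d <- cand - sum(cand * ax) * ax
  d / sqrt(sum(d^2))
}

#' Evaluate a primitive internal coordinate
#'
#' @param coord a \code{\link{prim_coord}}
#' @param coords N x 3 Cartesian coordinate matrix (angstrom)
#' @return coordinate value (angstrom or radians)
#' @export
evaluate_primitive <- function(coord, coords) {
  a <- coord$atoms
  if (max(a) > nrow(coords)) stop("atom index beyond molecule in ",
                                  format(coord))
  switch(coord$kind,
    bond = sqrt(sum((coords[a[2], ] - coords[a[1], ])^2)),
    angle = {
      u <- unit_vec(coords[a[2], ], coords[a[1], ])
      v <- unit_vec(coords[a[2], ], coords[a[3], ])
      acos(max(-1, min(1, sum(u$e * v$e))))
    },
    torsion = {
      b1 <- coords[a[2], ] - coords[a[1], ]
      b2 <- coords[a[3], ] - coords[a[2], ]
      b3 <- coords[a[4], ] - coords[a[3], ]
      n1 <- crossprod3(b1, b2)
      n2 <- crossprod3(b2, b3)
      n1n <- sqrt(sum(n1^2)); n2n <- sqrt(sum(n2^2))
      if (n1n < 1e-10 || n2n < 1e-10) {
        stop("degenerate geometry: collinear atoms in bounding plane of ",
             format(coord))
      }
      tau <- atan2(sum(crossprod3(n1, n2) * b2) / sqrt(sum(b2^2)),
                   sum(n1 * n2))
      if (tau <= -pi + 1e-10) tau <- tau + 2 * pi  # map -pi to +pi
      tau
    },
    out_of_plane = {
      u <- unit_vec(coords[a[2], ], coords[a[1], ])   # j -> i
      ek <- unit_vec(coords[a[2], ], coords[a[3], ])  # j -> k
      el <- unit_vec(coords[a[2], ], coords[a[4], ])  # j -> l
      n <- crossprod3(ek$e, el$e)
      nn <- sqrt(sum(n^2))
      if (nn < 1e-10) stop("degenerate geometry: collinear k-j-l in ",
                           format(coord))
      asin(max(-1, min(1, sum(u$e * n / nn))))
    },
    linear_bend = {
      d <- linear_bend_ref(coord, coords)
      u <- unit_vec(coords[a[2], ], coords[a[1], ])
      v <- unit_vec(coords[a[2], ], coords[a[3], ])
      asin(max(-1, min(1, sum(d * crossprod3(u$e, v$e)))))
    })
}

#' Analytic B-matrix row of a primitive coordinate
#'
#' Returns the gradient of the coordinate value with respect to all 3N
#' Cartesian coordinates (ordered x1 y1 z1 x2 ...). Entries of atoms not
#' participating in the coordinate are exactly zero, and each row obeys the
#' translational sum rule.
#'
#' @inheritParams evaluate_primitive
#' @return numeric vector of length 3N
#' @export
primitive_b_row <- function(coord, coords) {
  n <- nrow(coords)
  a <- coord$atoms
  if (max(a) > n) stop("atom index beyond molecule in ", format(coord))
  row <- numeric(3L * n)
  put <- function(atom, g) {
    idx <- (3L * (atom - 1L) + 1L):(3L * atom)
    row[idx] <<- row[idx] + g
  }
  switch(coord$kind,
    bond = {
      u <- unit_vec(coords[a[1], ], coords[a[2], ])
      put(a[1], -u$e); put(a[2], u$e)
    },
    angle = {
      u <- unit_vec(coords[a[2], ], coords[a[1], ])
      v <- unit_vec(coords[a[2], ], coords[a[3], ])
      cth <- sum(u$e * v$e)
      sth <- sqrt(max(0, 1 - cth^2))
      if (sth < 1e-10) stop("degenerate geometry: linear angle in ",
                            format(coord), " (use linear_bend)")
      si <- (cth * u$e - v$e) / (u$r * sth)
      sk <- (cth * v$e - u$e) / (v$r * sth)
      put(a[1], si); put(a[3], sk); put(a[2], -(si + sk))
    },
    torsion = {
      b1 <- coords[a[2], ] - coords[a[1], ]
      b2 <- coords[a[3], ] - coords[a[2], ]
      b3 <- coords[a[4], ] - coords[a[3], ]
      n1 <- crossprod3(b1, b2)
      n2 <- crossprod3(b2, b3)
      n1sq <- sum(n1^2); n2sq <- sum(n2^2)
      if (n1sq < 1e-20 || n2sq < 1e-20) {
        stop("degenerate geometry: collinear atoms in bounding plane of ",
             format(coord))
      }
      b2n <- sqrt(sum(b2^2))
      gi <- -b2n / n1sq * n1
      gl <-  b2n / n2sq * n2
      f1 <- sum(b1 * b2) / sum(b2^2)
      f3 <- sum(b3 * b2) / sum(b2^2)
      gj <- -(1 + f1) * gi + f3 * gl
      gk <- f1 * gi - (1 + f3) * gl
      put(a[1], gi); put(a[2], gj); put(a[3], gk); put(a[4], gl)
    },
    out_of_plane = {
      u <- unit_vec(coords[a[2], ], coords[a[1], ])
      ek <- unit_vec(coords[a[2], ], coords[a[3], ])
      el <- unit_vec(coords[a[2], ], coords[a[4], ])
      w <- crossprod3(ek$e, el$e)
      wn <- sqrt(sum(w^2))
      if (wn < 1e-10) stop("degenerate geometry: collinear k-j-l in ",
                           format(coord))
      nhat <- w / wn
      s <- sum(u$e * nhat)
      cg <- sqrt(max(1e-20, 1 - s^2))
      # ds = nhat^T du + u^T Pn/|w| dw, dw = -[el]x d(ek) + [ek]x d(el)
      Pn <- (diag(3) - tcrossprod(nhat)) / wn
      uPn <- drop(u$e %*% Pn)
      dw_dek <- -skew3(el$e)   # applied to d(ek)
      dw_del <-  skew3(ek$e)
      g_i <- drop(nhat %*% u$J)
      g_k <- drop(uPn %*% dw_dek %*% ek$J)
      g_l <- drop(uPn %*% dw_del %*% el$J)
      g_j <- -(g_i + g_k + g_l)
      put(a[1], g_i / cg); put(a[3], g_k / cg); put(a[4], g_l / cg)
      put(a[2], g_j / cg)
    },
    linear_bend = {
      d <- linear_bend_ref(coord, coords)
      u <- unit_vec(coords[a[2], ], coords[a[1], ])
      v <- unit_vec(coords[a[2], ], coords[a[3], ])
      s <- sum(d * crossprod3(u$e, v$e))
      cg <- sqrt(max(1e-20, 1 - s^2))
      # ds = d . (du x v + u x dv) = d^T(-[v]x Ju + [u]x Jv)
      g_i <- drop(d %*% (-skew3(v$e)) %*% u$J)
      g_k <- drop(d %*% skew3(u$e) %*% v$J)
      g_j <- -(g_i + g_k)
      put(a[1], g_i / cg); put(a[3], g_k / cg); put(a[2], g_j / cg)
    })
  row
}
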