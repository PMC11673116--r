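test_that("GF solution matches the diatomic closed form and Cartesian route", {
  # 1x1: omega = kappa * sqrt(k * g), checked against the mass-weighted
  # Cartesian Hessian of the same diatomic
  k <- 5.7
  mol <- molecule(c("H", "Cl"), rbind(c(0, 0, 0), c(0, 0, 1.27)))
  nics <- nic_set(list(prim_coord("bond", c(1, 2))), 1)
  B <- build_b_matrix(nics, mol$coords)
  G <- build_g_matrix(B, mol$masses)
  nm <- solve_gf(matrix(k), G)
  mu <- 1 / (1 / mol$masses[1] + 1 / mol$masses[2])
  expect_equal(nm$freq, freq_conversion_factor() * sqrt(k / mu),
               tolerance = 1e-12)
  Fx <- internal_hessian_to_cartesian(matrix(k), B)
  expect_equal(nm$freq, cartesian_frequencies(Fx, mol), tolerance = 1e-10)
  # zero force field gives zero frequencies
  expect_equal(solve_gf(matrix(0), G)$freq, 0)
})

test_that("GF and mass-weighted Cartesian frequencies agree on all fixtures", {
  for (kind in toy_kinds) {
    for (s in c(3, 14)) {
      toy <- make_toy_molecule(kind, seed = s)
      B <- build_b_matrix(toy$nics, toy$mol$coords)
      nm <- solve_gf(toy$F, toy$G)
      cf <- cartesian_frequencies(internal_hessian_to_cartesian(toy$F, B),
                                  toy$mol)
      expect_lt(max(abs(sort(nm$freq) - sort(cf))), 1e-6)
      # eigen-normalization: L^T F L = diag(lambda), L^-1 G L^-T = I
      LFL <- crossprod(nm$L, toy$F$matrix %*% nm$L)
      expect_lt(max(abs(LFL - diag(nm$lambda))), 1e-10 * max(abs(nm$lambda)))
      Li <- solve(nm$L)
      expect_lt(max(abs(Li %*% toy$G %*% t(Li) - diag(length(nm$freq)))),
                1e-9)
    }
  }
})

test_that("Cartesian-to-internal transformation inverts the congruence", {
  toy <- make_toy_molecule("planar_ring", seed = 8)
  B <- build_b_matrix(toy$nics, toy$mol$coords)
  Fx <- internal_hessian_to_cartesian(toy$F, B)
  FS <- cartesian_hessian_to_internal(Fx, B, toy$G, toy$mol$masses)
  expect_lt(max(abs(FS$matrix - toy$F$matrix)), 1e-10)
  # frequencies survive the round trip
  expect_equal(solve_gf(FS, toy$G)$freq, solve_gf(toy$F, toy$G)$freq,
               tolerance = 1e-10)
  # rigid-motion eigenvectors of F_x contribute nothing: F_x has 6 zero roots
  ev <- eigen(Fx$matrix, symmetric = TRUE, only.values = TRUE)$values
  expect_lt(sort(abs(ev))[6], 1e-10)
  # a non-stationary gradient triggers a warning
  expect_warning(
    cartesian_hessian_to_internal(Fx, B, toy$G, toy$mol$masses,
                                  gradient = rep(0.01, ncol(B))),
    "stationary")
})

test_that("qb transforms are mutually inverse and diagonalize Level B", {
  toy <- make_toy_molecule("chain", seed = 21)
  nm <- solve_gf(toy$F, toy$G)
  # the generating field becomes strictly diagonal in its own mode basis
  FQ <- internal_to_qb(toy$F, nm)
  off <- FQ$matrix - diag(diag(FQ$matrix))
  expect_lt(max(abs(off)), 1e-10)
  expect_equal(diag(FQ$matrix), nm$lambda, tolerance = 1e-10)
  # identity modes leave the matrix unchanged
  id <- normal_modes(diag(6), rep(1, 6), rep(1, 6))
  expect_equal(internal_to_qb(toy$F, id)$matrix, toy$F$matrix)
  # round trips on random symmetric matrices
  set.seed(5)
  for (t in 1:20) {
    M <- crossprod(matrix(rnorm(36), 6))
    rt <- qb_to_internal(internal_to_qb(M, nm), nm)
    expect_lt(max(abs(rt$matrix - M)), 1e-10 * max(abs(M)))
    # spectrum of G F is invariant under the congruence chain
    expect_equal(sort(eigen(toy$G %*% rt$matrix, only.values = TRUE)$values),
                 sort(eigen(toy$G %*% M, only.values = TRUE)$values),
                 tolerance = 1e-9)
  }
  expect_equal(qb_to_internal(matrix(0, 6, 6), nm)$matrix, matrix(0, 6, 6))
})

test_that("ZPVE is half the frequency sum and linear in residuals", {
  expect_equal(zpve(c(100, 200)), 150)
  expect_equal(zpve(numeric(0)), 0)
  expect_warning(z <- zpve(c(100, -50)), "imaginary")
  expect_equal(z, 50)
  set.seed(3)
  a <- runif(9, 200, 3000); b <- a + rnorm(9)
  expect_equal(zpve(b) - zpve(a), sum(b - a) / 2)
})

test_that("Hessian files round-trip at full precision", {
  toy <- make_toy_molecule("bent_triatomic", seed = 6)
  path <- withr::local_tempfile(fileext = ".dat")
  write_hessian(toy$F, path)
  back <- read_hessian(path)
  expect_equal(back$matrix, toy$F$matrix, tolerance = 1e-14)
  expect_identical(back$basis, "internal")
  expect_identical(back$level, "A")
})
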