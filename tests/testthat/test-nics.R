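test_that("NIC rows are unit-normalized with raw coefficients preserved", {
  prims <- list(prim_coord("bond", c(1, 2)), prim_coord("bond", c(1, 3)))
  nics <- nic_set(prims, rbind(c(1, 1), c(2, -1)))
  expect_equal(rowSums(nics$coeffs^2), c(1, 1))
  expect_equal(nics$raw_coeffs, rbind(c(1, 1), c(2, -1)))
  expect_error(nic_set(prims, rbind(c(0, 0))), "zero coefficient")
})

test_that("B matrix is the coefficient-weighted stack of primitive rows", {
  g <- rbind(c(0, 0, 0), c(0.96, 0, 0), c(-0.3, 0.9, 0))
  prims <- list(prim_coord("bond", c(1, 2)), prim_coord("bond", c(1, 3)),
                prim_coord("angle", c(2, 1, 3)))
  # single-primitive NIC with coefficient 1 equals the primitive row
  nics <- nic_set(prims[1], 1)
  expect_equal(drop(build_b_matrix(nics, g)),
               primitive_b_row(prims[[1]], g))
  # general combination
  nics <- nic_set(prims, rbind(c(1, 1, 0), c(1, -1, 0), c(0, 0, 1)))
  B <- build_b_matrix(nics, g)
  expect_equal(B[1, ], (primitive_b_row(prims[[1]], g) +
                          primitive_b_row(prims[[2]], g)) / sqrt(2))
  # (1, -1) on two identical primitives cancels and is flagged
  bad <- nic_set(list(prims[[1]], prim_coord("bond", c(1, 2))),
                 rbind(c(1, -1)))
  expect_error(build_b_matrix(bad, g), "zero B row")
})

test_that("ring-breathing B row on a regular hexagon has 6-fold symmetry", {
  ang <- (0:5) * pi / 3
  g <- cbind(1.4 * cos(ang), 1.4 * sin(ang), 0)
  bonds <- lapply(1:6, function(i) prim_coord("bond", c(i, (i %% 6) + 1)))
  nics <- nic_set(bonds, rbind(rep(1, 6)))
  row <- matrix(drop(build_b_matrix(nics, g)), ncol = 3, byrow = TRUE)
  # rotating atom a's block by 60 degrees gives atom a+1's block
  rot <- matrix(c(cos(pi / 3), -sin(pi / 3), 0,
                  sin(pi / 3), cos(pi / 3), 0, 0, 0, 1), 3, 3, byrow = TRUE)
  for (a in 1:5) {
    expect_equal(drop(rot %*% row[a, ]), row[a + 1, ], tolerance = 1e-12)
  }
})

test_that("G matrix matches closed forms and the direct-summation oracle", {
  # diatomic: G = 1/m1 + 1/m2
  g <- rbind(c(0, 0, 0), c(0, 0, 1.1))
  nics <- nic_set(list(prim_coord("bond", c(1, 2))), 1)
  B <- build_b_matrix(nics, g)
  m <- c(12, 15.9949146196)
  expect_equal(drop(build_g_matrix(B, m)), 1 / m[1] + 1 / m[2])
  # infinite-mass limit sends G to zero
  expect_lt(abs(build_g_matrix(B, c(1e14, 1e14))), 1e-13)
  # brute-force element-wise sum over atoms on random small molecules
  set.seed(20)
  for (t in 1:20) {
    toy <- make_toy_molecule(toy_kinds[((t - 1) %% 4) + 1], seed = t)
    B <- build_b_matrix(toy$nics, toy$mol$coords)
    G <- build_g_matrix(B, toy$mol$masses)
    n <- n_nics(toy$nics)
    Gbf <- matrix(0, n, n)
    for (i in 1:n) for (j in 1:n) {
      for (a in seq_along(toy$mol$masses)) {
        idx <- (3 * (a - 1) + 1):(3 * a)
        Gbf[i, j] <- Gbf[i, j] + sum(B[i, idx] * B[j, idx]) / toy$mol$masses[a]
      }
    }
    expect_lt(max(abs(G - Gbf)), 1e-12)
  }
})

test_that("rank diagnostics detect completeness and redundancy", {
  toy <- make_toy_molecule("chain", seed = 2)
  B <- build_b_matrix(toy$nics, toy$mol$coords)
  expect_true(check_nonredundancy(B, 6)$ok)
  # duplicating a coordinate row leaves the rank short of the new count
  rep <- check_nonredundancy(rbind(B, B[1, ]), 7)
  expect_false(rep$ok)
  expect_identical(rep$rank, 6L)
})

test_that("NIC files round-trip through write and read", {
  toy <- make_toy_molecule("planar_ring", seed = 4)
  path <- withr::local_tempfile(fileext = ".nic")
  write_nic_file(toy$nics, path)
  back <- read_nic_file(path, geometry = toy$mol$coords)
  expect_equal(back$coeffs, toy$nics$coeffs, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back$names, toy$nics$names)
  expect_equal(evaluate_nics(back, toy$mol$coords),
               evaluate_nics(toy$nics, toy$mol$coords))
})

test_that("packaged fixture NIC sets are complete", {
  pyr <- load_fixture("pyridine")
  expect_identical(n_nics(pyr$nics), 27L)
  expect_true(check_nonredundancy(pyr$B, 27)$ok)
  # irrep block sizes of the published set
  expect_equal(unname(table(pyr$nics$irreps)[c("a1", "a2", "b1", "b2")]),
               c(10L, 3L, 5L, 9L), ignore_attr = TRUE)
  pe <- load_fixture("pyrrolylethanol")
  expect_identical(n_nics(pe$nics), 45L)
  expect_true(check_nonredundancy(pe$B, 45)$ok)
})
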