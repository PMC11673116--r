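test_that("displacement plans have the expected geometry counts", {
  toy <- make_toy_molecule("chain", seed = 1)
  n <- n_nics(toy$nics)
  # n diagonal elements at order 4: 4n + 1 unique geometries (shared center)
  diag_els <- cbind(1:n, 1:n)
  plan <- plan_displacements(toy$nics, toy$mol, diag_els, order = 4)
  expect_identical(length(plan$jobs), 4L * n + 1L)
  # empty element set: only the reference geometry
  plan0 <- plan_displacements(toy$nics, toy$mol, NULL)
  expect_identical(names(plan0$jobs), "ref")
  # order 2, one diagonal element: 3 geometries
  plan2 <- plan_displacements(toy$nics, toy$mol, cbind(1, 1), order = 2)
  expect_identical(length(plan2$jobs), 3L)
  # deterministic job ordering
  plan_b <- plan_displacements(toy$nics, toy$mol, diag_els, order = 4)
  expect_identical(names(plan$jobs), names(plan_b$jobs))
})

test_that("stencils are exact on polynomials through degree 5", {
  toy <- make_toy_molecule("chain", seed = 2)
  plan <- plan_displacements(toy$nics, toy$mol,
                             rbind(c(1, 1), c(2, 2), c(1, 2)), step = 0.01)
  # energies computed directly from the planned displacement vectors, so
  # only the stencil weights are under test
  poly_E <- function(f) vapply(plan$jobs, function(j) f(j$displacement), 0)
  k <- 3.7; c12 <- 0.45
  FF <- assemble_force_constants(plan, poly_E(function(q) {
    0.5 * k * q[1]^2 + 0.5 * 1.1 * q[2]^2 + c12 * q[1] * q[2] + 0.2 * q[1]^5
  }))
  expect_equal(FF$matrix[1, 1], k, tolerance = 1e-9)
  expect_equal(FF$matrix[2, 2], 1.1, tolerance = 1e-9)
  expect_equal(FF$matrix[1, 2], c12, tolerance = 1e-9)
  expect_equal(FF$matrix[2, 1], c12, tolerance = 1e-9)
  # unrequested elements are absent (NA), not zero
  expect_true(is.na(FF$matrix[3, 3]))
})

test_that("the diagonal stencil shows fourth-order Richardson convergence", {
  toy <- make_toy_molecule("chain", seed = 2)
  err_at <- function(h) {
    plan <- plan_displacements(toy$nics, toy$mol, cbind(1, 1), step = h)
    E <- vapply(plan$jobs, function(j) j$displacement[1]^6, 0)
    abs(assemble_force_constants(plan, E)$matrix[1, 1])  # true d2/dq2 = 0
  }
  ratio <- err_at(0.04) / err_at(0.02)
  expect_gt(ratio, 14)
  expect_lt(ratio, 18)
})

test_that("assembly on the analytic quadratic potential recovers the field", {
  for (kind in c("bent_triatomic", "planar_ring")) {
    toy <- make_toy_molecule(kind, seed = 11)
    n <- n_nics(toy$nics)
    for (h in c(0.001, 0.01, 0.02)) {
      plan <- plan_displacements(toy$nics, toy$mol, all_pairs_with_diag(n),
                                 step = h, order = 4)
      FF <- assemble_force_constants(plan, model_energies(plan, toy))
      expect_lt(max(abs(FF$matrix - toy$F$matrix)), 1e-10)
    }
  }
  # missing energies are reported by label
  toy <- make_toy_molecule("chain", seed = 3)
  plan <- plan_displacements(toy$nics, toy$mol, cbind(1, 1))
  E <- model_energies(plan, toy)
  expect_error(assemble_force_constants(plan, E[-2]),
               "missing energies.*d1")
})

test_that("qb-basis plans differentiate along the Level-B normal modes", {
  toy <- make_toy_molecule("bent_triatomic", seed = 13)
  tri <- quiet_triple(toy$F, seed = 14)
  modes_B <- solve_gf(tri$F_B, toy$G)
  plan <- plan_displacements(toy$nics, toy$mol, all_pairs_with_diag(3),
                             step = 0.01, modes = modes_B)
  expect_identical(plan$basis, "qb")
  FF <- assemble_force_constants(plan, model_energies(plan, toy))
  # the potential is the Level-A field, so the assembled matrix is F_CMA(A)
  expect_lt(max(abs(FF$matrix - internal_to_qb(toy$F, modes_B)$matrix)),
            1e-10)
})

test_that("symmetry enforcement zeroes exactly the cross-irrep couplings", {
  irr <- c("a1", "b2", "a1")
  F <- matrix(c(2, 1e-5, 0.3, 1e-5, 1, 2e-5, 0.3, 2e-5, 1.5), 3, 3)
  Fs <- enforce_symmetry(F, irr)
  expect_identical(Fs[1, 2], 0); expect_identical(Fs[2, 3], 0)
  expect_identical(Fs[1, 3], 0.3)
  # single-irrep matrix is untouched
  expect_identical(enforce_symmetry(F, rep("a", 3)), F)
  expect_warning(out <- enforce_symmetry(F, c("a1", NA, "a1")), "irrep")
  expect_identical(out, F)
  # pyridine labels produce the published 10/3/5/9 block structure
  pyr <- load_fixture("pyridine")
  M <- enforce_symmetry(matrix(1, 27, 27), pyr$nics$irreps)
  blk <- vapply(unique(pyr$nics$irreps),
                function(g) sum(pyr$nics$irreps == g), 0)
  expect_equal(sum(M), sum(blk^2))
})

test_that("plans round-trip through JSON export", {
  toy <- make_toy_molecule("chain", seed = 4)
  plan <- plan_displacements(toy$nics, toy$mol, rbind(c(1, 2), c(3, 3)))
  path <- withr::local_tempfile(fileext = ".json")
  write_plan_json(plan, toy$mol, path)
  back <- read_plan_json(path)
  expect_identical(names(back$jobs), names(plan$jobs))
  expect_equal(back$jobs[["ref"]]$geometry, unname(plan$jobs[["ref"]]$geometry),
               tolerance = 1e-10)
  # energies computed on the re-imported geometries still recover the field
  E <- vapply(back$jobs, function(j) model_energy(j$geometry, toy), 0)
  FF <- assemble_force_constants(back, E)
  expect_equal(FF$matrix[1, 2], toy$F$matrix[1, 2], tolerance = 1e-8)
})
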