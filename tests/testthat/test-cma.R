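test_that("xi diagnostic is dimensionless and matches hand evaluation", {
  # strictly diagonal field has zero xi everywhere
  xi <- xi_matrix(diag(c(4, 1, 2.5)))
  expect_equal(max(xi), 0)
  # hand-evaluated default normalization
  F <- matrix(c(4, 0.4, 0.4, 1), 2, 2)
  expect_equal(xi_matrix(F)[1, 2], 0.4 / sqrt(4 * 1))
  # invariant under overall positive scaling
  expect_equal(unclass(xi_matrix(17.3 * F)), unclass(xi_matrix(F)),
               ignore_attr = TRUE)
  # zero diagonal is undefined
  expect_error(xi_matrix(matrix(c(0, 1, 1, 2), 2)), "zero diagonal")
  # provenance records the normalization strategy
  expect_identical(attr(xi_matrix(F), "provenance")$normalization, "diag")
  expect_equal(xi_matrix(F, "lambdaB", lambda_B = c(4, 1))[1, 2], 0.2)
})

test_that("off-diagonal selection is strict and nested in the cutoff", {
  xi <- matrix(0, 3, 3); xi[1, 2] <- xi[2, 1] <- 0.05
  expect_equal(nrow(select_offdiagonals(xi, 0.04)), 1L)
  expect_equal(select_offdiagonals(xi, 0.04)[1, ], c(i = 1L, j = 2L))
  # strict "greater than": a cutoff equal to the value excludes it
  expect_equal(nrow(select_offdiagonals(xi, 0.05)), 0L)
  expect_equal(nrow(select_offdiagonals(xi, 0.06)), 0L)
  expect_equal(nrow(select_offdiagonals(xi, Inf)), 0L)
  expect_error(select_offdiagonals(xi, -1), "positive")
  # nesting over a random xi matrix and a descending cutoff sweep
  set.seed(8)
  for (t in 1:20) {
    M <- matrix(runif(64), 8); M <- (M + t(M)) / 2; diag(M) <- 0
    prev <- NULL
    for (ct in sort(runif(6, 0, 1), decreasing = TRUE)) {
      sel <- select_offdiagonals(M, ct)
      keys <- paste(sel[, 1], sel[, 2])
      if (!is.null(prev)) expect_true(all(prev %in% keys))
      prev <- keys
    }
  }
})

test_that("eta reproduces the published count-to-percent arithmetic", {
  # one coupling in a 4-DOF linear triatomic: 25%
  expect_equal(eta(1, 4), 25)
  # two couplings in a 9-DOF system: 22% at table rounding
  expect_equal(round(eta(2, 9)), 22)
  expect_equal(eta(matrix(integer(), 0, 2), 12), 0)
  expect_error(eta(1, 0), "positive")
})

test_that("CMA field assembly places exactly the selected couplings", {
  F <- assemble_cma_field(c(2, 3, 4))
  expect_equal(F$matrix, diag(c(2, 3, 4)))
  F1 <- assemble_cma_field(c(2, 3, 4), rbind(c(1, 3)), 0.25)
  expect_equal(sum(F1$matrix != 0), 5L)
  expect_equal(F1$matrix[3, 1], 0.25)
  expect_error(assemble_cma_field(c(2, NA, 4)), "complete")
  expect_error(assemble_cma_field(c(2, 3), rbind(c(1, 2)), numeric(0)),
               "one value per")
})

test_that("CMA frequencies are exact in the limiting cases", {
  toy <- make_toy_molecule("planar_ring", seed = 31)
  tri <- quiet_triple(toy$F, seed = 32)
  modes_B <- solve_gf(tri$F_B, toy$G)
  # F_CMA = diag(lambda_B) reproduces Level B exactly
  FB_cma <- assemble_cma_field(modes_B$lambda)
  nm <- cma_frequencies(FB_cma, modes_B, toy$G)
  expect_lt(max(abs(sort(nm$freq) - sort(modes_B$freq))), 1e-8)
  # the full F_CMA(A) reproduces Level A exactly
  FQ <- internal_to_qb(tri$F_A, modes_B)
  nmA <- cma_frequencies(FQ, modes_B, toy$G)
  expect_lt(max(abs(sort(nmA$freq) - sort(solve_gf(tri$F_A, toy$G)$freq))),
            1e-8)
})

test_that("mode matching recovers permutations and signs", {
  toy <- make_toy_molecule("planar_ring", seed = 41)
  nm <- solve_gf(toy$F, toy$G)
  # identical sets: identity permutation, zero residuals
  mm <- match_modes(nm, nm)
  expect_identical(mm$permutation, seq_along(nm$freq))
  expect_equal(mm$residuals, rep(0, length(nm$freq)))
  # a swapped pair is recovered as the transposition
  swap <- nm
  swap$L <- nm$L[, c(2, 1, 3:12)]
  swap$freq <- nm$freq[c(2, 1, 3:12)]
  swap$lambda <- nm$lambda[c(2, 1, 3:12)]
  expect_identical(match_modes(nm, swap)$permutation[1:2], c(2L, 1L))
  # random permutations with random sign flips, 20 seeds
  set.seed(77)
  for (t in 1:20) {
    p <- sample(12)
    s <- sample(c(-1, 1), 12, replace = TRUE)
    perm <- nm
    perm$L <- sweep(nm$L[, p], 2, s, `*`)
    perm$freq <- nm$freq[p]
    perm$lambda <- nm$lambda[p]
    got <- match_modes(nm, perm)$permutation
    expect_identical(order(p), got)
  }
})

test_that("protocol limits: A = B gives zero CMA-0 residuals; full inclusion is exact", {
  toy <- make_toy_molecule("chain", seed = 51)
  tri <- quiet_triple(toy$F, seed = 52)
  r0 <- cma_run(tri$F_B, tri$F_B, toy$G, "cma0")
  expect_lt(max(abs(r0$residuals)), 1e-8)
  # alpha = 0 collapses the triple onto Level A
  tri0 <- quiet_triple(toy$F, alpha = 0, seed = 53)
  expect_equal(tri0$F_B$matrix, toy$F$matrix)
  rall <- cma_run(tri$F_A, tri$F_B, toy$G, "cma1",
                  pairs = all_offdiag_pairs(6))
  expect_lt(max(abs(rall$residuals)), 1e-8)
  # cma2 with infinite cutoff reduces to cma0
  r2 <- cma_run(tri$F_A, tri$F_B, toy$G, "cma2", F_C = tri$F_C, cutoff = Inf)
  rd <- cma_run(tri$F_A, tri$F_B, toy$G, "cma0")
  expect_equal(r2$residuals, rd$residuals, tolerance = 1e-12)
})

test_that("at rho = 1 the xi ranking reproduces the A-B coupling ranking", {
  toy <- make_toy_molecule("planar_ring", seed = 61)
  tri <- quiet_triple(toy$F, rho = 1, seed = 62)
  modes_B <- solve_gf(tri$F_B, toy$G)
  xi <- xi_matrix(internal_to_qb(tri$F_C, modes_B),
                  normalization = "lambdaB", lambda_B = modes_B$lambda)
  dA <- internal_to_qb(tri$F_A$matrix - tri$F_B$matrix, modes_B)$matrix
  ref <- abs(dA) / sqrt(tcrossprod(abs(modes_B$lambda)))
  up <- upper.tri(xi)
  expect_equal(cor(xi[up], ref[up], method = "spearman"), 1)
})

test_that("expected CMA-2 error is non-increasing as the cutoff tightens", {
  cuts <- c(Inf, 0.1, 0.05, 0.02, 0.01, 1e-9)
  maes <- matrix(NA_real_, 30, length(cuts))
  for (t in 1:30) {
    toy <- make_toy_molecule(toy_kinds[((t - 1) %% 4) + 1], seed = 700 + t)
    tri <- quiet_triple(toy$F, rho = 0.9, seed = 800 + t)
    for (c in seq_along(cuts)) {
      r <- cma_run(tri$F_A, tri$F_B, toy$G, "cma2", F_C = tri$F_C,
                   cutoff = cuts[c])
      maes[t, c] <- mean(abs(r$residuals))
    }
  }
  avg <- colMeans(maes)
  expect_true(all(diff(avg) <= 1e-12))
  # rank correlation between cutoff index and mean MAE is strongly negative
  expect_lt(cor(seq_along(cuts), avg, method = "spearman"), -0.9)
  # exactness at cutoff ~ 0
  expect_lt(avg[length(cuts)], 1e-8)
})
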