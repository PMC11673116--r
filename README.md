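# cmavib — Concordant Mode Approach for harmonic vibrational frequencies

`cmavib` implements harmonic vibrational analysis in natural internal
coordinates (NICs) and the **Concordant Mode Approach (CMA)**: computing a
high-level ("Level A") vibrational force field in the normal-mode basis of a
cheaper "Level B" theory, evaluating only selected force constants
explicitly. It is aimed at computational chemists who need near-benchmark
harmonic frequencies for molecules where a full high-level Hessian is out of
reach.

## The method

For a complete nonredundant set of internal coordinates **S**, the Wilson GF
eigenproblem at Level B,

    G F_B L_B = L_B Λ_B,   G = B u Bᵀ,   S = L_B Q_B,

yields the *concordant modes* Q_B. The Level-A force field is then composed
through the ansatz

    F_A = (L_B⁻¹)ᵀ F_CMA(A) L_B⁻¹,

where F_CMA(A) is the Level-A force-constant matrix expressed in the Q_B
basis. Because normal modes nearly diagonalize the potential, F_CMA(A) is
strongly diagonal-dominant:

* **CMA-0** keeps only the diagonal of F_CMA(A);
* **CMA-1(n)** adds n hand-picked off-diagonal couplings;
* **CMA-2** selects couplings automatically: a cheap auxiliary "Level C"
  field is transformed to the Q_B basis and cast into the dimensionless
  diagnostic ξᵢⱼ = |F^C_ij| / √(|F^C_ii F^C_jj|); every element with
  ξᵢⱼ above a user cutoff is computed explicitly at Level A. The
  transformation is exact when all elements are included, so CMA-2 converges
  to the true Level-A frequencies as the cutoff tightens.

The cost proxy is η = 100 · (number of included off-diagonals) /
(vibrational degrees of freedom), roughly the percent cost increase over
CMA-0.

The package also provides fourth-order-accurate finite-difference
force-constant assembly with symmetry enforcement, iterative
back-transformation of normal-mode displacements to Cartesian geometries,
total energy distributions (TEDs), benchmark residual statistics, and a
seeded generator of correlated Level A/B/C force-field triples so the entire
pipeline runs without an electronic-structure engine.

## Worked example

A synthetic six-membered-ring system with a correlated A/B/C triple:

```r
library(cmavib)

toy <- make_toy_molecule("planar_ring", seed = 1)
tri <- make_level_triple(toy$F, rho = 0.9, sparsity = 0.12, seed = 2)

# diagonal-only CMA-0
cma_run(tri$F_A, tri$F_B, toy$G, "cma0")
#> CMA result (cma0): 12 modes, 0 off-diagonals (eta = 0.0%)
#>   max |residual| = 0.4212 cm^-1, MAE = 0.07796 cm^-1, ZPVE residual = 0.2853 cm^-1

# convergent CMA-2 with a xi cutoff of 0.02
r2 <- cma_run(tri$F_A, tri$F_B, toy$G, "cma2", F_C = tri$F_C, cutoff = 0.02)
r2
#> CMA result (cma2): 12 modes, 2 off-diagonals (eta = 16.7%)
#>   max |residual| = 0.07874 cm^-1, MAE = 0.02555 cm^-1, ZPVE residual = 0.08216 cm^-1
r2$selection
#>      i  j
#> [1,] 2 11
#> [2,] 2 12
```

The diagonal-only run already reproduces the Level-A frequencies to a mean
absolute error of 0.078 cm⁻¹; the ξ diagnostic then flags two mode couplings
(a 17% cost increase) that cut the worst-case error from 0.42 to
0.08 cm⁻¹. A cutoff sweep shows the convergent behaviour:

```r
convergence_curve(list(list(F_A = tri$F_A, F_B = tri$F_B, F_C = tri$F_C,
                            G = toy$G, dof = 12)),
                  cutoffs = c(Inf, 0.05, 0.02, 1e-9))
#>   cutoff     eta pct_offdiag   mae eps_max eps_MAX
#> 1    Inf   0.000        0.00 0.078   0.421   0.421
#> 2   0.05   0.000        0.00 0.078   0.421   0.421
#> 3   0.02  16.667        3.03 0.026   0.079   0.079
#> 4   0.00 550.000      100.00 0.000   0.000   0.000
```

The terminal row is exact (MAE = 0) because the back-and-forth
transformation between the S and Q_B bases is an identity once every
element is kept.

File-driven runs use `run_config()` / `run_protocol()` on XYZ geometries,
NIC definition files and plain-text Hessians, or the thin command-line
front end `inst/exec/concordant` (`freq`, `cma0`, `cma1`, `cma2`, `synth`
subcommands). Packaged NIC sets for pyridine (27 coordinates, C2v labels)
and 1-(1H-pyrrol-3-yl)ethanol (45 coordinates) ship under `inst/extdata/`
with idealized synthetic geometries.

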