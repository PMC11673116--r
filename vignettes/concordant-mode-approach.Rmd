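---
title: "The Concordant Mode Approach in cmavib: model, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Concordant Mode Approach in cmavib}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmavib)
```

## The problem and the model

Computing harmonic vibrational frequencies at a high level of electronic
structure theory requires the full quadratic force field — a cost that grows
quadratically in the number of atoms when assembled from single-point
energies. The Concordant Mode Approach (CMA) exploits the fact that normal
modes nearly diagonalize the potential: the force field of an expensive
"Level A" theory, expressed in the normal-mode basis of a cheaper "Level B"
theory, is strongly diagonal-dominant, so only a handful of its elements
need to be computed explicitly.

The machinery is Wilson's GF method in a complete, nonredundant set of
natural internal coordinates (NICs) $S$. With $B = \partial S/\partial x$
and $u$ the diagonal matrix of reciprocal atomic masses,

$$G = B\,u\,B^{\mathsf T}, \qquad
  G F_B L_B = L_B \Lambda_B, \qquad S = L_B Q_B .$$

`solve_gf()` fixes the eigenvector normalization through the symmetric
square root $W = G^{1/2}$: $L_B = W C$ with $C$ the orthonormal
eigenvectors of $W F_B W$, so that
$L_B^{\mathsf T} F_B L_B = \Lambda_B$ and
$L_B^{-1} G L_B^{-\mathsf T} = I$. No convention for $L_B$ is canonical;
any choice consistent with $S = L_B Q_B$ yields identical frequencies (the
test suite asserts this through the congruence round-trips). Frequencies
follow from $\omega_i = \kappa\sqrt{\lambda_i}$, with $\kappa$ assembled at
call time from CODATA-2018 constants for the internal unit system
(angstrom, amu, attojoule); imaginary modes are encoded as negative cm$^{-1}$
values, the common spectroscopic convention.

The CMA ansatz composes the Level-A internal-coordinate field from its
$Q_B$-basis representation:

$$F_A = (L_B^{-1})^{\mathsf T}\, F_{\mathrm{CMA}}(A)\, L_B^{-1},$$

which is exact when all of $F_{\mathrm{CMA}}(A)$ is kept and reduces to the
protocols

* **CMA-0** — diagonal elements only (by construction
  $F_{\mathrm{CMA}}(B) = \Lambda_B$ exactly, so A = B gives zero residuals);
* **CMA-1(n)** — diagonal plus $n$ hand-picked couplings;
* **CMA-2** — diagonal plus all couplings whose $\xi$ diagnostic exceeds a
  cutoff.

## The ξ diagnostic

An auxiliary Level C (cheaper than B, e.g. the uncorrelated reference
underlying a correlated Level B) is transformed to the $Q_B$ basis. Since
$F_{\mathrm{CMA}}(B)$ is strictly diagonal, the large off-diagonals of
$F_{\mathrm{CMA}}(C)$ mark the couplings most sensitive to raising the level
of theory from C to B — and, by extension, the ones expected to matter in
going from B to A ("photographic negative" reasoning: magnitudes track, signs
need not).

The published rendering of the defining equation for $\xi$ is a figure whose
algebraic content is not recoverable from the text we worked from; the prose
constrains it to be dimensionless and normalized by "the associated diagonal
force constants". `xi_matrix()` therefore implements the normalization as an
explicit strategy recorded in the object's provenance:

* `"diag"` (default): $\xi_{ij} = |F^C_{ij}| / \sqrt{|F^C_{ii} F^C_{jj}|}$ —
  the geometric-mean normalization, with absolute values guarding sign
  anomalies;
* `"lambdaB"`: normalization by the Level-B eigenvalues
  $\sqrt{\lambda_{Bi}\lambda_{Bj}}$ instead.

Both are invariant under overall scaling of $F^C$. Selection uses a strict
"greater than" comparison, so selections are nested in the cutoff and
`cutoff = Inf` reproduces CMA-0 exactly. The cost proxy
$\eta = 100\,n_{\text{off}}/\mathrm{DOF}$ is reported at full precision and
rounded only for display. The residual convention is fixed as
$\epsilon = \omega_{\mathrm{CMA}} - \omega_{\mathrm{ref}}$, and the default
outlier threshold used in discussion is 1.5 cm$^{-1}$ in magnitude.

## Internal coordinates and their derivatives

Five primitive kinds are supported — bonds, angles, torsions,
out-of-plane wags, and linear bends — with analytic B-matrix rows
(`primitive_b_row()`); a five-point numerical derivative of the coordinate
value serves as an independent oracle in the tests, never as the
implementation. Conventions that were genuinely open and are now fixed:

* torsions follow the IUPAC right-handed convention on $(-\pi, \pi]$, with
  values within $10^{-10}$ of $-\pi$ mapped to $+\pi$;
* the out-of-plane angle $\gamma(i,j,k,l)$ is positive when the $i$–$j$ bond
  lies on the side of the $k$–$j$–$l$ plane given by
  $(j\!\to\!k)\times(j\!\to\!l)$;
* linear bends measure the bending of a near-linear $i$–$j$–$k$ chain
  against a reference perpendicular vector; the reference is frozen from the
  load-time geometry (or supplied explicitly) so the coordinate definition
  does not drift during displacements. A degenerate pair with perpendicular
  references spans the two bending directions — needed only for linear
  molecules such as nitrous oxide;
* atom indices are 1-based in all files and converted at the I/O boundary.

NIC files list "unnormalized" chemically intuitive combinations; rows are
normalized to unit Euclidean norm on load so that a displacement of
"0.01 in NIC units" is well defined, while raw coefficients are preserved
for provenance. Unit-norm is our choice — the published coordinate tables
state no normalization for displacement purposes.

Rank diagnostics (`check_nonredundancy()`) treat singular values below
$10^{-8}$ of the largest as zero. The Cartesian-to-internal Hessian
transform omits the gradient term, which vanishes at stationary points — the
intended use; a warning fires if a supplied gradient norm exceeds
$10^{-6}$ aJ/Å.

## Back-transformation and finite differences

`back_transform()` maps a normal-mode displacement to Cartesians by
iterating $\delta x = u B^{\mathsf T} G^{-1}\,(S_{\mathrm{target}} - S(x))$
with $B$ and $G$ refreshed every step, converging to
$|S - S_{\mathrm{target}}| < 10^{-12}$ (cap 50 iterations; torsion residuals
are wrapped into $(-\pi,\pi]$ near the branch cut). Displacement planning
tightens this to $10^{-13}$ so stencil sums are not limited by the geometry
solve.

Finite differences default to a step of 0.01 NIC units and fourth-order
stencils: a five-point central second-derivative formula on the diagonal and
the tensor product of two four-point first-derivative stencils (the
$\pm 1, \pm 2$ grid) for mixed elements, exact for polynomials through
degree five. A 0.005 step and second-order stencils are available per
element; the literature offers "0.01 or 0.005" without a per-type rule, so
one global default with overrides seemed right. The mixed-derivative stencil
itself is not specified anywhere we could check — only its order of
accuracy — so the tensor-product form was chosen for its simple exactness
proof, and the weights are validated by the polynomial and Richardson tests.
Symmetry enforcement zeroes force constants coupling different irreducible
representations; modes alone in their irrep are then exact under every CMA
protocol, which the tests verify on the pyridine $a_2$ block.

## The synthetic generator

`make_level_triple()` emulates the statistical structure CMA-2 exploits,
nothing more. Starting from a positive-definite Level-A field, a sparse
symmetric perturbation $\Delta$ (element magnitudes scaled by
$\sqrt{F_{ii}F_{jj}}$ and drawn log-uniformly over 0.005–0.2, the ξ
operating range seen in practice) defines
$F_B = F_A + \alpha\Delta$, and
$F_C = F_B + \beta\,(\rho\,(-\Delta) + (1-\rho)\,\mathrm{Noise})$. At
$\rho = 1$ the ξ ranking from Level C reproduces the ranking of the A–B
coupling differences exactly; $\rho = 0.9$ — the default for ensemble
studies — leaves the diagnostic informative but imperfect, which is the
regime where the method's value shows. If $F_B$ loses positive definiteness,
$\alpha$ is halved with a message until it is restored. All generators take
an explicit seed and restore the caller's RNG state.

What the generator does *not* emulate: basis-set or correlation physics,
anharmonicity, geometry relaxation between levels, or realistic mode-mixing
patterns of any particular molecule class. Passing tests therefore
demonstrate the algebra, the selection logic and the convergence behaviour
of the implementation — not the accuracy of CMA for real electronic
structure data, which depends on how well a real Level C anticipates the
A–B difference.

Ensemble studies in the tests and the acceptance script use 50 systems of
4–6 atoms (3–12 vibrational modes each, roughly 300 frequencies per
ensemble); these sizes keep a full study under a couple of minutes on one
core while still giving stable paired comparisons between ξ-guided and
random coupling selection.

## TEDs and statistics

The total energy distribution of mode $k$ over coordinates is
$\mathrm{TED}_{ik} = 100\,L_{ik}\,(F L)_{ik}/\lambda_k$, the standard
decomposition of the classical vibrational energy; signed entries sum to
100 per mode. (The original TED reference formula is cited but not
reproduced in the text we worked from; the standard form above is adopted
and labelled as such.) Display follows the usual style: contributions of at
least 5% in magnitude, signed, largest first.

`summary_stats()` reports MAE, signed mean, sample standard deviation
($n-1$ denominator — a documented choice, not a published one), the average
per-molecule maximum absolute residual, and the global maximum. The ZPVE
residual of any CMA run equals half the signed residual sum — an identity
used as a consistency check, with no claim about the magnitude of error
cancellation in real data.

## Packaged fixtures and known limitations

The pyridine NIC set (27 coordinates, $C_{2v}$ labels, block sizes
10/3/5/9) and the 45-coordinate set for 1-(1H-pyrrol-3-yl)ethanol are
transcribed from the published coordinate tables. Two caveats, both noted
in the fixture documentation: the geometries shipped are idealized
synthetic stand-ins (regular-hexagon pyridine; an assembled idealized
conformer for the ethanol derivative — a perfectly tetrahedral methyl was
deliberately avoided because it makes the umbrella coordinate degenerate to
first order), and the five-ring combination constants for the latter are
the standard ring-symmetry values $\cos 144°$, $\cos 72°$, $\sin 144°$,
$\sin 72°$, reconstructed because the defining footnote is not present in
our source text.

Other limitations: no automatic NIC generation from connectivity, no
redundant-coordinate machinery, no anharmonic corrections, and no bundled
electronic-structure engine — external energies enter through the
displacement-plan JSON contract (`write_plan_json()` /
`assemble_force_constants()`), and engine convergence settings are the
adapter's business, not this package's. Reproducing published benchmark
statistics for real molecule sets requires exactly such engine data and
lies outside the test suite by design.
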