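---
title: "Methods: the APY model family and its equivalences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the APY model family and its equivalences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apyblup)
```

## The problem

Genomic evaluation of a population with `n_gt` genotyped animals can be
parameterized either by breeding values, with covariance proportional to
the genomic relationship matrix `G = kZZ'`, or by marker effects with
identity covariance. The breeding-value route needs `G⁻¹`, which is cubic
in `n_gt`; the Algorithm for Proven and Young (APY) replaces `G⁻¹` with a
structured sparse inverse built from a small *core* subset of animals.
`apyblup` implements the whole family of APY-based models — breeding-value
and marker-effect parameterizations, with and without a residual polygenic
effect, for genotyped-only and single-step (mixed genotyped/non-genotyped)
populations — with the goal of making their exact algebraic equivalences
checkable, not of scaling to national evaluations.

## Model and assumptions

The APY recursion writes non-core breeding values as a regression on the
core, `u_n = P_nc u_c + ξ`, with `P_nc = G_nc G_cc⁻¹` and
`Var(ξ) = M_nn σ_u²` taken to be *diagonal*: conditional on the core,
non-core animals are treated as independent. `M_nn` is the diagonal of the
Schur complement `G_nn − G_nc G_cc⁻¹ G_cn`. Everything else follows from
this single approximation:

* **APY-GBLUP** solves Henderson's equations with the structured
  `G_APY⁻¹` (`gApyInverse()`), or equivalently the partitioned system in
  `(b, u_c, ξ)` (`solveApyGblupPartitioned()`).
* **APY-SNP-BLUP** replaces non-core genotypes by their projection onto
  the core genotype row space, `Z† = [Z_c; Z_n𝒫]` with
  `𝒫 = Z_c'(Z_cZ_c')⁻¹Z_c`, and fits `(b, a, ξ)`
  (`solveApySnpBlup()`). When the core spans the full row space of `Z`,
  `M_nn = 0`, `ξ ≡ 0` and the model collapses onto plain SNP-BLUP.
* **Residual polygenic variants** split the genetic variance,
  `G* = (1−β)kZZ' + βA₂₂`; on the marker side the genotype matrix is
  augmented with the scaled Cholesky factor of `A₂₂` and a core polygenic
  vector `ε` with covariance `βA_cc σ_u²` is fitted.
* **Single-step variants** extend either parameterization to
  non-genotyped animals through `H_APY` (pedigree prediction of genotyped
  relatives, plus an imputation error `η` with covariance `(A¹¹)⁻¹σ_u²`
  on the marker side).

Assumptions inherited from the theory: genotypes have passed quality
control (the loaders reject missing calls unless mean-imputation is asked
for), the phenotype model is `y = Xb + Wu + e` with one animal per record
and known variance components, and `X` has full column rank (checked;
rank-deficient designs are rejected rather than constrained).

A deliberate implementation decision is that **every mixed-model system is
assembled by one generic normal-equations builder** from the model
statement (stacked record-level designs plus block penalties), rather than
by transcribing each printed coefficient matrix. This guarantees the
assembled systems are the normal equations of the stated models — the
cross-blocks can never disagree with the designs — and sidesteps
typesetting ambiguities in the more baroque four- and five-block systems.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `k` | `1/(2Σp_jq_j)` | scaling making `G` comparable to pedigree relationships (unitless); a user constant is accepted |
| allele frequencies | observed | centering frequencies; persisted in a sidecar so later cohorts are centered identically |
| `nCore` | user-chosen | core size; the theory assumes `n_core ≤ m`, warned otherwise |
| `beta` | 0 | residual polygenic fraction of the genetic variance, in [0, 1] |
| `sigmaU2`, `sigmaE2` | user inputs | variance components (no REML estimation is attempted) |
| `condLimit` | 1e10 | condition-number bound on `G_cc` before the decomposition refuses |
| `xiDropTol` | `1e-8 × mean diag` | below this conditional variance a non-core error term is fixed at zero |
| `mnnFloor` / `clampMnn()` | off | positive floor on `M_nn` defining a nearby non-degenerate APY model |

Centering consistency matters more than it looks: indirect predictions are
only *identities* when the new cohort is centered and scaled with the
stored `(p, k)` pair, so `centerWithSidecar()` refuses to proceed without
both values.

## Numerical choices

* **Solver.** Dense symmetric solves with one step of iterative
  refinement; refinement matters when `M_nn⁻¹` penalties are large. No
  iterative/preconditioned solvers: the package targets desk scale, where
  exactness of the equivalences is the point.
* **Degenerate conditional variances.** When a non-core genotype lies in
  the core row space, `M_nn = 0` and `G_APY` is singular. Two consistent
  treatments are provided: *drop* the error term (`xiDropTol`, the limit
  model, default in the solvers) or *floor* it (`clampMnn()`), which
  defines a nearby model in which all formulations remain exactly
  equivalent. The equivalence tests at full core rank use a floor of
  `1e-3` on a unit-diagonal `G`: large enough that the `M_nn⁻¹` penalties
  stay at ~1e3 and the materialized structured inverse remains accurate,
  small enough to stay close to the limit.
* **Symmetrization.** All relationship matrices are symmetrized
  (`(M + M')/2`) after assembly; the class validity check allows 1e-12
  relative asymmetry.
* **Tiny negative Schur diagonals** from roundoff are clamped to zero;
  genuinely negative values (non-PSD source) raise an error.
* **Ordering.** Core animals first, then non-core; in single-step models
  non-genotyped animals precede the genotyped block. All solution vectors
  are named by animal id, so external order never matters.
* **PEV scale.** `pevBlock()` returns observed-scale PEV
  (`σ_e² ×` inverse-LHS block); the back-solving and reliability formulas
  operate on the `σ_u² = 1` relationship scale, with `pevRelScale()` as
  the converter.

## What the simulator emulates — and what it does not

`simulatePopulation()` produces a multi-generation pedigree by random
non-selfing matings, founder genotypes at Hardy–Weinberg proportions with
MAF uniform on (0.15, 0.5), Mendelian gene dropping down the pedigree,
true marker effects drawn with variance `(1−β)kσ_u²`, an optional pedigree
polygenic term, and repeated records with residual variance set from the
heritability (default h² = 0.5, σ_u² = 1). Defaults give ~57 animals and
40 markers; the test suite uses sets of 20–50 genotyped animals and 30
markers, and a ~43-animal pedigree with 25 genotyped for single-step
checks — sizes chosen so every suite solves densely in seconds.

The simulator deliberately omits linkage disequilibrium (loci are
independent), selection and assortative mating, genotyping error and
missingness, and sequence-level structure. Passing equivalence tests on
these data therefore demonstrates the *algebra* — the formulations are the
same model — for essentially arbitrary relationship structures; it says
nothing about predictive accuracy on real livestock data, where LD,
selection history and core choice dominate.

## Open choices made

* Core selection is uniform random under a seed (or a user list); the
  spectrum-coverage heuristics in the literature are summarized only by a
  diagnostic (`coreSpectrumFraction()`), not implemented as an algorithm.
* The Cholesky factor of `A₂₂` is exact; approximate factors are out of
  scope.
* `A⁻¹` and `A₂₂⁻¹` are dense inverses — correct and simple at desk
  scale; sparse pedigree machinery would obscure the reference
  implementation.
* Marker weights (heteroscedastic marker prior) are supported for the
  genotyped-only models: `G = kZDZ'` pairs with penalty `D⁻¹γ` and the
  oblique projector `DZ_c'(Z_cDZ_c')⁻¹Z_c`, preserving all equivalences.
  They are not combined with the polygenic augmentation.

## Limitations

Dense algebra throughout: memory is quadratic and solves cubic in the
number of animals (or markers), so a few thousand animals is a practical
ceiling. Variance components are inputs, not estimates. Single records
carry no permanent-environment effect, and multi-trait models are not
implemented.
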