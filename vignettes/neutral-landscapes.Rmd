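---
title: "Robustness and recombination on neutral fitness landscapes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Robustness and recombination on neutral fitness landscapes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(neutralnets)
```

## The model

We consider haploid genomes with `L` diallelic loci, so genotypes are the
`2^L` vertices of a binary hypercube and the Hamming distance counts the
point mutations separating two genotypes. Each genotype carries a Wrightian
fitness `w` in `[0, 1]`; the *neutral* landscape models used throughout are
two-level, `w ∈ {0, 1}`, so that selection only removes lethal genotypes and
is blind among viable ones. The population is infinite and evolves in
discrete non-overlapping generations through three steps in fixed order:

1. **Selection.** `q = w f / w̄` with `w̄ = Σ w f`. A population entirely on
   lethal genotypes is extinct; solvers raise an error rather than continue.
2. **Mutation.** Every locus mutates independently and symmetrically with
   probability `μ` per generation, giving the kernel
   `U[σ,κ] = (1−μ)^(L−d(σ,κ)) μ^d(σ,κ)`. The operator factorizes into `L`
   rank-two per-locus updates, which is how it is applied (the dense matrix
   is only built for `L ≤ 12`, mostly for cross-checks).
3. **Recombination.** With probability `1−r` an individual is a parental
   clone; with probability `r` it is a recombinant. Uniform crossover draws
   each offspring locus from either parent with probability 1/2; one-point
   crossover cuts at one of the `L−1` positions uniformly and joins the
   complementary segments (both parent orders); the communal scheme
   assembles each locus from a parent drawn anew from the whole population,
   which enforces linkage equilibrium in one step.

Stationary states `f*` are fixed points of the composed map. The two
summary statistics are the population robustness
`m = Σ_{σ∈V} (n_σ/L) f*_σ` — the average fraction of viable point mutations,
with mass on lethal genotypes contributing zero — and the recombination
weight `λ_σ = 2^{-L} Σ_{κτ} R_{σ|κτ} w_κ w_τ`, whose maximizer is the
*recombination center*. The weight is linear in `r` (the tensor is), sums
to `|V|²/2^L` on neutral landscapes, and at `r = 0` reduces to the
genotype's own fitness times the unweighted mean fitness.

Robustness `m_σ = n_σ/L` is computed for every genotype, lethal ones
included (the multistability scan seeds delta distributions on every
genotype with `m_σ ≠ 0`); population averages run over viable genotypes
only. On graded landscapes a neighbour counts as viable iff `w > 0`,
matching the convention that "lethal" means exactly zero fitness.

`m` is measured at the generation boundary, i.e. on the state after the
recombination step, which is where stationarity is defined. The lumped
solvers additionally expose the after-selection (`M_nr`) and after-mutation
(`m_nr`) measurements because the two differ at order `U` and both appear
in the asymptotic analysis.

## Landscape generators

* `make_mesa(L, k)`: viable iff within `k` mutations of the all-zero wild
  type. `k` is the plateau (mesa) width.
* `make_percolation(L, p, seed)`: i.i.d. viable with probability `p`.
  Landscapes with empty viable sets are legal objects — the ensemble
  average behind the uniform baseline needs them — but solvers reject them.
* `make_seacliff(L, refs, d_lt, d_gt, seed)`: genotype viable iff a
  Gaussian threshold variable `η ~ N(c, s²)`, drawn independently per
  (genotype, reference) pair, exceeds the distance to the reference;
  viability with respect to any reference suffices. The calibration
  `c = (d_lt + d_gt)/2`, `s = 0.215 (d_gt − d_lt)` places mean viability at
  0.99 and 0.01 at the two given distances; the constant 0.215 is the
  conventional rounding of `1/(2√2 erf⁻¹(0.98))` and is used as such.
  Sharpening the cliff (`d_gt − d_lt → 0` with `k < c < k+1`) reproduces
  the mesa; widening it indefinitely approaches percolation.
* `make_atoll(L, inner, outer)`: viable ring `inner ≤ d ≤ outer`. This is
  the standard counterexample in which the recombination center (the lethal
  wild type inside the ring) decouples from robustness.
* `make_aniger_standin(seed)`: a synthetic `L = 8` landscape with exactly
  186 graded-fitness viable genotypes and 70 lethal ones, wild type fittest,
  fitness decaying on average by factor 0.92 per mutation with uniform
  multiplicative noise on `[0.8, 1]`. The empirical eight-locus fungal
  landscape it is shaped after has unpublished fitness values; this object
  reproduces only its dimensions and qualitative profile and is labeled
  synthetic in its metadata. Conclusions drawn from it concern the
  *protocols* (reset sweeps, weight/robustness correlations), not the
  organism.

All generators are deterministic under a fixed seed and save/restore the
caller's RNG state.

## Fast recombination steps

The recombination step never materializes the `8^L` tensor (that is only
built, for `L ≤ 8`, as a reference object for tests). Uniform crossover at
full strength is evaluated in Walsh–Hadamard coordinates, where it becomes
the subset convolution `f̂(S) = 2^{−|S|} Σ_{A⊆S} p̂(A) p̂(S∖A)` with `3^L`
terms; one-point crossover is an average over cut positions of outer
products of prefix/suffix marginals, `O(L 2^L)`; the communal projection is
the product measure of the per-locus allele frequencies. All three
preserve per-locus allele frequencies exactly, and the `r < 1` step is the
`r`-mixture with the identity. For the communal scheme the paper-level
definition only fixes the full-strength behaviour; the `r`-mixture is this
package's interpolation, chosen because it reduces correctly at both
endpoints and mirrors the clonal term of the pairwise schemes.

## Stationary-state solvers

The basic solver is fixed-point iteration of the generation map with a
max-norm tolerance of `1e-13` per generation and an iteration cap of `1e6`;
non-convergence is reported in the result object, not raised, because
near-critical parameter combinations relax arbitrarily slowly. Two
refinements matter in practice:

* **Without recombination the map is linear**, and its unique fixed point
  is the Perron eigenvector of `U·diag(w)`. That operator is similar to the
  symmetric `W^(1/2) U W^(1/2)`, so the default solver computes the fixed
  point by a symmetric eigendecomposition on the viable support (the exact
  limit of power iteration). This matters because landscapes with several
  nearly degenerate neutral clusters have spectral gaps of order `μ²`:
  plain iteration needs upwards of `10^7` generations there, while the
  eigensolution is exact and instantaneous. `method = "iterate"` remains
  available and the two agree to `~1e-12` on rugged test landscapes.
* **With recombination the map is nonlinear** and the same slow modes
  appear as slowly decaying transients. The solver therefore punctuates
  plain iteration every 2000 generations with a damped Newton refinement of
  the fixed-point residual (forward-difference Jacobian, simplex-sum
  constraint row, steps capped at max-norm 1, trial points projected back
  onto the simplex, best iterate kept only if it beats plain iteration).
  Warm-started sweep points typically finish in a handful of Newton steps
  with residuals below `1e-13`.

Because the `r > 0` dynamics can have several attractors, the sweep
protocols fix the initial condition explicitly: the *warm-start* protocol
follows the branch smoothly connected to the unique non-recombining state
(uniform start at `r = 0`, then each stationary state seeds the next grid
point), while the *reset* protocol restarts from the uniform distribution
at every grid point, which on graded landscapes avoids trapping on the
fitness peak. The default grid increment is 0.02; the multistability scan
clusters stationary states at max-norm distance `1e-6`, far below anything
the dynamics distinguishes and far above solver residuals. Frequency
vectors are renormalized once per generation, with a warning if the
pre-normalization drift exceeds `1e-9`.

## Lumped Hamming-class dynamics

On permutation-symmetric landscapes (mesa, atoll) the dynamics without
recombination — and with communal recombination — closes on the `L+1`
Hamming-class frequencies, which is what makes `L = 1000` tractable. The
class mutation kernel is either exact (convolution of reversion and
forward-mutation binomials) or the single-flip approximation
`P(d→d±1) = (L−d)μ, dμ` valid for `U = Lμ ≪ 1`. Selection truncates
classes beyond `k` and renormalizes, which is exact for two-level fitness.

The non-recombining stationary state is the Perron eigenvector of the
truncated selection∘mutation operator. Numerically this operator is
severely non-normal at large `L` (up-couplings `(L−d)μ` dwarf
down-couplings `dμ`), and a naive nonsymmetric eigendecomposition returns
pseudo-eigenvectors: in double precision it yields a state whose robustness
is off by 0.19 at `L = 1000`. The class chain is, however, reversible with
respect to the binomial(1/2) measure `π_d ∝ C(L,d)`, so the operator is
diagonally similar to the symmetric matrix `S[d,d'] = √(K[d→d'] K[d'→d])`.
The solver diagonalizes `S` and recovers the state as
`q_d ∝ √C(L,d) · u_d`, with the binomial weights evaluated in log space.
The result is confirmed by (i) exact agreement with the full-hypercube
solver for `L ≤ 10`, (ii) `U`-independence of `M_nr` to `1e-6` in the
single-flip regime, and (iii) the two-locus limit `M_nr → 1/√2`.

The communal solver iterates truncation, class mutation, and the binomial
projection `f ← Binom(L, x)` with `x` the post-mutation mean mutant-allele
frequency; the projection conserves `x` and total mass. At `L = 2` this
scheme coincides exactly with the full-crossover closed form, which the
tests exploit as a dual-route check.

Closed-form companions: `hermite_yk(k)` returns `y_k = 2z²` with `z` the
largest zero of the physicists' Hermite polynomial `H_{k+1}`, computed from
the Gauss–Hermite Jacobi matrix (Golub–Welsch). The convention — "`√(y_k/2)`
is the largest zero" — is pinned down by two independent checks: `y_1 = 1`
reproduces the exact two-locus `M_nr = 1/√2`, and `y_k/4k → 1` reproduces
the large-`k` behaviour. The after-selection/after-mutation link is read as
`m_nr = M_nr(1−U) + M_nr² U`, the only reading consistent with the
large-`L` forms, and the joint-limit robustness is `2√(x(1−x))` for
`x = k/L < 1/2` and 1 beyond (continuous at `x = 1/2`, small-`x` limit
`2√(k/L)`).

## Two-locus closed forms

The `L = 2` landscape with the double mutant lethal reduces to a cubic in
the post-selection wild-type frequency `q0`; the package solves it with
`polyroot` and keeps the root in `[0, 1]` (if several qualify, the one
continuously connected to the `ρ = 0` branch — not observed in the valid
domain). The effective parameter is `ρ = r` for one-point and `ρ = r/2`
for uniform crossover; this unification is a two-locus coincidence, so `ρ`
is deliberately kept internal to the two-locus module and the conversion is
exposed as `rho_from_r()`. Exact radicals for the `ρ ∈ {0, 1}` frequencies
and robustness are implemented independently and used as cross-checks of
the cubic route; printed series coefficients of those radicals are treated
as documentation only, since the exact forms are authoritative. The
critical recombination rate solves `m(μ, ρ_c) = 1/√2` by bisection; the
analytic expansion is `ρ_c = 2(5+4√2) μ²`.

## Wright–Fisher simulator

The finite-`N` check fuses selection and resampling into one multinomial
draw with weights `w·counts`, applies exact per-individual mutation, and
recombines by random pairing without replacement (two offspring per pair,
one per parent order, each a recombinant with probability `r`), or by
per-individual communal resampling. No finite-`N` pairing rule is implied
by the infinite-population model; this choice reduces to the deterministic
tensor contraction in expectation as `N → ∞`. All-lethal generations — a
real possibility at small `N` — restart from the last viable composition
and are counted rather than aborted. Burn-in defaults to
`min(10/μ, 1e5)` generations (about ten expected substitutions), a
package default rather than a derived quantity; the reported standard
error comes from replicate means or, for single replicates, from ten
batch means and therefore underestimates long autocorrelations — the tests
use it only with wide margins.

The informative parameter is `NμL`: well below 1 the population is
monomorphic, performs a neutral random walk on the viable network with
uniform per-edge rates, and shows the uniform baseline robustness; well
above 1 it tracks the deterministic stationary state.

## Problem sizes and what the tests show

The test suite runs on deliberately small instances chosen to make the
checks sharp rather than impressive: full-hypercube dynamics at `L ≤ 10`,
lumped solvers up to `L = 1000`, a 100-landscape percolation ensemble at
`L = 6, p = 0.4, μ = 0.001` with grid `{0, 0.5, 1}` (the ensemble ordering
"recombination > selection > uniform baseline" is a property of the
endpoint averages, so a dense grid adds nothing), a `10^4`-landscape
Monte-Carlo for the percolation baseline at `L = 4`, and Wright–Fisher runs
at `N = 30` (monomorphic regime, `1.5×10^5` generations) and `N = 5×10^4`
(polymorphic regime). The synthetic-data generators emulate the *structure*
of the studied landscape classes — they do not model epistasis beyond
viability, multi-allele loci, fitness measurement noise, or linkage maps
with unequal recombination rates, so green tests certify the solvers and
the stated asymptotics, not biological realism of any particular system.

## Known limitations

* Two alleles per locus only; `μ` homogeneous across loci and directions.
* Full-hypercube solvers are limited to `L ≤ 25` in principle and are
  comfortable up to `L ≈ 12`; beyond that only permutation-symmetric
  landscapes are supported (lumped solvers).
* The lumped module covers no-recombination and communal schemes; uniform
  and one-point crossover do not close on Hamming classes.
* `max_robustness` maximizes over viable genotypes, the reading consistent
  with robustness being defined within the viable set; lethal genotypes can
  in principle have more viable neighbours, but they cannot carry
  stationary population mass.
* The Newton refinement assumes a locally smooth fixed point; in the rare
  event it fails to improve the residual the solver falls back to plain
  iteration and reports non-convergence honestly.
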