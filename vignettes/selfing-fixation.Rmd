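---
title: "Fixation of mutant alleles under partial selfing: models and methods"
author: "selfix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fixation of mutant alleles under partial selfing: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(selfix)
```

## The model

`selfix` studies the fate of a single mutant allele `a` (ancestral allele
`A`) at one nuclear locus in a hermaphroditic plant population with
alternation of generations. The life cycle runs, in order: production of
haploid ovules and pollen, **gametophytic selection** on those gametes, a
**mixed mating system** (a fraction `alpha` of seeds from selfing, `1 -
alpha` from random outcrossing), seed formation, one-way **mutation**
`A -> a` at rate `mu` (irreversible: no back-mutation), **sporophytic
selection** on diploid genotypes, and finally genetic drift in a population
of `N` plants.

The two phases carry separate selection parameters with opposite sign
conventions, kept exactly as the field writes them:

* gametophyte: mutant ovule fitness `1 - sO`, mutant pollen fitness
  `1 - sP`; *deleterious means positive* coefficients. Only the composite
  `shap = sO + sP` enters the first-order dynamics.
* sporophyte: genotype fitnesses `1`, `1 + shet`, `1 + shom` for `AA`,
  `Aa`, `aa`; *deleterious means negative* coefficients.

`classify_selection()` names the joint regime (gametophyte-only,
sporophyte-only, antagonistic, synergistic) so that sign mistakes surface
immediately rather than as silently wrong results.

At a constant selfing rate the inbreeding coefficient equilibrates at
`Fis = alpha / (2 - alpha)`, the fixed point of `Fis' = alpha (1 + Fis)/2`.
All analytic formulas in the package use this equilibrium value; the
simulator instead tracks true genotype frequencies, which is one of the
ways the analytic approximations get checked.

## The one-generation recursion and its weak-selection form

`step_generation()` advances adult genotype frequencies through the full
cycle. The selfing part unites gametes within each plant (a heterozygote
contributes mutant ovules with share `(1-sO)/(2-sO)` after within-plant
gametophytic selection); the outcrossing part unites mass-action pools with
mutant ovule frequency `q(1-sO)/(1-sO q)` and the pollen analogue. Mutation
is applied to zygote genotype frequencies exactly (including the `mu^2`
class); a `mutation_phase = "gametophyte"` switch instead mutates the
gamete pools, which changes nothing at first order — a property the tests
assert rather than assume. Because the within-plant and population-level
gamete accounting is easy to get subtly wrong, the test suite validates the
recursion against an independently coded brute-force enumeration of all
parental pairs and gamete draws, to machine precision.

To first order in the selection coefficients and `mu`, the recursion
collapses to

$$\Delta q = p\mu - \tfrac12 pq(1-F_{is})s_{hap}
  - pq(q-p)(1-F_{is})s_{het} + pq(q+pF_{is})s_{hom},$$

(`delta_q_weak()`), and, mutation aside, to `(S + Tq)q(1-q)` with

$$S = -\tfrac12(1-F_{is})s_{hap} + (1-F_{is})s_{het} + F_{is}s_{hom},
\qquad T = (1-F_{is})(s_{hom} - 2s_{het}).$$

The two forms are algebraically identical; the tests check the identity on
a grid to `1e-13` and the recursion-vs-first-order error against a frozen
second-order bound (`C = 0.5` times the squared largest coefficient,
calibrated once at about `0.23`).

## Critical selfing rates

In an infinite population the mutant allele either settles at an interior
mutation–selection equilibrium or marches to fixation. Setting
`Delta q = 0` in the limit `q -> 1` gives the boundary condition
`mu + shom = (1 - Fis)(shet + shap/2)`, hence with
`r = (mu + shom)/(shet + shap/2)`:

$$\alpha^* = \frac{2(1-r)}{2-r}, \qquad 0 \le r \le 1.$$

When `shet + shap/2 > 0` fixation occurs *above* `alpha*` (selfing rescues
a gametophyte-deleterious allele from purging); when it is negative —
notably sporophyte-deleterious alleles — fixation occurs *below* `alpha*`:
selfing exposes the allele in homozygotes and impedes its fixation. The
direction is probed empirically by `critical_alpha_numeric()`, not assumed.

One subtlety the package documents and measures rather than hides: the
`q -> 1` condition is **necessary but not always sufficient**. For
sporophyte-deleterious alleles, heterozygote disadvantage pushes the rare
allele down, so `Delta q` can dip negative at low-to-mid frequencies even
when the endpoint condition holds. The recursion oracle then finds *two*
boundaries: a lower trapping threshold (below it the allele is stuck at a
low interior equilibrium) and the upper `q -> 1` boundary; and at some
parameter combinations the interior dip, not the endpoint, closes the
fixation window, so the true upper boundary sits strictly below the
analytic `alpha*`. The test grids for analytic-vs-oracle agreement use
parameter sets where a scan of `min_q Delta q` shows the endpoint is
binding; a separate test asserts the `<=` bound and the two-boundary
structure at a parameter set where it is not. For synergistic deleterious
alleles the existence condition
`shet + shap/2 > mu + shom > 0` is enforced; outside it the allele never
fixes deterministically.

`critical_alpha_numeric()` classifies each trial selfing rate by iterating
the exact recursion from `q0 = 0.01`. Near a threshold the dynamics suffer
critical slowing-down and the trajectory is Möbius-like, so a single Aitken
extrapolation converges too slowly; the classifier uses a two-level
(iterated) Aitken on progressively spaced block samples, accepts a call
only when the extrapolated limit is stable and consistent with the current
position, and at the generation cap falls back on the trend of the
log-distance slope (constant slope = exponential escape to fixation,
decaying slope = stalling at an interior equilibrium). Bisection then
brackets each boundary to `alpha_tol` (default `1e-3`, the scale at which
the first-order analytic boundary and the exact recursion agree at
coefficient magnitudes around `1e-3`).

## Wright's flux equilibrium

In a finite population with one-way mutation there is no stationary
distribution: probability mass leaks irreversibly into fixation. The
flux-equilibrium regime is the long-lived transient in which every
heteroallelic frequency class decays at a common rate `K` while the shape
of the distribution stays fixed. The package derives the density from the
constant-flux steady state of the forward equation with drift
`M(q) = (S+Tq)q(1-q)` and variance `V(q) = q(1-q)/2Ne`:

$$\phi(q) = \frac{4N_e\mu}{q(1-q)}\,e^{A(q)}
 \frac{\int_q^1 e^{-A(x)}\,dx}{\int_0^1 e^{-A(x)}\,dx},
 \qquad A(q) = 4N_eSq + 2N_eTq^2,$$

$$K = \frac{\mu}{\int_0^1 e^{-A(x)}\,dx}.$$

This single derivation reproduces the classical special cases at once: the
neutral density `4 Ne mu / q` (so `phi(q) * q` is constant), the neutral
decay `K = mu`, the additive closed form `K/mu = 4NeX/(1 - e^{-4NeX})`
with `X = -(1/2)(1-Fis) shap + (1+Fis) shet` when `shom = 2 shet` (exact,
asserted to `1e-8`), the subterminal-class relation `f(1-1/2Ne) ~ 2K`, and
the small-value expansion `K ~ mu (1 + 2NeS + (2/3) NeT)` — of which only
the `S` term is asserted in tests, the `T` coefficient being more
sensitive to the approximation order.

The integral connects to Wright's two-argument special function through

$$\psi(x,y) = \tfrac12\int_{-1}^1 e^{xt + y(1/2-t^2)}\,dt, \qquad
\int_0^1 e^{-A} = \psi(2N_eS + N_eT,\ N_eT/2)\,e^{-2N_eS - 3N_eT/4}.$$

This closed form of `psi` is *validated*, not assumed: it must reproduce
`psi(x,0) = sinh(x)/x` (relative error below `1e-10` for `|x| <= 20`) and
the series `psi(0,y) = 1 + y/3! + 7y^2/5! + 27y^3/7! + ...` (coefficients
recovered by polynomial fitting and by an independent double-series
implementation). `decay_rate_K()` exposes both the `psi` route and direct
quadrature; they agree to `1e-10`.

The fixation probability of a mutant present at frequency `1/2Ne` is the
ratio of the subterminal class frequencies,
`u = f(1-1/2Ne)/f(1/2Ne) = phi(1-1/2Ne)/phi(1/2Ne)`. Because
`q(1-q)` takes the same value at the two subterminal classes, `mu` cancels
exactly — the tests assert `u` is identical across four decades of `mu`.
Neutrally `u = (1/60)/(59/60) = 1/59` at `Ne = 30`, slightly above the
diffusion value `1/60`; that ordering (flux-equilibrium `u` slightly above
the diffusion `u`) holds across all eight canonical selection cases.

Genetic loads: `load_infinite()` evaluates
`L(q) = q(-shap + 2p(1-Fis)shet + (q+pFis)shom)`, which equals
`-shap + shom` at fixation; `load_finite_mean()` integrates `L` against
`phi` over the heteroallelic band `[1/2Ne, 1-1/2Ne]` (the density diverges
like `1/q` at zero, so the band is the natural domain). The raw,
unnormalised density is the default — the mean load is then an expectation
over class occupancies on the flux scale — with `normalize = TRUE`
offering the unit-mass variant.

## Diffusion comparison

`fixation_prob_diffusion()` is the classical ratio of integrals of
`G(x) = exp(-4NeSx - 2NeTx^2)` — the same `A(q)`, without mutation.
Neutrality gives `u(p0) = p0` exactly and `T = 0` the usual closed form.
Two census-vs-effective-size relations are quantified by
`scaling_relations_check()`: with `Ne = N/(1+Fis)`, the additive
sporophytic relation `u(1/2Ne) = (1+Fis) u(1/2N)` holds tightly (`u` is
nearly linear in `p0`, and `4NeS = 4N shet` is selfing-independent in that
regime — whence the exact `alpha`-independence of `u(1/2N)` checked by
`additivity_independence_check()`), while the gametophyte-only reverse
reading `u(1/2N) = (1-Fis) u(1/2Ne)` is a first-order-in-`Fis` statement
only: since `u(1/2N) ~ u(1/2Ne)/(1+Fis)`, its relative error is `Fis^2`
(about 11% at `alpha = 0.5`), and the tests assert precisely that `Fis^2`
behaviour rather than pretending the relation is tight.

## Exact oracle and Monte Carlo

Two independent stochastic routes check the analytics:

* `allele_count_chain()` is the `(2Ne+1)`-state Wright–Fisher chain with
  binomial sampling around `q + Delta q` — exactly the model the analytic
  formulas describe. Absorption probabilities come from the linear
  first-step system; with mutation on, the dominant eigenpair of the
  transient sub-kernel gives the decay rate (compared with `K` to 10% at
  `Ne = 12..15`) and the quasi-stationary distribution (compared with
  `phi` pointwise to 5% away from the boundaries, a band frozen after a
  one-off calibration that showed ~4% at `Ne = 12` and ~1% at `Ne = 30`).
* `simulate_fixation()` is the genotype-resolved forward simulator:
  deterministic life-cycle expectations followed by trinomial sampling of
  `N` individuals, all replicate runs stepped in lock-step with vectorised
  binomial draws. It validates the `Fis`-equilibrium collapse that the
  chain and the formulas share. `simulate_flux_histogram()` runs the
  mutation-on variant and estimates the decay rate as fixation events per
  surviving run-generation with a Poisson standard error (a log-linear fit
  of the survival curve would understate the error, because the counts
  share their randomness cumulatively).

Defaults follow the study conditions: `Ne = 30` (with `Ne = 15` as the
strong-drift variant), selection magnitudes `|shap| = 0.04`,
`|shet| = 0.02`, `|shom| = 0.03` in the eight canonical cases
(`selection_cases()`), 10,000 runs and 100 datasets per estimate, and a
95% interval of `u_hat ± 1.96 sd` across dataset means — the dispersion of
single-dataset estimates, which is what the replicate structure measures.
The test suite scales the Monte Carlo replication down to 2,000 runs and 20
datasets per case so the whole cross-validation stays a few minutes; at
that precision the flux-equilibrium prediction still falls inside every
95% interval and all eight selfing-response directions reproduce.

The simulator's census size is `N = round(Ne (1+Fis))` (nearest integer,
ties away from zero) when the input is an effective size, with a `size =
"census"` switch to interpret the input directly; initialisation is one
heterozygote (`1/2N`) by default, or a mixture over the integer
heterozygote counts bracketing `1+Fis` copies for frequency-`1/2Ne`
experiments. Fixation-probability runs exclude recurrent mutation (the
analytic `u` is mutation-free, and with one-way mutation every run would
fix trivially); the flux experiment includes it.

### What the generator does and does not emulate

The simulator reproduces the model's own idealisations: a single isolated
locus, constant selfing rate, constant population size, non-overlapping
generations, equilibrium inbreeding reached through the mating system
itself. Real plant populations violate several of these (linked loci and
background selection, seed banks, fluctuating size, pollen discounting),
so a passing cross-validation says the *formulas match the model*, not
that the model matches any particular species.

## Numerical choices

* Quadrature: `stats::integrate` with relative tolerance `1e-12`; all
  exponentials of `A` are scaled by the exponent maximum before
  integration, and scaled drift intensities are capped at
  `|4NeS|, |2NeT| <= 200` (beyond which a range error names the offending
  magnitudes).
* `psi`: quadrature with peak subtraction; arguments pushing the exponent
  past 700 raise a range error. The double series is a second, independent
  implementation used in tests.
* Equilibrium iteration: `|Delta q| < 1e-12` convergence, boundary
  tolerance `1e-9`, both configurable.
* `Ne`/`N` conversion rounds to nearest, ties away from zero, and records
  the mode.
* Eigen computations are dense up to `Ne = 50`, power iteration beyond
  (both paths tested against each other).
* Seeding: one master seed, datasets consume sequential substreams of R's
  generator; an RNG-substitution test (Mersenne-Twister vs L'Ecuyer-CMRG)
  guards against generator artifacts.

## Known limitations

* All analytic objects use the mating-system-equilibrium `Fis`; under
  strong selection the realised inbreeding deviates at order `s`, which is
  exactly the error bounded by the second-order tests.
* The flux-equilibrium density is a small-`mu` object (`2 Ne mu < 1`;
  violating parameter sets trigger a warning, not an error).
* The critical-rate closed forms describe the `q -> 1` endpoint condition;
  where an interior dip binds first, only `critical_alpha_numeric()`
  reports the true boundary (see above).
* Two-way (recurrent) mutation is out of scope: its stationary
  distribution has `K = 0` and no fixation flux.
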