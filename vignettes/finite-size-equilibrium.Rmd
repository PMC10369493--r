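---
title: "Equilibrium constants for multimerization in small systems"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Equilibrium constants for multimerization in small systems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multimerK)
```

## The problem

In a macroscopic solution the equilibrium constant of an association
reaction can be written as a ratio of mean concentrations. In a closed
system holding only a handful of molecules this breaks down: particle
numbers fluctuate strongly, compositions with zero copies of a species
occur, and counts of different species are correlated because they share a
fixed particle budget. The textbook expression
$K'_m = \langle c_{A_m}\rangle (c^\circ)^{m-1}/\langle c_A\rangle^m$
then depends on the volume and on the total particle number, and it does
not converge to the true constant even at large volume when the particle
number stays small.

The constant defined by $\Delta G^\circ = -RT\ln K$ is recovered by
keeping the cross- and self-correlations. For a two-body association of an
$i$-mer and a $j$-mer,

$$K^{2b}_{i+j} \;=\;
\frac{\langle c_{A_{i+j}}\rangle\, c^\circ}
     {\langle c_{A_i}\,(c_{A_j} - \delta_{ij}/V)\rangle},$$

and for a concerted $m$-body association of monomers the denominator picks
up $(m-1)$ successive $-1/V$ subtractions. In count space these products
are falling factorials: $c(c-1/V)\cdots(c-(k-1)/V) = n^{(k)}/V^k$ with
$n^{(k)} = n(n-1)\cdots(n-k+1)$. Every estimator in this package is built
on that one kernel (`series_moment()`, internal to all `*_K()` functions),
evaluated in integer count space and divided by powers of $V$ once at the
end, which avoids the cancellation the subtracted floating-point form would
incur.

A multimerization $mA \rightleftharpoons A_m$ can proceed through many
mechanisms (paths): gradual monomer additions, dimer pairings, mixed
two-/three-body steps, or a concerted $m$-body encounter. Each path gives a
*different expression* in correlated averages, but free energy is a state
function, so all expressions share one value. That equality — and its
failure for the uncorrelated forms — is the package's central, testable
claim.

## The exact oracle

`cluster_model()` defines an ideal associating mixture with a closed-form
answer. A composition $\{n_m\}$ (an integer partition of $N$) has canonical
weight

$$W(\{n_m\}) = \frac{N!}{\prod_m (m!)^{n_m}\, n_m!}\,
  \prod_m (V b_m)^{n_m},$$

the number of ways to partition labeled particles into clusters of the
given sizes times one configurational factor $V b_m$ per cluster. The
$b_m$ (units nm$^{3(m-1)}$, $b_1 = 1$) are free parameters of the oracle,
not physical predictions. Two properties make this the right test bed:

* every falling-factorial moment is computable exactly by enumeration
  (77 compositions suffice for $N = 12$), and
* every K expression evaluates to the same closed form
  $K_m = (c^\circ)^{m-1} b_m/m!$, independent of $V$ and $N$ — we derived
  this by noting that with $a_m = V b_m/m!$ the falling-factorial moments
  factor as $E[\prod n_m^{(k_m)}] = \prod a_m^{k_m}\,
  N!\,Q_{N-M}/[(N-M)!\,Q_N]$, so the partition functions cancel in every
  ratio with matched particle content.

Enumeration is over integer partitions, not labeled microstates, with the
multiplicities folded into $W$; weights are accumulated in log space so
models up to $N \approx 40$ stay well-conditioned, although the tested
range is $N \le 12$ plus spot checks at $N = 30$. `sample_states()` draws
i.i.d. frames from the exact distribution and is the synthetic-data
generator for all estimator-consistency tests.

## The Lennard-Jones model system

`simulation_spec()`/`metropolis_chain()` sample the actual model:
$N$ single-site particles with $u(r) = 4\epsilon[(\sigma/r)^{12} -
(\sigma/r)^6]$, $\sigma = 0.20$ nm, truncated (unshifted) at
$r_\mathrm{cut} = 2.0$ nm, in a periodic cubic box at $T = 300$ K. Two
particles are bonded when their minimum-image distance is strictly below
$r_\mathrm{bond} = 0.35$ nm; clusters are connected components of the bond
graph, so a chain A–B–C is one trimer even when A and C are far apart.
Equilibrium ensemble averages are all the estimators need, so the system
is sampled by Markov-chain Monte Carlo rather than by integrating
equations of motion; thermostat, masses and integrator parameters have no
bearing on the sampled distribution.

Move set and its rationale:

* *Displacement moves*, uniform in a cube of half-width `max_disp`
  (default $L/2$, i.e. effectively a fresh uniform position). Acceptance
  $\min(1, e^{-\Delta U/RT})$; symmetric proposal, detailed balance.
* *Aggregation-volume-bias swaps* (`p_swap`, default 0.5): a particle is
  proposed uniformly into — or, if already there, out of — the
  $r_\mathrm{bond}$-sphere of another particle, with the proposal-volume
  ratio $v_\mathrm{in}/(V - v_\mathrm{in})$ in the acceptance rule. For
  well depths of 14–20 kJ/mol, bare displacement sampling leaves the
  aggregate state correlated over $\sim 3\times 10^4$ sweeps because bond
  breaking costs several $\epsilon$ at once; the biased swaps shuttle
  particles directly between bonded and free states and cut that
  correlation time by roughly two orders of magnitude. Both move types
  target the same canonical distribution, which the test suite verifies
  against two independent oracles: the analytic bonded-volume fraction of
  the ideal gas and a radial-quadrature dimerization constant for $N = 2$
  (`two_particle_K_quadrature()`, converged to relative $10^{-8}$ by
  `stats::integrate`).

An optional equilibration-only step-width tuner (`adapt = TRUE`) targets
roughly 40% displacement acceptance. It is off by default: for deep wells
the tuned (smaller) steps slow bond-breaking, and the acceptance rate is
the wrong figure of merit when association events are the bottleneck.
Production always runs with a frozen step, preserving detailed balance.
The first 10% of sweeps are discarded as equilibration by default.

## Parameters that matter

| parameter | units | default | role |
|---|---|---|---|
| `epsilon` | kJ/mol | — | well depth; 10–20 covers monomeric to aggregated regimes |
| `sigma` | nm | 0.20 | LJ diameter |
| `r_bond` | nm | 0.35 | cluster criterion (open boundary, `<`) |
| `r_cut` | nm | 2.0 | plain truncation of the potential |
| `c_std` | molecules/nm³ | 0.602214076 (1 M) | standard concentration; all K are dimensionless, constancy claims do not depend on it |
| `p_swap` | — | 0.5 | fraction of association-biased moves |
| `thin` | sweeps | 10 | frame recording interval |
| `n_blocks` | — | 20 | block-averaging error bars |

## Error bars and degenerate inputs

All standard errors come from block averaging: the series is cut into 20
contiguous blocks, the *entire statistic* (not just individual moments) is
evaluated per block, and the spread of block values gives the error. This
keeps correlations among the moments inside one K — and among the four
constants inside a cycle closure — in the error bar. Estimates whose
denominator moment is zero (a species combination never observed, e.g. the
monomer pair in a fully aggregated series) are returned as flagged
`K_estimate` objects rather than errors, so volume scans can report gaps;
`prob_ratio_K()` returns 0 with an undefined error bar when the clustered
state was never seen and an undefined estimate when the monomeric state
was never seen.

## What the generators do and do not emulate

`sample_states()` draws independent frames from an exactly known
distribution: it validates estimator algebra and convergence, but has no
time correlation, so it says nothing about block-length adequacy for real
trajectories. `metropolis_chain()` adds realistic autocorrelation and the
actual LJ cluster statistics, but it is still a single-component,
structureless model: no solvent, no internal cluster degrees of freedom,
no orientation-dependent bonding. Conclusions about estimator consistency
transfer to real systems only insofar as those systems are equilibrated
and their cluster criterion is as unambiguous as the deep first minimum of
the radial distribution function is here.

## Worked example

```{r oracle-example}
mod <- cluster_model(N_total = 4, V = 10, b = factorial(1:4), c_std = 1)
# three mechanisms, one value
path_K(mod, list(c(1, 1), c(1, 2), c(1, 3)))
path_K(mod, list(c(1, 1), c(1, 1), c(2, 2)))
elementary_K(mod, c(1, 1, 1, 1))
# the uncorrelated expression disagrees and depends on V
uncorrelated_K(mod, 4)
```

```{r sampling-example}
spec <- simulation_spec(N_total = 2, L_box = 5, epsilon = 10, seed = 1)
cs <- metropolis_chain(spec, n_sweeps = 2e5, thin = 10, c_std = 1)
elementary_K(cs, c(1, 1))
two_particle_K_quadrature(spec, c_std = 1)
```

## Problem sizes used in the shipped checks

The package's own verification uses: exact-oracle identities for all
$N \le 12$ over five-decade volume grids (instantaneous); sampled-series
consistency at $2\times 10^4$–$10^6$ i.i.d. frames; LJ validation runs of
$2\times 10^5$–$2\times 10^6$ sweeps for the two-particle system; and a
$10^7$-sweep chain for the four-particle thermodynamic-cycle closure
(seconds to a couple of minutes on one core). These lengths give
block-average error bars a few percent of the estimated constants, which
is the regime the consistency checks are designed for.

## Design choices and limitations

* The oracle's weight is an implementer-chosen idealization (ideal cluster
  mixture); it certifies estimator algebra, not LJ numerics. No attempt is
  made to compute $b_m$ for the LJ model beyond the pair integral.
* Transfer reactions are handled in two independently coded forms — the
  direct falling-factorial ratio and the ratio of two monomer-addition
  constants — which must and do agree; the ratio form covers exactly the
  monomer-transfer reactions $A_i + A_{j+1} \rightleftharpoons
  A_{i+1} + A_j$ (a self-inverse reaction returns 1 by construction).
* The chain's random numbers come from its own 64-bit generator seeded
  through `simulation_spec(seed=)`, so runs are reproducible across
  platforms and independent of R's RNG state.
* No kinetics: identical equilibrium constants across mechanisms say
  nothing about rates, and none are computed. No grand-canonical ensemble,
  no mixtures, no pressure, and no claim about the two-state approximation
  regime.
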