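# multimerK

Equilibrium constants for cluster formation (multimerization) in systems
with **small numbers of molecules**, where the textbook law of mass action
fails.

## The problem

A closed box holding a handful of associating particles fluctuates
strongly in composition: counts of monomers, dimers, trimers, ... are
correlated because they share one fixed particle budget, and frames with
zero copies of a species are common. The widely used expression

```
K'_m = <c_Am> (c°)^(m-1) / <c_A>^m
```

is then *not* a constant — it varies with volume and particle number by up
to orders of magnitude, and it does not converge to the true constant even
at large volume while the particle number stays small. The constant
defined by ΔG° = −RT ln K is recovered by keeping cross- and
self-correlations. For a two-body association of an i-mer and a j-mer,

```
K2b_{i+j} = <c_{A(i+j)}> c° / <c_Ai (c_Aj − δ_ij/V)>
```

and a concerted m-body association carries (m−1) successive −1/V
self-correlation subtractions, which in count space are falling factorials
n(n−1)···(n−k+1). A multimerization m·A ⇌ A_m can be decomposed into many
reaction paths (gradual monomer additions, dimer pairings, mixed
higher-order steps, one concerted encounter); each path yields a
*different expression* in correlated averages but — free energy being a
state function — the *same value*. multimerK implements every such
expression, the transfer-reaction constants that are free of c°, the
probability-ratio form for N = m, and the fluctuation identities linking
mean cluster numbers to normalized covariances, together with:

* an **exact oracle** (`cluster_model`): an ideal-cluster canonical
  ensemble enumerated over integer partitions, with closed-form
  K_m = (c°)^(m−1) b_m / m! against which every expression is verified to
  machine precision;
* a **Lennard-Jones Metropolis Monte Carlo sampler**
  (`metropolis_chain`): N single-site particles (σ = 0.20 nm, truncated at
  2.0 nm) in a periodic cubic box at 300 K, with a 0.35 nm distance
  cluster criterion and association-biased swap moves for fast
  bonded/free exchange, plus an independent radial-quadrature oracle for
  the two-particle system;
* **block-average error bars**, thermodynamic **cycle closures** as a
  convergence diagnostic, CSV/XYZ I/O, and scripted volume (R1) and
  system-size-at-fixed-concentration (R2) scans.

## Worked example

Three mechanisms for tetramer formation on an exactly solvable model, and
the failure of the uncorrelated expression:

```r
library(multimerK)
mod <- cluster_model(N_total = 4, V = 10, b = c(1, 2, 9, 60), c_std = 1)

path_K(mod, list(c(1, 1), c(1, 2), c(1, 3)))  # gradual monomer additions
#> K4[path 1+1; 1+2; 1+3] = 2.5 +/- 0
path_K(mod, list(c(1, 1), c(1, 1), c(2, 2)))  # via two dimers
#> K4[path 1+1; 1+1; 2+2] = 2.5 +/- 0
elementary_K(mod, c(1, 1, 1, 1))              # concerted four-body
#> K4b_1+1+1+1 = 2.5 +/- 0
closed_form_K(mod, 4)
#> [1] 2.5
uncorrelated_K(mod, 4)                        # the textbook expression
#> K'_4 = 0.591039 +/- 0
```

All correlated expressions agree with the closed form c°³·b₄/4! = 2.5
exactly; the uncorrelated one is off by more than a factor of four *and*
changes when V or N_total changes.

Sampling a bound Lennard-Jones pair and checking against the independent
quadrature oracle:

```r
spec <- simulation_spec(N_total = 2, L_box = 5, epsilon = 10, seed = 1)
cs <- metropolis_chain(spec, n_sweeps = 5e5, thin = 10, c_std = 1)
elementary_K(cs, c(1, 1))
#> K2b_1+1 = 0.840315 +/- 0.027  (20 blocks)
two_particle_K_quadrature(spec, c_std = 1)
#> [1] 0.8494101
```

The Monte Carlo estimate agrees with the quadrature value within its
block-average error bar.

A command-line front end (`exec/multimerk`) exposes `simulate`, `oracle`,
`estimate`, `scan` and `fixtures` verbs over the same functions, with YAML
configs and CSV output; see the script header for usage. The methods
vignette (`vignettes/finite-size-equilibrium.Rmd`) documents the model,
the move set, the error analysis and the design choices.

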