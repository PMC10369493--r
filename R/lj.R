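#' Lennard-Jones simulation specification
#'
#' Parameters of the model system: `N_total` single-site particles
#' interacting through a truncated (unshifted) Lennard-Jones potential in a
#' periodic cubic box, sampled canonically at temperature `T`. Two particles
#' closer than `r_bond` (minimum-image) are bonded; connected components of
#' the bond graph are clusters.
#'
#' @param N_total particle count.
#' @param L_box box edge in nm; must admit the minimum-image convention
#'   (`L_box >= 2 * r_cut`).
#' @param epsilon LJ well depth in kJ/mol (may be 0 for an ideal gas).
#' @param sigma LJ diameter in nm (default 0.20).
#' @param T temperature in K (default 300).
#' @param r_cut interaction cutoff in nm (default 2.0, plain truncation).
#' @param r_bond cluster criterion distance in nm (default 0.35; bonded
#'   strictly below).
#' @param max_disp trial-move half-width in nm; defaults to `L_box / 2`
#'   (global moves), optionally tuned during equilibration by
#'   [metropolis_chain()].
#' @param seed integer seed for the sampler.
#' @return Object of class `simulation_spec`.
#' @examples
#' simulation_spec(N_total = 4, L_box = 6, epsilon = 16)
#' @export
simulation_spec <- function(N_total, L_box, epsilon, sigma = 0.20, T = 300,
                            r_cut = 2.0, r_bond = 0.35, max_disp = NULL,
                            seed = 1L) {
  if (N_total < 1 || N_total != as.integer(N_total)) {
    stop("`N_total` must be a positive integer", call. = FALSE)
  }
  for (nm in c("L_box", "sigma", "T", "r_cut", "r_bond")) {
    v <- get(nm)
    if (length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("`", nm, "` must be a single positive number", call. = FALSE)
    }
  }
  if (length(epsilon) != 1L || !is.finite(epsilon) || epsilon < 0) {
    stop("`epsilon` must be a single non-negative number", call. = FALSE)
  }
  if (L_box < 2 * r_cut) {
    stop("`L_box` must be at least 2 * r_cut for the minimum-image ",
         "convention", call. = FALSE)
  }
  if (r_bond >= r_cut) stop("`r_bond` must be smaller than `r_cut`",
                            call. = FALSE)
  if (is.null(max_disp)) max_disp <- L_box / 2
  if (max_disp <= 0 || max_disp > L_box / 2) {
    stop("`max_disp` must lie in (0, L_box / 2]", call. = FALSE)
  }
  structure(
    list(N_total = as.integer(N_total), L_box = L_box, epsilon = epsilon,
         sigma = sigma, T = T, r_cut = r_cut, r_bond = r_bond,
         max_disp = max_disp, seed = as.integer(seed)),
    class = "simulation_spec"
  )
}

#' @export
print.simulation_spec <- function(x, ...) {
  cat(sprintf(
    "LJ simulation spec: N = %d, L_box = %g nm, epsilon = %g kJ/mol,\n",
    x$N_total, x$L_box, x$epsilon))
  cat(sprintf(
    "  sigma = %g nm, T = %g K, r_cut = %g nm, r_bond = %g nm, seed = %d\n",
    x$sigma, x$T, x$r_cut, x$r_bond, x$seed))
  invisible(x)
}

#' Truncated Lennard-Jones pair energy
#'
#' \eqn{u(r) = 4\epsilon[(\sigma/r)^{12} - (\sigma/r)^6]} for distances up
#' to `r_cut`, zero beyond (plain truncation, no shift, no tail
#' correction).
#'
#' @param r distance(s) in nm, positive.
#' @param spec a [simulation_spec()].
#' @return Energy in kJ/mol, vectorized over `r`.
#' @examples
#' s <- simulation_spec(2, 5, epsilon = 10)
#' pair_energy(s$sigma, s)             # 0 at the zero crossing
#' pair_energy(2^(1/6) * s$sigma, s)   # -epsilon at the minimum
#' @export
pair_energy <- function(r, spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  if (any(!is.finite(r)) || any(r <= 0)) {
    stop("`r` must be positive", call. = FALSE)
  }
  sr6 <- (spec$sigma / r)^6
  u <- 4 * spec$epsilon * (sr6^2 - sr6)
  u[r > spec$r_cut] <- 0
  u
}

# minimum-image displacement(s) for a cubic box
min_image <- function(d, L) d - L * round(d / L)

# minimum-image distance matrix for an n x 3 position matrix
min_image_dist <- function(positions, L) {
  n <- nrow(positions)
  d <- matrix(0, n, n)
  for (k in 1:3) {
    dk <- min_image(outer(positions[, k], positions[, k], "-"), L)
    d <- d + dk^2
  }
  sqrt(d)
}

#' Total potential energy of a configuration
#'
#' Sum of [pair_energy()] over all particle pairs at their minimum-image
#' distances. Invariant under rigid box translations.
#'
#' @param config numeric matrix, one row per particle, columns x, y, z (nm).
#' @param spec a [simulation_spec()].
#' @return Energy in kJ/mol.
#' @export
total_energy <- function(config, spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  config <- as.matrix(config)
  n <- nrow(config)
  if (n < 2) return(0)
  d <- min_image_dist(config, spec$L_box)
  r <- d[upper.tri(d)]
  sum(pair_energy(r, spec))
}

#' Cluster composition of a configuration
#'
#' Builds the bond graph joining particle pairs whose minimum-image distance
#' is strictly below `r_bond` and returns the size histogram of its
#' connected components as a composition vector (`counts[m]` = number of
#' m-mers). Particles are always conserved: `sum(m * counts[m]) == N`.
#'
#' @param config numeric matrix, one row per particle, columns x, y, z (nm).
#' @param spec a [simulation_spec()].
#' @return Integer composition vector of length `nrow(config)`.
#' @examples
#' s <- simulation_spec(3, L_box = 5, epsilon = 10)
#' cfg <- rbind(c(1, 1, 1), c(1.3, 1, 1), c(1.6, 1, 1))
#' cluster_counts(cfg, s) # one trimer by transitivity
#' @export
cluster_counts <- function(config, spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  config <- as.matrix(config)
  n <- nrow(config)
  parent <- seq_len(n)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  if (n > 1) {
    d <- min_image_dist(config, spec$L_box)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (d[i, j] < spec$r_bond) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[ri] <- rj
        }
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  sizes <- tabulate(roots, nbins = n)
  counts <- tabulate(sizes[sizes > 0], nbins = n)
  storage.mode(counts) <- "integer"
  counts
}

#' Metropolis Monte Carlo chain producing a cluster-count series
#'
#' Samples the canonical ensemble of the Lennard-Jones system by
#' single-particle displacement moves, uniform in a cube of half-width
#' `max_disp`, accepted with probability `min(1, exp(-dU / (R T)))`
#' (`R = 0.0083144626` kJ/(mol K)). The move set is symmetric, so detailed
#' balance holds and the chain targets the canonical distribution; the
#' sampled observable is the cluster composition under the `r_bond`
#' criterion, recorded every `thin`-th sweep after discarding the first
#' `equil_frac` of the sweeps as equilibration. With `adapt = TRUE` the step
#' width is tuned toward roughly 40% acceptance during equilibration only —
#' production always runs with a frozen step.
#'
#' @param spec a [simulation_spec()].
#' @param n_sweeps total number of sweeps (one sweep = `N_total` trial
#'   moves).
#' @param thin record the composition every `thin`-th production sweep.
#' @param equil_frac fraction of sweeps discarded as equilibration
#'   (default 0.1).
#' @param adapt tune `max_disp` during equilibration (default `FALSE`: the
#'   default full-box moves are what make bond-breaking and re-binding fast
#'   for deep wells; see the package vignette). Only displacement moves are
#'   used for the tuning statistics.
#' @param p_swap probability that a trial move is an aggregation-volume-bias
#'   swap instead of a displacement: particle `i` is proposed uniformly
#'   into, or out of, the association shell (radius `r_bond`) of another
#'   particle `j`, with the proposal-volume ratio in the acceptance rule.
#'   These swaps shuttle particles directly between bonded and free states
#'   and cut the correlation time of the cluster composition by orders of
#'   magnitude for deep wells (default 0.5; set 0 for pure displacement
#'   sampling).
#' @param c_std standard concentration for downstream estimators,
#'   molecules/nm^3 (default 1 M).
#' @param traj_every if positive, also keep particle positions every
#'   `traj_every`-th production sweep (retrievable from the provenance and
#'   writable with [write_xyz()]).
#' @return A [counts_series()]; `provenance` records the spec, the seed, the
#'   production acceptance rate and the (possibly tuned) step width.
#' @examples
#' s <- simulation_spec(2, L_box = 5, epsilon = 0, seed = 7)
#' cs <- metropolis_chain(s, n_sweeps = 2000, thin = 5)
#' mean(cs$counts[, 2]) # bonded fraction, near (4/3) pi r_bond^3 / V
#' @export
metropolis_chain <- function(spec, n_sweeps, thin = 10L, equil_frac = 0.1,
                             adapt = FALSE, p_swap = 0.5,
                             c_std = 0.602214076, traj_every = 0L) {
  stopifnot(inherits(spec, "simulation_spec"))
  if (n_sweeps < 1) stop("`n_sweeps` must be >= 1", call. = FALSE)
  if (thin < 1) stop("`thin` must be >= 1", call. = FALSE)
  if (equil_frac < 0 || equil_frac >= 1) {
    stop("`equil_frac` must lie in [0, 1)", call. = FALSE)
  }
  if ((1 - equil_frac) * n_sweeps < thin) {
    stop("no production frames: n_sweeps too small for this thinning",
         call. = FALSE)
  }
  if (p_swap < 0 || p_swap >= 1) {
    stop("`p_swap` must lie in [0, 1)", call. = FALSE)
  }
  res <- .mc_chain_cpp(spec$N_total, spec$L_box, spec$epsilon, spec$sigma,
                       spec$T, spec$r_cut, spec$r_bond, spec$max_disp,
                       as.numeric(n_sweeps), as.integer(thin), equil_frac,
                       isTRUE(adapt), as.numeric(spec$seed),
                       as.integer(traj_every), p_swap)
  prov <- list(sampler = "lj_metropolis", seed = spec$seed, spec = spec,
               n_sweeps = n_sweeps, thin = thin, p_swap = p_swap,
               equil_sweeps = res$equil_sweeps,
               acceptance = res$acceptance,
               max_disp_used = res$max_disp_final)
  if (!is.null(res$trajectory)) prov$trajectory <- res$trajectory
  counts_series(res$counts, V = spec$L_box^3, c_std = c_std,
                N_total = spec$N_total, provenance = prov)
}

#' Two-particle equilibrium constant by radial quadrature
#'
#' Independent oracle for the `N = 2` Lennard-Jones system: the
#' dimerization constant follows from one-dimensional integrals over the
#' pair distance,
#' \deqn{K = \frac{c^\circ V\, I_b}{2\, I_u},\qquad
#'   I_b = \int_0^{r_b} e^{-u(r)/RT} 4\pi r^2\,dr,}
#' \deqn{I_u = V - \tfrac{4}{3}\pi r_b^3 +
#'   \int_{r_b}^{r_{cut}} (e^{-u(r)/RT} - 1)\, 4\pi r^2\,dr,}
#' the factor 2 being the homo-dimer self-correlation combinatorics of the
#' two-body binding constant. Used to validate the Monte Carlo sampler.
#'
#' @param spec a [simulation_spec()] (requires `L_box / 2 > r_cut` so the
#'   radial decomposition is exact).
#' @param c_std standard concentration, molecules/nm^3 (default 1 M).
#' @return Dimensionless equilibrium constant.
#' @examples
#' s <- simulation_spec(2, L_box = 5, epsilon = 10)
#' two_particle_K_quadrature(s)
#' @export
two_particle_K_quadrature <- function(spec, c_std = 0.602214076) {
  stopifnot(inherits(spec, "simulation_spec"))
  if (spec$L_box / 2 <= spec$r_cut) {
    stop("quadrature oracle needs L_box / 2 > r_cut", call. = FALSE)
  }
  beta <- 1 / (.R_GAS * spec$T)
  V <- spec$L_box^3
  fb <- function(r) exp(-beta * pair_energy(r, spec)) * 4 * pi * r^2
  fu <- function(r) (exp(-beta * pair_energy(r, spec)) - 1) * 4 * pi * r^2
  I_b <- integrate(fb, 0, spec$r_bond, rel.tol = 1e-10,
                   subdivisions = 500L)
  I_tail <- integrate(fu, spec$r_bond, spec$r_cut, rel.tol = 1e-10,
                      subdivisions = 500L)
  if (I_b$message != "OK" || I_tail$message != "OK") {
    stop("quadrature failed to converge", call. = FALSE)
  }
  I_u <- V - 4 / 3 * pi * spec$r_bond^3 + I_tail$value
  c_std * V * I_b$value / (2 * I_u)
}

#' Write a stored trajectory in XYZ format
#'
#' Writes frames kept by [metropolis_chain()] (`traj_every > 0`) as a
#' multi-frame XYZ file with element tag "A" and coordinates in nm.
#'
#' @param series a [counts_series()] whose provenance holds a trajectory.
#' @param path output file.
#' @return Invisibly, the number of frames written.
#' @export
write_xyz <- function(series, path) {
  stopifnot(inherits(series, "counts_series"))
  traj <- series$provenance$trajectory
  if (is.null(traj)) stop("series carries no stored trajectory", call. = FALSE)
  n <- ncol(traj) / 3
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(nrow(traj))) {
    writeLines(c(as.character(n), sprintf("frame %d", f)), con)
    xyz <- matrix(traj[f, ], ncol = 3, byrow = TRUE)
    writeLines(sprintf("A %.6f %.6f %.6f", xyz[, 1], xyz[, 2], xyz[, 3]),
               con)
  }
  invisible(nrow(traj))
}
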