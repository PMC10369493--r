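# Lennard-Jones model, cluster detection, Monte Carlo chain, quadrature oracle

test_that("pair energy has the LJ shape with plain truncation", {
  s <- simulation_spec(2, L_box = 5, epsilon = 10, seed = 1)
  expect_equal(pair_energy(s$sigma, s), 0)
  expect_equal(pair_energy(2^(1 / 6) * s$sigma, s), -s$epsilon)
  expect_equal(pair_energy(2.5, s), 0) # beyond cutoff
  # continuous approach to the cutoff from below (unshifted truncation)
  expect_equal(pair_energy(s$r_cut, s),
               4 * 10 * ((0.2 / 2)^12 - (0.2 / 2)^6))
  expect_error(pair_energy(0, s), "positive")
  expect_error(pair_energy(-1, s), "positive")
})

test_that("simulation spec validates its geometry", {
  expect_error(simulation_spec(2, L_box = 3, epsilon = 1), "2 \\* r_cut")
  expect_error(simulation_spec(2, L_box = 5, epsilon = 1, r_bond = 2.5),
               "r_cut")
  expect_error(simulation_spec(0, L_box = 5, epsilon = 1), "positive")
  expect_error(simulation_spec(2, L_box = 5, epsilon = -2), "non-negative")
  # the paper-style box equal to twice the cutoff is admitted
  expect_s3_class(simulation_spec(3, L_box = 4, epsilon = 20),
                  "simulation_spec")
})

test_that("total energy sums minimum-image pairs and is translation invariant", {
  s <- simulation_spec(3, L_box = 5, epsilon = 10, seed = 1)
  expect_equal(total_energy(matrix(c(1, 1, 1), 1, 3), s), 0)
  r_min <- 2^(1 / 6) * s$sigma
  two <- rbind(c(0.1, 1, 1), c(0.1 + r_min, 1, 1))
  expect_equal(total_energy(two[1:2, ], simulation_spec(2, 5, 10)), -10,
               tolerance = 1e-12)
  # pair across the periodic boundary at the same minimum-image distance
  wrapped <- rbind(c(0.05, 1, 1), c(5 - r_min + 0.05, 1, 1))
  expect_equal(total_energy(wrapped, simulation_spec(2, 5, 10)), -10,
               tolerance = 1e-12)
  # three mutually distant particles
  far <- rbind(c(0.5, 0.5, 0.5), c(3, 3, 0.5), c(0.5, 3, 3))
  expect_equal(total_energy(far, s), 0)
  # rigid shift leaves the energy unchanged
  cfg <- rbind(c(0.2, 0.3, 0.4), c(0.5, 0.3, 0.4), c(4.9, 4.8, 0.1))
  expect_equal(total_energy(cfg, s), total_energy(cfg + 1.7, s),
               tolerance = 1e-10)
})

test_that("cluster detection is transitive, conservative and periodic", {
  s <- simulation_spec(3, L_box = 5, epsilon = 10)
  # A-B at 0.30, B-C at 0.30, A-C at 0.55: one trimer by connectivity
  tri <- rbind(c(0, 0, 0), c(0.3, 0, 0), c(0.504, 0.2195, 0))
  d <- dist(tri)
  expect_true(d[1] < 0.35 && d[3] < 0.35 && d[2] > 0.35)
  expect_equal(cluster_counts(tri, s), c(0L, 0L, 1L))

  # all pairs beyond r_bond: only monomers
  mono <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  expect_equal(cluster_counts(mono, s), c(3L, 0L, 0L))

  # dimer straddling the periodic boundary at wrapped distance 0.2
  s2 <- simulation_spec(2, L_box = 5, epsilon = 10)
  wrap_pair <- rbind(c(0.1, 2, 2), c(4.9, 2, 2))
  expect_equal(cluster_counts(wrap_pair, s2), c(0L, 1L))

  # particle conservation for arbitrary configurations
  set.seed(5)
  for (rep in 1:10) {
    n <- sample(2:8, 1)
    cfg <- matrix(runif(3 * n, 0, 5), n, 3)
    sp <- simulation_spec(n, L_box = 5, epsilon = 10)
    cc <- cluster_counts(cfg, sp)
    expect_equal(sum(seq_along(cc) * cc), n)
  }
})

test_that("the chain is deterministic given a seed and conserves particles", {
  s <- simulation_spec(3, L_box = 5, epsilon = 10, seed = 21)
  a <- metropolis_chain(s, n_sweeps = 5000, thin = 5)
  b <- metropolis_chain(s, n_sweeps = 5000, thin = 5)
  expect_identical(a$counts, b$counts)
  expect_equal(unname(as.integer(a$counts %*% 1:3)),
               rep(3L, nrow(a$counts)))
  # a different seed gives a different trajectory
  s2 <- simulation_spec(3, L_box = 5, epsilon = 10, seed = 22)
  expect_false(identical(metropolis_chain(s2, 5000, thin = 5)$counts,
                         a$counts))
  expect_error(metropolis_chain(s, n_sweeps = 0), ">= 1")
})

test_that("ideal-gas sampling reproduces the geometric bonded fraction", {
  s <- simulation_spec(2, L_box = 5, epsilon = 0, seed = 31)
  cs <- metropolis_chain(s, n_sweeps = 1.5e5, thin = 5)
  p_hat <- mean(cs$counts[, 2])
  p_geom <- 4 / 3 * pi * s$r_bond^3 / s$L_box^3
  se <- block_error(cs, function(x) mean(x$counts[, 2]), 20)
  expect_lt(abs(p_hat - p_geom), 3 * se)
})

test_that("displacement acceptance decreases with step width", {
  accs <- vapply(c(0.05, 0.5, 2.5), function(d) {
    s <- simulation_spec(5, L_box = 5, epsilon = 10, max_disp = d, seed = 8)
    metropolis_chain(s, n_sweeps = 4000, thin = 10,
                     p_swap = 0)$provenance$acceptance
  }, numeric(1))
  expect_true(all(diff(accs) <= 0))
})

test_that("quadrature oracle matches analytics and volume invariance", {
  # Boltzmann factor 1 everywhere: pure geometry
  s0 <- simulation_spec(2, L_box = 5, epsilon = 0)
  vb <- 4 / 3 * pi * s0$r_bond^3
  V <- 125
  expect_equal(two_particle_K_quadrature(s0, c_std = 1),
               V * vb / (2 * (V - vb)), tolerance = 1e-8)
  # V cancels to leading order: doubling the box barely moves K
  s1 <- simulation_spec(2, L_box = 5, epsilon = 10)
  s2 <- simulation_spec(2, L_box = 10, epsilon = 10)
  k1 <- two_particle_K_quadrature(s1, c_std = 1)
  k2 <- two_particle_K_quadrature(s2, c_std = 1)
  expect_equal(k1, k2, tolerance = 2e-3)
  expect_error(two_particle_K_quadrature(
    simulation_spec(2, L_box = 4, epsilon = 10)), "r_cut")
})

test_that("the chain agrees with the quadrature oracle for a bound pair", {
  s <- simulation_spec(2, L_box = 5, epsilon = 10, seed = 41)
  cs <- metropolis_chain(s, n_sweeps = 5e5, thin = 10, c_std = 1)
  kq <- two_particle_K_quadrature(s, c_std = 1)
  km <- elementary_K(cs, c(1, 1))
  expect_lt(abs(km$value - kq), 3 * km$stderr)
})

test_that("stored trajectories round-trip through XYZ output", {
  s <- simulation_spec(3, L_box = 5, epsilon = 5, seed = 2)
  cs <- metropolis_chain(s, n_sweeps = 2000, thin = 10, traj_every = 100)
  path <- tempfile(fileext = ".xyz")
  n_frames <- write_xyz(cs, path)
  lines <- readLines(path)
  expect_equal(length(lines), n_frames * (3 + 2))
  expect_equal(lines[1], "3")
  coords <- as.numeric(strsplit(lines[3], " ")[[1]][-1])
  expect_true(all(coords >= 0 & coords < 5))
})
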