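# equilibrium-constant expressions on exact oracle moments and sampled series

test_that("elementary K reproduces the closed form on worked examples", {
  m <- model_two()
  expect_equal(elementary_K(m, c(1, 1))$value, 1, tolerance = 1e-12)
  expect_equal(elementary_K(model_unit_K(3), c(1, 1, 1))$value, 1,
               tolerance = 1e-12)
  # identity reaction: a monomer "associating" alone
  expect_equal(elementary_K(m, 1)$value, 1)
  expect_error(elementary_K(m, c(1, 1, 1)), "more than N_total")
})

test_that("every path expression equals the closed form on the oracle", {
  # the central state-function property: different mechanisms, one value
  paths4 <- list(
    list(c(1, 1), c(1, 2), c(1, 3)),        # gradual monomer additions
    list(c(1, 1), c(1, 1), c(2, 2)),        # via two dimers
    list(c(1, 1), c(1, 1, 2)),              # mixed two-/three-body
    list(c(1, 1, 1), c(1, 3)),              # trimer first, concerted
    list(c(1, 1, 1, 1))                     # concerted four-body
  )
  for (N in c(4, 7, 12)) {
    for (V in c(3, 30, 300)) {
      mod <- model_geometric(N, V = V, base = 1.6)
      K4 <- closed_form_K(mod, 4)
      for (p in paths4) {
        expect_equal(path_K(mod, p)$value, K4, tolerance = 1e-10,
                     label = sprintf("N=%d V=%g path", N, V))
      }
    }
  }
})

test_that("two-body K is invariant of system size at fixed b", {
  vals <- vapply(2:9, function(N) {
    elementary_K(model_geometric(N, V = 12, base = 2), c(1, 1))$value
  }, numeric(1))
  expect_equal(vals, rep(vals[1], length(vals)), tolerance = 1e-12)
})

test_that("path validation rejects non-telescoping sequences", {
  m <- model_unit_K(4)
  expect_error(path_K(m, list(c(1, 1), c(1, 1))), "telescope")
  expect_error(path_K(m, list(c(2, 2))), "telescope")
  expect_error(path_K(m, list()), "non-empty")
  # single-step path delegates to the concerted constant
  expect_equal(path_K(m, list(c(1, 1, 1)))$value,
               elementary_K(m, c(1, 1, 1))$value)
})

test_that("uncorrelated K' carries the exact finite-size bias", {
  m <- model_two()
  expect_equal(uncorrelated_K(m, 2)$value, 0.6, tolerance = 1e-12)
  # K'_2 / K_2 = (1 + b_2/V)/2 for N = 2, hence -> 1/2 as V grows
  for (V in c(5, 50, 500, 5e4)) {
    mod <- cluster_model(2, V = V, b = c(1, 3), c_std = 1)
    ratio <- uncorrelated_K(mod, 2)$value / elementary_K(mod, c(1, 1))$value
    expect_equal(ratio, (1 + 3 / V) / 2, tolerance = 1e-12)
  }
  mod <- cluster_model(2, V = 1e8, b = c(1, 3), c_std = 1)
  expect_equal(uncorrelated_K(mod, 2)$value / elementary_K(mod, c(1, 1))$value,
               0.5, tolerance = 1e-6)
})

test_that("transfer constants: direct and ratio forms agree exactly", {
  r13 <- reaction_spec(c(1, 3), c(2, 2))
  r14 <- reaction_spec(c(1, 4), c(2, 3))
  mu <- model_unit_K(5)
  expect_equal(transfer_K_direct(mu, r13)$value, 1, tolerance = 1e-12)
  expect_equal(transfer_K_ratio(mu, r13)$value, 1, tolerance = 1e-12)
  expect_equal(transfer_K_direct(mu, r14)$value, 1, tolerance = 1e-12)

  for (N in c(5, 8)) {
    mod <- model_geometric(N, V = 4, base = 2.7)
    for (r in list(r13, r14)) {
      expect_equal(transfer_K_direct(mod, r)$value,
                   transfer_K_ratio(mod, r)$value, tolerance = 1e-10)
    }
  }

  # self-inverse reaction is exactly 1
  ident <- reaction_spec(c(1, 3), c(1, 3))
  expect_equal(transfer_K_direct(model_geometric(5), ident)$value, 1)
  expect_equal(transfer_K_ratio(model_geometric(5), ident)$value, 1)
  expect_equal(transfer_K_uncorrelated(model_geometric(5), ident)$value, 1)

  expect_error(reaction_spec(c(1, 3), c(2, 3)), "conserve")
  # a dimer transfer cannot be written as one monomer-addition difference
  expect_error(transfer_K_ratio(model_unit_K(6), reaction_spec(c(1, 5), c(3, 3))),
               "difference of two monomer additions")
})

test_that("uncorrelated transfer form is biased but less than association", {
  mod <- model_geometric(4, V = 10, base = 2)
  r13 <- reaction_spec(c(1, 3), c(2, 2))
  kt <- transfer_K_direct(mod, r13)$value
  ktu <- transfer_K_uncorrelated(mod, r13)$value
  expect_gt(abs(log(ktu / kt)), 0) # bias witness

  # partial cancellation: transfer log-bias below association log-bias
  km <- elementary_K(mod, c(1, 1, 1, 1))$value
  kmu <- uncorrelated_K(mod, 4)$value
  expect_lt(abs(log(ktu / kt)), abs(log(kmu / km)))

  # correlations vanish in the large-volume, large-N regime: the bias
  # shrinks like 1/N along a growing-system sequence at large V
  devs <- vapply(c(12, 20, 30), function(N) {
    big <- model_geometric(N, V = 1e6, base = 2)
    abs(transfer_K_uncorrelated(big, r13)$value /
          transfer_K_direct(big, r13)$value - 1)
  }, numeric(1))
  expect_true(all(diff(devs) < 0))
  expect_lt(devs[3], 0.05)
})

test_that("probability-ratio K equals the concerted constant frame by frame", {
  m <- model_two()
  expect_equal(prob_ratio_K(m)$value, 1, tolerance = 1e-12)

  # exact equality with the m-monomer elementary constant on any series
  for (seed in c(1, 5)) {
    mod <- model_geometric(3, V = 6, base = 1.4)
    s <- sample_states(mod, 4000, seed = seed)
    expect_equal(prob_ratio_K(s)$value, elementary_K(s, c(1, 1, 1))$value,
                 tolerance = 1e-12)
  }

  # no fully-clustered frame: K = 0 with undefined error bar
  s0 <- counts_series(matrix(c(3L, 0L, 0L), 5, 3, byrow = TRUE),
                      V = 10, c_std = 1)
  k0 <- prob_ratio_K(s0)
  expect_equal(k0$value, 0)
  expect_true(is.na(k0$stderr))

  # all frames aggregated: undefined (no all-monomer frame)
  s1 <- counts_series(matrix(c(0L, 0L, 1L), 5, 3, byrow = TRUE),
                      V = 10, c_std = 1)
  expect_false(prob_ratio_K(s1)$defined)
  expect_false(uncorrelated_K(s1, 3)$defined)
})

test_that("sampled-series estimators converge to oracle values", {
  mod <- model_geometric(4, V = 8, base = 1.8)
  estimators <- list(
    function(x) elementary_K(x, c(1, 1)),
    function(x) elementary_K(x, c(1, 1, 2)),
    function(x) uncorrelated_K(x, 2)
  )
  z_ok <- 0; n_tot <- 0
  for (seed in 1:20) {
    s <- sample_states(mod, 4000, seed = seed)
    for (est in estimators) {
      truth <- est(mod)$value
      e <- est(s)
      if (!e$defined || is.na(e$stderr) || e$stderr == 0) next
      n_tot <- n_tot + 1
      if (abs(e$value - truth) < 3 * e$stderr) z_ok <- z_ok + 1
    }
  }
  expect_gte(z_ok / n_tot, 0.95)
})

test_that("estimator values are invariant under frame permutation", {
  mod <- model_geometric(4, V = 8, base = 1.8)
  s <- sample_states(mod, 2000, seed = 3)
  set.seed(14)
  perm <- series_subset(s, sample(nrow(s$counts)))
  expect_equal(elementary_K(perm, c(1, 1))$value,
               elementary_K(s, c(1, 1))$value)
  expect_equal(path_K(perm, list(c(1, 1), c(1, 2)))$value,
               path_K(s, list(c(1, 1), c(1, 2)))$value)
  expect_equal(transfer_K_direct(perm, reaction_spec(c(1, 3), c(2, 2)))$value,
               transfer_K_direct(s, reaction_spec(c(1, 3), c(2, 2)))$value)
})

test_that("free energies and cycle closures behave as state functions", {
  expect_equal(delta_G(K_estimate(1, 0), T = 300)$value, 0)
  dg <- delta_G(K_estimate(exp(1), 0), T = 300)
  expect_equal(dg$value, -2.4943, tolerance = 1e-4)
  expect_equal(dg$stderr, 0)
  dg2 <- delta_G(K_estimate(2, 0.1), T = 300)
  expect_equal(dg2$stderr, 0.0083144626 * 300 * 0.1 / 2)
  expect_error(delta_G(K_estimate(-1, 0), T = 300), "positive")

  mod <- model_geometric(5, V = 9, base = 2.2)
  cc <- cycle_closure(mod, cycle_N4, T = 300)
  expect_lt(abs(cc$value), 1e-10)

  flipped <- lapply(cycle_N4, function(s) { s$sign <- -s$sign; s })
  s <- sample_states(mod, 5000, seed = 2)
  expect_equal(cycle_closure(mod, flipped, T = 300)$value,
               -cycle_closure(mod, cycle_N4, T = 300)$value)
  expect_equal(cycle_closure(s, flipped, T = 300)$value,
               -cycle_closure(s, cycle_N4, T = 300)$value)

  bad <- cycle_N4[1:3]
  expect_error(cycle_closure(mod, bad, T = 300), "does not close")
})

test_that("series moments agree with exact moments within sampling error", {
  mod <- model_geometric(4, V = 8, base = 1.8)
  s <- sample_states(mod, 20000, seed = 11)
  for (spec in list(c("1" = 1), c("2" = 1), c("1" = 2), c("1" = 1, "2" = 1))) {
    sm <- series_moment(s, spec)
    expect_lt(abs(sm$value - exact_moment(mod, spec)), 3 * sm$stderr)
  }
  # empty spec is exactly 1 with no error
  expect_identical(series_moment(s, c()), list(value = 1, stderr = 0))
  # a frame with n_1 = 1 contributes zero to the order-2 falling factorial
  one <- counts_series(matrix(c(1L, 0L, 1L), 1, 3), V = 5, c_std = 1)
  expect_equal(series_moment(one, c("1" = 2))$value, 0)
})

test_that("block errors are zero for constants and shrink as 1/sqrt(n)", {
  const <- counts_series(matrix(c(2L, 1L), 100, 2, byrow = TRUE),
                         V = 4, c_std = 1)
  expect_equal(block_error(const, function(x) mean(x$counts[, 2]), 10), 0)
  expect_error(block_error(const, function(x) 1, 60), "too short")
  expect_error(block_error(const, function(x) 1, 1), ">= 2")

  mod <- model_geometric(3, V = 6, base = 1.5)
  lens <- c(2000, 8000, 32000)
  ses <- vapply(lens, function(n) {
    s <- sample_states(mod, n, seed = 17)
    block_error(s, function(x) mean(x$counts[, 1]), 20)
  }, numeric(1))
  slope <- coef(lm(log(ses) ~ log(lens)))[2]
  expect_lt(slope, -0.25)
  expect_gt(slope, -0.8)
})
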