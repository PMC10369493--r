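# exact ideal-cluster ensemble: enumeration, weights, moments, sampling

test_that("composition enumeration returns each integer partition once", {
  two <- enumerate_compositions(2)
  expect_length(two, 2)
  expect_true(any(vapply(two, function(x) identical(x, c(2L, 0L)), TRUE)))
  expect_true(any(vapply(two, function(x) identical(x, c(0L, 1L)), TRUE)))

  four <- enumerate_compositions(4)
  expect_length(four, 5)

  for (N in c(1, 3, 6, 9, 12)) {
    comps <- enumerate_compositions(N)
    # count matches the independent pentagonal-number oracle
    expect_identical(length(comps), as.integer(partition_count(N)))
    # each conserves particles, none repeats
    expect_true(all(vapply(comps, function(x)
      sum(seq_along(x) * x) == N, TRUE)))
    keys <- vapply(comps, paste, character(1), collapse = ",")
    expect_identical(anyDuplicated(keys), 0L)
  }
  expect_length(enumerate_compositions(12), 77)

  expect_error(enumerate_compositions(0), "positive integer")
  expect_error(enumerate_compositions(-3), "positive integer")
})

test_that("canonical weights and probabilities match direct evaluation", {
  m <- model_two() # N=2, V=10, b_2=2
  expect_equal(state_weight(c(2, 0), m), 100)
  expect_equal(state_weight(c(0, 1), m), 20)
  expect_equal(m$prob[which(m$compositions[, 2] == 1)], 1 / 6)

  # N=1: a single state with probability 1
  m1 <- cluster_model(1, V = 3, b = 1, c_std = 1)
  expect_length(m1$prob, 1)
  expect_equal(m1$prob, 1)

  # composition that does not conserve particles is rejected
  expect_error(state_weight(c(1, 1), m), "conserve")
  # degenerate parameters are rejected up front
  expect_error(cluster_model(2, V = 10, b = c(1, 0)), "positive")
  expect_error(cluster_model(2, V = -1, b = c(1, 2)), "positive")
  expect_error(cluster_model(2, V = 10, b = c(2, 2)), "b\\[1\\]")
})

test_that("state probabilities normalize to machine precision up to N = 12", {
  for (N in c(2, 5, 8, 12)) {
    for (b_base in c(0.5, 1, 3)) {
      m <- model_geometric(N, V = 7.3, base = b_base)
      expect_lt(abs(sum(m$prob) - 1), 1e-12)
    }
  }
})

test_that("exact falling-factorial moments reproduce hand-computed values", {
  m <- model_two()
  expect_equal(exact_moment(m, c("2" = 1)), 1 / 60)
  # <c_1 (c_1 - 1/V)>: only the two-monomer state contributes (2/V)(1/V)
  expect_equal(exact_moment(m, c("1" = 2)), 1 / 60)
  # empty spec is the expectation of a constant
  expect_equal(exact_moment(m, c()), 1)
  expect_equal(exact_moment(m, NULL), 1)
  # order beyond occupancy vanishes: three monomers never exist
  expect_equal(exact_moment(m, c("1" = 3)), 0)
  expect_error(exact_moment(m, c("5" = 1)), "larger than N_total")
})

test_that("closed-form K matches its definition and the moment ratio", {
  m <- model_two()
  expect_equal(closed_form_K(m, 2), 1)
  # K from the two-body moment ratio equals the closed form
  expect_equal(exact_moment(m, c("2" = 1)) / exact_moment(m, c("1" = 2)),
               closed_form_K(m, 2))

  mu <- model_unit_K(6)
  for (m_size in 2:6) expect_equal(closed_form_K(mu, m_size), 1)

  m3 <- cluster_model(3, V = 5, b = c(1, 1, 6), c_std = 2)
  expect_equal(closed_form_K(m3, 3), 2^2 * 6 / 6) # c_std^2 * b_3 / 3!

  expect_error(closed_form_K(m, 1), "2 <= m")
  expect_error(closed_form_K(m, 3), "2 <= m")
})

test_that("sampling is reproducible and converges to exact probabilities", {
  m <- model_two()
  s1 <- sample_states(m, 500, seed = 42)
  s2 <- sample_states(m, 500, seed = 42)
  expect_identical(s1$counts, s2$counts)
  expect_identical(nrow(sample_states(m, 1, seed = 1)$counts), 1L)

  big <- sample_states(m, 40000, seed = 7)
  p_hat <- mean(big$counts[, 2])
  se <- sqrt(p_hat * (1 - p_hat) / 40000)
  expect_lt(abs(p_hat - 1 / 6), 3 * se)

  # sampling leaves the caller's RNG stream untouched
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(sample_states(m, 10, seed = 3)); after <- runif(1)
  expect_identical(before, after)
})
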