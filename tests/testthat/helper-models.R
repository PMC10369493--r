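# standard small oracle models used across the tests

# b_m = m! makes every formation constant exactly 1 at c_std = 1
model_unit_K <- function(N, V = 10) {
  cluster_model(N, V, factorial(seq_len(N)), c_std = 1)
}

# geometric configuration integrals: K_m = base^(m-1) at c_std = 1
model_geometric <- function(N, V = 10, base = 2) {
  cluster_model(N, V, factorial(seq_len(N)) * base^(seq_len(N) - 1),
                c_std = 1)
}

# the reference two-particle model of the worked examples:
# P(dimer) = 1/6, <c_2> = 1/60, K = 1
model_two <- function() cluster_model(2, V = 10, b = c(1, 2), c_std = 1)

# independent partition-count oracle (Euler's pentagonal-number recurrence);
# used to certify the enumerator without sharing its algorithm
partition_count <- function(n) {
  p <- c(1, rep(0, n)) # p[k+1] = p(k)
  for (k in seq_len(n)) {
    total <- 0
    j <- 1L
    repeat {
      g1 <- j * (3 * j - 1) / 2
      g2 <- j * (3 * j + 1) / 2
      if (g1 > k && g2 > k) break
      sgn <- if (j %% 2 == 1) 1 else -1
      if (g1 <= k) total <- total + sgn * p[k - g1 + 1]
      if (g2 <= k) total <- total + sgn * p[k - g2 + 1]
      j <- j + 1L
    }
    p[k + 1] <- total
  }
  p[n + 1]
}

# the single independent two-body cycle of the 4-particle system
cycle_N4 <- list(
  list(reactants = c(1, 2), sign = +1),
  list(reactants = c(1, 3), sign = +1),
  list(reactants = c(1, 1), sign = -1),
  list(reactants = c(2, 2), sign = -1)
)
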