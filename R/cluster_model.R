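#' Exact ideal-cluster ensemble model
#'
#' Defines an exactly solvable canonical ensemble of `N_total` identical
#' particles that associate into clusters, parameterized by per-size
#' configuration integrals `b_m`. A composition with counts `n_m` carries the
#' canonical weight
#' \deqn{W(n) = \frac{N!}{\prod_m (m!)^{n_m} n_m!} \prod_m (V b_m)^{n_m},}
#' i.e. the number of ways to partition labeled particles into the clusters,
#' times a factor `V * b_m` of configurational phase space per cluster.
#' Apart from cluster formation the mixture is ideal: clusters do not
#' interact. The model gives closed-form equilibrium constants and exact
#' falling-factorial moments of the cluster counts, and serves as the
#' reference against which sampling-based estimators are verified.
#'
#' @param N_total positive integer, total particle number (practical bound
#'   around 40; enumeration is over integer partitions).
#' @param V box volume in nm^3.
#' @param b numeric vector of configuration integrals; `b[m]` has units
#'   nm^(3(m-1)) and `b[1]` must equal 1. Sizes beyond `length(b)` default
#'   to... they do not: `b` is recycled to length `N_total` with zeros
#'   disallowed, so supply a value for every size up to `N_total`.
#' @param c_std standard concentration in molecules/nm^3; defaults to 1 M.
#' @return An object of class `cluster_model` with components `N_total`, `V`,
#'   `b`, `c_std`, the enumerated `compositions` (a matrix, one row per
#'   composition) and their exact probabilities `prob`.
#' @examples
#' m <- cluster_model(N_total = 2, V = 10, b = c(1, 2), c_std = 1)
#' m$prob # P(two monomers) = 5/6, P(dimer) = 1/6
#' @seealso [exact_moment()], [closed_form_K()], [sample_states()]
#' @export
cluster_model <- function(N_total, V, b, c_std = 0.602214076) {
  if (length(N_total) != 1L || N_total < 1 || N_total != as.integer(N_total)) {
    stop("`N_total` must be a single positive integer", call. = FALSE)
  }
  if (length(V) != 1L || !is.finite(V) || V <= 0) {
    stop("`V` must be a positive volume (nm^3)", call. = FALSE)
  }
  if (length(c_std) != 1L || !is.finite(c_std) || c_std <= 0) {
    stop("`c_std` must be a positive concentration (molecules/nm^3)",
         call. = FALSE)
  }
  N_total <- as.integer(N_total)
  if (length(b) < N_total) {
    stop("`b` must supply a configuration integral for every size up to ",
         N_total, call. = FALSE)
  }
  b <- as.numeric(b[seq_len(N_total)])
  if (b[1] != 1) stop("`b[1]` must be 1 (a monomer has unit integral)",
                      call. = FALSE)
  if (any(!is.finite(b)) || any(b <= 0)) {
    stop("all configuration integrals `b_m` must be positive and finite",
         call. = FALSE)
  }

  comps <- enumerate_compositions(N_total)
  comp_mat <- do.call(rbind, comps)
  sizes <- seq_len(N_total)
  # log weight, dropping the constant N! (cancels in normalization):
  # -sum n_m log m! - sum log n_m! + sum n_m log(V b_m)
  log_vb <- log(V * b)
  log_mfac <- lfactorial(sizes)
  logw <- comp_mat %*% (log_vb - log_mfac) - rowSums(lfactorial(comp_mat))
  logw <- as.numeric(logw)
  prob <- exp(logw - max(logw))
  prob <- prob / sum(prob)

  structure(
    list(N_total = N_total, V = V, b = b, c_std = c_std,
         compositions = comp_mat, prob = prob),
    class = "cluster_model"
  )
}

#' @export
print.cluster_model <- function(x, ...) {
  cat("Ideal cluster ensemble model\n")
  cat(sprintf("  N_total = %d, V = %g nm^3, c_std = %g molecules/nm^3\n",
              x$N_total, x$V, x$c_std))
  cat(sprintf("  %d compositions enumerated; b_m = %s\n",
              nrow(x$compositions),
              paste(signif(x$b, 4), collapse = ", ")))
  invisible(x)
}

#' Canonical weight of one composition
#'
#' Unnormalized canonical weight of a composition under an ideal-cluster
#' model: the multinomial count of labeled set partitions into the given
#' cluster sizes times `prod((V * b_m)^n_m)`. Probabilities are weights
#' normalized over all compositions of `N_total`.
#'
#' @param counts integer vector, `counts[m]` = number of m-mers (may be
#'   shorter than `N_total`; missing sizes count zero).
#' @param model a [cluster_model()].
#' @return Non-negative weight (not normalized).
#' @examples
#' m <- cluster_model(2, V = 10, b = c(1, 2), c_std = 1)
#' state_weight(c(2, 0), m) # 100
#' state_weight(c(0, 1), m) # 20
#' @export
state_weight <- function(counts, model) {
  stopifnot(inherits(model, "cluster_model"))
  counts <- as.integer(counts)
  if (length(counts) < model$N_total) {
    counts <- c(counts, integer(model$N_total - length(counts)))
  }
  check_composition(counts, model$N_total)
  sizes <- seq_len(model$N_total)
  logw <- lfactorial(model$N_total) +
    sum(counts * (log(model$V * model$b) - lfactorial(sizes))) -
    sum(lfactorial(counts))
  exp(logw)
}

#' Exact falling-factorial concentration moment
#'
#' Computes the exact ensemble average
#' \deqn{E\Big[\prod_m n_m^{(k_m)}\Big] / V^{\sum_m k_m},}
#' where \eqn{n^{(k)} = n(n-1)\cdots(n-k+1)} is the falling factorial. These
#' are the correlated concentration averages entering finite-system
#' equilibrium constants: the successive \eqn{-1/V} self-correlation
#' subtractions in concentration space are products of falling factorials in
#' count space, evaluated here without cancellation error.
#'
#' @param model a [cluster_model()].
#' @param spec named numeric vector mapping cluster size to falling-factorial
#'   order, e.g. `c("1" = 2, "2" = 1)` for \eqn{\langle c_1(c_1 - 1/V) c_2\rangle}.
#'   An empty spec gives 1.
#' @return Exact moment (numeric scalar), units nm^(-3 * sum(orders)).
#' @examples
#' m <- cluster_model(2, V = 10, b = c(1, 2), c_std = 1)
#' exact_moment(m, c("2" = 1)) # <c_2> = 1/60
#' exact_moment(m, c("1" = 2)) # <c_1 (c_1 - 1/V)> = 1/60
#' @export
exact_moment <- function(model, spec) {
  stopifnot(inherits(model, "cluster_model"))
  spec <- as_moment_spec(spec, model$N_total)
  if (length(spec) == 0L) return(1)
  per_state <- rep(1, nrow(model$compositions))
  for (i in seq_along(spec)) {
    size <- as.integer(names(spec)[i])
    k <- spec[[i]]
    per_state <- per_state * falling_factorial(model$compositions[, size], k)
  }
  sum(model$prob * per_state) / model$V^sum(spec)
}

# normalize a size -> order mapping; drop zero orders, validate
as_moment_spec <- function(spec, N_total) {
  if (is.null(spec) || length(spec) == 0L) return(numeric(0))
  if (is.list(spec)) spec <- unlist(spec)
  if (is.null(names(spec)) || any(!nzchar(names(spec)))) {
    stop("moment spec must be a named vector: names are cluster sizes",
         call. = FALSE)
  }
  sizes <- suppressWarnings(as.integer(names(spec)))
  if (any(is.na(sizes)) || any(sizes < 1)) {
    stop("moment spec names must be positive integer sizes", call. = FALSE)
  }
  if (!missing(N_total) && any(sizes > N_total)) {
    stop("moment spec refers to a cluster size larger than N_total",
         call. = FALSE)
  }
  orders <- as.numeric(spec)
  if (any(orders < 0) || any(orders != as.integer(orders))) {
    stop("falling-factorial orders must be non-negative integers",
         call. = FALSE)
  }
  spec <- spec[orders > 0]
  if (anyDuplicated(names(spec))) {
    spec <- tapply(as.numeric(spec), names(spec), sum)
  }
  spec
}

# n(n-1)...(n-k+1), vectorized in n; exactly 0 when an integer n < k
falling_factorial <- function(n, k) {
  out <- rep(1, length(n))
  for (j in seq_len(k)) out <- out * (n - (j - 1))
  out[n < k] <- 0
  out
}

#' Closed-form equilibrium constant of the ideal-cluster model
#'
#' For the ideal-cluster ensemble every expression of the m-mer formation
#' constant (any reaction path, any order of elementary steps) evaluates to
#' the same volume- and size-independent value
#' \deqn{K_m = (c^\circ)^{m-1}\, b_m / m!.}
#' This is the analytic reference against which the estimator expressions
#' are verified.
#'
#' @param model a [cluster_model()].
#' @param m cluster size, `2 <= m <= N_total`.
#' @return Dimensionless equilibrium constant.
#' @examples
#' m <- cluster_model(2, V = 10, b = c(1, 2), c_std = 1)
#' closed_form_K(m, 2) # 1
#' @export
closed_form_K <- function(model, m) {
  stopifnot(inherits(model, "cluster_model"))
  if (length(m) != 1L || m != as.integer(m) || m < 2 || m > model$N_total) {
    stop("`m` must be an integer with 2 <= m <= N_total", call. = FALSE)
  }
  model$c_std^(m - 1) * model$b[m] / factorial(m)
}

# closed-form K of an arbitrary elementary association: reactant multiset
# `reactants` (sizes), product s = sum(reactants). Telescopes from the
# formation constants K_m = c_std^(m-1) b_m / m! (with K_1 = 1).
closed_form_elementary_K <- function(model, reactants) {
  s <- sum(reactants)
  formation <- function(m) model$c_std^(m - 1) * model$b[m] / factorial(m)
  formation(s) / prod(vapply(reactants, formation, numeric(1)))
}

#' Draw i.i.d. composition samples from the exact distribution
#'
#' Samples compositions from an ideal-cluster model's exact probabilities,
#' returning a [counts_series()]. Useful as a synthetic-data generator with
#' known ground truth: every estimator in the package converges to the
#' model's closed-form constants on such series.
#'
#' @param model a [cluster_model()].
#' @param n_frames number of frames to draw.
#' @param seed integer seed; the draw is reproducible and does not disturb
#'   the caller's RNG state.
#' @return A [counts_series()] with provenance metadata.
#' @examples
#' m <- cluster_model(2, V = 10, b = c(1, 2), c_std = 1)
#' s <- sample_states(m, 1000, seed = 1)
#' mean(s$counts[, 2]) # approx 1/6
#' @export
sample_states <- function(model, n_frames, seed = 1L) {
  stopifnot(inherits(model, "cluster_model"))
  if (length(n_frames) != 1L || n_frames < 1) {
    stop("`n_frames` must be >= 1", call. = FALSE)
  }
  n_frames <- as.integer(n_frames)
  idx <- local_rng(seed, sample.int(nrow(model$compositions), n_frames,
                                    replace = TRUE, prob = model$prob))
  counts_series(
    counts = model$compositions[idx, , drop = FALSE],
    V = model$V, c_std = model$c_std, N_total = model$N_total,
    provenance = list(sampler = "ideal_cluster_ensemble", seed = seed,
                      b = model$b)
  )
}

# run `expr` under a temporary RNG seed, restoring the caller's state
local_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
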