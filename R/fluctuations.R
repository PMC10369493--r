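# Relative-fluctuation identities linking average cluster numbers to
# correlated count fluctuations.

#' Count expression: falling-factorial product over a size multiset
#'
#' Builds the count-space observable \eqn{\prod_m N_m^{(k_m)}} from a
#' multiset of cluster sizes (repeats raise the falling-factorial order),
#' e.g. `count_product(c(1, 1))` is \eqn{N_1(N_1 - 1)} and
#' `count_product(3)` is \eqn{N_3}. The returned function maps a frame
#' matrix of counts to per-frame values; pass it to
#' [relative_fluctuation()].
#'
#' @param sizes integer multiset of cluster sizes.
#' @return Function: counts matrix -> numeric vector (one value per row).
#' @export
count_product <- function(sizes) {
  spec <- sizes_to_spec(check_sizes(sizes, NULL))
  force(spec)
  function(counts) {
    vals <- rep(1, nrow(counts))
    for (i in seq_along(spec)) {
      size <- as.integer(names(spec)[i])
      vals <- vals * falling_factorial(counts[, size], spec[[i]])
    }
    vals
  }
}

# evaluate a count expression (function or size multiset) on a backend:
# returns list(mean = <zeta>, values = per-state values, prob/weights)
eval_count_expr <- function(x, expr) {
  f <- if (is.function(expr)) expr else count_product(expr)
  if (inherits(x, "cluster_model")) {
    v <- f(x$compositions)
    list(values = v, w = x$prob)
  } else {
    v <- f(x$counts)
    list(values = v, w = rep(1 / length(v), length(v)))
  }
}

#' Relative fluctuation of two count observables
#'
#' \deqn{l(\zeta, \eta) = \frac{\langle\zeta\eta\rangle}
#'   {\langle\zeta\rangle\langle\eta\rangle} - 1,}
#' the normalized covariance of two functions of the cluster counts. Zero
#' for independent observables; symmetric in its arguments.
#'
#' @param x a [counts_series()] or [cluster_model()].
#' @param zeta,eta count expressions: either functions of the counts matrix
#'   (see [count_product()]) or size multisets, which are interpreted as
#'   falling-factorial products.
#' @return Numeric scalar.
#' @examples
#' mod <- cluster_model(2, V = 10, b = c(1, 2), c_std = 1)
#' relative_fluctuation(mod, 1, 1) # l(N_1, N_1) from exact moments
#' @export
relative_fluctuation <- function(x, zeta, eta) {
  a <- eval_count_expr(x, zeta)
  b <- eval_count_expr(x, eta)
  mz <- sum(a$values * a$w)
  me <- sum(b$values * b$w)
  if (mz == 0 || me == 0) {
    stop("relative fluctuation undefined: an observable has zero mean",
         call. = FALSE)
  }
  sum(a$values * b$values * a$w) / (mz * me) - 1
}

#' Fluctuation relation for the average number of (i+j)-mers
#'
#' The two-body binding constant ties the mean cluster number to correlated
#' count fluctuations:
#' \deqn{\langle N_{i+j}\rangle = \frac{K^{2b}_{i+j}}{c^\circ V}
#'   \langle N_i\rangle(\langle N_j\rangle - \delta_{ij})
#'   \,[1 + l(N_i, N_j - \delta_{ij})]
#'   = \frac{K^{2b}_{i+j}}{c^\circ V}\langle N_i (N_j - \delta_{ij})\rangle.}
#' On exact oracle moments the two sides agree identically (the relation is
#' a restatement of the correlated K expression in count space); on sampled
#' series they agree within joint sampling error even though both clusters
#' participate in further equilibria.
#'
#' @param x a [counts_series()] or [cluster_model()].
#' @param i,j cluster sizes with `i + j <= N_total`.
#' @param K optional [K_estimate()] for the i+j two-body constant; computed
#'   from `x` via [elementary_K()] when missing.
#' @param n_blocks blocks for the error bars (series backend).
#' @return List with `lhs` (\eqn{\langle N_{i+j}\rangle}), `rhs`, and their
#'   standard errors (`0` on the exact backend).
#' @export
fluctuation_relation <- function(x, i, j, K = NULL, n_blocks = 20L) {
  sizes <- check_sizes(c(i, j), backend_N(x), "sizes i, j")
  i <- sizes[1]; j <- sizes[2]
  if (is.null(K)) K <- elementary_K(x, c(i, j), n_blocks = n_blocks)
  if (!K$defined) stop("K estimate undefined; cannot form the relation",
                       call. = FALSE)
  V <- backend_V(x); c_std <- backend_c_std(x)
  lhs_fn <- function(b) ff_moment(b, setNames(1, i + j)) * V # <N_{i+j}>
  rhs_fn <- function(b) {
    K$value / (c_std * V) * ff_moment(b, sizes_to_spec(c(i, j))) * V^2
  }
  if (inherits(x, "cluster_model")) {
    return(list(lhs = lhs_fn(x), rhs = rhs_fn(x), lhs_se = 0, rhs_se = 0))
  }
  lhs_se <- block_error(x, lhs_fn, n_blocks)
  rhs_se0 <- block_error(x, rhs_fn, n_blocks)
  # fold the K uncertainty into the rhs error bar
  rhs <- rhs_fn(x)
  rel_K <- if (is.na(K$stderr)) 0 else K$stderr / K$value
  list(lhs = lhs_fn(x), rhs = rhs, lhs_se = lhs_se,
       rhs_se = sqrt(rhs_se0^2 + (rhs * rel_K)^2))
}

#' Equality of relative fluctuations across partitions of a cluster size
#'
#' If `i + j = k + s`, the fluctuation relation applied to both
#' decompositions of the same \eqn{\langle N_{i+j}\rangle} forces
#' \deqn{l[N_{i+j},\, N_i(N_j-\delta_{ij})] =
#'       l[N_{k+s},\, N_k(N_s-\delta_{ks})].}
#' The equality is exact on the ideal-cluster oracle and holds within
#' sampling error on simulated series; it is the sharpest check that the
#' fluctuation-relation transcription is correct.
#'
#' @param x a [counts_series()] or [cluster_model()].
#' @param i,j,k,s cluster sizes with `i + j == k + s <= N_total`.
#' @param n_blocks blocks for the error bars.
#' @return List with `l_ij`, `l_ks` and standard errors.
#' @examples
#' mod <- cluster_model(8, V = 50, b = factorial(1:8), c_std = 1)
#' pe <- partition_fluctuation_equality(mod, 1, 3, 2, 2)
#' abs(pe$l_ij - pe$l_ks) < 1e-10
#' @export
partition_fluctuation_equality <- function(x, i, j, k, s, n_blocks = 20L) {
  sz <- check_sizes(c(i, j, k, s), NULL, "sizes")
  if (sz[1] + sz[2] != sz[3] + sz[4]) {
    stop("need i + j == k + s", call. = FALSE)
  }
  if (sz[1] + sz[2] > backend_N(x)) {
    stop("i + j exceeds N_total", call. = FALSE)
  }
  l_fn <- function(a, b) {
    function(x) relative_fluctuation(x, count_product(a + b),
                                     count_product(c(a, b)))
  }
  f_ij <- l_fn(sz[1], sz[2]); f_ks <- l_fn(sz[3], sz[4])
  if (inherits(x, "cluster_model")) {
    return(list(l_ij = f_ij(x), l_ks = f_ks(x), l_ij_se = 0, l_ks_se = 0))
  }
  list(l_ij = f_ij(x), l_ks = f_ks(x),
       l_ij_se = block_error(x, f_ij, n_blocks),
       l_ks_se = block_error(x, f_ks, n_blocks))
}
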