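# Every equilibrium-constant expression is a pure function of either a
# sampled counts_series (time averages + block errors) or a cluster_model
# (exact ensemble moments, zero error). `x` below is either backend.

#' Equilibrium-constant estimate
#'
#' Container for a dimensionless equilibrium constant: the value, a
#' block-average standard error, and a label recording which expression
#' (reaction path) produced it. Estimates whose denominator moment vanishes
#' (a species combination never observed) are returned flagged as undefined
#' rather than raising, so scans over volumes or system sizes can report
#' gaps.
#'
#' @param value dimensionless equilibrium constant.
#' @param stderr standard error (0 for exact-oracle backends, `NA` when not
#'   estimable).
#' @param expression label of the expression/path.
#' @param n_blocks blocks used for the error bar (`NA` for exact backends).
#' @param defined logical; `FALSE` marks an undefined estimate.
#' @return Object of class `K_estimate`.
#' @export
K_estimate <- function(value, stderr = NA_real_, expression = "K",
                       n_blocks = NA_integer_, defined = TRUE) {
  structure(list(value = value, stderr = stderr, expression = expression,
                 n_blocks = n_blocks, defined = defined),
            class = "K_estimate")
}

#' @export
print.K_estimate <- function(x, ...) {
  if (!x$defined) {
    cat(sprintf("%s: undefined (denominator species never observed)\n",
                x$expression))
  } else if (is.na(x$stderr)) {
    cat(sprintf("%s = %.6g\n", x$expression, x$value))
  } else {
    cat(sprintf("%s = %.6g +/- %.2g", x$expression, x$value, x$stderr))
    if (!is.na(x$n_blocks)) cat(sprintf("  (%d blocks)", x$n_blocks))
    cat("\n")
  }
  invisible(x)
}

# evaluate a scalar statistic on either backend, attaching block errors on
# series; fn must return NA (not error) on undefined input
evaluate_estimate <- function(x, fn, label, n_blocks = 20L) {
  if (inherits(x, "cluster_model")) {
    v <- fn(x)
    return(K_estimate(v, stderr = 0, expression = label,
                      defined = is.finite(v)))
  }
  if (!inherits(x, "counts_series")) {
    stop("expected a cluster_model or counts_series", call. = FALSE)
  }
  v <- fn(x)
  if (!is.finite(v)) {
    return(K_estimate(NA_real_, NA_real_, label, n_blocks, defined = FALSE))
  }
  se <- if (nrow(x$counts) >= 2L * n_blocks) {
    block_error(x, fn, n_blocks)
  } else NA_real_
  K_estimate(v, se, label, as.integer(n_blocks))
}

check_sizes <- function(sizes, N_total, what = "cluster sizes") {
  sizes <- as.integer(sizes)
  if (length(sizes) == 0L || any(is.na(sizes)) || any(sizes < 1)) {
    stop(what, " must be positive integers", call. = FALSE)
  }
  if (!is.null(N_total) && sum(sizes) > N_total) {
    stop(what, " sum to more than N_total particles", call. = FALSE)
  }
  sizes
}

# multiset of sizes -> falling-factorial moment spec (repeats raise order)
sizes_to_spec <- function(sizes) {
  tb <- table(sizes)
  setNames(as.numeric(tb), names(tb))
}

backend_N <- function(x) x$N_total
backend_c_std <- function(x) x$c_std
backend_V <- function(x) x$V

#' Correlation-aware equilibrium constant of an elementary association
#'
#' Equilibrium constant for the elementary reaction in which the clusters in
#' `reactants` (a multiset of sizes) associate into a single cluster of size
#' `s = sum(reactants)`:
#' \deqn{K = \frac{\langle c_s\rangle (c^\circ)^{n-1}}
#'              {\big\langle \prod \text{(falling-factorial concentrations)}\big\rangle},}
#' where `n` is the number of reacting clusters and a size repeated k times
#' contributes \eqn{c(c-1/V)\cdots(c-(k-1)/V)} — the successive self-
#' correlation subtractions of a finite system. With two reactants this is
#' the two-body binding constant; with m monomers it is the concerted m-body
#' constant; mixed cases (e.g. two monomers + one dimer) are covered by the
#' same kernel.
#'
#' @param x a [counts_series()] or [cluster_model()].
#' @param reactants integer multiset of reacting cluster sizes, e.g.
#'   `c(1, 1)` for dimerization, `c(1, 1, 2)` for a three-body step.
#' @param n_blocks blocks for the error bar (series backend).
#' @return A [K_estimate()].
#' @examples
#' m <- cluster_model(2, V = 10, b = c(1, 2), c_std = 1)
#' elementary_K(m, c(1, 1)) # exactly 1
#' @export
elementary_K <- function(x, reactants, n_blocks = 20L) {
  reactants <- check_sizes(reactants, backend_N(x), "reactant sizes")
  s <- sum(reactants)
  n <- length(reactants)
  spec <- sizes_to_spec(reactants)
  label <- sprintf("K%db_%s", n, paste(sort(reactants), collapse = "+"))
  c_std <- backend_c_std(x)
  fn <- function(b) {
    den <- ff_moment(b, spec)
    if (!is.finite(den) || den <= 0) return(NA_real_)
    num <- ff_moment(b, setNames(1, s))
    num * c_std^(n - 1) / den
  }
  evaluate_estimate(x, fn, label, n_blocks)
}

#' Equilibrium constant of a multimerization along a reaction path
#'
#' Multiplies the elementary constants of a sequence of association steps
#' whose net result is `m` monomers forming one m-mer. Different paths give
#' different expressions in terms of correlated averages, but — free energy
#' being a state function — the same value; on the exact oracle the
#' agreement is to machine precision, which is the central consistency
#' property of these estimators.
#'
#' @param x a [counts_series()] or [cluster_model()].
#' @param path list of reactant multisets, one per elementary step (each
#'   step's product is the sum of its reactants). Steps may repeat: listing
#'   `c(1, 1)` twice squares the dimerization constant, as needed for e.g.
#'   the 2+2 route to a tetramer.
#' @param n_blocks blocks for the error bar.
#' @return A [K_estimate()] labeled with the path.
#' @examples
#' m <- cluster_model(4, V = 10, b = factorial(1:4), c_std = 1)
#' path_K(m, list(c(1, 1), c(1, 2), c(1, 3)))  # gradual monomer additions
#' path_K(m, list(c(1, 1), c(1, 1), c(2, 2)))  # dimer + dimer route
#' @export
path_K <- function(x, path, n_blocks = 20L) {
  if (!is.list(path) || length(path) == 0L) {
    stop("`path` must be a non-empty list of reactant multisets",
         call. = FALSE)
  }
  N <- backend_N(x)
  # net ledger over sizes: reactants consumed, step product produced
  net <- numeric(N)
  for (step in path) {
    step <- check_sizes(step, N, "step reactant sizes")
    for (sz in step) net[sz] <- net[sz] - 1
    net[sum(step)] <- net[sum(step)] + 1
  }
  m <- which(net > 0)
  if (length(m) != 1L || net[m] != 1 || m < 2 || net[1] != -m ||
      any(net[-c(1L, m)] != 0)) {
    stop("path does not telescope to `m monomers -> one m-mer`",
         call. = FALSE)
  }
  steps <- lapply(path, function(s) sizes_to_spec(check_sizes(s, N)))
  prods <- vapply(path, sum, numeric(1))
  ns <- vapply(path, length, numeric(1))
  c_std <- backend_c_std(x)
  label <- sprintf("K%d[path %s]", m,
                   paste(vapply(path, function(s)
                     paste(sort(s), collapse = "+"), character(1)),
                     collapse = "; "))
  fn <- function(b) {
    val <- 1
    for (i in seq_along(steps)) {
      den <- ff_moment(b, steps[[i]])
      if (!is.finite(den) || den <= 0) return(NA_real_)
      num <- ff_moment(b, setNames(1, prods[i]))
      val <- val * num * c_std^(ns[i] - 1) / den
    }
    val
  }
  evaluate_estimate(x, fn, label, n_blocks)
}

#' Uncorrelated (textbook) expression of the multimerization constant
#'
#' The commonly applied expression that ignores all correlations between
#' particle numbers,
#' \deqn{K'_m = \langle c_{A_m}\rangle (c^\circ)^{m-1} / \langle c_A\rangle^m.}
#' For small systems this quantity is not constant: it varies with volume
#' and particle number and does not converge to the true `K_m` even at large
#' volume, because self-correlations remain significant at small `N_total`.
#' It is provided as the comparison baseline.
#'
#' @param x a [counts_series()] or [cluster_model()].
#' @param m cluster size of the product.
#' @param n_blocks blocks for the error bar.
#' @return A [K_estimate()].
#' @examples
#' mod <- cluster_model(2, V = 10, b = c(1, 2), c_std = 1)
#' uncorrelated_K(mod, 2) # 0.6, while elementary_K gives 1
#' @export
uncorrelated_K <- function(x, m, n_blocks = 20L) {
  m <- check_sizes(m, backend_N(x), "`m`")
  if (length(m) != 1L) stop("`m` must be a single size", call. = FALSE)
  c_std <- backend_c_std(x)
  fn <- function(b) {
    c1 <- ff_moment(b, c("1" = 1))
    if (!is.finite(c1) || c1 <= 0) return(NA_real_)
    ff_moment(b, setNames(1, m)) * c_std^(m - 1) / c1^m
  }
  evaluate_estimate(x, fn, sprintf("K'_%d", m), n_blocks)
}

#' Reaction specification
#'
#' A multiset of reactant cluster sizes and (for transfer reactions) product
#' cluster sizes. Particle conservation is enforced; an association reaction
#' may omit `products`, implying a single product of the summed size.
#'
#' @param reactants integer multiset of reactant sizes.
#' @param products integer multiset of product sizes (default: one cluster
#'   of size `sum(reactants)`).
#' @return Object of class `reaction_spec`.
#' @examples
#' reaction_spec(c(1, 3), c(2, 2)) # the transfer A + A3 <-> 2 A2
#' @export
reaction_spec <- function(reactants, products = NULL) {
  reactants <- check_sizes(reactants, NULL, "reactant sizes")
  if (is.null(products)) products <- sum(reactants)
  products <- check_sizes(products, NULL, "product sizes")
  if (sum(reactants) != sum(products)) {
    stop("reaction does not conserve particles", call. = FALSE)
  }
  structure(list(reactants = sort(reactants), products = sort(products)),
            class = "reaction_spec")
}

#' @export
print.reaction_spec <- function(x, ...) {
  side <- function(s) paste(sprintf("A_%d", s), collapse = " + ")
  cat(side(x$reactants), "<->", side(x$products), "\n")
  invisible(x)
}

rxn_label <- function(rxn, tag) {
  sprintf("K%s[%s>%s]", tag,
          paste(rxn$reactants, collapse = "+"),
          paste(rxn$products, collapse = "+"))
}

#' Transfer-reaction constant from correlated averages (direct form)
#'
#' Equilibrium constant of a transfer (exchange) reaction — association and
#' dissociation on both sides, e.g. `A + A3 <-> 2 A2` — as the ratio of the
#' product-side to reactant-side correlated concentration averages, with
#' repeated species carrying the same falling-factorial self-correlation
#' subtractions as in [elementary_K()]. Both sides hold the same number of
#' clusters, so the standard concentration cancels and never enters.
#'
#' @param x a [counts_series()] or [cluster_model()].
#' @param rxn a [reaction_spec()] with equally many reactant and product
#'   clusters.
#' @param n_blocks blocks for the error bar.
#' @return A [K_estimate()].
#' @examples
#' mod <- cluster_model(4, V = 10, b = factorial(1:4), c_std = 1)
#' transfer_K_direct(mod, reaction_spec(c(1, 3), c(2, 2))) # exactly 1
#' @export
transfer_K_direct <- function(x, rxn, n_blocks = 20L) {
  stopifnot(inherits(rxn, "reaction_spec"))
  if (length(rxn$reactants) != length(rxn$products)) {
    stop("transfer reaction needs equal falling-factorial order on both ",
         "sides (same number of clusters)", call. = FALSE)
  }
  check_sizes(rxn$reactants, backend_N(x))
  spec_r <- sizes_to_spec(rxn$reactants)
  spec_p <- sizes_to_spec(rxn$products)
  fn <- function(b) {
    den <- ff_moment(b, spec_r)
    if (!is.finite(den) || den <= 0) return(NA_real_)
    ff_moment(b, spec_p) / den
  }
  evaluate_estimate(x, fn, rxn_label(rxn, "trans"), n_blocks)
}

#' Transfer-reaction constant as a ratio of two-body binding constants
#'
#' Writes a monomer-transfer reaction `A_i + A_{j+1} <-> A_{i+1} + A_j` as
#' the difference of two monomer-addition reactions and evaluates its
#' constant as the ratio of the corresponding two-body binding constants,
#' e.g. `A + A3 <-> 2 A2` as `K2b_{1+1} / K2b_{1+2}`. Agrees with
#' [transfer_K_direct()] exactly on oracle moments and within joint
#' sampling error on simulated series.
#'
#' @inheritParams transfer_K_direct
#' @return A [K_estimate()].
#' @export
transfer_K_ratio <- function(x, rxn, n_blocks = 20L) {
  stopifnot(inherits(rxn, "reaction_spec"))
  if (identical(rxn$reactants, rxn$products)) {
    return(K_estimate(1, 0, rxn_label(rxn, "trans-ratio")))
  }
  if (length(rxn$reactants) != 2L || length(rxn$products) != 2L) {
    stop("ratio form covers monomer-transfer reactions with two clusters ",
         "on each side", call. = FALSE)
  }
  r <- rxn$reactants
  decomp <- NULL
  for (perm in list(r, rev(r))) {
    a <- perm[1]           # size gaining the monomer
    b_ <- perm[2] - 1L     # product of the subtracted addition
    if (b_ >= 1L && identical(sort(c(a + 1L, b_)), rxn$products)) {
      decomp <- c(a, b_)
      break
    }
  }
  if (is.null(decomp)) {
    stop("reaction is not a difference of two monomer additions",
         call. = FALSE)
  }
  check_sizes(rxn$reactants, backend_N(x))
  spec_num_den <- sizes_to_spec(c(1, decomp[1]))
  spec_den_den <- sizes_to_spec(c(1, decomp[2]))
  fn <- function(b) {
    d1 <- ff_moment(b, spec_num_den)
    n2 <- ff_moment(b, setNames(1, decomp[2] + 1))
    if (!is.finite(d1) || d1 <= 0 || !is.finite(n2) || n2 <= 0) {
      return(NA_real_)
    }
    k_num <- ff_moment(b, setNames(1, decomp[1] + 1)) / d1
    k_den <- n2 / ff_moment(b, spec_den_den)
    k_num / k_den
  }
  evaluate_estimate(x, fn, rxn_label(rxn, "trans-ratio"), n_blocks)
}

#' Uncorrelated transfer-reaction expression
#'
#' The transfer analogue of [uncorrelated_K()]: products of mean
#' concentrations on each side, with all cross-correlations and `1/V`
#' self-correlation terms dropped. Not constant for small systems, though
#' its bias is smaller than for association constants because correlations
#' on the two sides partially cancel.
#'
#' @inheritParams transfer_K_direct
#' @return A [K_estimate()].
#' @export
transfer_K_uncorrelated <- function(x, rxn, n_blocks = 20L) {
  stopifnot(inherits(rxn, "reaction_spec"))
  if (length(rxn$reactants) != length(rxn$products)) {
    stop("transfer reaction needs the same number of clusters on both sides",
         call. = FALSE)
  }
  check_sizes(rxn$reactants, backend_N(x))
  fn <- function(b) {
    means_r <- vapply(rxn$reactants, function(s)
      ff_moment(b, setNames(1, s)), numeric(1))
    if (any(!is.finite(means_r)) || any(means_r <= 0)) return(NA_real_)
    means_p <- vapply(rxn$products, function(s)
      ff_moment(b, setNames(1, s)), numeric(1))
    prod(means_p) / prod(means_r)
  }
  evaluate_estimate(x, fn, rxn_label(rxn, "'trans"), n_blocks)
}

#' Multimerization constant from the probability ratio of end states
#'
#' For the special case `N_total = m`, the concerted m-body constant reduces
#' to a ratio of occupation probabilities of the two end states:
#' \deqn{K_m = \frac{f^{A_m}}{f^{mA}} \frac{(c^\circ V)^{m-1}}{m!},}
#' where \eqn{f^{A_m}} is the fraction of frames in which all particles form
#' one m-mer and \eqn{f^{mA}} the fraction in which all are monomers. The
#' identity is frame-by-frame: the m-fold falling-factorial moment is
#' nonzero only on all-monomer frames and the numerator only on m-mer
#' frames, so this equals [elementary_K()] with `m` monomer reactants
#' evaluated on the same series, exactly.
#'
#' @param x a [counts_series()] or [cluster_model()] with `N_total = m`.
#' @param n_blocks blocks for the error bar.
#' @return A [K_estimate()]. If no fully-clustered frame was observed the
#'   value is 0 with an undefined error bar; if no all-monomer frame was
#'   observed the estimate is flagged undefined.
#' @examples
#' mod <- cluster_model(2, V = 10, b = c(1, 2), c_std = 1)
#' prob_ratio_K(mod) # 1: (1/6)/(5/6) * 10/2
#' @export
prob_ratio_K <- function(x, n_blocks = 20L) {
  m <- backend_N(x)
  if (m < 2) stop("probability-ratio form needs N_total >= 2", call. = FALSE)
  c_std <- backend_c_std(x)
  V <- backend_V(x)
  pref <- (c_std * V)^(m - 1) / factorial(m)
  frac <- function(b, test_col, test_val) {
    if (inherits(b, "cluster_model")) {
      sum(b$prob[b$compositions[, test_col] == test_val])
    } else {
      mean(b$counts[, test_col] == test_val)
    }
  }
  fn <- function(b) {
    f_mA <- frac(b, 1L, m)        # all monomers
    f_Am <- frac(b, m, 1L)        # single m-mer
    if (f_mA <= 0) return(NA_real_)
    f_Am / f_mA * pref
  }
  est <- evaluate_estimate(x, fn, sprintf("Kprob_%d", m), n_blocks)
  if (est$defined && est$value == 0) est$stderr <- NA_real_
  est
}

#' Standard free energy from an equilibrium constant
#'
#' \eqn{\Delta G^\circ = -RT \ln K}, with the error bar propagated as
#' \eqn{RT \cdot \mathrm{se}(K)/K}. Gas constant
#' `R = 0.0083144626 kJ/(mol K)`.
#'
#' @param K a [K_estimate()] or a positive number.
#' @param T temperature in K.
#' @return List with `value` and `stderr`, in kJ/mol.
#' @examples
#' delta_G(K_estimate(exp(1), 0), T = 300) # -2.4943 kJ/mol
#' @export
delta_G <- function(K, T) {
  if (inherits(K, "K_estimate")) {
    if (!K$defined) stop("cannot take delta G of an undefined K estimate",
                         call. = FALSE)
    val <- K$value; se <- K$stderr
  } else {
    val <- K; se <- NA_real_
  }
  if (!is.finite(val) || val <= 0) {
    stop("`K` must be positive for a free energy", call. = FALSE)
  }
  rt <- .R_GAS * T
  list(value = -rt * log(val),
       stderr = if (is.na(se)) NA_real_ else rt * se / val)
}

#' Thermodynamic cycle closure
#'
#' Signed sum of standard free energies \eqn{\pm\Delta G = \mp RT\ln K}
#' around a closed loop of association reactions. Free energy is a state
#' function, so the sum vanishes identically on exact oracle moments; on
#' sampled series its magnitude is a convergence diagnostic. The whole
#' closure is block-averaged as one statistic, so correlations among the
#' constituent constants are accounted for in the error bar.
#'
#' @param x a [counts_series()] or [cluster_model()].
#' @param cycle list of steps, each `list(reactants = <sizes>, sign = +-1)`;
#'   the signed reactions must sum to the null reaction.
#' @param T temperature in K (only sets the kJ/mol scale).
#' @param n_blocks blocks for the error bar.
#' @return List with `value` (kJ/mol) and `stderr`.
#' @examples
#' mod <- cluster_model(4, V = 10, b = c(1, 2, 5, 14), c_std = 1)
#' cc <- cycle_closure(mod, list(
#'   list(reactants = c(1, 2), sign = +1),
#'   list(reactants = c(1, 3), sign = +1),
#'   list(reactants = c(1, 1), sign = -1),
#'   list(reactants = c(2, 2), sign = -1)), T = 300)
#' abs(cc$value) < 1e-10
#' @export
cycle_closure <- function(x, cycle, T = 300, n_blocks = 20L) {
  N <- backend_N(x)
  net <- numeric(N)
  for (st in cycle) {
    rs <- check_sizes(st$reactants, N, "cycle step sizes")
    sgn <- st$sign
    if (!sgn %in% c(-1, 1)) stop("each cycle step needs sign +1 or -1",
                                 call. = FALSE)
    for (sz in rs) net[sz] <- net[sz] - sgn
    net[sum(rs)] <- net[sum(rs)] + sgn
  }
  if (any(net != 0)) {
    stop("cycle does not close: signed reactions do not sum to the null ",
         "reaction", call. = FALSE)
  }
  c_std <- backend_c_std(x)
  rt <- .R_GAS * T
  steps <- lapply(cycle, function(st) {
    rs <- sort(as.integer(st$reactants))
    list(spec = sizes_to_spec(rs), s = sum(rs), n = length(rs),
         sign = st$sign)
  })
  fn <- function(b) {
    total <- 0
    for (st in steps) {
      den <- ff_moment(b, st$spec)
      num <- ff_moment(b, setNames(1, st$s))
      if (!is.finite(den) || den <= 0 || !is.finite(num) || num <= 0) {
        return(NA_real_)
      }
      total <- total + st$sign * (-rt * log(num * c_std^(st$n - 1) / den))
    }
    total
  }
  if (inherits(x, "cluster_model")) {
    return(list(value = fn(x), stderr = 0))
  }
  v <- fn(x)
  se <- if (is.finite(v) && nrow(x$counts) >= 2L * n_blocks) {
    block_error(x, fn, n_blocks)
  } else NA_real_
  list(value = v, stderr = se)
}
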