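# Scripted reproductions of the two experiment designs: R1 varies the box
# length at fixed particle number; R2 varies the particle number at fixed
# concentration (box length derived); oracle scans do the same on the exact
# ideal-cluster ensemble.

#' Equilibrium-constant expressions for scans
#'
#' Small wrappers pairing an estimator with a label so a scan can evaluate a
#' list of expressions at every grid point: `expr_elementary()` for
#' [elementary_K()], `expr_path()` for [path_K()], `expr_uncorrelated()` for
#' [uncorrelated_K()], `expr_transfer()` for the transfer forms, and
#' `expr_prob_ratio()` for [prob_ratio_K()].
#'
#' @param reactants,path,m,rxn,form arguments forwarded to the estimator.
#' @param n_blocks blocks for error bars.
#' @return An object of class `K_expression` (a label plus an evaluator).
#' @name K_expressions
NULL

new_K_expression <- function(label, fn) {
  structure(list(label = label, fn = fn), class = "K_expression")
}

#' @rdname K_expressions
#' @export
expr_elementary <- function(reactants, n_blocks = 20L) {
  reactants <- sort(as.integer(reactants))
  new_K_expression(
    sprintf("K%db_%s", length(reactants), paste(reactants, collapse = "+")),
    function(x) elementary_K(x, reactants, n_blocks = n_blocks))
}

#' @rdname K_expressions
#' @export
expr_path <- function(path, n_blocks = 20L) {
  lbl <- sprintf("K%d[path %s]", sum(path[[length(path)]]),
                 paste(vapply(path, function(s)
                   paste(sort(s), collapse = "+"), character(1)),
                   collapse = "; "))
  new_K_expression(lbl, function(x) path_K(x, path, n_blocks = n_blocks))
}

#' @rdname K_expressions
#' @export
expr_uncorrelated <- function(m, n_blocks = 20L) {
  new_K_expression(sprintf("K'_%d", m),
                   function(x) uncorrelated_K(x, m, n_blocks = n_blocks))
}

#' @rdname K_expressions
#' @export
expr_transfer <- function(rxn, form = c("direct", "ratio", "uncorrelated"),
                          n_blocks = 20L) {
  form <- match.arg(form)
  est <- switch(form, direct = transfer_K_direct, ratio = transfer_K_ratio,
                uncorrelated = transfer_K_uncorrelated)
  tag <- switch(form, direct = "trans", ratio = "trans-ratio",
                uncorrelated = "'trans")
  new_K_expression(rxn_label(rxn, tag),
                   function(x) est(x, rxn, n_blocks = n_blocks))
}

#' @rdname K_expressions
#' @export
expr_prob_ratio <- function(n_blocks = 20L) {
  new_K_expression("Kprob",
                   function(x) prob_ratio_K(x, n_blocks = n_blocks))
}

#' Scan configuration
#'
#' Describes one experiment series. Modes:
#' * `"R1-volume-scan"`: Metropolis sampling of a fixed-`N` LJ system over a
#'   grid of box lengths (`grid` = L_box values, nm); `base` is a
#'   [simulation_spec()] whose `L_box` is replaced grid-point-wise.
#' * `"R2-size-scan"`: LJ sampling over a grid of particle numbers at fixed
#'   concentration (`grid` = N values; `concentration` in molecules/nm^3;
#'   L_box derived by [derive_box_length()]).
#' * `"oracle-scan"`: exact ideal-cluster ensemble over a grid of volumes
#'   (`base` = list with `N_total`, `b`, `c_std`, `grid` = V values) or of
#'   particle numbers (`grid_var = "N_total"`, fixed `concentration` or
#'   fixed `base$V`).
#'
#' @param mode one of `"R1-volume-scan"`, `"R2-size-scan"`, `"oracle-scan"`.
#' @param base a [simulation_spec()] (sampling modes) or a list with
#'   `N_total`, `b`, `c_std` (oracle mode).
#' @param grid numeric grid (non-empty): box lengths, particle numbers or
#'   volumes according to the mode.
#' @param expressions list of `K_expression` objects (see [K_expressions]).
#' @param n_sweeps,thin,equil_frac,adapt sampling lengths for the LJ modes.
#' @param concentration fixed number density (molecules/nm^3) for
#'   `"R2-size-scan"` and for oracle size scans.
#' @param grid_var for `"oracle-scan"`: `"V"` (default) or `"N_total"`.
#' @param c_std standard concentration for the estimators (sampling modes).
#' @param seed base seed; grid point `i` uses `seed + i - 1`.
#' @return Object of class `scan_config`.
#' @export
scan_config <- function(mode = c("oracle-scan", "R1-volume-scan",
                                 "R2-size-scan"),
                        base, grid, expressions,
                        n_sweeps = 1e5, thin = 10L, equil_frac = 0.1,
                        adapt = FALSE, concentration = NULL,
                        grid_var = "V", c_std = 0.602214076, seed = 1L) {
  mode <- match.arg(mode)
  if (length(grid) == 0L) stop("`grid` must be non-empty", call. = FALSE)
  if (!is.list(expressions) ||
      !all(vapply(expressions, inherits, logical(1), "K_expression"))) {
    stop("`expressions` must be a list of K_expression objects",
         call. = FALSE)
  }
  if (mode == "R2-size-scan" && is.null(concentration)) {
    stop("R2-size-scan needs a fixed `concentration`", call. = FALSE)
  }
  structure(list(mode = mode, base = base, grid = grid,
                 expressions = expressions, n_sweeps = n_sweeps,
                 thin = thin, equil_frac = equil_frac, adapt = adapt,
                 concentration = concentration, grid_var = grid_var,
                 c_std = c_std, seed = as.integer(seed)),
            class = "scan_config")
}

#' Run an experiment scan
#'
#' Evaluates every configured K expression at every grid point and returns a
#' long-form table: one row per (grid point, expression) with the value, the
#' block standard error, a `defined` flag and sampler diagnostics. A grid
#' point at which an expression's preconditions fail (e.g. a species never
#' observed) is reported flagged, not fatal. Given the same config and seed
#' the report is identical.
#'
#' @param config a [scan_config()].
#' @return A `data.frame` with columns `mode`, `N_total`, `L_box`, `V`,
#'   `expression`, `value`, `stderr`, `defined`, `acceptance`.
#' @examples
#' cfg <- scan_config("oracle-scan",
#'   base = list(N_total = 4, b = factorial(1:4), c_std = 1),
#'   grid = c(5, 10, 20),
#'   expressions = list(expr_elementary(c(1, 1)), expr_uncorrelated(2)))
#' run_scan(cfg)
#' @export
run_scan <- function(config) {
  stopifnot(inherits(config, "scan_config"))
  rows <- list()
  for (i in seq_along(config$grid)) {
    g <- config$grid[i]
    point_seed <- config$seed + i - 1L
    if (config$mode == "oracle-scan") {
      b <- config$base
      if (config$grid_var == "N_total") {
        N <- as.integer(g)
        V <- if (!is.null(config$concentration)) {
          N / config$concentration
        } else b$V
        bm <- if (length(b$b) >= N) b$b[seq_len(N)] else {
          stop("oracle base `b` shorter than scanned N_total", call. = FALSE)
        }
        backend <- cluster_model(N, V, bm, b$c_std %||% config$c_std)
      } else {
        backend <- cluster_model(b$N_total, g, b$b,
                                 b$c_std %||% config$c_std)
      }
      N <- backend$N_total; V <- backend$V; L <- V^(1 / 3); acc <- NA_real_
    } else {
      base <- config$base
      stopifnot(inherits(base, "simulation_spec"))
      if (config$mode == "R1-volume-scan") {
        N <- base$N_total
        L <- g
      } else {
        N <- as.integer(g)
        L <- derive_box_length(N, config$concentration)
      }
      spec <- simulation_spec(N, L, base$epsilon, base$sigma, base$T,
                              base$r_cut, base$r_bond, seed = point_seed)
      backend <- metropolis_chain(spec, n_sweeps = config$n_sweeps,
                                  thin = config$thin,
                                  equil_frac = config$equil_frac,
                                  adapt = config$adapt,
                                  c_std = config$c_std)
      V <- spec$L_box^3
      acc <- backend$provenance$acceptance
    }
    for (ex in config$expressions) {
      est <- tryCatch(ex$fn(backend), error = function(e) NULL)
      rows[[length(rows) + 1L]] <- data.frame(
        mode = config$mode, N_total = N, L_box = L, V = V,
        expression = ex$label,
        value = if (is.null(est) || !est$defined) NA_real_ else est$value,
        stderr = if (is.null(est)) NA_real_ else est$stderr,
        defined = !is.null(est) && est$defined,
        acceptance = acc)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(mode = character(), N_total = integer(),
                      L_box = numeric(), V = numeric(),
                      expression = character(), value = numeric(),
                      stderr = numeric(), defined = logical(),
                      acceptance = numeric()))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
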