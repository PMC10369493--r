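# Falling-factorial moment kernel shared by every K expression.
#
# All correlated concentration averages in the package are of one form:
#   E[ prod_m n_m^(k_m) ] / V^(sum k_m),
# the count-space equivalent of products c (c - 1/V) (c - 2/V) ... in
# concentration space. Computing in integer count space and dividing by V
# powers once at the end avoids the cancellation the subtracted form incurs.

# per-frame values of prod_m n_m^(k_m) / V^(sum k) for a counts_series
ff_frame_values <- function(series, spec) {
  spec <- as_moment_spec(spec, series$N_total)
  if (length(spec) == 0L) return(rep(1, nrow(series$counts)))
  vals <- rep(1, nrow(series$counts))
  for (i in seq_along(spec)) {
    size <- as.integer(names(spec)[i])
    vals <- vals * falling_factorial(series$counts[, size], spec[[i]])
  }
  vals / series$V^sum(spec)
}

# moment value on either backend (exact model or sampled series)
ff_moment <- function(x, spec) {
  if (inherits(x, "cluster_model")) return(exact_moment(x, spec))
  if (inherits(x, "counts_series")) return(mean(ff_frame_values(x, spec)))
  stop("expected a cluster_model or counts_series", call. = FALSE)
}

#' Time-average falling-factorial concentration moment with error bar
#'
#' Sample mean over frames of \eqn{\prod_m n_m^{(k_m)} / V^{\sum k_m}}, the
#' estimator of the correlated concentration averages that enter
#' finite-system equilibrium constants, with a block-average standard error.
#'
#' @param series a [counts_series()].
#' @param spec named vector mapping cluster size to falling-factorial order
#'   (see [exact_moment()]).
#' @param n_blocks number of contiguous blocks for the error estimate.
#' @return List with `value` and `stderr`.
#' @examples
#' m <- cluster_model(2, V = 10, b = c(1, 2), c_std = 1)
#' s <- sample_states(m, 2000, seed = 1)
#' series_moment(s, c("2" = 1)) # near exact_moment(m, c("2" = 1)) = 1/60
#' @export
series_moment <- function(series, spec, n_blocks = 20L) {
  stopifnot(inherits(series, "counts_series"))
  vals <- ff_frame_values(series, spec)
  spec_n <- as_moment_spec(spec, series$N_total)
  if (length(spec_n) == 0L) return(list(value = 1, stderr = 0))
  stderr <- block_stderr_values(vals, n_blocks)
  list(value = mean(vals), stderr = stderr)
}

# block stderr of a mean from a per-frame value vector
block_stderr_values <- function(vals, n_blocks) {
  n <- length(vals)
  if (n < 2L * n_blocks) return(NA_real_)
  blk <- rep(seq_len(n_blocks), each = ceiling(n / n_blocks))[seq_len(n)]
  means <- tapply(vals, blk, mean)
  sd(means) / sqrt(n_blocks)
}

#' Block-average standard error of an arbitrary series statistic
#'
#' Splits a (generally autocorrelated) series into `n_blocks` contiguous
#' blocks, evaluates the statistic on each block, and reports the standard
#' error of the block values treated as independent replicates. This is the
#' error model used for every reported K estimate.
#'
#' @param series a [counts_series()].
#' @param statistic function taking a `counts_series` and returning a single
#'   number.
#' @param n_blocks number of blocks (>= 2); the series must hold at least
#'   `2 * n_blocks` frames.
#' @return Standard error (numeric scalar); `NA` if any block evaluates to a
#'   non-finite value.
#' @examples
#' m <- cluster_model(2, V = 10, b = c(1, 2), c_std = 1)
#' s <- sample_states(m, 400, seed = 1)
#' block_error(s, function(x) mean(x$counts[, 2]), n_blocks = 10)
#' @export
block_error <- function(series, statistic, n_blocks = 20L) {
  stopifnot(inherits(series, "counts_series"), is.function(statistic))
  n <- nrow(series$counts)
  if (n_blocks < 2L) stop("`n_blocks` must be >= 2", call. = FALSE)
  if (n < 2L * n_blocks) {
    stop("series too short for ", n_blocks, " blocks (need >= ",
         2L * n_blocks, " frames)", call. = FALSE)
  }
  edges <- floor(seq(0, n, length.out = n_blocks + 1L))
  vals <- vapply(seq_len(n_blocks), function(i) {
    statistic(series_subset(series, (edges[i] + 1L):edges[i + 1L]))
  }, numeric(1))
  if (any(!is.finite(vals))) return(NA_real_)
  sd(vals) / sqrt(n_blocks)
}
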