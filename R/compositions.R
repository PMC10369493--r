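#' Enumerate cluster compositions of a closed system
#'
#' Lists every way `N_total` identical particles can be partitioned into
#' clusters (an integer partition of `N_total`), each returned as a named
#' count vector: element `"m"` is the number of m-mers. Compositions are the
#' microstate classes of a closed associating system; their number is the
#' partition number p(N).
#'
#' @param N_total positive integer, total number of particles.
#' @return A list of composition vectors. Each is an integer vector of length
#'   `N_total` whose m-th entry is the count of m-mers; `sum(m * n_m)` equals
#'   `N_total` for every element.
#' @examples
#' enumerate_compositions(4) # 5 compositions: p(4) = 5
#' @export
enumerate_compositions <- function(N_total) {
  if (length(N_total) != 1L || is.na(N_total) || N_total < 1 ||
      N_total != as.integer(N_total)) {
    stop("`N_total` must be a single positive integer", call. = FALSE)
  }
  N_total <- as.integer(N_total)
  out <- list()
  # descending-part recursion: parts <= max_part summing to `remaining`
  recurse <- function(remaining, max_part, acc) {
    if (remaining == 0L) {
      counts <- integer(N_total)
      tb <- tabulate(acc, nbins = N_total)
      out[[length(out) + 1L]] <<- tb
      return(invisible(NULL))
    }
    for (part in seq_len(min(remaining, max_part))) {
      recurse(remaining - part, part, c(acc, part))
    }
  }
  recurse(N_total, N_total, integer(0))
  out
}

# total particle count carried by a composition vector
composition_N <- function(counts) {
  sum(seq_along(counts) * counts)
}

# validate a composition against a model's N_total
check_composition <- function(counts, N_total) {
  if (any(counts < 0)) stop("cluster counts must be non-negative", call. = FALSE)
  if (composition_N(counts) != N_total) {
    stop("composition does not conserve particles: sum(m * n_m) != N_total",
         call. = FALSE)
  }
  invisible(TRUE)
}
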