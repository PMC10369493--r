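#' Cluster-count time series
#'
#' The interchange container between samplers and estimators: an ordered
#' sequence of cluster compositions (one frame per row), together with the
#' box volume, the standard concentration and provenance metadata. Every
#' frame must conserve particles: `sum(m * n_m) == N_total`.
#'
#' @param counts integer matrix, frames in rows; column m holds the count of
#'   m-mers. A matrix narrower than `N_total` columns is zero-padded.
#' @param V box volume in nm^3.
#' @param c_std standard concentration in molecules/nm^3 (default 1 M).
#' @param N_total total particle number; inferred from the first frame if
#'   missing.
#' @param provenance optional list of metadata (sampler, seed, spec, ...).
#' @return An object of class `counts_series` with fields `counts`, `V`,
#'   `c_std`, `N_total`, `provenance`.
#' @examples
#' s <- counts_series(rbind(c(2, 0), c(0, 1)), V = 10, c_std = 1)
#' s$N_total # 2
#' @export
counts_series <- function(counts, V, c_std = 0.602214076, N_total = NULL,
                          provenance = list()) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (nrow(counts) < 1L) stop("a counts series needs at least one frame",
                              call. = FALSE)
  if (any(is.na(counts)) || any(counts < 0)) {
    stop("cluster counts must be non-negative integers", call. = FALSE)
  }
  if (length(V) != 1L || !is.finite(V) || V <= 0) {
    stop("`V` must be a positive volume (nm^3)", call. = FALSE)
  }
  per_frame_N <- as.integer(counts %*% seq_len(ncol(counts)))
  if (is.null(N_total)) N_total <- per_frame_N[1]
  N_total <- as.integer(N_total)
  bad <- which(per_frame_N != N_total)
  if (length(bad) > 0L) {
    stop("frame(s) ", paste(head(bad, 5L), collapse = ", "),
         " violate particle conservation (sum(m * n_m) != ", N_total, ")",
         call. = FALSE)
  }
  if (ncol(counts) < N_total) {
    counts <- cbind(counts, matrix(0L, nrow(counts), N_total - ncol(counts)))
  } else if (ncol(counts) > N_total) {
    counts <- counts[, seq_len(N_total), drop = FALSE]
  }
  colnames(counts) <- paste0("n_", seq_len(ncol(counts)))
  structure(
    list(counts = counts, V = V, c_std = c_std, N_total = N_total,
         provenance = provenance),
    class = "counts_series"
  )
}

#' @export
print.counts_series <- function(x, ...) {
  cat("Cluster-count series\n")
  cat(sprintf("  %d frames, N_total = %d, V = %g nm^3, c_std = %g /nm^3\n",
              nrow(x$counts), x$N_total, x$V, x$c_std))
  occ <- colMeans(x$counts)
  occupied <- which(occ > 0)
  cat("  mean counts:",
      paste(sprintf("<n_%d>=%.3g", occupied, occ[occupied]), collapse = " "),
      "\n")
  if (length(x$provenance)) {
    cat("  provenance:", x$provenance$sampler %||% "unknown",
        if (!is.null(x$provenance$seed)) sprintf("(seed %s)", x$provenance$seed),
        "\n")
  }
  invisible(x)
}

#' @export
summary.counts_series <- function(object, ...) {
  df <- as.data.frame(object)
  cat(sprintf("counts_series: %d frames, N_total = %d, V = %g nm^3\n",
              nrow(df) , object$N_total, object$V))
  print(summary(df[, -1, drop = FALSE]))
  invisible(object)
}

#' @export
as.data.frame.counts_series <- function(x, ...) {
  data.frame(frame = seq_len(nrow(x$counts)), x$counts)
}

#' @export
length.counts_series <- function(x) nrow(x$counts)

# subset frames, keeping metadata
series_subset <- function(series, idx) {
  out <- series
  out$counts <- series$counts[idx, , drop = FALSE]
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
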