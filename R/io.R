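# CSV dialect for cluster-count series: comment header lines declare the
# ensemble metadata, then one row per frame with the per-size counts.
#
#   # N_total=4
#   # V=216
#   # c_std=0.602214076
#   frame,n_1,n_2,n_3,n_4
#   1,4,0,0,0
#   ...

#' Write a cluster-count series as CSV
#'
#' @param series a [counts_series()].
#' @param path output file.
#' @return Invisibly, `path`.
#' @seealso [read_counts_csv()] for the inverse; `read(write(x))` is the
#'   identity.
#' @export
write_counts_csv <- function(series, path) {
  stopifnot(inherits(series, "counts_series"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# N_total=%d", series$N_total),
    sprintf("# V=%.17g", series$V),
    sprintf("# c_std=%.17g", series$c_std)
  ), con)
  df <- as.data.frame(series)
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cluster-count series from CSV
#'
#' Parses the dialect written by [write_counts_csv()]: `# key=value` header
#' lines declaring `N_total`, `V` and `c_std`, then columns
#' `frame, n_1, ..., n_max`. Malformed rows — non-integer counts or a frame
#' violating particle conservation — are rejected with their line numbers.
#'
#' @param path input file.
#' @return A [counts_series()].
#' @export
read_counts_csv <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) stop("empty counts file: ", path, call. = FALSE)
  hdr_idx <- grep("^#", lines)
  header <- lines[hdr_idx]
  meta <- list()
  for (h in header) {
    kv <- regmatches(h, regexec("^#\\s*([A-Za-z_]+)\\s*=\\s*(.+)$", h))[[1]]
    if (length(kv) == 3L) meta[[kv[2]]] <- as.numeric(kv[3])
  }
  for (key in c("N_total", "V", "c_std")) {
    if (is.null(meta[[key]]) || is.na(meta[[key]])) {
      stop("counts CSV header must declare `", key, "`", call. = FALSE)
    }
  }
  body <- lines[setdiff(seq_along(lines), hdr_idx)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < 2L) {
    stop("counts CSV has no data rows: ", path, call. = FALSE)
  }
  df <- read.csv(text = paste(body, collapse = "\n"))
  count_cols <- grep("^n_", names(df))
  if (!"frame" %in% names(df) || length(count_cols) == 0L) {
    stop("counts CSV must have columns frame, n_1, ...", call. = FALSE)
  }
  counts <- as.matrix(df[, count_cols, drop = FALSE])
  if (any(is.na(counts)) || any(counts != round(counts)) || any(counts < 0)) {
    bad <- which(rowSums(is.na(counts) | counts != round(counts) |
                           counts < 0) > 0)
    stop("malformed count row(s) at data line(s): ",
         paste(head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  sizes <- as.integer(sub("^n_", "", names(df)[count_cols]))
  ord <- order(sizes)
  counts <- counts[, ord, drop = FALSE]
  per_frame_N <- as.integer(counts %*% sizes[ord])
  bad <- which(per_frame_N != meta$N_total)
  if (length(bad) > 0L) {
    stop("particle conservation violated at data row(s): ",
         paste(head(bad, 5L), collapse = ", "),
         " (sum(m * n_m) != ", meta$N_total, ")", call. = FALSE)
  }
  counts_series(counts, V = meta$V, c_std = meta$c_std,
                N_total = as.integer(meta$N_total),
                provenance = list(sampler = "csv", path = path))
}
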