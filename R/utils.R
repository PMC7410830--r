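## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stop with a formatted message
#' @noRd
stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)

#' Validate 0-based half-open genomic intervals
#'
#' All coordinates in this package are 0-based half-open: an interval
#' [start, end) covers bases start .. end-1.
#' @noRd
check_intervals <- function(chrom, start, end, context = "interval") {
  if (any(!nzchar(chrom))) stopf("%s: empty chromosome name", context)
  if (any(start < 0)) stopf("%s: negative start coordinate", context)
  bad <- which(start >= end)
  if (length(bad)) {
    stopf("%s: start >= end at record %d (%s:%d-%d)", context, bad[1],
          chrom[bad[1]], start[bad[1]], end[bad[1]])
  }
  invisible(TRUE)
}

#' Convert 0-based half-open intervals to IRanges (1-based closed)
#' @noRd
to_iranges <- function(start, end) IRanges::IRanges(start = start + 1L, end = end)

#' Convert a 0-based half-open interval data.frame to GRanges
#' @noRd
to_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = to_iranges(df$start, df$end),
    strand = if ("strand" %in% names(df)) df$strand else "*"
  )
}

#' Deterministic child seed derived from a parent seed
#'
#' A single user-facing seed fans out to independent per-generator streams.
#' Kept strictly below 2^31.
#' @noRd
child_seed <- function(seed, stream) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(stream)
}

#' Truncated rolling mean via cumulative sums
#'
#' Window of `half` bins on each side, truncated at vector ends (the window
#' shrinks near the edges rather than being padded).
#' @noRd
roll_mean_trunc <- function(x, half) {
  n <- length(x)
  if (half <= 0L) return(x)
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}
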