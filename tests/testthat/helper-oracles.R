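# Independent brute-force oracles used across test files. These never call
# the implementation paths they check.

# Upper-tail P(X >= x) by direct pmf summation (NB by moments, Poisson when
# v <= m). Sums until terms are negligible.
oracle_upper_tail <- function(x, m, v) {
  x <- floor(x)
  if (x <= 0) return(1)
  kmax <- max(1000, ceiling(x + 50 * sqrt(v) + 10 * m))
  ks <- x:kmax
  if (v <= m) {
    sum(dpois(ks, lambda = m))
  } else {
    size <- m^2 / (v - m)
    sum(dnbinom(ks, size = size, mu = m))
  }
}

# Interval union by per-bp coverage (0-based half-open); bookended
# neighbours coalesce because coverage is contiguous.
oracle_merge <- function(df, max_end = max(df$end) + 1L) {
  out <- list()
  for (ch in sort(unique(df$chrom))) {
    sub <- df[df$chrom == ch, , drop = FALSE]
    cov <- logical(max_end)
    for (i in seq_len(nrow(sub))) cov[(sub$start[i] + 1L):sub$end[i]] <- TRUE
    r <- rle(cov)
    ends <- cumsum(r$lengths)
    starts <- c(0L, ends[-length(ends)])
    keep <- r$values
    if (any(keep)) {
      out[[ch]] <- data.frame(chrom = ch, start = starts[keep],
                              end = ends[keep], stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Exhaustive nearest-TSS scan: for every peak, compute the distance to every
# TSS on its chromosome and take the minimum, ties by gene id.
oracle_nearest <- function(peaks, tss) {
  genes <- character(nrow(peaks))
  dists <- integer(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    tt <- tss[tss$chrom == peaks$chrom[i], , drop = FALSE]
    d <- pmax(peaks$start[i] - tt$tss, tt$tss - peaks$end[i], 0L)
    best <- which(d == min(d))
    best <- best[order(tt$gene_id[best])][1]
    genes[i] <- tt$gene_id[best]
    dists[i] <- d[best]
  }
  data.frame(gene = genes, distance = dists, stringsAsFactors = FALSE)
}

# Hypergeometric upper tail by direct summation.
oracle_hyper_tail <- function(k, nA, nB, nU) {
  sum(dhyper(k:min(nA, nB), nA, nU - nA, nB))
}

# Truncated rolling-mean-ratio adjustment by an explicit per-position loop.
oracle_local_adjust <- function(sig, inp, m, half) {
  n <- length(sig)
  ratio <- numeric(n)
  for (i in seq_len(n)) {
    w <- max(1, i - half):min(n, i + half)
    rs <- mean(sig[w]); ri <- mean(inp[w])
    ratio[i] <- if (ri == 0) 1 else rs / ri
  }
  ratio <- ratio / mean(ratio)
  m * ratio
}

# Key for comparing candidate-element tables with planted truth.
element_key <- function(chrom, start, end, gene, category, state_class) {
  paste(chrom, start, end, gene, category, state_class, sep = "|")
}
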