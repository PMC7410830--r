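## Conversion of raw epigenomic signal tracks to locally-adjusted, capped
## -log10 P tracks under a negative-binomial background, plus promoter-window
## fold-change and de-repression statistics.

#' Fit a negative-binomial background to a signal track
#'
#' The background mean and variance are the sample mean and variance of the
#' bin values at or below the empirical 99th percentile (the bottom 99% of
#' the data), pooling all chromosomes. When the variance does not exceed
#' the mean the model degenerates and a Poisson background is flagged.
#'
#' @param track \code{signal_track}.
#' @param fit_quantile Quantile bounding the fitted values (default 0.99).
#' @return Object of class \code{nb_params}: list with \code{mean},
#'   \code{variance}, \code{poisson_fallback}, \code{fit_quantile}.
#' @export
fit_nb_background <- function(track, fit_quantile = 0.99) {
  v <- unlist(track$bins, use.names = FALSE)
  if (length(v) < 1000L) stopf("need at least 1000 bins to fit a background")
  if (all(v == 0)) stopf("all-zero track: cannot fit a background model")
  q <- stats::quantile(v, fit_quantile, names = FALSE)  # type-7 interpolation
  vv <- v[v <= q]
  m <- mean(vv)
  s2 <- stats::var(vv)
  if (m <= 0 || s2 <= 0) stopf("degenerate background (mean %g, variance %g)", m, s2)
  structure(list(mean = m, variance = s2, poisson_fallback = s2 <= m,
                 fit_quantile = fit_quantile),
            class = "nb_params")
}

#' @export
print.nb_params <- function(x, ...) {
  cat(sprintf("nb_params: mean %.3f, variance %.3f%s\n", x$mean, x$variance,
              if (x$poisson_fallback) " (Poisson fallback)" else ""))
  invisible(x)
}

#' Locally adjust the background mean from an input track
#'
#' Rolling means over a window centred at each bin (default 20 kb,
#' truncated at chromosome ends) are computed for the signal and its input
#' control. Their per-bin ratio (set to 1 where the input rolling mean is
#' zero) is normalized to genome-wide mean 1 and multiplied onto the
#' overall background mean, yielding a per-bin adjusted mean that accounts
#' for local genomic variation without changing the global mean.
#'
#' @param signal,input \code{signal_track}s on the same binning.
#' @param params \code{nb_params} fitted on the signal.
#' @param window Window width in bp (default 20000).
#' @return Named list of per-chromosome adjusted-mean vectors, with the
#'   normalized ratio list in attribute \code{"ratio"}.
#' @export
local_mean_adjust <- function(signal, input, params, window = 20000) {
  if (signal$bin_width != input$bin_width ||
      !identical(names(signal$bins), names(input$bins)) ||
      !identical(lengths(signal$bins), lengths(input$bins))) {
    stopf("signal and input tracks must share binning")
  }
  half <- window %/% (2L * signal$bin_width)
  ratio <- lapply(names(signal$bins), function(ch) {
    rs <- roll_mean_trunc(signal$bins[[ch]], half)
    ri <- roll_mean_trunc(input$bins[[ch]], half)
    r <- ifelse(ri == 0, 1, rs / ri)
    r
  })
  names(ratio) <- names(signal$bins)
  g <- mean(unlist(ratio, use.names = FALSE))
  ratio <- lapply(ratio, function(r) r / g)
  adj <- lapply(ratio, function(r) params$mean * r)
  attr(adj, "ratio") <- ratio
  adj
}

## Upper-tail P(X >= x) under the moment-matched background.
## NB: size r = m^2/(v-m), prob p = m/v; Poisson(m) when v <= m.
## Computed in log space for precision deep in the tail.
nb_upper_tail <- function(x, m, v) {
  x <- floor(x)
  if (x <= 0) return(1)
  if (v <= m) {
    exp(stats::ppois(x - 1, lambda = m, lower.tail = FALSE, log.p = TRUE))
  } else {
    size <- m^2 / (v - m)
    exp(stats::pnbinom(x - 1, size = size, mu = m, lower.tail = FALSE,
                       log.p = TRUE))
  }
}

## -log10 upper-tail, capped, staying in log space so caps beyond double
## underflow are still exact.
neglog10_upper_tail <- function(x, m, v, cap = 16) {
  x <- floor(x)
  if (x <= 0) return(0)
  lp <- if (v <= m) {
    stats::ppois(x - 1, lambda = m, lower.tail = FALSE, log.p = TRUE)
  } else {
    size <- m^2 / (v - m)
    stats::pnbinom(x - 1, size = size, mu = m, lower.tail = FALSE, log.p = TRUE)
  }
  min(-lp / log(10), cap)
}

#' Convert a signal track to a capped -log10 P track
#'
#' Each bin value is converted to the upper-tail probability
#' \eqn{P(X \ge x)} under a negative binomial parameterized by the locally
#' adjusted mean and a variance scaled to preserve the fitted
#' variance-to-mean ratio (Poisson when that ratio does not exceed 1), then
#' to \code{-log10 P}, capped at \code{cap}. Non-integer bin values are
#' floored with a warning.
#'
#' @param track \code{signal_track}.
#' @param params \code{nb_params} from \code{\link{fit_nb_background}}.
#' @param adjusted_means Optional output of \code{\link{local_mean_adjust}};
#'   when absent the global mean is used everywhere.
#' @param cap Upper bound on -log10 P (default 16).
#' @return \code{signal_track} of per-bin -log10 P values.
#' @export
signal_to_neglog10p <- function(track, params, adjusted_means = NULL, cap = 16) {
  vmr <- params$variance / params$mean
  warned <- FALSE
  bins <- lapply(names(track$bins), function(ch) {
    x <- track$bins[[ch]]
    if (!warned && any(x != floor(x))) {
      warned <<- TRUE
      warnf("non-integer signal values floored before tail computation")
    }
    x <- floor(x)
    m_i <- if (is.null(adjusted_means)) rep(params$mean, length(x))
           else adjusted_means[[ch]]
    v_i <- m_i * vmr
    out <- numeric(length(x))
    pos <- x > 0
    if (any(pos)) {
      if (vmr <= 1) {
        lp <- stats::ppois(x[pos] - 1, lambda = m_i[pos],
                           lower.tail = FALSE, log.p = TRUE)
      } else {
        size <- m_i[pos]^2 / (v_i[pos] - m_i[pos])
        lp <- stats::pnbinom(x[pos] - 1, size = size, mu = m_i[pos],
                             lower.tail = FALSE, log.p = TRUE)
      }
      out[pos] <- pmin(-lp / log(10), cap)
    }
    out
  })
  names(bins) <- names(track$bins)
  signal_track(bins, track$bin_width, sample_id = track$sample_id,
               mark = track$mark, role = "pvalue")
}

#' Per-bin log2 fold change of signal over input
#'
#' \code{log2((s + pc) / (i + pc))} per bin.
#'
#' @param signal,input \code{signal_track}s on the same binning.
#' @param pseudocount Added to both tracks (default 1).
#' @return \code{signal_track} of log2 ratios (may be negative).
#' @export
log2_ratio_track <- function(signal, input, pseudocount = 1) {
  if (signal$bin_width != input$bin_width ||
      !identical(lengths(signal$bins)[names(signal$bins)],
                 lengths(input$bins)[names(signal$bins)])) {
    stopf("signal and input tracks must share binning")
  }
  bins <- lapply(names(signal$bins), function(ch) {
    log2((signal$bins[[ch]] + pseudocount) / (input$bins[[ch]] + pseudocount))
  })
  names(bins) <- names(signal$bins)
  out <- list(bins = bins, bin_width = signal$bin_width,
              sample_id = signal$sample_id, mark = signal$mark, role = "log2fc")
  class(out) <- "signal_track"  # bypass >= 0 check: ratios are signed
  out
}

#' Average track value in a window centred on each TSS
#'
#' The mean of all bins overlapping \code{[tss - window/2, tss + window/2)},
#' strand-independent; windows running off a chromosome end are truncated
#' with a warning.
#'
#' @param fc_track \code{signal_track} (typically log2 fold-change).
#' @param tss TSS table (see \code{\link{read_tss_table}}).
#' @param window Window width in bp (default 4000).
#' @return Named numeric vector over \code{tss$gene_id}.
#' @export
promoter_window_signal <- function(fc_track, tss, window = 4000) {
  bw <- fc_track$bin_width
  out <- stats::setNames(rep(NA_real_, nrow(tss)), tss$gene_id)
  truncated <- FALSE
  for (i in seq_len(nrow(tss))) {
    ch <- tss$chrom[i]
    v <- fc_track$bins[[ch]]
    if (is.null(v)) stopf("TSS chromosome %s absent from track", ch)
    w0 <- tss$tss[i] - window %/% 2L
    w1 <- tss$tss[i] + window %/% 2L
    b0 <- floor(w0 / bw)        # first bin overlapping [w0, w1)
    b1 <- ceiling(w1 / bw) - 1  # last bin overlapping
    if (b0 < 0 || b1 >= length(v)) truncated <- TRUE
    b0 <- max(b0, 0)
    b1 <- min(b1, length(v) - 1L)
    out[i] <- mean(v[(b0 + 1L):(b1 + 1L)])
  }
  if (truncated) warnf("promoter window truncated at chromosome end for some genes")
  out
}

#' Promoter score table across time points
#'
#' Stacks \code{\link{promoter_window_signal}} columns for an ordered
#' series of fold-change tracks and records the fold decrease per gene:
#' the difference between the earliest and the latest time point.
#'
#' @param fc_tracks Named list of \code{signal_track}s ordered from
#'   earliest to latest time point.
#' @param tss TSS table.
#' @param window Window width in bp (default 4000).
#' @return data.frame with \code{gene_id}, one column per time point, and
#'   \code{fold_decrease}.
#' @export
promoter_score_table <- function(fc_tracks, tss, window = 4000) {
  stopifnot(length(fc_tracks) >= 2L, !is.null(names(fc_tracks)))
  cols <- lapply(fc_tracks, promoter_window_signal, tss = tss, window = window)
  df <- data.frame(gene_id = tss$gene_id, do.call(cbind, cols),
                   check.names = FALSE, stringsAsFactors = FALSE)
  df$fold_decrease <- cols[[1]] - cols[[length(cols)]]
  df
}

#' Rank gene clusters by promoter de-repression
#'
#' Per cluster: the mean fold decrease of its member genes' promoter
#' signal, optionally paired with the mean per-gene expression slope over
#' stages (ordinary least squares on the stage index) to highlight
#' clusters where a repressive mark decays while RNA rises.
#'
#' @param score_table Output of \code{\link{promoter_score_table}}.
#' @param clusters Named list of gene-id vectors.
#' @param expr_log Optional genes x samples log-expression matrix whose
#'   columns are ordered by stage (stage index 1..n).
#' @return data.frame, one row per cluster, sorted by descending mean fold
#'   decrease: \code{cluster}, \code{mean_fold_decrease},
#'   \code{mean_rna_slope} (NA when no expression given), \code{rank}.
#' @export
cluster_derepression_score <- function(score_table, clusters, expr_log = NULL) {
  fd <- stats::setNames(score_table$fold_decrease, score_table$gene_id)
  rows <- lapply(names(clusters), function(cl) {
    g <- intersect(clusters[[cl]], names(fd))
    slope <- NA_real_
    if (!is.null(expr_log)) {
      gg <- intersect(g, rownames(expr_log))
      if (length(gg)) {
        idx <- seq_len(ncol(expr_log))
        sl <- apply(expr_log[gg, , drop = FALSE], 1, function(y)
          stats::cov(idx, y) / stats::var(idx))
        slope <- mean(sl)
      }
    }
    data.frame(cluster = cl, mean_fold_decrease = mean(fd[g]),
               mean_rna_slope = slope, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$mean_fold_decrease, out$cluster), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Upper-tail hypergeometric overlap P value
#'
#' Probability of observing at least the given overlap between two gene
#' sets drawn from a common universe, e.g. scoring the overlap of a
#' de-repressed cluster with known repressor (REST) targets.
#'
#' @param setA,setB Character vectors, both subsets of \code{universe}.
#' @param universe Character vector of all eligible genes.
#' @return P value, \eqn{P(K \ge |A \cap B|)}.
#' @export
hypergeom_overlap <- function(setA, setB, universe) {
  setA <- unique(setA); setB <- unique(setB); universe <- unique(universe)
  if (!all(setA %in% universe) || !all(setB %in% universe)) {
    stopf("both sets must be subsets of the universe")
  }
  k <- length(intersect(setA, setB))
  stats::phyper(k - 1, length(setA), length(universe) - length(setA),
                length(setB), lower.tail = FALSE)
}
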