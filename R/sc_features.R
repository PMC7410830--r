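## Single-cell QC, normalization, dispersion-based tight-cluster feature
## selection, one-vs-rest Wilcoxon marker calling and exclusive-marker
## derivation.

#' Construct a single-cell matrix container
#'
#' @param values Cells x genes non-negative matrix: UMI counts for tag-based
#'   data, FPKM for full-length data. Rownames are cell barcodes, colnames
#'   gene ids.
#' @param platform \code{"tag"} or \code{"full_length"}.
#' @param total_mapped Optional per-cell mapped-read totals (full-length QC).
#' @param mito_genes Optional gene ids counted as mitochondrial; when absent,
#'   genes prefixed \code{"mt-"} (case-insensitive) are used.
#' @return Object of class \code{cell_matrix} with per-cell QC fields
#'   \code{total_mapped}, \code{n_genes_detected}, \code{mito_fraction}
#'   derived from the values.
#' @export
cell_matrix <- function(values, platform = c("tag", "full_length"),
                        total_mapped = NULL, mito_genes = NULL) {
  platform <- match.arg(platform)
  stopifnot(is.matrix(values))
  if (any(values < 0)) stopf("cell matrix values must be >= 0")
  if (is.null(rownames(values)) || anyDuplicated(rownames(values))) {
    stopf("values must have unique cell rownames")
  }
  if (is.null(colnames(values)) || anyDuplicated(colnames(values))) {
    stopf("values must have unique gene colnames")
  }
  if (is.null(mito_genes)) {
    mito_genes <- colnames(values)[grepl("^mt-", colnames(values), ignore.case = TRUE)]
  }
  tot <- rowSums(values)
  mito <- if (length(mito_genes)) {
    rowSums(values[, intersect(mito_genes, colnames(values)), drop = FALSE]) /
      pmax(tot, .Machine$double.eps)
  } else rep(0, nrow(values))
  qc <- data.frame(
    cell = rownames(values),
    total_mapped = if (!is.null(total_mapped)) total_mapped else tot,
    n_genes_detected = rowSums(values > 0),
    mito_fraction = mito,
    stringsAsFactors = FALSE
  )
  rownames(qc) <- qc$cell
  structure(list(values = values, qc = qc, platform = platform,
                 mito_genes = mito_genes),
            class = "cell_matrix")
}

#' @export
print.cell_matrix <- function(x, ...) {
  cat(sprintf("cell_matrix (%s): %d cells x %d genes; median %d genes/cell\n",
              x$platform, nrow(x$values), ncol(x$values),
              as.integer(stats::median(x$qc$n_genes_detected))))
  invisible(x)
}

subset_cell_matrix <- function(x, cells = NULL, genes = NULL) {
  v <- x$values
  if (!is.null(cells)) v <- v[cells, , drop = FALSE]
  if (!is.null(genes)) v <- v[, genes, drop = FALSE]
  out <- cell_matrix(v, platform = x$platform,
                     total_mapped = x$qc[rownames(v), "total_mapped"],
                     mito_genes = x$mito_genes)
  out
}

#' QC filter for full-length (FPKM) single-cell data
#'
#' Cells are removed when fewer than \code{min_reads} reads map to the
#' transcriptome or fewer than \code{min_genes} genes exceed
#' \code{fpkm_cut} FPKM. Genes are then removed when detected (> 0) in
#' fewer than \code{min_cells} cells, or below \code{fpkm_cut} FPKM in all
#' cells, or (when a read-count companion matrix is supplied) covered by
#' fewer than \code{min_gene_reads} mapped reads in all cells. An input
#' mask can pre-remove libraries flagged by microscopy (doublet chambers,
#' biased chips).
#'
#' @param x \code{cell_matrix} with platform \code{"full_length"}.
#' @param min_reads,min_genes,fpkm_cut Cell-level thresholds
#'   (defaults 100000 reads, 4000 genes above 10 FPKM).
#' @param min_cells,min_gene_reads Gene-level thresholds (defaults 5 cells,
#'   100 reads).
#' @param read_counts Optional cells x genes mapped-read matrix.
#' @param keep_cells Optional logical/character mask of cells to keep
#'   before any computed rule.
#' @return Filtered \code{cell_matrix}.
#' @export
qc_filter_full_length <- function(x, min_reads = 1e5, min_genes = 4000,
                                  fpkm_cut = 10, min_cells = 5,
                                  min_gene_reads = 100, read_counts = NULL,
                                  keep_cells = NULL) {
  stopifnot(inherits(x, "cell_matrix"))
  v <- x$values
  if (!is.null(keep_cells)) {
    v <- if (is.logical(keep_cells)) v[keep_cells, , drop = FALSE]
         else v[intersect(rownames(v), keep_cells), , drop = FALSE]
  }
  tot <- x$qc[rownames(v), "total_mapped"]
  ok_cell <- tot >= min_reads & rowSums(v > fpkm_cut | v == fpkm_cut) >= min_genes
  v <- v[ok_cell, , drop = FALSE]
  if (!nrow(v)) stopf("no cells pass QC")
  detected <- colSums(v > 0)
  any_hi <- apply(v, 2, max) >= fpkm_cut
  ok_gene <- detected >= min_cells & any_hi
  if (!is.null(read_counts)) {
    rc <- read_counts[rownames(v), colnames(v), drop = FALSE]
    ok_gene <- ok_gene & apply(rc, 2, max) >= min_gene_reads
  }
  v <- v[, ok_gene, drop = FALSE]
  if (!ncol(v)) stopf("no genes pass QC")
  subset_cell_matrix(x, cells = rownames(v), genes = colnames(v))
}

#' QC filter for tag-based (UMI) single-cell data
#'
#' Cell rules: at least \code{min_genes} genes detected, mitochondrial read
#' fraction no more than \code{max_mito}, and no more than \code{max_genes}
#' genes detected (a doublet proxy). The gene rule — detected in at least
#' \code{min_cell_frac} of cells — is applied after cell removal.
#'
#' @param x \code{cell_matrix} with platform \code{"tag"}.
#' @param min_genes,max_genes,max_mito Cell thresholds (defaults 1000,
#'   8000, 0.20).
#' @param min_cell_frac Gene detection fraction threshold (default 0.001).
#' @return Filtered \code{cell_matrix}.
#' @export
qc_filter_tag <- function(x, min_genes = 1000, min_cell_frac = 0.001,
                          max_mito = 0.20, max_genes = 8000) {
  stopifnot(inherits(x, "cell_matrix"))
  v <- x$values
  qc <- x$qc
  ok_cell <- qc$n_genes_detected >= min_genes &
    qc$n_genes_detected <= max_genes &
    qc$mito_fraction <= max_mito
  v <- v[ok_cell, , drop = FALSE]
  if (!nrow(v)) stopf("no cells pass QC")
  ok_gene <- colSums(v > 0) >= min_cell_frac * nrow(v)
  v <- v[, ok_gene, drop = FALSE]
  if (!ncol(v)) stopf("no genes pass QC")
  subset_cell_matrix(x, cells = rownames(v), genes = colnames(v))
}

#' Library-size normalize and log-transform UMI counts
#'
#' Per cell, counts are divided by the cell total, multiplied by 10,000,
#' incremented by 1 and natural-log transformed:
#' \code{ln(10000 * x / sum(x) + 1)}.
#'
#' @param x \code{cell_matrix} (tag platform) or cells x genes count matrix.
#' @param scale_factor Library-size target (default 10000).
#' @return Cells x genes matrix of normalized log values.
#' @export
normalize_tag <- function(x, scale_factor = 1e4) {
  v <- if (inherits(x, "cell_matrix")) x$values else x
  tot <- rowSums(v)
  if (any(tot == 0)) stopf("zero-sum cell found; run QC first")
  log1p(scale_factor * v / tot)
}

#' Rank genes by dispersion
#'
#' Dispersion is the per-gene sample variance (n-1 denominator) divided by
#' the mean. Genes with zero mean are excluded.
#'
#' @param m Cells x genes matrix (normalized values).
#' @param top_n How many top genes to return; if larger than the number of
#'   nonzero-mean genes, all are returned with a warning.
#' @return data.frame with \code{gene_id}, \code{mean}, \code{variance},
#'   \code{dispersion}, sorted by descending dispersion (ties by gene id).
#' @export
dispersion_rank <- function(m, top_n = ncol(m)) {
  mu <- colMeans(m)
  keep <- mu > 0
  mu <- mu[keep]
  mm <- m[, keep, drop = FALSE]
  n <- nrow(mm)
  vr <- (colSums(mm^2) - n * mu^2) / (n - 1)
  vr[vr < 0] <- 0  # numeric guard
  disp <- vr / mu
  ord <- order(-disp, colnames(mm))
  out <- data.frame(gene_id = colnames(mm)[ord], mean = mu[ord],
                    variance = vr[ord], dispersion = disp[ord],
                    stringsAsFactors = FALSE, row.names = NULL)
  if (top_n > nrow(out)) {
    warnf("top_n (%d) exceeds usable genes (%d); returning all", top_n, nrow(out))
    top_n <- nrow(out)
  }
  out[seq_len(top_n), , drop = FALSE]
}

#' Select feature genes falling in tight co-expression clusters
#'
#' The top \code{top_n} high-dispersion genes are hierarchically clustered
#' (distance 1 - Pearson correlation over cells, average linkage), the
#' dendrogram is cut at height \code{cut}, and only genes in clusters with
#' more than two members are retained. This removes sporadic genes with
#' high dispersion that are not co-expressed with anything.
#'
#' @param m_norm Cells x genes normalized matrix.
#' @param top_n High-dispersion pre-selection size (default 4000).
#' @param cut Dendrogram cut height on the correlation distance (default 0.8).
#' @param min_members Minimum cluster size, exclusive bound is
#'   \code{min_members} itself, i.e. clusters must have more than two
#'   members under the default 3.
#' @return Object of class \code{feature_gene_set}: data.frame with
#'   \code{gene_id}, \code{dispersion}, \code{tight_cluster_id}.
#' @export
select_tight_cluster_features <- function(m_norm, top_n = 4000, cut = 0.8,
                                          min_members = 3) {
  dr <- suppressWarnings(dispersion_rank(m_norm, top_n = min(top_n, ncol(m_norm))))
  genes <- sort(dr$gene_id)  # canonical order for determinism
  if (length(genes) < min_members) {
    warnf("fewer than %d candidate genes; returning empty feature set", min_members)
    out <- data.frame(gene_id = character(), dispersion = numeric(),
                      tight_cluster_id = integer())
    class(out) <- c("feature_gene_set", class(out))
    return(out)
  }
  mm <- m_norm[, genes, drop = FALSE]
  sds <- apply(mm, 2, stats::sd)
  cc <- suppressWarnings(stats::cor(mm))
  cc[is.na(cc)] <- 0
  diag(cc) <- 1
  hc <- stats::hclust(stats::as.dist(1 - cc), method = "average")
  grp <- stats::cutree(hc, h = cut)
  tab <- table(grp)
  tight <- names(tab)[tab >= min_members]
  keep <- names(grp)[grp %in% as.integer(tight)]
  disp <- stats::setNames(dr$dispersion, dr$gene_id)
  out <- data.frame(gene_id = keep, dispersion = disp[keep],
                    tight_cluster_id = as.integer(grp[keep]),
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(out$tight_cluster_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("feature_gene_set", class(out))
  out
}

## Vectorized one-vs-rest Wilcoxon rank-sum with normal approximation and
## tie correction (two-sided). Equivalent to wilcox.test(exact = FALSE,
## correct = FALSE) per gene, but computed per cluster in one pass.
wilcox_onevsrest <- function(m, in_group, genes) {
  n1 <- sum(in_group)
  n2 <- sum(!in_group)
  n <- n1 + n2
  p <- numeric(length(genes))
  for (j in seq_along(genes)) {
    x <- m[, genes[j]]
    r <- rank(x)
    R1 <- sum(r[in_group])
    U <- R1 - n1 * (n1 + 1) / 2
    ties <- table(x)
    tie_term <- sum(ties^3 - ties)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
    if (sigma2 <= 0) { p[j] <- 1; next }
    z <- (U - n1 * n2 / 2) / sqrt(sigma2)
    p[j] <- 2 * stats::pnorm(-abs(z))
  }
  pmin(p, 1)
}

#' One-vs-rest cluster marker genes (Wilcoxon rank-sum)
#'
#' For each cluster, each gene is tested against all remaining cells with a
#' two-sided Wilcoxon rank-sum test (normal approximation with tie
#' correction). A gene is tested only if its detection fraction is at least
#' \code{min_pct} in either group and the detection-fraction difference is
#' at least \code{min_diff_pct}. P values are Bonferroni-adjusted by the
#' total number of genes in the matrix; only positive markers (higher in
#' the cluster) are reported.
#'
#' @param m_norm Cells x genes normalized log matrix.
#' @param labels Cluster label per cell (character/factor, length =
#'   number of cells).
#' @param min_pct Detection-fraction floor (default 0.25).
#' @param min_diff_pct Minimum |pct_in - pct_out| (0.2 or 0.4 in practice;
#'   default 0.2).
#' @param max_p_adj Report rows with adjusted P below this (default 0.05).
#' @return \code{marker_table} data.frame: \code{cluster}, \code{gene},
#'   \code{p_value}, \code{p_adjusted}, \code{log_fold_change} (log2 of
#'   de-logged group means with pseudocount 1), \code{pct_in}, \code{pct_out}.
#' @export
find_markers <- function(m_norm, labels, min_pct = 0.25, min_diff_pct = 0.2,
                         max_p_adj = 0.05) {
  labels <- as.character(labels)
  if (length(labels) != nrow(m_norm)) stopf("one label per cell required")
  if (anyNA(labels)) stopf("unknown (NA) cluster label")
  tab <- table(labels)
  if (length(tab) < 2L) stopf("need at least 2 clusters")
  if (any(tab < 3L)) stopf("every cluster needs at least 3 cells")
  n_genes <- ncol(m_norm)
  det <- m_norm > 0
  res <- list()
  for (cl in sort(names(tab))) {
    ing <- labels == cl
    pct_in <- colMeans(det[ing, , drop = FALSE])
    pct_out <- colMeans(det[!ing, , drop = FALSE])
    testable <- (pmax(pct_in, pct_out) >= min_pct) &
      (abs(pct_in - pct_out) >= min_diff_pct)
    genes <- colnames(m_norm)[testable]
    if (!length(genes)) next
    p <- wilcox_onevsrest(m_norm, ing, genes)
    p_adj <- pmin(p * n_genes, 1)
    mu_in <- colMeans(expm1(m_norm[ing, genes, drop = FALSE]))
    mu_out <- colMeans(expm1(m_norm[!ing, genes, drop = FALSE]))
    lfc <- log2((mu_in + 1) / (mu_out + 1))
    keep <- p_adj < max_p_adj & lfc > 0
    if (!any(keep)) next
    res[[cl]] <- data.frame(cluster = cl, gene = genes[keep],
                            p_value = p[keep], p_adjusted = p_adj[keep],
                            log_fold_change = lfc[keep],
                            pct_in = pct_in[genes[keep]],
                            pct_out = pct_out[genes[keep]],
                            stringsAsFactors = FALSE, row.names = NULL)
  }
  out <- if (length(res)) do.call(rbind, res) else {
    data.frame(cluster = character(), gene = character(), p_value = numeric(),
               p_adjusted = numeric(), log_fold_change = numeric(),
               pct_in = numeric(), pct_out = numeric())
  }
  out <- out[order(out$cluster, out$p_adjusted, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "thresholds") <- list(min_pct = min_pct, min_diff_pct = min_diff_pct,
                                  max_p_adj = max_p_adj)
  class(out) <- c("marker_table", class(out))
  out
}

#' Derive exclusively expressed markers of cell types or lineage groups
#'
#' Cross-intersects per-cluster marker calls: a gene is an exclusive marker
#' of a cell type iff it is a marker there and nowhere else; a gene is an
#' exclusive marker of a declared lineage group (e.g. Muscle1+Muscle2) iff
#' it is a marker in every member and in no non-member.
#'
#' @param markers A \code{marker_table} (or data.frame with \code{cluster}
#'   and \code{gene}).
#' @param groups Named list of character vectors declaring lineage groups,
#'   e.g. \code{list("Muscle1+Muscle2" = c("Muscle1", "Muscle2"))}.
#' @return Named character vector: gene id -> cell type or group name.
#'   Genes whose marker set matches neither a single type nor a declared
#'   group are dropped.
#' @export
derive_exclusive_markers <- function(markers, groups = list()) {
  if (length(groups)) {
    keyset <- vapply(groups, function(g) paste(sort(g), collapse = "\r"), character(1))
    if (anyDuplicated(keyset)) {
      stopf("ambiguous group definitions: two groups share the same member set")
    }
  }
  sets <- split(markers$cluster, markers$gene)
  out <- character(0)
  for (g in names(sets)) {
    s <- sort(unique(sets[[g]]))
    if (length(s) == 1L) {
      out[g] <- s
    } else if (length(groups)) {
      key <- paste(s, collapse = "\r")
      hit <- names(groups)[vapply(groups, function(gr)
        identical(sort(gr), s), logical(1))]
      if (length(hit) == 1L) out[g] <- hit
    }
  }
  out[order(names(out))]
}
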