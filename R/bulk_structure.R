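## Structuring the bulk tissue x stage transcriptome: gene partition, PCA,
## hierarchical clustering with major-clade extraction, metadata CCA, embryo
## sex inference and ubiquitous-gene stratification.

#' Construct an expression matrix container
#'
#' Couples a genes x samples abundance matrix (FPKM or TPM, linear scale)
#' with per-sample metadata and optional per-gene biotypes.
#'
#' @param values Non-negative numeric matrix, genes in rows (rownames = gene
#'   ids), samples in columns (colnames = sample ids).
#' @param meta data.frame with one row per sample and columns
#'   \code{tissue}, \code{stage}, \code{sex}, \code{batch} (and optionally
#'   \code{replicate}); rownames or a \code{sample} column must match
#'   \code{colnames(values)}.
#' @param biotype Optional character vector of per-gene biotypes.
#' @param units Abundance units, \code{"FPKM"} (default) or \code{"TPM"}.
#' @return An object of class \code{expr_matrix}.
#' @export
expr_matrix <- function(values, meta, biotype = NULL, units = "FPKM") {
  stopifnot(is.matrix(values))
  if (any(values < 0)) stopf("expression values must be >= 0")
  if (is.null(rownames(values)) || anyDuplicated(rownames(values))) {
    stopf("values must have unique gene rownames")
  }
  if (is.null(colnames(values)) || anyDuplicated(colnames(values))) {
    stopf("values must have unique sample colnames")
  }
  if ("sample" %in% names(meta)) rownames(meta) <- meta$sample
  if (!setequal(rownames(meta), colnames(values))) {
    stopf("sample metadata rows must match matrix columns")
  }
  meta <- meta[colnames(values), , drop = FALSE]
  need <- c("tissue", "stage", "sex", "batch")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stopf("metadata missing column(s): %s", paste(miss, collapse = ", "))
  if (anyNA(meta[need])) stopf("every sample needs complete metadata")
  if (!is.null(biotype) && length(biotype) != nrow(values)) {
    stopf("biotype length must equal number of genes")
  }
  structure(list(values = values, meta = meta, biotype = biotype, units = units),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples (%s); tissues: %s\n",
              nrow(x$values), ncol(x$values), x$units,
              paste(unique(x$meta$tissue), collapse = ", ")))
  invisible(x)
}

#' Log-transform an abundance matrix
#'
#' Elementwise \code{log2(x + pseudocount)}. The 0.1 pseudocount unmasks
#' lowly expressed transcripts while keeping zeros finite.
#'
#' @param m Non-negative numeric matrix (or \code{expr_matrix}).
#' @param pseudocount Added before the log (default 0.1).
#' @return Matrix of the same shape, log2 scale.
#' @examples
#' log_transform(matrix(c(0, 0.9), 1)) # log2(0.1), 0
#' @export
log_transform <- function(m, pseudocount = 0.1) {
  if (inherits(m, "expr_matrix")) m <- m$values
  if (any(m < 0)) stopf("log_transform: negative input")
  log2(m + pseudocount)
}

#' Remove unexpressed and tRNA genes before structuring
#'
#' A gene is retained iff at least one sample covers it with
#' \code{min_reads} mapped reads; tRNA-biotype genes are always removed.
#' The read filter operates on a companion read-count matrix, since
#' abundance units do not carry coverage.
#'
#' @param x \code{expr_matrix}.
#' @param read_counts Genes x samples integer matrix of mapped reads with
#'   rownames matching \code{x}; required.
#' @param min_reads Retention threshold (default 10).
#' @return Filtered \code{expr_matrix}.
#' @export
prefilter_genes <- function(x, read_counts, min_reads = 10) {
  stopifnot(inherits(x, "expr_matrix"))
  if (missing(read_counts) || is.null(read_counts)) {
    stopf("prefilter_genes needs a read-count companion matrix")
  }
  if (!all(rownames(x$values) %in% rownames(read_counts))) {
    stopf("read_counts missing genes present in the expression matrix")
  }
  rc <- read_counts[rownames(x$values), colnames(x$values), drop = FALSE]
  keep <- apply(rc, 1, max) >= min_reads
  if (!is.null(x$biotype)) keep <- keep & x$biotype != "tRNA"
  expr_matrix(x$values[keep, , drop = FALSE], x$meta,
              biotype = x$biotype[keep], units = x$units)
}

#' Partition genes into dynamic and ubiquitous
#'
#' A gene is dynamic iff its max/min abundance ratio across samples is at
#' least \code{fold} (boundary inclusive), on the linear scale, with a zero
#' minimum clamped to the 0.1 pseudocount to avoid infinite ratios;
#' otherwise it is ubiquitous (flat).
#'
#' @param x \code{expr_matrix} in linear units (not log-transformed).
#' @param fold Dynamic threshold on the max/min ratio (default 10).
#' @param pseudocount Floor applied to the per-gene minimum (default 0.1).
#' @return data.frame with \code{gene_id}, \code{label}
#'   (\code{"dynamic"}/\code{"ubiquitous"}) and \code{fold_ratio}.
#' @export
partition_dynamic_genes <- function(x, fold = 10, pseudocount = 0.1) {
  m <- if (inherits(x, "expr_matrix")) x$values else x
  if (ncol(m) < 2L) stopf("partition_dynamic_genes: need at least 2 samples")
  hi <- apply(m, 1, max)
  lo <- pmax(apply(m, 1, min), pseudocount)
  ratio <- hi / lo
  data.frame(gene_id = rownames(m),
             label = ifelse(ratio >= fold, "dynamic", "ubiquitous"),
             fold_ratio = ratio, stringsAsFactors = FALSE)
}

#' Principal component analysis of the log-scale transcriptome
#'
#' Samples are observations and genes are variables; genes are centred but
#' not scaled. Sample scores are z-scored per component for visualization and
#' downstream CCA; loadings are the unit-norm eigenvector coefficients. The
#' sign of each component is fixed so that the gene with the largest
#' absolute loading is positive (ties by lexicographic gene id), making
#' results reproducible across linear-algebra backends.
#'
#' @param m_log Genes x samples matrix, already log-transformed.
#' @param n_pcs Number of components to keep (default 20).
#' @return Object of class \code{pca_result}: list with \code{loadings}
#'   (genes x PCs), \code{scores} (samples x PCs, mean 0, sd 1 per column),
#'   \code{var_explained}, \code{sdev}, \code{center}.
#' @export
run_pca <- function(m_log, n_pcs = 20) {
  stopifnot(is.matrix(m_log))
  maxpc <- min(nrow(m_log), ncol(m_log) - 1L)
  if (n_pcs > min(dim(m_log))) stopf("n_pcs (%d) exceeds matrix rank bound (%d)",
                                     n_pcs, min(dim(m_log)))
  p <- stats::prcomp(t(m_log), center = TRUE, scale. = FALSE)
  k <- min(n_pcs, ncol(p$rotation))
  load <- p$rotation[, seq_len(k), drop = FALSE]
  scr <- p$x[, seq_len(k), drop = FALSE]
  # deterministic sign: largest-|loading| gene positive
  ids <- rownames(m_log)
  for (j in seq_len(k)) {
    a <- abs(load[, j])
    top <- which(a == max(a))
    top <- top[order(ids[top])][1]
    if (load[top, j] < 0) {
      load[, j] <- -load[, j]
      scr[, j] <- -scr[, j]
    }
  }
  zscr <- scale(scr)
  ve <- p$sdev^2 / sum(p$sdev^2)
  structure(list(loadings = load, scores = zscr[, , drop = FALSE],
                 raw_scores = scr, var_explained = ve[seq_len(k)],
                 sdev = p$sdev[seq_len(k)], center = p$center),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("pca_result: %d PCs over %d genes x %d samples; PC1 %.1f%% variance\n",
              ncol(x$loadings), nrow(x$loadings), nrow(x$scores),
              100 * x$var_explained[1]))
  invisible(x)
}

#' Genes with extreme loadings on one principal component
#'
#' Returns the \code{k} genes with the highest positive and the \code{k}
#' with the lowest negative loading coefficients, used to interpret the
#' biological meaning of a component. Ties are broken by lexicographic
#' gene id.
#'
#' @param pca A \code{pca_result}.
#' @param pc Component index.
#' @param k Set size (default 100).
#' @return List with \code{positive} and \code{negative} gene-id vectors.
#' @export
top_loading_genes <- function(pca, pc, k = 100) {
  load <- pca$loadings[, pc]
  ids <- rownames(pca$loadings)
  if (k > length(ids)) stopf("k (%d) exceeds number of genes (%d)", k, length(ids))
  pos <- ids[order(-load, ids)][seq_len(k)]
  neg <- ids[order(load, ids)][seq_len(k)]
  list(positive = pos, negative = neg)
}

#' Hierarchically cluster dynamic genes and extract major clusters
#'
#' Distance is 1 - Pearson correlation across samples, with average linkage.
#' Constant (zero-variance) genes are assigned distance 1 to every other
#' gene, with a warning. Major clusters are extracted automatically by
#' traversing from the root towards the leaves: a clade is split into its
#' two children while both children hold at least \code{min_clade} leaves;
#' a clade that can no longer be split and holds at least \code{min_clade}
#' leaves is a major cluster.
#'
#' @param m_log Genes x samples log-scale matrix (dynamic genes only).
#' @param min_clade Minimum leaves for a major cluster (default 30).
#' @return Object of class \code{cluster_set}: list with \code{hclust}
#'   (the dendrogram), \code{major_clusters} (named list of gene-id
#'   vectors), \code{membership} (cluster id per gene, NA if unassigned).
#' @export
cluster_genes <- function(m_log, min_clade = 30) {
  stopifnot(is.matrix(m_log), !is.null(rownames(m_log)))
  # order-invariance: canonical internal gene order
  m_log <- m_log[order(rownames(m_log)), , drop = FALSE]
  v <- apply(m_log, 1, stats::var)
  cc <- suppressWarnings(stats::cor(t(m_log)))
  if (any(v == 0)) {
    warnf("%d constant gene(s): distance to all others set to 1", sum(v == 0))
    cc[v == 0, ] <- 0
    cc[, v == 0] <- 0
    diag(cc) <- 1
  }
  d <- stats::as.dist(1 - cc)
  hc <- stats::hclust(d, method = "average")
  n <- nrow(m_log)
  ids <- rownames(m_log)

  leaves_of <- function(node) {
    # hclust merge encoding: negative = leaf index, positive = earlier merge
    if (node < 0) return(-node)
    stack <- node
    out <- integer(0)
    while (length(stack)) {
      nd <- stack[[1]]; stack <- stack[-1]
      ch <- hc$merge[nd, ]
      for (c1 in ch) {
        if (c1 < 0) out <- c(out, -c1) else stack <- c(stack, c1)
      }
    }
    out
  }
  sizes <- integer(nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    ch <- hc$merge[i, ]
    sizes[i] <- sum(ifelse(ch < 0, 1L, sizes[pmax(ch, 1L)]))
  }
  node_size <- function(node) if (node < 0) 1L else sizes[node]

  clusters <- list()
  walk <- function(node) {
    if (node_size(node) < min_clade) return(invisible(NULL))
    if (node > 0) {
      ch <- hc$merge[node, ]
      if (node_size(ch[1]) >= min_clade && node_size(ch[2]) >= min_clade) {
        walk(ch[1]); walk(ch[2])
        return(invisible(NULL))
      }
    }
    clusters[[length(clusters) + 1L]] <<- sort(ids[leaves_of(node)])
    invisible(NULL)
  }
  if (n >= min_clade) walk(nrow(hc$merge))
  # deterministic cluster order: by first member gene id
  if (length(clusters)) {
    clusters <- clusters[order(vapply(clusters, `[[`, character(1), 1))]
    names(clusters) <- paste0("cluster_", seq_along(clusters))
  }
  membership <- stats::setNames(rep(NA_character_, n), ids)
  for (nm in names(clusters)) membership[clusters[[nm]]] <- nm
  structure(list(hclust = hc, major_clusters = clusters, membership = membership,
                 min_clade = min_clade),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("cluster_set: %d major cluster(s) (min %d leaves) over %d genes; %d unassigned\n",
              length(x$major_clusters), x$min_clade, length(x$membership),
              sum(is.na(x$membership))))
  invisible(x)
}

#' Boolean design matrix from sample metadata
#'
#' One indicator column per level of tissue, stage, sex and batch;
#' collinear columns (including the redundant last level of each factor
#' given the others) are dropped by a QR rank check.
#'
#' @param meta Sample metadata data.frame.
#' @param fields Metadata fields to encode.
#' @return Numeric 0/1 matrix, samples in rows.
#' @export
metadata_design <- function(meta, fields = c("tissue", "stage", "sex", "batch")) {
  cols <- list()
  for (f in fields) {
    v <- as.factor(meta[[f]])
    for (lev in levels(v)) cols[[paste0(f, ":", lev)]] <- as.numeric(v == lev)
  }
  X <- do.call(cbind, cols)
  rownames(X) <- rownames(meta)
  qr_x <- qr(cbind(1, X))
  keep <- qr_x$pivot[seq_len(qr_x$rank)] - 1L  # drop the implicit intercept
  keep <- sort(keep[keep > 0])
  X[, keep, drop = FALSE]
}

#' Canonical correlation of PC scores against sample metadata
#'
#' Runs CCA between the top PC score matrix and the Boolean metadata design.
#' Gene-side loadings for each canonical variate are the PCA gene-loading
#' matrix multiplied by the PC-side canonical coefficients, which maps the
#' metadata axes back onto genes.
#'
#' @param pca \code{pca_result} (its z-scored \code{scores} are used).
#' @param meta Sample metadata data.frame, or a ready-made design matrix.
#' @param n_pcs How many leading PCs enter the CCA (default 20).
#' @return Object of class \code{cca_result}: \code{cor} (canonical
#'   correlations), \code{pc_coef} (PC-side coefficients), \code{meta_coef},
#'   \code{pc_variates} and \code{meta_variates} (standardized sample
#'   scores), \code{gene_loadings} (genes x variates), \code{design}.
#' @export
run_cca <- function(pca, meta, n_pcs = 20) {
  stopifnot(inherits(pca, "pca_result"))
  n_pcs <- min(n_pcs, ncol(pca$scores))
  X <- pca$scores[, seq_len(n_pcs), drop = FALSE]
  Y <- if (is.matrix(meta)) meta else metadata_design(meta)
  if (nrow(X) != nrow(Y)) stopf("PC scores and metadata disagree on sample count")
  if (nrow(Y) <= qr(Y)$rank) stopf("fewer samples than metadata rank")
  cc <- stats::cancor(X, Y)
  k <- length(cc$cor)
  xc <- cc$xcoef[, seq_len(k), drop = FALSE]
  yc <- cc$ycoef[, seq_len(k), drop = FALSE]
  Xc <- scale(X, center = cc$xcenter, scale = FALSE)
  Yc <- scale(Y, center = cc$ycenter, scale = FALSE)
  U <- scale(Xc %*% xc)  # standardized canonical variates
  V <- scale(Yc %*% yc)
  gl <- pca$loadings[, seq_len(n_pcs), drop = FALSE] %*% xc
  colnames(gl) <- colnames(U) <- colnames(V) <- paste0("CC", seq_len(k))
  structure(list(cor = cc$cor, pc_coef = xc, meta_coef = yc,
                 pc_variates = U, meta_variates = V, gene_loadings = gl,
                 design = Y),
            class = "cca_result")
}

#' @export
print.cca_result <- function(x, ...) {
  cat(sprintf("cca_result: %d canonical pairs; correlations %s\n",
              length(x$cor), paste(sprintf("%.2f", x$cor[seq_len(min(5, length(x$cor)))]),
                                   collapse = ", ")))
  invisible(x)
}

#' Infer embryo sex from Xist and Ddx3y expression
#'
#' A sample expressing only the female marker (Xist) is female; only the
#' male marker (Ddx3y), male; both detected, a mixed embryo pool; neither,
#' unknown.
#'
#' @param x \code{expr_matrix} in linear units.
#' @param xist_id,ddx3y_id Gene ids of the two sex markers.
#' @param detect_threshold Abundance at or above which a marker counts as
#'   detected (default 1.0 FPKM).
#' @return Named character vector over samples with values
#'   \code{female}, \code{male}, \code{mixed}, \code{unknown}.
#' @export
infer_sex <- function(x, xist_id = "Xist", ddx3y_id = "Ddx3y",
                      detect_threshold = 1.0) {
  m <- if (inherits(x, "expr_matrix")) x$values else x
  for (g in c(xist_id, ddx3y_id)) {
    if (!g %in% rownames(m)) stopf("sex marker gene %s absent from matrix", g)
  }
  f <- m[xist_id, ] >= detect_threshold
  ml <- m[ddx3y_id, ] >= detect_threshold
  out <- ifelse(f & ml, "mixed",
         ifelse(f, "female",
         ifelse(ml, "male", "unknown")))
  stats::setNames(out, colnames(m))
}

#' Stratify ubiquitous genes into high/medium/low expression groups
#'
#' Among ubiquitous genes, those whose mean log2(FPKM + 0.1) is no higher
#' than 2 are removed; of the rest, the \code{n} genes with the smallest
#' sample variance (log scale) are split into three equal groups by their
#' average linear-scale abundance.
#'
#' @param x \code{expr_matrix} in linear units.
#' @param ubiquitous_ids Gene ids labelled ubiquitous by
#'   \code{\link{partition_dynamic_genes}}.
#' @param n Number of low-variance genes stratified (default 3000).
#' @param pseudocount Log pseudocount (default 0.1).
#' @return List with gene-id vectors \code{high}, \code{medium}, \code{low}.
#' @export
stratify_ubiquitous <- function(x, ubiquitous_ids, n = 3000, pseudocount = 0.1) {
  m <- if (inherits(x, "expr_matrix")) x$values else x
  m <- m[intersect(ubiquitous_ids, rownames(m)), , drop = FALSE]
  ml <- log2(m + pseudocount)
  elig <- rowMeans(ml) > 2  # values no higher than 2 are removed
  m <- m[elig, , drop = FALSE]
  ml <- ml[elig, , drop = FALSE]
  if (nrow(m) < n) {
    warnf("only %d eligible ubiquitous genes (< n = %d); using all", nrow(m), n)
    n <- nrow(m)
  }
  vr <- apply(ml, 1, stats::var)
  ids <- rownames(m)[order(vr, rownames(m))][seq_len(n)]
  mu <- rowMeans(m[ids, , drop = FALSE])
  ord <- ids[order(-mu, ids)]
  third <- n %/% 3
  sizes <- c(third, third, n - 2L * third)
  list(high = ord[seq_len(sizes[1])],
       medium = ord[sizes[1] + seq_len(sizes[2])],
       low = ord[sizes[1] + sizes[2] + seq_len(sizes[3])])
}
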