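## Promoter extraction, PWM scanning with shuffled-sequence thresholds,
## Fisher-based motif enrichment with dual-annotation significance, and the
## bipartite motif-cluster graph.

#' Extract fixed-length promoter sequences upstream of each TSS
#'
#' Plus-strand genes yield \code{[tss - upstream, tss)}; minus-strand genes
#' the reverse complement of \code{[tss, tss + upstream)} (0-based
#' half-open). Windows are truncated at chromosome ends with a warning; a
#' TSS off the chromosome is an error.
#'
#' @param tss TSS table.
#' @param genome \code{DNAStringSet} named by chromosome.
#' @param upstream Promoter length in bp (default 500).
#' @return \code{DNAStringSet} named by gene id.
#' @export
extract_promoters <- function(tss, genome, upstream = 500) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  seqs <- character(nrow(tss))
  truncated <- FALSE
  for (i in seq_len(nrow(tss))) {
    ch <- tss$chrom[i]
    if (!ch %in% names(genome)) stopf("chromosome %s absent from genome", ch)
    len <- Biostrings::width(genome[ch])
    pos <- tss$tss[i]
    if (pos < 0 || pos >= len) stopf("TSS of %s off chromosome %s", tss$gene_id[i], ch)
    if (tss$strand[i] == "+") {
      s0 <- pos - upstream
      if (s0 < 0) { truncated <- TRUE; s0 <- 0 }
      if (pos == 0) { seqs[i] <- ""; next }
      seqs[i] <- as.character(Biostrings::subseq(genome[[ch]], s0 + 1L, pos))
    } else {
      e1 <- pos + upstream
      if (e1 > len) { truncated <- TRUE; e1 <- len }
      s <- Biostrings::subseq(genome[[ch]], pos + 1L, e1)
      seqs[i] <- as.character(Biostrings::reverseComplement(s))
    }
  }
  if (truncated) warnf("promoter window truncated at chromosome end for some genes")
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- tss$gene_id
  out
}

## Integer-encode a DNA string: A=1 C=2 G=3 T=4, anything else NA.
encode_dna <- function(s) {
  v <- utf8ToInt(toupper(s))
  code <- rep(NA_integer_, 128)
  code[utf8ToInt("A")] <- 1L; code[utf8ToInt("C")] <- 2L
  code[utf8ToInt("G")] <- 3L; code[utf8ToInt("T")] <- 4L
  code[v]
}

revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

## Max log-odds score of a PWM over one strand of an encoded sequence.
## Windows containing N score -Inf. Uniform 0.25 background; probabilities
## floored at 1e-4 so zero entries stay finite.
pwm_max_score_1strand <- function(enc, score_mat) {
  L <- ncol(score_mat)
  n <- length(enc) - L + 1L
  if (n < 1L) return(-Inf)
  sc <- numeric(n)
  ok <- rep(TRUE, n)
  for (j in seq_len(L)) {
    b <- enc[j:(j + n - 1L)]
    na <- is.na(b)
    ok <- ok & !na
    b[na] <- 1L
    sc <- sc + score_mat[cbind(b, j)]
  }
  sc[!ok] <- -Inf
  if (all(!ok)) -Inf else max(sc)
}

pwm_score_matrix <- function(pwm) {
  log2(pmax(pwm$mat, 1e-4) / 0.25)
}

## Max log-odds over both strands.
pwm_max_score <- function(seq_chr, score_mat) {
  if (!nzchar(seq_chr)) return(-Inf)
  s1 <- pwm_max_score_1strand(encode_dna(seq_chr), score_mat)
  s2 <- pwm_max_score_1strand(encode_dna(revcomp_chr(seq_chr)), score_mat)
  max(s1, s2)
}

## Mononucleotide shuffle of each sequence (composition-preserving).
shuffle_seqs <- function(seqs, seed) {
  set.seed(seed)
  vapply(seqs, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    paste(sample(ch), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Scan sequences for PWM hits
#'
#' Each sequence is scanned on both strands with the motif's log-odds
#' matrix (uniform background). A sequence is a hit iff its maximum window
#' score reaches the score threshold, defined as the
#' \code{threshold_quantile} quantile of maximum scores over
#' mononucleotide-shuffled copies of the same sequences (seeded, hence
#' reproducible).
#'
#' @param seqs \code{DNAStringSet} or character vector.
#' @param pwm A PWM (list with \code{id}, \code{mat}).
#' @param threshold_quantile Null-score quantile (default 0.999).
#' @param seed Seed for the shuffle (default 1).
#' @return Logical vector, one hit flag per sequence, with the threshold in
#'   attribute \code{"threshold"}.
#' @export
scan_pwm_hits <- function(seqs, pwm, threshold_quantile = 0.999, seed = 1) {
  seqs <- as.character(seqs)
  sm <- pwm_score_matrix(pwm)
  obs <- vapply(seqs, pwm_max_score, numeric(1), score_mat = sm, USE.NAMES = FALSE)
  null_scores <- vapply(shuffle_seqs(seqs, seed = seed), pwm_max_score, numeric(1),
                        score_mat = sm, USE.NAMES = FALSE)
  null_scores <- null_scores[is.finite(null_scores)]
  if (!length(null_scores)) {
    thr <- Inf
  } else {
    thr <- stats::quantile(null_scores, threshold_quantile, names = FALSE)
  }
  out <- obs >= thr
  attr(out, "threshold") <- thr
  out
}

#' Motif enrichment of a foreground sequence pool against a background
#'
#' For each motif and each annotation variant, sequences are scanned for
#' hits and a one-sided Fisher exact test compares the foreground hit count
#' with the background (the foreground must be contained in the
#' background after de-duplication by name). Raw P values are
#' Bonferroni-corrected over the motif library; a motif is significant iff
#' its corrected P is below \code{alpha} in every annotation variant.
#'
#' @param foreground,background Named lists of sequence sets (one per
#'   annotation variant, same names in both), or single sequence sets
#'   (treated as one variant). Sequences are named by gene.
#' @param motifs List of PWMs.
#' @param alpha Significance level on corrected P (default 0.01).
#' @param threshold_quantile,seed Passed to \code{\link{scan_pwm_hits}};
#'   hit thresholds are derived from the background pool of each variant.
#' @return \code{enrichment_result} data.frame: \code{motif},
#'   \code{variant}, \code{fg_hits}, \code{fg_n}, \code{bg_hits},
#'   \code{bg_n}, \code{p_raw}, \code{p_corrected}, plus a per-motif
#'   \code{significant} flag (TRUE iff significant under all variants).
#' @export
enrich_motifs <- function(foreground, background, motifs, alpha = 0.01,
                          threshold_quantile = 0.999, seed = 1) {
  as_variants <- function(x) {
    if (is.list(x) && !methods::is(x, "XStringSet")) x else list(default = x)
  }
  fg <- as_variants(foreground)
  bg <- as_variants(background)
  if (!identical(sort(names(fg)), sort(names(bg)))) {
    stopf("foreground and background must declare the same annotation variants")
  }
  as_named_chr <- function(x) {
    nm <- names(x)
    x <- as.character(x)
    names(x) <- nm
    x
  }
  rows <- list()
  for (va in names(fg)) {
    f <- as_named_chr(fg[[va]]); b <- as_named_chr(bg[[va]])
    if (is.null(names(f)) || is.null(names(b))) {
      stopf("variant %s: sequences must be named by gene", va)
    }
    f <- f[!duplicated(names(f))]
    b <- b[!duplicated(names(b))]
    if (!all(names(f) %in% names(b))) {
      stopf("variant %s: foreground must be a subset of the background", va)
    }
    for (k in seq_along(motifs)) {
      pwm <- motifs[[k]]
      hits_b <- scan_pwm_hits(b, pwm, threshold_quantile, seed = seed + k)
      hits_f <- hits_b[match(names(f), names(b))]
      tab <- matrix(c(sum(hits_f), sum(!hits_f),
                      sum(hits_b) - sum(hits_f),
                      sum(!hits_b) - sum(!hits_f)), 2, 2)
      p <- stats::fisher.test(tab, alternative = "greater")$p.value
      rows[[length(rows) + 1L]] <- data.frame(
        motif = pwm$id, variant = va,
        fg_hits = sum(hits_f), fg_n = length(f),
        bg_hits = sum(hits_b), bg_n = length(b),
        p_raw = p, p_corrected = min(1, p * length(motifs)),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  sig_by_motif <- tapply(out$p_corrected < alpha, out$motif, all)
  out$significant <- unname(sig_by_motif[out$motif])
  attr(out, "alpha") <- alpha
  class(out) <- c("enrichment_result", class(out))
  out
}

#' Bipartite motif-cluster graph from enrichment results
#'
#' One node per expression cluster (attribute \code{size}) and one per
#' motif ever significant; an edge joins a motif to each cluster where it
#' is significant, weighted by \code{-log10} of the corrected P (the worse
#' of the annotation variants). Motifs enriched in more than one cluster
#' are tagged \code{shared}, others \code{unique}.
#'
#' @param results Named list of \code{enrichment_result}s, one per cluster.
#' @param cluster_sizes Optional named numeric vector of cluster gene
#'   counts.
#' @return An \code{igraph} bipartite graph (vertex attribute \code{type}:
#'   FALSE for clusters, TRUE for motifs; \code{kind} in
#'   \code{{cluster, shared, unique}}).
#' @export
build_bipartite_graph <- function(results, cluster_sizes = NULL) {
  stopifnot(is.list(results), !is.null(names(results)))
  edges <- list()
  for (cl in names(results)) {
    r <- results[[cl]]
    sig <- r[r$significant, , drop = FALSE]
    if (!nrow(sig)) next
    # worst corrected P across variants per motif
    pm <- tapply(sig$p_corrected, sig$motif, max)
    edges[[cl]] <- data.frame(cluster = cl, motif = names(pm),
                              weight = -log10(pmax(unname(pm), 1e-300)),
                              stringsAsFactors = FALSE)
  }
  ed <- if (length(edges)) do.call(rbind, edges) else {
    data.frame(cluster = character(), motif = character(), weight = numeric())
  }
  clusters <- sort(names(results))
  motifs <- sort(unique(ed$motif))
  g <- igraph::make_empty_graph(directed = FALSE)
  g <- igraph::add_vertices(g, length(clusters), name = clusters, type = FALSE,
                            kind = "cluster",
                            size = if (!is.null(cluster_sizes))
                              unname(cluster_sizes[clusters]) else NA_real_)
  deg <- table(ed$motif)
  g <- igraph::add_vertices(g, length(motifs), name = motifs, type = TRUE,
                            kind = ifelse(deg[motifs] > 1, "shared", "unique"),
                            size = NA_real_)
  if (nrow(ed)) {
    g <- igraph::add_edges(g, rbind(match(ed$cluster, clusters),
                                    length(clusters) + match(ed$motif, motifs)),
                           weight = ed$weight)
  }
  g
}

#' Export a motif-cluster graph as JSON
#'
#' Nodes with their attributes and edges with weights, written via
#' jsonlite so downstream viewers can consume it.
#'
#' @param graph igraph object from \code{\link{build_bipartite_graph}}.
#' @param path Output JSON path.
#' @return Invisibly, the path.
#' @export
write_graph_json <- function(graph, path) {
  nodes <- data.frame(
    name = igraph::V(graph)$name,
    kind = igraph::V(graph)$kind,
    size = igraph::V(graph)$size,
    stringsAsFactors = FALSE)
  el <- igraph::as_edgelist(graph)
  edges <- data.frame(from = el[, 1], to = el[, 2],
                      weight = if (igraph::ecount(graph))
                        igraph::E(graph)$weight else numeric(0),
                      stringsAsFactors = FALSE)
  jsonlite::write_json(list(nodes = nodes, edges = edges), path,
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export a motif-cluster graph in DOT format
#' @param graph igraph object.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_graph_dot <- function(graph, path) {
  # DOT has no boolean attribute type; make the bipartite flag numeric
  igraph::V(graph)$type <- as.integer(igraph::V(graph)$type)
  igraph::write_graph(graph, path, format = "dot")
  invisible(path)
}
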