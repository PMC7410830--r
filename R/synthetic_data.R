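## Seeded generators for every input the pipeline consumes, with ground
## truth tables sufficient to score every downstream module. All generators
## are pure functions of (config, seed): the single global seed fans out to
## independent per-generator child streams.

#' Synthetic-data configuration
#'
#' Collects the study conditions the generators emulate: the tissue x stage
#' bulk design, the cell-type structure and planted marker effect sizes of
#' the single-cell data, and the toy epigenome geometry.
#'
#' @param seed Global seed; per-generator child seeds derive from it.
#' @param n_tissues,n_stages,n_replicates Bulk design (default 5 x 4 x 2).
#' @param n_genes Bulk gene count (default 2000).
#' @param n_cells,n_celltypes Single-cell design (default 1000 cells in 5
#'   types, i.e. 200 cells per type).
#' @param markers_per_type Planted exclusive markers per cell type
#'   (default 10).
#' @param marker_fold Marker mean fold change, detected cells (default 4).
#' @param marker_pct_in,marker_pct_out Detection fractions inside/outside
#'   the marked type (defaults 0.9 / 0.05).
#' @param sex_fold Abundance of the sex marker genes when on (default 30
#'   FPKM against a zero background).
#' @param batch_fold Multiplicative batch effect on the batch-gene block
#'   (default 2).
#' @param n_module_genes Planted co-expression module size (default 10).
#' @param n_noise_genes Independent high-dispersion noise genes
#'   (default 50).
#' @param genome_length Total toy genome size in bp, split over two
#'   chromosomes (default 2e6).
#' @param n_enhancers Planted elements (default 50).
#' @param n_marker_tss Marker genes receiving planted elements
#'   (default 20).
#' @param n_decoys Decoy peaks on non-whitelisted states (default 30).
#' @param nb_mean,nb_variance Background signal NB moments (defaults 5, 20;
#'   a variance at or below the mean exercises the Poisson fallback).
#' @param bin_width Signal track bin width in bp (default 200).
#' @return Validated list of class \code{synth_config}.
#' @export
synth_config <- function(seed = 1,
                         n_tissues = 5, n_stages = 4, n_replicates = 2,
                         n_genes = 2000,
                         n_cells = 1000, n_celltypes = 5,
                         markers_per_type = 10, marker_fold = 4,
                         marker_pct_in = 0.9, marker_pct_out = 0.05,
                         sex_fold = 30, batch_fold = 2,
                         n_module_genes = 10, n_noise_genes = 50,
                         genome_length = 2e6, n_enhancers = 50,
                         n_marker_tss = 20, n_decoys = 30,
                         nb_mean = 5, nb_variance = 20, bin_width = 200) {
  cfg <- as.list(environment())
  counts <- c("n_tissues", "n_stages", "n_replicates", "n_genes", "n_cells",
              "n_celltypes", "markers_per_type", "n_module_genes",
              "n_noise_genes", "n_enhancers", "n_marker_tss", "n_decoys",
              "genome_length", "bin_width")
  for (nm in counts) if (cfg[[nm]] <= 0) stopf("synth_config: %s must be > 0", nm)
  if (cfg$marker_pct_in <= cfg$marker_pct_out) {
    stopf("marker_pct_in must exceed marker_pct_out")
  }
  if (cfg$nb_mean <= 0 || cfg$nb_variance <= 0) stopf("NB moments must be > 0")
  if (cfg$n_cells %% cfg$n_celltypes != 0) {
    stopf("n_cells must be a multiple of n_celltypes")
  }
  structure(cfg, class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat(sprintf(paste0("synth_config (seed %d): %d tissues x %d stages x %d reps, ",
                     "%d genes; %d cells in %d types; %.0f bp genome\n"),
              x$seed, x$n_tissues, x$n_stages, x$n_replicates, x$n_genes,
              x$n_cells, x$n_celltypes, x$genome_length))
  invisible(x)
}

## Bounded multiplicative noise keeps planted fold-ratio guarantees exact:
## each value moves by at most exp(0.15) ~ 1.16x.
bnoise <- function(n, amp = 0.15) exp(stats::runif(n, -amp, amp))

#' Generate a bulk tissue x stage expression matrix with planted structure
#'
#' Contains tissue-specific dynamic blocks (ratio >= 10 by construction),
#' flat ubiquitous genes (ratio < 10), a stage-decaying cell-cycle-like
#' block, Xist/Ddx3y-like sex marker genes driven by a planted per-sample
#' sex, and an additive (log-scale) batch covariate on a gene block.
#' Multiplicative noise is bounded so the planted dynamic/ubiquitous
#' partition is exact for every seed.
#'
#' @param config \code{synth_config}.
#' @return List with \code{matrix} (an \code{expr_matrix}, FPKM) and
#'   \code{truth}: \code{planted_dynamic} (named logical),
#'   \code{planted_sex} (per sample), \code{tissue_blocks},
#'   \code{cellcycle_genes}, \code{sex_genes}, \code{batch_genes},
#'   \code{ubiquitous_genes}.
#' @export
generate_bulk_matrix <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(child_seed(config$seed, 1L))
  tissues <- paste0("T", seq_len(config$n_tissues))
  stages <- paste0("E", seq_len(config$n_stages))
  reps <- seq_len(config$n_replicates)
  meta <- expand.grid(replicate = reps, stage = stages, tissue = tissues,
                      stringsAsFactors = FALSE)[, c("tissue", "stage", "replicate")]
  meta$sample <- sprintf("%s_%s_r%d", meta$tissue, meta$stage, meta$replicate)
  n_smp <- nrow(meta)
  # balanced then shuffled, so every sex and batch level is always present
  meta$sex <- sample(rep_len(c("female", "male", "mixed"), n_smp))
  meta$batch <- sample(rep_len(c("b1", "b2"), n_smp))

  per_block <- 40L
  tissue_genes <- lapply(tissues, function(tt)
    sprintf("dyn_%s_%02d", tt, seq_len(per_block)))
  names(tissue_genes) <- tissues
  cc_genes <- sprintf("cc_%02d", seq_len(per_block))
  sex_genes <- c("Xist", "Ddx3y")
  batch_genes <- sprintf("bat_%02d", seq_len(30L))
  n_used <- per_block * (config$n_tissues + 1L) + 2L + 30L
  if (config$n_genes <= n_used) stopf("n_genes too small for planted blocks")
  ubiq_genes <- sprintf("ubi_%04d", seq_len(config$n_genes - n_used))

  genes <- c(unlist(tissue_genes, use.names = FALSE), cc_genes, sex_genes,
             batch_genes, ubiq_genes)
  m <- matrix(0, nrow = length(genes), ncol = n_smp,
              dimnames = list(genes, meta$sample))

  for (tt in tissues) {
    on <- meta$tissue == tt
    base <- matrix(1, per_block, n_smp)
    base[, on] <- 30
    m[tissue_genes[[tt]], ] <- base
  }
  stage_idx <- match(meta$stage, stages)
  m[cc_genes, ] <- matrix(rep(30 * 0.2^(stage_idx - 1), each = per_block),
                          per_block, n_smp)
  m["Xist", ] <- ifelse(meta$sex %in% c("female", "mixed"), config$sex_fold, 0)
  m["Ddx3y", ] <- ifelse(meta$sex %in% c("male", "mixed"), config$sex_fold, 0)
  bat <- ifelse(meta$batch == "b2", config$batch_fold, 1)
  m[batch_genes, ] <- 10 * matrix(rep(bat, each = length(batch_genes)),
                                  length(batch_genes), n_smp)
  ubase <- exp(stats::runif(length(ubiq_genes), log(4), log(100)))
  m[ubiq_genes, ] <- matrix(rep(ubase, n_smp), ncol = n_smp)

  m <- m * matrix(bnoise(length(m)), nrow(m), ncol(m))

  dynamic <- c(unlist(tissue_genes, use.names = FALSE), cc_genes, sex_genes)
  planted_dynamic <- stats::setNames(genes %in% dynamic, genes)
  em <- expr_matrix(m, meta)
  list(matrix = em,
       truth = list(planted_dynamic = planted_dynamic,
                    planted_sex = stats::setNames(meta$sex, meta$sample),
                    tissue_blocks = tissue_genes,
                    cellcycle_genes = cc_genes,
                    sex_genes = sex_genes,
                    batch_genes = batch_genes,
                    ubiquitous_genes = c(batch_genes, ubiq_genes)))
}

## Canonical marker/cell-type naming shared between the single-cell and
## epigenome generators so exclusive markers line up with planted elements.
synth_celltypes <- function(config) paste0("CT", seq_len(config$n_celltypes))

synth_marker_genes <- function(config) {
  cts <- synth_celltypes(config)
  out <- lapply(cts, function(ct)
    sprintf("mk%s_%02d", ct, seq_len(config$markers_per_type)))
  names(out) <- cts
  out
}

#' Generate cell-type-structured single-cell UMI counts
#'
#' Per-cell library sizes are log-normal; each cell type carries planted
#' exclusive markers detected in \code{marker_pct_in} of its cells versus
#' \code{marker_pct_out} elsewhere at \code{marker_fold} higher mean; a
#' planted co-expression module (shared on/off latent factor, independent
#' of cell type) supports tight-cluster tests; independent high-dispersion
#' noise genes should never co-cluster. Mitochondria-tagged genes plus a
#' handful of deliberately failing cells (high mito, low complexity)
#' exercise the QC filters.
#'
#' @param config \code{synth_config}.
#' @return List with \code{matrix} (a \code{cell_matrix}, platform tag) and
#'   \code{truth}: \code{planted_markers} (gene -> cell type),
#'   \code{celltype} (per cell), \code{planted_module_genes},
#'   \code{noise_genes}, \code{qc_fail_cells}.
#' @export
generate_sc_counts <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(child_seed(config$seed, 2L))
  cts <- synth_celltypes(config)
  per_type <- config$n_cells %/% config$n_celltypes
  celltype <- rep(cts, each = per_type)
  n_cells <- length(celltype)
  cells <- sprintf("cell_%04d", seq_len(n_cells))

  markers <- synth_marker_genes(config)
  marker_genes <- unlist(markers, use.names = FALSE)
  n_base <- 400L
  base_genes <- sprintf("base_%03d", seq_len(n_base))
  module_genes <- sprintf("mod_%02d", seq_len(config$n_module_genes))
  noise_genes <- sprintf("noise_%02d", seq_len(config$n_noise_genes))
  mito_genes <- sprintf("mt-%d", 1:5)
  genes <- c(marker_genes, base_genes, module_genes, noise_genes, mito_genes)

  lib <- exp(stats::rnorm(n_cells, 0, 0.3))  # log-normal library factor
  v <- matrix(0L, n_cells, length(genes), dimnames = list(cells, genes))

  # markers: detection Bernoulli(pct), detected counts 1 + Pois(lambda - 1)
  lam_out <- 2; lam_in <- config$marker_fold * lam_out
  for (ct in cts) {
    for (g in markers[[ct]]) {
      pct <- ifelse(celltype == ct, config$marker_pct_in, config$marker_pct_out)
      lam <- ifelse(celltype == ct, lam_in, lam_out)
      det <- stats::rbinom(n_cells, 1, pct)
      v[, g] <- det * (1L + stats::rpois(n_cells, pmax(lam * lib - 1, 0)))
    }
  }
  lam_base <- exp(stats::runif(n_base, log(0.5), log(4)))
  for (j in seq_len(n_base)) {
    v[, base_genes[j]] <- stats::rpois(n_cells, lam_base[j] * lib)
  }
  z <- stats::rbinom(n_cells, 1, 0.3)  # shared module driver
  for (g in module_genes) {
    v[, g] <- stats::rpois(n_cells, (z * 10 + 0.1) * lib)
  }
  for (g in noise_genes) {
    # high dispersion, independent across genes and cells
    v[, g] <- stats::rnbinom(n_cells, size = 0.1, mu = 1.5 * lib)
  }
  for (g in mito_genes) v[, g] <- stats::rpois(n_cells, 2 * lib)

  # planted QC failures: 6 high-mito cells, 6 near-empty cells
  hi_mito <- cells[seq_len(6)]
  # scaled by the library factor so the mito fraction stays ~0.3 regardless
  # of cell depth
  v[hi_mito, mito_genes] <- v[hi_mito, mito_genes] +
    matrix(stats::rpois(6L * 5L, 60 * rep(lib[seq_len(6)], 5L)), 6, 5)
  lo_cells <- cells[7:12]
  keep_gene <- seq_len(20)
  v[lo_cells, -keep_gene] <- 0L

  cm <- cell_matrix(v, platform = "tag", mito_genes = mito_genes)
  planted_markers <- stats::setNames(
    rep(cts, each = config$markers_per_type), marker_genes)
  list(matrix = cm,
       truth = list(planted_markers = planted_markers,
                    celltype = stats::setNames(celltype, cells),
                    planted_module_genes = module_genes,
                    noise_genes = noise_genes,
                    qc_fail_cells = c(hi_mito, lo_cells)))
}

#' Generate a toy epigenome with planted regulatory elements
#'
#' Two synthetic chromosomes of random sequence carry regularly spaced
#' gene TSSs; a subset are the single-cell marker genes. Planted enhancers
#' are DHS peaks at controlled distances (100 bp, 1 kb, 5 kb) from marker
#' TSSs, each overlapping a whitelisted chromatin state (rotating active /
#' poised / bivalent); decoy peaks sit on non-whitelisted states. Signal
#' tracks are negative-binomial with elevated means over planted elements;
#' the input track is flat NB background.
#'
#' @param config \code{synth_config}.
#' @return List with \code{genome} (DNAStringSet), \code{tss} (TSS table
#'   with \code{expressed}), \code{peaks} (list of two DHS peak sets),
#'   \code{segmentation} (classified state intervals), \code{signal} and
#'   \code{input} (\code{signal_track}s), \code{exclusive_markers}
#'   (gene -> cell type) and \code{truth}: \code{planted_elements}
#'   (data.frame with interval, gene, distance, category, state class,
#'   cell type) and \code{decoy_peaks}.
#' @export
generate_epigenome <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(child_seed(config$seed, 3L))
  bw <- config$bin_width
  chrom_len <- as.integer(config$genome_length / 2)
  chrom_len <- (chrom_len %/% bw) * bw
  chroms <- c("chrS1", "chrS2")
  genome <- Biostrings::DNAStringSet(vapply(chroms, function(ch)
    paste(sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE),
          collapse = ""), character(1)))
  names(genome) <- chroms

  spacing <- 20000L
  per_chrom <- (chrom_len - spacing) %/% spacing
  pos <- lapply(chroms, function(ch) spacing * seq_len(per_chrom))
  n_genes <- per_chrom * 2L
  markers <- synth_marker_genes(config)
  marker_pool <- unlist(markers, use.names = FALSE)
  if (config$n_marker_tss > length(marker_pool)) {
    stopf("n_marker_tss exceeds available marker genes")
  }
  marker_ids <- marker_pool[seq_len(config$n_marker_tss)]
  other_ids <- sprintf("gene_%03d", seq_len(n_genes - length(marker_ids)))
  # marker genes occupy every other slot from the start, interleaved with
  # ordinary genes, alternating strand
  ids <- character(n_genes)
  mslot <- seq(1L, by = 2L, length.out = length(marker_ids))
  ids[mslot] <- marker_ids
  ids[setdiff(seq_len(n_genes), mslot)] <- other_ids
  tss <- data.frame(gene_id = ids,
                    chrom = rep(chroms, each = per_chrom),
                    tss = unlist(pos),
                    strand = rep(c("+", "-"), length.out = n_genes),
                    stringsAsFactors = FALSE)
  tss$expressed <- TRUE
  # a few unexpressed genes to exercise the expression filter
  unexpr <- setdiff(tss$gene_id, marker_ids)[1:5]
  tss$expressed[tss$gene_id %in% unexpr] <- FALSE

  ct_of <- stats::setNames(rep(synth_celltypes(config),
                               each = config$markers_per_type), marker_pool)
  dists <- c(100L, 1000L, 5000L)
  classes <- c("active", "poised", "bivalent")
  state_of <- c(active = 14L, poised = 8L, bivalent = 26L)
  width <- 300L
  el <- vector("list", config$n_enhancers)
  for (k in seq_len(config$n_enhancers)) {
    g <- marker_ids[((k - 1L) %% length(marker_ids)) + 1L]
    ti <- which(tss$gene_id == g)
    d <- dists[((k - 1L) %/% length(marker_ids)) %% length(dists) + 1L]
    side <- if (k %% 2L == 0L) 1L else -1L
    if (side > 0) {
      start <- tss$tss[ti] + d
      end <- start + width
    } else {
      end <- tss$tss[ti] - d
      start <- end - width
    }
    cls <- classes[((k - 1L) %% 3L) + 1L]
    el[[k]] <- data.frame(chrom = tss$chrom[ti], start = start, end = end,
                          gene = g, distance = d,
                          category = categorize_distance(d),
                          state_class = cls, cell_type = unname(ct_of[g]),
                          stringsAsFactors = FALSE)
  }
  planted <- do.call(rbind, el)
  if (anyDuplicated(planted[c("chrom", "start", "end")])) {
    stopf("internal: planted elements collide")  # geometry guard
  }

  # segmentation: background state 1 everywhere, whitelisted states over
  # planted elements (padded to the bin grid)
  seg_rows <- list()
  for (ch in chroms) {
    pe <- planted[planted$chrom == ch, , drop = FALSE]
    pe <- pe[order(pe$start), , drop = FALSE]
    s0 <- (pe$start %/% bw) * bw
    s1 <- ((pe$end + bw - 1L) %/% bw) * bw
    cursor <- 0L
    for (i in seq_len(nrow(pe))) {
      if (s0[i] > cursor) {
        seg_rows[[length(seg_rows) + 1L]] <-
          data.frame(chrom = ch, start = cursor, end = s0[i], state = 1L)
      }
      seg_rows[[length(seg_rows) + 1L]] <-
        data.frame(chrom = ch, start = s0[i], end = s1[i],
                   state = unname(state_of[pe$state_class[i]]))
      cursor <- s1[i]
    }
    if (cursor < chrom_len) {
      seg_rows[[length(seg_rows) + 1L]] <-
        data.frame(chrom = ch, start = cursor, end = chrom_len, state = 1L)
    }
  }
  segmentation <- classify_states(do.call(rbind, seg_rows))

  # decoy peaks on state-1 ground, kept clear of planted states
  occupied <- to_granges(planted)
  decoys <- list()
  tries <- 0L
  while (length(decoys) < config$n_decoys && tries < 10000L) {
    tries <- tries + 1L
    ch <- sample(chroms, 1)
    start <- sample.int(chrom_len - width - 1L, 1)
    cand <- data.frame(chrom = ch, start = start, end = start + width)
    pad <- data.frame(chrom = ch, start = max(start - bw, 0L),
                      end = start + width + bw)
    ov <- suppressWarnings(GenomicRanges::findOverlaps(to_granges(pad), occupied))
    if (!length(ov)) {
      decoys[[length(decoys) + 1L]] <- cand
    }
  }
  decoys <- do.call(rbind, decoys)

  all_peaks <- rbind(planted[c("chrom", "start", "end")], decoys)
  split_idx <- seq_len(nrow(all_peaks)) %% 2L == 0L
  peak_sets <- list(sampleA = all_peaks[split_idx, , drop = FALSE],
                    sampleB = all_peaks[!split_idx, , drop = FALSE])

  # NB signal with elevated means over planted elements; flat NB input
  n_bins <- chrom_len %/% bw
  size_bg <- if (config$nb_variance > config$nb_mean) {
    config$nb_mean^2 / (config$nb_variance - config$nb_mean)
  } else Inf
  draw <- function(mu, n) {
    if (is.finite(size_bg)) stats::rnbinom(n, size = size_bg, mu = mu)
    else stats::rpois(n, mu)
  }
  sig_bins <- inp_bins <- list()
  for (ch in chroms) {
    mu <- rep(config$nb_mean, n_bins)
    pe <- planted[planted$chrom == ch, , drop = FALSE]
    for (i in seq_len(nrow(pe))) {
      b0 <- pe$start[i] %/% bw
      b1 <- (pe$end[i] - 1L) %/% bw
      mu[(b0 + 1L):(b1 + 1L)] <- config$nb_mean * 8
    }
    sig_bins[[ch]] <- as.numeric(draw(mu, n_bins))
    inp_bins[[ch]] <- as.numeric(draw(rep(config$nb_mean, n_bins), n_bins))
  }
  list(genome = genome, tss = tss, peaks = peak_sets,
       segmentation = segmentation,
       signal = signal_track(sig_bins, bw, sample_id = "synthetic", role = "signal"),
       input = signal_track(inp_bins, bw, sample_id = "synthetic", role = "input"),
       exclusive_markers = ct_of[marker_ids],
       truth = list(planted_elements = planted, decoy_peaks = decoys,
                    unexpressed_genes = unexpr))
}

#' Generate a promoter histone-modification time course with one
#' de-repressed cluster
#'
#' Builds per-timepoint signal/input track pairs over the toy genome in
#' which the promoters of one planted gene cluster lose signal
#' monotonically across timepoints (the de-repression signature of a
#' repressive mark) while the other clusters stay flat, together with a
#' stage-ordered expression matrix in which the de-repressed cluster's RNA
#' rises.
#'
#' @param config \code{synth_config}.
#' @param epigenome Output of \code{\link{generate_epigenome}} (re-used for
#'   its TSS table and geometry).
#' @param n_clusters Number of gene clusters (default 10; cluster 1 is the
#'   de-repressed one).
#' @param n_timepoints Time points (default 4).
#' @return List with \code{fc_tracks} (named list of log2 fold-change
#'   \code{signal_track}s, earliest first), \code{clusters} (named list of
#'   gene-id vectors), \code{expr_log} (genes x stages matrix) and
#'   \code{truth} (\code{derepressed_cluster}).
#' @export
generate_histone_timecourse <- function(config, epigenome = NULL,
                                        n_clusters = 10, n_timepoints = 4) {
  stopifnot(inherits(config, "synth_config"))
  if (is.null(epigenome)) epigenome <- generate_epigenome(config)
  set.seed(child_seed(config$seed, 4L))
  tss <- epigenome$tss
  bw <- config$bin_width
  genes <- tss$gene_id
  per <- length(genes) %/% n_clusters
  clusters <- split(genes[seq_len(per * n_clusters)],
                    rep(seq_len(n_clusters), each = per))
  names(clusters) <- paste0("gc", seq_len(n_clusters))

  n_bins <- lengths(epigenome$signal$bins)
  fc_tracks <- list()
  for (t in seq_len(n_timepoints)) {
    bins <- lapply(names(n_bins), function(ch) stats::rnorm(n_bins[[ch]], 0, 0.05))
    names(bins) <- names(n_bins)
    # promoter elevation: de-repressed cluster decays 3 -> 0; others flat 1.5
    for (ci in seq_len(n_clusters)) {
      level <- if (ci == 1L) 3 * (n_timepoints - t) / (n_timepoints - 1) else 1.5
      for (g in clusters[[ci]]) {
        gi <- which(tss$gene_id == g)
        b0 <- max((tss$tss[gi] - 2000L) %/% bw, 0L)
        b1 <- min((tss$tss[gi] + 2000L - 1L) %/% bw, n_bins[[tss$chrom[gi]]] - 1L)
        bins[[tss$chrom[gi]]][(b0 + 1L):(b1 + 1L)] <-
          bins[[tss$chrom[gi]]][(b0 + 1L):(b1 + 1L)] + level
      }
    }
    tr <- list(bins = bins, bin_width = bw, sample_id = sprintf("t%d", t),
               mark = "H3K27me3", role = "log2fc")
    class(tr) <- "signal_track"
    fc_tracks[[sprintf("t%d", t)]] <- tr
  }
  stages <- paste0("E", seq_len(n_timepoints))
  expr <- matrix(5, length(genes), n_timepoints,
                 dimnames = list(genes, stages))
  expr[clusters[["gc1"]], ] <- matrix(rep(2 * seq_len(n_timepoints),
                                          each = length(clusters[["gc1"]])),
                                      length(clusters[["gc1"]]), n_timepoints)
  expr <- expr + matrix(stats::rnorm(length(expr), 0, 0.1), nrow(expr))
  list(fc_tracks = fc_tracks, clusters = clusters, expr_log = expr,
       truth = list(derepressed_cluster = "gc1"))
}

#' A synthetic position weight matrix with a strong consensus
#'
#' 0.85 probability on each consensus base (default \code{TGACGTCATG});
#' used to plant and recover motifs in promoter tests.
#'
#' @param id Motif id (default \code{"SYNTH1"}).
#' @param consensus Consensus string over ACGT (>= 4 bases).
#' @return A PWM list (\code{id}, \code{mat}, \code{source}).
#' @export
synth_pwm <- function(id = "SYNTH1", consensus = "TGACGTCATG") {
  consensus <- strsplit(toupper(consensus), "", fixed = TRUE)[[1]]
  stopifnot(length(consensus) >= 4, all(consensus %in% c("A", "C", "G", "T")))
  bases <- c("A", "C", "G", "T")
  mat <- matrix(0.05, 4, length(consensus), dimnames = list(bases, NULL))
  for (j in seq_along(consensus)) mat[consensus[j], j] <- 0.85
  list(id = id, mat = mat, source = "human")
}

#' Plant a motif consensus into promoter regions of selected genes
#'
#' Overwrites a fixed window at \code{offset} bp upstream of each selected
#' gene's TSS (strand-aware) with the motif consensus, so that promoter
#' extraction under either of two slightly shifted TSS annotations still
#' contains the site.
#'
#' @param genome \code{DNAStringSet}.
#' @param tss TSS table.
#' @param genes Gene ids to receive the motif.
#' @param pwm PWM whose per-column argmax defines the consensus.
#' @param offset Upstream offset of the site start (default 300 bp).
#' @return The modified genome.
#' @export
plant_promoter_motifs <- function(genome, tss, genes, pwm, offset = 300) {
  bases <- rownames(pwm$mat)
  consensus <- paste(bases[apply(pwm$mat, 2, which.max)], collapse = "")
  L <- nchar(consensus)
  rc <- revcomp_chr(consensus)
  seqs <- as.character(genome)
  for (g in genes) {
    i <- which(tss$gene_id == g)
    if (!length(i)) stopf("gene %s absent from TSS table", g)
    ch <- tss$chrom[i]
    if (tss$strand[i] == "+") {
      s0 <- tss$tss[i] - offset  # 0-based start of the site
      substr(seqs[ch], s0 + 1L, s0 + L) <- consensus
    } else {
      s0 <- tss$tss[i] + offset - L
      substr(seqs[ch], s0 + 1L, s0 + L) <- rc
    }
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- names(genome)
  out
}

#' Write every synthetic fixture to a directory
#'
#' Materializes the bulk matrix and metadata, single-cell counts, genome
#' FASTA, TSS table, DHS peak BEDs, state segmentation BED, signal and
#' input bedGraphs and the truth tables (JSON), all through the package's
#' own writers.
#'
#' @param config \code{synth_config}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
synth_write_all <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  bulk <- generate_bulk_matrix(config)
  sc <- generate_sc_counts(config)
  epi <- generate_epigenome(config)
  write_matrix(bulk$matrix$values, file.path(dir, "bulk_fpkm.tsv"))
  utils::write.table(bulk$matrix$meta, file.path(dir, "bulk_meta.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_matrix(t(sc$matrix$values), file.path(dir, "sc_counts.tsv"))
  write_fasta(epi$genome, file.path(dir, "genome.fa"))
  write_tss_table(epi$tss, file.path(dir, "tss.tsv"))
  write_bed(epi$peaks$sampleA, file.path(dir, "dhs_sampleA.bed"))
  write_bed(epi$peaks$sampleB, file.path(dir, "dhs_sampleB.bed"))
  write_bed(epi$segmentation[c("chrom", "start", "end", "state")],
            file.path(dir, "states.bed"))
  write_bedgraph(epi$signal, file.path(dir, "signal.bedgraph"))
  write_bedgraph(epi$input, file.path(dir, "input.bedgraph"))
  truth <- list(bulk = lapply(bulk$truth, unclass),
                sc = lapply(sc$truth, unclass),
                epigenome = list(
                  planted_elements = epi$truth$planted_elements,
                  decoy_peaks = epi$truth$decoy_peaks,
                  unexpressed_genes = epi$truth$unexpressed_genes,
                  exclusive_markers = as.list(epi$exclusive_markers)))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
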