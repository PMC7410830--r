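## The cell-type cCRE pipeline: merge DHS peaks, filter by chromatin-state
## class, assign to the nearest expressed TSS, categorize by distance, and
## attribute elements to cell types through exclusive marker genes.

#' Default chromatin-state class map
#'
#' Integer segmentation states classified as active
#' (14, 19, 20, 21, 23, 24, 25, 27, 28, 30-32), poised (8, 13) or bivalent
#' (26, 29); every other state is \code{"other"}.
#'
#' @return Named list of integer vectors \code{active}, \code{poised},
#'   \code{bivalent}.
#' @export
default_state_classes <- function() {
  list(active = c(14L, 19L, 20L, 21L, 23L, 24L, 25L, 27L, 28L, 30L, 31L, 32L),
       poised = c(8L, 13L),
       bivalent = c(26L, 29L))
}

#' Classify segmentation intervals by chromatin-state class
#'
#' @param segmentation data.frame of intervals with a \code{state} column
#'   (integer state ids), e.g. from \code{\link{read_bed}}.
#' @param class_map Named list of state-id vectors per class; defaults to
#'   \code{\link{default_state_classes}}. States absent from the map are
#'   classified \code{"other"}; set \code{strict} to require full coverage.
#' @param strict Error on a state id missing from the map (default FALSE).
#' @return The segmentation with a \code{state_class} column added.
#' @export
classify_states <- function(segmentation, class_map = default_state_classes(),
                            strict = FALSE) {
  if (!"state" %in% names(segmentation)) stopf("segmentation needs a state column")
  lut <- character(0)
  for (cl in names(class_map)) lut[as.character(class_map[[cl]])] <- cl
  cls <- lut[as.character(segmentation$state)]
  if (strict && anyNA(cls)) {
    stopf("state id %s has no class", segmentation$state[which(is.na(cls))[1]])
  }
  cls[is.na(cls)] <- "other"
  segmentation$state_class <- unname(cls)
  segmentation
}

#' Merge DHS peak sets into a single non-redundant interval set
#'
#' Union of all peaks across samples; overlapping or bookended intervals
#' coalesce. Output is sorted by chromosome then start.
#'
#' @param ... data.frames of 0-based half-open intervals (or one list of
#'   them).
#' @param chrom_whitelist Optional chromosome names; intervals on other
#'   chromosomes are an error.
#' @return data.frame with \code{chrom}, \code{start}, \code{end}.
#' @export
merge_peaks <- function(..., chrom_whitelist = NULL) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1]]) && !is.data.frame(sets[[1]])) {
    sets <- sets[[1]]
  }
  df <- do.call(rbind, lapply(sets, function(s) s[c("chrom", "start", "end")]))
  if (!nrow(df)) return(data.frame(chrom = character(), start = integer(),
                                   end = integer()))
  check_intervals(df$chrom, df$start, df$end, "merge_peaks")
  if (!is.null(chrom_whitelist)) {
    bad <- setdiff(unique(df$chrom), chrom_whitelist)
    if (length(bad)) stopf("interval on unknown chromosome: %s", bad[1])
  }
  gr <- GenomicRanges::reduce(to_granges(df))  # merges bookended neighbours
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1L,
                    end = GenomicRanges::end(gr),
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Keep peaks overlapping whitelisted chromatin states
#'
#' A merged peak is retained iff it overlaps (by at least 1 bp) an active,
#' poised or bivalent state interval in at least one segmentation sample.
#' When classes conflict across overlaps, the recorded class follows the
#' precedence active > bivalent > poised.
#'
#' @param peaks Merged peak data.frame.
#' @param segmentations One classified segmentation (from
#'   \code{\link{classify_states}}) or a list of them (one per sample).
#' @return Retained peaks with a \code{state_class} column.
#' @export
filter_peaks_by_state <- function(peaks, segmentations) {
  if (is.data.frame(segmentations)) segmentations <- list(segmentations)
  seg <- do.call(rbind, lapply(segmentations, function(s)
    s[c("chrom", "start", "end", "state_class")]))
  seg <- seg[seg$state_class %in% c("active", "poised", "bivalent"), , drop = FALSE]
  if (!nrow(peaks)) return(cbind(peaks, state_class = character(0)))
  if (!nrow(seg)) return(peaks[integer(0), , drop = FALSE])
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(to_granges(peaks), to_granges(seg)))
  if (!length(hits)) return(peaks[integer(0), , drop = FALSE])
  prec <- c(active = 1L, bivalent = 2L, poised = 3L)
  cls_hit <- seg$state_class[S4Vectors::subjectHits(hits)]
  best <- tapply(prec[cls_hit], S4Vectors::queryHits(hits), min)
  idx <- as.integer(names(best))
  out <- peaks[idx, , drop = FALSE]
  out$state_class <- names(prec)[as.integer(best)]
  rownames(out) <- NULL
  out
}

#' Expressed-gene filter combining bulk and single-cell evidence
#'
#' A gene is expressed iff its maximum bulk abundance exceeds
#' \code{bulk_min} (strictly) or it is detected (> 0) in strictly more
#' than \code{min_cells} single cells.
#'
#' @param bulk Genes x samples bulk matrix (or \code{expr_matrix}), or NULL.
#' @param cells Cells x genes single-cell matrix (or \code{cell_matrix}),
#'   or NULL.
#' @param bulk_min Bulk FPKM threshold (default 0.1, exclusive).
#' @param min_cells Detected-cell threshold (default 4, exclusive:
#'   "more than four cells").
#' @return Character vector of expressed gene ids.
#' @export
expressed_gene_filter <- function(bulk = NULL, cells = NULL,
                                  bulk_min = 0.1, min_cells = 4) {
  ids <- character(0)
  if (!is.null(bulk)) {
    m <- if (inherits(bulk, "expr_matrix")) bulk$values else bulk
    ids <- c(ids, rownames(m)[apply(m, 1, max) > bulk_min])
  }
  if (!is.null(cells)) {
    v <- if (inherits(cells, "cell_matrix")) cells$values else cells
    ids <- c(ids, colnames(v)[colSums(v > 0) > min_cells])
  }
  sort(unique(ids))
}

## Distance from a peak [start, end) to a TSS position: 0 when the TSS lies
## within [start, end], otherwise the gap to the nearer interval edge
## (half-open end coordinate; a TSS bookending the peak is at distance 0).
peak_tss_distance <- function(start, end, tss) {
  pmax(start - tss, tss - end, 0L)
}

#' Assign each peak to its nearest expressed TSS
#'
#' Distance is the absolute offset from the TSS to the nearer peak edge
#' (0 when the TSS lies inside the peak). The nearest
#' expressed TSS on the same chromosome wins; exact ties are broken by
#' lexicographic gene id. Chromosomes with no expressed TSS leave their
#' peaks unassigned, with a warning.
#'
#' @param peaks Peak data.frame (\code{chrom}, \code{start}, \code{end},
#'   extra columns carried through).
#' @param tss TSS table restricted to (or flagged for) expressed genes; if
#'   an \code{expressed} column is present only TRUE rows are used.
#' @return Peaks with \code{assigned_gene} and \code{distance} columns
#'   (NA where unassigned).
#' @export
assign_nearest_tss <- function(peaks, tss) {
  if ("expressed" %in% names(tss)) tss <- tss[tss$expressed, , drop = FALSE]
  peaks$assigned_gene <- NA_character_
  peaks$distance <- NA_integer_
  warn_chroms <- character(0)
  for (ch in unique(peaks$chrom)) {
    pi <- which(peaks$chrom == ch)
    tt <- tss[tss$chrom == ch, , drop = FALSE]
    if (!nrow(tt)) { warn_chroms <- c(warn_chroms, ch); next }
    ord <- order(tt$tss, tt$gene_id)
    tpos <- tt$tss[ord]
    tid <- tt$gene_id[ord]
    for (i in pi) {
      s <- peaks$start[i]; e <- peaks$end[i]
      # nearest TSS at/below the start and at/above the end bound the
      # minimal distance
      lo <- findInterval(s, tpos)   # last tss <= s
      hi <- findInterval(e, tpos)   # last tss <= e
      cand <- unique(pmin(pmax(c(lo, lo + 1L, hi, hi + 1L), 1L), length(tpos)))
      inside <- tpos >= s & tpos <= e
      dmin <- if (any(inside)) 0L else
        min(peak_tss_distance(s, e, tpos[cand]))
      # all TSSs achieving dmin (several genes can share a position)
      at_min <- if (dmin == 0L) which(inside) else
        which(tpos == s - dmin | tpos == e + dmin)
      best <- at_min[order(tid[at_min])][1]
      peaks$assigned_gene[i] <- tid[best]
      peaks$distance[i] <- dmin
    }
  }
  if (length(warn_chroms)) {
    warnf("no expressed TSS on chromosome(s) %s: peaks left unassigned",
          paste(warn_chroms, collapse = ", "))
  }
  peaks
}

#' Categorize an element-to-TSS distance
#'
#' Proximal when the distance is no greater than 200 bp, middle when
#' greater than 200 and no greater than 2,000 bp, distal beyond 2,000 bp
#' (absolute distance, either direction).
#'
#' @param distance Non-negative distance(s) in bp.
#' @return Character vector in \code{{proximal, middle, distal}}.
#' @examples
#' categorize_distance(c(200, 201, 2000, 2001))
#' @export
categorize_distance <- function(distance) {
  if (any(distance < 0, na.rm = TRUE)) stopf("distances must be >= 0")
  ifelse(distance <= 200, "proximal",
         ifelse(distance <= 2000, "middle", "distal"))
}

#' Attribute candidate elements to cell types via exclusive markers
#'
#' Elements assigned to a gene carried in the exclusive-marker map inherit
#' that gene's cell type or lineage group; elements assigned to non-marker
#' genes are dropped from the cell-type table (they remain in the full
#' cCRE table produced upstream).
#'
#' @param elements Peak table from \code{\link{assign_nearest_tss}} with
#'   \code{state_class} and \code{distance} columns.
#' @param exclusive_markers Named vector gene id -> cell type/group, from
#'   \code{\link{derive_exclusive_markers}}.
#' @return \code{candidate_elements} data.frame: interval, assigned gene,
#'   distance, \code{category}, \code{state_class}, \code{cell_type}.
#' @export
derive_celltype_elements <- function(elements, exclusive_markers) {
  keep <- !is.na(elements$assigned_gene) &
    elements$assigned_gene %in% names(exclusive_markers)
  out <- elements[keep, , drop = FALSE]
  out$category <- categorize_distance(out$distance)
  out$cell_type <- unname(exclusive_markers[out$assigned_gene])
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("candidate_elements", class(out))
  out
}

#' Coverage of exclusive marker genes by candidate elements
#'
#' @param elements \code{candidate_elements} table.
#' @param marker_genes Character vector of exclusive marker gene ids.
#' @param classes State classes that count as affiliation (default active
#'   and poised).
#' @return List: \code{n_marker_genes}, \code{n_with_element},
#'   \code{fraction}, \code{n_elements}.
#' @export
coverage_stats <- function(elements, marker_genes,
                           classes = c("active", "poised")) {
  el <- elements[elements$state_class %in% classes, , drop = FALSE]
  covered <- intersect(marker_genes, el$assigned_gene)
  list(n_marker_genes = length(marker_genes),
       n_with_element = length(covered),
       fraction = if (length(marker_genes)) length(covered) / length(marker_genes) else 0,
       n_elements = nrow(el))
}

#' Full cCRE pipeline
#'
#' Merge peaks, filter by whitelisted chromatin states, restrict the TSS
#' table to expressed genes, assign nearest TSSs, categorize distances and
#' attribute cell types.
#'
#' @param peak_sets List of DHS peak data.frames.
#' @param segmentations Classified segmentation(s) (with \code{state_class})
#'   or raw segmentation(s) with a \code{state} column, classified with the
#'   default map.
#' @param tss TSS table; its \code{expressed} flag is replaced when
#'   \code{bulk}/\code{cells} evidence is given.
#' @param exclusive_markers Named vector gene -> cell type/group.
#' @param bulk,cells Optional expression evidence for
#'   \code{\link{expressed_gene_filter}}.
#' @return List with \code{ccres} (all retained elements, categorized) and
#'   \code{celltype_elements} (the \code{candidate_elements} table).
#' @export
call_celltype_elements <- function(peak_sets, segmentations, tss,
                                   exclusive_markers, bulk = NULL, cells = NULL) {
  if (is.data.frame(segmentations)) segmentations <- list(segmentations)
  segmentations <- lapply(segmentations, function(s) {
    if (!"state_class" %in% names(s)) classify_states(s) else s
  })
  merged <- merge_peaks(peak_sets)
  kept <- filter_peaks_by_state(merged, segmentations)
  if (!is.null(bulk) || !is.null(cells)) {
    expressed <- expressed_gene_filter(bulk, cells)
    tss$expressed <- tss$gene_id %in% expressed
  } else if (!"expressed" %in% names(tss)) {
    tss$expressed <- TRUE
  }
  assigned <- assign_nearest_tss(kept, tss)
  assigned$category <- categorize_distance(assigned$distance)
  list(ccres = assigned,
       celltype_elements = derive_celltype_elements(assigned, exclusive_markers))
}
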