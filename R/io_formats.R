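## Readers and writers for the external formats the pipeline touches.
## Convention everywhere: BED/bedGraph/TSS coordinates are 0-based half-open,
## asserted at the boundary on both read and write.

#' Read a BED file of genomic intervals
#'
#' Parses BED3+ into a data.frame of 0-based half-open intervals. Optional
#' columns 4-6 are kept as \code{name}, \code{score}, \code{strand}; a
#' numeric 4th column (as in chromatin-state segmentations) is exposed as
#' \code{state}.
#'
#' @param path Path to a tab-separated BED file.
#' @return A data.frame with columns \code{chrom}, \code{start}, \code{end}
#'   and any optional columns present, rows in input order.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t200", bed)
#' read_bed(bed)
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stopf("BED file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(data.frame(chrom = character(), start = integer(), end = integer()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stopf("BED parse error at line %d: fewer than 3 tab-separated columns",
          which(nf < 3L)[1])
  }
  ncol_use <- min(nf)
  get <- function(i) vapply(fields, `[[`, character(1), i)
  start <- suppressWarnings(as.integer(get(2)))
  end <- suppressWarnings(as.integer(get(3)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) stopf("BED parse error at line %d: non-integer coordinate", bad[1])
  df <- data.frame(chrom = get(1), start = start, end = end,
                   stringsAsFactors = FALSE)
  check_intervals(df$chrom, df$start, df$end, context = basename(path))
  if (ncol_use >= 4L) {
    col4 <- get(4)
    num4 <- suppressWarnings(as.numeric(col4))
    if (!anyNA(num4)) df$state <- as.integer(num4) else df$name <- col4
  }
  if (ncol_use >= 5L) df$score <- suppressWarnings(as.numeric(get(5)))
  if (ncol_use >= 6L) {
    strand <- get(6)
    if (!all(strand %in% c("+", "-", "."))) stopf("invalid strand field in %s", path)
    df$strand <- strand
  }
  df
}

#' Write intervals to a BED file
#'
#' @param df data.frame with \code{chrom}, \code{start}, \code{end} and
#'   optional \code{name}/\code{state}, \code{score}, \code{strand} columns.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_bed <- function(df, path) {
  check_intervals(df$chrom, df$start, df$end, context = "write_bed")
  cols <- list(df$chrom, df$start, df$end)
  extra <- intersect(c("state", "name", "score", "strand"), names(df))
  # standard BED order: name/state, score, strand
  for (nm in c("state", "name")) if (nm %in% extra) cols <- c(cols, list(df[[nm]]))
  if ("score" %in% extra) cols <- c(cols, list(df$score))
  if ("strand" %in% extra) cols <- c(cols, list(df$strand))
  lines <- do.call(paste, c(cols, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a bedGraph file into a dense binned signal track
#'
#' Intervals must align to a fixed bin grid of \code{bin_width}; an interval
#' spanning several bins assigns its value to each covered bin. Bins absent
#' from the file are zero.
#'
#' @param path bedGraph path (chrom, start, end, value).
#' @param bin_width Bin width in bp.
#' @param chrom_lengths Optional named vector of chromosome lengths in bp;
#'   when absent each chromosome ends at the last covered bin.
#' @return A \code{signal_track}: list with \code{bins} (named list of
#'   per-chromosome numeric vectors) and \code{bin_width}.
#' @export
read_bedgraph <- function(path, bin_width, chrom_lengths = NULL) {
  if (!file.exists(path)) stopf("bedGraph file not found: %s", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "value"),
                          colClasses = c("character", "integer", "integer", "numeric"))
  check_intervals(df$chrom, df$start, df$end, context = basename(path))
  mis <- which(df$start %% bin_width != 0L | df$end %% bin_width != 0L)
  if (length(mis)) {
    stopf("bedGraph interval not aligned to %d-bp bin grid: %s:%d-%d",
          bin_width, df$chrom[mis[1]], df$start[mis[1]], df$end[mis[1]])
  }
  chroms <- unique(df$chrom)
  bins <- lapply(chroms, function(ch) {
    sub <- df[df$chrom == ch, , drop = FALSE]
    len <- if (!is.null(chrom_lengths)) {
      if (is.na(chrom_lengths[ch])) stopf("no length for chromosome %s", ch)
      chrom_lengths[[ch]]
    } else max(sub$end)
    n <- len %/% bin_width
    v <- numeric(n)
    b0 <- sub$start %/% bin_width
    b1 <- sub$end %/% bin_width
    for (i in seq_len(nrow(sub))) v[(b0[i] + 1L):b1[i]] <- sub$value[i]
    v
  })
  names(bins) <- chroms
  signal_track(bins, bin_width)
}

#' Construct a signal track
#'
#' @param bins Named list of per-chromosome numeric bin vectors.
#' @param bin_width Bin width in bp.
#' @param sample_id,mark,role Optional identifying metadata; \code{role} is
#'   \code{"signal"} or \code{"input"}.
#' @return A \code{signal_track} object.
#' @export
signal_track <- function(bins, bin_width, sample_id = NA_character_,
                         mark = NA_character_, role = "signal") {
  stopifnot(is.list(bins), !is.null(names(bins)), bin_width >= 1)
  if (any(vapply(bins, function(v) any(v < 0), logical(1)))) {
    stopf("signal track values must be >= 0")
  }
  structure(list(bins = bins, bin_width = as.integer(bin_width),
                 sample_id = sample_id, mark = mark, role = role),
            class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  cat(sprintf("signal_track: %d chromosome(s), %d bp bins, %d bins total\n",
              length(x$bins), x$bin_width, sum(lengths(x$bins))))
  invisible(x)
}

#' Write a signal track as bedGraph
#'
#' Runs of equal-valued adjacent bins are written as single intervals, so the
#' file round-trips losslessly through \code{\link{read_bedgraph}}.
#'
#' @param track A \code{signal_track}.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_bedgraph <- function(track, path) {
  bw <- track$bin_width
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (ch in names(track$bins)) {
    v <- track$bins[[ch]]
    if (!length(v)) next
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- c(0L, ends[-length(ends)])
    keep <- r$values != 0 | ends == length(v)  # keep final run so length survives
    lines <- sprintf("%s\t%d\t%d\t%s", ch, starts[keep] * bw, ends[keep] * bw,
                     format(r$values[keep], trim = TRUE, scientific = FALSE, digits = 15))
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read an expression or cell matrix from TSV
#'
#' Rows are genes and columns are samples (bulk convention). The first column
#' holds gene ids; the header holds sample ids. Duplicate ids are an error.
#'
#' @param path TSV path.
#' @return Numeric matrix with gene rownames and sample colnames.
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) stopf("matrix file not found: %s", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          row.names = NULL, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) stopf("duplicate gene id in %s: %s", path,
                                ids[duplicated(ids)][1])
  if (anyDuplicated(names(df)[-1])) stopf("duplicate sample id in %s", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- ids
  storage.mode(m) <- "double"
  m
}

#' Write a matrix as TSV (genes in rows, first column \code{gene_id})
#' @param m Numeric matrix with rownames and colnames.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_matrix <- function(m, path) {
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genome FASTA
#' @param path FASTA path.
#' @return A \code{Biostrings::DNAStringSet} named by chromosome.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stopf("FASTA file not found: %s", path)
  Biostrings::readDNAStringSet(path)
}

#' Write a genome FASTA
#' @param genome A \code{DNAStringSet} (or named character vector).
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_fasta <- function(genome, path) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Read a TSS table
#'
#' Tab-separated with header \code{gene_id, chrom, tss, strand[, expressed]};
#' TSS positions are 0-based.
#'
#' @param path TSV path.
#' @return data.frame with one row per gene.
#' @export
read_tss_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "tss", "strand")
  if (!all(need %in% names(df))) {
    stopf("TSS table %s must have columns %s", path, paste(need, collapse = ", "))
  }
  if (anyDuplicated(df$gene_id)) stopf("duplicate gene_id in TSS table %s", path)
  if (any(df$tss < 0)) stopf("negative TSS position in %s", path)
  if (!all(df$strand %in% c("+", "-"))) stopf("TSS strand must be + or - in %s", path)
  if ("expressed" %in% names(df)) df$expressed <- as.logical(df$expressed)
  df
}

#' Write a TSS table
#' @param tss data.frame as returned by \code{\link{read_tss_table}}.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_tss_table <- function(tss, path) {
  utils::write.table(tss, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read position weight matrices in MEME format
#'
#' Parses the minimal MEME motif format (MOTIF blocks with letter-probability
#' matrices over ACGT). Columns whose probabilities sum to 1 within
#' \code{tol} are renormalized; a larger deviation is an error, since it
#' usually signals a corrupt file rather than rounding.
#'
#' @param path MEME-format file.
#' @param tol Renormalization tolerance on column sums (default 1e-3).
#' @return List of PWMs; each a list with \code{id}, \code{mat} (4 x L matrix,
#'   rows A,C,G,T) and \code{source}.
#' @export
read_meme_motifs <- function(path, tol = 1e-3) {
  if (!file.exists(path)) stopf("MEME file not found: %s", path)
  lines <- readLines(path)
  starts <- grep("^MOTIF\\b", lines)
  if (!length(starts)) stopf("no MOTIF blocks in %s", path)
  motifs <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    id <- strsplit(trimws(lines[starts[k]]), "\\s+")[[1]][2]
    i <- starts[k] + 1L
    while (i <= length(lines) && !grepl("letter-probability", lines[i])) i <- i + 1L
    if (i > length(lines)) stopf("motif %s: missing letter-probability matrix", id)
    rows <- list()
    j <- i + 1L
    while (j <= length(lines) && grepl("^\\s*[0-9.eE+-]", lines[j])) {
      rows[[length(rows) + 1L]] <- as.numeric(strsplit(trimws(lines[j]), "\\s+")[[1]])
      j <- j + 1L
    }
    if (length(rows) < 4L) stopf("motif %s: matrix shorter than 4 positions", id)
    mat <- t(do.call(rbind, rows))  # 4 x L, rows A C G T
    if (nrow(mat) != 4L) stopf("motif %s: expected 4 letter columns", id)
    rownames(mat) <- c("A", "C", "G", "T")
    sums <- colSums(mat)
    off <- abs(sums - 1)
    if (any(off > tol)) {
      stopf("motif %s: column %d probabilities sum to %.4f (tolerance %g)",
            id, which(off > tol)[1], sums[which(off > tol)[1]], tol)
    }
    mat <- sweep(mat, 2, sums, "/")
    motifs[[k]] <- list(id = id, mat = mat,
                        source = if (id == toupper(id)) "human" else "mouse")
  }
  names(motifs) <- vapply(motifs, `[[`, character(1), "id")
  motifs
}

#' Write motifs in minimal MEME format
#' @param motifs List of PWMs as from \code{\link{read_meme_motifs}}.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_meme_motifs <- function(motifs, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", ""), con)
  for (m in motifs) {
    writeLines(sprintf("MOTIF %s", m$id), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d", ncol(m$mat)), con)
    writeLines(apply(m$mat, 2, function(p) paste(format(p, digits = 6), collapse = " ")), con)
    writeLines("", con)
  }
  invisible(path)
}
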