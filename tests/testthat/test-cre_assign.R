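test_that("state classification follows the published whitelists", {
  seg <- data.frame(chrom = "c1", start = (0:5) * 100, end = (1:6) * 100,
                    state = c(14L, 8L, 26L, 1L, 30L, 13L))
  cls <- classify_states(seg)
  expect_equal(cls$state_class,
               c("active", "poised", "bivalent", "other", "active", "poised"))
  # full whitelists
  cm <- default_state_classes()
  expect_setequal(cm$active, c(14, 19, 20, 21, 23, 24, 25, 27, 28, 30, 31, 32))
  expect_setequal(cm$poised, c(8, 13))
  expect_setequal(cm$bivalent, c(26, 29))
  expect_error(classify_states(seg, class_map = list(active = 14L),
                               strict = TRUE), "no class")
})

test_that("peak merging coalesces overlapping and bookended intervals and
           matches a coverage-union oracle", {
  a <- data.frame(chrom = "c1", start = c(100L, 150L), end = c(200L, 300L))
  expect_equal(merge_peaks(a), data.frame(chrom = "c1", start = 100L, end = 300L))
  b <- data.frame(chrom = "c1", start = c(100L, 200L), end = c(200L, 300L))
  expect_equal(merge_peaks(b), data.frame(chrom = "c1", start = 100L, end = 300L))
  expect_error(merge_peaks(a, chrom_whitelist = "c2"), "unknown chromosome")

  for (s in 1:3) {
    set.seed(400 + s)
    n <- 500
    df <- data.frame(chrom = sample(c("c1", "c2"), n, replace = TRUE),
                     start = sample.int(10000, n, replace = TRUE) - 1L)
    df$end <- df$start + sample.int(80, n, replace = TRUE)
    got <- merge_peaks(df)
    want <- oracle_merge(df)
    expect_equal(got, want)
  }
})

test_that("state filtering keeps whitelisted overlaps with the documented
           class precedence", {
  seg <- classify_states(data.frame(
    chrom = "c1", start = c(0L, 1000L, 2000L, 3000L),
    end = c(1000L, 2000L, 3000L, 4000L), state = c(14L, 1L, 8L, 26L)))
  peaks <- data.frame(chrom = "c1",
                      start = c(100L, 1100L, 2100L, 950L, 2950L),
                      end = c(300L, 1300L, 2300L, 1050L, 3050L))
  out <- filter_peaks_by_state(peaks, seg)
  # peak 2 overlaps only state 1 -> dropped
  expect_equal(out$start, c(100L, 2100L, 950L, 2950L))
  expect_equal(out$state_class, c("active", "poised", "active", "bivalent"))
  # peak 4 spans active+other -> active; peak 5 spans poised+bivalent -> bivalent

  # interval-intersection oracle on random fixtures
  set.seed(77)
  rp <- data.frame(chrom = "c1", start = sample.int(4000, 200) - 1L)
  rp$end <- rp$start + sample.int(60, 200, replace = TRUE)
  got <- filter_peaks_by_state(rp, seg)
  overlaps <- function(p, q) p$start < q$end & p$end > q$start
  wl <- seg[seg$state_class != "other", ]
  keep <- vapply(seq_len(nrow(rp)), function(i)
    any(overlaps(rp[i, ], wl)), logical(1))
  expect_equal(got[c("chrom", "start", "end")],
               rp[keep, c("chrom", "start", "end")], ignore_attr = TRUE)
})

test_that("expression filter ORs bulk abundance and single-cell detection
           with strict thresholds", {
  bulk <- rbind(g1 = c(0.05, 0.08), g2 = c(0.2, 0), g3 = c(0.1, 0.1))
  colnames(bulk) <- c("s1", "s2")
  cells <- matrix(0, 6, 3, dimnames = list(paste0("c", 1:6),
                                           c("g1", "g2", "g3")))
  cells[1:5, "g1"] <- 1  # detected in 5 cells: "more than four" -> expressed
  cells[1:4, "g3"] <- 1  # 4 cells and bulk max exactly 0.1 -> not expressed
  expect_equal(expressed_gene_filter(bulk, cells), c("g1", "g2"))

  set.seed(5)
  b2 <- matrix(rexp(60, 5), 20, 3,
               dimnames = list(sprintf("g%02d", 1:20), paste0("s", 1:3)))
  c2 <- matrix(rbinom(200, 1, 0.3), 10, 20,
               dimnames = list(paste0("c", 1:10), rownames(b2)))
  want <- sort(rownames(b2)[apply(b2, 1, max) > 0.1 | colSums(c2 > 0) > 4])
  expect_equal(expressed_gene_filter(b2, c2), want)
})

test_that("nearest-TSS assignment uses edge distance, prefers expressed
           genes, breaks ties lexicographically, and matches an exhaustive
           scan", {
  tss <- data.frame(gene_id = c("gA", "gB", "gC"), chrom = "c1",
                    tss = c(10000L, 12000L, 500L), strand = "+",
                    expressed = c(TRUE, TRUE, FALSE), stringsAsFactors = FALSE)
  peaks <- data.frame(chrom = "c1", start = c(9900L, 9500L, 10995L),
                      end = c(9950L, 10500L, 11005L))
  out <- assign_nearest_tss(peaks, tss)
  expect_equal(out$distance, c(50L, 0L, 995L))   # edge distance; inside -> 0
  expect_equal(out$assigned_gene, c("gA", "gA", "gA"))  # exact tie -> gA

  # unexpressed gC never wins even when closest
  p2 <- data.frame(chrom = "c1", start = 480L, end = 520L)
  expect_equal(assign_nearest_tss(p2, tss)$assigned_gene, "gA")

  expect_warning(
    assign_nearest_tss(data.frame(chrom = "c9", start = 1L, end = 5L), tss),
    "unassigned")

  for (s in 1:3) {
    set.seed(500 + s)
    n <- 400
    tt <- data.frame(gene_id = sprintf("g%03d", sample(1000, 300)),
                     chrom = sample(c("c1", "c2"), 300, replace = TRUE),
                     tss = sample.int(50000, 300, replace = TRUE),
                     strand = "+", stringsAsFactors = FALSE)
    pk <- data.frame(chrom = sample(c("c1", "c2"), n, replace = TRUE),
                     start = sample.int(49000, n, replace = TRUE))
    pk$end <- pk$start + sample.int(500, n, replace = TRUE)
    got <- assign_nearest_tss(pk, tt)
    want <- oracle_nearest(pk, tt)
    expect_equal(got$assigned_gene, want$gene)
    expect_equal(got$distance, want$distance)
  }
})

test_that("distance categories implement the boundary-inclusive piecewise rule", {
  expect_equal(categorize_distance(c(200, 201, 2000, 2001)),
               c("proximal", "middle", "middle", "distal"))
  d <- 0:3000
  want <- ifelse(d <= 200, "proximal", ifelse(d <= 2000, "middle", "distal"))
  expect_equal(categorize_distance(d), want)
  expect_error(categorize_distance(-1), ">= 0")
})

test_that("cell-type attribution keeps only exclusive-marker genes", {
  el <- data.frame(chrom = "c1", start = c(0L, 500L), end = c(100L, 600L),
                   assigned_gene = c("mk1", "other"), distance = c(50L, 30L),
                   state_class = c("active", "active"),
                   stringsAsFactors = FALSE)
  ex <- c(mk1 = "Muscle")
  ct <- derive_celltype_elements(el, ex)
  expect_equal(nrow(ct), 1)
  expect_equal(ct$cell_type, "Muscle")
  expect_equal(ct$category, "proximal")

  cov <- coverage_stats(ct, c("mk1", "mk2"))
  expect_equal(cov$fraction, 0.5)
  expect_equal(coverage_stats(ct[0, ], c("mk1", "mk2"))$fraction, 0)
})

test_that("the full pipeline recovers every planted element and rejects all
           decoys across seeds", {
  for (s in 1:3) {
    epi <- generate_epigenome(synth_config(seed = s))
    res <- call_celltype_elements(epi$peaks, epi$segmentation, epi$tss,
                                  epi$exclusive_markers)
    tr <- epi$truth$planted_elements
    ce <- res$celltype_elements
    want <- element_key(tr$chrom, tr$start, tr$end, tr$gene, tr$category,
                        tr$state_class)
    got <- element_key(ce$chrom, ce$start, ce$end, ce$assigned_gene,
                       ce$category, ce$state_class)
    expect_equal(mean(want %in% got), 1)  # recall
    expect_equal(mean(got %in% want), 1)  # precision
    expect_equal(unname(epi$exclusive_markers[ce$assigned_gene]), ce$cell_type)
    # no decoy interval survives
    dk <- paste(epi$truth$decoy_peaks$chrom, epi$truth$decoy_peaks$start)
    expect_length(intersect(paste(ce$chrom, ce$start), dk), 0)
    # every emitted element overlaps a whitelisted state and an expressed gene
    expect_true(all(res$ccres$state_class %in% c("active", "poised", "bivalent")))
    expect_true(all(ce$assigned_gene %in% epi$tss$gene_id[epi$tss$expressed]))
  }
})
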