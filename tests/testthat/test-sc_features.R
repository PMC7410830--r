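make_cells <- function(v, platform = "tag", total_mapped = NULL) {
  cell_matrix(v, platform = platform, total_mapped = total_mapped)
}

test_that("full-length QC applies inclusive cell and gene thresholds", {
  set.seed(2)
  v <- matrix(rexp(30 * 20, rate = 0.05), 30, 20,
              dimnames = list(sprintf("c%02d", 1:30), sprintf("g%02d", 1:20)))
  tot <- rep(150000, 30)
  tot[1] <- 99999  # one read short -> removed
  cm <- make_cells(v, "full_length", total_mapped = tot)
  out <- qc_filter_full_length(cm, min_reads = 1e5, min_genes = 5, fpkm_cut = 10,
                               min_cells = 5)
  expect_false("c01" %in% rownames(out$values))

  # gene at exactly 10 FPKM in exactly 5 cells is retained
  v2 <- matrix(20, 10, 6, dimnames = list(paste0("c", 1:10), paste0("g", 1:6)))
  v2[, "g6"] <- c(rep(10, 5), rep(0, 5))
  cm2 <- make_cells(v2, "full_length", total_mapped = rep(2e5, 10))
  out2 <- qc_filter_full_length(cm2, min_genes = 3, min_cells = 5)
  expect_true("g6" %in% colnames(out2$values))
  out3 <- qc_filter_full_length(cm2, min_genes = 3, min_cells = 6)
  expect_false("g6" %in% colnames(out3$values))

  # brute-force oracle on a random fixture
  keep_cell <- tot >= 1e5 & rowSums(v >= 10) >= 5
  vk <- v[keep_cell, ]
  keep_gene <- colSums(vk > 0) >= 5 & apply(vk, 2, max) >= 10
  expect_equal(dimnames(out$values),
               list(rownames(v)[keep_cell], colnames(v)[keep_gene]))
})

test_that("tag QC removes low-complexity, high-mito and over-complex cells,
           then sparse genes", {
  sc <- generate_sc_counts(synth_config(seed = 1))
  out <- qc_filter_tag(sc$matrix, min_genes = 30)
  expect_length(intersect(sc$truth$qc_fail_cells, rownames(out$values)), 0)

  # brute-force per-cell/per-gene reference
  v <- sc$matrix$values
  qc <- sc$matrix$qc
  ok_cell <- qc$n_genes_detected >= 30 & qc$n_genes_detected <= 8000 &
    qc$mito_fraction <= 0.20
  vk <- v[ok_cell, ]
  ok_gene <- colSums(vk > 0) >= 0.001 * nrow(vk)
  expect_equal(dimnames(out$values),
               list(rownames(v)[ok_cell], colnames(v)[ok_gene]))

  # explicit mito boundary
  v3 <- matrix(10, 5, 10, dimnames = list(paste0("c", 1:5),
                                          c(paste0("g", 1:8), "mt-1", "mt-2")))
  v3[1, c("mt-1", "mt-2")] <- c(20, 10)  # mito fraction 30/100 = 0.3
  cm3 <- cell_matrix(v3, platform = "tag")
  out3 <- qc_filter_tag(cm3, min_genes = 2)
  expect_false("c1" %in% rownames(out3$values))
})

test_that("tag normalization is ln(1e4 * x / libsize + 1), per cell", {
  v <- rbind(c1 = c(1, 3), c2 = c(10, 0))
  colnames(v) <- c("gA", "gB")
  out <- normalize_tag(v)
  expect_equal(out["c1", ], c(gA = log(2500 + 1), gB = log(7500 + 1)))
  expect_equal(out["c2", "gB"], 0)  # zero count -> ln(1) = 0
  # scalar-loop oracle
  set.seed(4)
  m <- matrix(rpois(60, 4) + 1, 6, 10,
              dimnames = list(paste0("c", 1:6), paste0("g", 1:10)))
  norm <- normalize_tag(m)
  for (i in 1:6) for (j in 1:10) {
    expect_equal(norm[i, j], log(1e4 * m[i, j] / sum(m[i, ]) + 1))
  }
  m[1, ] <- 0
  expect_error(normalize_tag(m), "zero-sum")
})

test_that("dispersion ranking is variance/mean with n-1 denominator", {
  v <- cbind(gA = c(0, 4), gB = c(2, 2), gC = c(5, 1))
  rownames(v) <- c("c1", "c2")
  dr <- dispersion_rank(v)
  expect_equal(dr$dispersion[dr$gene_id == "gA"], 4)  # var 8 / mean 2
  expect_equal(dr$dispersion[dr$gene_id == "gB"], 0)  # constant -> last
  expect_equal(dr$gene_id[3], "gB")
  expect_warning(dispersion_rank(v, top_n = 10), "exceeds")

  # brute-force oracle
  set.seed(6)
  m <- matrix(rpois(500, 3), 50, 10,
              dimnames = list(sprintf("c%02d", 1:50), sprintf("g%02d", 1:10)))
  dr2 <- dispersion_rank(m)
  disp <- apply(m, 2, var) / colMeans(m)
  disp <- disp[colMeans(m) > 0]
  expect_equal(dr2$gene_id, names(sort(disp, decreasing = TRUE)))
  expect_equal(dr2$dispersion, unname(sort(disp, decreasing = TRUE)))
})

test_that("tight-cluster selection keeps planted co-expressed genes and sheds
           independent noise", {
  # 3 perfectly correlated planted genes among 50 independent noise genes
  set.seed(21)
  n <- 500
  z <- rpois(n, 5)
  noise <- matrix(rpois(n * 50, 2), n, 50,
                  dimnames = list(NULL, sprintf("noise%02d", 1:50)))
  v <- cbind(planted1 = z, planted2 = z, planted3 = z, noise)
  rownames(v) <- sprintf("c%03d", seq_len(n))
  fs <- select_tight_cluster_features(normalize_tag(v + 1), top_n = 53)
  expect_setequal(fs$gene_id, c("planted1", "planted2", "planted3"))

  # all-independent genes -> at most 1% retained
  fs0 <- select_tight_cluster_features(normalize_tag(noise + 1), top_n = 50)
  expect_lte(nrow(fs0), 0.01 * 50)

  # output is a subset of the dispersion pre-selection
  sc <- generate_sc_counts(synth_config(seed = 3))
  nm <- normalize_tag(qc_filter_tag(sc$matrix, min_genes = 30))
  top <- dispersion_rank(nm, top_n = 200)$gene_id
  fs2 <- select_tight_cluster_features(nm, top_n = 200)
  expect_true(all(fs2$gene_id %in% top))
})

test_that("the internal rank-sum test matches wilcox.test with normal
           approximation and tie correction", {
  set.seed(30)
  m <- matrix(rpois(400, 2), 40, 10,
              dimnames = list(paste0("c", 1:40), paste0("g", 1:10)))
  grp <- rep(c(TRUE, FALSE), each = 20)
  p <- devdecomp:::wilcox_onevsrest(m, grp, colnames(m))
  for (j in 1:10) {
    ref <- suppressWarnings(
      wilcox.test(m[grp, j], m[!grp, j], exact = FALSE, correct = FALSE))
    expect_equal(p[j], ref$p.value, tolerance = 1e-12)
  }
})

test_that("marker calling detects planted markers and filters by detection
           fractions", {
  sc <- generate_sc_counts(synth_config(seed = 1))
  cm <- qc_filter_tag(sc$matrix, min_genes = 30)
  nm <- normalize_tag(cm)
  labels <- sc$truth$celltype[rownames(nm)]
  mk <- find_markers(nm, labels, min_diff_pct = 0.4)
  truth_keys <- paste(sc$truth$planted_markers, names(sc$truth$planted_markers))
  called_keys <- paste(mk$cluster, mk$gene)
  sens <- mean(truth_keys %in% called_keys)
  fdr <- if (length(called_keys)) mean(!(called_keys %in% truth_keys)) else 0
  expect_gte(sens, 0.95)
  expect_lte(fdr, 0.05)
  expect_true(all(abs(mk$pct_in - mk$pct_out) >= 0.4))
  expect_true(all(pmax(mk$pct_in, mk$pct_out) >= 0.25))

  # pct filter excludes low-detection genes regardless of effect
  v <- matrix(0, 60, 2, dimnames = list(paste0("c", 1:60), c("gLow", "gRef")))
  v[1:6, "gLow"] <- 5    # pct 0.2 in group1, 0 in group2 -> below min_pct
  v[, "gRef"] <- rpois(60, 5)
  lab <- rep(c("A", "B"), each = 30)
  mk2 <- find_markers(normalize_tag(v + 1), lab, min_pct = 0.25,
                      min_diff_pct = 0.2, max_p_adj = 1)
  expect_false("gLow" %in% mk2$gene)
  expect_error(find_markers(nm, rep("one", nrow(nm))), "2 clusters")
})

test_that("identical groups yield near-uniform p values and few calls", {
  set.seed(17)
  v <- matrix(rpois(400 * 100, 3), 400, 100,
              dimnames = list(sprintf("c%03d", 1:400), sprintf("g%03d", 1:100)))
  lab <- rep(c("A", "B"), each = 200)
  mk <- find_markers(normalize_tag(v), lab, min_pct = 0, min_diff_pct = 0,
                     max_p_adj = 0.05)
  expect_lte(nrow(mk), 0.05 * 100)
})

test_that("exclusive markers cross-intersect cell types and declared groups", {
  mk <- data.frame(
    cluster = c("A", "B", "A", "B", "A", "C"),
    gene = c("g1", "g2", "g3", "g3", "g4", "g4"),
    stringsAsFactors = FALSE)
  groups <- list("A+B" = c("A", "B"))
  ex <- derive_exclusive_markers(mk, groups)
  expect_equal(ex[["g1"]], "A")       # single type
  expect_equal(ex[["g2"]], "B")
  expect_equal(ex[["g3"]], "A+B")     # declared group
  expect_false("g4" %in% names(ex))   # A+C has no declared group -> dropped
  expect_error(
    derive_exclusive_markers(mk, list(g1 = c("A", "B"), g2 = c("B", "A"))),
    "ambiguous")
})
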