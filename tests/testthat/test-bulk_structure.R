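make_expr <- function(m, tissues = NULL, stages = NULL) {
  n <- ncol(m)
  meta <- data.frame(
    sample = colnames(m),
    tissue = tissues %||% rep("T1", n),
    stage = stages %||% paste0("E", seq_len(n)),
    sex = rep("mixed", n), batch = rep("b1", n),
    stringsAsFactors = FALSE)
  expr_matrix(m, meta)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("log_transform applies log2(x + 0.1) elementwise", {
  expect_equal(log_transform(matrix(0)), matrix(log2(0.1)))
  expect_equal(log_transform(matrix(0.9)), matrix(0))
  set.seed(1)
  m <- matrix(rexp(30), 5, 6)
  out <- log_transform(m)
  for (i in seq_len(5)) for (j in seq_len(6)) {
    expect_equal(out[i, j], log2(m[i, j] + 0.1))
  }
  expect_error(log_transform(matrix(-1)), "negative")
})

test_that("prefilter_genes keeps genes with >= 10 reads somewhere, drops tRNA", {
  m <- matrix(1, 4, 3, dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
  rc <- matrix(c(9, 9, 9,    # g1: removed
                 9, 10, 0,   # g2: retained
                 50, 0, 0,   # g3: retained but tRNA
                 0, 0, 0),   # g4: removed
               4, 3, byrow = TRUE, dimnames = dimnames(m))
  em <- make_expr(m)
  em$biotype <- c("protein_coding", "protein_coding", "tRNA", "lincRNA")
  out <- prefilter_genes(em, rc)
  expect_equal(rownames(out$values), "g2")
  expect_error(prefilter_genes(em, NULL), "companion")

  # brute-force oracle on a random fixture
  set.seed(7)
  m2 <- matrix(rexp(200), 40, 5,
               dimnames = list(sprintf("r%02d", 1:40), paste0("s", 1:5)))
  rc2 <- matrix(rpois(200, 9), 40, 5, dimnames = dimnames(m2))
  keep <- vapply(seq_len(40), function(i) any(rc2[i, ] >= 10), logical(1))
  out2 <- prefilter_genes(make_expr(m2), rc2)
  expect_equal(rownames(out2$values), rownames(m2)[keep])
})

test_that("dynamic partition uses an inclusive tenfold max/min ratio with 0.1 floor", {
  m <- rbind(a = c(1.0, 10.0, 3.0),   # ratio exactly 10 -> dynamic
             b = c(2.0, 19.9, 3.0),   # 9.95 -> ubiquitous
             c = c(0.0, 0.5, 0.2))    # min clamped to 0.1 -> ratio 5
  colnames(m) <- paste0("s", 1:3)
  p <- partition_dynamic_genes(m)
  expect_equal(p$label, c("dynamic", "ubiquitous", "ubiquitous"))
  expect_equal(p$fold_ratio, c(10, 9.95, 5))
  expect_error(partition_dynamic_genes(m[, 1, drop = FALSE]), "2 samples")
})

test_that("partition recovers planted truth and matches a brute-force scan", {
  for (s in c(1, 2)) {
    b <- generate_bulk_matrix(synth_config(seed = s))
    p <- partition_dynamic_genes(b$matrix)
    expect_equal(p$label == "dynamic",
                 unname(b$truth$planted_dynamic[p$gene_id]))
    # independent scalar scan
    v <- b$matrix$values
    ratio <- vapply(seq_len(nrow(v)), function(i)
      max(v[i, ]) / max(min(v[i, ]), 0.1), numeric(1))
    expect_equal(p$fold_ratio, ratio, tolerance = 1e-12)
    expect_equal(p$label == "dynamic", ratio >= 10)
  }
})

test_that("PCA: duplicated samples coincide, planted rank-1 axis dominates,
           loadings orthonormal, reconstruction exact", {
  set.seed(11)
  m <- matrix(rnorm(300), 30, 10,
              dimnames = list(sprintf("g%02d", 1:30), sprintf("s%02d", 1:10)))
  m[, 10] <- m[, 9]  # duplicate sample
  pca <- run_pca(m, n_pcs = 8)
  expect_equal(pca$scores[9, ], pca$scores[10, ], tolerance = 1e-8)
  # orthonormal loadings
  G <- crossprod(pca$loadings)
  expect_equal(G, diag(8), tolerance = 1e-8, ignore_attr = TRUE)
  # score columns z-scored
  expect_equal(colMeans(pca$scores), rep(0, 8), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(apply(pca$scores, 2, sd), rep(1, 8), tolerance = 1e-10,
               ignore_attr = TRUE)
  # sign convention: the largest-|loading| gene is positive
  for (j in 1:8) expect_gt(pca$loadings[which.max(abs(pca$loadings[, j])), j], 0)

  # planted rank-1 structure
  u <- rnorm(30); v <- rnorm(10)
  m1 <- 5 * outer(u, v) + matrix(rnorm(300, sd = 1e-3), 30, 10)
  dimnames(m1) <- dimnames(m)
  p1 <- run_pca(m1, n_pcs = 5)
  expect_gte(p1$var_explained[1], 0.99)

  # full-rank reconstruction within 1e-8 relative Frobenius
  pf <- run_pca(m, n_pcs = 10)
  recon <- pf$raw_scores %*% t(pf$loadings) +
    matrix(pf$center, 10, 30, byrow = TRUE)
  expect_lt(norm(recon - t(m), "F") / norm(t(m), "F"), 1e-8)

  expect_error(run_pca(m, n_pcs = 11), "exceeds")
})

test_that("top_loading_genes returns extreme, disjoint, tie-stable sets", {
  set.seed(3)
  m <- matrix(rnorm(200), 20, 10,
              dimnames = list(sprintf("g%02d", 1:20), sprintf("s%02d", 1:10)))
  m["g01", ] <- m["g01", ] + 8 * scale(seq_len(10))[, 1]  # planted driver
  pca <- run_pca(m, n_pcs = 5)
  tl <- top_loading_genes(pca, 1, k = 1)
  expect_equal(tl$positive, "g01")
  tl5 <- top_loading_genes(pca, 1, k = 5)
  expect_length(intersect(tl5$positive, tl5$negative), 0)
  expect_error(top_loading_genes(pca, 1, k = 100), "exceeds")

  # ties broken lexicographically
  pca2 <- pca
  pca2$loadings[, 2] <- rep(c(0.5, -0.5), each = 10)
  rownames(pca2$loadings) <- rownames(m)
  expect_equal(top_loading_genes(pca2, 2, k = 2)$positive, c("g01", "g02"))
})

test_that("gene clustering finds planted anti-correlated blocks and respects
           the clade-size floor", {
  set.seed(5)
  n_per <- 40
  base <- sin(seq(0, 3 * pi, length.out = 24))
  m <- rbind(
    matrix(rep(base, each = n_per), n_per) + matrix(rnorm(n_per * 24, sd = 0.1), n_per),
    matrix(rep(-base, each = n_per), n_per) + matrix(rnorm(n_per * 24, sd = 0.1), n_per))
  rownames(m) <- sprintf("g%03d", seq_len(2 * n_per))
  colnames(m) <- sprintf("s%02d", 1:24)
  cs <- cluster_genes(m, min_clade = 30)
  expect_length(cs$major_clusters, 2)
  sizes <- lengths(cs$major_clusters)
  expect_equal(sort(unname(sizes)), c(40, 40))
  found <- lapply(cs$major_clusters, sort)
  expect_true(list(sort(rownames(m)[1:40])) %in% found ||
                identical(found[[1]], sort(rownames(m)[1:40])) ||
                identical(found[[2]], sort(rownames(m)[1:40])))
  # leaf conservation
  expect_equal(sum(sizes) + sum(is.na(cs$membership)), nrow(m))

  # a 25-gene block is below the floor
  cs25 <- cluster_genes(m[1:25, ], min_clade = 30)
  expect_length(cs25$major_clusters, 0)

  # input-order invariance
  perm <- sample(nrow(m))
  cs2 <- cluster_genes(m[perm, ], min_clade = 30)
  expect_equal(lapply(cs2$major_clusters, sort), lapply(cs$major_clusters, sort))

  # constant gene handled with a warning
  m2 <- m[1:45, ]
  m2[45, ] <- 3
  expect_warning(cluster_genes(m2, min_clade = 30), "constant")
})

test_that("CCA recovers planted metadata axes and its gene loadings equal the
           explicit matrix product", {
  b <- generate_bulk_matrix(synth_config(seed = 2))
  ml <- log_transform(b$matrix)
  pca <- run_pca(ml, n_pcs = 20)

  cca <- run_cca(pca, b$matrix$meta, n_pcs = 20)
  expect_true(all(diff(cca$cor) <= 1e-12))
  expect_true(all(cca$cor >= 0 & cca$cor <= 1 + 1e-12))
  # explicit product oracle
  expect_equal(cca$gene_loadings,
               pca$loadings[, 1:20] %*% cca$pc_coef, tolerance = 1e-10,
               ignore_attr = TRUE)

  # metadata equal to PC1 scores -> first canonical correlation ~ 1
  self <- run_cca(pca, cbind(pc1copy = pca$scores[, 1]), n_pcs = 20)
  expect_gte(self$cor[1], 1 - 1e-8)

  # planted sex axis: sex-only CCA recovers the sex genes in top loadings
  ccs <- run_cca(pca, metadata_design(b$matrix$meta, "sex"), n_pcs = 20)
  expect_gte(ccs$cor[1], 0.9)
  top <- rownames(ccs$gene_loadings)[order(-abs(ccs$gene_loadings[, 1]))][1:5]
  expect_true(all(c("Xist", "Ddx3y") %in% top))

  # invariance to invertible linear re-coding of the design
  Y <- metadata_design(b$matrix$meta)
  set.seed(8)
  A <- matrix(rnorm(ncol(Y)^2), ncol(Y))
  cc1 <- run_cca(pca, Y, n_pcs = 20)
  cc2 <- run_cca(pca, Y %*% A, n_pcs = 20)
  expect_equal(cc1$cor, cc2$cor, tolerance = 1e-5)
})

test_that("sex inference follows the Xist/Ddx3y detection rule exactly", {
  m <- cbind(s1 = c(Xist = 5, Ddx3y = 0),
             s2 = c(Xist = 0, Ddx3y = 3),
             s3 = c(Xist = 4, Ddx3y = 2),
             s4 = c(Xist = 0.5, Ddx3y = 0))
  expect_equal(unname(infer_sex(m)), c("female", "male", "mixed", "unknown"))
  expect_error(infer_sex(m[1, , drop = FALSE]), "absent")

  b <- generate_bulk_matrix(synth_config(seed = 4))
  sx <- infer_sex(b$matrix)
  expect_equal(sx, b$truth$planted_sex[names(sx)])
})

test_that("ubiquitous stratification removes low expressors and splits the
           lowest-variance genes into equal thirds by mean", {
  # 3 eligible genes with means 1, 5, 9 (times above-threshold base)
  m <- rbind(lo = c(8, 8.4), mid = c(40, 42), hi = c(72, 75),
             dim1 = c(3.9, 3.9))  # log2(3.9 + 0.1) == 2 exactly -> removed
  colnames(m) <- c("s1", "s2")
  st <- stratify_ubiquitous(m, rownames(m), n = 3)
  expect_equal(st, list(high = "hi", medium = "mid", low = "lo"))

  # fewer eligible genes than n -> warn and use all
  expect_warning(stratify_ubiquitous(m, rownames(m), n = 100), "eligible")

  # sort-based oracle on a random fixture
  set.seed(13)
  mm <- matrix(exp(rnorm(600, 3, 0.2)), 100, 6,
               dimnames = list(sprintf("u%03d", 1:100), paste0("s", 1:6)))
  st2 <- stratify_ubiquitous(mm, rownames(mm), n = 60)
  ml <- log2(mm + 0.1)
  vr <- apply(ml, 1, var)
  chosen <- names(sort(vr))[1:60]
  mu <- sort(rowMeans(mm[chosen, ]), decreasing = TRUE)
  expect_equal(sort(st2$high), sort(names(mu)[1:20]))
  expect_equal(sort(st2$low), sort(names(mu)[41:60]))
  expect_equal(lengths(st2), c(high = 20L, medium = 20L, low = 20L))
})
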