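test_that("per_gene_de: identity, closed-form fold change, label swap", {
  set.seed(50)
  n <- 30
  # gene 1 identical across groups; gene 2 case mean ~3x control on the
  # de-logged scale with means large enough that the +1 pseudocount is
  # negligible
  g2_case <- log1p(rnorm(n, 3000, 1))
  g2_ctrl <- log1p(rnorm(n, 1000, 1))
  mat <- rbind(rep(c(1, 2), n), c(g2_case, g2_ctrl))
  nm <- nm_from_dense(mat)
  case <- nm$barcodes[1:n]
  ctrl <- nm$barcodes[(n + 1):(2 * n)]
  degs <- per_gene_de(nm, case, ctrl)
  i1 <- which(degs$gene == nm$gene_ids[1])
  i2 <- which(degs$gene == nm$gene_ids[2])
  expect_equal(degs$log2_fold_change[i1], 0, tolerance = 1e-9)
  expect_equal(degs$p_value[i1], 1)
  expect_equal(degs$log2_fold_change[i2], log2(3), tolerance = 0.01)
  expect_lt(degs$p_value[i2], 1e-6)
  expect_true(all(degs$adj_p_value >= degs$p_value - 1e-15))
  # swapping groups negates fold changes, keeps p-values
  swapped <- per_gene_de(nm, ctrl, case)
  expect_equal(swapped$log2_fold_change, -degs$log2_fold_change,
               tolerance = 1e-9)
  expect_equal(swapped$p_value, degs$p_value, tolerance = 1e-12)
})

test_that("per_gene_de null simulation: p<0.05 rate within binomial 99% bounds", {
  set.seed(61)
  n_genes <- 200; n_cells <- 100
  counts <- matrix(rnbinom(n_genes * 2 * n_cells, mu = 5, size = 2),
                   n_genes, 2 * n_cells)
  v <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "generalMatrix")
  m <- count_matrix(v, gene_ids = sprintf("g%03d", 1:n_genes),
                    barcodes = sprintf("c%03d", 1:(2 * n_cells)))
  nm <- log_normalize(m)
  degs <- per_gene_de(nm, m$barcodes[1:n_cells],
                      m$barcodes[(n_cells + 1):(2 * n_cells)],
                      min_frac_expressing = 0)
  rate <- mean(degs$p_value < 0.05)
  half <- 2.576 * sqrt(0.05 * 0.95 / nrow(degs))
  expect_gte(rate, 0.05 - half)
  expect_lte(rate, 0.05 + half)
})

test_that("count_significant equals a brute-force scan with strict thresholds", {
  tab <- data.frame(
    gene = paste0("g", 1:5),
    log2_fold_change = c(0.6, -0.7, 0.5, 2.0, 0.1),
    p_value = c(0.01, 0.2, 0.01, 0.04, 0.001),
    adj_p_value = c(0.05, 0.4, 0.05, 0.04, 0.01))
  # brute force: genes 1 and 4 pass (|lfc|>0.5 AND p<0.05)
  expect_equal(count_significant(tab), 2L)
  # |lfc| = 0.5 exactly is excluded (strict ">")
  expect_equal(count_significant(tab[3, ]), 0L)
  expect_equal(count_significant(tab[integer(0), ]), 0L)
  # adjusted mode
  expect_equal(count_significant(tab, use_adjusted = TRUE), 1L)
  # random tables vs independent row scan
  set.seed(9)
  for (i in 1:10) {
    rt <- data.frame(gene = paste0("g", 1:50),
                     log2_fold_change = rnorm(50),
                     p_value = runif(50))
    rt$adj_p_value <- pmin(1, rt$p_value * 2)
    expect_equal(count_significant(rt, 0.4, 0.1),
                 sum(abs(rt$log2_fold_change) > 0.4 & rt$p_value < 0.1))
  }
})

test_that("BH adjustment is monotone in p", {
  set.seed(10)
  nm <- nm_from_dense(matrix(abs(rnorm(60 * 40)), 60, 40))
  degs <- per_gene_de(nm, nm$barcodes[1:20], nm$barcodes[21:40],
                      min_frac_expressing = 0)
  o <- order(degs$p_value)
  expect_false(is.unsorted(degs$adj_p_value[o]))
})

test_that("deg_counts_per_cluster flags small clusters and handles one cluster", {
  set.seed(11)
  nm <- nm_from_dense(matrix(abs(rnorm(30 * 26)), 30, 26))
  ann <- data.frame(barcode = nm$barcodes, sample_id = "s",
                    condition = c(rep(c("case", "control"), each = 10),
                                  rep(c("case", "control"), 3)),
                    cluster = c(rep("big", 20), rep("tiny", 6)),
                    stringsAsFactors = FALSE)
  tab <- deg_counts_per_cluster(nm, ann, min_cells = 5)
  expect_equal(nrow(tab), 2)
  expect_true(tab$tested[tab$cluster == "big"])
  expect_false(tab$tested[tab$cluster == "tiny"])
  expect_true(is.na(tab$n_deg[tab$cluster == "tiny"]))
  # single-cluster input -> one-row table
  ann1 <- ann[ann$cluster == "big", ]
  expect_equal(nrow(deg_counts_per_cluster(nm, ann1)), 1)
})

test_that("gene-set activity: identity, null contrast, antisymmetry, planted signal", {
  # one gene, one cell: activity equals that value
  nm1 <- nm_from_dense(matrix(1.7, 1, 1), gene_ids = "TP53")
  ann1 <- data.frame(barcode = nm1$barcodes, sample_id = "s",
                     condition = "case", cluster = "X",
                     stringsAsFactors = FALSE)
  act1 <- geneset_activity(nm1, ann1, list(S = "TP53"), contrast = "clusters")
  expect_equal(act1$activity$mean_activity, 1.7)

  # two clusters with identical expression -> zero fold change; sets with
  # no matching gene are reported skipped
  block <- matrix(rep(c(0.5, 1.5), each = 6), 2, 6, byrow = FALSE)
  nm2 <- nm_from_dense(cbind(block, block), gene_ids = c("CD19", "MS4A1"))
  ann2 <- data.frame(barcode = nm2$barcodes, sample_id = "s",
                     condition = "case",
                     cluster = rep(c("c1", "c2"), each = 6),
                     stringsAsFactors = FALSE)
  act2 <- geneset_activity(nm2, ann2,
                           list(B = c("CD19", "MS4A1"), NONE = "ZZZ"),
                           contrast = "clusters")
  expect_identical(act2$skipped, "NONE")
  expect_equal(act2$contrast$log2_fold_change, c(0, 0), tolerance = 1e-12)
  # antisymmetry under swapping the contrasted groups
  i_ab <- act2$contrast$cluster_a == "c1"
  expect_equal(act2$contrast$log2_fold_change[i_ab],
               -act2$contrast$log2_fold_change[!i_ab], tolerance = 1e-12)

  # planted 2-fold (linear) up-shift of set genes in case cells of one
  # cluster: positive condition log fold change recovered
  set.seed(12)
  base <- matrix(abs(rnorm(10 * 160, 1)), 10, 160)
  base[1:3, 1:40] <- base[1:3, 1:40] * 2
  nm3 <- nm_from_dense(base)
  ann3 <- data.frame(barcode = nm3$barcodes, sample_id = "s",
                     condition = rep(c("case", "control"), each = 40, times = 2),
                     cluster = rep(c("up", "other"), each = 80),
                     stringsAsFactors = FALSE)
  act3 <- geneset_activity(nm3, ann3,
                           list(S = nm3$gene_symbols[1:3]),
                           contrast = "condition")
  lfc_up <- act3$contrast$log2_fold_change[act3$contrast$cluster == "up"]
  lfc_other <- act3$contrast$log2_fold_change[act3$contrast$cluster == "other"]
  expect_gt(lfc_up, 0.5)
  expect_lt(abs(lfc_other), 0.3)
})

test_that("proportion_shift matches the pooled two-proportion z hand computation", {
  ann <- data.frame(
    barcode = sprintf("b%03d", 1:200), sample_id = "s",
    condition = rep(c("case", "control"), each = 100),
    cluster = c(rep("X", 60), rep("Y", 40), rep("X", 40), rep("Y", 60)),
    stringsAsFactors = FALSE)
  tab <- proportion_shift(ann)
  x <- tab[tab$cluster == "X", ]
  # hand: p1=0.6, p2=0.4, pooled 0.5 -> z = 0.2/sqrt(0.5*0.5*0.02) = 2.8284
  expect_equal(x$prop_case, 0.6)
  expect_equal(x$prop_control, 0.4)
  expect_equal(x$z, 0.2 / sqrt(0.5 * 0.5 * 0.02), tolerance = 1e-12)
  expect_equal(x$p_value, 2 * pnorm(-2.8284271), tolerance = 1e-6)
  expect_equal(x$direction, "expanded_in_case")
  # proportions sum to 1 within each condition
  expect_equal(sum(tab$prop_case), 1, tolerance = 1e-12)
  expect_equal(sum(tab$prop_control), 1, tolerance = 1e-12)

  # identical composition -> p = 1 everywhere
  ann2 <- ann
  ann2$cluster <- rep(c(rep("X", 50), rep("Y", 50)), 2)
  expect_true(all(proportion_shift(ann2)$p_value == 1))

  # cluster absent from one condition: proportion 0, test defined
  ann3 <- ann
  ann3$cluster[1:5] <- "caseonly"
  tab3 <- proportion_shift(ann3)
  co <- tab3[tab3$cluster == "caseonly", ]
  expect_equal(co$prop_control, 0)
  expect_true(is.finite(co$p_value) && co$p_value > 0)
})
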