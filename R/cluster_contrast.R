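#' Per-gene differential expression between conditions
#'
#' Genes expressed (value > 0) in at least `min_frac_expressing` of either
#' group are tested. The log2 fold change is computed on de-logged
#' normalized means with a fixed pseudocount of 1:
#' `log2((mean_case + 1) / (mean_control + 1))`; the p-value is a per-gene
#' two-sided Wilcoxon rank-sum test on the log-normalized values, adjusted
#' by Benjamini-Hochberg over the tested genes.
#'
#' @param nm a [log_normalize()] result.
#' @param cells_case,cells_control barcode vectors (>= 3 cells each).
#' @param min_frac_expressing minimum expressing fraction in either group
#'   for a gene to be tested (default 0.1).
#' @return data.frame (class `deg_table`), one row per tested gene:
#'   `gene`, `log2_fold_change`, `p_value`, `adj_p_value`,
#'   `frac_case`, `frac_control`.
#' @export
per_gene_de <- function(nm, cells_case, cells_control,
                        min_frac_expressing = 0.1) {
  if (min_frac_expressing < 0 || min_frac_expressing >= 1)
    stop_validation("min_frac_expressing must be in [0, 1)")
  ic <- match(cells_case, nm$barcodes)
  ik <- match(cells_control, nm$barcodes)
  if (anyNA(ic) || anyNA(ik))
    stop_validation("some barcodes are absent from the normalized matrix")
  if (length(ic) < 3 || length(ik) < 3)
    stop_validation("both groups need at least 3 cells")
  X <- nm$values[, ic, drop = FALSE]
  Y <- nm$values[, ik, drop = FALSE]
  frac_x <- Matrix::rowSums(X > 0) / ncol(X)
  frac_y <- Matrix::rowSums(Y > 0) / ncol(Y)
  tested <- which(frac_x >= min_frac_expressing | frac_y >= min_frac_expressing)
  delog_mean <- function(M) {
    Me <- M
    if (length(Me@x)) Me@x <- expm1(Me@x)
    Matrix::rowSums(Me) / ncol(Me)
  }
  mx <- delog_mean(X)[tested]
  my <- delog_mean(Y)[tested]
  lfc <- log2((mx + 1) / (my + 1))
  Xd <- as.matrix(X[tested, , drop = FALSE])
  Yd <- as.matrix(Y[tested, , drop = FALSE])
  p <- vapply(seq_along(tested), function(i)
    wilcoxon_rank_sum(Xd[i, ], Yd[i, ]), numeric(1))
  out <- data.frame(gene = nm$gene_ids[tested],
                    log2_fold_change = lfc,
                    p_value = p,
                    adj_p_value = stats::p.adjust(p, method = "BH"),
                    frac_case = frac_x[tested],
                    frac_control = frac_y[tested],
                    stringsAsFactors = FALSE)
  class(out) <- c("deg_table", "data.frame")
  out
}

#' Count significant differentially expressed genes
#'
#' The study's rule: `|log2FC| > lfc_threshold` AND p-value
#' `< p_threshold`, both strict inequalities.
#'
#' @param degs a [per_gene_de()] table.
#' @param lfc_threshold absolute log2 fold-change threshold (default 0.5).
#' @param p_threshold p-value threshold (default 0.05).
#' @param use_adjusted compare `adj_p_value` instead of raw `p_value`.
#' @return integer count.
#' @export
count_significant <- function(degs, lfc_threshold = 0.5, p_threshold = 0.05,
                              use_adjusted = FALSE) {
  if (lfc_threshold <= 0 || p_threshold <= 0)
    stop_validation("thresholds must be > 0")
  if (!nrow(degs)) return(0L)
  p <- if (use_adjusted) degs$adj_p_value else degs$p_value
  sum(abs(degs$log2_fold_change) > lfc_threshold & p < p_threshold)
}

#' DEG counts per cluster
#'
#' Applies [per_gene_de()] and [count_significant()] within every cluster
#' (case vs control). Clusters with fewer than `min_cells` cells in either
#' condition are flagged as not tested rather than dropped.
#'
#' @param nm a [log_normalize()] result.
#' @param ann annotation data.frame (barcode, condition, cluster).
#' @param lfc_threshold,p_threshold,use_adjusted see [count_significant()].
#' @param min_frac_expressing see [per_gene_de()].
#' @param min_cells minimum cells per condition within a cluster.
#' @return data.frame, one row per cluster: `cluster`, `n_case`,
#'   `n_control`, `tested`, `n_deg`.
#' @export
deg_counts_per_cluster <- function(nm, ann, lfc_threshold = 0.5,
                                   p_threshold = 0.05, use_adjusted = FALSE,
                                   min_frac_expressing = 0.1, min_cells = 3L) {
  validate_cell_annotation(ann)
  ann <- ann[ann$barcode %in% nm$barcodes, , drop = FALSE]
  clusters <- sort(unique(ann$cluster))
  rows <- lapply(clusters, function(ct) {
    case <- ann$barcode[ann$cluster == ct & ann$condition == "case"]
    ctrl <- ann$barcode[ann$cluster == ct & ann$condition == "control"]
    if (length(case) < min_cells || length(ctrl) < min_cells) {
      return(data.frame(cluster = ct, n_case = length(case),
                        n_control = length(ctrl), tested = FALSE,
                        n_deg = NA_integer_, stringsAsFactors = FALSE))
    }
    degs <- per_gene_de(nm, case, ctrl, min_frac_expressing)
    data.frame(cluster = ct, n_case = length(case), n_control = length(ctrl),
               tested = TRUE,
               n_deg = count_significant(degs, lfc_threshold, p_threshold,
                                         use_adjusted),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Gene-set mean activity and log fold changes
#'
#' The activity of a gene set in a group of cells is the mean of the
#' log-normalized values over (set genes present in the matrix) x (group
#' cells). Per cluster the function reports the activity, and a log2 fold
#' change (pseudocount `pseudo`) either between conditions within each
#' cluster (`contrast = "condition"`) or between every ordered cluster
#' pair (`contrast = "clusters"`). Sets sharing no gene with the matrix
#' are reported in `skipped`.
#'
#' @param nm a [log_normalize()] result.
#' @param ann annotation data.frame.
#' @param sets named list from [read_gmt()] (symbols).
#' @param pseudo pseudocount for the fold change (default 0.01).
#' @param contrast `"condition"` (case vs control within cluster) or
#'   `"clusters"` (ordered cluster pairs, condition-pooled).
#' @return list (class `geneset_activity`): `activity` (cluster, set,
#'   mean_activity, n_genes), `contrast` (long-format log2 fold changes),
#'   `skipped` (set names).
#' @export
geneset_activity <- function(nm, ann, sets, pseudo = 0.01,
                             contrast = c("condition", "clusters")) {
  contrast <- match.arg(contrast)
  validate_cell_annotation(ann)
  if (!length(sets)) stop_validation("empty gene-set collection")
  ann <- ann[ann$barcode %in% nm$barcodes, , drop = FALSE]
  clusters <- sort(unique(ann$cluster))
  gene_idx <- lapply(sets, function(g) which(nm$gene_symbols %in% g))
  skipped <- names(sets)[vapply(gene_idx, length, integer(1)) == 0]
  kept <- setdiff(names(sets), skipped)

  grp_mean <- function(gidx, barcodes) {
    cidx <- match(barcodes, nm$barcodes)
    sum(nm$values[gidx, cidx, drop = FALSE]) / (length(gidx) * length(cidx))
  }

  activity <- do.call(rbind, lapply(clusters, function(ct) {
    bcs <- ann$barcode[ann$cluster == ct]
    do.call(rbind, lapply(kept, function(s)
      data.frame(cluster = ct, set = s,
                 mean_activity = grp_mean(gene_idx[[s]], bcs),
                 n_genes = length(gene_idx[[s]]), stringsAsFactors = FALSE)))
  }))

  lfc <- function(a, b) log2((a + pseudo) / (b + pseudo))
  ct_rows <- if (contrast == "condition") {
    do.call(rbind, lapply(clusters, function(ct) {
      case <- ann$barcode[ann$cluster == ct & ann$condition == "case"]
      ctrl <- ann$barcode[ann$cluster == ct & ann$condition == "control"]
      if (!length(case) || !length(ctrl)) return(NULL)
      do.call(rbind, lapply(kept, function(s)
        data.frame(cluster = ct, set = s,
                   log2_fold_change = lfc(grp_mean(gene_idx[[s]], case),
                                          grp_mean(gene_idx[[s]], ctrl)),
                   stringsAsFactors = FALSE)))
    }))
  } else {
    pairs <- expand.grid(a = clusters, b = clusters,
                         stringsAsFactors = FALSE)
    pairs <- pairs[pairs$a != pairs$b, , drop = FALSE]
    do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
      ba <- ann$barcode[ann$cluster == pairs$a[i]]
      bb <- ann$barcode[ann$cluster == pairs$b[i]]
      do.call(rbind, lapply(kept, function(s)
        data.frame(cluster_a = pairs$a[i], cluster_b = pairs$b[i], set = s,
                   log2_fold_change = lfc(grp_mean(gene_idx[[s]], ba),
                                          grp_mean(gene_idx[[s]], bb)),
                   stringsAsFactors = FALSE)))
    }))
  }
  structure(list(activity = activity, contrast = ct_rows, skipped = skipped,
                 pseudo = pseudo, mode = contrast),
            class = "geneset_activity")
}

#' Cell-proportion shifts between conditions
#'
#' Within each condition, cluster proportions are normalized to sum to 1;
#' each cluster's membership rate is compared between conditions with a
#' two-sided two-proportion z-test (pooled variance).
#'
#' @param ann annotation data.frame with both conditions present.
#' @return data.frame, one row per cluster: counts and proportions per
#'   condition, `z`, `p_value`, `direction` (relative to case).
#' @export
proportion_shift <- function(ann) {
  validate_cell_annotation(ann)
  n_case <- sum(ann$condition == "case")
  n_ctrl <- sum(ann$condition == "control")
  if (n_case == 0 || n_ctrl == 0)
    stop_validation("both conditions must have at least one cell")
  clusters <- sort(unique(ann$cluster))
  rows <- lapply(clusters, function(ct) {
    k1 <- sum(ann$cluster == ct & ann$condition == "case")
    k2 <- sum(ann$cluster == ct & ann$condition == "control")
    p1 <- k1 / n_case; p2 <- k2 / n_ctrl
    ph <- (k1 + k2) / (n_case + n_ctrl)
    se <- sqrt(ph * (1 - ph) * (1 / n_case + 1 / n_ctrl))
    z <- if (se > 0) (p1 - p2) / se else 0
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    data.frame(cluster = ct, n_case = k1, n_control = k2,
               prop_case = p1, prop_control = p2, z = z, p_value = p,
               direction = if (p1 > p2) "expanded_in_case"
                           else if (p1 < p2) "depleted_in_case" else "none",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
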